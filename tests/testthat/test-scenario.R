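test_that("generator equals the forward model at zero noise", {
  spec <- scenario_spec("POPC", 10, noise = 0, lb_hz = 150,
                        isotropic_fraction = 0, seed = 1)
  gen <- generate_scenario(spec)
  prof <- scenario_truth_profile("POPC", 10)
  direct <- compose_spectrum(chain_to_quad_components(prof),
                             gen$spectra$h2_10$axis, lb_hz = 150)
  expect_equal(gen$spectra$h2_10$intensity, direct$intensity,
               tolerance = 1e-12)
})

test_that("identical spec and seed give byte-identical output files", {
  withr::with_tempdir({
    spec <- scenario_spec("NER", c(0, 10), seed = 42)
    generate_scenario(spec, out_dir = "a")
    generate_scenario(spec, out_dir = "b")
    for (f in list.files("a")) {
      expect_identical(readLines(file.path("a", f)),
                       readLines(file.path("b", f)), label = f)
    }
    # a different seed changes the data
    generate_scenario(scenario_spec("NER", c(0, 10), seed = 43), out_dir = "c")
    expect_false(identical(readLines("a/h2_10.txt"), readLines("c/h2_10.txt")))
  })
})

test_that("phase coexistence mixes a 120 kHz gel envelope with the fluid spectrum", {
  ax <- seq(-150, 150, length.out = 2048)
  prof <- scenario_truth_profile("POPC", -5)
  fluid <- chain_to_quad_components(prof)
  g0 <- phase_coexistence_spectrum(fluid, gel_fraction = 0, axis = ax)
  pure_fluid <- compose_spectrum(fluid, ax, lb_hz = 200)
  expect_equal(g0$intensity, pure_fluid$intensity, tolerance = 1e-12)
  g1 <- phase_coexistence_spectrum(fluid, gel_fraction = 1, axis = ax)
  # gel envelope: 90-degree edge maxima separated by ~120 kHz
  smooth_max <- function(s, side) {
    i <- if (side > 0) s$axis > 20 else s$axis < -20
    s$axis[i][which.max(s$intensity[i])]
  }
  expect_equal(smooth_max(g1, 1) - smooth_max(g1, -1), 120, tolerance = 4)
  # convex combination preserves the integral
  g5 <- phase_coexistence_spectrum(fluid, gel_fraction = 0.5, axis = ax)
  expect_equal(spectrum_integral(g5), sum(fluid$weight), tolerance = 0.01)
  expect_error(phase_coexistence_spectrum(fluid, gel_fraction = 1.2, axis = ax),
               "0, 1")
})

test_that("at equal phase fractions the two central doublets have near-equal areas", {
  ax <- seq(-150, 150, length.out = 2048)
  prof <- scenario_truth_profile("POPC", -5)
  fluid <- chain_to_quad_components(prof)
  g5 <- phase_coexistence_spectrum(fluid, gel_fraction = 0.5, axis = ax,
                                   lb_hz = 100)
  # the two coexisting methyl doublets (fluid at the k16 truth splitting, gel
  # at ~11.8 kHz) overlap heavily in the powder spectrum; integrate each via
  # the de-Paked splitting distribution
  dp <- depake(g5)
  s_grid <- dp$meta$s_grid_khz
  amp <- dp$meta$amplitude
  fl_k16 <- prof$splitting_khz[prof$position == "16"]
  a_fluid <- sum(amp[abs(s_grid - fl_k16) < 2])
  a_gel <- sum(amp[abs(s_grid - 11.8) < 2])
  expect_equal(a_fluid / a_gel, 1, tolerance = 0.10)
})

test_that("scenario plateau truths preserve the composition ordering at every temperature", {
  temps <- c(0, 10, 20)
  plateau <- function(comp) vapply(temps, function(t)
    attr(scenario_truth_profile(comp, t), "two_s_cd"), 0)
  popc <- plateau("POPC"); chol <- plateau("POPC/Chol")
  cholpi <- plateau("POPC/Chol/PI"); ner <- plateau("NER")
  mv1 <- plateau("MV1"); mv2 <- plateau("MV2"); pi_ <- plateau("POPC/PI")
  expect_true(all(chol > ner))          # phosphoinositides disorder lo phase
  expect_true(all(ner > cholpi))        # PIP2 re-orders relative to +PI
  expect_true(all(cholpi > popc))       # cholesterol family stays ordered
  expect_true(all(popc > mv1))          # MV1-like unusually fluid
  expect_true(all(abs(mv1 - pi_) < 0.02))  # MV1 ~ POPC/PI
  expect_true(all(mv2 > mv1 & mv2 < ner))  # MV2 intermediate
})

test_that("the recovery pipeline preserves the cholesterol ordering effect", {
  recover <- function(comp) {
    gen <- generate_scenario(scenario_spec(comp, 10, seed = 5, noise = 0.005))
    dp <- depake(gen$spectra$h2_10)
    pr <- assemble_order_profile(measure_splittings(dp), 10, comp)
    pr$plateau$two_s_cd
  }
  expect_gt(recover("POPC/Chol"), recover("POPC"))
})

test_that("scenario validation", {
  expect_error(scenario_spec("DOPC", 10, seed = 1), "unknown composition")
  expect_error(scenario_spec("POPC", 10), "seed")
  expect_error(scenario_spec("POPC", c(0, 10), gel_fraction = 0.5, seed = 1),
               "one value per temperature")
})
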