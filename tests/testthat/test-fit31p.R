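test_that("noise-free single-component fit recovers parameters to grid resolution", {
  ax <- ax_31p()
  truth <- csa_component(-47, -1, 120, 1, "PC")
  sp <- compose_spectrum(truth, ax, lb_hz = 80)
  init <- csa_component(-42, -0.5, 200, 1, "PC")
  f <- fit_p31(sp, fit_config(init, lb_hz = 80))
  expect_true(f$converged)
  expect_lt(abs(f$components$delta_sigma_ppm + 47), 0.2)
  expect_lt(abs(f$components$delta_iso_ppm + 1), 0.1)
  expect_lt(abs(f$components$linewidth_hz - 120), 10)
  # refitting the model's own output is a fixed point
  f2 <- fit_p31(predict(f), fit_config(f$components, lb_hz = 80))
  expect_lt(abs(f2$components$delta_sigma_ppm - f$components$delta_sigma_ppm),
            0.05)
})

test_that("initial guesses from the de-Paked trace localize the anisotropies", {
  ax <- ax_31p()
  sp <- compose_spectrum(csa_component(-47, -1, 120), ax, lb_hz = 80)
  ig <- initial_guesses_from_depaked(sp)
  expect_lt(abs(ig$delta_sigma_ppm[1] + 47), 3)
  # a singlet at zero yields one near-zero-anisotropy candidate
  s0 <- compose_spectrum(csa_component(0, 0, 200), ax, lb_hz = 80)
  ig0 <- initial_guesses_from_depaked(s0)
  expect_lt(abs(ig0$delta_sigma_ppm[1]), 3)
  # a POPC/PIP2 mixture shows at least 3 distinguishable anisotropies
  mix <- compose_spectrum(composition_to_phosphorus_components("POPC/PIP2"),
                          ax, lb_hz = 80)
  igm <- initial_guesses_from_depaked(mix)
  expect_gte(nrow(igm), 3L)
})

test_that("multi-component fit with ties and stoichiometric weights recovers within the accuracy bands", {
  ax <- ax_31p()
  true <- composition_to_phosphorus_components("POPC/PIP2")
  sp <- compose_spectrum(true, ax, lb_hz = 80)
  set.seed(101)
  sp$intensity <- sp$intensity + rnorm(length(ax), 0, 0.01 * max(sp$intensity))
  init <- true
  init$delta_sigma_ppm <- init$delta_sigma_ppm * 1.12
  init$linewidth_hz <- 180
  f <- fit_p31(sp, fit_config(init, ties = glycerol_ties(init), lb_hz = 80))
  expect_true(f$converged)
  for (i in seq_len(nrow(true))) {
    rel <- abs(f$components$delta_sigma_ppm[i] - true$delta_sigma_ppm[i]) /
      abs(true$delta_sigma_ppm[i])
    expect_lt(rel, if (abs(true$delta_sigma_ppm[i]) >= 30) 0.10 else 0.50)
  }
})

test_that("frozen stoichiometric weights beat uniform weights on stoichiometric data", {
  ax <- ax_31p()
  true <- composition_to_phosphorus_components("POPC/PI")
  sp <- compose_spectrum(true, ax, lb_hz = 80)
  init <- true
  init$delta_sigma_ppm <- init$delta_sigma_ppm * 1.1
  f_stoich <- fit_p31(sp, fit_config(init, lb_hz = 80))
  init_u <- init
  init_u$weight <- rep(mean(true$weight), nrow(true))
  cfg_u <- fit_config(init_u, lb_hz = 80,
                      free = list(delta_sigma = FALSE, delta_iso = FALSE,
                                  linewidth = FALSE))
  f_unif <- fit_p31(sp, cfg_u)
  expect_lte(f_stoich$deviance, f_unif$deviance)
})

test_that("free deformation parameter is recovered from a deformed spectrum", {
  ax <- ax_31p()
  truth <- csa_component(-47, -1, 120, 1, "PC")
  sp <- compose_spectrum(truth, ax, orientation_dist(0.3), lb_hz = 80)
  init <- csa_component(-44, -0.7, 150, 1, "PC")
  f <- fit_p31(sp, fit_config(init, epsilon = "free", lb_hz = 80))
  expect_lt(abs(f$epsilon - 0.3), 0.1)
  # deformation leaves a parallel-edge intensity deficit in the fit too
  par_region <- ax > -33 & ax < -25
  sph <- compose_spectrum(f$components, ax, orientation_dist(0), lb_hz = 80)
  expect_lt(sum(predict(f)$intensity[par_region]),
            sum(sph$intensity[par_region]))
})

test_that("fit object implements the standard modelling methods", {
  ax <- ax_31p(512)
  sp <- compose_spectrum(csa_component(-47, -1, 150), ax, lb_hz = 100)
  f <- fit_p31(sp, fit_config(csa_component(-45, -1, 150), lb_hz = 100,
                              n_angles = 1024L))
  expect_s3_class(f, "p31_fit")
  expect_named(coef(f), c("delta_sigma.", "delta_iso.", "linewidth.", "scale"))
  expect_equal(length(residuals(f)), length(ax))
  expect_equal(fitted(f) + residuals(f), sp$intensity)
  expect_s3_class(predict(f), "nmr_spectrum")
  expect_output(print(f), "component")
  expect_output(print(summary(f)), "relative residual")
  reps <- simulate(f, nsim = 3, seed = 5)
  expect_length(reps, 3L)
  reps2 <- simulate(f, nsim = 3, seed = 5)
  expect_identical(reps[[1]]$intensity, reps2[[1]]$intensity)
  expect_gte(deviance(f), 0)
})

test_that("bootstrap intervals are deterministic, contain the estimate, and shrink with noise", {
  ax <- ax_31p(512)
  model <- compose_spectrum(csa_component(-47, -1, 150), ax, lb_hz = 100)
  set.seed(77)
  noisy <- model
  noisy$intensity <- model$intensity + rnorm(length(ax), 0,
                                             0.01 * max(model$intensity))
  f <- fit_p31(noisy, fit_config(csa_component(-45, -1, 150), lb_hz = 100,
                                 n_angles = 1024L))
  b1 <- bootstrap_uncertainty(noisy, f, n_replicates = 12, seed = 9)
  b2 <- bootstrap_uncertainty(noisy, f, n_replicates = 12, seed = 9)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= b1$estimate & b1$estimate <= b1$upper))
  ds_row <- b1[grepl("delta_sigma", b1$parameter), ]
  # interval half-width of the order of the tabulated +/- 1.5 ppm
  expect_lt((ds_row$upper - ds_row$lower) / 2, 3)
  # zero-noise fit: interval width collapses
  f0 <- fit_p31(model, fit_config(csa_component(-45, -1, 150), lb_hz = 100,
                                  n_angles = 1024L))
  b0 <- bootstrap_uncertainty(model, f0, n_replicates = 12, seed = 9)
  ds0 <- b0[grepl("delta_sigma", b0$parameter), ]
  expect_lt(ds0$upper - ds0$lower, 0.1)
  expect_error(bootstrap_uncertainty(noisy, f, n_replicates = 5), "at least 10")
})

test_that("fit configuration validates ties, bounds and nucleus", {
  comp <- csa_component(-47, -1, 120, 1, "PC")
  expect_error(fit_config(comp, ties = list(c("PC", "nope"))), "nope")
  expect_error(fit_config(comp, bounds = list(delta_sigma = c(-40, 0))),
               "outside bounds")
  sp2h <- doublet_spectrum(29.4, ax_2h(512))
  expect_error(fit_p31(sp2h, fit_config(comp)), "31P")
})
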