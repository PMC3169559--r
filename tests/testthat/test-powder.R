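test_that("orientation weights are normalized, sin-theta for a sphere, and depleted at 0 by deformation", {
  d0 <- orientation_dist(0, 1000)
  w <- orientation_weights(d0)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  expect_equal(which.max(w$weight), 1000L)          # max at 90 degrees
  # proportional to sin(theta)
  expect_equal(w$weight / sin(w$theta_deg * pi / 180),
               rep(w$weight[1000] / sin(w$theta_deg[1000] * pi / 180), 1000),
               tolerance = 1e-9)
  d3 <- orientation_dist(0.3, 1000)
  expect_lt(d3$weight[1] / d0$weight[1], 1)          # theta = 0 bin depleted
  expect_equal(sum(d3$weight), 1, tolerance = 1e-12)
  expect_error(orientation_dist(-0.1), "epsilon")
  expect_error(orientation_dist(0, 32), "n_angles")
})

test_that("quadrupolar subspectrum has the Pake geometry and conserves weight", {
  ax <- ax_2h(4096)
  comp <- quad_component(29.4, weight = 2)
  s <- quad_powder_subspectrum(comp, orientation_dist(), ax, broaden = FALSE)
  step <- ax[2] - ax[1]
  # symmetric about zero
  expect_lt(l1_dist(s$intensity, rev(s$intensity)), 1e-10)
  # 90-degree edge maxima separated by splitting_90 (within a grid step)
  hi <- ax[which.max(s$intensity * (ax > 0))]
  lo <- ax[which.max(s$intensity * (ax < 0))]
  expect_equal(hi - lo, 29.4, tolerance = 2 * step)
  # outer shoulders at +/- splitting_90: intensity dies just beyond
  beyond <- abs(ax) > 29.4 + 2 * step
  expect_lt(max(s$intensity[beyond]), 1e-3 * max(s$intensity))
  expect_gt(s$intensity[which.min(abs(ax - 29.3))], 0)
  # integral = weight
  expect_equal(spectrum_integral(s), 2, tolerance = 2e-3)
  # zero splitting collapses to a line at the carrier
  s0 <- quad_powder_subspectrum(quad_component(0), orientation_dist(), ax,
                                broaden = FALSE)
  expect_lt(sum(abs(ax[s0$intensity > 0])), 2 * step)
  # narrow grids are refused rather than silently truncated
  expect_error(quad_powder_subspectrum(quad_component(80), orientation_dist(),
                                       ax_2h(512, span = 30)), "too narrow")
  expect_error(quad_component(130), "rigid limit")
})

test_that("CSA subspectrum has edges at delta_iso - ds/3 and + 2ds/3 and first moment delta_iso", {
  ax <- ax_31p(2048)
  comp <- csa_component(-47, -1, weight = 1, label = "PC")
  s <- csa_powder_subspectrum(comp, orientation_dist(), ax, broaden = FALSE)
  step <- ax[2] - ax[1]
  # perpendicular (intense) edge at -1 + 47/3 = 14.667 ppm
  expect_equal(ax[which.max(s$intensity)], 14.667, tolerance = 2 * step)
  # parallel (weak) edge at -1 - 2*47/3 = -32.333 ppm: support ends there
  expect_lt(max(s$intensity[ax < -32.333 - 2 * step]), 1e-3 * max(s$intensity))
  expect_gt(s$intensity[which.min(abs(ax + 32.2))], 0)
  # breadth |delta_sigma|
  supp <- range(ax[s$intensity > 1e-6 * max(s$intensity)])
  expect_equal(diff(supp), 47, tolerance = 4 * step)
  expect_equal(first_moment(s), -1, tolerance = 1e-2)
  expect_equal(spectrum_integral(s), 1, tolerance = 2e-3)
  # zero anisotropy collapses to a singlet at delta_iso
  s0 <- csa_powder_subspectrum(csa_component(0, -1), orientation_dist(), ax,
                               broaden = FALSE)
  expect_lt(max(abs(ax[s0$intensity > 0] + 1)), 2 * step)
})

test_that("motional tilt scales the anisotropy by P2 and nulls at the magic angle", {
  expect_equal(effective_delta_sigma(-60, 0), -60)
  expect_equal(effective_delta_sigma(-60, 90), 30)
  expect_lt(abs(effective_delta_sigma(-60, 54.7356)), 1e-6 * 60)
  expect_lt(abs(effective_delta_sigma(123.4, 54.7356)), 1e-6 * 123.4)
  expect_error(effective_delta_sigma(-60, 91), "90")
  expect_error(effective_delta_sigma(-60, -1), "0")
})

test_that("Lorentzian broadening is unit-area convolution and conserves the integral", {
  ax <- ax_2h(2048)
  s <- quad_powder_subspectrum(quad_component(29.4), orientation_dist(), ax,
                               broaden = FALSE)
  expect_identical(apply_lorentzian_broadening(s, 0), s)    # lb = 0 identity
  b <- apply_lorentzian_broadening(s, 200)
  expect_equal(spectrum_integral(b) / spectrum_integral(s), 1,
               tolerance = 1e-3)
  # a delta function broadens to a Lorentzian of the requested FWHM
  d <- nmr_spectrum(ax, as.numeric(seq_along(ax) == 1024), "2H", 76)
  bl <- apply_lorentzian_broadening(d, 300)
  half <- max(bl$intensity) / 2
  above <- range(ax[bl$intensity >= half])
  expect_equal(diff(above), 0.300, tolerance = 2 * (ax[2] - ax[1]))
  expect_error(apply_lorentzian_broadening(
    nmr_spectrum(c(1:15, 17)^1.01, rep(1, 16), "2H", 76), 100), "uniform")
})

test_that("composition expands to the correct phosphorus component count", {
  expect_equal(nrow(composition_to_phosphorus_components("NER")), 7L)
  expect_equal(nrow(composition_to_phosphorus_components("MV1")), 7L)
  pip2 <- composition_to_phosphorus_components("POPC/PIP2")
  expect_equal(sum(grepl("^PIP2", pip2$label)), 3L)
  popc <- composition_to_phosphorus_components("POPC")
  expect_equal(nrow(popc), 1L)
  expect_equal(nrow(composition_to_phosphorus_components("MV2")), 4L)
  # cholesterol contributes no phosphorus: weights track mol% only of P lipids
  ner <- composition_to_phosphorus_components("NER")
  expect_false("Chol" %in% ner$label)
  expect_equal(ner$weight[ner$label == "PC"], 28)
  # missing parameter row errors with the label
  params <- p31_reference_parameters("POPC")
  expect_error(composition_to_phosphorus_components(
    membrane_composition("POPC/PI"), params), "PI_g")
})

test_that("perdeuterated palmitoyl chain expands to 15 groups of total weight 31", {
  prof <- data.frame(position = c("2-10", as.character(11:16)),
                     splitting_khz = c(29.4, 28.2, 25.9, 22.3, 18.2, 13.5, 3.7))
  merged <- chain_to_quad_components(prof)
  expect_equal(sum(merged$weight), 31)
  expect_equal(merged$weight[merged$label == "k2-10"], 18)  # 9 CD2 x 2
  expect_equal(merged$weight[merged$label == "k16"], 3)     # CD3
  full <- chain_to_quad_components(
    data.frame(position = as.character(2:16),
               splitting_khz = c(rep(29.4, 9), 28.2, 25.9, 22.3, 18.2, 13.5, 3.7)))
  expect_equal(nrow(full), 15L)
  expect_equal(sum(full$weight), 31)
  single <- chain_to_quad_components(
    data.frame(position = "16", splitting_khz = 3.7))
  expect_equal(nrow(single), 1L)
  expect_error(chain_to_quad_components(prof, chain = "DPPC-d62"),
               "unknown chain")
  expect_error(chain_to_quad_components(
    data.frame(position = c("2-10", "9"), splitting_khz = c(29, 28))),
    "twice")
})

test_that("compose is linear, conserves weight, and refuses mixed nuclei", {
  ax <- ax_2h()
  one <- compose_spectrum(quad_component(20, 2, 150), ax, lb_hz = 100)
  sub <- apply_lorentzian_broadening(
    quad_powder_subspectrum(quad_component(20, 2, 150), orientation_dist(), ax),
    100)
  expect_equal(one$intensity, sub$intensity, tolerance = 1e-12)
  # two half-weight components equal one double-weight component
  two <- compose_spectrum(rbind(quad_component(20, 1, 150),
                                quad_component(20, 1, 150)), ax, lb_hz = 100)
  expect_equal(two$intensity, one$intensity, tolerance = 1e-9)
  expect_equal(spectrum_integral(two), 2, tolerance = 2e-3)
  mixed <- cbind(quad_component(20), delta_sigma_ppm = -47)
  expect_error(compose_spectrum(mixed, ax), "mixes")
})

test_that("pattern breadth grows monotonically with splitting and |delta_sigma|", {
  ax <- ax_2h(2048, span = 120)
  breadth_at <- function(int, axis)
    diff(range(axis[int > 1e-4 * max(int)]))
  b_quad <- vapply(c(10, 20, 40, 60, 90), function(s)
    breadth_at(quad_powder_subspectrum(quad_component(s), orientation_dist(1e-9, 1024),
                                       ax, broaden = FALSE)$intensity, ax), 0)
  expect_true(all(diff(b_quad) > 0))
  axp <- seq(-120, 90, length.out = 2048)
  b_csa <- vapply(c(-10, -25, -47, -80), function(ds)
    breadth_at(csa_powder_subspectrum(csa_component(ds, -1), orientation_dist(0, 1024),
                                      axp, broaden = FALSE)$intensity, axp), 0)
  expect_true(all(diff(b_csa) > 0))
})

test_that("prolate deformation reduces the high-frequency (0-degree) edge intensity", {
  ax <- ax_31p(2048)
  comp <- csa_component(-47, -1, 200)
  sph <- csa_powder_subspectrum(comp, orientation_dist(0), ax)
  def <- csa_powder_subspectrum(comp, orientation_dist(0.4), ax)
  # the parallel edge of a negative-ds pattern is the low-frequency shoulder
  par_region <- ax < -25 & ax > -33
  expect_lt(sum(def$intensity[par_region]), sum(sph$intensity[par_region]))
  # total integral unchanged
  expect_equal(spectrum_integral(def), spectrum_integral(sph),
               tolerance = 1e-3)
})
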