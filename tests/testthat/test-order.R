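test_that("splittings are measured as symmetric pair separations, descending", {
  ax <- ax_2h()
  mk_oriented <- function(splits, heights = rep(1, length(splits))) {
    int <- numeric(length(ax))
    for (i in seq_along(splits)) {
      j <- which.min(abs(ax - splits[i] / 2))
      k <- which.min(abs(ax + splits[i] / 2))
      int[j] <- int[j] + heights[i]
      int[k] <- int[k] + heights[i]
    }
    s <- nmr_spectrum(ax, int, "2H", 76)
    apply_lorentzian_broadening(s, 150)
  }
  one <- measure_splittings(mk_oriented(29.4))
  expect_equal(length(one), 1L)
  expect_equal(one[1], 29.4, tolerance = 0.01)
  three <- measure_splittings(mk_oriented(c(29.4, 18.0, 3.6)), 3)
  expect_equal(attr(three, "resolved"), 3L)
  expect_equal(as.numeric(three), c(29.4, 18.0, 3.6), tolerance = 0.02)
  # singlet only: no pairs, but the central line is reported
  singlet <- nmr_spectrum(ax, exp(-(ax / 0.4)^2), "2H", 76)
  s0 <- measure_splittings(singlet)
  expect_equal(length(s0), 0L)
  expect_equal(attr(s0, "resolved"), 0L)
  expect_gt(attr(s0, "central"), 0)
  flat <- nmr_spectrum(ax, rep(0, length(ax)) + 1e-12 * seq_along(ax), "2H", 76)
  expect_error(measure_splittings(flat), "no peaks")
})

test_that("order-parameter mapping reproduces the printed anchors", {
  # 2|S_CD| anchors of the characterized systems at 10 degC
  expect_equal(splitting_to_order(29.4)$two_s_cd, 0.47, tolerance = 5e-3)
  expect_equal(splitting_to_order(50.7)$two_s_cd, 0.81, tolerance = 5e-3)
  expect_equal(splitting_to_order(43.2)$two_s_cd, 0.69, tolerance = 5e-3)
  expect_equal(splitting_to_order(45.7)$two_s_cd, 0.73, tolerance = 5e-3)
  expect_equal(splitting_to_order(0)$two_s_cd, 0)
  # rigid bound maps exactly to 2|S_CD| = 1
  expect_equal(splitting_to_order(62.625)$two_s_cd, 1.000)
  expect_error(splitting_to_order(130), "rigid bound")
  # methyl correction multiplies by 3 (fast CD3 rotation, |P2| = 1/3)
  expect_equal(splitting_to_order(3.7, methyl = TRUE)$s_cd,
               3 * splitting_to_order(3.7)$s_cd)
})

test_that("splitting-to-order mapping is linear and inverts exactly", {
  s <- c(0, 5.3, 29.4, 50.7, 62.625)
  back <- order_to_splitting(splitting_to_order(s)$s_cd)
  expect_equal(back, s, tolerance = 1e-12)
  # linearity
  expect_equal(splitting_to_order(2 * 10)$s_cd, 2 * splitting_to_order(10)$s_cd)
})

test_that("profile assembly assigns plateau, mid-chain and methyl correctly", {
  p <- assemble_order_profile(c(29.4, 18.0, 3.6), 10, "POPC")
  expect_s3_class(p, "order_profile")
  expect_equal(p$plateau$splitting_khz, 29.4)
  expect_equal(p$entries$position_k, c("2-10", "11", "16"))
  expect_equal(p$methyl$splitting_khz, 3.6)
  expect_true(p$partial)
  # splittings within 8% of the largest merge into the plateau
  merged <- assemble_order_profile(c(29.4, 28.2, 18.0, 3.6), 10)
  expect_equal(merged$plateau$splitting_khz, mean(c(29.4, 28.2)))
  expect_false("11" %in% merged$entries$position_k[
    merged$entries$splitting_khz > 20])
  one <- assemble_order_profile(29.4, 10)
  expect_equal(nrow(one$entries), 1L)
  expect_null(one$methyl)
  expect_error(assemble_order_profile(numeric(0)), "at least one")
})

test_that("thermal table propagates the +/-1 kHz splitting accuracy", {
  p1 <- assemble_order_profile(c(29.4, 3.6), 10, "POPC")
  p2 <- assemble_order_profile(c(27.1, 3.2), 20, "POPC")
  tab <- thermal_table(list(p1, p2))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$two_s_cd_err, rep(2 * (4 / 3) / 167, 2), tolerance = 1e-9)
  expect_lt(max(abs(tab$two_s_cd_err - 0.016)), 5e-4)
  expect_error(thermal_table(list(p1, p1)), "duplicate")
  # a monotone input series stays monotone in the table
  series <- lapply(1:4, function(i)
    assemble_order_profile(30 - 2 * i, temperature_c = 10 * i, "POPC"))
  tt <- thermal_table(series)
  expect_true(all(diff(tt$two_s_cd) < 0))
})
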