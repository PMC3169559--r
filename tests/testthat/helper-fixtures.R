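# shared grids
ax_2h <- function(n = 2048L, span = 75) seq(-span, span, length.out = n)
ax_31p <- function(n = 1024L) seq(-70, 40, length.out = n)

# normalized L1 distance between two non-negative traces on one grid
l1_dist <- function(a, b) sum(abs(a - b)) / max(sum(abs(a)), .Machine$double.eps)

# Independent brute-force oracle: histogram of orientations sampled from the
# sphere (or the deformed weighting, by rejection), mapped through the
# per-orientation resonance positions and binned on the axis grid. Shares no
# code with the deterministic powder engine.
oracle_hist <- function(positions_of_theta, axis, n_samples = 4e6L,
                        epsilon = 0, seed = 1) {
  set.seed(seed)
  u <- runif(n_samples)                # cos(theta) uniform on [0, 1] = sphere
  if (epsilon > 0) {
    dens <- pmax(0, 1 + epsilon * (1 - 3 * u^2) / 2)
    keep <- runif(n_samples) * max(dens) < dens
    u <- u[keep]
  }
  theta <- acos(u) * 180 / pi
  pos <- positions_of_theta(theta)
  step <- axis[2] - axis[1]
  # linear (triangular-kernel) binning, written independently of the package
  n <- length(axis)
  z <- (pos - axis[1]) / step
  z <- z[z >= 0 & z <= n - 1]
  lo <- floor(z)
  fr <- z - lo
  counts <- numeric(n)
  t_lo <- tapply(1 - fr, factor(lo + 1L, levels = seq_len(n)), sum)
  t_hi <- tapply(fr, factor(lo + 2L, levels = seq_len(n)), sum)
  counts <- ifelse(is.na(t_lo), 0, t_lo) + ifelse(is.na(t_hi), 0, t_hi)
  as.numeric(counts) / sum(counts) / step
}

oracle_quad <- function(s90, axis, n_samples = 4e6L, seed = 1) {
  oracle_hist(function(theta) {
    nu <- s90 * (3 * cos(theta * pi / 180)^2 - 1) / 2
    sgn <- rep(c(1, -1), length.out = length(nu))
    nu * sgn
  }, axis, n_samples, seed = seed)
}

oracle_csa <- function(ds, di, axis, n_samples = 4e6L, seed = 1) {
  oracle_hist(function(theta)
    di + ds * (3 * cos(theta * pi / 180)^2 - 1) / 3,
    axis, n_samples, seed = seed)
}

# quick single-doublet powder spectrum
doublet_spectrum <- function(s90, axis = ax_2h(), lw = 200, lb = 100,
                             weight = 1) {
  compose_spectrum(quad_component(s90, weight, lw), axis, lb_hz = lb)
}
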