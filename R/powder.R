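#' Static quadrupolar coupling constant of the C-D bond, kHz
#'
#' Used throughout to convert quadrupolar splittings into C-D bond order
#' parameters; the rigid-limit 90-degree-edge splitting is (3/4)*A_Q.
#' @export
AQ_KHZ <- 167

# second Legendre polynomial of cos(theta), theta in degrees
.p2_deg <- function(theta_deg) {
  c2 <- cos(theta_deg * pi / 180)^2
  (3 * c2 - 1) / 2
}

#' Orientation distribution of bilayer normals in a (deformed) vesicle
#'
#' Multilamellar vesicles present all bilayer orientations to the field. For a
#' sphere the weight of the angle theta between bilayer normal and field is
#' proportional to sin(theta). A magnetic-field-induced prolate deformation
#' elongates vesicles along the field and depletes membrane area oriented at
#' theta = 0, which empties the high-frequency (parallel) edge of the powder
#' pattern. The single-parameter family used here is
#' \deqn{w(\theta) \propto \sin\theta \, [1 + \epsilon (1 - 3\cos^2\theta)/2]_+}
#' so that \code{epsilon = 0} is the sphere and increasing \code{epsilon}
#' strictly reduces the relative weight near theta = 0.
#'
#' @param epsilon prolate deformation parameter, >= 0 (0 = sphere).
#' @param n_angles number of equal-width theta bins on [0, 90] degrees, >= 64.
#' @return Object of class \code{orientation_dist}: list with \code{theta_deg}
#'   (bin midpoints), \code{weight} (normalized to sum 1), \code{epsilon},
#'   \code{n_angles}.
#' @export
orientation_dist <- function(epsilon = 0, n_angles = 4096L) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon < 0)
    stop("epsilon must be a single number >= 0")
  n_angles <- as.integer(n_angles)
  if (n_angles < 64L) stop("n_angles must be at least 64")
  edges <- seq(0, 90, length.out = n_angles + 1L)
  theta <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  th <- theta * pi / 180
  w <- sin(th) * pmax(0, 1 + epsilon * (1 - 3 * cos(th)^2) / 2)
  w <- w / sum(w)
  structure(list(theta_deg = theta, weight = w,
                 epsilon = epsilon, n_angles = n_angles),
            class = "orientation_dist")
}

#' Orientation weights as a table
#'
#' @param dist an \code{orientation_dist}.
#' @return data.frame with columns \code{theta_deg}, \code{weight}
#'   (weights sum to 1).
#' @export
orientation_weights <- function(dist) {
  stopifnot(inherits(dist, "orientation_dist"))
  data.frame(theta_deg = dist$theta_deg, weight = dist$weight)
}

#' One deuteron group of a powder pattern
#'
#' @param splitting_90_khz quadrupolar splitting between the 90-degree edges,
#'   kHz, in [0, (3/4)*A_Q].
#' @param weight relative deuteron abundance (deuteron count x mole fraction), > 0.
#' @param linewidth_hz intrinsic Lorentzian FWHM, Hz.
#' @param label chain-position label (e.g. "k2-10").
#' @return One-row data.frame usable with [compose_spectrum()];
#'   rows may be combined with \code{rbind}.
#' @export
quad_component <- function(splitting_90_khz, weight = 1, linewidth_hz = 0,
                           label = "") {
  if (!is.finite(splitting_90_khz) || splitting_90_khz < 0)
    stop("splitting_90_khz must be finite and >= 0")
  if (splitting_90_khz > 0.75 * AQ_KHZ)
    stop("splitting_90_khz exceeds the rigid limit (3/4)*A_Q = ",
         0.75 * AQ_KHZ, " kHz")
  if (!is.finite(weight) || weight <= 0) stop("weight must be > 0")
  if (!is.finite(linewidth_hz) || linewidth_hz < 0)
    stop("linewidth_hz must be >= 0")
  data.frame(label = as.character(label),
             splitting_90_khz = splitting_90_khz,
             weight = weight, linewidth_hz = linewidth_hz,
             stringsAsFactors = FALSE)
}

#' One phosphate environment of a 31P powder pattern
#'
#' @param delta_sigma_ppm axially symmetric chemical shielding anisotropy
#'   (sigma_parallel - sigma_perp), ppm, signed, |value| < 300.
#' @param delta_iso_ppm isotropic chemical shift relative to 85\% H3PO4, ppm.
#' @param linewidth_hz intrinsic Lorentzian FWHM, Hz.
#' @param weight relative phosphorus abundance, > 0.
#' @param label phosphate identity (e.g. "PC", "PIP2_5P").
#' @return One-row data.frame usable with [compose_spectrum()].
#' @export
csa_component <- function(delta_sigma_ppm, delta_iso_ppm = 0,
                          linewidth_hz = 0, weight = 1, label = "") {
  if (!is.finite(delta_sigma_ppm) || abs(delta_sigma_ppm) >= 300)
    stop("|delta_sigma_ppm| must be finite and < 300 ppm")
  if (!is.finite(weight) || weight <= 0) stop("weight must be > 0")
  if (!is.finite(linewidth_hz) || linewidth_hz < 0)
    stop("linewidth_hz must be >= 0")
  data.frame(label = as.character(label),
             delta_sigma_ppm = delta_sigma_ppm,
             delta_iso_ppm = delta_iso_ppm,
             linewidth_hz = linewidth_hz, weight = weight,
             stringsAsFactors = FALSE)
}

# which nucleus does a component table describe?
.components_nucleus <- function(components) {
  is_quad <- "splitting_90_khz" %in% names(components)
  is_csa <- "delta_sigma_ppm" %in% names(components)
  if (is_quad && is_csa) stop("component table mixes 2H and 31P columns")
  if (!is_quad && !is_csa)
    stop("component table has neither splitting_90_khz nor delta_sigma_ppm")
  if (is_quad) "2H" else "31P"
}

# accumulate point masses onto a uniform grid by linear splitting between
# the two bracketing grid points; returns intensity per unit axis
.deposit <- function(pos, w, axis) {
  step <- .uniform_step(axis, "powder accumulation")
  n <- length(axis)
  x <- (pos - axis[1]) / step
  i0 <- floor(x)
  f <- x - i0
  idx1 <- as.integer(i0) + 1L
  idx2 <- idx1 + 1L
  out <- numeric(n)
  ok1 <- idx1 >= 1L & idx1 <= n
  if (any(ok1)) {
    r <- rowsum((w * (1 - f))[ok1], idx1[ok1])
    out[as.integer(rownames(r))] <- out[as.integer(rownames(r))] + r
  }
  ok2 <- idx2 >= 1L & idx2 <= n
  if (any(ok2)) {
    r <- rowsum((w * f)[ok2], idx2[ok2])
    out[as.integer(rownames(r))] <- out[as.integer(rownames(r))] + r
  }
  out / step
}

.check_span <- function(axis, lo, hi, what) {
  if (min(axis) > lo || max(axis) < hi)
    stop("axis grid [", signif(min(axis), 6), ", ", signif(max(axis), 6),
         "] too narrow for ", what, " (needs to cover [", signif(lo, 6), ", ",
         signif(hi, 6), "]); widen the grid to avoid silent truncation")
  invisible(TRUE)
}

#' Unbroadened 2H quadrupolar powder sub-spectrum of one deuteron group
#'
#' Each bilayer orientation theta contributes a doublet at
#' +/- splitting_90 * P2(cos theta); integrating over the orientation
#' distribution yields the Pake pattern with its intense 90-degree edges
#' separated by \code{splitting_90_khz} and outer (0-degree) shoulders at
#' twice that. The pattern integral equals the component weight.
#'
#' @param comp one-row data.frame from [quad_component()].
#' @param dist an [orientation_dist()].
#' @param axis uniform kHz grid spanning at least +/- 1.2 x splitting_90.
#' @param sfrq_mhz spectrometer frequency recorded in the result, MHz.
#' @param broaden apply the component's intrinsic Lorentzian linewidth.
#' @param strict error (rather than silently truncate) when the grid does not
#'   span the pattern; the lineshape fit disables this while exploring.
#' @return An \code{nmr_spectrum} (2H, kHz axis).
#' @export
quad_powder_subspectrum <- function(comp, dist = orientation_dist(), axis,
                                    sfrq_mhz = 76, broaden = TRUE,
                                    strict = TRUE) {
  stopifnot(inherits(dist, "orientation_dist"))
  s90 <- comp$splitting_90_khz
  if (s90 > 0.75 * AQ_KHZ)
    stop("splitting_90 exceeds the rigid limit (3/4)*A_Q")
  if (strict && s90 > 0)
    .check_span(axis, -1.2 * s90, 1.2 * s90, "quadrupolar pattern")
  nu <- s90 * .p2_deg(dist$theta_deg)   # + branch; - branch mirrored
  w <- comp$weight * dist$weight / 2
  intens <- .deposit(c(nu, -nu), c(w, w), axis)
  out <- nmr_spectrum(axis, intens, nucleus = "2H", sfrq_mhz = sfrq_mhz,
                      label = comp$label)
  if (broaden && comp$linewidth_hz > 0)
    out <- apply_lorentzian_broadening(out, comp$linewidth_hz)
  out
}

#' Unbroadened 31P CSA powder sub-spectrum of one phosphate environment
#'
#' Axially symmetric pattern: orientation theta resonates at
#' \code{delta_iso + delta_sigma * (3 cos^2(theta) - 1)/3}, giving the intense
#' perpendicular edge at \code{delta_iso - delta_sigma/3}, the weak parallel
#' edge at \code{delta_iso + 2*delta_sigma/3}, total breadth |delta_sigma|, and
#' first moment \code{delta_iso}.
#'
#' @param comp one-row data.frame from [csa_component()].
#' @param dist an [orientation_dist()].
#' @param axis uniform ppm grid spanning the pattern.
#' @param sfrq_mhz 31P spectrometer frequency, MHz (needed to convert Hz line
#'   widths to ppm).
#' @param broaden apply the component's intrinsic Lorentzian linewidth.
#' @param strict error (rather than silently truncate) when the grid does not
#'   span the pattern.
#' @return An \code{nmr_spectrum} (31P, ppm axis).
#' @export
csa_powder_subspectrum <- function(comp, dist = orientation_dist(), axis,
                                   sfrq_mhz = 162, broaden = TRUE,
                                   strict = TRUE) {
  stopifnot(inherits(dist, "orientation_dist"))
  ds <- comp$delta_sigma_ppm
  di <- comp$delta_iso_ppm
  edges <- di + c(-ds / 3, 2 * ds / 3)
  margin <- 0.05 * max(abs(ds), 1)
  if (strict)
    .check_span(axis, min(edges) - margin, max(edges) + margin, "CSA pattern")
  nu <- di + ds * (3 * cos(dist$theta_deg * pi / 180)^2 - 1) / 3
  intens <- .deposit(nu, comp$weight * dist$weight, axis)
  out <- nmr_spectrum(axis, intens, nucleus = "31P", sfrq_mhz = sfrq_mhz,
                      label = comp$label)
  if (broaden && comp$linewidth_hz > 0)
    out <- apply_lorentzian_broadening(out, comp$linewidth_hz)
  out
}

#' Motionally averaged CSA under axial rotation about a tilted axis
#'
#' Fast rotation of a phosphate about an axis tilted by \code{tilt} degrees
#' from the shielding tensor's unique axis scales the observable anisotropy by
#' the second Legendre polynomial: \code{delta_sigma * (3 cos^2(tilt) - 1)/2}.
#' At the magic angle (54.7356 degrees) the effective anisotropy vanishes.
#'
#' @param delta_sigma_static static (unaveraged) anisotropy, ppm.
#' @param tilt_deg tilt of the averaging axis, degrees, in [0, 90].
#' @return Effective anisotropy, ppm.
#' @examples
#' effective_delta_sigma(-60, 0)        # -60
#' effective_delta_sigma(-60, 90)       # +30
#' effective_delta_sigma(-60, 54.7356)  # ~0
#' @export
effective_delta_sigma <- function(delta_sigma_static, tilt_deg) {
  if (!is.numeric(tilt_deg) || any(!is.finite(tilt_deg)) ||
      any(tilt_deg < 0) || any(tilt_deg > 90))
    stop("tilt_deg must lie in [0, 90] degrees")
  delta_sigma_static * .p2_deg(tilt_deg)
}

#' Lorentzian line broadening by FFT convolution
#'
#' Convolves the spectrum with a unit-area Lorentzian of full width at half
#' maximum \code{lb_hz} (specified in Hz, as set on the spectrometer, and
#' converted to axis units internally: /1000 for a kHz axis, /sfrq_mhz for a
#' ppm axis). The grid must be uniform; zero-padded FFT convolution preserves
#' the total integral.
#'
#' @param spectrum an \code{nmr_spectrum} on a uniform grid.
#' @param lb_hz Lorentzian FWHM in Hz, >= 0. \code{lb_hz = 0} is the identity.
#' @return The broadened \code{nmr_spectrum}.
#' @export
apply_lorentzian_broadening <- function(spectrum, lb_hz) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (!is.finite(lb_hz) || lb_hz < 0) stop("lb_hz must be >= 0")
  if (lb_hz == 0) return(spectrum)
  step <- .uniform_step(spectrum$axis, "Lorentzian broadening")
  fw <- if (spectrum$axis_kind == "kHz") lb_hz / 1000
        else lb_hz / spectrum$sfrq_mhz
  n <- length(spectrum$axis)
  m <- stats::nextn(2L * n, 2)
  # kernel sampled in wrap-around order on the padded grid
  k_idx <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1))
  x <- k_idx * step
  kern <- (2 / (pi * fw)) / (1 + (2 * x / fw)^2)
  kern <- kern / (sum(kern) * step)      # exact unit area on the grid
  sig <- c(spectrum$intensity, numeric(m - n))
  conv <- Re(stats::fft(stats::fft(sig) * stats::fft(kern), inverse = TRUE)) / m
  out <- spectrum
  out$intensity <- conv[seq_len(n)] * step
  out
}

#' Compose a multi-component powder spectrum
#'
#' Weighted superposition of the powder sub-spectra of all components (each
#' with its intrinsic line width), followed by a global Lorentzian broadening
#' \code{lb_hz} as applied before Fourier transformation of the experimental
#' data. The total integral equals the sum of the component weights.
#'
#' @param components data.frame of rows from [quad_component()] or
#'   [csa_component()] (one nucleus only).
#' @param axis uniform axis grid (kHz for 2H, ppm for 31P).
#' @param dist an [orientation_dist()].
#' @param lb_hz global Lorentzian FWHM, Hz.
#' @param sfrq_mhz spectrometer frequency, MHz.
#' @param temperature_c,label metadata for the result.
#' @param strict error when the grid does not span some component's pattern.
#' @return An \code{nmr_spectrum}.
#' @export
compose_spectrum <- function(components, axis, dist = orientation_dist(),
                             lb_hz = 0, sfrq_mhz = NULL,
                             temperature_c = NA_real_, label = "",
                             strict = TRUE) {
  nucleus <- .components_nucleus(components)
  if (is.null(sfrq_mhz)) sfrq_mhz <- if (nucleus == "2H") 76 else 162
  intens <- numeric(length(axis))
  for (i in seq_len(nrow(components))) {
    sub <- if (nucleus == "2H")
      quad_powder_subspectrum(components[i, ], dist, axis, sfrq_mhz,
                              strict = strict)
    else
      csa_powder_subspectrum(components[i, ], dist, axis, sfrq_mhz,
                             strict = strict)
    intens <- intens + sub$intensity
  }
  out <- nmr_spectrum(axis, intens, nucleus = nucleus, sfrq_mhz = sfrq_mhz,
                      temperature_c = temperature_c, label = label)
  if (lb_hz > 0) out <- apply_lorentzian_broadening(out, lb_hz)
  out
}
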