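#' One-dimensional frequency-domain NMR spectrum
#'
#' Canonical in-memory container for a wide-line spectrum. The axis is stored
#' strictly increasing; for \code{"2H"} it is the frequency offset from the
#' carrier in kHz (carrier at the centre of the symmetric Pake pattern), for
#' \code{"31P"} it is the chemical shift in ppm relative to 85\% H3PO4 (0 ppm).
#' Plotting routines may display a ppm axis decreasing left-to-right, but the
#' stored representation is always increasing.
#'
#' @param axis numeric vector, strictly monotonically increasing, length >= 16.
#' @param intensity numeric vector, same length as \code{axis}, all finite.
#' @param nucleus \code{"2H"} or \code{"31P"}.
#' @param sfrq_mhz spectrometer (Larmor) frequency of the observed nucleus, MHz.
#' @param axis_kind \code{"kHz"} (offset from carrier) or \code{"ppm"}. Defaults
#'   to the canonical kind for the nucleus: kHz for 2H, ppm for 31P.
#' @param temperature_c sample temperature in degrees Celsius, or \code{NA}.
#' @param label free-text label.
#' @param meta optional named list of extra metadata carried along unchanged.
#'
#' @return An object of class \code{nmr_spectrum}: a list with elements
#'   \code{axis}, \code{intensity}, \code{nucleus}, \code{sfrq_mhz},
#'   \code{axis_kind}, \code{temperature_c}, \code{label}, \code{meta}.
#' @examples
#' s <- nmr_spectrum(seq(-50, 50, length.out = 64), rep(1, 64),
#'                   nucleus = "2H", sfrq_mhz = 76)
#' print(s)
#' @export
nmr_spectrum <- function(axis, intensity, nucleus, sfrq_mhz,
                         axis_kind = NULL, temperature_c = NA_real_,
                         label = "", meta = list()) {
  nucleus <- match.arg(nucleus, c("2H", "31P"))
  if (is.null(axis_kind))
    axis_kind <- if (nucleus == "2H") "kHz" else "ppm"
  axis_kind <- match.arg(axis_kind, c("kHz", "ppm"))
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity))
    stop("axis and intensity must have the same length (", length(axis),
         " vs ", length(intensity), ")")
  if (length(axis) < 16L)
    stop("spectrum must have at least 16 points, got ", length(axis))
  if (!all(is.finite(axis)) || !all(is.finite(intensity)))
    stop("axis and intensity must be finite throughout")
  if (any(diff(axis) <= 0))
    stop("axis must be strictly monotonically increasing")
  if (!is.numeric(sfrq_mhz) || length(sfrq_mhz) != 1L || !is.finite(sfrq_mhz) ||
      sfrq_mhz <= 0)
    stop("sfrq_mhz must be a single positive number")
  # nucleus/axis-kind consistency is a storage convention, not a display one
  canonical <- if (nucleus == "2H") "kHz" else "ppm"
  if (axis_kind != canonical)
    stop("nucleus ", nucleus, " spectra are stored on a ", canonical,
         " axis; got ", axis_kind, " (use convert_axis() explicitly)")
  structure(
    list(axis = axis, intensity = intensity, nucleus = nucleus,
         sfrq_mhz = as.numeric(sfrq_mhz), axis_kind = axis_kind,
         temperature_c = as.numeric(temperature_c), label = as.character(label),
         meta = meta),
    class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s  %d points, %s axis [%.4g, %.4g]\n",
              x$nucleus, length(x$axis), x$axis_kind,
              min(x$axis), max(x$axis)))
  cat(sprintf("  spectrometer %.6g MHz", x$sfrq_mhz))
  if (is.finite(x$temperature_c)) cat(sprintf(", %.4g degC", x$temperature_c))
  if (nzchar(x$label)) cat(", label: ", x$label, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
plot.nmr_spectrum <- function(x, ..., xlab = NULL, ylab = "intensity") {
  if (is.null(xlab))
    xlab <- if (x$axis_kind == "ppm")
      expression(delta ~ "(ppm)") else "frequency offset (kHz)"
  xlim <- range(x$axis)
  # ppm axes are drawn decreasing left-to-right (field convention)
  if (x$axis_kind == "ppm") xlim <- rev(xlim)
  graphics::plot(x$axis, x$intensity, type = "l", xlab = xlab, ylab = ylab,
                 xlim = xlim, main = x$label, ...)
  invisible(x)
}

#' Numerical integral of a spectrum (trapezoidal rule)
#'
#' @param spectrum an \code{nmr_spectrum}.
#' @return Scalar integral of intensity over the axis.
#' @export
spectrum_integral <- function(spectrum) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  sum(diff(spectrum$axis) *
        (utils::head(spectrum$intensity, -1) + utils::tail(spectrum$intensity, -1)) / 2)
}

#' First spectral moment (intensity-weighted mean frequency)
#'
#' Diagnostic utility: for an unbroadened axially symmetric CSA powder pattern
#' the first moment equals the isotropic shift.
#'
#' @param spectrum an \code{nmr_spectrum}.
#' @return Scalar first moment in axis units.
#' @export
first_moment <- function(spectrum) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  w <- spectrum$intensity
  tot <- sum(w)
  if (tot <= 0) stop("cannot take first moment of a non-positive spectrum")
  sum(spectrum$axis * w) / tot
}

#' Convert a spectrum axis between ppm and kHz offset
#'
#' The conversion uses the spectrometer frequency carried by the spectrum:
#' \code{offset[kHz] = shift[ppm] * sfrq[MHz] / 1000} (1 ppm corresponds to
#' \code{sfrq} Hz). The intensities are untouched; the round trip is the
#' identity.
#'
#' @param spectrum an \code{nmr_spectrum}.
#' @param target \code{"kHz"} or \code{"ppm"}.
#' @return A spectrum (plain list with the same fields, class
#'   \code{nmr_spectrum}) whose \code{axis_kind} is \code{target}. Converting
#'   to the current kind returns the input unchanged.
#' @examples
#' s <- nmr_spectrum(seq(-60, 20, length.out = 64), rep(1, 64),
#'                   nucleus = "31P", sfrq_mhz = 162)
#' k <- convert_axis(s, "kHz")
#' range(k$axis)  # -9.72 to 3.24 kHz
#' @export
convert_axis <- function(spectrum, target) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (!is.character(target) || length(target) != 1L ||
      !(target %in% c("kHz", "ppm")))
    stop("unknown axis kind: ", deparse(substitute(target)),
         " (must be \"kHz\" or \"ppm\")")
  if (identical(spectrum$axis_kind, target)) return(spectrum)
  f <- spectrum$sfrq_mhz
  if (!is.finite(f) || f <= 0) stop("spectrometer frequency must be positive")
  out <- spectrum
  if (target == "kHz") {
    out$axis <- spectrum$axis * f / 1000      # ppm -> kHz
  } else {
    out$axis <- spectrum$axis * 1000 / f      # kHz -> ppm
  }
  out$axis_kind <- target
  out
}

# internal: enforce a uniform grid; returns the step
.uniform_step <- function(axis, what = "spectrum") {
  d <- diff(axis)
  step <- mean(d)
  if (max(abs(d - step)) > 1e-6 * abs(step))
    stop(what, " requires a uniform axis grid")
  step
}
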