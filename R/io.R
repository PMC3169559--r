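#' Read a spectrum from a two-column text file with JSON sidecar
#'
#' The spectral text format is two whitespace-separated numeric columns
#' (axis, intensity), UTF-8, '#' comment lines, '.' decimal separator.
#' Metadata lives in a JSON sidecar named \code{<path>.json} (or passed
#' explicitly) with required keys \code{nucleus},
#' \code{spectrometer_frequency_mhz}, \code{axis_kind} and optional
#' \code{temperature_c}, \code{label}, \code{seed}.
#'
#' @param path path to the two-column spectrum file.
#' @param sidecar path to the JSON sidecar; default \code{paste0(path, ".json")}.
#' @return An \code{nmr_spectrum}. Extra sidecar keys are kept in \code{$meta}.
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  if (!file.exists(sidecar)) stop("JSON sidecar not found: ", sidecar)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no data rows in ", path)
  parts <- strsplit(trimws(lines[idx]), "\\s+")
  n_col <- lengths(parts)
  if (any(n_col != 2L)) {
    bad <- idx[which(n_col != 2L)[1]]
    stop("line ", bad, " of ", path, " does not have two columns")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 2, byrow = TRUE)
  if (anyNA(m)) {
    bad <- idx[which(rowSums(is.na(m)) > 0)[1]]
    stop("non-numeric value on line ", bad, " of ", path)
  }
  md <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  required <- c("nucleus", "spectrometer_frequency_mhz", "axis_kind")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("sidecar ", sidecar, " is missing required key(s): ",
         paste(missing, collapse = ", "))
  extra <- md[setdiff(names(md),
                      c(required, "temperature_c", "label"))]
  nmr_spectrum(m[, 1], m[, 2],
               nucleus = md$nucleus,
               sfrq_mhz = md$spectrometer_frequency_mhz,
               axis_kind = md$axis_kind,
               temperature_c = if (is.null(md$temperature_c)) NA_real_
                               else md$temperature_c,
               label = if (is.null(md$label)) "" else md$label,
               meta = as.list(extra))
}

#' Write a spectrum to a two-column text file with JSON sidecar
#'
#' Values are written with 15 significant digits so that
#' \code{read_spectrum(write_spectrum(s))} reproduces the spectrum to full
#' double precision for all practical purposes.
#'
#' @param spectrum an \code{nmr_spectrum}.
#' @param path output path; the sidecar is written to \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  hdr <- c(sprintf("# %s spectrum%s", spectrum$nucleus,
                   if (nzchar(spectrum$label)) paste0(": ", spectrum$label) else ""),
           sprintf("# axis (%s)  intensity", spectrum$axis_kind))
  body <- sprintf("%.15g %.15g", spectrum$axis, spectrum$intensity)
  writeLines(c(hdr, body), path, useBytes = TRUE)
  md <- c(list(nucleus = spectrum$nucleus,
               spectrometer_frequency_mhz = spectrum$sfrq_mhz,
               axis_kind = spectrum$axis_kind,
               temperature_c = spectrum$temperature_c,
               label = spectrum$label),
          spectrum$meta)
  jsonlite::write_json(md, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}
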