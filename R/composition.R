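# Per-lipid phosphate inventory. Cholesterol carries no phosphorus; PIP2
# carries three distinct 31P environments (glycerol-bound phosphodiester plus
# the 4- and 5-phosphates on the inositol ring).
.LIPID_PHOSPHATES <- list(
  POPC = "PC",
  POPE = "PE",
  POPS = "PS",
  Chol = character(0),
  PI   = "PI_g",
  PIP  = c("PIP_g", "PIP_4P"),
  PIP2 = c("PIP2_g", "PIP2_4P", "PIP2_5P")
)

#' Membrane composition (lipid list with mol%)
#'
#' Either look up one of the built-in model-membrane compositions (see
#' [builtin_compositions()]) by name, or supply a data.frame with columns
#' \code{lipid} and \code{mol_percent}. Proportions are treated as relative
#' molar amounts; several of the built-in mixtures are specified as molar
#' ratios that do not total 100.
#'
#' @param x a composition name or a data.frame(lipid, mol_percent).
#' @return Object of class \code{membrane_composition}: data.frame with
#'   columns \code{lipid}, \code{mol_percent}, \code{n_phosphates}, plus a
#'   \code{name} attribute.
#' @examples
#' membrane_composition("NER")
#' membrane_composition(data.frame(lipid = c("POPC", "PIP2"),
#'                                 mol_percent = c(30, 12)))
#' @export
membrane_composition <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    tab <- builtin_compositions()
    rows <- tab[tab$composition == x, ]
    if (!nrow(rows))
      stop("unknown composition name: ", x, " (see builtin_compositions())")
    df <- data.frame(lipid = rows$lipid, mol_percent = rows$mol_percent,
                     stringsAsFactors = FALSE)
    name <- x
  } else if (is.data.frame(x)) {
    if (!all(c("lipid", "mol_percent") %in% names(x)))
      stop("composition data.frame needs columns lipid, mol_percent")
    df <- data.frame(lipid = as.character(x$lipid),
                     mol_percent = as.numeric(x$mol_percent),
                     stringsAsFactors = FALSE)
    name <- paste(df$lipid, collapse = "/")
  } else stop("x must be a composition name or a data.frame")
  unknown <- setdiff(df$lipid, names(.LIPID_PHOSPHATES))
  if (length(unknown))
    stop("unknown lipid(s): ", paste(unknown, collapse = ", "))
  if (any(df$mol_percent <= 0) || any(!is.finite(df$mol_percent)))
    stop("mol_percent must be positive and finite")
  if (sum(df$mol_percent) > 101)
    stop("mol_percent sums to more than 100 (within the 1% accuracy of the table)")
  df$n_phosphates <- lengths(.LIPID_PHOSPHATES[df$lipid])
  structure(df, name = name, class = c("membrane_composition", "data.frame"))
}

#' Built-in model-membrane compositions
#'
#' The twelve lipid systems of the study (pure POPC and POPC with
#' phosphoinositides and/or cholesterol, up to the complex MV1-, MV2- and
#' NER-like mixtures), as a long table.
#'
#' @return data.frame with columns \code{composition}, \code{lipid},
#'   \code{mol_percent}.
#' @export
builtin_compositions <- function() {
  path <- system.file("extdata", "compositions.csv", package = "lipidorder",
                      mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Reference 31P shielding parameters per composition
#'
#' Per-phosphate chemical shielding anisotropy, isotropic shift and line width
#' for each composition with a characterized 31P spectrum. These are the
#' parameters the synthetic generator simulates from and the values parameter
#' recovery is judged against.
#'
#' @param composition optional composition name to filter on.
#' @return data.frame with columns \code{composition}, \code{label},
#'   \code{delta_sigma_ppm}, \code{delta_iso_ppm}, \code{linewidth_hz}.
#' @export
p31_reference_parameters <- function(composition = NULL) {
  path <- system.file("extdata", "p31_parameters.csv", package = "lipidorder",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(composition)) {
    tab <- tab[tab$composition == composition, ]
    if (!nrow(tab)) stop("no 31P reference parameters for composition: ",
                         composition)
  }
  tab
}

#' Expand a membrane composition into 31P CSA components
#'
#' One component per distinct phosphate environment; the component weight is
#' mol\% x (one per phosphate). Cholesterol contributes nothing. Parameters
#' (anisotropy, isotropic shift, line width) are taken from \code{params} by
#' phosphate label.
#'
#' @param composition a [membrane_composition()] (or name).
#' @param params data.frame(label, delta_sigma_ppm, delta_iso_ppm,
#'   linewidth_hz); defaults to the composition's row set in
#'   [p31_reference_parameters()] when the composition is a built-in name.
#' @return data.frame of CSA components ([csa_component()] rows).
#' @examples
#' nrow(composition_to_phosphorus_components("NER"))  # 7
#' @export
composition_to_phosphorus_components <- function(composition, params = NULL) {
  if (is.character(composition)) {
    if (is.null(params)) params <- p31_reference_parameters(composition)
    composition <- membrane_composition(composition)
  }
  stopifnot(inherits(composition, "membrane_composition"))
  if (is.null(params))
    stop("params table required for a custom composition")
  out <- NULL
  for (i in seq_len(nrow(composition))) {
    labels <- .LIPID_PHOSPHATES[[composition$lipid[i]]]
    for (lab in labels) {
      row <- params[params$label == lab, , drop = FALSE]
      if (!nrow(row))
        stop("no 31P parameters for phosphate label: ", lab)
      comp <- csa_component(row$delta_sigma_ppm[1], row$delta_iso_ppm[1],
                            row$linewidth_hz[1],
                            weight = composition$mol_percent[i], label = lab)
      out <- rbind(out, comp)
    }
  }
  if (is.null(out))
    stop("composition contains no phosphorus-bearing lipid")
  out
}

#' Expand a deuterated chain into quadrupolar components
#'
#' A perdeuterated palmitoyl chain (POPC-2H31) carries 15 inequivalent
#' deuteron groups: CD2 at positions k = 2..15 (2 deuterons each) and the
#' terminal CD3 at k = 16 (3 deuterons). A splitting profile assigns one
#' 90-degree-edge splitting per position or per merged group (e.g. the
#' plateau, positions 2 to 8-10, as \code{"2-10"}).
#'
#' @param profile data.frame with columns \code{position} (integer 2..16 or a
#'   range string like \code{"2-10"}) and \code{splitting_khz}; optional
#'   \code{linewidth_hz}.
#' @param chain chain label; only \code{"POPC-d31"} (perdeuterated sn-1
#'   palmitoyl) is known.
#' @param linewidth_hz default intrinsic line width for positions without one.
#' @return data.frame of quadrupolar components; the weight of a group is its
#'   deuteron count (2 per CD2 position, 3 for the CD3).
#' @examples
#' prof <- data.frame(position = c("2-10", "11", "16"),
#'                    splitting_khz = c(29.4, 27.0, 3.6))
#' chain_to_quad_components(prof)
#' @export
chain_to_quad_components <- function(profile, chain = "POPC-d31",
                                     linewidth_hz = 150) {
  if (!identical(chain, "POPC-d31"))
    stop("unknown chain label: ", chain, " (known: POPC-d31)")
  if (!all(c("position", "splitting_khz") %in% names(profile)))
    stop("profile needs columns position, splitting_khz")
  lw <- if ("linewidth_hz" %in% names(profile)) profile$linewidth_hz
        else rep(linewidth_hz, nrow(profile))
  seen <- integer(0)
  out <- NULL
  for (i in seq_len(nrow(profile))) {
    pos <- as.character(profile$position[i])
    if (grepl("^[0-9]+-[0-9]+$", pos)) {
      rng <- as.integer(strsplit(pos, "-")[[1]])
      ks <- seq(rng[1], rng[2])
    } else if (grepl("^[0-9]+$", pos)) {
      ks <- as.integer(pos)
    } else stop("unparseable chain position: ", pos)
    if (any(ks < 2L | ks > 16L))
      stop("chain positions must lie in 2..16, got: ", pos)
    if (any(ks %in% seen))
      stop("chain position assigned twice: ", pos)
    seen <- c(seen, ks)
    wt <- sum(ifelse(ks == 16L, 3, 2))
    out <- rbind(out, quad_component(profile$splitting_khz[i], weight = wt,
                                     linewidth_hz = lw[i],
                                     label = paste0("k", pos)))
  }
  out
}
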