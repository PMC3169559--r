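# Scenario truth defaults. The four 10-degree plateau anchors (POPC 0.47,
# POPC/Chol 0.81, POPC/Chol/PI 0.69, NER 0.73) reproduce the characterized
# systems; all other values (remaining compositions, temperature slopes,
# mid-chain fractions, gel-phase parameters) are synthetic defaults chosen to
# respect the qualitative ordering of the thermal plateau curves:
# POPC/Chol > NER > POPC/Chol/PI > MV2 > POPC > MV1 ~ POPC/PI.
.SCENARIO_TRUTH <- list(
  "POPC"              = list(plateau10 = 0.47, slope = -0.0040, tm_c = -5),
  "POPC/PI"           = list(plateau10 = 0.42, slope = -0.0040, tm_c = -20),
  "POPC/PI-40"        = list(plateau10 = 0.38, slope = -0.0040, tm_c = -20),
  "POPC/PIP"          = list(plateau10 = 0.46, slope = -0.0040, tm_c = -20),
  "POPC/PIP2"         = list(plateau10 = 0.47, slope = -0.0040, tm_c = -5),
  "POPC/PI/PIP"       = list(plateau10 = 0.43, slope = -0.0040, tm_c = -20),
  "POPC/PI/PIP2"      = list(plateau10 = 0.44, slope = -0.0040, tm_c = -20),
  "MV1"               = list(plateau10 = 0.42, slope = -0.0040, tm_c = -20),
  "MV2"               = list(plateau10 = 0.62, slope = -0.0020, tm_c = -5),
  "POPC/Chol"         = list(plateau10 = 0.81, slope = -0.0015, tm_c = -Inf),
  "POPC/Chol/PI"      = list(plateau10 = 0.69, slope = -0.0015, tm_c = -Inf),
  "POPC/Chol/PI/PIP"  = list(plateau10 = 0.67, slope = -0.0015, tm_c = -Inf),
  "POPC/Chol/PI/PIP2" = list(plateau10 = 0.71, slope = -0.0015, tm_c = -Inf),
  "NER"               = list(plateau10 = 0.73, slope = -0.0015, tm_c = -Inf)
)

# mid-chain splittings as fractions of the plateau splitting (k = 11..15),
# and the terminal CD3; synthetic defaults shaped like a fluid-phase profile
.MIDCHAIN_FRACTIONS <- c(`11` = 0.96, `12` = 0.88, `13` = 0.76, `14` = 0.62,
                         `15` = 0.46, `16` = 0.125)

#' Scenario specification for the synthetic-spectrum generator
#'
#' @param composition one of the built-in composition names
#'   (see [builtin_compositions()]).
#' @param temperatures_c temperatures to generate, degrees C.
#' @param noise relative Gaussian noise sigma on intensity (fraction of the
#'   maximum intensity; default 0.01).
#' @param lb_hz Lorentzian line broadening applied to the spectra, Hz.
#' @param epsilon prolate deformation parameter.
#' @param gel_fraction optional named/numeric vector of gel fractions per
#'   temperature; by default inferred from the scenario's melting temperature
#'   (0.5 at T_m, 1 well below, 0 above).
#' @param isotropic_fraction weight fraction of the sharp isotropic
#'   (small-vesicle) line, < 0.05 in the characterized samples.
#' @param seed mandatory RNG seed; identical spec + seed gives byte-identical
#'   output files.
#' @return list of class \code{scenario_spec}.
#' @export
scenario_spec <- function(composition, temperatures_c = c(-5, 0, 10, 20),
                          noise = 0.01, lb_hz = 200, epsilon = 0,
                          gel_fraction = NULL, isotropic_fraction = 0.02,
                          seed) {
  if (!composition %in% names(.SCENARIO_TRUTH))
    stop("unknown composition name: ", composition,
         " (known: ", paste(names(.SCENARIO_TRUTH), collapse = ", "), ")")
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  if (noise < 0 || isotropic_fraction < 0 || isotropic_fraction > 1)
    stop("fractions must lie in [0, 1] and noise must be >= 0")
  if (!is.null(gel_fraction)) {
    if (length(gel_fraction) != length(temperatures_c))
      stop("gel_fraction must have one value per temperature")
    if (any(gel_fraction < 0 | gel_fraction > 1))
      stop("gel_fraction values must lie in [0, 1]")
  }
  structure(list(composition = composition,
                 temperatures_c = temperatures_c, noise = noise,
                 lb_hz = lb_hz, epsilon = epsilon,
                 gel_fraction = gel_fraction,
                 isotropic_fraction = isotropic_fraction,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# default gel fraction from the melting temperature: sigmoidal coexistence
# window centred on T_m (0.5 at T_m, ~1 a few degrees below, 0 well above)
.default_gel_fraction <- function(tm_c, t_c) {
  if (!is.finite(tm_c)) return(rep(0, length(t_c)))
  g <- 1 / (1 + exp((t_c - tm_c) / 1.5))
  g[t_c >= tm_c + 10] <- 0
  round(g, 6)
}

#' True per-position splitting profile of a scenario at one temperature
#'
#' @param composition composition name.
#' @param temperature_c temperature, degrees C.
#' @return data.frame(position, splitting_khz) for positions "2-10" and
#'   11..16, plus attributes \code{two_s_cd} (plateau) and
#'   \code{plateau_splitting_khz}.
#' @export
scenario_truth_profile <- function(composition, temperature_c) {
  tr <- .SCENARIO_TRUTH[[composition]]
  if (is.null(tr)) stop("unknown composition name: ", composition)
  two_s <- tr$plateau10 + tr$slope * (temperature_c - 10)
  two_s <- min(max(two_s, 0.02), 1)
  plateau <- order_to_splitting(two_s / 2)
  prof <- data.frame(
    position = c("2-10", names(.MIDCHAIN_FRACTIONS)),
    splitting_khz = plateau * c(1, unname(.MIDCHAIN_FRACTIONS)),
    stringsAsFactors = FALSE)
  attr(prof, "two_s_cd") <- two_s
  attr(prof, "plateau_splitting_khz") <- plateau
  prof
}

#' Gel/fluid two-phase coexistence spectrum
#'
#' Convex combination of a fluid-phase chain spectrum and a gel-phase
#' spectrum near the chain-melting transition. The gel phase is approximated
#' by a broad axially symmetric envelope (default 120 kHz 90-degree-edge
#' width) for the CD2 positions plus a gel methyl doublet, so that at equal
#' phase fractions the two central (methyl) doublets appear in near-equal
#' amounts. The total integral equals the summed fluid component weight.
#'
#' @param fluid_components quadrupolar component table of the fluid phase.
#' @param gel_width_khz 90-degree-edge width of the gel envelope, kHz.
#' @param gel_fraction gel weight fraction in [0, 1].
#' @param dist an [orientation_dist()].
#' @param lb_hz global line broadening, Hz.
#' @param axis uniform kHz grid.
#' @param gel_methyl_khz gel-phase CD3 splitting, kHz.
#' @param sfrq_mhz 2H spectrometer frequency, MHz.
#' @return An \code{nmr_spectrum}.
#' @export
phase_coexistence_spectrum <- function(fluid_components, gel_width_khz = 120,
                                       gel_fraction, dist = orientation_dist(),
                                       lb_hz = 200, axis,
                                       gel_methyl_khz = 11.8, sfrq_mhz = 76) {
  if (gel_fraction < 0 || gel_fraction > 1)
    stop("gel_fraction must lie in [0, 1]")
  total <- sum(fluid_components$weight)
  parts <- NULL
  if (gel_fraction < 1) {
    fl <- fluid_components
    fl$weight <- fl$weight * (1 - gel_fraction)
    parts <- rbind(parts, fl)
  }
  if (gel_fraction > 0) {
    # 28 of 31 deuterons in the broad CD2 envelope, 3 in the gel methyl
    parts <- rbind(parts,
      quad_component(gel_width_khz, weight = gel_fraction * total * 28 / 31,
                     linewidth_hz = 3000, label = "gel"),
      quad_component(gel_methyl_khz, weight = gel_fraction * total * 3 / 31,
                     linewidth_hz = 300, label = "gel_k16"))
  }
  compose_spectrum(parts, axis, dist, lb_hz = lb_hz, sfrq_mhz = sfrq_mhz)
}

#' Generate a synthetic scenario (spectra + machine-readable ground truth)
#'
#' Emulates the study conditions for one model-membrane composition: a 2H
#' spectrum of the perdeuterated POPC probe per temperature (gel/fluid
#' coexistence near T_m, a small isotropic contaminant line, Lorentzian
#' broadening, optional prolate deformation, Gaussian noise) and, where the
#' composition has a characterized 31P parameter set, a 31P spectrum built
#' from it. The generator contains no lineshape physics of its own: at zero
#' noise every spectrum equals the forward model output.
#'
#' @param spec a [scenario_spec()].
#' @param out_dir optional directory; when given, spectra (+ JSON sidecars),
#'   \code{ground_truth.json} and \code{truth.csv} are written there,
#'   deterministically for a given spec + seed.
#' @param axis_2h,axis_31p uniform axis grids.
#' @return list with \code{spectra} (named list of \code{nmr_spectrum}) and
#'   \code{truth} (per-temperature ground truth and the 31P parameter table).
#' @export
generate_scenario <- function(spec, out_dir = NULL,
                              axis_2h = seq(-150, 150, length.out = 2048L),
                              axis_31p = seq(-70, 40, length.out = 1024L)) {
  stopifnot(inherits(spec, "scenario_spec"))
  tr <- .SCENARIO_TRUTH[[spec$composition]]
  gel <- if (is.null(spec$gel_fraction))
    .default_gel_fraction(tr$tm_c, spec$temperatures_c) else spec$gel_fraction
  dist <- orientation_dist(spec$epsilon)
  has_p31 <- spec$composition %in% p31_reference_parameters()$composition
  p31_params <- if (has_p31) p31_reference_parameters(spec$composition) else NULL
  spectra <- list()
  truth_rows <- NULL
  truth <- list(composition = spec$composition, seed = spec$seed,
                isotropic_fraction = spec$isotropic_fraction,
                epsilon = spec$epsilon, lb_hz = spec$lb_hz,
                temperatures = list())
  for (i in seq_along(spec$temperatures_c)) {
    t_c <- spec$temperatures_c[i]
    prof <- scenario_truth_profile(spec$composition, t_c)
    comps <- chain_to_quad_components(prof)
    # small-vesicle isotropic contaminant: zero-anisotropy component
    if (spec$isotropic_fraction > 0)
      comps <- rbind(comps,
                     quad_component(0, weight = spec$isotropic_fraction *
                                      sum(comps$weight) /
                                      (1 - spec$isotropic_fraction),
                                    linewidth_hz = 100, label = "iso"))
    sp2h <- phase_coexistence_spectrum(comps, gel_fraction = gel[i],
                                       dist = dist, lb_hz = spec$lb_hz,
                                       axis = axis_2h)
    sp2h$temperature_c <- t_c
    sp2h$label <- sprintf("%s 2H %gC", spec$composition, t_c)
    # deterministic per-spectrum noise streams derived from the master seed
    if (spec$noise > 0) {
      set.seed(spec$seed + 1000L * i)
      sp2h$intensity <- sp2h$intensity +
        stats::rnorm(length(sp2h$intensity), 0,
                     spec$noise * max(sp2h$intensity))
    }
    sp2h$meta$seed <- spec$seed
    nm2h <- sprintf("h2_%s", gsub("[^0-9a-zA-Z-]", "", format(t_c)))
    spectra[[nm2h]] <- sp2h
    t_entry <- list(temperature_c = t_c, gel_fraction = gel[i],
                    plateau_splitting_khz = attr(prof, "plateau_splitting_khz"),
                    plateau_two_s_cd = attr(prof, "two_s_cd"),
                    profile = prof)
    if (has_p31) {
      pcomp <- composition_to_phosphorus_components(spec$composition,
                                                    p31_params)
      if (spec$isotropic_fraction > 0)
        pcomp <- rbind(pcomp,
                       csa_component(0, 0, 60,
                                     weight = spec$isotropic_fraction *
                                       sum(pcomp$weight) /
                                       (1 - spec$isotropic_fraction),
                                     label = "iso"))
      sp31 <- compose_spectrum(pcomp, axis_31p, dist,
                               lb_hz = min(spec$lb_hz, 100),
                               temperature_c = t_c,
                               label = sprintf("%s 31P %gC",
                                               spec$composition, t_c))
      if (spec$noise > 0) {
        set.seed(spec$seed + 1000L * i + 500L)
        sp31$intensity <- sp31$intensity +
          stats::rnorm(length(sp31$intensity), 0,
                       spec$noise * max(sp31$intensity))
      }
      sp31$meta$seed <- spec$seed
      spectra[[sprintf("p31_%s", gsub("[^0-9a-zA-Z-]", "", format(t_c)))]] <- sp31
    }
    truth$temperatures[[as.character(t_c)]] <- t_entry
    truth_rows <- rbind(truth_rows,
                        data.frame(composition = spec$composition,
                                   temperature_c = t_c,
                                   gel_fraction = gel[i],
                                   plateau_splitting_khz =
                                     attr(prof, "plateau_splitting_khz"),
                                   plateau_two_s_cd = attr(prof, "two_s_cd")))
  }
  truth$p31_parameters <- p31_params
  truth$table <- truth_rows
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(spectra))
      write_spectrum(spectra[[nm]], file.path(out_dir, paste0(nm, ".txt")))
    jsonlite::write_json(
      list(composition = spec$composition, seed = spec$seed,
           isotropic_fraction = spec$isotropic_fraction,
           epsilon = spec$epsilon, lb_hz = spec$lb_hz,
           table = truth_rows, p31_parameters = p31_params),
      file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    utils::write.csv(truth_rows, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(spectra = spectra, truth = truth)
}
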