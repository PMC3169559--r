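#' Configuration for the multi-component 31P lineshape fit
#'
#' @param components initial CSA components (data.frame of
#'   [csa_component()] rows); usually from
#'   [composition_to_phosphorus_components()] or
#'   [initial_guesses_from_depaked()].
#' @param free named list of logical vectors (one entry per component) saying
#'   which parameters float: \code{delta_sigma}, \code{delta_iso},
#'   \code{linewidth}, \code{weight}. Defaults: anisotropies, isotropic
#'   shifts and line widths free; weights frozen to the supplied
#'   stoichiometry (a global amplitude scale always floats).
#' @param ties list of character vectors of component labels whose
#'   \code{delta_sigma} (and line width) are constrained equal, e.g. the
#'   glycerol-bound phosphates of PI/PIP/PIP2. Use [glycerol_ties()] for that
#'   default; \code{list()} disables tying.
#' @param bounds list with elements \code{delta_sigma}, \code{delta_iso},
#'   \code{linewidth}, \code{epsilon}: each a c(lower, upper) pair.
#' @param epsilon prolate deformation: a number (fixed) or \code{"free"}.
#' @param lb_hz global line broadening applied to the model, Hz.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @param tol convergence tolerance on the relative residual change.
#' @param n_angles orientation-grid size of the forward model.
#' @param n_restarts extra fits from jittered starting values (best kept).
#' @param seed seed for the jittered restarts.
#' @return list of class \code{fit_config}.
#' @export
fit_config <- function(components, free = NULL, ties = list(),
                       bounds = NULL, epsilon = 0, lb_hz = 0,
                       max_iter = 500L, tol = 1e-8, n_angles = 2048L,
                       n_restarts = 0L, seed = 1L) {
  stopifnot(is.data.frame(components), nrow(components) >= 1,
            "delta_sigma_ppm" %in% names(components))
  n <- nrow(components)
  default_free <- list(delta_sigma = rep(TRUE, n), delta_iso = rep(TRUE, n),
                       linewidth = rep(TRUE, n), weight = rep(FALSE, n))
  if (is.null(free)) free <- list()
  free <- utils::modifyList(default_free, free)
  for (p in names(default_free))
    if (length(free[[p]]) == 1L) free[[p]] <- rep(free[[p]], n)
  default_bounds <- list(delta_sigma = c(-150, 150), delta_iso = c(-20, 20),
                         linewidth = c(5, 3000), epsilon = c(0, 1))
  if (is.null(bounds)) bounds <- list()
  bounds <- utils::modifyList(default_bounds, bounds)
  if (!identical(epsilon, "free")) {
    if (!is.numeric(epsilon) || epsilon < 0) stop("epsilon must be >= 0 or \"free\"")
  }
  for (grp in ties) {
    missing <- setdiff(grp, components$label)
    if (length(missing))
      stop("tie group names unknown component label(s): ",
           paste(missing, collapse = ", "))
  }
  ok <- components$delta_sigma_ppm >= bounds$delta_sigma[1] &
        components$delta_sigma_ppm <= bounds$delta_sigma[2] &
        components$delta_iso_ppm >= bounds$delta_iso[1] &
        components$delta_iso_ppm <= bounds$delta_iso[2]
  if (!all(ok)) stop("initial values outside bounds for component(s): ",
                     paste(components$label[!ok], collapse = ", "))
  structure(list(components = components, free = free, ties = ties,
                 bounds = bounds, epsilon = epsilon, lb_hz = lb_hz,
                 max_iter = as.integer(max_iter), tol = tol,
                 n_angles = as.integer(n_angles),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed)),
            class = "fit_config")
}

#' Default tie groups for glycerol-bound phosphoinositide phosphates
#'
#' The phosphodiester phosphates of PI, PIP and PIP2 share orientation and
#' dynamics closely enough that multi-component fits cannot separate them;
#' they are constrained to one common anisotropy (and line width), mirroring
#' the degeneracy of the recovered parameter tables.
#'
#' @param components component table; the tie is restricted to the labels
#'   present.
#' @return list with at most one character vector of labels.
#' @export
glycerol_ties <- function(components = NULL) {
  grp <- c("PI_g", "PIP_g", "PIP2_g")
  if (!is.null(components)) grp <- intersect(grp, components$label)
  if (length(grp) >= 2) list(grp) else list()
}

# --- parameter packing -------------------------------------------------------
# Build the map between the free-parameter vector handed to the optimizer and
# the full (n_components x 4, + epsilon, + scale) parameter set, honoring
# frozen masks and tie groups.
.build_pmap <- function(config) {
  comps <- config$components
  n <- nrow(comps)
  pars <- c("delta_sigma", "delta_iso", "linewidth", "weight")
  cols <- c(delta_sigma = "delta_sigma_ppm", delta_iso = "delta_iso_ppm",
            linewidth = "linewidth_hz", weight = "weight")
  id <- matrix(NA_integer_, n, length(pars), dimnames = list(NULL, pars))
  start <- numeric(0); lower <- numeric(0); upper <- numeric(0); nm <- character(0)
  next_id <- 0L
  tie_of <- function(i, par) {
    if (par %in% c("delta_sigma", "linewidth")) {
      for (g in seq_along(config$ties))
        if (comps$label[i] %in% config$ties[[g]]) return(g)
    }
    NA_integer_
  }
  tie_reg <- list(delta_sigma = list(), linewidth = list())
  for (par in pars) {
    for (i in seq_len(n)) {
      if (!config$free[[par]][i]) next
      g <- tie_of(i, par)
      if (!is.na(g) && !is.null(tie_reg[[par]][[as.character(g)]])) {
        id[i, par] <- tie_reg[[par]][[as.character(g)]]
        next
      }
      next_id <- next_id + 1L
      id[i, par] <- next_id
      if (!is.na(g)) tie_reg[[par]][[as.character(g)]] <- next_id
      start <- c(start, comps[[cols[par]]][i])
      bnd <- switch(par,
                    delta_sigma = config$bounds$delta_sigma,
                    delta_iso = config$bounds$delta_iso,
                    linewidth = config$bounds$linewidth,
                    weight = c(1e-6, Inf))
      lower <- c(lower, bnd[1]); upper <- c(upper, bnd[2])
      nm <- c(nm, paste0(par, ".", comps$label[i]))
    }
  }
  eps_id <- NA_integer_
  if (identical(config$epsilon, "free")) {
    next_id <- next_id + 1L
    eps_id <- next_id
    start <- c(start, 0.05)
    lower <- c(lower, config$bounds$epsilon[1])
    upper <- c(upper, config$bounds$epsilon[2])
    nm <- c(nm, "epsilon")
  }
  next_id <- next_id + 1L
  scale_id <- next_id
  start <- c(start, 1)
  lower <- c(lower, 1e-12); upper <- c(upper, Inf)
  nm <- c(nm, "scale")
  names(start) <- nm
  list(id = id, eps_id = eps_id, scale_id = scale_id,
       start = start, lower = lower, upper = upper)
}

.unpack <- function(p, pmap, config) {
  comps <- config$components
  cols <- c(delta_sigma = "delta_sigma_ppm", delta_iso = "delta_iso_ppm",
            linewidth = "linewidth_hz", weight = "weight")
  for (par in colnames(pmap$id)) {
    idx <- pmap$id[, par]
    has <- !is.na(idx)
    comps[[cols[par]]][has] <- p[idx[has]]
  }
  eps <- if (!is.na(pmap$eps_id)) p[pmap$eps_id]
         else as.numeric(config$epsilon)
  list(components = comps, epsilon = eps, scale = p[pmap$scale_id])
}

.p31_model <- function(p, pmap, config, axis, sfrq_mhz) {
  st <- .unpack(p, pmap, config)
  dist <- orientation_dist(st$epsilon, config$n_angles)
  sp <- compose_spectrum(st$components, axis, dist, lb_hz = config$lb_hz,
                         sfrq_mhz = sfrq_mhz, strict = FALSE)
  st$scale * sp$intensity
}

#' Fit a multi-component axially symmetric 31P powder spectrum
#'
#' Weighted least-squares fit of the composed forward lineshape model
#' ([compose_spectrum()]) to a measured 31P spectrum by damped
#' (Levenberg-Marquardt) least squares, honoring per-parameter freeze masks,
#' tie groups, box bounds and an optionally free prolate deformation. Weights
#' default to the supplied stoichiometry (only a global amplitude floats), as
#' the relative abundance of each phosphate is known from the composition.
#'
#' @param spectrum a 31P \code{nmr_spectrum}.
#' @param config a [fit_config()] (or a bare component table, in which case a
#'   default config is built around it).
#' @param weights optional per-point least-squares weights.
#' @return Object of class \code{p31_fit} with components table (fitted
#'   parameters), \code{epsilon}, \code{scale}, \code{residual_norm},
#'   \code{iterations}, \code{converged}, \code{fitted}, and the inputs;
#'   methods: \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{fitted}, \code{plot}, \code{simulate},
#'   \code{deviance}.
#' @export
fit_p31 <- function(spectrum, config, weights = NULL) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (spectrum$nucleus != "31P")
    stop("fit_p31 fits 31P spectra; got ", spectrum$nucleus)
  if (is.data.frame(config)) config <- fit_config(config)
  stopifnot(inherits(config, "fit_config"))
  axis <- spectrum$axis
  y <- spectrum$intensity
  w <- if (is.null(weights)) rep(1, length(y)) else sqrt(weights)
  pmap <- .build_pmap(config)
  resid_fn <- function(p) w * (.p31_model(p, pmap, config, axis, spectrum$sfrq_mhz) - y)
  ctrl <- minpack.lm::nls.lm.control(maxiter = min(config$max_iter, 1024L),
                                     ftol = config$tol, ptol = 1e-10)
  run_one <- function(start) {
    minpack.lm::nls.lm(par = start, lower = pmap$lower, upper = pmap$upper,
                       fn = resid_fn, control = ctrl)
  }
  fit <- run_one(pmap$start)
  best <- fit
  if (config$n_restarts > 0) {
    set.seed(config$seed)
    for (r in seq_len(config$n_restarts)) {
      jit <- pmap$start * stats::runif(length(pmap$start), 0.9, 1.1)
      jit <- pmin(pmax(jit, pmap$lower), pmap$upper)
      alt <- try(run_one(jit), silent = TRUE)
      if (!inherits(alt, "try-error") && alt$deviance < best$deviance)
        best <- alt
    }
  }
  diverged <- best$deviance > sum(resid_fn(pmap$start)^2) * (1 + 1e-12)
  st <- .unpack(best$par, pmap, config)
  fitted_int <- .p31_model(best$par, pmap, config, axis, spectrum$sfrq_mhz)
  converged <- best$info %in% 1:4 && !diverged
  structure(list(components = st$components, epsilon = st$epsilon,
                 scale = st$scale,
                 par = best$par, pmap = pmap, config = config,
                 residual_norm = sqrt(best$deviance),
                 deviance = best$deviance,
                 iterations = best$niter, converged = converged,
                 diverged = diverged,
                 message = best$message,
                 fitted = fitted_int,
                 spectrum = spectrum, weights = weights),
            class = "p31_fit")
}

#' @export
print.p31_fit <- function(x, ...) {
  cat(sprintf("<p31_fit> %d component(s), %s after %d iteration(s)\n",
              nrow(x$components),
              if (x$converged) "converged" else
                if (x$diverged) "DIVERGED (partial result)" else "not converged",
              x$iterations))
  cat(sprintf("  residual norm %.4g, epsilon %.3g, scale %.4g\n",
              x$residual_norm, x$epsilon, x$scale))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' @export
summary.p31_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.p31_fit")
}

#' @export
print.summary.p31_fit <- function(x, ...) {
  print(x$fit)
  rel <- x$fit$residual_norm /
    max(sqrt(sum(x$fit$spectrum$intensity^2)), .Machine$double.eps)
  cat(sprintf("  relative residual: %.3g\n", rel))
  invisible(x)
}

#' @export
coef.p31_fit <- function(object, ...) object$par

#' @export
deviance.p31_fit <- function(object, ...) object$deviance

#' @export
fitted.p31_fit <- function(object, ...) object$fitted

#' @export
residuals.p31_fit <- function(object, ...) object$spectrum$intensity - object$fitted

#' Predict the fitted lineshape, optionally on a new axis
#' @param object a \code{p31_fit}.
#' @param axis optional new uniform ppm grid.
#' @param ... unused.
#' @return An \code{nmr_spectrum} of the fitted model.
#' @export
predict.p31_fit <- function(object, axis = NULL, ...) {
  if (is.null(axis)) axis <- object$spectrum$axis
  dist <- orientation_dist(object$epsilon, object$config$n_angles)
  sp <- compose_spectrum(object$components, axis, dist,
                         lb_hz = object$config$lb_hz,
                         sfrq_mhz = object$spectrum$sfrq_mhz,
                         label = paste(object$spectrum$label, "(fit)"))
  sp$intensity <- sp$intensity * object$scale
  sp
}

#' @export
plot.p31_fit <- function(x, ...) {
  s <- x$spectrum
  xlim <- rev(range(s$axis))
  graphics::plot(s$axis, s$intensity, type = "l", xlim = xlim,
                 xlab = expression(delta ~ "(ppm)"), ylab = "intensity",
                 main = s$label, ...)
  graphics::lines(s$axis, x$fitted, col = 2)
  graphics::legend("topleft", legend = c("data", "fit"), col = 1:2, lty = 1,
                   bty = "n")
  invisible(x)
}

#' Simulate replicate spectra from a fitted 31P model
#'
#' Residual-resampling parametric replicates: the fitted lineshape plus
#' residuals resampled with replacement.
#'
#' @param object a \code{p31_fit}.
#' @param nsim number of replicates.
#' @param seed RNG seed (restores the caller's RNG state afterwards).
#' @param ... unused.
#' @return list of \code{nmr_spectrum} replicates.
#' @export
simulate.p31_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
           else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  res <- residuals(object)
  lapply(seq_len(nsim), function(i) {
    out <- object$spectrum
    out$intensity <- object$fitted + sample(res, length(res), replace = TRUE)
    out$label <- sprintf("%s (replicate %d)", object$spectrum$label, i)
    out
  })
}

#' Initial CSA component guesses from a de-Paked 31P spectrum
#'
#' Deconvolves the orientational average out of the 31P powder pattern with
#' the isotropic shift pinned at the spectral first moment, then reads peak
#' positions of the oriented-like trace as candidate anisotropies via the
#' perpendicular-edge convention (edge at delta_iso - delta_sigma/3).
#'
#' @param spectrum a 31P \code{nmr_spectrum}.
#' @param n_max maximum number of candidates returned (strongest first).
#' @param linewidth_hz line width assigned to the candidates, Hz.
#' @param threshold_frac peak threshold relative to the strongest amplitude.
#' @return data.frame of [csa_component()] rows (uniform weights), strongest
#'   amplitude first.
#' @export
initial_guesses_from_depaked <- function(spectrum, n_max = 8L,
                                         linewidth_hz = 120,
                                         threshold_frac = 0.04) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (spectrum$nucleus != "31P") stop("expected a 31P spectrum")
  dec <- .depake_csa(spectrum)
  # smooth the amplitude trace so adjacent columns fuse into single peaks
  amp <- stats::filter(dec$amplitude, rep(1 / 5, 5), sides = 2)
  amp[is.na(amp)] <- 0
  pk <- .find_peaks(dec$delta_sigma, as.numeric(amp),
                    threshold_frac = threshold_frac,
                    min_sep = 3 * diff(dec$delta_sigma[1:2]))
  if (!nrow(pk)) stop("no detectable features in the de-Paked trace")
  pk <- pk[order(-pk$height), , drop = FALSE]
  pk <- utils::head(pk, n_max)
  out <- NULL
  for (i in seq_len(nrow(pk)))
    out <- rbind(out, csa_component(pk$position[i], dec$delta_iso,
                                    linewidth_hz, weight = 1,
                                    label = sprintf("cand%d", i)))
  out
}

#' Bootstrap parameter uncertainties for a converged 31P fit
#'
#' Residual-resampling bootstrap: replicate spectra are simulated from the
#' fitted model ([simulate.p31_fit()]) and refitted from the fitted
#' parameters; percentile intervals are reported per free parameter.
#'
#' @param spectrum the measured spectrum (kept for interface symmetry; the
#'   replicates are built from \code{result}).
#' @param result a converged \code{p31_fit}.
#' @param n_replicates number of bootstrap replicates, >= 10.
#' @param seed RNG seed; identical seeds give identical intervals.
#' @param level interval coverage (default 0.95).
#' @return data.frame with one row per free parameter: \code{parameter},
#'   \code{estimate}, \code{lower}, \code{upper}, \code{se}.
#' @export
bootstrap_uncertainty <- function(spectrum, result, n_replicates = 100L,
                                  seed = 1L, level = 0.95) {
  stopifnot(inherits(result, "p31_fit"))
  if (!result$converged) stop("bootstrap requires a converged fit")
  if (n_replicates < 10) stop("n_replicates must be at least 10")
  reps <- simulate(result, nsim = n_replicates, seed = seed)
  cfg <- result$config
  cfg$components <- result$components   # restart each refit at the optimum
  draws <- matrix(NA_real_, n_replicates, length(result$par),
                  dimnames = list(NULL, names(result$par)))
  for (i in seq_len(n_replicates)) {
    f <- try(fit_p31(reps[[i]], cfg, weights = result$weights), silent = TRUE)
    if (!inherits(f, "try-error")) draws[i, ] <- f$par
  }
  a <- (1 - level) / 2
  est <- result$par
  out <- data.frame(parameter = names(est), estimate = as.numeric(est),
                    lower = NA_real_, upper = NA_real_, se = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(est)) {
    v <- draws[, j]
    v <- v[is.finite(v)]
    qs <- stats::quantile(v, c(a, 1 - a), names = FALSE)
    # percentile interval, widened if needed to contain the point estimate
    out$lower[j] <- min(qs[1], est[j])
    out$upper[j] <- max(qs[2], est[j])
    out$se[j] <- stats::sd(v)
  }
  out
}

#' Write a fit report table (one column per phosphate environment)
#'
#' @param fit a \code{p31_fit}.
#' @param path optional CSV path; when given the table is written there.
#' @return data.frame with rows delta_sigma_ppm, linewidth_hz, weight and
#'   delta_iso_ppm (last), one column per component label.
#' @export
fit_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "p31_fit"))
  comps <- fit$components
  tab <- rbind(delta_sigma_ppm = comps$delta_sigma_ppm,
               linewidth_hz = comps$linewidth_hz,
               weight = comps$weight,
               delta_iso_ppm = comps$delta_iso_ppm)
  colnames(tab) <- comps$label
  df <- data.frame(quantity = rownames(tab), tab, check.names = FALSE,
                   row.names = NULL)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
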