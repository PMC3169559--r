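# local maxima above a threshold, with parabolic apex interpolation;
# returns data.frame(position, height) sorted by position
.find_peaks <- function(axis, y, threshold_frac = 0.02, min_sep = 0) {
  n <- length(y)
  thr <- threshold_frac * max(y)
  i <- which(y > thr)
  i <- i[i > 1 & i < n]
  i <- i[y[i] >= y[i - 1] & y[i] > y[i + 1]]
  if (!length(i)) return(data.frame(position = numeric(0), height = numeric(0)))
  pos <- numeric(length(i)); hgt <- numeric(length(i))
  step <- axis[2] - axis[1]
  for (k in seq_along(i)) {
    j <- i[k]
    denom <- y[j - 1] - 2 * y[j] + y[j + 1]
    delta <- if (denom < 0) 0.5 * (y[j - 1] - y[j + 1]) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    pos[k] <- axis[j] + delta * step
    hgt[k] <- y[j] - 0.25 * (y[j - 1] - y[j + 1]) * delta
  }
  df <- data.frame(position = pos, height = hgt)
  if (min_sep > 0 && nrow(df) > 1) {
    # greedily keep the taller of any pair closer than min_sep
    df <- df[order(-df$height), ]
    keep <- rep(TRUE, nrow(df))
    for (a in seq_len(nrow(df))) {
      if (!keep[a]) next
      closer <- abs(df$position - df$position[a]) < min_sep
      closer[a] <- FALSE
      keep[keep & closer] <- FALSE
    }
    df <- df[keep, ]
  }
  df[order(df$position), , drop = FALSE]
}

#' Measure quadrupolar splittings from an oriented-like spectrum
#'
#' Detects symmetric peak pairs in a de-Paked (or otherwise sharply resolved)
#' 2H spectrum, pairs them across zero, and returns the pair separations as
#' splittings in descending order. Peaks in a 90-degree-oriented spectrum sit
#' at +/- splitting/2, so the separation of a pair is the 90-degree-edge
#' quadrupolar splitting directly.
#'
#' @param oriented a 2H \code{nmr_spectrum} (typically from [depake()]).
#' @param n_expected number of doublets expected; if fewer are resolved the
#'   available ones are returned and \code{attr(, "resolved")} reports the
#'   count.
#' @param threshold_frac peak threshold as a fraction of the maximum intensity.
#' @param pair_tol_khz tolerance for pairing a peak at +nu with one at -nu;
#'   defaults to the larger of 0.5 kHz and 3 grid steps.
#' @param satellite_frac a pair whose height is below this fraction of a
#'   nearby (within \code{max(1.5, 0.08 s)} kHz) taller pair is discarded as a
#'   deconvolution side lobe.
#' @return Numeric vector of splittings (kHz), descending, with attributes
#'   \code{resolved} (number of pairs found), \code{heights} (pair mean
#'   heights) and \code{central} (intensity of any unpaired line at zero).
#' @export
measure_splittings <- function(oriented, n_expected = NULL,
                               threshold_frac = 0.06, pair_tol_khz = NULL,
                               satellite_frac = 0.25) {
  stopifnot(inherits(oriented, "nmr_spectrum"))
  step <- .uniform_step(oriented$axis, "measure_splittings")
  if (is.null(pair_tol_khz)) pair_tol_khz <- max(0.5, 3 * step)
  pk <- .find_peaks(oriented$axis, oriented$intensity,
                    threshold_frac = threshold_frac, min_sep = 2 * step)
  if (!nrow(pk)) stop("no peaks above threshold")
  pos <- pk[pk$position > pair_tol_khz / 2, , drop = FALSE]
  neg <- pk[pk$position < -pair_tol_khz / 2, , drop = FALSE]
  splittings <- numeric(0); heights <- numeric(0)
  used_neg <- rep(FALSE, nrow(neg))
  for (a in seq_len(nrow(pos))) {
    d <- abs(-neg$position - pos$position[a])
    d[used_neg] <- Inf
    if (length(d) && min(d) <= pair_tol_khz) {
      b <- which.min(d)
      used_neg[b] <- TRUE
      splittings <- c(splittings, pos$position[a] - neg$position[b])
      heights <- c(heights, (pos$height[a] + neg$height[b]) / 2)
    }
  }
  if (length(splittings) > 1) {
    keep <- rep(TRUE, length(splittings))
    for (a in seq_along(splittings)) {
      win <- max(1.5, 0.08 * splittings[a])
      near <- abs(splittings - splittings[a]) < win
      near[a] <- FALSE
      if (any(near & heights > heights[a] / satellite_frac))
        keep[a] <- FALSE
    }
    splittings <- splittings[keep]
    heights <- heights[keep]
  }
  o <- order(-splittings)
  out <- splittings[o]
  attr(out, "resolved") <- length(out)
  attr(out, "heights") <- heights[o]
  central <- pk[abs(pk$position) <= pair_tol_khz / 2, , drop = FALSE]
  attr(out, "central") <- if (nrow(central)) max(central$height) else 0
  if (!is.null(n_expected) && length(out) < n_expected)
    message("resolved ", length(out), " of ", n_expected, " expected doublets")
  out
}

#' Convert a quadrupolar splitting to a C-D bond order parameter
#'
#' Uses the 90-degree-edge convention: \code{|S_CD| = (4/3) * dnu90 / A_Q}.
#' For plateau positions the average C-D bond lies at 90 degrees to the long
#' molecular axis, so \code{2|S_CD|} is the quantity reported against the
#' bilayer normal (0 = fully disordered, 1 = rigid limit). For the terminal
#' CD3 the fast methyl rotation scales the observed splitting by
#' \code{|P2(cos 109.47 deg)| = 1/3}; \code{methyl = TRUE} multiplies the
#' mapped value by 3 to recover the chain-axis order.
#'
#' @param splitting_khz 90-degree-edge quadrupolar splitting(s), kHz, >= 0.
#' @param a_q static quadrupolar coupling constant, kHz (default 167).
#' @param methyl apply the x3 CD3 correction.
#' @return data.frame with columns \code{splitting_khz}, \code{s_cd},
#'   \code{two_s_cd}.
#' @examples
#' splitting_to_order(29.4)$two_s_cd   # 0.47
#' splitting_to_order(50.7)$two_s_cd   # 0.81
#' @export
splitting_to_order <- function(splitting_khz, a_q = AQ_KHZ, methyl = FALSE) {
  if (any(!is.finite(splitting_khz)) || any(splitting_khz < 0))
    stop("splitting_khz must be finite and >= 0")
  bound <- 0.75 * a_q / (if (methyl) 3 else 1)
  if (any(splitting_khz > bound * (1 + 1e-9)))
    stop("splitting ", max(splitting_khz), " kHz exceeds the rigid bound ",
         bound, " kHz")
  s <- (4 / 3) * splitting_khz / a_q * (if (methyl) 3 else 1)
  data.frame(splitting_khz = splitting_khz, s_cd = s, two_s_cd = 2 * s)
}

#' Inverse of [splitting_to_order()]
#'
#' @param s_cd |S_CD| value(s) in [0, 1].
#' @param a_q static quadrupolar coupling constant, kHz.
#' @param methyl invert the CD3-corrected mapping.
#' @return 90-degree-edge splitting(s), kHz.
#' @export
order_to_splitting <- function(s_cd, a_q = AQ_KHZ, methyl = FALSE) {
  if (any(s_cd < 0) || any(s_cd > 1)) stop("|S_CD| must lie in [0, 1]")
  (3 / 4) * a_q * s_cd / (if (methyl) 3 else 1)
}

#' Assemble an acyl-chain order profile from measured splittings
#'
#' Assignment rule: splittings within \code{merge_rel} of the largest are
#' merged (intensity-weighted mean if heights are available) into the plateau
#' group (positions k = 2 to 8-10); the smallest remaining splitting is the
#' terminal methyl (k = 16); intermediates are assigned to k = 11, 12, ... in
#' descending order. A profile covering fewer positions than expected is
#' returned flagged partial, never an error.
#'
#' @param splittings numeric vector of splittings, kHz (e.g. from
#'   [measure_splittings()]; its \code{heights} attribute is used for
#'   plateau weighting when present).
#' @param temperature_c temperature of the measurement, degrees C.
#' @param composition composition label carried into tables.
#' @param merge_rel relative window below the largest splitting merged into
#'   the plateau (default 0.08).
#' @param a_q static quadrupolar coupling constant, kHz.
#' @return Object of class \code{order_profile}: list with \code{entries}
#'   (data.frame position_k, splitting_khz, s_cd, two_s_cd, role),
#'   \code{plateau}, \code{methyl} (with raw and CD3-corrected order),
#'   \code{temperature_c}, \code{composition}, \code{partial}.
#' @export
assemble_order_profile <- function(splittings, temperature_c = NA_real_,
                                   composition = "", merge_rel = 0.08,
                                   a_q = AQ_KHZ) {
  if (!length(splittings)) stop("need at least one splitting")
  heights <- attr(splittings, "heights")
  o <- order(-as.numeric(splittings))
  sp <- as.numeric(splittings)[o]
  ht <- if (is.null(heights)) rep(1, length(sp)) else heights[o]
  in_plateau <- sp >= sp[1] * (1 - merge_rel)
  plateau_sp <- sum(sp[in_plateau] * ht[in_plateau]) / sum(ht[in_plateau])
  rest <- sp[!in_plateau]
  entries <- data.frame(position_k = "2-10",
                        splitting_khz = plateau_sp,
                        role = "plateau", stringsAsFactors = FALSE)
  methyl <- NULL
  if (length(rest)) {
    methyl_sp <- rest[length(rest)]
    mids <- rest[-length(rest)]
    if (length(mids)) {
      ks <- seq(11L, length.out = length(mids))
      ks <- pmin(ks, 15L)
      entries <- rbind(entries,
                       data.frame(position_k = as.character(ks),
                                  splitting_khz = mids, role = "mid",
                                  stringsAsFactors = FALSE))
    }
    entries <- rbind(entries,
                     data.frame(position_k = "16", splitting_khz = methyl_sp,
                                role = "methyl", stringsAsFactors = FALSE))
    methyl <- c(splitting_to_order(methyl_sp, a_q, methyl = FALSE),
                list(s_cd_corrected =
                       splitting_to_order(methyl_sp, a_q, methyl = TRUE)$s_cd))
  }
  ord <- splitting_to_order(entries$splitting_khz, a_q)
  entries$s_cd <- ord$s_cd
  entries$two_s_cd <- ord$two_s_cd
  partial <- length(sp) < 7
  structure(list(entries = entries,
                 plateau = list(splitting_khz = plateau_sp,
                                two_s_cd = 2 * (4 / 3) * plateau_sp / a_q),
                 methyl = methyl,
                 temperature_c = temperature_c,
                 composition = composition,
                 partial = partial, a_q = a_q),
            class = "order_profile")
}

#' @export
print.order_profile <- function(x, ...) {
  cat(sprintf("<order_profile> %s at %.4g degC%s\n",
              if (nzchar(x$composition)) x$composition else "(unlabelled)",
              x$temperature_c, if (x$partial) " [partial]" else ""))
  cat(sprintf("  plateau (k=2-10): %.3g kHz, 2|S_CD| = %.3f\n",
              x$plateau$splitting_khz, x$plateau$two_s_cd))
  if (!is.null(x$methyl))
    cat(sprintf("  methyl (k=16): %.3g kHz, |S_CD| = %.3f (chain-axis %.3f)\n",
                x$methyl$splitting_khz, x$methyl$s_cd, x$methyl$s_cd_corrected))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Thermal table of plateau order parameters
#'
#' Collates order profiles into one row per (composition, temperature), with
#' the measurement uncertainty of +/- 1 kHz on a splitting propagated linearly
#' to \code{2|S_CD|}.
#'
#' @param profiles list of [assemble_order_profile()] results.
#' @param splitting_err_khz splitting accuracy, kHz (default 1).
#' @return data.frame with columns \code{composition}, \code{temperature_c},
#'   \code{plateau_splitting_khz}, \code{splitting_err_khz}, \code{two_s_cd},
#'   \code{two_s_cd_err}.
#' @export
thermal_table <- function(profiles, splitting_err_khz = 1) {
  stopifnot(length(profiles) >= 1, all(vapply(profiles, inherits, TRUE,
                                              "order_profile")))
  rows <- lapply(profiles, function(p) {
    data.frame(composition = p$composition,
               temperature_c = p$temperature_c,
               plateau_splitting_khz = p$plateau$splitting_khz,
               splitting_err_khz = splitting_err_khz,
               two_s_cd = p$plateau$two_s_cd,
               two_s_cd_err = 2 * (4 / 3) * splitting_err_khz / p$a_q,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- paste(out$composition, out$temperature_c)
  if (anyDuplicated(key))
    stop("duplicate (composition, temperature) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  out[order(out$composition, out$temperature_c), , drop = FALSE]
}
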