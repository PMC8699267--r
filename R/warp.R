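# Retention-time alignment between two runs. Anchors are mutually
# nearest high-S/N feature pairs within the alignment tolerances; the
# warp is a penalized smoothing spline of reference RT on target RT,
# fitted after trimming anchors against a running-median offset,
# constrained to be strictly monotone and to shift no point by more
# than max_rt_shift.

# Candidate pairs within ppm and RT windows, each side's nearest match
# under a scaled Euclidean distance; keeps only mutual nearest pairs.
mutual_nearest_pairs <- function(target, reference, ppm_tol, rt_tol) {
  ord <- order(reference$mz)
  ref_mz <- reference$mz[ord]
  n_t <- nrow(target)
  best_for_t <- integer(n_t)
  dist_for_t <- rep(Inf, n_t)
  lo <- findInterval(target$mz * (1 - ppm_tol * 1e-6), ref_mz) + 1L
  hi <- findInterval(target$mz * (1 + ppm_tol * 1e-6), ref_mz)
  for (i in seq_len(n_t)) {
    if (lo[i] > hi[i]) next
    cand <- ord[lo[i]:hi[i]]
    drt <- abs(reference$rt[cand] - target$rt[i])
    ok <- drt <= rt_tol
    if (!any(ok)) next
    cand <- cand[ok]; drt <- drt[ok]
    dppm <- abs(reference$mz[cand] - target$mz[i]) /
      target$mz[i] * 1e6
    d <- sqrt((dppm / ppm_tol)^2 + (drt / rt_tol)^2)
    j <- which.min(d)
    best_for_t[i] <- cand[j]
    dist_for_t[i] <- d[j]
  }
  has <- which(best_for_t > 0L)
  if (!length(has)) return(cbind(target = integer(0), reference = integer(0)))
  # mutual: for each reference feature, keep only its closest claimant
  o <- has[order(best_for_t[has], dist_for_t[has])]
  keep <- o[!duplicated(best_for_t[o])]
  cbind(target = keep, reference = best_for_t[keep])
}

#' Estimate a retention-time warp between two runs
#'
#' Anchor pairs are mutually nearest features within `align_ppm` in m/z
#' and `max_rt_shift` in RT, with S/N at least `min_snr` on both sides.
#' The warp (target RT to reference RT) is fitted robustly: anchor
#' offsets are trimmed against a running median, a penalized smoothing
#' spline is fitted to the kept anchors, and the result is evaluated on
#' a dense grid, clamped to the `max_rt_shift` bound, forced strictly
#' monotone, and tapered to the identity outside the anchor range.
#'
#' @param target,reference Feature tables for the two runs (single run
#'   each).
#' @param cfg A [transfer_config()].
#' @param max_anchors Cap on the number of anchors used for the smooth
#'   (highest-S/N anchors kept); keeps the fit affordable on dense runs.
#' @return Object of class `rt_warp`: the warp function is applied with
#'   [predict.rt_warp()]; carries `anchors` (data.frame rt_target,
#'   rt_reference, ppm_residual) and `rt_residual` after warping.
#' @export
estimate_rt_warp <- function(target, reference, cfg = transfer_config(),
                             max_anchors = 1000) {
  stopifnot(nrow(target) > 0, nrow(reference) > 0, cfg$align_ppm > 0)
  t_ok <- target[target$snr >= cfg$min_snr, ]
  r_ok <- reference[reference$snr >= cfg$min_snr, ]
  pairs <- mutual_nearest_pairs(t_ok, r_ok, cfg$align_ppm,
                                cfg$max_rt_shift)
  if (nrow(pairs) < 5)
    stop("insufficient anchors: ", nrow(pairs), " found (need >= 5)")
  anchors <- data.frame(
    rt_target = t_ok$rt[pairs[, "target"]],
    rt_reference = r_ok$rt[pairs[, "reference"]],
    ppm_residual = (r_ok$mz[pairs[, "reference"]] -
                      t_ok$mz[pairs[, "target"]]) /
      t_ok$mz[pairs[, "target"]] * 1e6,
    snr = pmin(t_ok$snr[pairs[, "target"]],
               r_ok$snr[pairs[, "reference"]]))
  fit_anchors <- anchors
  if (nrow(fit_anchors) > max_anchors)
    fit_anchors <- fit_anchors[order(-fit_anchors$snr)[seq_len(max_anchors)], ]
  fit_anchors <- fit_anchors[order(fit_anchors$rt_target), ]

  # robustness: trim anchors against a running-median of the offset
  # (tracks sharp local drift without being pulled by wrong anchors),
  # then fit a penalized smoothing spline to the kept anchors; its
  # GCV-chosen flexibility follows the drift curvature
  off <- fit_anchors$rt_reference - fit_anchors$rt_target
  k <- min(31L, 2L * (nrow(fit_anchors) %/% 2L) - 1L)
  rmed <- if (k >= 3) stats::runmed(off, k, endrule = "median") else off
  res0 <- off - rmed
  cut <- max(0.1, 6 * stats::mad(res0))
  keep <- abs(res0) <= cut
  if (sum(keep) < 5) keep <- rep(TRUE, nrow(fit_anchors))
  kept <- fit_anchors[keep, ]
  ss <- stats::smooth.spline(kept$rt_target, kept$rt_reference,
                             cv = FALSE)
  rng <- range(fit_anchors$rt_target)
  grid <- seq(rng[1], rng[2], length.out = 512)
  offset <- stats::predict(ss, grid)$y - grid
  offset <- pmax(pmin(offset, cfg$max_rt_shift), -cfg$max_rt_shift)
  # taper to identity over one max_rt_shift beyond the anchor range
  taper <- cfg$max_rt_shift
  grid_ext <- c(rng[1] - taper, grid, rng[2] + taper)
  offset_ext <- c(0, offset, 0)
  warped <- grid_ext + offset_ext
  warped <- cummax_strict(warped)
  warp_fun <- stats::approxfun(grid_ext, warped, rule = 2)
  res <- warp_eval(warp_fun, grid_ext, anchors$rt_target) -
    anchors$rt_reference
  structure(list(fun = warp_fun, grid = grid_ext, warped = warped,
                 anchors = anchors, rt_residual = res,
                 max_rt_shift = cfg$max_rt_shift),
            class = "rt_warp")
}

# enforce strictly increasing values (ties nudged by 1e-9)
cummax_strict <- function(x) {
  x <- cummax(x)
  for (i in seq_along(x)[-1])
    if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + 1e-9
  x
}

# apply warp inside the grid; identity beyond the tapered ends
warp_eval <- function(fun, grid, t) {
  out <- t
  inside <- t >= grid[1] & t <= grid[length(grid)]
  out[inside] <- fun(t[inside])
  out
}

#' Identity warp (used for the reference run)
#' @return An `rt_warp` that maps every RT to itself.
#' @export
identity_warp <- function() {
  structure(list(fun = identity, grid = c(-Inf, Inf), warped = NULL,
                 anchors = data.frame(rt_target = numeric(0),
                                      rt_reference = numeric(0),
                                      ppm_residual = numeric(0),
                                      snr = numeric(0)),
                 rt_residual = numeric(0), max_rt_shift = 0),
            class = "rt_warp")
}

#' Apply a retention-time warp
#' @param object An `rt_warp`.
#' @param newdata Numeric vector of target-run retention times (min).
#' @param ... Unused.
#' @return Warped retention times in the reference frame.
#' @export
predict.rt_warp <- function(object, newdata, ...) {
  if (is.null(object$warped)) return(newdata)
  warp_eval(object$fun, object$grid, newdata)
}

#' @export
print.rt_warp <- function(x, ...) {
  if (is.null(x$warped)) {
    cat("Identity RT warp\n")
    return(invisible(x))
  }
  cat(sprintf("RT warp: %d anchors, RT residual SD %.3f min, ppm residual SD %.2f\n",
              nrow(x$anchors), stats::sd(x$rt_residual),
              stats::sd(x$anchors$ppm_residual)))
  invisible(x)
}

#' @export
plot.rt_warp <- function(x, ...) {
  if (is.null(x$warped)) stop("identity warp: nothing to plot")
  graphics::plot(x$anchors$rt_target, x$anchors$rt_reference - x$anchors$rt_target,
       pch = ".", xlab = "target RT (min)",
       ylab = "reference - target RT (min)",
       main = "RT alignment", ...)
  sh <- predict(x, x$grid[is.finite(x$grid)]) -
    x$grid[is.finite(x$grid)]
  graphics::lines(x$grid[is.finite(x$grid)], sh, col = 2, lwd = 2)
  invisible(x)
}
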