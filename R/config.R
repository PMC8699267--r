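#' Transfer configuration
#'
#' Bundles the tolerances and thresholds used by alignment, linking and
#' acceptance. Defaults follow common practice for Orbitrap-class data:
#' a maximum chromatographic shift of 3 minutes and a 10 ppm mass
#' tolerance for alignment anchors, a minimum feature signal-to-noise of
#' 5, and a 5% FDR threshold for accepting transfers.
#'
#' @param max_rt_shift Maximum retention-time shift (minutes) allowed
#'   between aligned runs. Anchor pairs further apart are rejected and
#'   fitted warps are clamped to this bound.
#' @param align_ppm Mass tolerance (ppm) for alignment anchor pairs.
#' @param link_rt_tol Retention-time tolerance (minutes) for consensus
#'   feature linking, or `"auto"` to derive it from the 95th percentile
#'   of anchor RT residuals (floor 0.2 min).
#' @param link_ppm Mass tolerance (ppm) for linking, or `"auto"` for the
#'   95th percentile of anchor ppm residuals (floor 5 ppm).
#' @param min_snr Minimum signal-to-noise for a feature to serve as an
#'   alignment anchor or to seed a consensus feature.
#' @param fdr_threshold q-value cutoff for accepting transfers, in (0,1).
#' @param seed Integer seed used by any randomized step downstream.
#' @return An object of class `transfer_config` (a validated list).
#' @export
transfer_config <- function(max_rt_shift = 3, align_ppm = 10,
                            link_rt_tol = "auto", link_ppm = "auto",
                            min_snr = 5, fdr_threshold = 0.05,
                            seed = 1L) {
  stopifnot(is.numeric(max_rt_shift), max_rt_shift > 0,
            is.numeric(align_ppm), align_ppm > 0,
            is.numeric(min_snr), min_snr >= 0)
  for (tol in list(link_rt_tol = link_rt_tol, link_ppm = link_ppm)) {
    if (!(identical(tol, "auto") || (is.numeric(tol) && tol > 0)))
      stop("link tolerances must be positive numbers or \"auto\"")
  }
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold >= 1)
    stop("fdr_threshold must lie in (0, 1)")
  structure(list(max_rt_shift = max_rt_shift, align_ppm = align_ppm,
                 link_rt_tol = link_rt_tol, link_ppm = link_ppm,
                 min_snr = min_snr, fdr_threshold = fdr_threshold,
                 seed = as.integer(seed)),
            class = "transfer_config")
}

#' @export
print.transfer_config <- function(x, ...) {
  cat("Transfer configuration\n")
  cat(sprintf("  max RT shift : %g min\n", x$max_rt_shift))
  cat(sprintf("  align ppm    : %g\n", x$align_ppm))
  cat(sprintf("  link RT tol  : %s\n", format(x$link_rt_tol)))
  cat(sprintf("  link ppm     : %s\n", format(x$link_ppm)))
  cat(sprintf("  min S/N      : %g\n", x$min_snr))
  cat(sprintf("  FDR threshold: %g\n", x$fdr_threshold))
  cat(sprintf("  seed         : %d\n", x$seed))
  invisible(x)
}

#' Read a flat key-value configuration file
#'
#' The file holds one `key = value` pair per line; blank lines and lines
#' starting with `#` are ignored. Keys must match [transfer_config()]
#' arguments exactly; unknown keys are an error (fail fast rather than
#' silently ignoring a typo).
#'
#' @param path Path to the configuration file.
#' @return A `transfer_config` object.
#' @export
read_transfer_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!all(grepl("=", lines, fixed = TRUE)))
    stop("malformed config line (expected key = value): ",
         lines[!grepl("=", lines, fixed = TRUE)][1])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  known <- names(formals(transfer_config))
  bad <- setdiff(keys, known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicate config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  args <- lapply(vals, function(v) {
    if (identical(v, "auto")) return("auto")
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) stop("non-numeric config value: ", v)
    num
  })
  names(args) <- keys
  do.call(transfer_config, args)
}
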