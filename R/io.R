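# TSV interchange dialects. All tables are plain tab-separated text with a
# fixed header; RT is stored in minutes (column rt_min), m/z in Thomson,
# intensities on the linear scale. Log transforms happen only in
# computations, never in files.

FEATURE_COLS <- c("run_id", "feature_id", "mz", "rt_min", "charge",
                  "intensity", "snr")
ID_COLS <- c("run_id", "psm_id", "peptide", "charge", "mz", "rt_min",
             "proteins", "qvalue")

read_tsv_checked <- function(path, expected_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          check.names = FALSE, quote = "",
                          comment.char = "")
  missing <- setdiff(expected_cols, names(df))
  extra <- setdiff(names(df), expected_cols)
  if (length(missing) || length(extra))
    stop("bad header in ", path,
         if (length(missing)) paste0("; missing column(s): ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected column(s): ",
                                   paste(extra, collapse = ", ")))
  df[, expected_cols, drop = FALSE]
}

# Parse a character column as numeric; returns values, remembering which
# rows failed so the caller can report row numbers (1-based, data rows).
parse_num <- function(x, col, bad) {
  out <- suppressWarnings(as.numeric(x))
  bad$add(which(is.na(out) & !(x %in% c("NA", ""))),
          paste0("non-numeric ", col))
  bad$add(which(x %in% c("NA", "")), paste0("missing ", col))
  out
}

violation_collector <- function() {
  rows <- integer(0); msgs <- character(0)
  list(
    add = function(idx, msg) {
      if (length(idx)) {
        rows <<- c(rows, idx)
        msgs <<- c(msgs, rep(msg, length(idx)))
      }
    },
    raise = function(path) {
      if (length(rows)) {
        ord <- order(rows)
        detail <- paste0("  row ", rows[ord], ": ", msgs[ord])
        if (length(detail) > 20)
          detail <- c(detail[1:20],
                      sprintf("  ... and %d more", length(detail) - 20))
        stop("invalid rows in ", path, ":\n",
             paste(detail, collapse = "\n"), call. = FALSE)
      }
    })
}

#' Read an MS1 feature table
#'
#' Reads a TSV with columns `run_id`, `feature_id`, `mz`, `rt_min`,
#' `charge`, `intensity`, `snr` (exactly, in any order). The whole file
#' is validated before anything is returned: rows violating the feature
#' invariants (`mz > 0`, `rt_min >= 0`, `charge >= 1`,
#' `intensity > 0`, `snr >= 0`, unique `(run_id, feature_id)`) are
#' reported with their row numbers as a single error. Rows are never
#' silently dropped.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of class `feature_table` with columns `run_id`,
#'   `feature_id` (character), `mz`, `rt` (minutes), `charge` (integer),
#'   `intensity`, `snr` (numeric).
#' @export
read_feature_table <- function(path) {
  df <- read_tsv_checked(path, FEATURE_COLS)
  bad <- violation_collector()
  mz <- parse_num(df$mz, "mz", bad)
  rt <- parse_num(df$rt_min, "rt_min", bad)
  charge <- parse_num(df$charge, "charge", bad)
  intensity <- parse_num(df$intensity, "intensity", bad)
  snr <- parse_num(df$snr, "snr", bad)
  bad$add(which(mz <= 0), "mz must be > 0")
  bad$add(which(rt < 0), "rt_min must be >= 0")
  bad$add(which(charge < 1 | charge != floor(charge)),
          "charge must be an integer >= 1")
  bad$add(which(intensity <= 0), "intensity must be > 0")
  bad$add(which(snr < 0), "snr must be >= 0")
  key <- paste(df$run_id, df$feature_id, sep = "\r")
  bad$add(which(duplicated(key)), "duplicate (run_id, feature_id)")
  bad$raise(path)
  feature_table(data.frame(run_id = df$run_id, feature_id = df$feature_id,
                           mz = mz, rt = rt, charge = as.integer(charge),
                           intensity = intensity, snr = snr,
                           stringsAsFactors = FALSE))
}

feature_table <- function(df) {
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Write an MS1 feature table
#'
#' Inverse of [read_feature_table()]; numeric fields are written with 15
#' significant digits so read/write round-trips are lossless well beyond
#' the 6 significant digits the dialect guarantees.
#'
#' @param x Feature table (as returned by [read_feature_table()] or the
#'   simulators).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  out <- data.frame(run_id = x$run_id, feature_id = x$feature_id,
                    mz = fmt_num(x$mz), rt_min = fmt_num(x$rt),
                    charge = x$charge, intensity = fmt_num(x$intensity),
                    snr = fmt_num(x$snr), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' Read a peptide identification table
#'
#' Reads a TSV with columns `run_id`, `psm_id`, `peptide`, `charge`,
#' `mz`, `rt_min`, `proteins`, `qvalue`. The `proteins` cell is a
#' semicolon-separated accession list, split preserving order; `qvalue`
#' must lie in \[0, 1\]. These identifications come from an upstream
#' MS2 search already filtered at the peptide level; the q-value is
#' consumed, not recomputed.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of class `id_table` with a list-column
#'   `proteins` and a convenience column `protein` (first accession).
#' @export
read_id_table <- function(path) {
  df <- read_tsv_checked(path, ID_COLS)
  bad <- violation_collector()
  mz <- parse_num(df$mz, "mz", bad)
  rt <- parse_num(df$rt_min, "rt_min", bad)
  charge <- parse_num(df$charge, "charge", bad)
  qvalue <- parse_num(df$qvalue, "qvalue", bad)
  bad$add(which(mz <= 0), "mz must be > 0")
  bad$add(which(rt < 0), "rt_min must be >= 0")
  bad$add(which(charge < 1 | charge != floor(charge)),
          "charge must be an integer >= 1")
  bad$add(which(qvalue < 0 | qvalue > 1), "qvalue must be in [0, 1]")
  bad$add(which(!nzchar(trimws(df$proteins))), "empty proteins field")
  bad$raise(path)
  proteins <- strsplit(df$proteins, ";", fixed = TRUE)
  id_table(data.frame(run_id = df$run_id, psm_id = df$psm_id,
                      peptide = df$peptide, charge = as.integer(charge),
                      mz = mz, rt = rt,
                      proteins = I(proteins),
                      protein = vapply(proteins, `[`, "", 1L),
                      qvalue = qvalue, stringsAsFactors = FALSE))
}

id_table <- function(df) {
  if (!"protein" %in% names(df))   # $ would partial-match "proteins"
    df$protein <- vapply(df$proteins, `[`, "", 1L)
  class(df) <- c("id_table", "data.frame")
  df
}

#' Write a peptide identification table
#'
#' @param x Identification table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_id_table <- function(x, path) {
  out <- data.frame(run_id = x$run_id, psm_id = x$psm_id,
                    peptide = x$peptide, charge = x$charge,
                    mz = fmt_num(x$mz), rt_min = fmt_num(x$rt),
                    proteins = vapply(x$proteins, paste, "",
                                      collapse = ";"),
                    qvalue = fmt_num(x$qvalue), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load reference plasma-protein intensities
#'
#' Reads a two-column TSV (`accession`, `intensity`) of previously
#' identified plasma proteins with representative MS intensities, the
#' input for the plasma-probability cumulative distribution function.
#' Duplicate accessions are collapsed by keeping the maximum intensity.
#'
#' @param path Path to the TSV file.
#' @return A list with `accessions` (character, order matching
#'   `log2_intensity` before sorting is collapsed) and `log2_intensity`
#'   (sorted ascending numeric vector of log2 intensities).
#' @export
load_reference_intensities <- function(path) {
  df <- read_tsv_checked(path, c("accession", "intensity"))
  if (nrow(df) == 0) stop("empty reference file: ", path)
  bad <- violation_collector()
  intensity <- parse_num(df$intensity, "intensity", bad)
  bad$add(which(intensity <= 0), "intensity must be > 0")
  bad$raise(path)
  collapsed <- tapply(intensity, df$accession, max)
  list(accessions = names(collapsed),
       log2_intensity = sort(as.numeric(log2(collapsed))))
}

#' Write a long protein-intensity table
#'
#' Columns `protein`, `run_id`, `intensity`; the standard output of
#' [rollup_protein_intensity()].
#'
#' @param x data.frame with columns `protein`, `run_id`, `intensity`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(x, path) {
  out <- data.frame(protein = x$protein, run_id = x$run_id,
                    intensity = fmt_num(x$intensity),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long protein-intensity table
#' @param path TSV with columns protein, run_id, intensity.
#' @return data.frame with parsed numeric intensity.
#' @export
read_intensity_table <- function(path) {
  df <- read_tsv_checked(path, c("protein", "run_id", "intensity"))
  bad <- violation_collector()
  intensity <- parse_num(df$intensity, "intensity", bad)
  bad$raise(path)
  data.frame(protein = df$protein, run_id = df$run_id,
             intensity = intensity, stringsAsFactors = FALSE)
}

#' Read a run-annotation table
#'
#' Columns `run_id` plus any of `amount` (ng loaded), `level`
#' (depletion level 1-4), `replicate`. Used by the CLI to map runs to
#' dilution points or depletion levels.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_run_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, comment.char = "")
  if (!"run_id" %in% names(df)) stop("run table needs a run_id column")
  if (anyDuplicated(df$run_id)) stop("duplicate run_id in run table")
  df
}

write_simple_tsv <- function(x, path, num_cols = NULL) {
  for (cn in intersect(num_cols, names(x))) x[[cn]] <- fmt_num(x[[cn]])
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
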