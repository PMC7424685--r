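COHORT_COLUMNS <- c("patient_id", EVG_CLASSES, "os_days", "event",
                    "tissue_her2", "manual_ctc")

#' Read a per-patient cohort table from CSV
#'
#' The documented header is `patient_id`, the six subclass count columns
#' (`r paste(EVG_CLASSES, collapse = ", ")`), `os_days`, `event`,
#' `tissue_her2` (`positive` / `negative` / `unknown`), `manual_ctc`
#' (optional). Validation failures report the offending row.
#'
#' @param path CSV file path.
#' @return An `evg_cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_col <- setdiff(setdiff(COHORT_COLUMNS, "manual_ctc"), names(df))
  if (length(missing_col) > 0L) {
    stop("cohort file lacks column(s): ", paste(missing_col, collapse = ", "))
  }
  if (!"manual_ctc" %in% names(df)) df$manual_ctc <- NA_integer_
  validate_cohort(df)
  df <- df[, COHORT_COLUMNS]
  class(df) <- c("evg_cohort", "data.frame")
  df
}

validate_cohort <- function(df) {
  dup <- which(duplicated(df$patient_id))
  if (length(dup) > 0L) {
    stop("duplicate patient_id at row ", dup[1], ": ", df$patient_id[dup[1]])
  }
  for (cl in EVG_CLASSES) {
    bad <- which(is.na(df[[cl]]) | df[[cl]] < 0 | df[[cl]] != round(df[[cl]]))
    if (length(bad) > 0L) {
      stop("invalid count in column ", cl, " at row ", bad[1],
           " (must be a non-negative integer)")
    }
  }
  bad <- which(is.na(df$os_days) != is.na(df$event))
  if (length(bad) > 0L) {
    stop("os_days and event must be present together; violated at row ", bad[1])
  }
  bad <- which(!is.na(df$os_days) & df$os_days < 0)
  if (length(bad) > 0L) stop("negative os_days at row ", bad[1])
  bad <- which(!is.na(df$event) & !df$event %in% c(0, 1))
  if (length(bad) > 0L) stop("event must be 0/1; violated at row ", bad[1])
  bad <- which(!df$tissue_her2 %in% c("positive", "negative", "unknown"))
  if (length(bad) > 0L) {
    stop("tissue_her2 must be positive/negative/unknown; violated at row ", bad[1])
  }
  invisible(df)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` restores
#' the table (numerically, to write precision). Unknown tissue status is
#' written explicitly as `"unknown"`.
#'
#' @param cohort an `evg_cohort` (or conforming data frame).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  if (!"manual_ctc" %in% names(df)) df$manual_ctc <- NA_integer_
  df$tissue_her2[is.na(df$tissue_her2)] <- "unknown"
  validate_cohort(df)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(df[, COHORT_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
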