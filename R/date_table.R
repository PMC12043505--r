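# Radiocarbon date tables: one row per laboratory determination.

DATE_TABLE_REQUIRED <- c("lab_code", "c14_age", "c14_sigma", "material")
DATE_TABLE_OPTIONAL <- c("phase_id", "context_id", "depth_m")
MATERIALS <- c("terrestrial", "marine")

#' Construct / validate a radiocarbon date table
#'
#' A date table holds one row per determination: laboratory code,
#' conventional radiocarbon age and one-sigma lab error (14C yr BP),
#' material class (`"terrestrial"` for charcoal/seed/bone dated against
#' IntCal-type curves, `"marine"` for shell dated against Marine-type
#' curves), and optional phase, context and depth fields.
#'
#' @param df A data.frame with columns `lab_code`, `c14_age`, `c14_sigma`,
#'   `material` and optionally `phase_id`, `context_id`, `depth_m`.
#' @return The validated data.frame with class `date_table`.
#' @export
date_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(DATE_TABLE_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop_bc(paste0("date table missing required column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "baychron_validation_error")
  }
  df$lab_code <- as.character(df$lab_code)
  df$c14_age <- as.numeric(df$c14_age)
  df$c14_sigma <- as.numeric(df$c14_sigma)
  df$material <- as.character(df$material)
  if (anyDuplicated(df$lab_code)) {
    stop_bc(sprintf("duplicate lab_code: %s",
                    paste(unique(df$lab_code[duplicated(df$lab_code)]),
                          collapse = ", ")),
            "baychron_validation_error")
  }
  if (any(is.na(df$c14_sigma)) || any(df$c14_sigma <= 0)) {
    stop_bc("c14_sigma must be > 0 for every row", "baychron_validation_error")
  }
  bad <- !df$material %in% MATERIALS
  if (any(bad)) {
    stop_bc(sprintf("material must be one of {%s}; got: %s",
                    paste(MATERIALS, collapse = ", "),
                    paste(unique(df$material[bad]), collapse = ", ")),
            "baychron_validation_error")
  }
  for (col in DATE_TABLE_OPTIONAL) {
    if (!col %in% names(df)) next
    if (col == "depth_m") {
      df$depth_m <- as.numeric(df$depth_m)
      if (any(df$depth_m < 0, na.rm = TRUE)) {
        stop_bc("depth_m must be >= 0 when present", "baychron_validation_error")
      }
    } else {
      df[[col]] <- as.character(df[[col]])
      df[[col]][!nzchar(df[[col]]) | is.na(df[[col]])] <- NA_character_
    }
  }
  class(df) <- c("date_table", "data.frame")
  df
}

#' Read a radiocarbon date table from delimited text
#'
#' Expects a header row naming at least `lab_code`, `c14_age`, `c14_sigma`,
#' `material`; `phase_id`, `context_id` and `depth_m` are optional and
#' stored as absent (`NA`) when missing.
#'
#' @param path Path to a delimited text file (comma default).
#' @param sep Field separator.
#' @return A [date_table].
#' @export
read_date_table <- function(path, sep = ",") {
  if (!file.exists(path)) {
    stop_bc(sprintf("date table file not found: %s", path), "baychron_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#",
                          strip.white = TRUE)
  date_table(df)
}

#' Write a date table to delimited text
#'
#' @param dates A [date_table].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_date_table <- function(dates, path, sep = ",") {
  stopifnot(inherits(dates, "date_table"))
  utils::write.table(as.data.frame(dates), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a summary table with a stable column order
#'
#' Utility writer used by the pipeline commands. Columns are emitted in
#' alphabetical order so the byte content does not depend on the order in
#' which result fields were assembled; re-reading reproduces the values.
#'
#' @param results A non-empty data.frame (or coercible list of equal-length
#'   columns).
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(results, path, sep = ",") {
  df <- as.data.frame(results, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop_bc("empty results: nothing to write", "baychron_validation_error")
  }
  df <- df[, order(names(df)), drop = FALSE]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
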