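#' Read a long-format plate-reader table into dose-response series
#'
#' Expects delimited text (comma for `.csv`, tab otherwise) with one row
#' per well and columns `pair_id`, `replicate`, `ampicillin_ug_ml`,
#' `a544`; optional `n_tmd`, `c_tmd` and `condition` columns are carried
#' as metadata. Rows are grouped by (pair, replicate) into
#' [dose_series()] objects, and every violation (missing column,
#' non-numeric dose or reading, duplicated dose within a series) is
#' reported with its file line number.
#'
#' @param path Path to the table.
#' @return Named list of `dose_series` (names `pair_id/replicate`).
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) stop("plate table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  required <- c("pair_id", "replicate", "ampicillin_ug_ml", "a544")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("plate table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  check_numeric <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    bad <- union(bad, which(is.na(raw[[col]]) | !nzchar(raw[[col]])))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric or missing `%s` at line(s): %s", col,
                   paste(line_no[sort(bad)], collapse = ", ")))
    }
    v
  }
  dose <- check_numeric("ampicillin_ug_ml")
  a544 <- check_numeric("a544")

  key <- paste(raw$pair_id, raw$replicate, sep = "/")
  dup <- duplicated(paste(key, dose))
  if (any(dup)) {
    stop("duplicate (pair, replicate, dose) row(s) at line(s): ",
         paste(line_no[dup], collapse = ", "))
  }
  series <- lapply(split(seq_len(nrow(raw)), key), function(idx) {
    cond <- if ("condition" %in% names(raw)) {
      paste(unique(raw$condition[idx]), collapse = ";")
    } else NULL
    dose_series(raw$pair_id[idx[1L]], dose[idx], a544[idx],
                replicate_id = raw$replicate[idx[1L]], condition = cond)
  })
  series[order(names(series))]
}

#' Write dose-response series to a long-format plate table
#'
#' Inverse of [read_plate_table()]; format is chosen from the file
#' extension (`.csv` comma, otherwise tab).
#'
#' @param series List of [dose_series()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(series, path) {
  stopifnot(is.list(series),
            all(vapply(series, inherits, logical(1), "dose_series")))
  tab <- do.call(rbind, lapply(series, as.data.frame))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(tab, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an isolate table
#'
#' Tab-separated list of sequenced pair isolates with columns
#' `n_position`, `n_residue`, `c_position`, `c_residue` and
#' `observed_count`; optional `n_id`, `c_id` and
#' `percent_of_reference` columns. Wild-type sides use empty/`NA`
#' position and residue. When `percent_of_reference` is present an
#' `affinity_class` column is derived via [classify_affinity()].
#'
#' @param path Path to the TSV.
#' @return A data.frame of isolated pairs.
#' @export
read_isolate_table <- function(path) {
  if (!file.exists(path)) stop("isolate table not found: ", path)
  tab <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("n_position", "n_residue", "c_position", "c_residue",
                "observed_count")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("isolate table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$n_position <- as.integer(tab$n_position)
  tab$c_position <- as.integer(tab$c_position)
  tab$n_residue <- ifelse(nzchar(tab$n_residue) & !is.na(tab$n_residue),
                          tab$n_residue, NA_character_)
  tab$c_residue <- ifelse(nzchar(tab$c_residue) & !is.na(tab$c_residue),
                          tab$c_residue, NA_character_)
  tab$observed_count <- as.integer(tab$observed_count)
  if ("percent_of_reference" %in% names(tab)) {
    tab$affinity_class <- classify_affinity(tab$percent_of_reference)
  }
  tab
}

#' Write an isolate table
#'
#' @param isolates Data.frame of isolated pairs (e.g. from
#'   [simulate_selection()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_isolate_table <- function(isolates, path) {
  utils::write.table(isolates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a key-value run configuration file
#'
#' Plain Debian-control (DCF) `Key: value` text; unknown keys are kept
#' verbatim so downstream stages can consume them. Numeric-looking
#' values are converted, and comma-separated values become vectors.
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  m <- read.dcf(path)
  if (nrow(m) != 1L) stop("config must contain exactly one record")
  vals <- lapply(as.list(m[1L, ]), function(v) {
    parts <- trimws(strsplit(v, ",")[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  vals
}
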