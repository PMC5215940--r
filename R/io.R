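#' Write an epoch series as delimited text
#'
#' One header row then one row per epoch: ISO-8601 `timestamp`, integer
#' `counts`, integer `steps`. The epoch length is recoverable from the
#' timestamp spacing.
#'
#' @param series an [epoch_series()].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_epoch_file <- function(series, path) {
  df <- data.frame(timestamp = format(series$timestamp,
                                      "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   counts = series$counts, steps = series$steps)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an epoch file into an epoch series
#'
#' Accepts the plain dialect written by [write_epoch_file()] (header
#' `timestamp,counts,steps`) and the vendor-export dialect whose first
#' lines form a device header: any leading lines before the column header
#' are skipped when detected. Gaps in the timestamp grid are filled with
#' zero-count epochs (indistinguishable from non-wear) with a warning.
#'
#' @param path file to read.
#' @param subject_id identifier; defaults to the file name without
#'   extension.
#' @return An [epoch_series()].
#' @export
read_epoch_file <- function(path, subject_id = NULL) {
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, n = 50)
  hdr <- grep("^\\s*\"?timestamp", lines, ignore.case = TRUE)[1]
  if (is.na(hdr)) stop("no 'timestamp' column header found in ", path)
  df <- utils::read.csv(path, skip = hdr - 1, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  stopifnot(all(c("timestamp", "counts") %in% names(df)))
  if (!"steps" %in% names(df)) df$steps <- 0
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts)) stop("unparseable timestamps in ", path)
  ep <- if (length(ts) > 1) min(diff(as.numeric(ts))) else 15
  grid <- seq(ts[1], ts[length(ts)], by = ep)
  if (length(grid) != length(ts)) {
    warning(length(grid) - length(ts),
            " missing epoch(s) filled with zero counts (treated as non-wear)")
    idx <- match(as.numeric(grid), as.numeric(ts))
    df <- data.frame(timestamp = grid,
                     counts = ifelse(is.na(idx), 0, df$counts[idx]),
                     steps = ifelse(is.na(idx), 0, df$steps[idx]))
    ts <- grid
  }
  epoch_series(subject_id, ts, df$counts, df$steps, epoch_length = ep)
}

#' Column mapping from canonical names to source headers
#'
#' Adapts arbitrary table headers (e.g. a deposited spreadsheet's) to the
#' canonical variable names the pipeline uses. Unmapped canonical names
#' requested by a reader raise a named error before any computation.
#'
#' @param ... `canonical = "source_header"` pairs, or a single named
#'   character vector / list.
#' @return Named character vector of class `"column_mapping"`.
#' @export
column_mapping <- function(...) {
  m <- c(...)
  m <- unlist(m)
  if (anyDuplicated(names(m))) stop("duplicate canonical names in mapping")
  structure(m, class = "column_mapping")
}

#' Read a per-subject table through a column mapping
#'
#' Reads a delimited file (or, when `readxl` is installed and the path ends
#' in `.xls`/`.xlsx`, a spreadsheet) and renames source columns to
#' canonical names. Cells that fail numeric parsing (e.g. `"n/a"`) become
#' missing, with a message counting them.
#'
#' @param path file to read.
#' @param mapping a [column_mapping()]; canonical names not found among the
#'   source headers raise an error listing the absentees.
#' @param numeric_vars canonical names coerced to numeric (default: all
#'   mapped except `subject_id`).
#' @return Data frame with canonical column names.
#' @export
read_subject_table <- function(path, mapping,
                               numeric_vars = setdiff(names(mapping),
                                                      "subject_id")) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading spreadsheets requires the 'readxl' package")
    df <- as.data.frame(readxl::read_excel(path))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  }
  absent <- mapping[!(mapping %in% names(df))]
  if (length(absent) > 0)
    stop("missing required column(s): ",
         paste0(names(absent), " (source '", absent, "')", collapse = ", "))
  out <- df[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  n_bad <- 0
  for (v in intersect(numeric_vars, names(out))) {
    raw <- out[[v]]
    num <- suppressWarnings(as.numeric(raw))
    n_bad <- n_bad + sum(is.na(num) & !is.na(raw) & trimws(raw) != "")
    out[[v]] <- num
  }
  if (n_bad > 0)
    message(n_bad, " unparseable cell(s) set to missing")
  out
}

#' Run the full pipeline on a synthetic or on-disk cohort
#'
#' Ties the stages together: reduce epoch files (when given) to subject
#' profiles, score the questionnaire table, and run the comparison battery
#' (descriptives, correlation matrix, paired and stratified bias tests,
#' Bland-Altman summaries, regression models). All outputs are returned as
#' a result bundle and, when `out_dir` is given, written as delimited
#' tables with 3-decimal minutes.
#'
#' @param table a comparison table (one row per subject, accelerometer
#'   columns prefixed `acc_`, questionnaire score columns as produced by
#'   [score_questionnaires()]); typically from
#'   [simulate_comparison_table()] or assembled via [read_subject_table()]
#'   and [reduce_cohort()].
#' @param out_dir optional directory for the delimited outputs.
#' @param strata_threshold MVPA split for the stratified bias (min/day).
#' @param offset log offset for the transformed analyses.
#' @return List of class `"actipaq_results"`: `descriptives`,
#'   `correlations`, `paired`, `stratified`, `bland_altman` (list per
#'   method pair), `regressions` (list of models).
#' @export
run_pipeline <- function(table, out_dir = NULL, strata_threshold = 60,
                         offset = 1) {
  acc_vars <- c("acc_mvpa", "acc_vigorous", "acc_moderate", "acc_light",
                "acc_sedentary", "acc_steps")
  q_vars <- intersect(c("tpaq_index", "tpaq_q5", "tpaq_q1", "ipaq_mpa",
                        "ipaq_vpa", "ipaq_mvpa", "ipaq_walking",
                        "ipaq_sedentary", "dsi_inactivity"), names(table))
  log_vars <- intersect(c(acc_vars, "tpaq_index", "ipaq_mpa", "ipaq_vpa",
                          "ipaq_mvpa", "ipaq_walking", "ipaq_sedentary",
                          "tpaq_q1"), names(table))
  res <- list()
  res$descriptives <- describe_cohort(table, c(acc_vars, "acc_wear", q_vars))
  res$correlations <- correlation_matrix(table, q_vars, acc_vars,
                                         log_vars = log_vars, offset = offset)
  pairs <- list(c("ipaq_mvpa", "acc_mvpa"),
                c("tpaq_index", "acc_mvpa"),
                c("ipaq_sedentary", "acc_sedentary"))
  pairs <- Filter(function(p) all(p %in% names(table)), pairs)
  res$paired <- do.call(rbind, lapply(pairs, function(p)
    cbind(pair = paste(p[1], "-", p[2]), paired_comparison(table, p[1], p[2]))))
  res$stratified <- if (all(c("ipaq_mvpa", "acc_mvpa") %in% names(table)))
    stratified_bias(table, "ipaq_mvpa", "acc_mvpa", "acc_mvpa",
                    threshold = strata_threshold) else NULL
  res$bland_altman <- lapply(pairs, function(p) bland_altman(table, p[1], p[2]))
  names(res$bland_altman) <- vapply(pairs, paste, "", collapse = "-")
  res$regressions <- list()
  m1 <- c("ipaq_vpa", "ipaq_mpa", "ipaq_walking", "ipaq_sedentary")
  if (all(c("acc_mvpa", m1) %in% names(table))) {
    res$regressions$model1 <- fit_mvpa_regression(table, "acc_mvpa", m1,
                                                  offset = offset)
    res$regressions$model2 <- fit_mvpa_regression(
      table, "acc_mvpa", c("ipaq_vpa", "ipaq_mpa", "ipaq_walking"),
      offset = offset)
    res$regressions$vpa_mpa <- fit_mvpa_regression(
      table, "acc_mvpa", c("ipaq_vpa", "ipaq_mpa"), offset = offset)
  }
  class(res) <- "actipaq_results"
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

# delimited output with minutes at 3 decimals
write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  num3 <- function(df) {
    for (v in names(df)) if (is.numeric(df[[v]])) df[[v]] <- round(df[[v]], 3)
    df
  }
  w <- function(df, f) utils::write.csv(num3(df), file.path(out_dir, f),
                                        row.names = FALSE)
  w(res$descriptives, "descriptives.csv")
  cm <- res$correlations
  long <- expand.grid(row = rownames(cm$r), col = colnames(cm$r),
                      stringsAsFactors = FALSE)
  long$r <- as.vector(cm$r); long$n <- as.vector(cm$n); long$p <- as.vector(cm$p)
  w(long, "correlations.csv")
  if (!is.null(res$paired)) w(res$paired, "paired_tests.csv")
  if (!is.null(res$stratified)) w(res$stratified, "stratified_bias.csv")
  ba <- do.call(rbind, lapply(names(res$bland_altman), function(nm) {
    b <- res$bland_altman[[nm]]
    data.frame(pair = nm, bias = b$bias, sd_diff = b$sd_diff,
               loa_low = b$loa_low, loa_high = b$loa_high,
               prop_bias_r = b$prop_bias_r, prop_bias_p = b$prop_bias_p,
               n = b$n)
  }))
  if (!is.null(ba)) w(ba, "bland_altman.csv")
  for (nm in names(res$bland_altman))
    w(res$bland_altman[[nm]]$data, paste0("bland_altman_points_", nm, ".csv"))
  reg <- do.call(rbind, lapply(names(res$regressions), function(nm) {
    r <- res$regressions[[nm]]
    cbind(model = nm, term = rownames(r$coefficients), r$coefficients,
          r_squared = r$r_squared, n = r$n)
  }))
  if (!is.null(reg)) w(reg, "regressions.csv")
  invisible(out_dir)
}

#' @export
print.actipaq_results <- function(x, ...) {
  cat("actipaq comparison battery\n")
  cat("- descriptives:", nrow(x$descriptives), "variables\n")
  cat("- correlations:", nrow(x$correlations$r), "x",
      ncol(x$correlations$r), "(n ", min(x$correlations$n, na.rm = TRUE),
      "-", max(x$correlations$n, na.rm = TRUE), ")\n")
  if (!is.null(x$paired)) {
    cat("- paired bias (self-report minus accelerometer):\n")
    print(x$paired, row.names = FALSE, digits = 3)
  }
  for (nm in names(x$regressions))
    cat(sprintf("- regression %s: R^2 = %.3f (N = %d)\n", nm,
                x$regressions[[nm]]$r_squared, x$regressions[[nm]]$n))
  invisible(x)
}
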