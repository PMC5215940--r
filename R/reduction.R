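#' Reduction settings for epoch-level accelerometer data
#'
#' Bundles every threshold used when turning raw count streams into daily
#' activity summaries: the counts-per-minute (cpm) cut-points separating
#' intensity classes, the zero-run length that defines non-wear, and the
#' valid-day / valid-subject rules.
#'
#' Intensity classes are lower-inclusive on the upper side:
#' sedentary `[0, cut_sed)`, light `[cut_sed, cut_mod)`, moderate
#' `[cut_mod, cut_vig)`, vigorous `[cut_vig, Inf)`, all in cpm. When
#' classifying epochs shorter than a minute the thresholds are rescaled by
#' `epoch_length / 60`.
#'
#' @param cut_sed,cut_mod,cut_vig cpm cut-points (defaults 100 / 2000 / 4000,
#'   the GT1M uniaxial thresholds for adolescents).
#' @param nonwear_zero_run minutes of consecutive zero counts that define a
#'   non-wear episode (default 20).
#' @param min_wear_per_day minutes of wear required for a valid day
#'   (default 480, i.e. 8 h).
#' @param min_valid_days valid days required for a subject to be included
#'   (default 3).
#' @param target_epoch epoch length in seconds at which classification is
#'   performed; shorter recorded epochs are reintegrated up to this
#'   (default 60).
#' @return A list of class `"reduction_config"`.
#' @export
reduction_config <- function(cut_sed = 100, cut_mod = 2000, cut_vig = 4000,
                             nonwear_zero_run = 20, min_wear_per_day = 480,
                             min_valid_days = 3, target_epoch = 60) {
  stopifnot(cut_sed > 0, cut_sed < cut_mod, cut_mod < cut_vig,
            nonwear_zero_run > 0, min_wear_per_day > 0,
            min_valid_days >= 1, target_epoch > 0)
  structure(list(cut_sed = cut_sed, cut_mod = cut_mod, cut_vig = cut_vig,
                 nonwear_zero_run = nonwear_zero_run,
                 min_wear_per_day = min_wear_per_day,
                 min_valid_days = min_valid_days,
                 target_epoch = target_epoch),
            class = "reduction_config")
}

#' Construct an epoch series
#'
#' An epoch series is one subject's ordered stream of fixed-length recording
#' intervals, each carrying an activity-count total and a step total. The
#' constructor enforces the grid invariants every downstream operation relies
#' on: strictly increasing timestamps with constant spacing equal to the
#' epoch length, and non-negative counts and steps.
#'
#' @param subject_id opaque subject identifier.
#' @param timestamp `POSIXct` vector of epoch start times.
#' @param counts integer activity counts per epoch (>= 0).
#' @param steps integer steps per epoch (>= 0); defaults to zero.
#' @param epoch_length epoch length in seconds (default 15, the device
#'   recording interval).
#' @return A data frame of class `"epoch_series"` with attributes
#'   `subject_id` and `epoch_length`.
#' @export
epoch_series <- function(subject_id, timestamp, counts, steps = NULL,
                         epoch_length = 15) {
  if (is.null(steps)) steps <- integer(length(counts))
  stopifnot(inherits(timestamp, "POSIXct"),
            length(timestamp) == length(counts),
            length(steps) == length(counts))
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts are not allowed")
  if (any(steps < 0, na.rm = TRUE)) stop("negative steps are not allowed")
  if (length(timestamp) > 1) {
    sp <- diff(as.numeric(timestamp))
    if (any(abs(sp - epoch_length) > 1e-6))
      stop("timestamps must be strictly increasing with constant spacing ",
           "equal to epoch_length (", epoch_length, " s)")
  }
  structure(data.frame(timestamp = timestamp,
                       counts = as.numeric(counts),
                       steps = as.numeric(steps)),
            subject_id = subject_id, epoch_length = epoch_length,
            class = c("epoch_series", "data.frame"))
}

#' @export
print.epoch_series <- function(x, ...) {
  cat("<epoch_series> subject", attr(x, "subject_id"),
      "-", nrow(x), "epochs of", attr(x, "epoch_length"), "s\n")
  if (nrow(x) > 0)
    cat("  ", format(x$timestamp[1]), "to", format(x$timestamp[nrow(x)]), "\n")
  invisible(x)
}

#' Reintegrate an epoch series to a longer epoch length
#'
#' Sums counts and steps over consecutive blocks so that, e.g., 15-s recorded
#' epochs become the 60-s epochs on which cpm cut-points are stated.
#' Timestamps are aligned to block starts. A trailing partial block is
#' dropped with a warning.
#'
#' @param series an [epoch_series()].
#' @param target_epoch target epoch length in seconds; must be an integer
#'   multiple of the series epoch length.
#' @return An `epoch_series` at `target_epoch` resolution.
#' @export
reintegrate_epochs <- function(series, target_epoch = 60) {
  ep <- attr(series, "epoch_length")
  if (target_epoch == ep) return(series)
  k <- target_epoch / ep
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("target_epoch (", target_epoch, " s) must be an integer multiple of ",
         "the series epoch length (", ep, " s)")
  k <- as.integer(round(k))
  n_blocks <- nrow(series) %/% k
  dropped <- nrow(series) - n_blocks * k
  if (dropped > 0)
    warning("dropping trailing partial block of ", dropped, " epoch(s)")
  if (n_blocks == 0) {
    return(epoch_series(attr(series, "subject_id"),
                        series$timestamp[0], numeric(0), numeric(0),
                        epoch_length = target_epoch))
  }
  idx <- rep(seq_len(n_blocks), each = k)
  use <- seq_len(n_blocks * k)
  epoch_series(attr(series, "subject_id"),
               series$timestamp[seq(1, by = k, length.out = n_blocks)],
               counts = as.numeric(rowsum(series$counts[use], idx)),
               steps = as.numeric(rowsum(series$steps[use], idx)),
               epoch_length = target_epoch)
}

#' Classify epoch counts into intensity classes
#'
#' Maps counts to one of sedentary / light / moderate / vigorous using cpm
#' cut-points rescaled to the epoch length. Boundaries are lower-inclusive
#' for the upper class (100 cpm is light, 2000 cpm moderate, 4000 cpm
#' vigorous).
#'
#' @param counts non-negative numeric vector of epoch counts.
#' @param epoch_length epoch length in seconds the counts were accumulated
#'   over.
#' @param cfg a [reduction_config()].
#' @return Factor with levels `sedentary`, `light`, `moderate`, `vigorous`.
#' @export
classify_epoch <- function(counts, epoch_length = 60, cfg = reduction_config()) {
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts are not allowed")
  f <- epoch_length / 60
  cut(counts,
      breaks = c(-Inf, cfg$cut_sed * f, cfg$cut_mod * f, cfg$cut_vig * f, Inf),
      labels = c("sedentary", "light", "moderate", "vigorous"),
      right = FALSE)
}

#' Detect non-wear episodes as long zero-count runs
#'
#' Scans a minute-resolution series for maximal runs of zero-count epochs
#' lasting at least `cfg$nonwear_zero_run` minutes. Shorter zero runs remain
#' wear time. Runs are detected on the whole series, so an episode crossing
#' midnight is found once and later attributed to each day by overlap.
#'
#' @param series an [epoch_series()] at minute resolution (reintegrate
#'   first).
#' @param cfg a [reduction_config()].
#' @return Data frame with one row per episode: `start`, `end` (half-open
#'   `[start, end)` `POSIXct`), `duration` in minutes.
#' @export
detect_nonwear <- function(series, cfg = reduction_config()) {
  ep <- attr(series, "epoch_length")
  empty <- data.frame(start = series$timestamp[0], end = series$timestamp[0],
                      duration = numeric(0))
  if (nrow(series) == 0) return(empty)
  r <- rle(series$counts == 0)
  len_min <- r$lengths * ep / 60
  keep <- r$values & len_min >= cfg$nonwear_zero_run
  if (!any(keep)) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = series$timestamp[starts[keep]],
             end = series$timestamp[ends[keep]] + ep,
             duration = len_min[keep])
}

#' Summarise a series into per-day wear and intensity minutes
#'
#' Works on the minute-resolution series: flags every minute falling inside
#' a detected non-wear episode, classifies the remaining (wear) minutes by
#' cpm cut-point, and aggregates by calendar date of the device's local
#' timestamps. Per day it reports wear minutes, minutes per intensity class
#' (which sum to wear minutes exactly), steps accumulated over wear minutes,
#' and the valid-day flag (`wear >= min_wear_per_day`).
#'
#' @param series an [epoch_series()] at minute resolution.
#' @param nonwear non-wear episodes from [detect_nonwear()]; computed if
#'   omitted.
#' @param cfg a [reduction_config()].
#' @return Data frame with one row per calendar day present in the series:
#'   `date`, `wear_minutes`, `sedentary`, `light`, `moderate`, `vigorous`,
#'   `steps`, `valid`.
#' @export
summarize_days <- function(series, nonwear = NULL, cfg = reduction_config()) {
  if (is.null(nonwear)) nonwear <- detect_nonwear(series, cfg)
  ep <- attr(series, "epoch_length")
  if (nrow(series) == 0)
    return(data.frame(date = as.Date(character(0)), wear_minutes = numeric(0),
                      sedentary = numeric(0), light = numeric(0),
                      moderate = numeric(0), vigorous = numeric(0),
                      steps = numeric(0), valid = logical(0)))
  minutes <- ep / 60
  nw <- rep(FALSE, nrow(series))
  if (nrow(nonwear) > 0) {
    t0 <- as.numeric(series$timestamp)
    for (i in seq_len(nrow(nonwear)))
      nw <- nw | (t0 >= as.numeric(nonwear$start[i]) &
                    t0 < as.numeric(nonwear$end[i]))
  }
  cls <- classify_epoch(series$counts, ep, cfg)
  date <- as.Date(series$timestamp, tz = attr(series$timestamp, "tzone") %||% "UTC")
  wear <- !nw
  agg <- function(v) as.numeric(rowsum(v, date))
  days <- data.frame(
    date = sort(unique(date)),
    wear_minutes = agg(wear * minutes),
    sedentary = agg((wear & cls == "sedentary") * minutes),
    light = agg((wear & cls == "light") * minutes),
    moderate = agg((wear & cls == "moderate") * minutes),
    vigorous = agg((wear & cls == "vigorous") * minutes),
    steps = agg(series$steps * wear))
  days$valid <- days$wear_minutes >= cfg$min_wear_per_day
  rownames(days) <- NULL
  days
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a subject profile of wear-time-adjusted daily minutes
#'
#' Averages valid days only. Raw mean daily minutes per class are rescaled to
#' "adjusted minutes" — `(raw / subject mean wear) * cohort mean wear` — so
#' subjects who wore the device longer do not mechanically accrue more
#' minutes. MVPA is the sum of the moderate and vigorous classes. Steps are
#' averaged over valid days without wear adjustment. A subject with fewer
#' than `min_valid_days` valid days is flagged `included = FALSE` and all
#' summaries are `NA`.
#'
#' @param days per-day summaries from [summarize_days()].
#' @param cohort_mean_wear cohort average wear time in min/day used as the
#'   adjustment target (e.g. 769.3 in the reference cohort).
#' @param cfg a [reduction_config()].
#' @param subject_id identifier copied into the result.
#' @return One-row data frame: `subject_id`, `n_valid_days`, `mean_wear`,
#'   `sedentary`, `light`, `moderate`, `vigorous`, `mvpa` (adjusted min/day),
#'   `steps_per_day`, `included`.
#' @export
build_profile <- function(days, cohort_mean_wear, cfg = reduction_config(),
                          subject_id = NA_character_) {
  stopifnot(nrow(days) >= 1, cohort_mean_wear > 0)
  v <- days[days$valid, , drop = FALSE]
  included <- nrow(v) >= cfg$min_valid_days
  if (!included || sum(v$wear_minutes) == 0) {
    return(data.frame(subject_id = subject_id, n_valid_days = nrow(v),
                      mean_wear = NA_real_, sedentary = NA_real_,
                      light = NA_real_, moderate = NA_real_,
                      vigorous = NA_real_, mvpa = NA_real_,
                      steps_per_day = NA_real_, included = FALSE))
  }
  mean_wear <- mean(v$wear_minutes)
  adj <- function(cl) mean(v[[cl]]) / mean_wear * cohort_mean_wear
  out <- data.frame(subject_id = subject_id, n_valid_days = nrow(v),
                    mean_wear = mean_wear,
                    sedentary = adj("sedentary"), light = adj("light"),
                    moderate = adj("moderate"), vigorous = adj("vigorous"),
                    mvpa = NA_real_, steps_per_day = mean(v$steps),
                    included = TRUE)
  out$mvpa <- out$moderate + out$vigorous
  out
}

#' Reduce a cohort of epoch series to subject profiles
#'
#' Runs the full reduction for each subject — reintegration to the
#' classification epoch, non-wear detection, day summaries — then computes
#' the cohort mean wear over included subjects (unless pinned via
#' `cohort_mean_wear`) and builds adjusted profiles against it.
#'
#' @param series_list list of [epoch_series()] objects, one per subject.
#' @param cfg a [reduction_config()].
#' @param cohort_mean_wear optional fixed adjustment target in min/day; when
#'   `NULL` it is the mean over included subjects of their mean daily wear.
#' @return List with `days` (per subject-day rows), `profiles` (one row per
#'   subject) and `cohort_mean_wear`.
#' @export
reduce_cohort <- function(series_list, cfg = reduction_config(),
                          cohort_mean_wear = NULL) {
  day_tabs <- lapply(series_list, function(s) {
    m <- reintegrate_epochs(s, cfg$target_epoch)
    d <- summarize_days(m, detect_nonwear(m, cfg), cfg)
    d$subject_id <- attr(s, "subject_id")
    d
  })
  days <- do.call(rbind, day_tabs)
  subj_wear <- vapply(day_tabs, function(d) {
    v <- d[d$valid, , drop = FALSE]
    if (nrow(v) >= cfg$min_valid_days) mean(v$wear_minutes) else NA_real_
  }, numeric(1))
  if (is.null(cohort_mean_wear)) {
    cohort_mean_wear <- mean(subj_wear, na.rm = TRUE)
    if (!is.finite(cohort_mean_wear))
      stop("no subject meets the valid-day rule; cannot derive cohort mean wear")
  }
  profiles <- do.call(rbind, Map(function(d, s)
    build_profile(d, cohort_mean_wear, cfg,
                  subject_id = attr(s, "subject_id")),
    day_tabs, series_list))
  rownames(profiles) <- NULL
  list(days = days, profiles = profiles, cohort_mean_wear = cohort_mean_wear)
}
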