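#' IPAQ-SF cleaning rules
#'
#' The short-form scoring protocol cleans each activity category before
#' converting to minutes per day: bouts reported below a daily minimum are
#' set to zero, and per-category daily time is truncated at a cap. Because
#' published analyses do not always state which rules were applied, each is
#' independently switchable.
#'
#' @param min_daily minimum reported min/day for a category to count
#'   (default 10; below it the category is recoded to 0).
#' @param cap_daily per-category truncation cap in min/day (default 180,
#'   i.e. 3 h).
#' @param apply_min,apply_cap logical switches for the two rules.
#' @return A list of class `"ipaq_rules"`.
#' @export
ipaq_rules <- function(min_daily = 10, cap_daily = 180,
                       apply_min = TRUE, apply_cap = TRUE) {
  structure(list(min_daily = min_daily, cap_daily = cap_daily,
                 apply_min = apply_min, apply_cap = apply_cap),
            class = "ipaq_rules")
}

#' Score the IPAQ Short Form in minutes per day
#'
#' For each activity category (vigorous, moderate, walking) the weekly
#' volume is `days * min/day` after cleaning, and the daily score is that
#' volume divided by 7. Sitting is taken directly as sedentary min/day.
#' MVPA is the sum of the moderate and vigorous scores. Missingness is
#' propagated per category, never imputed as zero; MVPA is missing if either
#' component is.
#'
#' @param resp data frame with one row per subject and columns `vig_days`,
#'   `vig_min`, `mod_days`, `mod_min`, `walk_days`, `walk_min`, `sit_min`
#'   (days in 0–7, minutes per day on active days).
#' @param rules an [ipaq_rules()] object.
#' @return Data frame with columns `walking`, `mpa`, `vpa`, `mvpa`,
#'   `sedentary`, all in min/day.
#' @export
score_ipaq_sf <- function(resp, rules = ipaq_rules()) {
  clean <- function(m) {
    if (rules$apply_cap) m <- pmin(m, rules$cap_daily)
    if (rules$apply_min) m <- ifelse(!is.na(m) & m < rules$min_daily, 0, m)
    m
  }
  daily <- function(d, m) {
    bad <- !is.na(d) & (d < 0 | d > 7)
    if (any(bad)) stop("days per week outside [0, 7]")
    if (any(!is.na(m) & m < 0)) stop("negative minutes")
    d * clean(m) / 7
  }
  out <- data.frame(walking = daily(resp$walk_days, resp$walk_min),
                    mpa = daily(resp$mod_days, resp$mod_min),
                    vpa = daily(resp$vig_days, resp$vig_min),
                    sedentary = as.numeric(resp$sit_min))
  out$mvpa <- out$mpa + out$vpa
  out[, c("walking", "mpa", "vpa", "mvpa", "sedentary")]
}

#' Derive the five TPAQ activity items
#'
#' The questionnaire's activity content is condensed into five variables:
#' `Q1` weekly minutes of walking/cycling to and from school (to-school days
#' times one-way minutes, plus the same for the way home); `Q2` weekly
#' sports-club minutes (days times minutes); `Q3` days in the past week with
#' at least 30 min of at-least-moderate activity (0–7); `Q4` indicator of
#' being active at least 30 min on at least 5 days; `Q5` daily screen time
#' coded ordinally 1–5 (none / <1 h / 2–3 h / 4–5 h / >6 h). Missing
#' components propagate to a missing item. When the yes/no answer behind
#' `Q4` is absent it defaults to `Q3 >= 5`, matching the item's wording.
#'
#' @param resp data frame with columns `school_days`, `school_min_oneway`,
#'   `home_days`, `home_min_oneway`, `club_days`, `club_min`, `active_days`,
#'   `active_5x30` (logical/0-1, optional), `screen_category`.
#' @return Data frame with columns `Q1`...`Q5`.
#' @export
derive_tpaq_items <- function(resp) {
  stopifnot(all(resp$screen_category %in% c(1:5, NA)))
  q4 <- if ("active_5x30" %in% names(resp) && !all(is.na(resp$active_5x30)))
    as.integer(resp$active_5x30) else as.integer(resp$active_days >= 5)
  data.frame(
    Q1 = resp$school_days * resp$school_min_oneway +
      resp$home_days * resp$home_min_oneway,
    Q2 = resp$club_days * resp$club_min,
    Q3 = as.numeric(resp$active_days),
    Q4 = q4,
    Q5 = as.numeric(resp$screen_category))
}

#' Fixed coefficients of the TPAQ MVPA index
#'
#' Logit-scale regression weights calibrated once against accelerometer MVPA
#' in an earlier wave of the source cohort and treated as constants here:
#' intercept and weights for Q1 (school-commute min/week), Q2 (sports-club
#' min/week), Q3 (active days), Q4 (5x30 indicator) and Q5 (screen-time
#' ordinal, negative).
#'
#' @return Named numeric vector `b0`...`b5`.
#' @export
tpaq_coefficients <- function() {
  c(b0 = -2.25476, b1 = 0.00018, b2 = 0.00023,
    b3 = 0.01543, b4 = 0.18694, b5 = -0.05822)
}

#' TPAQ MVPA index in adjusted minutes per day
#'
#' Evaluates the linear predictor `L = b0 + b1 Q1 + ... + b5 Q5` on the
#' logit scale, back-transforms with the inverse logit to a proportion of
#' the day, and multiplies by the cohort mean wear time so the result is
#' comparable with accelerometer MVPA in adjusted min/day. The index is
#' strictly inside `(0, mean_wear)`, increasing in Q1–Q4 and decreasing in
#' Q5. Any missing item yields a missing index.
#'
#' @param items data frame from [derive_tpaq_items()] with columns
#'   `Q1`...`Q5`.
#' @param coef coefficient vector as from [tpaq_coefficients()].
#' @param mean_wear cohort mean wear time in min/day (> 0).
#' @return Numeric vector of index values in min/day.
#' @export
tpaq_mvpa_index <- function(items, coef = tpaq_coefficients(), mean_wear) {
  stopifnot(mean_wear > 0,
            all(c("Q1", "Q2", "Q3", "Q4", "Q5") %in% names(items)))
  L <- coef["b0"] + coef["b1"] * items$Q1 + coef["b2"] * items$Q2 +
    coef["b3"] * items$Q3 + coef["b4"] * items$Q4 + coef["b5"] * items$Q5
  unname(mean_wear * stats::plogis(L))
}

#' Score the DSI Inactivity scale
#'
#' Sums five ordinal items, each rated 0 ("Never") to 4 ("Very often"),
#' giving a 0–20 inactivity score. Subjects with any missing item get a
#' missing score (listwise within the scale).
#'
#' @param items matrix or data frame with five columns of ratings in 0–4.
#' @return Integer vector of scores 0–20 (NA where any item is missing).
#' @export
score_dsi <- function(items) {
  m <- as.matrix(items)
  stopifnot(ncol(m) == 5)
  if (any(m < 0 | m > 4, na.rm = TRUE)) stop("DSI ratings must be in 0..4")
  as.integer(rowSums(m))
}

#' Score all questionnaires into a per-subject table
#'
#' Convenience wrapper applying [score_ipaq_sf()], [derive_tpaq_items()] +
#' [tpaq_mvpa_index()] and [score_dsi()] to a cohort's response tables.
#'
#' @param ipaq,tpaq data frames of responses (see the per-instrument
#'   scorers); `dsi` a five-column table of ratings. Any may be `NULL`.
#' @param mean_wear cohort mean wear time (min/day) for the TPAQ index.
#' @param rules an [ipaq_rules()] set.
#' @param subject_id identifier vector; taken from `ipaq$subject_id` when
#'   present.
#' @return Data frame with columns `subject_id`, `ipaq_walking`, `ipaq_mpa`,
#'   `ipaq_vpa`, `ipaq_mvpa`, `ipaq_sedentary`, `tpaq_q1`..`tpaq_q5`,
#'   `tpaq_index`, `dsi_inactivity`.
#' @export
score_questionnaires <- function(ipaq, tpaq = NULL, dsi = NULL,
                                 mean_wear, rules = ipaq_rules(),
                                 subject_id = NULL) {
  if (is.null(subject_id)) subject_id <- ipaq$subject_id
  s <- score_ipaq_sf(ipaq, rules)
  out <- data.frame(subject_id = subject_id,
                    ipaq_walking = s$walking, ipaq_mpa = s$mpa,
                    ipaq_vpa = s$vpa, ipaq_mvpa = s$mvpa,
                    ipaq_sedentary = s$sedentary)
  if (!is.null(tpaq)) {
    it <- derive_tpaq_items(tpaq)
    out$tpaq_q1 <- it$Q1; out$tpaq_q2 <- it$Q2; out$tpaq_q3 <- it$Q3
    out$tpaq_q4 <- it$Q4; out$tpaq_q5 <- it$Q5
    out$tpaq_index <- tpaq_mvpa_index(it, mean_wear = mean_wear)
  }
  if (!is.null(dsi)) out$dsi_inactivity <- score_dsi(dsi)
  out
}
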