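#' Specification of a synthetic validation cohort
#'
#' Describes the stated world the generator emulates: adolescent subjects
#' wearing an accelerometer during a waking window for a week, with
#' embedded zero-count non-wear episodes, an intensity composition matched
#' to the reference cohort's descriptives, and self-report instruments whose
#' latent log-scale correlation with objective MVPA is a planted parameter.
#'
#' Default distributional targets (mean, SD in min/day): sedentary
#' 545.2/56.1, light 167.7/39.6, moderate 37.4/15.7, vigorous 19.0/14.7,
#' MVPA 56.4/25.0, wear 769.3/108.9 — the reference cohort's accelerometer
#' block. The reporting-bias factors (0.82 below / 0.72 at-or-above the
#' 60 min/day threshold, applied to true MVPA) were chosen analytically so
#' the paired self-report-minus-accelerometer bias is near zero in the
#' less-active stratum and strongly negative in the active stratum, with an
#' overall reported mean near 43 min/day.
#'
#' @param n_subjects number of subjects (default 191).
#' @param days monitored days per subject (default 7).
#' @param epoch_length recording epoch in seconds (default 15).
#' @param wear_mean,wear_sd subject-level daily wear target (min/day).
#' @param day_wear_sd day-to-day wear jitter within subject (minutes).
#' @param p_low_wear_day probability a day is a short-wear day (wear
#'   drawn in 120–450 min, hence invalid under the 8-h rule).
#' @param class_profile data frame of per-class targets with columns
#'   `class`, `mean`, `sd` (rows sedentary, light, moderate, vigorous,
#'   mvpa).
#' @param nonwear_rate expected embedded non-wear episodes per day
#'   (Poisson, capped at 2).
#' @param nonwear_range min/max duration of an embedded episode in minutes
#'   (both >= the 20-min detection rule).
#' @param latent_rho planted correlation, on the log scale, between true
#'   MVPA and self-reported MVPA (default 0.3).
#' @param reporting_bias named factors `inactive` and `active`:
#'   multiplicative under-/over-report of MVPA below / at-or-above
#'   `active_threshold` of true MVPA.
#' @param active_threshold min/day of true MVPA separating the bias strata
#'   (default 60, the guideline value).
#' @param rho_sed correlation target between true and reported sedentary
#'   minutes.
#' @param dsi_zero_prop fraction of the cohort intended to score 0 on the
#'   inactivity scale (default 0.47).
#' @param missing_ipaq,missing_tpaq,missing_dsi per-instrument probability
#'   of a wholly missing response (defaults 0.02 / 0.02 / 0.32, mirroring
#'   the reference cohort's pairwise sample sizes).
#' @param seed integer RNG seed; every downstream draw derives from it.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 191, days = 7, epoch_length = 15,
                        wear_mean = 769.3, wear_sd = 108.9,
                        day_wear_sd = 35, p_low_wear_day = 0.05,
                        class_profile = default_class_profile(),
                        nonwear_rate = 0.7, nonwear_range = c(20, 90),
                        latent_rho = 0.3,
                        reporting_bias = c(inactive = 0.82, active = 0.72),
                        active_threshold = 60,
                        rho_sed = 0.2, dsi_zero_prop = 0.47,
                        missing_ipaq = 0.02, missing_tpaq = 0.02,
                        missing_dsi = 0.32,
                        seed = 1L) {
  stopifnot(n_subjects > 0, days > 0, latent_rho >= -1, latent_rho <= 1,
            nonwear_range[1] >= 20, nonwear_range[2] >= nonwear_range[1],
            all(c("inactive", "active") %in% names(reporting_bias)))
  cp <- class_profile
  stopifnot(all(c("sedentary", "light", "moderate", "vigorous", "mvpa") %in%
                  cp$class))
  if (sum(cp$mean[cp$class %in% c("sedentary", "light", "mvpa")]) >
      wear_mean + 3 * wear_sd)
    stop("infeasible class profile: class means exceed the wear window")
  structure(list(n_subjects = n_subjects, days = days,
                 epoch_length = epoch_length,
                 wear_mean = wear_mean, wear_sd = wear_sd,
                 day_wear_sd = day_wear_sd, p_low_wear_day = p_low_wear_day,
                 class_profile = cp, nonwear_rate = nonwear_rate,
                 nonwear_range = nonwear_range, latent_rho = latent_rho,
                 reporting_bias = reporting_bias,
                 active_threshold = active_threshold, rho_sed = rho_sed,
                 dsi_zero_prop = dsi_zero_prop,
                 missing_ipaq = missing_ipaq, missing_tpaq = missing_tpaq,
                 missing_dsi = missing_dsi,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default intensity-class targets (reference cohort descriptives)
#' @return Data frame with columns `class`, `mean`, `sd` (min/day).
#' @export
default_class_profile <- function() {
  data.frame(class = c("sedentary", "light", "moderate", "vigorous", "mvpa"),
             mean = c(545.2, 167.7, 37.4, 19.0, 56.4),
             sd = c(56.1, 39.6, 15.7, 14.7, 25.0))
}

# integer allocation by largest remainder; sum(out) == total, out >= 0
alloc_int <- function(total, weights) {
  total <- as.integer(round(total))
  if (total <= 0 || sum(weights) <= 0) return(integer(length(weights)))
  raw <- total * weights / sum(weights)
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    ord <- order(raw - out, decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1
  }
  as.integer(out)
}

#' Simulate a cohort's ground truth
#'
#' Draws, under the spec seed, every subject- and day-level planted
#' quantity: a standard-normal latent activity propensity; true MVPA as a
#' log-normal matched to the MVPA target moments (so the propensity is its
#' log z-score); sedentary/light filling the remaining wear; per-day integer
#' class minutes (largest-remainder allocation with day-level composition
#' jitter, summing exactly to the day's wear); embedded non-wear episode
#' durations; and planted daily steps from per-subject per-class step rates.
#' Also computes the subject profiles the reduction stage must recover —
#' valid-day filtering, wear adjustment against the cohort mean wear.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `"cohort_truth"`: `spec`, `subjects`, `days`,
#'   `nonwear` (planned episode durations), `profiles`,
#'   `cohort_mean_wear`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  n <- spec$n_subjects
  cp <- spec$class_profile
  tgt <- function(cl, col) cp[[col]][cp$class == cl]

  # true MVPA: log-normal with the target mean/SD; z is its log z-score
  m <- tgt("mvpa", "mean"); s <- tgt("mvpa", "sd")
  sigma2 <- log(1 + (s / m)^2)
  mu <- log(m) - sigma2 / 2
  z <- stats::rnorm(n)
  mvpa <- exp(mu + sqrt(sigma2) * z)

  # vigorous share of MVPA around the target ratio
  vr <- tgt("vigorous", "mean") / m
  share <- stats::plogis(stats::qlogis(vr) + stats::rnorm(n, 0, 0.5))
  vig <- share * mvpa
  mod <- mvpa - vig

  # subject wear, then sedentary/light filling the remainder
  wear <- stats::rnorm(n, spec$wear_mean, spec$wear_sd)
  wear <- pmin(pmax(wear, mvpa + 300), 1250)
  rem <- wear - mvpa
  f_target <- tgt("sedentary", "mean") /
    (tgt("sedentary", "mean") + tgt("light", "mean"))
  f <- pmin(pmax(f_target + stats::rnorm(n, 0, 0.045), 0.55), 0.92)
  sed <- f * rem
  light <- rem - sed

  # per-subject step rates (steps per minute in each active class)
  sr_light <- pmax(stats::rnorm(n, 30, 5), 5)
  sr_mod <- pmax(stats::rnorm(n, 45, 8), 10)
  sr_vig <- pmax(stats::rnorm(n, 60, 10), 15)

  ids <- sprintf("S%03d", seq_len(n))
  seed_base <- (spec$seed %% 1000000L) * 1000L
  subjects <- data.frame(subject_id = ids, z = z, mvpa = mvpa,
                         sedentary = sed, light = light, moderate = mod,
                         vigorous = vig, wear = wear,
                         sr_light = sr_light, sr_mod = sr_mod,
                         sr_vig = sr_vig,
                         stream_seed = seed_base + seq_len(n))

  # subject-day grid, subject-major so draws stay in a fixed order
  nd <- n * spec$days
  si <- rep(seq_len(n), each = spec$days)
  di <- rep(seq_len(spec$days), times = n)
  base_date <- as.Date("2026-01-05")

  low <- stats::runif(nd) < spec$p_low_wear_day
  w <- wear[si] + stats::rnorm(nd, 0, spec$day_wear_sd)
  w[low] <- stats::runif(sum(low), 120, 450)
  w <- as.integer(round(pmin(pmax(w, 60), 1250)))
  # day composition: subject proportions with log-scale jitter, then
  # largest-remainder integer allocation summing exactly to day wear
  props <- cbind(sed[si], light[si], mod[si], vig[si]) *
    exp(matrix(stats::rnorm(nd * 4, 0, 0.15), nd, 4))
  mins <- matrix(0L, nd, 4)
  for (r in seq_len(nd)) mins[r, ] <- alloc_int(w[r], props[r, ])
  # embedded non-wear episodes, capped so the wake block fits the day
  k <- pmin(stats::rpois(nd, spec$nonwear_rate), 2L)
  dur1 <- as.integer(round(stats::runif(nd, spec$nonwear_range[1],
                                        spec$nonwear_range[2])))
  dur2 <- as.integer(round(stats::runif(nd, spec$nonwear_range[1],
                                        spec$nonwear_range[2])))
  dur2[k < 2] <- NA; dur1[k < 1] <- NA
  dur2[!is.na(dur2) & (w + dur1 + dur2 > 1380)] <- NA
  dur1[is.na(dur2) & !is.na(dur1) & (w + dur1 > 1380)] <- NA
  n_nw <- (!is.na(dur1)) + (!is.na(dur2))
  steps <- as.integer(round(mins[, 2] * sr_light[si] +
                              mins[, 3] * sr_mod[si] +
                              mins[, 4] * sr_vig[si]))
  days <- data.frame(subject_id = ids[si], day = di,
                     date = base_date + di - 1, wear_minutes = w,
                     sedentary = mins[, 1], light = mins[, 2],
                     moderate = mins[, 3], vigorous = mins[, 4],
                     steps = steps, n_nonwear = n_nw)
  nonwear <- data.frame(
    subject_id = c(ids[si][!is.na(dur1)], ids[si][!is.na(dur2)]),
    day = c(di[!is.na(dur1)], di[!is.na(dur2)]),
    episode = c(rep(1L, sum(!is.na(dur1))), rep(2L, sum(!is.na(dur2)))),
    duration = c(dur1[!is.na(dur1)], dur2[!is.na(dur2)]))
  nonwear <- nonwear[order(match(nonwear$subject_id, ids), nonwear$day,
                           nonwear$episode), ]
  rownames(nonwear) <- NULL

  truth <- structure(list(spec = spec, subjects = subjects, days = days,
                          nonwear = nonwear),
                     class = "cohort_truth")
  truth$profiles <- truth_profiles(truth)
  truth$cohort_mean_wear <- attr(truth$profiles, "cohort_mean_wear")
  truth
}

# what the reduction stage should output, computed from planted day minutes
truth_profiles <- function(truth, cfg = reduction_config()) {
  d <- truth$days
  ids <- truth$subjects$subject_id
  v <- d[d$wear_minutes >= cfg$min_wear_per_day, , drop = FALSE]
  f <- factor(v$subject_id, levels = ids)
  nv <- as.integer(table(f))
  mean_by <- function(x) {
    s <- rowsum(x, f)
    out <- rep(NA_real_, length(ids))
    idx <- match(rownames(s), ids)
    out[idx] <- s[, 1] / nv[idx]
    out
  }
  p <- data.frame(subject_id = ids, n_valid_days = nv,
                  mean_wear = mean_by(v$wear_minutes),
                  raw_sed = mean_by(v$sedentary),
                  raw_light = mean_by(v$light),
                  raw_mod = mean_by(v$moderate),
                  raw_vig = mean_by(v$vigorous),
                  steps_per_day = mean_by(v$steps))
  p$included <- p$n_valid_days >= cfg$min_valid_days
  cmw <- mean(p$mean_wear[p$included])
  scale <- ifelse(p$included, cmw / p$mean_wear, NA_real_)
  p$sedentary <- p$raw_sed * scale
  p$light <- p$raw_light * scale
  p$moderate <- p$raw_mod * scale
  p$vigorous <- p$raw_vig * scale
  p$mvpa <- p$moderate + p$vigorous
  p$steps_per_day[!p$included] <- NA_real_
  p$mean_wear[!p$included] <- NA_real_
  rownames(p) <- NULL
  attr(p, "cohort_mean_wear") <- cmw
  p
}

# per-15s-epoch count ranges per class; minute totals land inside the
# cpm cut-point bands, and sedentary epochs are floored at 1 so wear time
# can never contain a chance zero run
.count_range <- list(sedentary = c(1, 24), light = c(25, 499),
                     moderate = c(500, 999), vigorous = c(1000, 2400))

#' Simulate one subject's epoch-level count stream
#'
#' Emits 15-s epochs covering each monitored day from midnight to midnight:
#' a contiguous wake block (planted wear minutes in shuffled class order,
#' with the planted non-wear episodes inserted at distinct interior cut
#' points so each is a maximal zero run) surrounded by overnight zeros.
#' Per-epoch counts are drawn uniformly within the class's count range;
#' planted daily steps are spread over active minutes exactly. Everything is
#' drawn under the subject's stream seed, so the stream is reproducible and
#' independent of generation order.
#'
#' @param truth a [simulate_cohort()] result.
#' @param subject_id subject to emit.
#' @return An [epoch_series()]; attribute `"planted"` carries the expected
#'   non-wear intervals (`start`, `end`, `duration`) for oracle checks.
#' @export
simulate_epoch_stream <- function(truth, subject_id) {
  spec <- truth$spec
  i <- match(subject_id, truth$subjects$subject_id)
  if (is.na(i)) stop("unknown subject: ", subject_id)
  set.seed(truth$subjects$stream_seed[i])
  epm <- as.integer(60 / spec$epoch_length)  # epochs per minute
  days <- truth$days[truth$days$subject_id == subject_id, , drop = FALSE]
  nw <- truth$nonwear[truth$nonwear$subject_id == subject_id, , drop = FALSE]

  counts_all <- steps_all <- vector("list", nrow(days))
  planted <- vector("list", nrow(days))
  for (d in seq_len(nrow(days))) {
    row <- days[d, ]
    day0 <- as.POSIXct(paste(row$date, "00:00:00"), tz = "UTC")
    cls_min <- rep(c("sedentary", "light", "moderate", "vigorous"),
                   times = c(row$sedentary, row$light, row$moderate,
                             row$vigorous))
    cls_min <- sample(cls_min)
    w <- length(cls_min)
    dur <- nw$duration[nw$day == row$day]
    total <- w + sum(dur)
    start_min <- if (total >= 1380) 30L else
      sample(seq.int(30L, 1440L - total - 30L), 1)
    # insert non-wear at distinct interior cut points (>=1 wear min apart)
    cuts <- if (length(dur) > 0) sort(sample(seq_len(w - 1), length(dur)))
    else integer(0)
    seq_cls <- character(0)
    prev <- 0L
    nw_starts <- integer(0)
    for (j in seq_along(cuts)) {
      seq_cls <- c(seq_cls, cls_min[(prev + 1):cuts[j]])
      nw_starts <- c(nw_starts, start_min + length(seq_cls))
      seq_cls <- c(seq_cls, rep("nonwear", dur[j]))
      prev <- cuts[j]
    }
    seq_cls <- c(seq_cls, cls_min[(prev + 1):w])

    day_cls <- rep("night", 1440L)
    day_cls[(start_min + 1):(start_min + total)] <- seq_cls

    cnt <- integer(1440L * epm)
    for (cl in names(.count_range)) {
      mins <- which(day_cls == cl)
      if (length(mins) == 0) next
      eidx <- rep((mins - 1L) * epm, each = epm) + seq_len(epm)
      rg <- .count_range[[cl]]
      cnt[eidx] <- sample(rg[1]:rg[2], length(eidx), replace = TRUE)
    }
    # distribute planted daily steps over active minutes, then over epochs
    stp <- integer(1440L * epm)
    act <- which(day_cls %in% c("light", "moderate", "vigorous"))
    if (length(act) > 0 && row$steps > 0) {
      wt <- c(light = 1, moderate = 1.5, vigorous = 2)[day_cls[act]]
      per_min <- alloc_int(row$steps, wt)
      for (q in seq_len(epm)) {
        sh <- per_min %/% epm + as.integer((per_min %% epm) >= q)
        stp[(act - 1L) * epm + q] <- sh
      }
    }
    counts_all[[d]] <- cnt
    steps_all[[d]] <- stp
    planted[[d]] <- if (length(dur) > 0)
      data.frame(start = day0 + nw_starts * 60,
                 end = day0 + (nw_starts + dur) * 60,
                 duration = as.numeric(dur)) else NULL
  }
  t0 <- as.POSIXct(paste(days$date[1], "00:00:00"), tz = "UTC")
  n_ep <- 1440L * epm * nrow(days)
  series <- epoch_series(subject_id,
                         t0 + (seq_len(n_ep) - 1) * spec$epoch_length,
                         counts = unlist(counts_all),
                         steps = unlist(steps_all),
                         epoch_length = spec$epoch_length)
  planted <- planted[!vapply(planted, is.null, logical(1))]
  attr(series, "planted") <- list(
    nonwear = if (length(planted)) do.call(rbind, planted) else
      data.frame(start = t0[0], end = t0[0], duration = numeric(0)),
    days = days)
  series
}

#' Simulate questionnaire responses for a cohort
#'
#' Self-reported MVPA is generated on the log scale from a bivariate-normal
#' construction: its log z-score is `rho * z + sqrt(1 - rho^2) * z'` with
#' `z` the subject's true-activity z-score, so the planted log-scale
#' correlation with true MVPA is exactly `latent_rho` (when the reporting
#' bias is a constant factor). The activity-dependent bias factor then
#' multiplies reported MVPA according to whether true MVPA is at or above
#' the active threshold. Reported MVPA is decomposed into IPAQ vigorous /
#' moderate day-and-minute answers that the scorer inverts exactly; walking
#' and sitting, the TPAQ items and the inactivity ratings are generated
#' from correlated latents with marginals near the reference cohort's
#' descriptives. Per-instrument missingness blanks whole responses.
#'
#' @param truth a [simulate_cohort()] result.
#' @param spec the cohort spec (defaults to the one inside `truth`).
#' @return List with data frames `ipaq`, `tpaq`, `dsi` (each keyed by
#'   `subject_id`) and `expected` (noise-free reported quantities kept for
#'   oracle checks: `rep_mvpa`, `rep_sedentary`).
#' @export
simulate_questionnaires <- function(truth, spec = truth$spec) {
  set.seed(spec$seed + 1L)
  n <- spec$n_subjects
  sub <- truth$subjects
  z <- sub$z
  rho <- spec$latent_rho

  cp <- spec$class_profile
  m <- cp$mean[cp$class == "mvpa"]; s <- cp$sd[cp$class == "mvpa"]
  sigma2 <- log(1 + (s / m)^2)
  mu <- log(m) - sigma2 / 2

  z2 <- stats::rnorm(n)
  z_r <- rho * z + sqrt(1 - rho^2) * z2
  bias <- ifelse(sub$mvpa >= spec$active_threshold,
                 spec$reporting_bias[["active"]],
                 spec$reporting_bias[["inactive"]])
  rep_mvpa <- bias * exp(mu + sqrt(sigma2) * z_r)

  # split reported MVPA into vigorous/moderate and invertible day/min pairs
  vshare <- stats::plogis(stats::qlogis(0.64) + stats::rnorm(n, 0, 0.6))
  rep_vpa <- vshare * rep_mvpa
  rep_mpa <- rep_mvpa - rep_vpa
  to_days_min <- function(daily) {
    dmax <- pmax(1, pmin(7, floor(daily * 7 / 10)))
    dmin <- pmax(1, pmin(7, ceiling(daily * 7 / 180)))
    d <- ifelse(dmin > dmax, dmin,
                dmin + floor(stats::runif(n) * (dmax - dmin + 1)))
    d <- ifelse(daily < 1.5, 0, d)
    list(days = as.integer(d), min = ifelse(d > 0, daily * 7 / d, 0))
  }
  vg <- to_days_min(rep_vpa)
  md <- to_days_min(rep_mpa)

  # walking: right-skewed, moderately tied to activity, occasional zeros
  z3 <- stats::rnorm(n)
  lw <- log(15) + 0.85 * (0.4 * z + sqrt(1 - 0.4^2) * z3)
  walk <- ifelse(stats::runif(n) < 0.15, 0, exp(lw))
  wk <- to_days_min(walk)

  # sitting: weakly tied to true sedentary minutes
  e_sd <- sqrt(max(107.7^2 - (spec$rho_sed * 107.7)^2, 1))
  rep_sit <- 519.2 + spec$rho_sed * 107.7 / stats::sd(sub$sedentary) *
    (sub$sedentary - mean(sub$sedentary)) + stats::rnorm(n, 0, e_sd)
  rep_sit <- round(pmin(pmax(rep_sit, 60), 1100) / 10) * 10

  ipaq <- data.frame(subject_id = sub$subject_id,
                     vig_days = vg$days, vig_min = vg$min,
                     mod_days = md$days, mod_min = md$min,
                     walk_days = wk$days, walk_min = wk$min,
                     sit_min = rep_sit)

  # TPAQ items from mildly correlated latents
  zq <- 0.5 * z + sqrt(1 - 0.5^2) * stats::rnorm(n)
  active_days <- pmin(7L, pmax(0L, as.integer(round(3.5 + 1.8 * zq))))
  z5 <- stats::rnorm(n)
  screen <- pmin(5L, pmax(1L, as.integer(round(3.3 - 0.8 *
    (0.4 * z + sqrt(1 - 0.4^2) * z5)))))
  school_days <- sample(c(0L, 3L, 5L), n, replace = TRUE,
                        prob = c(0.15, 0.15, 0.7))
  oneway <- round(exp(log(25) + 0.25 * z + stats::rnorm(n, 0, 0.7)))
  club_p <- stats::plogis(-0.2 + 0.6 * (0.5 * z + sqrt(0.75) * stats::rnorm(n)))
  club_days <- stats::rbinom(n, 5, club_p)
  club_min <- sample(c(60L, 90L, 120L), n, replace = TRUE)
  tpaq <- data.frame(subject_id = sub$subject_id,
                     school_days = school_days, school_min_oneway = oneway,
                     home_days = school_days, home_min_oneway = oneway,
                     club_days = club_days,
                     club_min = ifelse(club_days > 0, club_min, 0L),
                     active_days = active_days,
                     active_5x30 = as.integer(active_days >= 5),
                     screen_category = screen)

  # inactivity scale: zero-inflated ordinal decreasing in activity
  z6 <- stats::rnorm(n)
  u <- -0.45 * z + sqrt(1 - 0.45^2) * z6
  q0 <- stats::qnorm(spec$dsi_zero_prop)
  total <- ifelse(u < q0, 0L,
                  pmin(20L, pmax(1L, as.integer(round(6 * (u - q0))))))
  dsi <- t(vapply(total, function(tt) {
    base <- tt %/% 5L
    extra <- tt %% 5L
    it <- rep(base, 5) + sample(c(rep(1L, extra), rep(0L, 5 - extra)))
    it
  }, integer(5)))
  dsi <- as.data.frame(dsi)
  names(dsi) <- paste0("item", 1:5)
  dsi <- cbind(subject_id = sub$subject_id, dsi)

  blank <- function(df, p, cols) {
    miss <- stats::runif(n) < p
    df[miss, cols] <- NA
    df
  }
  ipaq <- blank(ipaq, spec$missing_ipaq, setdiff(names(ipaq), "subject_id"))
  tpaq <- blank(tpaq, spec$missing_tpaq, setdiff(names(tpaq), "subject_id"))
  dsi <- blank(dsi, spec$missing_dsi, setdiff(names(dsi), "subject_id"))

  list(ipaq = ipaq, tpaq = tpaq, dsi = dsi,
       expected = data.frame(subject_id = sub$subject_id,
                             rep_mvpa = rep_mvpa, rep_sedentary = rep_sit))
}

#' Build the subject-level comparison table for a synthetic cohort
#'
#' Joins the planted accelerometer profiles (what reduction recovers
#' exactly) with scored questionnaires into the one-row-per-subject table
#' the comparison battery consumes. Accelerometer columns are prefixed
#' `acc_`.
#'
#' @param truth a [simulate_cohort()] result.
#' @param quest optional [simulate_questionnaires()] result (generated if
#'   omitted).
#' @param rules IPAQ cleaning rules.
#' @return Data frame with accelerometer and questionnaire measures per
#'   subject; excluded subjects carry `NA` accelerometer values.
#' @export
simulate_comparison_table <- function(truth, quest = NULL,
                                      rules = ipaq_rules()) {
  if (is.null(quest)) quest <- simulate_questionnaires(truth)
  p <- truth$profiles
  acc <- data.frame(subject_id = p$subject_id,
                    acc_sedentary = p$sedentary, acc_light = p$light,
                    acc_moderate = p$moderate, acc_vigorous = p$vigorous,
                    acc_mvpa = p$mvpa, acc_steps = p$steps_per_day,
                    acc_wear = p$mean_wear)
  scores <- score_questionnaires(
    quest$ipaq, quest$tpaq,
    quest$dsi[, paste0("item", 1:5)],
    mean_wear = truth$cohort_mean_wear, rules = rules)
  merge(acc, scores, by = "subject_id", sort = TRUE)
}

#' Write a synthetic cohort to disk
#'
#' Emits one delimited epoch file per subject under `epochs/`, the merged
#' per-subject questionnaire table (`subjects.csv`), and a ground-truth
#' sidecar (`ground_truth_days.csv`, `ground_truth_profiles.csv`) from
#' which every planted quantity can be recovered. All files are plain text.
#'
#' @param truth a [simulate_cohort()] result.
#' @param out_dir destination directory (created if needed).
#' @param quest optional questionnaire set; generated if omitted.
#' @param subjects subset of subject ids to emit epoch files for (default
#'   all; the tables always cover the whole cohort).
#' @return Invisibly, the output directory.
#' @export
emit_dataset <- function(truth, out_dir, quest = NULL, subjects = NULL) {
  if (is.null(quest)) quest <- simulate_questionnaires(truth)
  if (is.null(subjects)) subjects <- truth$subjects$subject_id
  dir.create(file.path(out_dir, "epochs"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in subjects) {
    s <- simulate_epoch_stream(truth, id)
    write_epoch_file(s, file.path(out_dir, "epochs", paste0(id, ".csv")))
  }
  subj <- Reduce(function(a, b) merge(a, b, by = "subject_id", all = TRUE),
                 list(quest$ipaq, quest$tpaq, quest$dsi))
  utils::write.csv(subj, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$days, file.path(out_dir, "ground_truth_days.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$profiles,
                   file.path(out_dir, "ground_truth_profiles.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
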