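cfg <- reduction_config()

test_that("reintegration sums counts into complete blocks and drops the tail", {
  t0 <- as.POSIXct("2026-01-05 08:00:00", tz = "UTC")
  s <- epoch_series("a", t0 + 0:3 * 15, c(10, 20, 30, 40), c(1, 2, 3, 4))
  r <- reintegrate_epochs(s, 60)
  expect_equal(nrow(r), 1)
  expect_equal(r$counts, 100)
  expect_equal(r$steps, 10)
  expect_equal(r$timestamp, t0)

  # already at target: identity
  m <- make_series(c(5, 10, 15))
  expect_identical(reintegrate_epochs(m, 60), m)

  # 7 x 15 s -> one 60 s epoch, 3 dropped with a warning
  s7 <- epoch_series("a", t0 + 0:6 * 15, rep(1, 7))
  expect_warning(r7 <- reintegrate_epochs(s7, 60), "partial block")
  expect_equal(nrow(r7), 1)
  expect_equal(r7$counts, 4)

  expect_error(reintegrate_epochs(s, 50), "integer multiple")
})

test_that("intensity classification uses lower-inclusive cpm boundaries", {
  cls <- classify_epoch(c(0, 99, 100, 1999, 2000, 2500, 3999, 4000, 4500), 60, cfg)
  expect_equal(as.character(cls),
               c("sedentary", "sedentary", "light", "light", "moderate",
                 "moderate", "moderate", "vigorous", "vigorous"))
  # thresholds rescale with epoch length: 25 counts/15 s == 100 cpm
  expect_equal(as.character(classify_epoch(c(24, 25), 15, cfg)),
               c("sedentary", "light"))
  expect_error(classify_epoch(-1, 60, cfg), "negative")
})

test_that("non-wear detection finds maximal zero runs of at least 20 min", {
  s <- make_series(c(rep(50, 5), rep(0, 25), rep(80, 5)))
  nw <- detect_nonwear(s, cfg)
  expect_equal(nrow(nw), 1)
  expect_equal(nw$duration, 25)
  expect_equal(nw$start, s$timestamp[6])
  expect_equal(as.numeric(nw$end - nw$start, units = "mins"), 25)

  # 19 zero minutes stay wear time
  s19 <- make_series(c(rep(50, 5), rep(0, 19), rep(80, 5)))
  expect_equal(nrow(detect_nonwear(s19, cfg)), 0)

  expect_equal(nrow(detect_nonwear(make_series(rep(100, 30)), cfg)), 0)
  expect_equal(nrow(detect_nonwear(make_series(numeric(0)), cfg)), 0)
})

test_that("non-wear detection matches a brute-force run-length oracle", {
  set.seed(41)
  for (rep_i in 1:25) {
    n <- sample(50:2000, 1)
    counts <- ifelse(runif(n) < 0.45, 0, sample(1:3000, n, replace = TRUE))
    s <- make_series(counts)
    nw <- detect_nonwear(s, cfg)
    runs <- oracle_nonwear(counts, cfg$nonwear_zero_run)
    expect_equal(nrow(nw), length(runs))
    if (length(runs) > 0) {
      expect_equal(nw$start, s$timestamp[vapply(runs, `[`, 0, 1)])
      expect_equal(nw$duration,
                   vapply(runs, function(r) r[2] - r[1] + 1, 0))
    }
  }
})

test_that("day summaries conserve minutes and apply the 8-h validity rule", {
  # 600 wear minutes all sedentary
  s <- make_series(rep(50, 600))
  d <- summarize_days(s, cfg = cfg)
  expect_equal(d$wear_minutes, 600)
  expect_equal(d$sedentary, 600)
  expect_equal(d$light + d$moderate + d$vigorous, 0)
  expect_true(d$valid)

  # 400 wear minutes -> invalid day
  d4 <- summarize_days(make_series(rep(50, 400)), cfg = cfg)
  expect_false(d4$valid)

  # planted composition recovered exactly, non-wear excluded
  counts <- c(rep(150, 100), rep(0, 30), rep(2500, 50), rep(4500, 20))
  d3 <- summarize_days(make_series(counts), cfg = cfg)
  expect_equal(d3$wear_minutes, 170)
  expect_equal(d3[, c("sedentary", "light", "moderate", "vigorous")],
               data.frame(sedentary = 0, light = 100, moderate = 50,
                          vigorous = 20))
  expect_equal(d3$sedentary + d3$light + d3$moderate + d3$vigorous,
               d3$wear_minutes)
})

test_that("a non-wear run crossing midnight is excluded from both days", {
  start <- as.POSIXct("2026-01-05 23:30:00", tz = "UTC")
  counts <- c(rep(50, 15), rep(0, 30), rep(50, 15))  # 23:30 - 00:30
  s <- epoch_series("x", start + (0:59) * 60, counts, epoch_length = 60)
  nw <- detect_nonwear(s, cfg)
  expect_equal(nrow(nw), 1)
  expect_equal(nw$duration, 30)
  d <- summarize_days(s, nw, cfg)
  expect_equal(nrow(d), 2)
  expect_equal(d$wear_minutes, c(15, 15))
})

test_that("profiles adjust minutes by wear time and apply the 3-day rule", {
  day <- function(wear, mvpa, valid_wear = wear) {
    data.frame(date = Sys.Date(), wear_minutes = wear,
               sedentary = wear - mvpa, light = 0, moderate = mvpa,
               vigorous = 0, steps = 1000, valid = wear >= 480)
  }
  days <- do.call(rbind, lapply(1:3, function(i) day(600, 30)))
  p <- build_profile(days, cohort_mean_wear = 769.3, cfg, "s1")
  expect_true(p$included)
  expect_equal(p$mvpa, 30 / 600 * 769.3, tolerance = 1e-12)
  expect_equal(p$mvpa, 38.465, tolerance = 1e-9)

  # subject wear equal to the cohort mean: adjusted == raw
  p2 <- build_profile(days, cohort_mean_wear = 600, cfg, "s1")
  expect_equal(p2$moderate, 30)
  expect_equal(p2$sedentary, 570)

  # 2 valid days -> excluded, summaries missing
  p3 <- build_profile(days[1:2, ], 769.3, cfg, "s1")
  expect_false(p3$included)
  expect_true(is.na(p3$mvpa))
})

test_that("wear adjustment is invariant to proportional wear scaling", {
  base <- data.frame(date = Sys.Date() + 0:2, wear_minutes = 600,
                     sedentary = 400, light = 150, moderate = 30,
                     vigorous = 20, steps = 0, valid = TRUE)
  k <- 1.3
  scaled <- base
  for (v in c("wear_minutes", "sedentary", "light", "moderate", "vigorous"))
    scaled[[v]] <- base[[v]] * k
  p1 <- build_profile(base, 769.3, cfg)
  p2 <- build_profile(scaled, 769.3, cfg)
  for (v in c("sedentary", "light", "moderate", "vigorous", "mvpa"))
    expect_equal(p1[[v]], p2[[v]], tolerance = 1e-12)
})

test_that("raising the moderate cut-point never increases moderate minutes", {
  set.seed(11)
  counts <- sample(0:6000, 800, replace = TRUE)
  s <- make_series(counts)
  d1 <- summarize_days(s, cfg = reduction_config(cut_mod = 2000))
  d2 <- summarize_days(s, cfg = reduction_config(cut_mod = 2500))
  expect_lte(sum(d2$moderate), sum(d1$moderate))
  # planting extra vigorous epochs can only raise MVPA
  s2 <- make_series(c(counts, rep(5000, 30)))
  d3 <- summarize_days(s2, cfg = reduction_config())
  expect_gte(sum(d3$moderate + d3$vigorous), sum(d1$moderate + d1$vigorous))
})

test_that("cohort reduction derives the adjustment target from included subjects", {
  set.seed(5)
  truth <- simulate_cohort(cohort_spec(n_subjects = 4, days = 3, seed = 9))
  streams <- lapply(truth$subjects$subject_id,
                    function(id) simulate_epoch_stream(truth, id))
  red <- reduce_cohort(streams, cfg)
  expect_equal(nrow(red$profiles), 4)
  expect_equal(red$cohort_mean_wear,
               mean(red$profiles$mean_wear[red$profiles$included]))
  # pinning the cohort mean wear rescales all adjusted minutes together
  red2 <- reduce_cohort(streams, cfg, cohort_mean_wear = 700)
  r <- red2$profiles$mvpa / red$profiles$mvpa
  expect_equal(r[red$profiles$included],
               rep(700 / red$cohort_mean_wear, sum(red$profiles$included)),
               tolerance = 1e-12)
})
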