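test_that("IPAQ-SF scoring converts weekly reports to min/day", {
  resp <- data.frame(vig_days = 3, vig_min = 40, mod_days = 0, mod_min = 0,
                     walk_days = 7, walk_min = 30, sit_min = 540)
  s <- score_ipaq_sf(resp)
  expect_equal(s$vpa, 3 * 40 / 7, tolerance = 1e-12)
  expect_equal(s$mpa, 0)
  expect_equal(s$mvpa, s$vpa)
  expect_equal(s$walking, 30)
  expect_equal(s$sedentary, 540)

  zero <- data.frame(vig_days = 0, vig_min = 0, mod_days = 0, mod_min = 0,
                     walk_days = 0, walk_min = 0, sit_min = 0)
  expect_true(all(unlist(score_ipaq_sf(zero)) == 0))
})

test_that("IPAQ cleaning rules truncate at 180 and drop sub-10-minute reports", {
  resp <- data.frame(vig_days = 7, vig_min = 300, mod_days = 5, mod_min = 5,
                     walk_days = 2, walk_min = 15, sit_min = 300)
  s <- score_ipaq_sf(resp, ipaq_rules())
  expect_equal(s$vpa, 180)          # 300 capped at 180, 7 d/wk
  expect_equal(s$mpa, 0)            # 5 min/day dropped
  expect_equal(s$walking, 2 * 15 / 7, tolerance = 1e-12)

  raw <- score_ipaq_sf(resp, ipaq_rules(apply_min = FALSE, apply_cap = FALSE))
  expect_equal(raw$vpa, 300)
  expect_equal(raw$mpa, 5 * 5 / 7, tolerance = 1e-12)
})

test_that("IPAQ missingness propagates per category, never zero-filled", {
  resp <- data.frame(vig_days = NA, vig_min = NA, mod_days = 2, mod_min = 30,
                     walk_days = 3, walk_min = 20, sit_min = NA)
  s <- score_ipaq_sf(resp)
  expect_true(is.na(s$vpa))
  expect_true(is.na(s$mvpa))
  expect_equal(s$mpa, 2 * 30 / 7, tolerance = 1e-12)
  expect_true(is.na(s$sedentary))
})

test_that("IPAQ scoring is homogeneous in minutes below the cap", {
  set.seed(2)
  for (i in 1:10) {
    m <- runif(1, 10, 80)
    d <- sample(1:7, 1)
    k <- runif(1, 1, 180 / m)
    r1 <- data.frame(vig_days = d, vig_min = m, mod_days = 0, mod_min = 0,
                     walk_days = 0, walk_min = 0, sit_min = 0)
    r2 <- r1; r2$vig_min <- m * k
    expect_equal(score_ipaq_sf(r2)$vpa, k * score_ipaq_sf(r1)$vpa,
                 tolerance = 1e-12)
  }
})

test_that("TPAQ items combine commute, club, frequency and screen answers", {
  resp <- data.frame(school_days = 5, school_min_oneway = 15,
                     home_days = 5, home_min_oneway = 15,
                     club_days = 0, club_min = 0,
                     active_days = 7, active_5x30 = 1, screen_category = 3)
  it <- derive_tpaq_items(resp)
  expect_equal(it$Q1, 150)
  expect_equal(it$Q2, 0)
  expect_equal(it$Q3, 7)
  expect_equal(it$Q4, 1)
  expect_equal(it$Q5, 3)

  # Q4 falls back to the 5-days-x-30-min wording when the yes/no is absent
  resp$active_5x30 <- NA
  expect_equal(derive_tpaq_items(resp)$Q4, 1L)
  resp$active_days <- 4
  expect_equal(derive_tpaq_items(resp)$Q4, 0L)

  # missing components propagate
  resp2 <- data.frame(school_days = NA, school_min_oneway = NA,
                      home_days = 2, home_min_oneway = 10, club_days = 1,
                      club_min = 60, active_days = 3, active_5x30 = 0,
                      screen_category = 2)
  expect_true(is.na(derive_tpaq_items(resp2)$Q1))
})

test_that("TPAQ MVPA index evaluates the printed logit formula exactly", {
  items <- data.frame(Q1 = 0, Q2 = 0, Q3 = 0, Q4 = 0, Q5 = 1)
  # independent closed form: mean_wear * inverse-logit(b0 + b5)
  expect_equal(tpaq_mvpa_index(items, mean_wear = 769.3),
               769.3 * plogis(-2.25476 - 0.05822), tolerance = 1e-12)
  expect_equal(tpaq_mvpa_index(items, mean_wear = 769.3),
               69.2782753336452, tolerance = 1e-9)

  # toggling Q4 adds exactly b4 on the logit scale
  i0 <- data.frame(Q1 = 120, Q2 = 90, Q3 = 4, Q4 = 0, Q5 = 3)
  i1 <- i0; i1$Q4 <- 1
  w <- 769.3
  l0 <- qlogis(tpaq_mvpa_index(i0, mean_wear = w) / w)
  l1 <- qlogis(tpaq_mvpa_index(i1, mean_wear = w) / w)
  expect_equal(l1 - l0, 0.18694, tolerance = 1e-9)
  expect_true(is.na(tpaq_mvpa_index(data.frame(Q1 = NA, Q2 = 0, Q3 = 0,
                                               Q4 = 0, Q5 = 1),
                                    mean_wear = w)))
})

test_that("TPAQ index is bounded and monotone per coefficient sign", {
  set.seed(8)
  w <- 769.3
  grid <- data.frame(Q1 = runif(300, 0, 1000), Q2 = runif(300, 0, 800),
                     Q3 = sample(0:7, 300, TRUE), Q4 = sample(0:1, 300, TRUE),
                     Q5 = sample(1:5, 300, TRUE))
  idx <- tpaq_mvpa_index(grid, mean_wear = w)
  expect_true(all(idx > 0 & idx < w))
  for (q in c("Q1", "Q2", "Q3", "Q4")) {
    up <- grid; up[[q]] <- up[[q]] + 1
    expect_true(all(tpaq_mvpa_index(up, mean_wear = w) > idx))
  }
  up5 <- grid; up5$Q5 <- up5$Q5 + 1
  expect_true(all(tpaq_mvpa_index(up5, mean_wear = w) < idx))
})

test_that("DSI inactivity scale sums five 0-4 items with listwise missing", {
  expect_equal(score_dsi(rbind(rep(0, 5))), 0L)
  expect_equal(score_dsi(rbind(rep(4, 5))), 20L)
  expect_equal(score_dsi(rbind(c(1, 0, 2, 0, 1))), 4L)
  expect_true(is.na(score_dsi(rbind(c(1, NA, 2, 0, 1)))))
  expect_error(score_dsi(rbind(c(5, 0, 0, 0, 0))), "0..4")
})
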