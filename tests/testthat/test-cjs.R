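test_that("encounter histories are built month by month from detections", {
  roster <- make_roster(c("A", "B"), tag_date = as.Date("2016-09-10"))
  t1 <- as.POSIXct("2016-09-15 08:00:00", tz = "UTC")
  t3 <- as.POSIXct("2016-11-02 08:00:00", tz = "UTC")
  det <- rbind(make_detections(0, tag = "A", t0 = t1),
               make_detections(0, tag = "A", t0 = t3))
  hx <- build_encounter_histories(det, roster, "2016-09", n_occasions = 3)
  expect_equal(hx$h[hx$tag_id == "A", ], c(1L, 0L, 1L))
  # bird B never detected after tagging: release month still counts
  expect_equal(hx$h[hx$tag_id == "B", ], c(1L, 0L, 0L))
  expect_equal(hx$f, c(1L, 1L))
  # tagging month outside the window -> excluded with warning
  roster2 <- rbind(roster, make_roster("C", tag_date = as.Date("2018-05-01")))
  expect_warning(hx2 <- build_encounter_histories(det, roster2, "2016-09",
                                                  n_occasions = 3),
                 "outside")
  expect_equal(nrow(hx2$h), 2L)
})

test_that("histories agree with the generator's detection log month by month", {
  cfg <- colony_config(
    n_birds = list(ANNA = c(F_AHY = 8, M_HY = 8)),
    sites = list(site1 = "S1"),
    start = "2016-09-01", end = "2017-01-31",
    visit_rate = 2, phi_monthly = 0.8,
    p_detect = c(AHY = 0.9, HY = 0.4, UNKNOWN = 0.4), night_frac = 0)
  roster <- simulate_roster(cfg, 13)
  v <- simulate_visits(roster, cfg, 13)
  det <- render_detections(v, cfg, 13)
  hx <- build_encounter_histories(det, roster, "2016-09", n_occasions = 5)
  for (i in seq_len(nrow(roster))) {
    tg <- roster$tag_id[i]
    months <- format(as.Date(det$timestamp[det$tag_id == tg]), "%Y-%m")
    expected <- as.integer(hx$occasion_months %in% months)
    rel <- which(hx$occasion_months == format(roster$tag_date[i], "%Y-%m"))
    expected[rel] <- 1L
    expect_equal(unname(hx$h[hx$tag_id == tg, ]), expected)
  }
})

test_that(".inp files use the fixed group order and round-trip", {
  hx <- encounter_histories(matrix(c(1L, 0L, 1L), 1), sex = "F", adult = 1L)
  f <- withr::local_tempfile(fileext = ".inp")
  write_mark_inp(hx, f)
  expect_equal(readLines(f), "101 1 0 0 0 ;")
  set.seed(4)
  h <- matrix(rbinom(40, 1, 0.5), 10)
  h[, 1] <- 1L
  hx2 <- encounter_histories(h, sex = sample(c("F", "M"), 10, TRUE),
                             adult = rbinom(10, 1, 0.5))
  write_mark_inp(hx2, f)
  back <- read_mark_inp(f)
  expect_equal(back$h, hx2$h)
  expect_equal(back$sex, hx2$sex)
  expect_equal(back$adult, hx2$adult)
  writeLines(c("101 1 0 0 0 ;", "110 0 1 0 0"), f)
  expect_error(read_mark_inp(f), "line 2")
})

test_that("the CJS likelihood matches hand-computed path probabilities", {
  # fully observed, perfect survival/detection: probability 1
  hx <- encounter_histories(matrix(c(1L, 1L, 1L), 1))
  expect_equal(cjs_loglik(hx, 1 - 1e-12, 1 - 1e-12), 0, tolerance = 1e-9)
  # h = (1,0,1): phi * (1-p) * phi * p = .8*.5*.8*.5 = 0.16
  hx2 <- encounter_histories(matrix(c(1L, 0L, 1L), 1))
  expect_equal(cjs_loglik(hx2, 0.8, 0.5), log(0.16))
  # h = (1,0,0): chi recursion gives 0.44
  hx3 <- encounter_histories(matrix(c(1L, 0L, 0L), 1))
  expect_equal(cjs_loglik(hx3, 0.8, 0.5), log(0.44))
})

test_that("single-history probabilities sum to one over all tails (T <= 6)", {
  set.seed(66)
  for (rep in 1:6) {
    T <- sample(3:6, 1)
    phi <- runif(1, 0.2, 0.95); p <- runif(1, 0.1, 0.95)
    f <- sample.int(T - 1L, 1)
    tails <- as.matrix(expand.grid(rep(list(0:1), T - f)))
    total <- 0
    for (k in seq_len(nrow(tails))) {
      h <- c(rep(0L, f - 1L), 1L, as.integer(tails[k, ]))
      hx <- encounter_histories(matrix(h, 1))
      pr_model <- exp(cjs_loglik(hx, phi, p))
      pr_oracle <- oracle_cjs_prob(h, phi, p)
      expect_equal(pr_model, pr_oracle, tolerance = 1e-12)
      total <- total + pr_model
    }
    expect_equal(total, 1, tolerance = 1e-12)
  }
  # chi stays a probability for random parameter matrices
  h <- matrix(1L, 3, 5)
  phi <- matrix(runif(12), 3); p <- matrix(runif(12), 3)
  chi <- matrix(1, 3, 5)
  for (t in 4:1)
    chi[, t] <- (1 - phi[, t]) + phi[, t] * (1 - p[, t]) * chi[, t + 1]
  expect_true(all(chi >= 0 & chi <= 1))
})

test_that("fit_cjs recovers constant parameters and is deterministic", {
  hx <- simulate_encounter_histories(c(`F-AHY` = 250, `M-AHY` = 250),
                                     T = 10, phi = 0.7,
                                     p_by_age = c(AHY = 0.7, HY = 0.7),
                                     seed = 8)
  fit <- fit_cjs(hx, ~1, ~1)
  expect_true(fit$converged)
  phi_hat <- fit$real$estimate[fit$real$parameter == "phi"][1]
  p_hat <- fit$real$estimate[fit$real$parameter == "p"][1]
  phi_se <- fit$real$se[fit$real$parameter == "phi"][1]
  p_se <- fit$real$se[fit$real$parameter == "p"][1]
  expect_lt(abs(phi_hat - 0.7), 3 * phi_se)
  expect_lt(abs(p_hat - 0.7), 3 * p_se)
  fit2 <- fit_cjs(hx, ~1, ~1)
  expect_identical(fit$beta, fit2$beta)
  # estimator bias shrinks with n
  hx_small <- simulate_encounter_histories(c(`F-AHY` = 50), T = 10,
                                           phi = 0.7,
                                           p_by_age = c(AHY = 0.7),
                                           seed = 9)
  fit_small <- fit_cjs(hx_small, ~1, ~1)
  expect_true(fit_small$converged)
  expect_gt(fit_small$real$se[1], fit$real$se[1])
})

test_that("perfect redetection drives p to the boundary and is flagged", {
  h <- matrix(1L, 30, 6)
  hx <- encounter_histories(h)
  fit <- fit_cjs(hx, ~1, ~1)
  expect_true(fit$boundary)
  expect_gt(fit$real$estimate[fit$real$parameter == "p"][1], 0.99)
})

test_that("aicc implements the small-sample correction", {
  expect_equal(aicc(-50, 2, 33), 104 + 12 / 30)
  expect_equal(aicc(-50, 0, 33), 100)
  expect_equal(aicc(-50, 3, 1e9), -2 * -50 + 6, tolerance = 1e-6)
  expect_error(aicc(-50, 5, 6), "exceed")
})

test_that("model tables rank by AICc with normalized weights", {
  hx <- simulate_encounter_histories(
    c(`F-AHY` = 40, `F-HY` = 40, `M-AHY` = 40, `M-HY` = 40), T = 8,
    phi = 0.75, p_by_age = c(AHY = 0.9, HY = 0.4), seed = 21)
  sel <- model_selection_two_step(hx)
  for (tab in list(sel$step1, sel$step2)) {
    expect_equal(sum(tab$Weight), 1, tolerance = 1e-12)
    expect_true(all(diff(tab$AICc) >= 0))
    expect_equal(tab$dAICc[1], 0)
  }
  # the adult detection effect is strong enough to win step 1 here
  expect_match(sel$step1$Model[1], "p\\(~adult\\)")
  # nesting: the full null never beats a model containing it on logLik
  full_null <- fit_cjs(hx, ~1, ~1)
  bigger <- fit_cjs(hx, ~adult, ~adult)
  expect_lte(full_null$logLik, bigger$logLik + 1e-6)
})

test_that("step-1 selection consistently finds an adult detection effect", {
  # scaled down from a 100-replicate design to stay inside the test budget
  wins <- 0L
  for (r in 1:20) {
    hx <- simulate_encounter_histories(
      c(`F-AHY` = 50, `F-HY` = 50, `M-AHY` = 50, `M-HY` = 50), T = 13,
      phi = 0.76, p_by_age = c(AHY = 0.91, HY = 0.39), seed = 3000 + r)
    sel <- suppressWarnings(model_selection_two_step(hx))
    if (grepl("p\\(~adult\\)", sel$step1$Model[1])) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("annual survival is the 12th power of monthly survival", {
  expect_equal(round(annual_survival(0.76), 2), 0.04)
  expect_equal(annual_survival(1), 1)
  expect_equal(annual_survival(0.9), 0.9^12)
  expect_error(annual_survival(1.2), "\\[0, 1\\]")
})
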