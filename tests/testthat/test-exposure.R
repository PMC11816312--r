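# exposure events -> profiles, dose-response fitting, TU conversion

test_that("discretization maps events to the documented pulse shapes", {
  # instantaneous contact dose: constant for one dt_unit, zero thereafter
  pr <- discretize_events(exposure_events("acute_contact", 1.0, 0),
                          dt_unit = 1 / 24)
  expect_equal(pr$breakpoints, c(0, 1 / 24))
  expect_equal(pr$levels, c(1, 0))
  expect_equal(profile_at(pr, c(0, 0.02, 1 / 24, 1)), c(1, 1, 0, 0))

  # empty event list -> all-zero profile
  empty <- discretize_events(exposure_events(character(0), numeric(0),
                                             numeric(0)))
  expect_true(all(empty$levels == 0))

  # feeding window keeps its own duration
  oral <- discretize_events(exposure_events("acute_oral", 0.5, 0, 0.25))
  expect_equal(profile_at(oral, c(0.1, 0.24, 0.26)), c(0.5, 0.5, 0))

  # chronic holds the level over the requested horizon
  chr <- discretize_events(exposure_events("chronic_oral", 0.3, 0, 10),
                           horizon = 10)
  expect_equal(profile_at(chr, c(0, 5, 9.99)), rep(0.3, 3))
})

test_that("discretization preserves the area under the curve", {
  # frozen example: 0.5 TU over 6 h -> 0.125 TU d
  # midpoint Riemann sum; robust for step functions with narrow pulses
  auc <- function(pr, upper, h = 1e-5) {
    mid <- seq(h / 2, upper, by = h)
    sum(profile_at(pr, mid)) * h
  }
  oral <- discretize_events(exposure_events("acute_oral", 0.5, 0, 0.25))
  expect_equal(auc(oral, 1), 0.125, tolerance = 1e-6)

  # property: area = magnitude * max(duration, dt_unit) for random events
  set.seed(42)
  for (k in 1:20) {
    mag <- runif(1, 0.1, 5)
    t0 <- runif(1, 0, 2)
    route <- sample(c("acute_contact", "acute_oral"), 1)
    dur <- if (route == "acute_contact") 0 else runif(1, 0, 0.5)
    dur_eff <- max(dur, 1 / 24)
    pr <- discretize_events(exposure_events(route, mag, t0, t0 + dur))
    expect_equal(auc(pr, t0 + dur + 1), mag * dur_eff, tolerance = 1e-3)
  }
})

test_that("discretization rejects invalid input", {
  expect_error(exposure_events("acute_contact", -1, 0), "magnitude")
  expect_error(exposure_events("overspray", 1, 0), "unknown exposure route")
  ev <- exposure_events(c("acute_oral", "acute_oral"), c(1, 2), c(0, 0.1),
                        c(0.25, 0.3))
  expect_error(discretize_events(ev), "conflicting")
  # same-level overlap is not a conflict
  ev2 <- exposure_events(c("acute_oral", "acute_oral"), c(1, 1), c(0, 0.1),
                         c(0.25, 0.3))
  expect_silent(discretize_events(ev2))
  expect_error(
    discretize_events(exposure_events("chronic_oral", 1, 0, 10)),
    "horizon")
})

test_that("BeeGUTS preprocessing reproduces the published kinetics", {
  # contact: first-order decline at 0.4/d from application
  pr <- beeguts_preprocess(exposure_events("acute_contact", 1, 0),
                           horizon = 2)
  expect_equal(profile_at(pr, 1), exp(-0.4), tolerance = 1e-6)
  expect_equal(profile_at(pr, 2), exp(-0.8), tolerance = 1e-6)

  # oral: linear ramp over the feeding window, then 0.625/d decline
  oral <- beeguts_preprocess(exposure_events("acute_oral", 2, 0, 0.25),
                             horizon = 2, grid_step = 1 / 4800)
  expect_equal(profile_at(oral, 0.125), 1, tolerance = 1e-3)
  expect_equal(profile_at(oral, 0.25), 2, tolerance = 1e-3)
  expect_equal(profile_at(oral, 1.25), 2 * exp(-0.625), tolerance = 1e-3)

  # chronic: constant over the whole period
  chr <- beeguts_preprocess(exposure_events("chronic_oral", 0.3, 0, 10),
                            horizon = 10)
  expect_true(all(abs(profile_at(chr, seq(0, 10, 0.5)) - 0.3) < 1e-12))

  # zero magnitude -> all-zero
  z <- beeguts_preprocess(exposure_events("acute_contact", 0, 0), horizon = 1)
  expect_true(all(z$dense$c == 0))
})

test_that("log-logistic dose-response fitting recovers exact inputs", {
  conc <- c(0.5, 1, 2, 4, 8)
  surv <- log_logistic_survival(conc, lc50 = 2, slope = 3)
  fit <- fit_dose_response(conc, surv, timepoint = 2)
  expect_equal(fit$lc50, 2, tolerance = 1e-4)
  expect_equal(fit$slope, 3, tolerance = 1e-4)

  # formula anchors
  expect_equal(log_logistic_survival(2, 2, 3), 0.5)
  expect_equal(log_logistic_survival(0, 2, 3), 1)

  # binomial-likelihood route on counts
  set.seed(7)
  n0 <- rep(30, 5)
  counts <- rbinom(5, n0, log_logistic_survival(conc, 2, 3))
  fitb <- fit_dose_response(conc, counts = counts, n0 = n0, timepoint = 2)
  expect_equal(fitb$objective, "binomial")
  expect_lt(abs(log(fitb$lc50 / 2)), log(1.8))
})

test_that("dose-response fitting rejects unidentifiable data", {
  expect_error(fit_dose_response(c(1, 2), c(1, 0), timepoint = 2),
               "3 distinct")
  expect_error(
    fit_dose_response(c(1, 2, 4), c(0.8, 0.8, 0.8), timepoint = 2),
    "identical")
  expect_error(
    fit_dose_response(c(1, 2, 4), c(0.99, 0.9, 0.8), timepoint = 2),
    "extrapolation")
  expect_silent(
    fit_dose_response(c(1, 2, 4), c(0.99, 0.9, 0.8), timepoint = 2,
                      allow_extrapolation = TRUE))
})

test_that("TU conversion scales, round-trips and rejects double conversion", {
  pr <- exposure_profile(c(0, 1), c(0.5, 2.0), unit = "ug/bee",
                         is_toxic_units = FALSE)
  tu <- to_toxic_units(pr, 2.0)
  expect_equal(tu$levels, c(0.25, 1.0))
  expect_true(tu$is_toxic_units)
  expect_error(to_toxic_units(tu, 2.0), "already")

  back <- from_toxic_units(tu, 2.0, unit = "ug/bee")
  expect_equal(back$levels, pr$levels)
  expect_error(from_toxic_units(back, 2.0), "not in toxic units")

  # round trip on random profiles
  set.seed(3)
  for (k in 1:10) {
    bp <- cumsum(runif(4, 0.1, 2)); bp <- c(0, bp)
    lv <- c(runif(4, 0, 5), 0)
    p0 <- exposure_profile(bp, lv, unit = "mg/kg", is_toxic_units = FALSE)
    lc <- runif(1, 0.1, 10)
    rt <- from_toxic_units(to_toxic_units(p0, lc), lc, unit = "mg/kg")
    expect_equal(rt$levels, p0$levels, tolerance = 1e-12)
  }
})

test_that("TU conversion is a linear bijection of model predictions", {
  # TU-system predictions == raw-system predictions with back-scaled
  # thresholds (z, alpha scale with LC50; b_kill scales with 1/LC50)
  lc50 <- 2.5
  raw <- pulse_profile(level = 4 * lc50)
  tu <- to_toxic_units(
    exposure_profile(raw$breakpoints, raw$levels, unit = "ug/bee",
                     is_toxic_units = FALSE), lc50)
  t_obs <- c(0.25, 1, 2, 4)

  s_tu <- solve_tktd("BUFFER_SD", sd_params(z = 0.2, b_kill = 2), tu,
                     t_obs, horizon = 4)$S_obs
  s_raw <- solve_tktd("BUFFER_SD",
                      sd_params(z = 0.2 * lc50, b_kill = 2 / lc50), raw,
                      t_obs, horizon = 4)$S_obs
  expect_equal(s_tu, s_raw, tolerance = 1e-12)

  s_tu_it <- solve_tktd("BUFFER_IT", it_params(alpha = 0.3, beta = 2), tu,
                        t_obs, horizon = 4)$S_obs
  s_raw_it <- solve_tktd("BUFFER_IT",
                         it_params(alpha = 0.3 * lc50, beta = 2), raw,
                         t_obs, horizon = 4)$S_obs
  expect_equal(s_tu_it, s_raw_it, tolerance = 1e-12)
})

test_that("halving the discretization unit barely moves predictions", {
  # the buffer is filled instantly, so for BufferGUTS the pulse duration
  # only shifts the start of the decline by half an hour
  ev <- exposure_events("acute_contact", 2, 0)
  t_obs <- c(0.25, 1, 2, 4)
  for (model in c("BUFFER_SD", "BUFFER_IT")) {
    p <- params_for(model)
    s1 <- solve_tktd(model, p, discretize_events(ev, dt_unit = 1 / 24),
                     t_obs, horizon = 4)$S_obs
    s2 <- solve_tktd(model, p, discretize_events(ev, dt_unit = 1 / 48),
                     t_obs, horizon = 4)$S_obs
    expect_lt(max(abs(s1 - s2)), 0.02)
  }
})
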