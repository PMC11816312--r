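# likelihood, priors, sampler, posterior prediction

make_curve_dataset <- function(times, counts, n0 = 10, level = 1) {
  data <- data.frame(treatment = "T1", replicate = "R1",
                     time_days = times, n_alive = counts, n_initial = n0)
  survival_dataset(data, list(T1 = pulse_profile(level)))
}

test_that("dataset validation enforces count invariants", {
  expect_error(make_curve_dataset(c(1, 2), c(5, 7)), "increase")
  expect_error(make_curve_dataset(c(1, 2), c(12, 5)), "n_alive")
  d <- data.frame(treatment = "T9", replicate = "R1", time_days = 1,
                  n_alive = 5, n_initial = 10)
  expect_error(survival_dataset(d, list(T1 = pulse_profile(1))),
               "no exposure defined")
  ds <- make_curve_dataset(c(1, 2), c(8, 6))
  expect_length(control_treatments(ds), 0)
})

test_that("likelihood matches direct binomial evaluation", {
  # S == 1 everywhere, no deaths -> log-likelihood 0 (certain event)
  ds0 <- make_curve_dataset(c(1, 2), c(10, 10))
  ll0 <- log_likelihood(ds0, list(T1 = list(times = c(1, 2), S = c(1, 1))))
  expect_equal(ll0, 0)

  # one interval, n0 = 10, S(t1) = 0.8, 8 alive:
  # log[ C(10,2) 0.8^8 0.2^2 ]
  ds1 <- make_curve_dataset(1, 8)
  ll1 <- log_likelihood(ds1, list(T1 = list(times = 1, S = 0.8)))
  expect_equal(ll1, log(choose(10, 2) * 0.8^8 * 0.2^2), tolerance = 1e-12)

  # collapsing two intervals into one changes the likelihood unless the
  # path is degenerate
  ds2 <- make_curve_dataset(c(1, 2), c(8, 6))
  s_path <- list(T1 = list(times = c(1, 2), S = c(0.8, 0.5)))
  ll2 <- log_likelihood(ds2, s_path)
  ds2c <- make_curve_dataset(2, 6)
  ll2c <- log_likelihood(ds2c, list(T1 = list(times = 2, S = 0.5)))
  expect_false(isTRUE(all.equal(ll2, ll2c)))
})

test_that("likelihood equals brute-force enumeration over individual fates",
{
  # every bee independently dies in interval 1 (p1), interval 2 (p2) or
  # survives (ps); enumerate all 3^n0 fate assignments
  brute_force <- function(S, counts, n0) {
    p <- c(1 - S[1], S[1] - S[2], S[2])
    fates <- expand.grid(rep(list(1:3), n0))
    prob <- 0
    for (r in seq_len(nrow(fates))) {
      f <- as.integer(fates[r, ])
      n1 <- sum(f != 1)            # alive after interval 1
      n2 <- sum(f == 3)            # alive at the end
      if (n1 == counts[1] && n2 == counts[2]) {
        prob <- prob + prod(p[f])
      }
    }
    log(prob)
  }
  S <- c(0.75, 0.4)
  for (n0 in 1:3) {
    for (c1 in 0:n0) {
      for (c2 in 0:c1) {
        ds <- make_curve_dataset(c(1, 2), c(c1, c2), n0 = n0)
        ll <- log_likelihood(ds, list(T1 = list(times = c(1, 2), S = S)))
        expect_equal(ll, brute_force(S, c(c1, c2), n0), tolerance = 1e-10)
      }
    }
  }
})

test_that("preliminary fit yields in-range priors and sane centres", {
  ds <- tiny_dataset(seed = 5)
  suppressWarnings(
    prior <- preliminary_fit("BUFFER_SD", ds, fast_settings(seed = 5)))
  expect_s3_class(prior, "tktd_prior")
  if (prior$type == "lognormal") {
    expect_true(all(prior$mu >= log(1e-10) & prior$mu <= log(1e3)))
    # preliminary medians within an order of magnitude of truth for the
    # well-identified kinetics parameter
    expect_lt(abs(prior$mu[1] - log(0.5)), log(10))
  }
})

test_that("degenerate all-survive data falls back to broad priors", {
  data <- expand.grid(replicate = c("R1", "R2"), time_days = 1:5)
  data$treatment <- "control"
  data$n_alive <- 10L
  data$n_initial <- 10L
  ds <- survival_dataset(data, list(control = exposure_profile(0, 0)))
  expect_warning(
    prior <- preliminary_fit("BUFFER_SD", ds,
                             fast_settings(n_tune = 200, n_draw = 200)),
    "broad priors")
  expect_equal(prior$type, "loguniform")
})

test_that("control-only data concentrates hb near its analytic MLE", {
  # 100 bees over 5 d, 13 deaths: MLE hb = -log(87/100)/5
  set.seed(11)
  true_hb <- 0.03
  n0 <- 50
  t_end <- 5
  surv <- rbinom(2, n0, exp(-true_hb * t_end))
  data <- data.frame(treatment = "control",
                     replicate = rep(c("R1", "R2"), each = 1),
                     time_days = t_end, n_alive = surv, n_initial = n0)
  ds <- survival_dataset(data, list(control = exposure_profile(0, 0)))
  hb_mle <- -log(sum(surv) / (2 * n0)) / t_end

  res <- suppressWarnings(
    calibrate("BUFFER_SD", ds, fast_settings(seed = 11)))
  hb_med <- res$summary$median[res$summary$parameter == "hb"]
  expect_lt(abs(log(hb_med / hb_mle)), log(1.6))
})

test_that("calibration output satisfies its structural contract", {
  ds <- tiny_dataset(seed = 2)
  res <- suppressWarnings(calibrate("BUFFER_SD", ds, fast_settings(seed = 2)))
  expect_s3_class(res, "calibration_result")
  expect_equal(dim(res$samples), c(2 * 400, 4))
  expect_true(all(res$summary$q2.5 <= res$summary$median))
  expect_true(all(res$summary$median <= res$summary$q97.5))
  expect_length(res$diagnostics$rhat, 4)
  expect_length(res$diagnostics$ess, 4)
  expect_false(is.null(res$diagnostics$flagged))
  # posterior support honours the global parameter range
  expect_true(all(res$samples >= 1e-10 & res$samples <= 1e3))
})

test_that("posterior predictions are integer counts inside [0, n0]", {
  ds <- tiny_dataset(seed = 3)
  res <- suppressWarnings(calibrate("BUFFER_SD", ds, fast_settings(seed = 3)))
  pred <- posterior_predict(res, n_draws = 100, seed = 3)
  expect_equal(nrow(pred), nrow(ds$data))
  for (col in c("pred_median", "pred_lower", "pred_upper")) {
    expect_true(all(pred[[col]] == round(pred[[col]])))
    expect_true(all(pred[[col]] >= 0 & pred[[col]] <= pred$n_initial))
  }
  expect_true(all(pred$pred_lower <= pred$pred_median))
  expect_true(all(pred$pred_median <= pred$pred_upper))
})

test_that("posterior prediction limits: single point and no-noise modes", {
  # degenerate posterior: one parameter point repeated
  ds <- tiny_dataset(seed = 4)
  res <- suppressWarnings(calibrate("BUFFER_SD", ds,
                                    fast_settings(seed = 4, n_tune = 200,
                                                  n_draw = 200)))
  p0 <- res$samples[1, ]
  res$samples <- matrix(rep(p0, each = 400), nrow = 400,
                        dimnames = list(NULL, colnames(res$samples)))

  # without sampling noise the interval collapses onto n0 * S
  det <- posterior_predict(res, n_draws = 200, include_sampling = FALSE,
                           seed = 4)
  expect_equal(det$pred_lower, det$pred_upper)

  # with sampling noise it is the binomial interval at that S
  noisy <- posterior_predict(res, n_draws = 400, seed = 4)
  S_det <- det$pred_median / det$n_initial
  expect_true(all(noisy$pred_upper >=
                    qbinom(0.975, noisy$n_initial, pmin(S_det, 1)) - 1))
  expect_true(all(noisy$pred_lower <=
                    qbinom(0.025, noisy$n_initial, pmin(S_det, 1)) + 1))
})

test_that("posterior-predictive coverage is near nominal under the truth", {
  # binomial-only uncertainty at the true parameters: the 95% intervals
  # should cover simulated observations at >= ~90% (discrete counts make
  # the check conservative)
  truth <- sd_params()
  des <- make_design("acute_contact", n_levels = 3, horizon = 5)
  ds <- simulate_dataset(des, "BUFFER_SD", truth, seed = 21)
  theta <- c(truth$kd, truth$hb, truth$z, truth$b_kill)
  fake <- structure(
    list(model = "BUFFER_SD", mechanism = "SD",
         samples = matrix(rep(theta, each = 300), nrow = 300,
                          dimnames = list(NULL, c("kd", "hb", "z", "b_kill"))),
         settings = list(n_steps = 1000), dataset = ds),
    class = "calibration_result")
  pred <- posterior_predict(fake, n_draws = 300, seed = 21)
  expect_gte(ppc(pred$observed, pred$pred_lower, pred$pred_upper), 90)
})
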