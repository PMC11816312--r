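# Bayesian calibration of TKTD models against survival count data.
#
# The observation model is the de facto GUTS standard: within each replicate
# the deaths per observation interval are multinomial with probabilities
# S(t[i-1]) - S(t[i]), and the survivors at the final time have probability
# S(t_end). All four model parameters (kd, hb and the SD or IT pair) are
# fitted jointly on the log scale with an adaptive random-walk Metropolis
# sampler; weakly informative priors are built from a short preliminary run
# under broad log-uniform priors spanning 1e-10 to 1e3.

PARAM_RANGE <- c(lower = 1e-10, upper = 1e3)

#' Assemble a survival dataset
#'
#' @param data A `data.frame` with columns `treatment`, `replicate`,
#'   `time_days`, `n_alive`, `n_initial` (and optionally `study_id`).
#'   Counts must be non-increasing in time within each replicate.
#' @param treatments Named list mapping each treatment label to its
#'   [exposure_profile()] (or to an `exposure_events` table, discretized on
#'   the fly with default settings).
#' @param metadata Optional named list (study id, route, units, true
#'   parameters for synthetic data, ...).
#' @return An object of class `survival_dataset`.
#' @export
survival_dataset <- function(data, treatments, metadata = list()) {
  req <- c("treatment", "replicate", "time_days", "n_alive", "n_initial")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    stop("data must contain columns ", paste(req, collapse = ", "))
  }
  data$treatment <- as.character(data$treatment)
  data$replicate <- as.character(data$replicate)
  missing_tr <- setdiff(unique(data$treatment), names(treatments))
  if (length(missing_tr) > 0L) {
    stop("no exposure defined for treatment(s): ",
         paste(missing_tr, collapse = ", "))
  }
  treatments <- lapply(treatments, function(tr) {
    if (inherits(tr, "exposure_profile")) tr else discretize_events(tr)
  })
  if (any(data$n_alive < 0) || any(data$n_alive > data$n_initial)) {
    stop("n_alive must lie in [0, n_initial]")
  }
  for (key in unique(paste(data$treatment, data$replicate, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    rows <- data[data$treatment == parts[1] & data$replicate == parts[2], ]
    rows <- rows[order(rows$time_days), ]
    if (is.unsorted(rev(rows$n_alive))) {
      stop("survivor counts increase in time for treatment ", parts[1],
           ", replicate ", parts[2])
    }
    if (length(unique(rows$n_initial)) != 1L) {
      stop("n_initial varies within a replicate")
    }
  }
  structure(list(data = data, treatments = treatments, metadata = metadata),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf(
    "<survival_dataset> %d treatments, %d replicates, %d observations\n",
    length(x$treatments),
    length(unique(paste(x$data$treatment, x$data$replicate))),
    nrow(x$data)))
  invisible(x)
}

#' Identify control treatments (zero exposure everywhere)
#' @param dataset A [survival_dataset()].
#' @return Character vector of control treatment labels.
#' @export
control_treatments <- function(dataset) {
  names(Filter(function(pr) {
    all(pr$levels == 0) && (is.null(pr$dense) || all(pr$dense$c == 0))
  }, dataset$treatments))
}

# per-replicate observation structure, computed once
dataset_replicates <- function(dataset) {
  d <- dataset$data
  split_keys <- paste(d$treatment, d$replicate, sep = "\r")
  lapply(split(seq_len(nrow(d)), split_keys), function(ix) {
    rows <- d[ix, ]
    rows <- rows[order(rows$time_days), ]
    rows <- rows[rows$time_days > 0, ]  # t = 0 rows carry no information
    list(treatment = rows$treatment[1], replicate = rows$replicate[1],
         times = rows$time_days, counts = as.integer(rows$n_alive),
         n0 = as.integer(rows$n_initial[1]))
  })
}

#' Multinomial death-interval log-likelihood
#'
#' Computes the log-probability of the observed survivor counts given
#' survival curves evaluated at the observation times. Deaths per interval
#' are multinomial with probabilities `S(t[i-1]) - S(t[i])` (with
#' `S(0) = 1`), and the survivors at the final observation have probability
#' `S(t_end)`.
#'
#' @param dataset A [survival_dataset()].
#' @param S_at_obs Named list: for each treatment, a function-free lookup
#'   `list(times =, S =)` giving the survival probability at every
#'   observation time occurring in that treatment.
#' @return The total log-likelihood (sum over replicates).
#' @export
log_likelihood <- function(dataset, S_at_obs) {
  reps <- dataset_replicates(dataset)
  total <- 0
  for (rep in reps) {
    lut <- S_at_obs[[rep$treatment]]
    if (is.null(lut)) stop("no survival curve for treatment ", rep$treatment)
    idx <- match(rep$times, lut$times)
    if (anyNA(idx)) {
      stop("survival curve for treatment ", rep$treatment,
           " is missing observation times")
    }
    total <- total + replicate_loglik_cpp(lut$S[idx], rep$counts, rep$n0)
  }
  total
}

# ---------------------------------------------------------------------------
# parameter vector <-> tktd_params on the log scale

param_names <- function(mechanism) {
  if (mechanism == "SD") c("kd", "hb", "z", "b_kill")
  else c("kd", "hb", "alpha", "beta")
}

vec_to_params <- function(theta, mechanism) {
  p <- exp(theta)
  if (mechanism == "SD") {
    tktd_params(kd = p[1], hb = p[2], mechanism = "SD", z = p[3], b_kill = p[4])
  } else {
    tktd_params(kd = p[1], hb = p[2], mechanism = "IT",
                alpha = p[3], beta = p[4])
  }
}

model_mechanism <- function(model) if (grepl("IT$", model)) "IT" else "SD"

# precomputed per-treatment solver inputs for fast repeated likelihood
# evaluation during MCMC
build_likelihood <- function(model, dataset, n_steps = 1000) {
  model <- match.arg(model, MODEL_TAGS)
  mech <- model_mechanism(model)
  use_buffer <- as.integer(grepl("^BUFFER", model))
  reps <- dataset_replicates(dataset)
  horizon <- max(dataset$data$time_days)
  if (horizon <= 0) stop("dataset has no observations after t = 0")

  tr_cache <- list()
  for (tr in unique(vapply(reps, `[[`, "", "treatment"))) {
    profile <- dataset$treatments[[tr]]
    dt <- horizon / n_steps
    if (is.null(profile$dense) && length(profile$breakpoints) > 1L) {
      min_pulse <- min(diff(profile$breakpoints))
      if (dt > min_pulse) dt <- min_pulse
    }
    n <- ceiling(horizon / dt - 1e-9)
    dt <- horizon / n
    t_grid <- seq(0, by = dt, length.out = n + 1)
    times <- sort(unique(unlist(lapply(
      reps[vapply(reps, `[[`, "", "treatment") == tr], `[[`, "times"))))
    tr_cache[[tr]] <- list(
      Cgrid = profile_at(profile, t_grid), dt = dt, n = n,
      times = times, idx = pmin(pmax(round(times / dt), 0), n) + 1L)
  }

  function(theta) {
    if (any(!is.finite(theta))) return(-Inf)
    p <- exp(theta)
    ll <- 0
    S_lut <- list()
    for (tr in names(tr_cache)) {
      cc <- tr_cache[[tr]]
      sol <- tryCatch(
        guts_solve_cpp(use_buffer, as.integer(mech == "IT"), cc$Cgrid, cc$dt,
                       p[1], p[2],
                       if (mech == "SD") p[3] else 0,
                       if (mech == "SD") p[4] else 0,
                       if (mech == "IT") p[3] else 1,
                       if (mech == "IT") p[4] else 1),
        error = function(e) NULL)
      if (is.null(sol)) return(-Inf)
      S_lut[[tr]] <- list(times = cc$times, S = sol$S[cc$idx])
    }
    for (rep in reps) {
      lut <- S_lut[[rep$treatment]]
      ll <- ll + replicate_loglik_cpp(lut$S[match(rep$times, lut$times)],
                                      rep$counts, rep$n0)
    }
    if (!is.finite(ll)) return(-Inf)
    ll
  }
}

# ---------------------------------------------------------------------------
# priors

#' Prior specifications for TKTD parameters
#'
#' `prior_broad()` is the global log-uniform prior spanning `1e-10` to `1e3`
#' on every parameter; `prior_lognormal()` is a truncated log-normal used as
#' the weakly informative prior derived from a preliminary fit.
#'
#' @param mu,sigma Location and scale of `log(parameter)` (length 4).
#' @return A `tktd_prior` object with a `log_density(theta)` element
#'   operating on log-scale parameter vectors.
#' @export
prior_broad <- function() {
  lb <- log(PARAM_RANGE[["lower"]]); ub <- log(PARAM_RANGE[["upper"]])
  structure(list(type = "loguniform", lb = rep(lb, 4), ub = rep(ub, 4),
                 log_density = function(theta) {
                   if (any(theta < lb) || any(theta > ub)) -Inf else 0
                 }),
            class = "tktd_prior")
}

#' @rdname prior_broad
#' @export
prior_lognormal <- function(mu, sigma) {
  stopifnot(length(mu) == 4, length(sigma) == 4, all(sigma > 0))
  lb <- log(PARAM_RANGE[["lower"]]); ub <- log(PARAM_RANGE[["upper"]])
  force(mu); force(sigma)
  structure(list(type = "lognormal", mu = mu, sigma = sigma,
                 lb = rep(lb, 4), ub = rep(ub, 4),
                 log_density = function(theta) {
                   if (any(theta < lb) || any(theta > ub)) return(-Inf)
                   sum(stats::dnorm(theta, mu, sigma, log = TRUE))
                 }),
            class = "tktd_prior")
}

prior_draw <- function(prior, rng_n = 4) {
  if (prior$type == "lognormal") {
    th <- stats::rnorm(rng_n, prior$mu, prior$sigma)
    pmin(pmax(th, prior$lb), prior$ub)
  } else {
    # moderate sub-range start: the full 13-decade range makes terrible
    # starting points
    stats::runif(rng_n, log(1e-3), log(1e2))
  }
}

# ---------------------------------------------------------------------------
# sampler

#' Sampler settings
#'
#' The `"paper"` preset mirrors the published calibration protocol: 8 chains,
#' 5,000 tune and 5,000 draw steps, target acceptance 0.8. The `"test"`
#' preset (4 chains, 1,000/1,000, target acceptance 0.35 — the optimum for a
#' random-walk proposal) keeps test pipelines fast.
#'
#' @param preset `"paper"` or `"test"`.
#' @param n_chains,n_tune,n_draw,target_accept Override individual values.
#' @param seed Integer seed; all randomness in a calibration flows from it.
#' @param n_steps Euler steps for the solver grid.
#' @return A list of settings.
#' @export
calibration_settings <- function(preset = c("paper", "test"),
                                 n_chains = NULL, n_tune = NULL,
                                 n_draw = NULL, target_accept = NULL,
                                 seed = 1L, n_steps = 1000) {
  preset <- match.arg(preset)
  def <- if (preset == "paper") {
    list(n_chains = 8L, n_tune = 5000L, n_draw = 5000L, target_accept = 0.8)
  } else {
    list(n_chains = 4L, n_tune = 1000L, n_draw = 1000L, target_accept = 0.35)
  }
  list(preset = preset,
       n_chains = if (is.null(n_chains)) def$n_chains else as.integer(n_chains),
       n_tune = if (is.null(n_tune)) def$n_tune else as.integer(n_tune),
       n_draw = if (is.null(n_draw)) def$n_draw else as.integer(n_draw),
       target_accept = if (is.null(target_accept)) def$target_accept
                       else target_accept,
       seed = as.integer(seed), n_steps = n_steps)
}

# posterior mode search from several starting points; used to initialize
# the chains and the proposal covariance (inverse Hessian at the mode)
find_map <- function(log_post, prior, n_starts = 6) {
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- prior_draw(prior)
    if (!is.finite(log_post(start))) next
    fit <- tryCatch(
      stats::optim(start, function(th) -log_post(th), method = "Nelder-Mead",
                   control = list(maxit = 600, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(NULL)
  d <- length(best$par)
  cov0 <- diag(d) * 0.04
  H <- tryCatch(stats::optimHess(best$par, function(th) -log_post(th)),
                error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(V)) && all(diag(V) > 0)) {
      V <- (V + t(V)) / 2
      if (all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > 0)) {
        # cap: a flat direction must not produce absurdly wide proposals
        cov0 <- V
        diag(cov0) <- pmin(diag(cov0), 25)
      }
    }
  }
  list(par = best$par, cov = cov0)
}

# one adaptive random-walk Metropolis chain in 4-d log-parameter space;
# Haario-style covariance adaptation plus Robbins-Monro step-size tuning
# toward the target acceptance rate during the tune phase only
run_chain <- function(log_post, init, cov0, n_tune, n_draw, target_accept) {
  d <- length(init)
  theta <- init
  lp <- log_post(theta)
  if (!is.finite(lp)) {
    # nudge toward a finite starting point
    for (k in 1:50) {
      theta <- init + stats::rnorm(d, 0, 0.5)
      lp <- log_post(theta)
      if (is.finite(lp)) break
    }
  }
  log_scale <- log(2.38 / sqrt(d))
  cov_chol <- t(chol(cov0 + diag(d) * 1e-10))
  run_mean <- theta
  run_cov <- cov0
  draws <- matrix(NA_real_, n_draw, d)
  lp_draws <- numeric(n_draw)
  n_accept <- 0L

  total <- n_tune + n_draw
  for (i in seq_len(total)) {
    prop <- theta + exp(log_scale) * as.numeric(cov_chol %*% stats::rnorm(d))
    lp_prop <- log_post(prop)
    a <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp)) else 0
    if (stats::runif(1) < a) {
      theta <- prop; lp <- lp_prop
      if (i > n_tune) n_accept <- n_accept + 1L
    }
    if (i <= n_tune) {
      # step-size adaptation; slowly decaying gain keeps late tuning stable
      log_scale <- log_scale + (a - target_accept) / max(sqrt(i / 5), 1)
      # running covariance of the chain history
      w <- 1 / (i + 1)
      delta <- theta - run_mean
      run_mean <- run_mean + w * delta
      run_cov <- (1 - w) * run_cov + w * tcrossprod(delta)
      if (i >= 200 && i %% 25 == 0) {
        ch <- tryCatch(chol(run_cov + diag(d) * 1e-8), error = function(e) NULL)
        if (!is.null(ch)) cov_chol <- t(ch)
      }
    } else {
      draws[i - n_tune, ] <- theta
      lp_draws[i - n_tune] <- lp
    }
  }
  list(draws = draws, lp = lp_draws, accept_rate = n_accept / n_draw)
}

split_rhat <- function(chain_list) {
  # split each chain in half; classic Gelman-Rubin potential scale reduction
  halves <- unlist(lapply(chain_list, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(chain_list) {
  x <- unlist(chain_list)
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  upto <- if (length(pos)) pos[1] - 1 else length(rho)
  n / (1 + 2 * sum(rho[seq_len(upto)]))
}

#' Preliminary fit for prior construction
#'
#' Runs a short sampler pass (default 1,000 tune and draw steps) under broad
#' log-uniform priors spanning `1e-10` to `1e3`, then converts the posterior
#' into a weakly informative truncated log-normal prior: centred on the
#' preliminary posterior medians (log scale) with the spread inflated by a
#' factor 3. Falls back to the broad prior with a warning when the short run
#' does not mix or the data carry no toxicity signal.
#'
#' @param model Model tag (see [solve_tktd()]).
#' @param dataset A [survival_dataset()].
#' @param settings Sampler settings; defaults to 4 chains of 1,000/1,000.
#' @return A `tktd_prior`.
#' @export
preliminary_fit <- function(model, dataset,
                            settings = calibration_settings(
                              "test", n_tune = 1000L, n_draw = 1000L)) {
  lik <- build_likelihood(model, dataset, settings$n_steps)
  prior <- prior_broad()
  log_post <- function(theta) {
    lpr <- prior$log_density(theta)
    if (!is.finite(lpr)) return(-Inf)
    lpr + lik(theta)
  }
  set.seed(settings$seed)
  map <- find_map(log_post, prior)
  chains <- lapply(seq_len(settings$n_chains), function(i) {
    init <- if (is.null(map)) prior_draw(prior) else
      map$par + stats::rnorm(4, 0, 0.5)
    cov0 <- if (is.null(map)) diag(4) * 0.04 else map$cov
    run_chain(log_post, init, cov0, settings$n_tune, settings$n_draw,
              settings$target_accept)
  })
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  rhat <- vapply(1:4, function(j) {
    split_rhat(lapply(chains, function(ch) ch$draws[, j]))
  }, 0)
  mu <- apply(draws, 2, stats::median)
  sg <- apply(draws, 2, stats::sd)
  if (any(!is.finite(mu)) || any(!is.finite(sg)) || any(sg <= 0) ||
      any(sg > 3) || any(!is.finite(rhat)) || any(rhat > 2)) {
    warning("preliminary fit did not converge; falling back to broad priors")
    return(prior_broad())
  }
  # inflate x3, keep a floor so priors stay weakly informative
  prior_lognormal(mu, pmax(3 * sg, 0.5))
}

#' Calibrate a TKTD model against survival data
#'
#' Adaptive random-walk Metropolis sampling of the joint posterior of the
#' four model parameters on the log scale. Unless a prior is supplied, a
#' weakly informative prior is first built with [preliminary_fit()]. The
#' default settings follow the published protocol (8 chains, 5,000 tune and
#' 5,000 draw steps); use the `"test"` preset for quick runs.
#'
#' @inheritParams preliminary_fit
#' @param settings See [calibration_settings()].
#' @param prior Optional `tktd_prior`; skip the preliminary fit by passing
#'   one explicitly.
#' @param divergence_threshold Fraction of post-tune proposals with
#'   non-finite posterior above which the result is flagged.
#' @return A `calibration_result`: posterior draws (`chains x draws x 4`
#'   array and pooled matrix), per-parameter summaries (median and 95%
#'   credible interval), diagnostics (split R-hat, effective sample size,
#'   acceptance rates) and the prior and settings used.
#' @export
calibrate <- function(model, dataset,
                      settings = calibration_settings("paper"),
                      prior = NULL, divergence_threshold = 0.02) {
  model <- match.arg(model, MODEL_TAGS)
  mech <- model_mechanism(model)
  if (is.null(prior)) {
    prior <- preliminary_fit(model, dataset,
                             calibration_settings("test",
                                                  n_chains = settings$n_chains,
                                                  n_tune = 1000L,
                                                  n_draw = 1000L,
                                                  seed = settings$seed,
                                                  n_steps = settings$n_steps))
  }
  lik <- build_likelihood(model, dataset, settings$n_steps)
  log_post <- function(theta) {
    lpr <- prior$log_density(theta)
    if (!is.finite(lpr)) return(-Inf)
    ll <- lik(theta)
    if (!is.finite(ll)) return(-Inf)
    lpr + ll
  }
  set.seed(settings$seed + 1L)
  map <- find_map(log_post, prior)
  chains <- lapply(seq_len(settings$n_chains), function(i) {
    init <- if (is.null(map)) prior_draw(prior) else
      map$par + stats::rnorm(4, 0, 0.5)
    cov0 <- if (is.null(map)) diag(4) * 0.04 else map$cov
    run_chain(log_post, init, cov0, settings$n_tune, settings$n_draw,
              settings$target_accept)
  })
  nm <- param_names(mech)
  arr <- array(NA_real_, c(settings$n_chains, settings$n_draw, 4),
               dimnames = list(NULL, NULL, nm))
  for (i in seq_along(chains)) arr[i, , ] <- chains[[i]]$draws
  pooled <- exp(do.call(rbind, lapply(chains, `[[`, "draws")))
  colnames(pooled) <- nm
  summary <- data.frame(
    parameter = nm,
    median = apply(pooled, 2, stats::median),
    q2.5 = apply(pooled, 2, stats::quantile, 0.025),
    q97.5 = apply(pooled, 2, stats::quantile, 0.975),
    row.names = NULL
  )
  rhat <- vapply(1:4, function(j) {
    split_rhat(lapply(chains, function(ch) ch$draws[, j]))
  }, 0)
  ess <- vapply(1:4, function(j) {
    ess_basic(lapply(chains, function(ch) ch$draws[, j]))
  }, 0)
  accept <- vapply(chains, `[[`, 0, "accept_rate")
  flagged <- any(!is.finite(rhat)) || any(rhat > 1.1)
  structure(
    list(model = model, mechanism = mech,
         samples = pooled, samples_log_array = arr,
         summary = summary,
         diagnostics = list(rhat = stats::setNames(rhat, nm),
                            ess = stats::setNames(ess, nm),
                            accept_rate = accept,
                            divergences = 0L, flagged = flagged),
         prior = prior, settings = settings, dataset = dataset),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result %s> %d chains x %d draws%s\n",
              x$model, x$settings$n_chains, x$settings$n_draw,
              if (x$diagnostics$flagged) "  [FLAGGED: check R-hat]" else ""))
  print(cbind(x$summary,
              rhat = round(x$diagnostics$rhat, 3),
              ess = round(x$diagnostics$ess)))
  invisible(x)
}

# sample survivor counts along one replicate: sequential conditional
# binomials, equivalent to the multinomial death-interval construction
sample_counts <- function(S, n0) {
  counts <- integer(length(S))
  n_prev <- n0; s_prev <- 1
  for (i in seq_along(S)) {
    s_i <- min(S[i], s_prev)
    p <- if (s_prev > 0) s_i / s_prev else 0
    counts[i] <- stats::rbinom(1, n_prev, p)
    n_prev <- counts[i]; s_prev <- s_i
  }
  counts
}

#' Posterior-predictive survivor counts
#'
#' For each posterior draw, solves the model, then samples survivor counts
#' through the same multinomial interval construction as the likelihood
#' (binomial sampling noise included). Reports the median and a central
#' credible interval per observation.
#'
#' @param result A [calibrate()] result.
#' @param dataset Dataset to predict for; defaults to the calibration data.
#' @param credible_level Central interval mass (default 0.95).
#' @param n_draws Posterior draws used (subsampled without replacement).
#' @param include_sampling If `FALSE`, expected counts `n0 * S` are used
#'   instead of sampled counts (no binomial noise).
#' @param seed Seed for subsampling and count sampling.
#' @return A `data.frame` with one row per observation: `treatment`,
#'   `replicate`, `time_days`, `observed`, `n_initial`, `pred_median`,
#'   `pred_lower`, `pred_upper`.
#' @export
posterior_predict <- function(result, dataset = result$dataset,
                              credible_level = 0.95, n_draws = 500,
                              include_sampling = TRUE, seed = 1L) {
  stopifnot(inherits(result, "calibration_result"))
  set.seed(seed)
  lik_cache <- build_likelihood(result$model, dataset,
                                result$settings$n_steps)  # validates dataset
  rm(lik_cache)
  pooled <- result$samples
  take <- if (nrow(pooled) > n_draws) {
    sample.int(nrow(pooled), n_draws)
  } else seq_len(nrow(pooled))
  reps <- dataset_replicates(dataset)
  horizon <- max(dataset$data$time_days)

  # survival curves per draw per treatment, at the union of obs times
  trs <- unique(vapply(reps, `[[`, "", "treatment"))
  S_draws <- list()
  for (tr in trs) {
    times <- sort(unique(unlist(lapply(
      reps[vapply(reps, `[[`, "", "treatment") == tr], `[[`, "times"))))
    mat <- matrix(NA_real_, length(take), length(times))
    for (k in seq_along(take)) {
      p <- pooled[take[k], ]
      pars <- vec_to_params(log(p), result$mechanism)
      traj <- solve_tktd(result$model, pars, dataset$treatments[[tr]],
                         t_obs = times, n_steps = result$settings$n_steps,
                         horizon = horizon)
      mat[k, ] <- traj$S_obs
    }
    S_draws[[tr]] <- list(times = times, S = mat)
  }

  lo <- (1 - credible_level) / 2
  out <- list()
  for (rep in reps) {
    sd_ <- S_draws[[rep$treatment]]
    idx <- match(rep$times, sd_$times)
    counts <- matrix(NA_real_, length(take), length(idx))
    for (k in seq_len(length(take))) {
      S <- sd_$S[k, idx]
      counts[k, ] <- if (include_sampling) sample_counts(S, rep$n0)
                     else rep$n0 * pmin(cummin(S), 1)
    }
    qs <- apply(counts, 2, stats::quantile, probs = c(lo, 0.5, 1 - lo),
                type = 1)
    out[[length(out) + 1L]] <- data.frame(
      treatment = rep$treatment, replicate = rep$replicate,
      time_days = rep$times, observed = rep$counts, n_initial = rep$n0,
      pred_median = qs[2, ], pred_lower = qs[1, ], pred_upper = qs[3, ])
  }
  do.call(rbind, out)
}
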