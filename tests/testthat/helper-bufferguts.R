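# shared fixtures, all generated in code

sd_params <- function(kd = 0.5, hb = 0.02, z = 0.2, b_kill = 2) {
  tktd_params(kd = kd, hb = hb, mechanism = "SD", z = z, b_kill = b_kill)
}

it_params <- function(kd = 0.5, hb = 0.02, alpha = 0.3, beta = 2) {
  tktd_params(kd = kd, hb = hb, mechanism = "IT", alpha = alpha, beta = beta)
}

# random parameter draw in a physically plausible range (log-uniform)
random_params <- function(mechanism) {
  r <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  if (mechanism == "SD") {
    tktd_params(kd = r(0.05, 5), hb = stats::runif(1, 0, 0.1),
                mechanism = "SD", z = r(0.01, 2), b_kill = r(0.1, 10))
  } else {
    tktd_params(kd = r(0.05, 5), hb = stats::runif(1, 0, 0.1),
                mechanism = "IT", alpha = r(0.05, 2), beta = r(0.5, 6))
  }
}

params_for <- function(model, ...) {
  if (grepl("IT$", model)) it_params(...) else sd_params(...)
}

pulse_profile <- function(level = 2, dt_unit = 1 / 24) {
  discretize_events(exposure_events("acute_contact", level, t_start = 0),
                    dt_unit = dt_unit)
}

constant_profile <- function(level = 1) {
  exposure_profile(0, level, unit = "TU")
}

# tiny two-treatment dataset for quick calibration runs
tiny_dataset <- function(seed = 1, model = "BUFFER_SD",
                         params = sd_params(), n_levels = 3, horizon = 5) {
  des <- make_design("acute_contact", n_levels = n_levels, horizon = horizon)
  simulate_dataset(des, model, params, seed = seed)
}

fast_settings <- function(seed = 1, n_chains = 2, n_tune = 400,
                          n_draw = 400) {
  calibration_settings("test", n_chains = n_chains, n_tune = n_tune,
                       n_draw = n_draw, seed = seed)
}
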