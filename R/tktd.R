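# TKTD model core: parameter container, single-step updates, death
# mechanisms and the fixed-step forward-Euler solver for the four model
# variants GUTS-RED-SD, GUTS-RED-IT, BufferGUTS-SD and BufferGUTS-IT.
#
# State variables (all in exposure-concentration units, typically TU):
#   C  external exposure concentration (input)
#   B  buffer level (BufferGUTS only): residues on the exoskeleton or in the
#      gut; filled instantly by C, drained first-order with rate kd
#   D  scaled damage, dD/dt = kd * (driver - D), driver = B or C
#   S  survival probability

MODEL_TAGS <- c("RED_SD", "RED_IT", "BUFFER_SD", "BUFFER_IT")

#' TKTD parameter set
#'
#' The four free parameters of a reduced-GUTS-type model: the dominant rate
#' constant `kd` (1/d), the background hazard rate `hb` (1/d), and either the
#' stochastic-death pair (threshold `z` in exposure units and killing rate
#' `b_kill` in 1/(d * exposure unit)) or the individual-tolerance pair
#' (log-logistic median `alpha` and shape `beta`).
#'
#' The field calls the killing rate both `b` and `d`; it is named `b_kill`
#' here to avoid clashing with the damage state.
#'
#' @param kd Dominant rate constant, > 0 (1/d).
#' @param hb Background hazard rate, >= 0 (1/d).
#' @param mechanism `"SD"` or `"IT"`.
#' @param z,b_kill SD parameters (threshold >= 0, killing rate >= 0).
#' @param alpha,beta IT parameters (median > 0, shape > 0).
#' @return An object of class `tktd_params`.
#' @examples
#' tktd_params(kd = 0.5, hb = 0.02, mechanism = "SD", z = 0.2, b_kill = 2)
#' @export
tktd_params <- function(kd, hb = 0, mechanism = c("SD", "IT"),
                        z = NULL, b_kill = NULL, alpha = NULL, beta = NULL) {
  mechanism <- match.arg(mechanism)
  if (!is.finite(kd) || kd <= 0) stop("kd must be > 0")
  if (!is.finite(hb) || hb < 0) stop("hb must be >= 0")
  if (mechanism == "SD") {
    if (is.null(z) || is.null(b_kill)) stop("SD requires z and b_kill")
    if (!is.null(alpha) || !is.null(beta)) {
      stop("alpha/beta must not be set for mechanism SD")
    }
    if (!is.finite(z) || z < 0) stop("z must be >= 0")
    if (!is.finite(b_kill) || b_kill < 0) stop("b_kill must be >= 0")
  } else {
    if (is.null(alpha) || is.null(beta)) stop("IT requires alpha and beta")
    if (!is.null(z) || !is.null(b_kill)) {
      stop("z/b_kill must not be set for mechanism IT")
    }
    if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
    if (!is.finite(beta) || beta <= 0) stop("beta must be > 0")
  }
  structure(list(kd = kd, hb = hb, mechanism = mechanism, z = z,
                 b_kill = b_kill, alpha = alpha, beta = beta),
            class = "tktd_params")
}

#' @export
print.tktd_params <- function(x, ...) {
  extra <- if (x$mechanism == "SD") {
    sprintf("z = %.4g, b_kill = %.4g", x$z, x$b_kill)
  } else {
    sprintf("alpha = %.4g, beta = %.4g", x$alpha, x$beta)
  }
  cat(sprintf("<tktd_params %s> kd = %.4g/d, hb = %.4g/d, %s\n",
              x$mechanism, x$kd, x$hb, extra))
  invisible(x)
}

#' Single Euler update of the buffer compartment
#'
#' The buffer fills instantly whenever the external concentration is at or
#' above the buffer level, and otherwise declines first-order toward it:
#' `B <- C` if `B <= C`, else `B + kd * (C - B) * dt`.
#'
#' @param B Current buffer level (>= 0).
#' @param C External concentration (>= 0).
#' @param kd Dominant rate constant (1/d).
#' @param dt Step size in days (> 0).
#' @return Updated buffer level; vectorized over `B`/`C`.
#' @export
step_buffer <- function(B, C, kd, dt) {
  if (any(B < 0) || any(C < 0) || kd < 0) stop("negative inputs not allowed")
  if (dt <= 0) stop("dt must be > 0")
  ifelse(B <= C, C, B + kd * (C - B) * dt)
}

#' Single Euler update of scaled damage
#'
#' `D + kd * (driver - D) * dt`; the driver is the buffer level for
#' BufferGUTS and the external concentration for GUTS-RED.
#'
#' @param D Current damage.
#' @param driver Damage driver level.
#' @inheritParams step_buffer
#' @return Updated damage level.
#' @export
step_damage <- function(D, driver, kd, dt) {
  if (dt <= 0) stop("dt must be > 0")
  D + kd * (driver - D) * dt
}

#' Stochastic-death survival from a damage series
#'
#' Integrates the hazard `b_kill * max(D - z, 0) + hb` along the grid
#' (left-endpoint rule, matching the forward-Euler solver) and returns
#' `S(t) = exp(-integral)`.
#'
#' @param D_series Damage values on the grid.
#' @param b_kill Killing rate.
#' @param z Damage threshold.
#' @param hb Background hazard rate.
#' @param t_grid Grid times in days (same length as `D_series`).
#' @return Survival probabilities on the grid; `S[1] = 1`.
#' @export
survival_sd <- function(D_series, b_kill, z, hb, t_grid) {
  stopifnot(length(D_series) == length(t_grid))
  n <- length(t_grid)
  if (n == 0L) return(numeric(0))
  dt <- diff(t_grid)
  haz <- b_kill * pmax(D_series - z, 0)
  H <- c(0, cumsum(haz[-n] * dt))
  exp(-H - hb * (t_grid - t_grid[1]))
}

#' Individual-tolerance survival from a damage series
#'
#' Tolerance thresholds are log-logistic with median `alpha` and shape
#' `beta`; an individual dies the instant the running-maximum damage exceeds
#' its threshold. `S(t) = (1 - F(max D up to t)) * exp(-hb t)` with
#' `F(x) = 1 / (1 + (x/alpha)^(-beta))`. After a damage peak, S stays flat
#' apart from background mortality — IT models cannot place mortality beyond
#' the exposure phase.
#'
#' @param D_series Damage values on the grid.
#' @param alpha Median tolerance (> 0).
#' @param beta Log-logistic shape (> 0).
#' @inheritParams survival_sd
#' @return Survival probabilities on the grid.
#' @export
survival_it <- function(D_series, alpha, beta, hb, t_grid) {
  stopifnot(length(D_series) == length(t_grid))
  dmax <- cummax(pmax(D_series, 0))
  F <- ifelse(dmax > 0, 1 / (1 + (dmax / alpha)^(-beta)), 0)
  (1 - F) * exp(-hb * (t_grid - t_grid[1]))
}

#' Solve a TKTD model on an exposure profile
#'
#' Fixed-step forward-Euler integration. The default grid is 1/1000 of the
#' modelling horizon, refined when necessary so that no step is longer than
#' the shortest exposure pulse (a 1-h pulse in a 10-d horizon must land on
#' the grid). Observation times are snapped to the nearest grid point.
#'
#' @param model One of `"RED_SD"`, `"RED_IT"`, `"BUFFER_SD"`, `"BUFFER_IT"`.
#'   The mechanism suffix must match `params$mechanism`.
#' @param params A [tktd_params()] object.
#' @param profile An [exposure_profile()].
#' @param t_obs Observation times in days (within the horizon).
#' @param n_steps Number of Euler steps over the horizon (default 1000).
#' @param horizon Optional explicit horizon; defaults to
#'   `max(t_obs, profile support)`.
#' @return An object of class `state_trajectory`: a list with grid vectors
#'   `t`, `C`, `B`, `D`, `S` and the observation-time values `t_obs`,
#'   `S_obs`.
#' @examples
#' pr <- discretize_events(exposure_events("acute_contact", 2, 0))
#' pars <- tktd_params(kd = 0.7, hb = 0, mechanism = "SD", z = 0.2, b_kill = 1)
#' traj <- solve_tktd("BUFFER_SD", pars, pr, t_obs = c(1, 2))
#' traj$S_obs
#' @export
solve_tktd <- function(model, params, profile, t_obs, n_steps = 1000,
                       horizon = NULL) {
  model <- match.arg(model, MODEL_TAGS)
  stopifnot(inherits(params, "tktd_params"),
            inherits(profile, "exposure_profile"))
  mech <- if (grepl("IT$", model)) "IT" else "SD"
  if (mech != params$mechanism) {
    stop("model ", model, " requires mechanism ", mech,
         " parameters, got ", params$mechanism)
  }
  t_obs <- as.numeric(t_obs)
  if (any(!is.finite(t_obs)) || any(t_obs < 0)) {
    stop("observation times must be finite and >= 0")
  }
  support <- if (!is.null(profile$dense)) max(profile$dense$t) else
    max(profile$breakpoints)
  if (is.null(horizon)) horizon <- max(t_obs, support)
  if (horizon <= 0) stop("horizon must be > 0")
  if (any(t_obs > horizon + 1e-9)) stop("t_obs outside the profile horizon")

  dt <- horizon / n_steps
  # no step may exceed the shortest exposure pulse
  if (is.null(profile$dense) && length(profile$breakpoints) > 1L) {
    min_pulse <- min(diff(profile$breakpoints))
    if (dt > min_pulse) dt <- min_pulse
  }
  n <- ceiling(horizon / dt - 1e-9)
  dt <- horizon / n
  t_grid <- seq(0, by = dt, length.out = n + 1)

  Cgrid <- profile_at(profile, t_grid)
  use_buffer <- grepl("^BUFFER", model)
  sol <- guts_solve_cpp(as.integer(use_buffer), as.integer(mech == "IT"),
                        Cgrid, dt, params$kd, params$hb,
                        if (is.null(params$z)) 0 else params$z,
                        if (is.null(params$b_kill)) 0 else params$b_kill,
                        if (is.null(params$alpha)) 1 else params$alpha,
                        if (is.null(params$beta)) 1 else params$beta)
  idx <- pmin(pmax(round(t_obs / dt), 0), n) + 1L
  structure(
    list(model = model, t = t_grid, C = Cgrid,
         B = if (use_buffer) sol$B else NULL,
         D = sol$D, S = sol$S,
         t_obs = t_obs, S_obs = sol$S[idx], dt = dt),
    class = "state_trajectory"
  )
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("<state_trajectory %s> %d grid points, dt = %.4g d\n",
              x$model, length(x$t), x$dt))
  cat(sprintf("  S at t_obs: %s\n",
              paste(sprintf("%.4f", x$S_obs), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.state_trajectory <- function(x, ...) {
  data.frame(t = x$t, C = x$C,
             B = if (is.null(x$B)) NA_real_ else x$B,
             D = x$D, S = x$S)
}

# pure-R reference solver; independent slow path used in tests against the
# compiled implementation
solve_tktd_r <- function(model, params, profile, t_obs, n_steps = 1000,
                         horizon = NULL) {
  model <- match.arg(model, MODEL_TAGS)
  support <- if (!is.null(profile$dense)) max(profile$dense$t) else
    max(profile$breakpoints)
  if (is.null(horizon)) horizon <- max(t_obs, support)
  dt <- horizon / n_steps
  if (is.null(profile$dense) && length(profile$breakpoints) > 1L) {
    min_pulse <- min(diff(profile$breakpoints))
    if (dt > min_pulse) dt <- min_pulse
  }
  n <- ceiling(horizon / dt - 1e-9)
  dt <- horizon / n
  t_grid <- seq(0, by = dt, length.out = n + 1)
  Cgrid <- profile_at(profile, t_grid)
  use_buffer <- grepl("^BUFFER", model)

  B <- D <- numeric(n + 1)
  B[1] <- if (use_buffer) Cgrid[1] else 0
  for (i in 2:(n + 1)) {
    driver <- if (use_buffer) B[i - 1] else Cgrid[i - 1]
    D[i] <- step_damage(D[i - 1], driver, params$kd, dt)
    if (use_buffer) {
      b <- if (B[i - 1] > Cgrid[i - 1]) {
        B[i - 1] + params$kd * (Cgrid[i - 1] - B[i - 1]) * dt
      } else B[i - 1]
      B[i] <- if (b <= Cgrid[i]) Cgrid[i] else b
    }
  }
  S <- if (grepl("IT$", model)) {
    survival_it(D, params$alpha, params$beta, params$hb, t_grid)
  } else {
    survival_sd(D, params$b_kill, params$z, params$hb, t_grid)
  }
  idx <- pmin(pmax(round(t_obs / dt), 0), n) + 1L
  list(t = t_grid, C = Cgrid, B = if (use_buffer) B else NULL, D = D, S = S,
       t_obs = t_obs, S_obs = S[idx], dt = dt)
}

#' Export a solved trajectory as delimited text
#'
#' Writes columns `t`, `C`, `B`, `D`, `S` as tab-separated values for
#' plotting or archiving.
#'
#' @param trajectory A `state_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  write_table_c14n(df, path)
  invisible(path)
}
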