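# Exposure events, piecewise-constant profiles and toxic-unit normalization.
#
# Exposure in above-ground terrestrial test systems is event-based: a topical
# droplet applied at one moment (acute contact), a feeding window on
# contaminated sugar solution (acute oral), or a food source kept contaminated
# for the whole test (chronic oral). The functions here turn such events into
# concentration time series a TKTD solver can consume, and rescale
# concentrations to toxic units (TU = concentration / LC50).

ROUTES <- c("acute_contact", "acute_oral", "chronic_oral")

#' Create a table of exposure events
#'
#' An exposure event is one discrete happening through which test organisms
#' take up a substance: a topical application (`acute_contact`), a feeding
#' window (`acute_oral`), or the maintenance of a contaminated food source
#' (`chronic_oral`). For instantaneous events use `t_end = t_start`.
#'
#' @param route Character vector; one of `"acute_contact"`, `"acute_oral"`,
#'   `"chronic_oral"` per event.
#' @param magnitude Non-negative dose or concentration in study units
#'   (e.g. ug/bee, mg/kg food, or TU).
#' @param t_start,t_end Event start/end times in days. `t_end` defaults to
#'   `t_start` (instantaneous event).
#' @param unit Free-text unit label shared by all events of the table.
#' @return A `data.frame` of class `exposure_events` with columns
#'   `route`, `magnitude`, `unit`, `t_start_days`, `t_end_days`.
#' @examples
#' exposure_events("acute_contact", magnitude = 1.0, t_start = 0)
#' @export
exposure_events <- function(route, magnitude, t_start, t_end = t_start,
                            unit = "TU") {
  n <- max(length(route), length(magnitude), length(t_start), length(t_end))
  route <- rep_len(as.character(route), n)
  magnitude <- rep_len(as.numeric(magnitude), n)
  t_start <- rep_len(as.numeric(t_start), n)
  t_end <- rep_len(as.numeric(t_end), n)
  bad <- !route %in% ROUTES
  if (any(bad)) {
    stop("unknown exposure route(s): ", paste(unique(route[bad]), collapse = ", "))
  }
  if (any(!is.finite(magnitude)) || any(magnitude < 0)) {
    stop("event magnitudes must be finite and >= 0")
  }
  if (any(!is.finite(t_start)) || any(!is.finite(t_end))) {
    stop("event times must be finite")
  }
  if (any(t_end < t_start)) stop("t_end must be >= t_start")
  out <- data.frame(
    route = route, magnitude = magnitude, unit = rep_len(unit, n),
    t_start_days = t_start, t_end_days = t_end,
    stringsAsFactors = FALSE
  )
  class(out) <- c("exposure_events", "data.frame")
  out
}

#' Construct an exposure profile
#'
#' A piecewise-constant concentration time series: `levels[i]` applies on the
#' right-open interval `[breakpoints[i], breakpoints[i+1])`; the last level
#' applies from the last breakpoint onwards (and must be 0 for finite acute
#' profiles). Profiles produced by [beeguts_preprocess()] additionally carry a
#' dense grid representation because exponential decay is not
#' piecewise-constant.
#'
#' @param breakpoints Strictly increasing times in days, starting at 0.
#' @param levels Non-negative concentration per interval, same length as
#'   `breakpoints`.
#' @param unit Unit label.
#' @param is_toxic_units Logical; `TRUE` once levels are expressed in TU.
#' @param dense Optional `list(t =, c =)` dense sampling used in place of the
#'   piecewise representation by the solver (BeeGUTS preprocessing mode).
#' @return An object of class `exposure_profile`.
#' @export
exposure_profile <- function(breakpoints, levels, unit = "TU",
                             is_toxic_units = identical(unit, "TU"),
                             dense = NULL) {
  breakpoints <- as.numeric(breakpoints)
  levels <- as.numeric(levels)
  if (length(breakpoints) != length(levels)) {
    stop("breakpoints and levels must have equal length")
  }
  if (length(breakpoints) == 0L) {
    breakpoints <- 0
    levels <- 0
  }
  if (any(!is.finite(breakpoints)) || any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be finite and strictly increasing")
  }
  if (any(!is.finite(levels)) || any(levels < 0)) {
    stop("levels must be finite and >= 0")
  }
  if (!is.null(dense)) {
    stopifnot(is.list(dense), length(dense$t) == length(dense$c))
  }
  structure(
    list(breakpoints = breakpoints, levels = levels, unit = unit,
         is_toxic_units = isTRUE(is_toxic_units), dense = dense),
    class = "exposure_profile"
  )
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat("<exposure_profile> ", length(x$breakpoints), " segment(s), unit=",
      x$unit, if (x$is_toxic_units) " [TU]" else "",
      if (!is.null(x$dense)) sprintf(", dense grid (%d pts)", length(x$dense$t)) else "",
      "\n", sep = "")
  n <- min(length(x$breakpoints), 8L)
  print(data.frame(t_start = x$breakpoints[seq_len(n)],
                   level = x$levels[seq_len(n)]))
  invisible(x)
}

#' Evaluate an exposure profile at arbitrary times
#'
#' Dense profiles are linearly interpolated; piecewise-constant profiles are
#' evaluated with right-open interval semantics (level 0 before the first
#' breakpoint).
#'
#' @param profile An `exposure_profile`.
#' @param t Numeric vector of times in days.
#' @return Concentrations at `t`.
#' @export
profile_at <- function(profile, t) {
  stopifnot(inherits(profile, "exposure_profile"))
  if (!is.null(profile$dense)) {
    return(stats::approx(profile$dense$t, profile$dense$c, xout = t,
                         rule = 2, yleft = 0)$y)
  }
  idx <- findInterval(t, profile$breakpoints)
  out <- numeric(length(t))
  out[idx > 0] <- profile$levels[idx[idx > 0]]
  out
}

#' Discretize exposure events into a piecewise-constant profile
#'
#' Events are mapped to constant exposure over their contact period and zero
#' otherwise, using a smallest time unit `dt_unit` (default 1 h): an
#' instantaneous contact dose becomes a pulse of duration `dt_unit` at its
#' magnitude; a feeding window covers `[t_start, t_end]` (at least one
#' `dt_unit` long); chronic events hold their level over the full modelling
#' horizon. The construction preserves the area under the curve:
#' `magnitude * max(duration, dt_unit)` per finite event.
#'
#' @param events An `exposure_events` table (or a `data.frame` with the same
#'   columns).
#' @param dt_unit Smallest time unit in days; default `1/24` (1 hour).
#' @param horizon Modelling horizon in days; required for chronic events,
#'   otherwise defaults to the end of the last pulse.
#' @return An [exposure_profile()].
#' @examples
#' ev <- exposure_events("acute_contact", 1.0, t_start = 0)
#' discretize_events(ev)  # 1.0 for one hour, zero thereafter
#' @export
discretize_events <- function(events, dt_unit = 1 / 24, horizon = NULL) {
  events <- as_exposure_events(events)
  if (!is.finite(dt_unit) || dt_unit <= 0) stop("dt_unit must be > 0")
  if (nrow(events) == 0L) {
    return(exposure_profile(0, 0, unit = "TU", is_toxic_units = FALSE))
  }
  unit <- events$unit[1L]

  # expand each event to its covered interval
  a <- numeric(nrow(events)); b <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    if (events$route[i] == "chronic_oral") {
      if (is.null(horizon)) {
        stop("chronic events require an explicit horizon")
      }
      a[i] <- 0; b[i] <- horizon
    } else if (events$route[i] == "acute_contact") {
      # topical application is instantaneous: one dt_unit at full level
      if (events$t_end_days[i] != events$t_start_days[i]) {
        stop("acute contact events are instantaneous (t_end must equal ",
             "t_start); row ", i)
      }
      a[i] <- events$t_start_days[i]
      b[i] <- events$t_start_days[i] + dt_unit
    } else {
      a[i] <- events$t_start_days[i]
      b[i] <- max(events$t_end_days[i], events$t_start_days[i] + dt_unit)
    }
  }
  if (!is.null(horizon) && any(b > horizon + 1e-12)) {
    stop("horizon does not cover all events")
  }

  bp <- sort(unique(c(0, a, b)))
  lev <- numeric(length(bp))
  for (k in seq_along(bp)) {
    covering <- which(a <= bp[k] & bp[k] < b)
    if (length(covering) == 0L) {
      lev[k] <- 0
    } else {
      mags <- unique(events$magnitude[covering])
      if (length(mags) > 1L) {
        stop("overlapping events with conflicting levels (rows ",
             paste(covering, collapse = ", "), ")")
      }
      lev[k] <- mags
    }
  }
  # drop redundant breakpoints where the level does not change
  keep <- c(TRUE, diff(lev) != 0)
  exposure_profile(bp[keep], lev[keep], unit = unit,
                   is_toxic_units = identical(unit, "TU"))
}

as_exposure_events <- function(events) {
  if (inherits(events, "exposure_events")) return(events)
  req <- c("route", "magnitude", "t_start_days", "t_end_days")
  if (!is.data.frame(events) || !all(req %in% names(events))) {
    stop("events must be an exposure_events table with columns ",
         paste(req, collapse = ", "))
  }
  exposure_events(events$route, events$magnitude, events$t_start_days,
                  events$t_end_days,
                  unit = if ("unit" %in% names(events)) events$unit else "TU")
}

#' BeeGUTS-style exposure preprocessing
#'
#' The honeybee-specific alternative to [discretize_events()]: instead of a
#' rectangular pulse, each route gets a fixed effective-exposure kinetic
#' derived from bee physiology. Acute contact doses decline first-order at
#' 0.4/d from the application time; acute oral exposure ramps linearly from 0
#' to the magnitude over the feeding window and then declines first-order at
#' 0.625/d; chronic exposure stays constant over the whole period. The result
#' is a dense-grid profile (the decay is not piecewise-constant) meant to be
#' fed to the standard GUTS-RED models as dose metric.
#'
#' @param events An `exposure_events` table.
#' @param horizon Modelling horizon in days; must cover all events.
#' @param grid_step Dense grid step in days; default `horizon / 1000`.
#' @return An [exposure_profile()] with a dense representation.
#' @examples
#' ev <- exposure_events("acute_contact", 1.0, t_start = 0)
#' pr <- beeguts_preprocess(ev, horizon = 2)
#' profile_at(pr, 1)  # exp(-0.4) ~ 0.670
#' @export
beeguts_preprocess <- function(events, horizon, grid_step = horizon / 1000) {
  events <- as_exposure_events(events)
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0")
  if (nrow(events) > 0L &&
      any(pmin(events$t_end_days, events$t_start_days) > horizon)) {
    stop("horizon does not cover all events")
  }
  t <- seq(0, horizon, by = grid_step)
  if (t[length(t)] < horizon) t <- c(t, horizon)
  conc <- numeric(length(t))
  for (i in seq_len(nrow(events))) {
    m <- events$magnitude[i]
    t0 <- events$t_start_days[i]
    t1 <- events$t_end_days[i]
    ci <- switch(events$route[i],
      acute_contact = ifelse(t >= t0, m * exp(-0.4 * (t - t0)), 0),
      acute_oral = {
        ramp <- if (t1 > t0) pmin(pmax((t - t0) / (t1 - t0), 0), 1) * m
                else ifelse(t >= t0, m, 0)
        ifelse(t <= t1, ramp, m * exp(-0.625 * (t - t1)))
      },
      chronic_oral = rep(m, length(t)),
      stop("unknown exposure route: ", events$route[i])
    )
    conc <- conc + ci
  }
  unit <- if (nrow(events) > 0L) events$unit[1L] else "TU"
  exposure_profile(0, 0, unit = unit,
                   is_toxic_units = identical(unit, "TU"),
                   dense = list(t = t, c = conc))
}

# ---------------------------------------------------------------------------
# Dose-response fitting and toxic-unit conversion

#' Two-parameter log-logistic dose-response model
#'
#' `h(c) = 1 / (1 + (c / lc50)^slope)`, the expected survival fraction at the
#' reference timepoint. `h(0) = 1`, `h(lc50) = 0.5`.
#'
#' @param conc Concentrations (>= 0).
#' @param lc50 Median lethal concentration (> 0).
#' @param slope Log-logistic slope (> 0).
#' @return Survival fractions in (0, 1].
#' @export
log_logistic_survival <- function(conc, lc50, slope) {
  ifelse(conc <= 0, 1, 1 / (1 + (conc / lc50)^slope))
}

#' Fit a log-logistic dose-response curve
#'
#' Fits `h(c) = 1/(1 + (c/LC50)^b)` to survival observed at a single reference
#' timepoint (conventionally 48 h in acute tests, 10 d in chronic tests). When
#' survivor counts and group sizes are supplied the fit maximizes the binomial
#' likelihood (counts are the native data); otherwise it minimizes squared
#' error on the survival fractions.
#'
#' @param concentrations Tested concentrations (controls at 0 allowed).
#' @param survival_fraction Observed surviving fraction in `[0, 1]` per entry.
#' @param timepoint Reference timepoint in days (e.g. 2 for 48 h acute,
#'   10 for chronic).
#' @param counts,n0 Optional surviving counts and initial group sizes; when
#'   both are given they override `survival_fraction` and a binomial
#'   likelihood is used.
#' @param endpoint_label `"LC50"` or `"LD50"`.
#' @param allow_extrapolation Set `TRUE` to accept data where no observation
#'   falls below 50% survival (the LC50 is then an extrapolation).
#' @return An object of class `dose_response_fit` with elements `lc50`,
#'   `slope`, `timepoint`, `endpoint_label`, `objective`.
#' @examples
#' conc <- c(0.5, 1, 2, 4, 8)
#' surv <- log_logistic_survival(conc, lc50 = 2, slope = 3)
#' fit_dose_response(conc, surv, timepoint = 2)
#' @export
fit_dose_response <- function(concentrations, survival_fraction = NULL,
                              timepoint, counts = NULL, n0 = NULL,
                              endpoint_label = "LC50",
                              allow_extrapolation = FALSE) {
  conc <- as.numeric(concentrations)
  if (length(unique(conc)) < 3L) {
    stop("need at least 3 distinct concentrations to fit a dose-response")
  }
  use_counts <- !is.null(counts) && !is.null(n0)
  if (use_counts) {
    counts <- as.numeric(counts); n0 <- rep_len(as.numeric(n0), length(counts))
    if (length(counts) != length(conc)) stop("counts must match concentrations")
    if (any(counts < 0) || any(counts > n0)) stop("counts must lie in [0, n0]")
    frac <- counts / n0
  } else {
    frac <- as.numeric(survival_fraction)
    if (length(frac) != length(conc)) {
      stop("survival_fraction must match concentrations")
    }
    if (any(frac < 0 | frac > 1)) stop("survival fractions must lie in [0, 1]")
  }
  if (length(unique(round(frac, 10))) == 1L) {
    stop("all survival values identical: LC50 not identifiable")
  }
  if (all(frac >= 0.5) && !allow_extrapolation) {
    stop("no observation below 50% survival; set allow_extrapolation = TRUE ",
         "to fit anyway")
  }

  pos <- conc > 0
  # start values: concentration nearest 50% survival, moderate slope
  lc0 <- if (any(pos & frac < 0.5)) min(conc[pos & frac < 0.5]) else
    exp(mean(log(conc[pos])))
  obj <- function(par) {
    lc50 <- exp(par[1]); slope <- exp(par[2])
    h <- log_logistic_survival(conc, lc50, slope)
    if (use_counts) {
      h <- pmin(pmax(h, 1e-12), 1 - 1e-12)
      -sum(stats::dbinom(counts, size = n0, prob = h, log = TRUE))
    } else {
      sum((frac - h)^2)
    }
  }
  fit <- stats::optim(c(log(lc0), log(2)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  structure(
    list(lc50 = exp(fit$par[1]), slope = exp(fit$par[2]),
         timepoint = timepoint, endpoint_label = endpoint_label,
         objective = if (use_counts) "binomial" else "least_squares",
         value = fit$value, convergence = fit$convergence),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> %s = %.6g, slope = %.4g (t = %g d, %s)\n",
              x$endpoint_label, x$lc50, x$slope, x$timepoint, x$objective))
  invisible(x)
}

#' Convert an exposure profile to toxic units
#'
#' Divides all levels by the study LC50/LD50 so that 1 TU is the concentration
#' killing half the test organisms at the reference timepoint. The inverse
#' operation is [from_toxic_units()]; the round trip is the identity up to
#' floating-point error. TU conversion is a linear bijection, so model
#' predictions are unchanged when thresholds are back-scaled accordingly.
#'
#' @param profile An [exposure_profile()] in raw study units.
#' @param fit A [dose_response_fit()] (or a number) providing the LC50.
#' @return The profile with levels in TU and `is_toxic_units = TRUE`.
#' @export
to_toxic_units <- function(profile, fit) {
  stopifnot(inherits(profile, "exposure_profile"))
  lc50 <- lc50_of(fit)
  if (profile$is_toxic_units) {
    stop("profile is already in toxic units")
  }
  scale_profile(profile, 1 / lc50, unit = "TU", is_toxic_units = TRUE)
}

#' @rdname to_toxic_units
#' @param unit Unit label restored on back-conversion.
#' @export
from_toxic_units <- function(profile, fit, unit = "study units") {
  stopifnot(inherits(profile, "exposure_profile"))
  lc50 <- lc50_of(fit)
  if (!profile$is_toxic_units) {
    stop("profile is not in toxic units")
  }
  scale_profile(profile, lc50, unit = unit, is_toxic_units = FALSE)
}

lc50_of <- function(fit) {
  lc50 <- if (inherits(fit, "dose_response_fit")) fit$lc50 else as.numeric(fit)
  if (!is.finite(lc50) || lc50 <= 0) stop("lc50 must be > 0")
  lc50
}

scale_profile <- function(profile, factor, unit, is_toxic_units) {
  dense <- profile$dense
  if (!is.null(dense)) dense$c <- dense$c * factor
  exposure_profile(profile$breakpoints, profile$levels * factor,
                   unit = unit, is_toxic_units = is_toxic_units,
                   dense = dense)
}
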