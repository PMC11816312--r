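# Synthetic study designs and survival datasets with known ground truth.
#
# The generator emulates the layout of the standard regulatory honeybee
# tests: acute contact (topical dose, observed from 6 h up to several days),
# acute oral (feeding window of up to 6 h) and chronic oral (contaminated
# food over 10 days); groups of 10 bees, at least three replicates per
# concentration, a geometric concentration ladder, plus untreated controls.
# Deaths are drawn from exactly the multinomial interval distribution the
# calibration likelihood assumes, so parameter-recovery tests are
# well-specified by construction.

#' Construct a synthetic study design
#'
#' Builds a geometric concentration ladder centred on 1 TU (plus an
#' untreated control), replicate structure and observation schedule matching
#' the standard test guidelines for the chosen route: a 1-h contact pulse, a
#' 6-h feeding window, or constant chronic exposure; observations at 6 h
#' (acute routes) and then daily.
#'
#' @param route `"acute_contact"`, `"acute_oral"` or `"chronic_oral"`.
#' @param n_levels Number of non-control concentration levels (>= 2).
#' @param spacing Geometric spacing factor between levels (default 2).
#' @param n_replicates Replicates per level (default 3).
#' @param n0 Individuals per replicate (default 10).
#' @param horizon Last observation in days; default 2 d for acute routes
#'   (48-h standard), 10 d chronic.
#' @param feeding_duration Acute-oral feeding window in days (default 6 h).
#' @param center Centre of the concentration ladder (default 1 TU).
#' @return An object of class `study_design`.
#' @examples
#' make_design("acute_contact", n_levels = 5)$levels  # 0, 0.25 ... 4 TU
#' @export
make_design <- function(route = c("acute_contact", "acute_oral",
                                  "chronic_oral"),
                        n_levels = 5, spacing = 2, n_replicates = 3,
                        n0 = 10, horizon = NULL, feeding_duration = 0.25,
                        center = 1) {
  route <- match.arg(route)
  if (n_levels < 2) stop("need at least 2 concentration levels")
  if (is.null(horizon)) horizon <- if (route == "chronic_oral") 10 else 2
  if (horizon <= 0) stop("horizon must be > 0")
  k <- seq_len(n_levels) - (n_levels + 1) / 2
  levels <- c(0, center * spacing^k)
  schedule <- if (route == "chronic_oral") seq_len(horizon) else
    unique(c(0.25, seq_len(horizon)))
  schedule <- sort(schedule[schedule <= horizon + 1e-9])
  structure(list(route = route, levels = levels,
                 n_replicates = n_replicates, n0 = n0,
                 schedule = schedule, horizon = horizon,
                 feeding_duration = feeding_duration),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design %s> levels: %s | %d reps x %d ind | obs at %s d\n",
              x$route, paste(signif(x$levels, 3), collapse = ", "),
              x$n_replicates, x$n0,
              paste(x$schedule, collapse = ", ")))
  invisible(x)
}

design_events <- function(design, level) {
  switch(design$route,
    acute_contact = exposure_events("acute_contact", level, t_start = 0),
    acute_oral = exposure_events("acute_oral", level, t_start = 0,
                                 t_end = design$feeding_duration),
    chronic_oral = exposure_events("chronic_oral", level, t_start = 0,
                                   t_end = design$horizon))
}

#' Exposure profiles for every level of a design
#'
#' @param design A [make_design()] object.
#' @param dt_unit Discretization unit in days (default 1 h).
#' @return Named list of [exposure_profile()]s, labels `"control"`,
#'   `"T1"`, ... in increasing concentration.
#' @export
design_profiles <- function(design, dt_unit = 1 / 24) {
  labels <- treatment_labels(design)
  profs <- lapply(seq_along(design$levels), function(i) {
    lv <- design$levels[i]
    if (lv == 0) {
      exposure_profile(0, 0)
    } else {
      discretize_events(design_events(design, lv), dt_unit = dt_unit,
                        horizon = design$horizon)
    }
  })
  names(profs) <- labels
  profs
}

treatment_labels <- function(design) {
  nz <- cumsum(design$levels > 0)
  ifelse(design$levels == 0, "control", paste0("T", nz))
}

#' Simulate a survival dataset from known TKTD parameters
#'
#' Solves the chosen model for every treatment of the design and draws
#' survivor counts from the multinomial death-interval distribution induced
#' by S(t) — the same construction the calibration likelihood uses. Counts
#' are non-increasing by construction; the same seed reproduces the same
#' dataset.
#'
#' @param design A [make_design()] object.
#' @param model Model tag (see [solve_tktd()]).
#' @param true_params A [tktd_params()] object (in TU if the design levels
#'   are in TU).
#' @param seed Integer seed.
#' @param dt_unit Discretization unit (default 1 h).
#' @param n_steps Euler steps for the solver.
#' @return A [survival_dataset()]; the true parameters, model and seed are
#'   kept in `metadata`.
#' @examples
#' des <- make_design("acute_contact", horizon = 2)
#' pars <- tktd_params(kd = 0.6, hb = 0.01, mechanism = "SD",
#'                     z = 0.2, b_kill = 1.5)
#' ds <- simulate_dataset(des, "BUFFER_SD", pars, seed = 42)
#' @export
simulate_dataset <- function(design, model, true_params, seed,
                             dt_unit = 1 / 24, n_steps = 1000) {
  stopifnot(inherits(design, "study_design"),
            inherits(true_params, "tktd_params"))
  model <- match.arg(model, MODEL_TAGS)
  set.seed(seed)
  profs <- design_profiles(design, dt_unit)
  labels <- names(profs)
  rows <- list()
  for (i in seq_along(profs)) {
    traj <- solve_tktd(model, true_params, profs[[i]],
                       t_obs = design$schedule, n_steps = n_steps,
                       horizon = design$horizon)
    for (r in seq_len(design$n_replicates)) {
      counts <- sample_counts(traj$S_obs, design$n0)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = labels[i], replicate = paste0("R", r),
        time_days = design$schedule, n_alive = counts,
        n_initial = design$n0)
    }
  }
  survival_dataset(
    do.call(rbind, rows), profs,
    metadata = list(route = design$route, model = model, seed = seed,
                    true_params = true_params,
                    unit = "TU", is_toxic_units = TRUE))
}
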