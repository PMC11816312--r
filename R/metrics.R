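# EFSA model-performance criteria for TKTD survival fits: the posterior
# predictive check (PPC), the normalized root-mean-square error (NRMSE) and
# the survival probability prediction error (SPPE).

#' Posterior predictive check
#'
#' Percentage of observed survivor numbers falling within the predicted
#' uncertainty limits; observations on the boundary count as inside. 100%
#' means every observation is covered; values below 50% indicate poor
#' performance.
#'
#' @param observed Observed survivor counts.
#' @param lower,upper Predicted uncertainty limits, one pair per observation.
#' @return Percentage in `[0, 100]`.
#' @export
ppc <- function(observed, lower, upper) {
  n <- length(observed)
  if (length(lower) != n || length(upper) != n) {
    stop("observed, lower and upper must have equal length")
  }
  if (n == 0L) stop("no observations")
  if (any(upper < lower)) stop("upper limits below lower limits")
  100 * mean(observed >= lower & observed <= upper)
}

#' Normalized root-mean-square error
#'
#' Classical RMSE between observed and predicted survivor numbers,
#' normalized by the mean of all observations; 0% is perfect agreement and
#' values below 50% are considered acceptable.
#'
#' @param observed Observed survivor counts.
#' @param predicted Predicted survivor numbers (posterior-predictive
#'   medians).
#' @return Percentage (>= 0).
#' @export
nrmse <- function(observed, predicted) {
  n <- length(observed)
  if (length(predicted) != n) stop("observed and predicted length mismatch")
  if (n == 0L) stop("no observations")
  m <- mean(observed)
  if (m <= 0) stop("mean of observations is zero: NRMSE undefined")
  100 * sqrt(mean((observed - predicted)^2)) / m
}

#' Survival probability prediction error
#'
#' Per-replicate difference between observed and predicted survivor numbers
#' at the last observation, normalized by the initial number of individuals:
#' `100 * (observed - predicted) / n_initial`. 0% is a perfect prediction;
#' the sign convention follows the formula as written (a model predicting
#' too many survivors gives a negative SPPE).
#'
#' @param observed_final,predicted_final Survivors at the last timepoint,
#'   one value per replicate.
#' @param n_initial Initial individuals per replicate (> 0).
#' @return Percentages in `[-100, 100]`, one per replicate.
#' @export
sppe <- function(observed_final, predicted_final, n_initial) {
  n <- length(observed_final)
  if (length(predicted_final) != n) stop("length mismatch")
  n_initial <- rep_len(n_initial, n)
  if (any(n_initial <= 0)) stop("n_initial must be > 0")
  100 * (observed_final - predicted_final) / n_initial
}

#' Model-performance report from posterior predictions
#'
#' Computes PPC over all observations, NRMSE of the posterior-predictive
#' medians (controls included), and per-replicate SPPE at each replicate's
#' final timepoint, with the dataset-level minimum and maximum.
#'
#' @param predictions A [posterior_predict()] data frame.
#' @return An object of class `metrics_report` with elements
#'   `ppc_pass_fraction`, `nrmse`, `sppe_per_replicate`, `sppe_min`,
#'   `sppe_max`.
#' @export
metrics_report <- function(predictions) {
  req <- c("treatment", "replicate", "time_days", "observed", "n_initial",
           "pred_median", "pred_lower", "pred_upper")
  if (!all(req %in% names(predictions))) {
    stop("predictions must come from posterior_predict()")
  }
  p <- ppc(predictions$observed, predictions$pred_lower,
           predictions$pred_upper)
  nr <- nrmse(predictions$observed, predictions$pred_median)
  key <- paste(predictions$treatment, predictions$replicate, sep = "\r")
  sp <- vapply(split(seq_len(nrow(predictions)), key), function(ix) {
    rows <- predictions[ix, ]
    last <- which.max(rows$time_days)
    sppe(rows$observed[last], rows$pred_median[last], rows$n_initial[last])
  }, 0)
  names(sp) <- gsub("\r", "/", names(sp), fixed = TRUE)
  structure(list(ppc_pass_fraction = p, nrmse = nr,
                 sppe_per_replicate = sp,
                 sppe_min = min(sp), sppe_max = max(sp)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> PPC = %.1f%%, NRMSE = %.1f%%, SPPE in [%.1f%%, %.1f%%]\n",
              x$ppc_pass_fraction, x$nrmse, x$sppe_min, x$sppe_max))
  invisible(x)
}
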