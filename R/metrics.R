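# PK metric extraction and the fold-error validation arithmetic: a
# prediction is conventionally acceptable when predicted/observed lies in
# the inclusive two-fold range [0.5, 2].

#' Non-compartmental PK metrics from a concentration-time curve
#'
#' `Cmax`/`tmax` from the grid maximum; `AUC_0_t` by linear trapezoid;
#' `AUC_0_inf = AUC_0_t + Clast/lambda_z`. The terminal rate constant
#' `lambda_z` is estimated by log-linear regression on the final descending
#' points (starting from the last 3 and extending backwards while the
#' regression R-squared improves), unless an analytic value is supplied
#' (e.g. the terminal eigenvalue of a known disposition model).
#'
#' @param times h, strictly increasing, >= 3 points.
#' @param conc ng/mL, non-negative.
#' @param lambda_z optional analytic terminal rate constant, 1/h.
#' @return A list of class `pk_metrics`: `Cmax` (ng/mL), `tmax` (h),
#'   `AUC_0_t`, `AUC_0_inf` (ng h/mL), `lambda_z` (1/h), `t_half` (h).
#' @examples
#' t <- seq(0, 24, 0.1)
#' pk_metrics(t, 10 * exp(-0.3 * t))$AUC_0_inf # ~ 10 / 0.3
#' @export
pk_metrics <- function(times, conc, lambda_z = NULL) {
  if (length(times) < 3 || length(times) != length(conc)) {
    stop("need >= 3 matched (time, conc) points", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be non-negative",
                          call. = FALSE)
  if (all(conc == 0)) {
    warning("all-zero concentration profile; returning zero metrics")
    return(structure(list(Cmax = 0, tmax = times[1], AUC_0_t = 0,
                          AUC_0_inf = 0, lambda_z = NA_real_,
                          t_half = NA_real_), class = "pk_metrics"))
  }
  imax <- which.max(conc)
  auc_t <- sum(diff(times) * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
  if (is.null(lambda_z)) lambda_z <- .lambda_z_regression(times, conc)
  clast <- conc[length(conc)]
  auc_inf <- auc_t + ifelse(is.finite(lambda_z) && lambda_z > 0,
                            clast / lambda_z, 0)
  structure(list(Cmax = conc[imax], tmax = times[imax],
                 AUC_0_t = auc_t, AUC_0_inf = auc_inf,
                 lambda_z = lambda_z, t_half = log(2) / lambda_z),
            class = "pk_metrics")
}

# log-linear tail regression: start from the last 3 positive, descending
# points after tmax; extend backwards while R-squared improves.
.lambda_z_regression <- function(times, conc) {
  imax <- which.max(conc)
  tail_idx <- seq(imax, length(conc))
  tail_idx <- tail_idx[conc[tail_idx] > 0]
  if (length(tail_idx) < 3) {
    stop("no descending terminal phase available for extrapolation",
         call. = FALSE)
  }
  n <- length(tail_idx)
  best <- NULL
  best_r2 <- -Inf
  for (k in 3:n) {
    idx <- tail_idx[(n - k + 1):n]
    fit <- stats::lm(log(conc[idx]) ~ times[idx])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > best_r2 + 1e-12) {
      best_r2 <- r2
      best <- fit
    } else {
      break
    }
  }
  slope <- unname(stats::coef(best)[2])
  if (slope >= 0) {
    stop("terminal phase is not descending; cannot extrapolate",
         call. = FALSE)
  }
  -slope
}

#' Fold error of a prediction
#'
#' `fold_error = predicted / observed`.
#'
#' @param predicted predicted value(s), >= 0.
#' @param observed observed value(s), > 0.
#' @return predicted/observed (vectorized).
#' @examples
#' fold_error(11.45, 10.80)
#' @export
fold_error <- function(predicted, observed) {
  if (any(observed <= 0)) stop("observed values must be positive",
                               call. = FALSE)
  if (any(predicted < 0)) stop("predicted values must be non-negative",
                               call. = FALSE)
  predicted / observed
}

#' Two-fold validation of predicted vs observed PK parameters
#'
#' Computes the fold error for each (parameter, predicted, observed) record
#' and flags whether it lies within the inclusive two-fold acceptance range
#' `[0.5, 2]`.
#'
#' @param records data frame with columns `parameter`, `predicted`,
#'   `observed` (extra columns are carried through).
#' @return The input with added columns `fold_error` and
#'   `within_two_fold`, plus an attribute `n_pass` (count of passing
#'   records).
#' @export
two_fold_validation <- function(records) {
  req <- c("parameter", "predicted", "observed")
  if (!all(req %in% names(records))) {
    stop("records must have columns parameter, predicted, observed",
         call. = FALSE)
  }
  records$fold_error <- fold_error(records$predicted, records$observed)
  records$within_two_fold <- records$fold_error >= 0.5 &
    records$fold_error <= 2.0
  attr(records, "n_pass") <- sum(records$within_two_fold)
  records
}

#' Percent improvement of a test value over a reference
#'
#' `100 * (test - reference) / reference`. A ratio-based measure: it is not
#' antisymmetric in its arguments.
#'
#' @param test test value(s).
#' @param reference reference value(s), > 0.
#' @return Percent improvement (vectorized).
#' @examples
#' percent_improvement(31, 18)
#' @export
percent_improvement <- function(test, reference) {
  if (any(reference <= 0)) stop("reference must be positive", call. = FALSE)
  100 * (test - reference) / reference
}
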