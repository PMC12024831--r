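# Cumulative dissolution profiles and the five classical release-kinetics
# models: zero-order, first-order, Higuchi, Korsmeyer-Peppas and
# Hixson-Crowell. Fits are nonlinear least squares on the untransformed
# cumulative percent released (linearization distorts error weighting); a
# linearized log-log option reproduces the classical Korsmeyer-Peppas fit.

#' Construct a cumulative dissolution profile
#'
#' @param time_min sampling times in minutes, strictly increasing, first >= 0.
#' @param released cumulative percent of dose released at each time. Small
#'   negative values or overshoot above 100 (assay noise) are tolerated
#'   within \[-2, 105\] and flagged with a warning.
#' @param pH optional per-point pH label (the dissolution stage medium).
#' @param formulation_id optional identifier carried through fitting reports.
#' @return An object of class `dissolution_profile`.
#' @export
dissolution_profile <- function(time_min, released, pH = NULL,
                                formulation_id = NA_character_) {
  if (length(time_min) != length(released) || length(time_min) < 3) {
    stop("profile needs >= 3 matched (time, released) points", call. = FALSE)
  }
  if (any(!is.finite(time_min)) || any(!is.finite(released))) {
    stop("profile values must be finite", call. = FALSE)
  }
  if (time_min[1] < 0 || any(diff(time_min) <= 0)) {
    stop("times must be strictly increasing and start at >= 0", call. = FALSE)
  }
  if (any(released < -2 | released > 105)) {
    stop("released values outside [-2, 105] are not plausible assay noise",
         call. = FALSE)
  }
  if (any(released < 0 | released > 100)) {
    warning("released values slightly outside [0, 100]; ",
            "treated as assay noise")
  }
  df <- data.frame(time_min = time_min, released = released)
  if (!is.null(pH)) {
    stopifnot(length(pH) == length(time_min))
    df$pH <- pH
  }
  structure(df, formulation_id = formulation_id,
            class = c("dissolution_profile", "data.frame"))
}

#' Evaluate a release-kinetics model
#'
#' Closed forms (F in percent released, t in minutes):
#' \itemize{
#'   \item zero-order: `F = k0 t`
#'   \item first-order: `F = Fmax (1 - exp(-k1 t))`
#'   \item Higuchi: `F = kH sqrt(t)`
#'   \item Korsmeyer-Peppas: `F = kKP t^n`
#'   \item Hixson-Crowell (cube-root law `W0^(1/3) - Wt^(1/3) = kHC t`):
#'     `F = Fmax - (Fmax^(1/3) - kHC t)^3`, complete once
#'     `kHC t >= Fmax^(1/3)`.
#' }
#' `Fmax` is 100 unless the fit estimated a lower release plateau.
#'
#' @param fit a `release_model_fit` (from [fit_release_model()]) or a list
#'   with elements `model` and `params`.
#' @param times times in minutes, all >= 0.
#' @param clip if `TRUE`, clip predictions at 100 percent.
#' @return Predicted cumulative percent released.
#' @export
predict_release <- function(fit, times, clip = FALSE) {
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  p <- fit$params
  fmax <- p[["Fmax"]] %||% 100
  out <- switch(fit$model,
    zero_order = p[["k0"]] * times,
    first_order = fmax * (1 - exp(-p[["k1"]] * times)),
    higuchi = p[["kH"]] * sqrt(times),
    korsmeyer_peppas = p[["kKP"]] * times^p[["n"]],
    hixson_crowell = {
      core <- pmax(fmax^(1 / 3) - p[["kHC"]] * times, 0)
      fmax - core^3
    },
    stop("unknown release model: ", fit$model, call. = FALSE)
  )
  if (clip) out <- pmin(out, 100)
  out
}

.rsq <- function(obs, pred) {
  sse <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(ifelse(sse == 0, 1, -Inf))
  1 - sse / sst
}

.new_fit <- function(model, params, profile, t, f) {
  pred <- predict_release(list(model = model, params = params), t)
  structure(list(model = model, params = params,
                 r_squared = .rsq(f, pred),
                 n_points_used = length(t),
                 formulation_id = attr(profile, "formulation_id")),
            class = "release_model_fit")
}

#' @export
print.release_model_fit <- function(x, ...) {
  cat("Release model fit:", x$model, "\n")
  cat("  parameters:",
      paste(names(x$params), signif(unlist(x$params), 6),
            sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  R-squared = %.4f on %d points\n",
              x$r_squared, x$n_points_used))
  invisible(x)
}

# Deterministic multi-start nonlinear LS on untransformed percent released.
# Starting grid: 5 log-spaced rate constants bracketing a scale estimate,
# and n in {0.5, 1, 1.5} for Korsmeyer-Peppas; best final SSE wins.
.nls_grid <- function(form, data, starts_list) {
  best <- NULL
  best_sse <- Inf
  for (st in starts_list) {
    fitted <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = data, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fitted)) next
    sse <- sum(stats::residuals(fitted)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fitted
    }
  }
  best
}

#' Fit one release-kinetics model to a dissolution profile
#'
#' Least-squares fit on the untransformed cumulative percent released;
#' `r_squared = 1 - SSres/SStot` on the points used. Only points with
#' `t > 0` enter the fit. Deterministic: the multi-start grid is fixed.
#'
#' @param profile a [dissolution_profile()].
#' @param model one of `"zero_order"`, `"first_order"`, `"higuchi"`,
#'   `"korsmeyer_peppas"`, `"hixson_crowell"`.
#' @param fmax_free for first-order and Hixson-Crowell: also estimate the
#'   release plateau `Fmax` instead of assuming complete (100 percent)
#'   release. Useful for profiles that level off below 100.
#' @param kp_max_fraction optional: restrict the Korsmeyer-Peppas fit to
#'   points with released fraction at most this value (classical "first
#'   60 percent" convention = 0.6). Default `NULL` uses all points.
#' @param linearized for Korsmeyer-Peppas only: classical log-log linear
#'   regression instead of nonlinear least squares.
#' @return A `release_model_fit` with elements `model`, `params`,
#'   `r_squared`, `n_points_used`.
#' @export
fit_release_model <- function(profile, model = .enum_release_models,
                              fmax_free = FALSE, kp_max_fraction = NULL,
                              linearized = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(profile, "dissolution_profile"))
  keep <- profile$time_min > 0
  t <- profile$time_min[keep]
  f <- profile$released[keep]
  if (model == "korsmeyer_peppas" && !is.null(kp_max_fraction)) {
    sub <- f <= 100 * kp_max_fraction
    if (sum(sub) >= 3) {
      t <- t[sub]
      f <- f[sub]
    }
  }
  n_par <- switch(model, zero_order = 1, higuchi = 1,
                  first_order = 1 + fmax_free,
                  hixson_crowell = 1 + fmax_free,
                  korsmeyer_peppas = 2)
  if (length(t) < n_par + 1) {
    stop("too few points with t > 0 to fit ", model,
         " (need at least ", n_par + 1, ")", call. = FALSE)
  }
  dat <- data.frame(t = t, f = f)
  scale_k <- max(mean(f) / mean(t), .Machine$double.eps)

  if (model == "zero_order") {
    k0 <- sum(f * t) / sum(t^2) # exact LS through the origin
    return(.new_fit(model, list(k0 = max(k0, 0)), profile, t, f))
  }
  if (model == "higuchi") {
    s <- sqrt(t)
    kH <- sum(f * s) / sum(s^2)
    return(.new_fit(model, list(kH = max(kH, 0)), profile, t, f))
  }
  if (model == "korsmeyer_peppas") {
    if (linearized) {
      ok <- f > 0
      if (sum(ok) < 3) stop("too few positive points for log-log fit",
                            call. = FALSE)
      lmfit <- stats::lm(log(f[ok]) ~ log(t[ok]))
      params <- list(kKP = exp(unname(stats::coef(lmfit)[1])),
                     n = unname(stats::coef(lmfit)[2]))
      return(.new_fit(model, params, profile, t, f))
    }
    starts <- list()
    for (k in scale_k * 10^seq(-2, 2)) {
      for (n0 in c(0.5, 1, 1.5)) {
        starts[[length(starts) + 1]] <- list(lk = log(k), n = n0)
      }
    }
    fitted <- .nls_grid(f ~ exp(lk) * t^n, dat, starts)
    if (is.null(fitted)) stop("Korsmeyer-Peppas fit did not converge",
                              call. = FALSE)
    co <- stats::coef(fitted)
    return(.new_fit(model, list(kKP = exp(unname(co["lk"])),
                                n = unname(co["n"])), profile, t, f))
  }
  if (model == "first_order") {
    k_starts <- (1 / stats::median(t)) * 10^seq(-2, 2)
    if (fmax_free) {
      starts <- lapply(k_starts, function(k)
        list(lk = log(k), lF = log(max(max(f), 1))))
      fitted <- .nls_grid(f ~ exp(lF) * (1 - exp(-exp(lk) * t)), dat, starts)
    } else {
      starts <- lapply(k_starts, function(k) list(lk = log(k)))
      fitted <- .nls_grid(f ~ 100 * (1 - exp(-exp(lk) * t)), dat, starts)
    }
    if (is.null(fitted)) stop("first-order fit did not converge",
                              call. = FALSE)
    co <- stats::coef(fitted)
    params <- list(k1 = exp(unname(co["lk"])))
    if (fmax_free) params$Fmax <- exp(unname(co["lF"]))
    return(.new_fit(model, params, profile, t, f))
  }
  # hixson_crowell
  k_starts <- (100^(1 / 3) / max(t)) * 10^seq(-2, 2)
  if (fmax_free) {
    starts <- lapply(k_starts, function(k)
      list(lk = log(k), lF = log(max(max(f), 1))))
    fitted <- .nls_grid(
      f ~ exp(lF) - pmax(exp(lF)^(1 / 3) - exp(lk) * t, 0)^3, dat, starts)
  } else {
    starts <- lapply(k_starts, function(k) list(lk = log(k)))
    fitted <- .nls_grid(
      f ~ 100 - pmax(100^(1 / 3) - exp(lk) * t, 0)^3, dat, starts)
  }
  if (is.null(fitted)) stop("Hixson-Crowell fit did not converge",
                            call. = FALSE)
  co <- stats::coef(fitted)
  params <- list(kHC = exp(unname(co["lk"])))
  if (fmax_free) params$Fmax <- exp(unname(co["lF"]))
  .new_fit("hixson_crowell", params, profile, t, f)
}

#' Fit all five release-kinetics models and rank them
#'
#' Fits the five models and returns them sorted by descending R-squared.
#' Ties (R-squared equal within 1e-9, e.g. nested models on noise-free
#' data) are broken by model order: zero-order, first-order, Higuchi,
#' Korsmeyer-Peppas, Hixson-Crowell. A model that fails to fit is kept in
#' the output as a failure record (with `r_squared = NA`) rather than
#' aborting the batch.
#'
#' @inheritParams fit_release_model
#' @return A list of `release_model_fit` objects, best first, with a
#'   `summary` attribute (data frame of model, R-squared, parameters).
#' @export
fit_all_models <- function(profile, fmax_free = FALSE,
                           kp_max_fraction = NULL) {
  fits <- lapply(.enum_release_models, function(m) {
    tryCatch(fit_release_model(profile, m, fmax_free = fmax_free,
                               kp_max_fraction = kp_max_fraction),
             error = function(e) {
               structure(list(model = m, params = list(),
                              r_squared = NA_real_, n_points_used = 0L,
                              error = conditionMessage(e)),
                         class = "release_model_fit")
             })
  })
  r2 <- vapply(fits, function(x) x$r_squared, numeric(1))
  key <- round(r2 / 1e-9) * 1e-9
  key[is.na(key)] <- -Inf
  ord <- order(-key, seq_along(fits))
  fits <- fits[ord]
  smry <- data.frame(
    model = vapply(fits, function(x) x$model, character(1)),
    r_squared = vapply(fits, function(x) x$r_squared, numeric(1)))
  attr(fits, "summary") <- smry
  fits
}

#' Classify the release mechanism from the Korsmeyer-Peppas exponent
#'
#' For the diffusional exponent `n`: `n <= 0.45` indicates Fickian
#' diffusion, `0.45 < n <= 0.89` anomalous (coupled diffusion/relaxation)
#' transport, and `n > 0.89` case-II transport or polymer erosion.
#'
#' @param n positive diffusional exponent (vectorized).
#' @return Character vector: `"fickian_diffusion"`, `"anomalous_transport"`
#'   or `"case_II_or_erosion"`.
#' @export
classify_mechanism <- function(n) {
  if (any(n <= 0)) stop("diffusional exponent must be positive",
                        call. = FALSE)
  ifelse(n <= 0.45, "fickian_diffusion",
         ifelse(n <= 0.89, "anomalous_transport", "case_II_or_erosion"))
}
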