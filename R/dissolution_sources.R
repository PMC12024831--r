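# In-simulation drug release mechanisms:
#  * solid_particles - a polydisperse (log-normal) particle population
#    dissolving by the shrinking-particle Noyes-Whitney rate with the
#    standard diffusion-layer convention h = min(r, 30 um) (the published
#    form of the Johnson dissolution model);
#  * dispersed_profile - a tabulated cumulative-release profile (the
#    controlled-release "dispersed" input used for solid dispersions),
#    applied to the unreleased formulation mass wherever it resides in the
#    GI tract.

#' Build a discretized log-normal particle size distribution
#'
#' Log-normal in diameter with median `D50` and 90th percentile `D90`
#' (`sigma = ln(D90/D50) / 1.281552`), discretized into `n_bins`
#' equal-probability bins, each represented by the median diameter of its
#' probability slice.
#'
#' @param D50 median particle diameter, um.
#' @param D90 90th-percentile diameter, um; must exceed `D50`.
#' @param n_bins number of bins (>= 1).
#' @return An object of class `particle_size_distribution` with fields
#'   `D50`, `D90`, `sigma`, and `bins` (data frame of `diameter_um`,
#'   `radius_um`, `number_fraction`, `mass_fraction`).
#' @examples
#' psd <- build_psd(150, 250, 10)
#' psd$bins
#' @export
build_psd <- function(D50, D90, n_bins = 10) {
  if (!(D90 > D50 && D50 > 0)) stop("need D90 > D50 > 0", call. = FALSE)
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  sigma <- log(D90 / D50) / stats::qnorm(0.9)
  p <- (seq_len(n_bins) - 0.5) / n_bins
  diam <- D50 * exp(sigma * stats::qnorm(p))
  number_fraction <- rep(1 / n_bins, n_bins)
  mass_fraction <- diam^3 / sum(diam^3)
  structure(list(D50 = D50, D90 = D90, sigma = sigma,
                 bins = data.frame(diameter_um = diam,
                                   radius_um = diam / 2,
                                   number_fraction = number_fraction,
                                   mass_fraction = mass_fraction)),
            class = "particle_size_distribution")
}

#' Shrinking-particle dissolution rate for one particle bin
#'
#' Noyes-Whitney rate for a population of identical spherical particles of
#' total mass `mass_mg` and current radius `radius_um`:
#' `dM/dt = -(3 D M) / (rho h r) * (Cs - C)`, with diffusion-layer
#' thickness `h = min(r, h_cap)`. The returned value is the (positive)
#' dissolution rate in mg/min; it is 0 when the bin is exhausted or when
#' the lumen is at or above saturation (no particle growth - supersaturated
#' drug is handled by the separate precipitation pathway).
#'
#' @param mass_mg remaining mass in the bin, mg.
#' @param radius_um current particle radius, um.
#' @param Cs local solubility, mg/mL.
#' @param C local dissolved concentration, mg/mL (>= 0).
#' @param Dw diffusion coefficient, cm^2/s.
#' @param density drug true density, g/mL.
#' @param h_cap_um diffusion-layer cap, um (default 30).
#' @return Dissolution rate, mg/min (non-negative).
#' @export
particle_dissolution_rate <- function(mass_mg, radius_um, Cs, C,
                                      Dw, density = DEFAULT_DRUG_DENSITY_G_ML,
                                      h_cap_um = H_DIFFUSION_CAP_UM) {
  if (Cs <= 0) stop("solubility Cs must be positive", call. = FALSE)
  if (C < 0) stop("lumen concentration must be non-negative", call. = FALSE)
  if (radius_um < 0) stop("radius must be non-negative", call. = FALSE)
  if (mass_mg <= 0 || radius_um == 0) return(0)
  r_cm <- radius_um / UM_PER_CM
  h_cm <- min(radius_um, h_cap_um) / UM_PER_CM
  rho <- density * 1000 # mg/mL == mg/cm^3
  Dw_min <- Dw * 60 # cm^2/min
  rate <- 3 * Dw_min * mass_mg / (rho * h_cm * r_cm) * (Cs - C)
  max(rate, 0)
}

#' Instantaneous release rate from a tabulated cumulative profile
#'
#' Derivative of the monotone piecewise-linear interpolant of the
#' cumulative released fraction versus time. A profile that is not
#' non-decreasing (assay noise) is first corrected by a running maximum,
#' with a warning. The rate is 0 before time zero and 0 after the last
#' tabulated time point.
#'
#' @param profile a [dissolution_profile()] (percent released vs minutes).
#' @param t_min query times in minutes.
#' @return Release rate as fraction of dose per minute.
#' @examples
#' p <- dissolution_profile(c(0, 50, 100), c(0, 50, 100))
#' tabulated_release_rate(p, 50)
#' @export
tabulated_release_rate <- function(profile, t_min) {
  stopifnot(inherits(profile, "dissolution_profile"))
  ft <- .profile_knots(profile)
  idx <- findInterval(t_min, ft$t, left.open = TRUE)
  rate <- rep(0, length(t_min))
  inside <- idx >= 1 & idx < length(ft$t) & t_min >= 0
  rate[inside] <- ft$slope[idx[inside]]
  # points exactly at t = 0 take the first segment's slope
  at0 <- t_min == 0 & length(ft$t) > 1
  rate[at0] <- ft$slope[1]
  rate
}

# Knot representation of a cumulative-release profile in fraction units:
# monotone (running-maximum corrected) with an implicit (0, 0) anchor.
.profile_knots <- function(profile) {
  t <- profile$time_min
  f <- profile$released / 100
  if (any(diff(f) < 0)) {
    warning("non-monotone cumulative profile corrected by running maximum")
    f <- cummax(f)
  }
  f <- pmin(pmax(f, 0), 1)
  if (t[1] > 0) {
    t <- c(0, t)
    f <- c(0, f)
  }
  slope <- diff(f) / diff(t)
  list(t = t, f = f, slope = slope)
}

#' Declare the in-simulation release source
#'
#' `release_source_solid()` describes an immediate-release solid (e.g. a
#' conventional tablet) dissolving by the shrinking-particle model from a
#' polydisperse particle population. `release_source_dispersed()` drives
#' release from a tabulated in vitro cumulative-release profile: the
#' unreleased formulation mass transits with lumen contents and releases
#' wherever it currently resides; released drug joins the local dissolved
#' pool, subject to local solubility and precipitation.
#'
#' For still-rising profiles the in vitro test may simply end before release
#' is complete. With `extend = "final_slope"` (default) the simulator
#' continues release beyond the last tabulated point at the mean release
#' rate over the final portion of the profile (last `extend_window`
#' fraction of the time span) until 100 percent; profiles that have
#' plateaued have near-zero final slope, so extension is a no-op for them
#' (slopes below 0.5 percent/h are treated as zero). `extend = "none"`
#' stops release at the last tabulated point.
#'
#' @param psd a [build_psd()] particle size distribution.
#' @param profile a [dissolution_profile()].
#' @param density drug true density, g/mL.
#' @param extend `"final_slope"` or `"none"`.
#' @param extend_window fraction of the profile time span used to estimate
#'   the final release rate (default 0.45, i.e. the final dissolution
#'   stage of a 330-min pH-gradient test).
#' @return An object of class `release_source`.
#' @export
release_source_solid <- function(psd, density = DEFAULT_DRUG_DENSITY_G_ML) {
  stopifnot(inherits(psd, "particle_size_distribution"))
  structure(list(kind = "solid_particles", psd = psd, density = density),
            class = "release_source")
}

#' @rdname release_source_solid
#' @export
release_source_dispersed <- function(profile,
                                     extend = c("final_slope", "none"),
                                     extend_window = 0.45,
                                     density = DEFAULT_DRUG_DENSITY_G_ML) {
  stopifnot(inherits(profile, "dissolution_profile"))
  extend <- match.arg(extend)
  structure(list(kind = "dispersed_profile", profile = profile,
                 extend = extend, extend_window = extend_window,
                 density = density),
            class = "release_source")
}

# Cumulative release fraction F(t_h) and rate r(t_h) (fraction/h) in
# simulation time (hours), including the optional final-slope extension.
# Returns list(F = function(t_h), rate = function(t_h), slope_ext_per_h).
.release_driver <- function(source) {
  stopifnot(source$kind == "dispersed_profile")
  kn <- suppressWarnings(.profile_knots(source$profile))
  t_h <- kn$t / MIN_PER_HOUR
  f <- kn$f
  t_last <- t_h[length(t_h)]
  f_last <- f[length(f)]
  slope_ext <- 0
  if (source$extend == "final_slope" && f_last < 1 && length(t_h) >= 2) {
    t0 <- t_last - source$extend_window * (t_last - t_h[1])
    i0 <- max(findInterval(t0, t_h), 1)
    if (t_h[length(t_h)] > t_h[i0]) {
      slope_ext <- (f_last - f[i0]) / (t_last - t_h[i0])
    }
    if (slope_ext < 0.005) slope_ext <- 0 # < 0.5 %/h: plateau reached
  }
  t_full <- if (slope_ext > 0) (1 - f_last) / slope_ext else 0
  Ffun <- function(th) {
    base <- stats::approx(t_h, f, xout = pmin(pmax(th, 0), t_last),
                          rule = 2)$y
    ext <- pmin(pmax(th - t_last, 0), t_full) * slope_ext
    pmin(base + ext, 1)
  }
  ratefun <- function(th) {
    r <- rep(0, length(th))
    idx <- findInterval(th, t_h, left.open = TRUE)
    inside <- idx >= 1 & idx < length(t_h) & th >= 0
    r[inside] <- kn$slope[idx[inside]] * MIN_PER_HOUR
    r[th == 0] <- kn$slope[1] * MIN_PER_HOUR
    in_ext <- th > t_last & th <= t_last + t_full
    r[in_ext] <- slope_ext
    r
  }
  list(F = Ffun, rate = ratefun, slope_ext_per_h = slope_ext)
}
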