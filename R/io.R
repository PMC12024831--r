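# Profile CSV I/O and the end-to-end pipeline: (synthetic or file) profile
# -> release-kinetics fitting -> oral simulation -> PK metrics ->
# fold-error validation, with provenance. Units are fixed at the boundary:
# minutes and percent in profile files, hours and ng/mL in PK outputs,
# mg doses.

#' Read / write a dissolution profile CSV
#'
#' The CSV dialect is `time_min,percent_released[,pH]`, decimal point only.
#' Round-trips are lossless.
#'
#' @param path file path.
#' @param profile a [dissolution_profile()].
#' @return `read_profile_csv()` returns a [dissolution_profile()];
#'   `write_profile_csv()` returns `path` invisibly.
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  req <- c("time_min", "percent_released")
  if (!all(req %in% names(df))) {
    stop("profile CSV must have header 'time_min,percent_released[,pH]'",
         call. = FALSE)
  }
  for (colname in intersect(c(req, "pH"), names(df))) {
    v <- df[[colname]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric value in column '", colname, "' at data line ",
           ifelse(is.na(bad), "?", bad), call. = FALSE)
    }
  }
  bad <- which(diff(df$time_min) <= 0)
  if (length(bad) > 0) {
    stop("times not strictly increasing at data line ", bad[1] + 1,
         call. = FALSE)
  }
  dissolution_profile(df$time_min, df$percent_released,
                      pH = if ("pH" %in% names(df)) df$pH else NULL)
}

#' @rdname read_profile_csv
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "dissolution_profile"))
  df <- as.data.frame(profile)
  names(df)[names(df) == "released"] <- "percent_released"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full in vitro - in silico pipeline
#'
#' Executes, from a single configuration: dissolution-profile acquisition
#' (formulation preset, profile CSV, or solid-particle source),
#' release-kinetics model fitting, oral simulation, PK metric extraction,
#' and (if observed values are supplied) two-fold validation. Writes a
#' time-series CSV, a metrics JSON, a release-fit CSV, a validation CSV and
#' a provenance record into `out_dir`.
#'
#' The configuration is a named list (or a path to a YAML/JSON file) with
#' blocks:
#' \describe{
#'   \item{formulation}{`list(type = "dispersed", preset = "P9")` or
#'     `list(type = "dispersed", profile_csv = "...")` or
#'     `list(type = "solid")`.}
#'   \item{dose}{`list(amount_mg = 75, water_mL = 200)`.}
#'   \item{solver}{optional: `t_end_h`, `dt_h`.}
#'   \item{drug, disposition}{optional overrides; defaults are the
#'     packaged clopidogrel parameter sets. For dispersed formulations the
#'     default assumes polymer-inhibited precipitation
#'     (`precipitation_time_s = Inf`).}
#'   \item{observed}{optional data frame/CSV path of
#'     `parameter,observed` rows for validation.}
#'   \item{seed}{RNG seed recorded in provenance and used for any
#'     generated noise.}
#' }
#'
#' @param config named list or path to a YAML/JSON config file.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   file output.
#' @return A list with `profile`, `release_fits`, `simulation`, `metrics`,
#'   `validation` (or `NULL`) and `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- .read_config(config)
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  known <- c("formulation", "dose", "solver", "drug", "disposition",
             "observed", "seed", "physiology_overrides")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config blocks: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fm <- config$formulation
  if (is.null(fm) || is.null(fm$type)) {
    stop("config$formulation with a 'type' is required for an oral run",
         call. = FALSE)
  }
  seed <- as.integer(config$seed %||% 1L)
  dose_mg <- config$dose$amount_mg %||% 75
  water <- config$dose$water_mL %||% 200
  t_end <- config$solver$t_end_h %||% 48
  dt <- config$solver$dt_h %||% 0.01

  dispersed <- identical(fm$type, "dispersed")
  default_tau_p <- if (dispersed) Inf else 900
  drug <- clopidogrel_parameters(
    precipitation_time_s = config$drug$precipitation_time_s %||% default_tau_p)
  for (nm in intersect(names(config$drug), setdiff(names(drug), "solubility"))) {
    drug[[nm]] <- config$drug[[nm]]
  }
  disp <- if (is.null(config$disposition)) clopidogrel_disposition() else
    do.call(disposition_parameters, config$disposition)
  phys <- default_fasted_physiology()
  if (!is.null(config$physiology_overrides)) {
    phys <- with_overrides(phys, config$physiology_overrides)
  }

  profile <- NULL
  fits <- NULL
  if (dispersed) {
    if (!is.null(fm$preset)) {
      presets <- formulation_presets(noise_sd = fm$noise_sd %||% 0,
                                     seed = seed)
      if (!fm$preset %in% names(presets)) {
        stop("unknown formulation preset: ", fm$preset, call. = FALSE)
      }
      profile <- generate_profile(presets[[fm$preset]])
    } else if (!is.null(fm$profile_csv)) {
      profile <- read_profile_csv(fm$profile_csv)
    } else {
      stop("a dispersed formulation needs 'preset' or 'profile_csv'",
           call. = FALSE)
    }
    fits <- fit_all_models(profile)
    source <- release_source_dispersed(profile,
                                       extend = fm$extend %||% "final_slope")
  } else if (identical(fm$type, "solid")) {
    psd <- if (!is.null(fm$d50_um)) {
      build_psd(fm$d50_um, fm$d90_um, fm$n_bins %||% 10)
    } else drug$psd
    source <- release_source_solid(psd, density = drug$density)
  } else {
    stop("formulation type must be 'dispersed' or 'solid'", call. = FALSE)
  }

  sim <- simulate_oral(drug, disp, phys, source,
                       dose_event("po", dose_mg,
                                  coadministered_water = water),
                       t_end = t_end, dt = dt)

  validation <- NULL
  if (!is.null(config$observed)) {
    obs <- config$observed
    if (is.character(obs)) obs <- utils::read.csv(obs)
    pred <- c(Cmax = sim$metrics$Cmax, tmax = sim$metrics$tmax,
              AUC_0_t = sim$metrics$AUC_0_t,
              AUC_0_inf = sim$metrics$AUC_0_inf)
    obs$predicted <- unname(pred[obs$parameter])
    validation <- two_fold_validation(obs)
  }

  provenance <- list(package_version =
                       as.character(utils::packageVersion("clopbbm")),
                     seed = seed,
                     config = config,
                     timestamp = format(Sys.time(), tz = "UTC"))
  provenance$config_md5 <- .config_md5(config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ts <- data.frame(time_h = sim$times,
                     plasma_ng_per_mL = sim$plasma_conc,
                     liver_ng_per_mL = sim$liver_conc)
    utils::write.csv(ts, file.path(out_dir, "timeseries.csv"),
                     row.names = FALSE)
    regional <- data.frame(compartment = names(sim$regional_absorbed),
                           percent_of_absorbed = unname(sim$regional_absorbed))
    utils::write.csv(regional, file.path(out_dir, "regional_absorption.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(list(Fa = sim$Fa, Fb = sim$Fb), unclass(sim$metrics)),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(fits)) {
      utils::write.csv(attr(fits, "summary"),
                       file.path(out_dir, "release_fits.csv"),
                       row.names = FALSE)
    }
    if (!is.null(validation)) {
      utils::write.csv(validation, file.path(out_dir, "validation.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  list(profile = profile, release_fits = fits, simulation = sim,
       metrics = sim$metrics, validation = validation,
       provenance = provenance)
}

.read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml/.yml or .json", call. = FALSE)
  }
}

.config_md5 <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
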