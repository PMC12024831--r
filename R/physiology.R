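# Nine-compartment fasted-state gastrointestinal physiology (ACAT-style):
# stomach, duodenum, two jejunum, three ileum, cecum, ascending colon.
#
# Per-compartment transit times and pH follow widely published fasted-human
# compartmental absorption and transit defaults; they are assumptions, fully
# overridable via with_overrides(). Cylinder dimensions use effective radii
# chosen so the geometric volumes match published fasted ACAT compartment
# volumes (duodenum ~41 mL down to ileum 3 ~49 mL, cecum and ascending
# colon ~50 mL; the gut is only partially distended, so effective radii are
# below anatomical ones). Fluid is a static fraction of geometric volume:
# 23% in the small intestine and 0.5% in the colon (the two fluid-volume
# overrides this model is built around); the stomach fraction gives ~48 mL
# resting gastric fluid.

.default_gi_table <- function() {
  data.frame(
    name = .enum_compartments,
    pH = c(1.3, 6.0, 6.2, 6.4, 6.6, 6.9, 7.4, 6.4, 6.8),
    transit_time = c(0.25, 0.26, 0.95, 0.76, 0.59, 0.43, 0.31, 4.55, 13.5),
    length = c(20, 14, 58, 58, 58, 58, 58, 14, 14),
    radius = c(2.0, 0.97, 0.92, 0.82, 0.72, 0.62, 0.52, 1.07, 1.07),
    fluid_fraction = c(0.19, 0.23, 0.23, 0.23, 0.23, 0.23, 0.23, 0.005, 0.005),
    absorption_scale = c(0, 1, 1, 1, 1, 1, 1, 0.4, 0.4),
    stringsAsFactors = FALSE
  )
}

#' Default fasted-state nine-compartment GI physiology
#'
#' Returns the fasted human gastrointestinal physiology used by
#' [simulate_oral()]: nine anatomically ordered compartments (stomach,
#' duodenum, jejunum 1-2, ileum 1-3, cecum, ascending colon), each with pH,
#' mean transit time (h), cylindrical dimensions (cm), a static luminal
#' fluid fraction, and an absorption scale factor multiplying the baseline
#' absorption rate constant (0 in the stomach, 1 in the small intestine,
#' reduced in the colon to reflect its smaller absorptive surface).
#'
#' The luminal fluid fractions are 23% of geometric volume in the small
#' intestine and 0.5% in the colon.
#'
#' @param small_intestine_fluid_fraction fraction of geometric volume that
#'   is fluid in duodenum through ileum 3 (default 0.23).
#' @param colon_fluid_fraction fluid fraction for cecum and ascending colon
#'   (default 0.005).
#' @return An object of class `gi_physiology`: a data frame with columns
#'   `name`, `pH`, `transit_time` (h), `length` (cm), `radius` (cm),
#'   `geometric_volume` (mL), `fluid_fraction`, `fluid_volume` (mL) and
#'   `absorption_scale`.
#' @examples
#' phys <- default_fasted_physiology()
#' phys$name
#' sum(phys$transit_time[2:7]) # total small-intestinal transit time (h)
#' @export
default_fasted_physiology <- function(small_intestine_fluid_fraction = 0.23,
                                      colon_fluid_fraction = 0.005) {
  stopifnot(small_intestine_fluid_fraction > 0,
            small_intestine_fluid_fraction <= 1,
            colon_fluid_fraction > 0, colon_fluid_fraction <= 1)
  tab <- .default_gi_table()
  tab$fluid_fraction[2:7] <- small_intestine_fluid_fraction
  tab$fluid_fraction[8:9] <- colon_fluid_fraction
  as_gi_physiology(tab,
                   small_intestine_fluid_fraction = small_intestine_fluid_fraction,
                   colon_fluid_fraction = colon_fluid_fraction)
}

#' Build a `gi_physiology` object from a compartment table
#'
#' Validates a nine-row compartment table (fixed anatomical order), derives
#' geometric volumes from cylinder dimensions and fluid volumes from the
#' fluid fractions.
#'
#' @param tab data frame with columns `name`, `pH`, `transit_time`,
#'   `length`, `radius`, `fluid_fraction`, `absorption_scale`.
#' @param small_intestine_fluid_fraction,colon_fluid_fraction recorded as
#'   attributes for provenance.
#' @return A `gi_physiology` object.
#' @export
as_gi_physiology <- function(tab,
                             small_intestine_fluid_fraction = NA_real_,
                             colon_fluid_fraction = NA_real_) {
  req <- c("name", "pH", "transit_time", "length", "radius",
           "fluid_fraction", "absorption_scale")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop("physiology table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) != 9 || !identical(tab$name, .enum_compartments)) {
    stop("physiology must have exactly 9 compartments in the fixed ",
         "anatomical order: ", paste(.enum_compartments, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$transit_time <= 0)) {
    stop("transit_time must be > 0 for every compartment", call. = FALSE)
  }
  if (any(tab$pH < 1 | tab$pH > 8)) {
    stop("compartment pH must lie in [1, 8]", call. = FALSE)
  }
  if (any(tab$fluid_fraction <= 0 | tab$fluid_fraction > 1)) {
    stop("fluid_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (any(tab$length <= 0 | tab$radius <= 0)) {
    stop("compartment length and radius must be positive", call. = FALSE)
  }
  if (any(tab$absorption_scale < 0)) {
    stop("absorption_scale must be non-negative", call. = FALSE)
  }
  tab$geometric_volume <- pi * tab$radius^2 * tab$length
  tab$fluid_volume <- tab$geometric_volume * tab$fluid_fraction
  tab <- tab[, c("name", "pH", "transit_time", "length", "radius",
                 "geometric_volume", "fluid_fraction", "fluid_volume",
                 "absorption_scale")]
  structure(tab,
            small_intestine_fluid_fraction = small_intestine_fluid_fraction,
            colon_fluid_fraction = colon_fluid_fraction,
            class = c("gi_physiology", "data.frame"))
}

#' Modify selected physiology fields
#'
#' Returns a new physiology in which only the named compartment fields are
#' changed; the base object is untouched. Derived columns (geometric and
#' fluid volume) are recomputed.
#'
#' @param base a `gi_physiology` object.
#' @param overrides named list: `list(<compartment> = list(<field> = value))`.
#'   Settable fields: `pH`, `transit_time`, `length`, `radius`,
#'   `fluid_fraction`, `absorption_scale`.
#' @return A new `gi_physiology` object.
#' @examples
#' phys <- default_fasted_physiology()
#' slow <- with_overrides(phys, list(stomach = list(transit_time = 0.5)))
#' slow$transit_time[1]
#' @export
with_overrides <- function(base, overrides = list()) {
  stopifnot(inherits(base, "gi_physiology"))
  settable <- c("pH", "transit_time", "length", "radius",
                "fluid_fraction", "absorption_scale")
  tab <- as.data.frame(base)[, c("name", settable)]
  for (comp in names(overrides)) {
    if (!comp %in% tab$name) {
      stop("unknown compartment in overrides: '", comp, "'", call. = FALSE)
    }
    fields <- overrides[[comp]]
    if (!is.list(fields) || is.null(names(fields))) {
      stop("override for '", comp, "' must be a named list of fields",
           call. = FALSE)
    }
    for (field in names(fields)) {
      if (!field %in% settable) {
        stop("unknown physiology field '", field, "' for compartment '",
             comp, "'", call. = FALSE)
      }
      value <- fields[[field]]
      if (!is.numeric(value) || length(value) != 1 || !is.finite(value)) {
        stop("override ", comp, "$", field, " must be a finite number",
             call. = FALSE)
      }
      tab[tab$name == comp, field] <- value
    }
  }
  as_gi_physiology(tab,
                   small_intestine_fluid_fraction =
                     attr(base, "small_intestine_fluid_fraction"),
                   colon_fluid_fraction = attr(base, "colon_fluid_fraction"))
}

#' Serialize / restore a physiology
#'
#' `write_physiology()` dumps the active physiology as JSON (one record per
#' compartment) for provenance; `read_physiology()` restores it losslessly.
#'
#' @param phys a `gi_physiology` object.
#' @param path file path.
#' @return `read_physiology()` returns a `gi_physiology`;
#'   `write_physiology()` returns `path` invisibly.
#' @export
write_physiology <- function(phys, path) {
  stopifnot(inherits(phys, "gi_physiology"))
  payload <- list(
    small_intestine_fluid_fraction =
      attr(phys, "small_intestine_fluid_fraction"),
    colon_fluid_fraction = attr(phys, "colon_fluid_fraction"),
    compartments = as.data.frame(phys)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_physiology
#' @export
read_physiology <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_gi_physiology(payload$compartments,
                   small_intestine_fluid_fraction =
                     payload$small_intestine_fluid_fraction %||% NA_real_,
                   colon_fluid_fraction =
                     payload$colon_fluid_fraction %||% NA_real_)
}
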