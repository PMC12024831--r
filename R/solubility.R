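# pH-dependent solubility of a weak base, consumed as tabulated data with
# interpolation between pH values, plus the dose-number solubility
# classification used in biowaiver assessments.

#' Construct a pH-solubility table
#'
#' @param pH numeric vector of pH values, strictly increasing, at least 2.
#' @param solubility matching solubilities in mg/mL, all positive.
#' @return An object of class `solubility_table`.
#' @examples
#' tab <- solubility_table(c(1.2, 4.5, 6.8), c(268.750, 0.055, 0.016))
#' interpolate_solubility(tab, 4.5)
#' @export
solubility_table <- function(pH, solubility) {
  if (length(pH) < 2 || length(pH) != length(solubility)) {
    stop("solubility table needs at least 2 matched (pH, S) points",
         call. = FALSE)
  }
  if (any(!is.finite(pH)) || any(!is.finite(solubility))) {
    stop("solubility table values must be finite", call. = FALSE)
  }
  if (any(diff(pH) <= 0)) {
    stop("pH values must be strictly increasing", call. = FALSE)
  }
  if (any(solubility <= 0)) {
    stop("solubilities must be positive", call. = FALSE)
  }
  structure(data.frame(pH = pH, solubility = solubility),
            class = c("solubility_table", "data.frame"))
}

#' Interpolate solubility at a given pH
#'
#' At a tabulated pH the tabulated value is returned exactly. Between
#' points, interpolation is linear in log10(S) versus pH by default - the
#' natural scale for a weak base whose solubility spans several orders of
#' magnitude (plain linear interpolation would be dominated by the acidic
#' endpoint). Outside the tabulated range the nearest endpoint value is
#' used (clamping).
#'
#' @param table a [solubility_table()].
#' @param pH numeric vector of query pH values.
#' @param method `"loglinear"` (default) or `"linear"`.
#' @return Solubility in mg/mL, same length as `pH`.
#' @examples
#' tab <- solubility_table(c(1.2, 4.5, 6.8), c(268.750, 0.055, 0.016))
#' interpolate_solubility(tab, c(1.2, 5.65, 7.4))
#' @export
interpolate_solubility <- function(table, pH,
                                   method = c("loglinear", "linear")) {
  if (!inherits(table, "solubility_table")) {
    stop("'table' must be a solubility_table", call. = FALSE)
  }
  method <- match.arg(method)
  x <- table$pH
  y <- if (method == "loglinear") log10(table$solubility) else table$solubility
  out <- stats::approx(x, y, xout = pH, rule = 2)$y
  if (method == "loglinear") out <- 10^out
  out
}

#' Dose number
#'
#' The dose number `D0 = D / (V0 * C0)` relates the administered dose `D`
#' (mg) to the amount soluble in a reference volume `V0` (mL, conventionally
#' 250 mL) at solubility `C0` (mg/mL). `D0 < 1` indicates the full dose
#' dissolves in a glass of water at that pH.
#'
#' @param D dose in mg.
#' @param V0 reference volume in mL (default 250).
#' @param C0 solubility in mg/mL.
#' @return The unitless dose number (vectorized).
#' @examples
#' dose_number(75, 250, 0.055)
#' @export
dose_number <- function(D, V0 = DOSE_NUMBER_REFERENCE_VOLUME_ML, C0) {
  if (any(D <= 0) || any(V0 <= 0) || any(C0 <= 0)) {
    stop("dose_number requires positive D, V0 and C0", call. = FALSE)
  }
  D / (V0 * C0)
}

#' Solubility class from the dose number
#'
#' A drug is highly soluble at a given pH if the dose number is less than 1
#' and poorly soluble if it is greater than 1. The boundary `D0 == 1` is
#' assigned to `highly_soluble` (the dose just dissolves in the reference
#' volume).
#'
#' @param D0 non-negative dose number (vectorized).
#' @return Character vector, `"highly_soluble"` or `"poorly_soluble"`.
#' @export
solubility_class <- function(D0) {
  if (any(D0 < 0)) stop("dose number must be non-negative", call. = FALSE)
  ifelse(D0 <= 1, "highly_soluble", "poorly_soluble")
}

#' Read a solubility table from CSV
#'
#' Expects a header `pH,solubility_mg_per_mL`.
#'
#' @param path CSV file path.
#' @return A [solubility_table()].
#' @export
read_solubility_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pH", "solubility_mg_per_mL") %in% names(df))) {
    stop("solubility CSV must have header 'pH,solubility_mg_per_mL'",
         call. = FALSE)
  }
  solubility_table(df$pH, df$solubility_mg_per_mL)
}
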