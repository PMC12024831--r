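# Packaged clopidogrel parameter sets and literature benchmark tables.
# Physicochemical and biopharmaceutic constants are literature /
# experimentally determined values for clopidogrel hydrogen sulfate;
# disposition constants were estimated from intravenous plasma data with a
# three-compartment model.

.extdata <- function(file) {
  system.file("extdata", file, package = "clopbbm", mustWork = TRUE)
}

#' Clopidogrel drug parameter set
#'
#' Physicochemical and biopharmaceutic input parameters for the
#' clopidogrel-specific absorption model: molecular weight 321.82 g/mol,
#' logD 3.9 (pH 7.4), basic pKa 4.55, human effective jejunal permeability
#' 4.7767e-4 cm/s, aqueous diffusion coefficient 0.7397e-5 cm^2/s, drug
#' particle diameters D50 150 / D90 250 um, plasma fraction unbound 2
#' percent, blood/plasma ratio 0.72, hepatic first-pass extraction 96.5
#' percent, and the tabulated pH-solubility data (freely soluble at pH 1.2,
#' practically insoluble at neutral pH).
#'
#' The fraction unbound and blood/plasma ratio are carried for completeness
#' of the parameter set; the minimal plasma-referenced disposition
#' equations do not use them.
#'
#' @param n_bins particle-size bins for the polydisperse dissolution model.
#' @param precipitation_time_s mean lifetime (s) of supersaturated
#'   dissolved drug before reverting to solid; `Inf` disables precipitation
#'   entirely (polymer-stabilized formulations).
#' @param max_supersat_ratio maximum sustainable supersaturation ratio
#'   C/Cs. The default 1 does not allow supersaturation to persist:
#'   dissolved drug above the cap precipitates rapidly, and absorption from
#'   solution is saturation-limited - the conventional default of
#'   compartmental absorption-and-transit simulators. Values above 1 let
#'   concentrations up to `ratio * Cs` decay by the slower first-order
#'   `1/precipitation_time` path.
#' @return A list of class `drug_parameters`.
#' @export
clopidogrel_parameters <- function(n_bins = 10, precipitation_time_s = 900,
                                   max_supersat_ratio = 1) {
  structure(list(
    name = "clopidogrel hydrogen sulfate",
    MW = 321.82,
    logD_7.4 = 3.9,
    pKa_base = 4.55,
    solubility = clopidogrel_solubility(),
    Peff = 4.7767e-4,        # cm/s
    Dw = 0.7397e-5,          # cm^2/s
    psd = build_psd(150, 250, n_bins),
    fu_plasma = 0.02,
    Rbp = 0.72,
    FPE = 0.965,
    density = DEFAULT_DRUG_DENSITY_G_ML,
    precipitation_time_s = precipitation_time_s,
    max_supersat_ratio = max_supersat_ratio
  ), class = "drug_parameters")
}

#' Clopidogrel three-compartment disposition parameters
#'
#' CL 1.2 L/h/kg, Vc 0.073 L/kg, k12 9.285, k21 2.058, k13 1.243,
#' k31 0.17 (all 1/h), 70 kg body weight. The implied terminal half-life is
#' 4.4 h.
#'
#' @param body_weight kg.
#' @return A [disposition_parameters()] object.
#' @export
clopidogrel_disposition <- function(body_weight = 70) {
  disposition_parameters(CL = 1.2, Vc = 0.073, k12 = 9.285, k21 = 2.058,
                         k13 = 1.243, k31 = 0.17,
                         body_weight = body_weight)
}

#' Tabulated clopidogrel pH-solubility data
#'
#' Shake-flask solubility of clopidogrel hydrogen sulfate at 37 C:
#' 268.750 mg/mL at pH 1.2, 0.055 at pH 4.5, 0.016 at pH 6.8.
#'
#' @return A [solubility_table()].
#' @export
clopidogrel_solubility <- function() {
  read_solubility_csv(.extdata("clopidogrel_solubility.csv"))
}

#' Literature benchmark PK tables
#'
#' `observed_pk()` returns literature-reported predicted and observed mean
#' pharmacokinetic parameters for intravenous (1/10/100/300 mg) or oral
#' (75/300 mg immediate-release tablet) clopidogrel, used in the fold-error
#' validation worked examples. `reference_formulation_pk()` returns
#' reported model-predicted Fa / Fb / PK benchmark values for a 75 mg
#' immediate-release tablet and four solid-dispersion formulations (P5, C5,
#' P9, C9).
#'
#' @param route `"iv"` or `"po"`.
#' @return A data frame.
#' @export
observed_pk <- function(route = c("iv", "po")) {
  route <- match.arg(route)
  utils::read.csv(.extdata(paste0("observed_pk_", route, ".csv")),
                  stringsAsFactors = FALSE)
}

#' @rdname observed_pk
#' @export
reference_formulation_pk <- function() {
  utils::read.csv(.extdata("reference_formulation_pk.csv"),
                  stringsAsFactors = FALSE)
}
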