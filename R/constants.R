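# Centralized unit conversions and numerical defaults. All in vitro profile
# I/O is in minutes and percent released; the simulator runs in hours, mg,
# mL. Conversions happen only through these constants.

MIN_PER_HOUR <- 60
SEC_PER_HOUR <- 3600

# Diffusion-layer thickness convention for shrinking-particle dissolution:
# h = min(r, H_DIFFUSION_CAP_UM).
H_DIFFUSION_CAP_UM <- 30

# Nominal radius of re-precipitated drug particles (um). Precipitate formed
# from supersaturated solution is fine material that re-dissolves quickly.
PRECIPITATE_RADIUS_UM <- 1

# True density of drug substance (g/mL); typical for an organic salt.
DEFAULT_DRUG_DENSITY_G_ML <- 1.2

# Reference volume (mL) for the dose number D0 = D / (V0 * C0).
DOSE_NUMBER_REFERENCE_VOLUME_ML <- 250

UM_PER_CM <- 1e4

.enum_release_models <- c("zero_order", "first_order", "higuchi",
                          "korsmeyer_peppas", "hixson_crowell")

.enum_compartments <- c("stomach", "duodenum", "jejunum1", "jejunum2",
                        "ileum1", "ileum2", "ileum3", "cecum", "asc_colon")

`%||%` <- function(a, b) if (is.null(a)) b else a
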