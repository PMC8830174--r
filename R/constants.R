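#' Default physicochemical and model constants
#'
#' Returns the constants used throughout the package: the Kjeldahl protein
#' factor, Buswell methane coefficients for the three macromolecule classes,
#' the microbial biomass yield on degraded VS and its protein fraction, the
#' ideal-gas reference state and gas densities used for the gas-mass volume
#' correction, the free-ammonia speciation constants, and VFA molar masses.
#'
#' @param ... named overrides for individual constants. Overrides are applied
#'   on top of the defaults and each one is reported via [message()] so that a
#'   non-default configuration is always visible in logs.
#' @return A named list of constants.
#' @examples
#' cfg <- ad_config()
#' cfg$tmp_coefficients
#' @export
ad_config <- function(...) {
  cfg <- list(
    protein_n_factor  = 6.25,    # g protein per g organic N (Kjeldahl)
    biomass_yield     = 0.1,     # g biomass formed per g VS degraded
    biomass_protein_fraction = 0.5,
    # NL CH4 per g of macromolecule (Buswell-based lumped coefficients)
    tmp_coefficients  = c(carbohydrate = 0.42, fat = 1.01, protein = 0.50),
    molar_volume      = 22.414,  # NL/mol at 273.2 K, 1.01325 bar
    stp_temperature   = 273.2,   # K
    stp_pressure      = 1.01325, # bar
    rho_ch4           = 0.716,   # g/NL at STP
    rho_co2           = 1.964,   # g/NL at STP
    # NH3/NH4+ equilibrium constants (temperature in Kelvin):
    # fraction free = 1 / (1 + 10^(-pH) / 10^(-(a + b/T_K)))
    ammonia_a         = 0.09018,
    ammonia_b         = 2729.92,
    # relative tolerance below which fiber-ordering / free-sugar violations
    # are clamped with a warning instead of raising an error
    clamp_tolerance   = 0.05,
    significance_thresholds = c(0.1, 0.05, 0.01)
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      stop("unknown configuration constant(s): ", paste(bad, collapse = ", "))
    }
    for (nm in names(overrides)) {
      message("ad_config: overriding '", nm, "' (default ",
              paste(format(cfg[[nm]]), collapse = "/"), " -> ",
              paste(format(overrides[[nm]]), collapse = "/"), ")")
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg
}

# Elemental composition (C, H, O) of the supported volatile fatty acids.
# Linear and iso forms of an acid share a molecular formula, hence molar
# mass and methane equivalent.
.vfa_formula <- list(
  acetic     = c(C = 2, H = 4,  O = 2),
  propionic  = c(C = 3, H = 6,  O = 2),
  isobutyric = c(C = 4, H = 8,  O = 2),
  n_butyric  = c(C = 4, H = 8,  O = 2),
  isovaleric = c(C = 5, H = 10, O = 2),
  n_valeric  = c(C = 5, H = 10, O = 2),
  isocaproic = c(C = 6, H = 12, O = 2),
  caproic    = c(C = 6, H = 12, O = 2)
)

.atomic_mass <- c(C = 12.011, H = 1.008, O = 15.999)

# Conventional molar masses (g/mol), as used for mg/L -> mmol/L conversion.
.vfa_molar_mass <- c(
  acetic = 60.05, propionic = 74.08,
  isobutyric = 88.11, n_butyric = 88.11,
  isovaleric = 102.13, n_valeric = 102.13,
  isocaproic = 116.16, caproic = 116.16
)

# Accept common aliases ("acetate", "n-butyric", ...) for acid names.
.normalize_acid <- function(acid) {
  key <- tolower(gsub("[ -]", "_", acid))
  key <- sub("ate$", "ic", key)           # acetate -> acetic
  key <- sub("^butyric$", "n_butyric", key)
  key <- sub("^valeric$", "n_valeric", key)
  key
}

#' Supported volatile fatty acids
#'
#' @return Character vector of canonical acid names accepted by
#'   [vfa_ch4_equivalent()] and [vfa_tmp()].
#' @export
supported_vfa <- function() names(.vfa_formula)
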