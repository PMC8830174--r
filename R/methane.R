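#' Theoretical methane potential of the macromolecule fractions
#'
#' Lumped Buswell coefficients: 0.42 NL CH4/g carbohydrate, 1.01 NL CH4/g
#' fat and 0.50 NL CH4/g protein.
#'
#' @param carbohydrate,fat,protein g/kg.
#' @param config constants, see [ad_config()].
#' @return TMP, NL CH4 per kg (same mass basis as the inputs).
#' @export
macromolecule_tmp <- function(carbohydrate, fat, protein,
                              config = ad_config()) {
  if (any(c(carbohydrate, fat, protein) < 0))
    stop("macromolecule contents must be >= 0")
  k <- config$tmp_coefficients
  k[["carbohydrate"]] * carbohydrate + k[["fat"]] * fat +
    k[["protein"]] * protein
}

#' Methane equivalent of a volatile fatty acid
#'
#' Buswell element balance for a compound CcHhOo: mol CH4 per mol compound
#' = c/2 + h/8 - o/4. Applied to the C2-C6 linear and iso acids (acetate 1,
#' propionate 1.75, (iso)butyrate 2.5, (iso)valerate 3.25, (iso)caproate 4).
#'
#' @param acid acid name; linear/iso aliases such as `"acetate"` or
#'   `"n-butyric"` are accepted.
#' @return mol CH4 per mol acid.
#' @examples
#' vfa_ch4_equivalent("propionate")  # 1.75
#' @export
vfa_ch4_equivalent <- function(acid) {
  key <- .normalize_acid(acid)
  f <- .vfa_formula[[key]]
  if (is.null(f))
    stop("unknown acid '", acid, "'; supported: ",
         paste(supported_vfa(), collapse = ", "))
  unname(f[["C"]] / 2 + f[["H"]] / 8 - f[["O"]] / 4)
}

#' Convert a VFA profile from mg/L to mmol/L
#'
#' @param vfa_mg named numeric vector, mg/L.
#' @return Named numeric vector, mmol/L.
#' @export
vfa_mg_to_mmol <- function(vfa_mg) {
  keys <- vapply(names(vfa_mg), .normalize_acid, "")
  bad <- keys[!keys %in% names(.vfa_molar_mass)]
  if (length(bad))
    stop("unknown acid(s): ", paste(bad, collapse = ", "))
  stats::setNames(unname(vfa_mg) / .vfa_molar_mass[keys], names(vfa_mg))
}

#' Theoretical methane potential of a VFA profile
#'
#' Each acid contributes its molar methane equivalent times the molar gas
#' volume (22.414 NL/mol at 273.2 K, 1.01325 bar).
#'
#' @param vfa named numeric vector of concentrations, mmol/L.
#' @param density stream density, kg/L (default 1, converting per-litre to
#'   per-kg).
#' @param config constants, see [ad_config()].
#' @return TMP from VFAs, NL CH4/kg.
#' @examples
#' vfa_tmp(c(acetic = 55))  # ~1.23
#' @export
vfa_tmp <- function(vfa, density = 1, config = ad_config()) {
  if (is.null(vfa) || length(vfa) == 0) return(0)
  if (any(vfa < 0)) stop("VFA concentrations must be >= 0")
  eq <- vapply(names(vfa), vfa_ch4_equivalent, 0)
  sum(vfa * eq) * config$molar_volume * 1e-3 / density
}

#' Theoretical methane potential of a stream
#'
#' Combines the macromolecule TMP (carbohydrates = free sugars +
#' hemicellulose + cellulose; lignin-like matter excluded) with the VFA
#' methane equivalents, per kg wet weight and per kg VS.
#'
#' @param stream a [stream_composition()] with protein, fat, fiber and
#'   sugar data present (a missing macromolecule is an error naming it).
#' @param fiber optionally a pre-computed complete [fiber_fractions()];
#'   derived from the stream by default.
#' @param config constants, see [ad_config()].
#' @return Object of class `methane_potential` with elements `tmp_macro`,
#'   `tmp_vfa`, `tmp_total` (NL CH4/kg ww) and `tmp_vs_basis` (NL CH4/kg VS,
#'   `NA` when the stream's solids are unknown).
#' @export
stream_tmp <- function(stream, fiber = NULL, config = ad_config()) {
  stopifnot(inherits(stream, "stream_composition"))
  if (is.na(stream$protein)) stop("stream is missing 'protein'")
  if (is.na(stream$crude_fat)) stop("stream is missing 'crude_fat'")
  if (is.null(fiber)) fiber <- stream_fiber(stream)
  carb <- total_carbohydrates(fiber)
  macro <- macromolecule_tmp(carb, stream$crude_fat, stream$protein, config)
  vfa <- vfa_tmp(stream$vfa, density = stream$density, config = config)
  vs <- vs_g_per_kg(stream)
  structure(list(
    tmp_macro = macro, tmp_vfa = vfa, tmp_total = macro + vfa,
    tmp_vs_basis = if (!is.na(vs) && vs > 0)
      (macro + vfa) / (vs / 1000) else NA_real_),
    class = "methane_potential")
}

#' @export
print.methane_potential <- function(x, ...) {
  cat("<methane_potential>  total", format(signif(x$tmp_total, 4)),
      "NL CH4/kg ww (macro", format(signif(x$tmp_macro, 4)), "+ VFA",
      format(signif(x$tmp_vfa, 3)), ")\n")
  invisible(x)
}

#' TMP reduction over digestion
#'
#' Fraction of the substrate's theoretical methane potential removed by a
#' digestion step: `(TMP_substrate - TMP_step) / TMP_substrate`, with the
#' step's TMP already adjusted to the per-kg-feed basis (see
#' [adjust_outflow()]).
#'
#' @param tmp_substrate substrate TMP, NL CH4/kg.
#' @param tmp_stage_adjusted volume-adjusted TMP of the digestion step,
#'   NL CH4/kg feed.
#' @return TMP reduction, fraction.
#' @export
tmp_red <- function(tmp_substrate, tmp_stage_adjusted) {
  if (any(is.na(tmp_substrate)) || any(tmp_substrate <= 0))
    stop("tmp_substrate must be > 0")
  (tmp_substrate - tmp_stage_adjusted) / tmp_substrate
}

#' Normalize a gas volume to standard temperature and pressure
#'
#' Ideal-gas correction to 273.2 K and 1.01325 bar.
#'
#' @param volume measured volume, L.
#' @param temperature measurement temperature, K.
#' @param pressure measurement pressure, bar.
#' @param config constants, see [ad_config()].
#' @return Normalized volume, NL.
#' @export
normalize_gas_volume <- function(volume, temperature, pressure,
                                 config = ad_config()) {
  if (any(temperature <= 0) || any(pressure <= 0))
    stop("temperature and pressure must be > 0")
  volume * (config$stp_temperature / temperature) *
    (pressure / config$stp_pressure)
}

#' One residual methane potential measurement
#'
#' @param methane_volume methane volume produced over the incubation, L, at
#'   `temperature_obs` / `pressure_obs` (defaults: already at STP).
#' @param vs_added g VS of digestate added to the bottle.
#' @param wet_mass_added kg wet digestate added.
#' @param temperature_obs,pressure_obs observation conditions, K and bar.
#' @return Object of class `rmp_measurement`.
#' @export
rmp_measurement <- function(methane_volume, vs_added, wet_mass_added,
                            temperature_obs = 273.2,
                            pressure_obs = 1.01325) {
  if (methane_volume < 0) stop("methane_volume must be >= 0")
  if (vs_added <= 0 || wet_mass_added <= 0)
    stop("vs_added and wet_mass_added must be > 0")
  structure(list(methane_volume = methane_volume, vs_added = vs_added,
                 wet_mass_added = wet_mass_added,
                 temperature_obs = temperature_obs,
                 pressure_obs = pressure_obs),
            class = "rmp_measurement")
}

#' Specific residual methane potential
#'
#' Normalizes the measured methane volume to STP and reports it per kg VS
#' added and per kg wet digestate added.
#'
#' @param m an [rmp_measurement()].
#' @return Named vector `c(per_kg_vs = ..., per_kg_ww = ...)`, NL CH4/kg.
#' @export
rmp_specific <- function(m) {
  stopifnot(inherits(m, "rmp_measurement"))
  v <- normalize_gas_volume(m$methane_volume, m$temperature_obs,
                            m$pressure_obs)
  c(per_kg_vs = v / (m$vs_added / 1000),
    per_kg_ww = v / m$wet_mass_added)
}

#' Residual methane potential as a fraction of digestate TMP
#'
#' @param rmp_ww measured RMP, NL CH4/kg ww.
#' @param tmp_digestate_ww digestate TMP, NL CH4/kg ww.
#' @return Fraction of the theoretical potential realized; values above 1
#'   are allowed but flagged.
#' @export
rmp_fraction_of_tmp <- function(rmp_ww, tmp_digestate_ww) {
  if (any(is.na(tmp_digestate_ww)) || any(tmp_digestate_ww <= 0))
    stop("tmp_digestate_ww must be > 0")
  frac <- rmp_ww / tmp_digestate_ww
  if (any(frac > 1))
    warning("RMP exceeds the theoretical methane potential (fraction ",
            paste(signif(frac[frac > 1], 3), collapse = ", "), ")")
  frac
}

#' Free ammonia nitrogen from ammonium, pH and temperature
#'
#' Speciation of total ammoniacal nitrogen into free (un-ionized) NH3-N:
#' `NH3-N = TAN / (1 + 10^(-pH) / 10^(-(0.09018 + 2729.92 / T_K)))`
#' with the temperature in Kelvin. Free ammonia, not ammonium, is the
#' species inhibitory to methanogens; it increases with both pH and
#' temperature.
#'
#' @param nh4_n ammonium (total ammoniacal) nitrogen, g N/kg.
#' @param ph pH (2..12).
#' @param temperature temperature, degrees C (0..80).
#' @param config constants, see [ad_config()].
#' @return Free ammonia nitrogen, g NH3-N/kg.
#' @examples
#' free_ammonia(3.4, 7.8, 42)  # ~0.34
#' @export
free_ammonia <- function(nh4_n, ph, temperature, config = ad_config()) {
  if (any(nh4_n < 0)) stop("nh4_n must be >= 0")
  if (any(ph < 2 | ph > 12)) stop("ph outside the supported range [2, 12]")
  if (any(temperature < 0 | temperature > 80))
    stop("temperature outside the supported range [0, 80] degC")
  t_k <- temperature + 273.15
  pka_term <- 10^(-(config$ammonia_a + config$ammonia_b / t_k))
  nh4_n / (1 + 10^(-ph) / pka_term)
}
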