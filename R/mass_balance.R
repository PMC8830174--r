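#' One digestion stage
#'
#' @param name stage label (e.g. `"digester"`, `"post-digester"`).
#' @param temperature operating temperature, degrees C (20..70).
#' @param hrt hydraulic retention time, days.
#' @param olr organic loading rate, kg VS/m3/day.
#' @param out the outgoing [stream_composition()] (digestate).
#' @param specific_gas specific biogas production, NL per kg feed (optional;
#'   used with `ch4_fraction` to infer the liquid volume reduction).
#' @param ch4_fraction methane fraction of the biogas (0..1, optional).
#' @param vol_red liquid volume reduction over the stage as a fraction
#'   (optional; inferred from gas data when absent).
#' @return Object of class `stage_record`.
#' @export
stage_record <- function(name, temperature, hrt, olr, out,
                         specific_gas = NA_real_, ch4_fraction = NA_real_,
                         vol_red = NA_real_) {
  stopifnot(inherits(out, "stream_composition"))
  if (temperature < 20 || temperature > 70)
    stop("temperature must lie in [20, 70] degC, got ", temperature)
  if (hrt <= 0) stop("hrt must be > 0")
  if (!is.na(vol_red) && (vol_red < 0 || vol_red >= 1))
    stop("vol_red must lie in [0, 1), got ", vol_red)
  structure(list(name = name, temperature = temperature, hrt = hrt,
                 olr = olr, out = out, specific_gas = specific_gas,
                 ch4_fraction = ch4_fraction, vol_red = vol_red),
            class = "stage_record")
}

#' Liquid volume reduction implied by gas production
#'
#' The mass leaving the liquid as biogas per kg of feed, expressed as a
#' fraction of the feed mass. Gas densities are taken at 273.2 K and
#' 1.01325 bar (ideal gas); the non-methane remainder of the biogas is
#' treated as CO2.
#'
#' @param specific_gas biogas production, NL per kg feed.
#' @param ch4_fraction methane volume fraction of the biogas (0..1).
#' @return Volume (mass) reduction as a fraction of feed mass.
#' @examples
#' volume_reduction_from_gas(100, 0.6)  # 0.1215
#' @export
volume_reduction_from_gas <- function(specific_gas, ch4_fraction) {
  if (any(specific_gas < 0)) stop("specific_gas must be >= 0")
  if (any(ch4_fraction < 0 | ch4_fraction > 1))
    stop("ch4_fraction must lie in [0, 1]")
  cfg <- ad_config()
  gas_mass <- specific_gas *
    (ch4_fraction * cfg$rho_ch4 + (1 - ch4_fraction) * cfg$rho_co2)
  gas_mass / 1000
}

#' Adjust an outgoing concentration to a per-kg-feed basis
#'
#' Concentrations measured in the digestate (g per kg digestate) are
#' re-expressed per kg of feed by multiplying with the remaining liquid
#' fraction `1 - vol_red`.
#'
#' @param conc_out concentration in the outgoing stream, g/kg digestate.
#' @param vol_red liquid volume reduction over the stage, fraction.
#' @return Amount per kg of feed, g/kg feed.
#' @export
adjust_outflow <- function(conc_out, vol_red) {
  if (any(vol_red < 0)) stop("vol_red must be >= 0")
  if (any(vol_red >= 1)) stop("vol_red must be < 1, got ", max(vol_red))
  conc_out * (1 - vol_red)
}

#' Gas-volume-adjusted VS reduction
#'
#' Fraction of the ingoing volatile solids destroyed over a stage, with the
#' outgoing VS corrected for the liquid volume lost as biogas:
#' `1 - ts_out * vs_out * (1 - vol_red) / (ts_in * vs_in)`.
#'
#' @param ts_in,ts_out total solids, fraction of ww.
#' @param vs_in,vs_out volatile solids, fraction of TS.
#' @param vol_red liquid volume reduction, fraction.
#' @return VS reduction as a fraction (may be negative on accumulation).
#' @examples
#' vs_reduction_adjusted(0.12, 1, 0.043, 0.715, 0.102)  # ~0.77
#' @export
vs_reduction_adjusted <- function(ts_in, vs_in, ts_out, vs_out, vol_red) {
  denom <- ts_in * vs_in
  if (any(is.na(denom)) || any(denom <= 0))
    stop("ingoing VS (ts_in * vs_in) must be > 0")
  1 - (ts_out * vs_out * (1 - vol_red)) / denom
}

#' Degradation efficiency of one organic fraction
#'
#' `(x_in - x_out) / x_in` with the outgoing amount already on the per-kg-feed
#' basis (see [adjust_outflow()]). Negative efficiencies (accumulation) are
#' allowed and flagged with a warning.
#'
#' @param x_in amount entering the step, g/kg feed.
#' @param x_out_per_feed volume-adjusted amount leaving, g/kg feed.
#' @return Degradation efficiency, fraction.
#' @export
degradation_efficiency <- function(x_in, x_out_per_feed) {
  if (any(is.na(x_in)) || any(x_in <= 0))
    stop("x_in must be > 0; degradation efficiency is undefined")
  eff <- (x_in - x_out_per_feed) / x_in
  if (any(eff < 0))
    warning("negative degradation efficiency (accumulation): ",
            paste(signif(eff[eff < 0], 3), collapse = ", "))
  eff
}

#' Degraded VS concentration
#'
#' @param ts_in TS fraction of ww; @param vs_in VS fraction of TS;
#' @param vs_red_adj adjusted VS reduction, fraction.
#' @return Degraded VS, g per kg feed.
#' @export
degraded_vs_conc <- function(ts_in, vs_in, vs_red_adj) {
  ts_in * vs_in * 1000 * vs_red_adj
}

#' Degraded VS rate
#'
#' @param olr organic loading rate, kg VS/m3/day.
#' @param vs_red_adj adjusted VS reduction, fraction.
#' @return Degraded VS per reactor volume and day, kg VS/m3/day.
#' @export
degraded_vs_rate <- function(olr, vs_red_adj) {
  if (any(olr < 0)) stop("olr must be >= 0")
  olr * vs_red_adj
}

#' Microbial biomass protein formed during digestion
#'
#' Assumes 0.1 g of new microbial biomass per g of VS degraded, of which
#' 50% is protein.
#'
#' @param degraded_vs degraded VS, g/kg.
#' @param config constants, see [ad_config()].
#' @return Biomass protein Y_prot, g/kg.
#' @examples
#' y_prot(92.4)  # 4.62
#' @export
y_prot <- function(degraded_vs, config = ad_config()) {
  if (any(degraded_vs < 0)) stop("degraded_vs must be >= 0")
  config$biomass_yield * config$biomass_protein_fraction * degraded_vs
}

#' Residual substrate-derived protein
#'
#' Measured digestate protein minus the estimated biomass protein Y_prot,
#' floored at zero (with a warning) since substrate-derived protein cannot
#' be negative.
#'
#' @param protein measured protein, g/kg.
#' @param yp biomass protein Y_prot, g/kg.
#' @return Residual protein, g/kg.
#' @export
protein_residual <- function(protein, yp) {
  if (any(c(protein, yp) < 0)) stop("inputs must be >= 0")
  out <- protein - yp
  if (out < 0) {
    warning("estimated biomass protein (", signif(yp, 3),
            ") exceeds measured protein (", signif(protein, 3),
            "); residual floored at 0")
    out <- 0
  }
  out
}

#' Nitrogen mineralization over a digestion step
#'
#' Fraction of the outgoing Kjeldahl nitrogen that was newly mineralized to
#' ammonium: `(nh4_out - nh4_in) / kjeldahl_out`. Negative values
#' (immobilization) are allowed and flagged.
#'
#' @param nh4_out,nh4_in ammonium nitrogen, g/kg.
#' @param kjeldahl_out outgoing Kjeldahl nitrogen, g/kg.
#' @return Mineralized fraction.
#' @export
nitrogen_mineralization <- function(nh4_out, nh4_in, kjeldahl_out) {
  if (any(is.na(kjeldahl_out)) || any(kjeldahl_out <= 0))
    stop("kjeldahl_out must be > 0")
  frac <- (nh4_out - nh4_in) / kjeldahl_out
  if (any(frac < 0))
    warning("negative nitrogen mineralization (immobilization): ",
            paste(signif(frac[frac < 0], 3), collapse = ", "))
  frac
}

# Named analyte vector of a stream (g/kg ww); fiber-derived entries are NA
# when the detergent-fiber or sugar data are absent.
stream_analytes <- function(stream) {
  fib <- tryCatch(stream_fiber(stream), error = function(e) NULL)
  c(protein = stream$protein,
    crude_fat = stream$crude_fat,
    hemicellulose = if (is.null(fib)) NA_real_ else fib$hemicellulose,
    cellulose = if (is.null(fib)) NA_real_ else fib$cellulose,
    free_sugars = if (is.null(fib)) NA_real_ else fib$free_sugars,
    lignin_like = if (is.null(fib)) NA_real_ else fib$lignin_like,
    carbohydrates = if (is.null(fib)) NA_real_ else total_carbohydrates(fib))
}

# Resolve a stage's volume reduction: given > inferred from gas > 0 (warn).
stage_vol_red <- function(stage) {
  if (!is.na(stage$vol_red)) return(stage$vol_red)
  if (!is.na(stage$specific_gas) && !is.na(stage$ch4_fraction))
    return(volume_reduction_from_gas(stage$specific_gas, stage$ch4_fraction))
  warning("stage '", stage$name, "': no volume reduction or gas data; ",
          "assuming vol_red = 0 (efficiencies biased downward)")
  0
}

#' Chain digestion stages into a full mass balance
#'
#' Computes per-stage and overall degradation efficiencies, the adjusted VS
#' reduction, the degraded VS, the biomass-protein correction Y_prot, the
#' residual substrate-derived protein, and nitrogen mineralization for a
#' plant consisting of a substrate followed by one or two digestion stages
#' (digester, optionally post-digester). Stage k is fed by stage k-1's
#' outgoing digestate; overall quantities compare the substrate with the
#' final digestate adjusted by the product of all stage volume reductions.
#'
#' Two protein efficiencies are reported: `raw`, straight from measured
#' concentrations (which include protein in newly formed microbial
#' biomass), and `corrected`, where each stage's outgoing protein is first
#' reduced by that stage's Y_prot so the efficiency refers to feed-derived
#' protein only. The overall corrected efficiency composes multiplicatively
#' across stages.
#'
#' @param substrate the ingoing [stream_composition()].
#' @param stages list of [stage_record()]s in flow order.
#' @param config constants, see [ad_config()].
#' @return Object of class `mass_balance_result`: a list with elements
#'   `stages` (per-stage results), `deg_overall` (named vector of raw
#'   overall efficiencies), `protein_deg_corrected`, `vs_red_adj`,
#'   `degraded_vs_conc`, `degraded_vs_rate`, `y_prot`, `protein_resid`,
#'   `n_mineralization`, `vol_red` (per stage), `shrink` (overall remaining
#'   liquid fraction).
#' @export
chain_stages <- function(substrate, stages, config = ad_config()) {
  stopifnot(inherits(substrate, "stream_composition"), length(stages) >= 1,
            all(vapply(stages, inherits, TRUE, "stage_record")))
  n <- length(stages)
  feeds <- c(list(substrate), lapply(stages[-n], `[[`, "out"))
  vr <- vapply(stages, stage_vol_red, 0)
  a_sub <- stream_analytes(substrate)

  per_stage <- vector("list", n)
  eff_corr <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    feed <- feeds[[k]]; out <- stages[[k]]$out
    a_in <- stream_analytes(feed); a_out <- stream_analytes(out)
    eff <- rep(NA_real_, length(a_in)); names(eff) <- names(a_in)
    for (nm in names(a_in)) {
      if (is.na(a_in[[nm]]) || is.na(a_out[[nm]])) {
        warning("stage '", stages[[k]]$name, "': analyte '", nm,
                "' missing; skipped")
        next
      }
      if (a_in[[nm]] <= 0) next
      eff[[nm]] <- degradation_efficiency(a_in[[nm]],
                                          adjust_outflow(a_out[[nm]], vr[k]))
    }
    vs_red_k <- if (!any(is.na(c(feed$ts, feed$vs_of_ts, out$ts,
                                 out$vs_of_ts)))) {
      vs_reduction_adjusted(feed$ts, feed$vs_of_ts, out$ts, out$vs_of_ts,
                            vr[k])
    } else NA_real_
    dvs_k <- if (!is.na(vs_red_k))
      degraded_vs_conc(feed$ts, feed$vs_of_ts, vs_red_k) else NA_real_
    yp_k <- if (!is.na(dvs_k)) y_prot(max(dvs_k, 0), config) else NA_real_
    ec_k <- if (!is.na(eff[["protein"]]) && !is.na(yp_k)) {
      (a_in[["protein"]] -
         (adjust_outflow(a_out[["protein"]], vr[k]) - yp_k)) /
        a_in[["protein"]]
    } else NA_real_
    eff_corr[k] <- ec_k
    nmin_k <- if (!any(is.na(c(out$nh4_n, feed$nh4_n, out$kjeldahl_n))))
      nitrogen_mineralization(out$nh4_n, feed$nh4_n, out$kjeldahl_n)
    else NA_real_
    per_stage[[k]] <- list(
      name = stages[[k]]$name, vol_red = vr[k], eff = eff,
      protein_eff_corrected = ec_k, vs_red_adj = vs_red_k,
      degraded_vs_conc = dvs_k, y_prot = yp_k,
      degraded_vs_rate = if (!is.na(vs_red_k))
        degraded_vs_rate(stages[[k]]$olr, vs_red_k) else NA_real_,
      n_mineralization = nmin_k)
  }

  final <- stages[[n]]$out
  shrink <- prod(1 - vr)
  a_fin <- stream_analytes(final)
  deg_overall <- rep(NA_real_, length(a_sub)); names(deg_overall) <- names(a_sub)
  for (nm in names(a_sub)) {
    if (is.na(a_sub[[nm]]) || is.na(a_fin[[nm]]) || a_sub[[nm]] <= 0) next
    deg_overall[[nm]] <- degradation_efficiency(a_sub[[nm]],
                                                a_fin[[nm]] * shrink)
  }
  vs_red <- if (!any(is.na(c(substrate$ts, substrate$vs_of_ts, final$ts,
                             final$vs_of_ts)))) {
    vs_reduction_adjusted(substrate$ts, substrate$vs_of_ts, final$ts,
                          final$vs_of_ts, 1 - shrink)
  } else NA_real_
  dvs <- if (!is.na(vs_red))
    degraded_vs_conc(substrate$ts, substrate$vs_of_ts, vs_red) else NA_real_
  yp <- if (!is.na(dvs)) y_prot(max(dvs, 0), config) else NA_real_
  presid <- if (!is.na(yp) && !is.na(a_fin[["protein"]]))
    protein_residual(a_fin[["protein"]] * shrink, yp) else NA_real_
  pcorr <- if (!any(is.na(eff_corr))) 1 - prod(1 - eff_corr) else NA_real_
  nmin <- if (!any(is.na(c(final$nh4_n, substrate$nh4_n, final$kjeldahl_n))))
    nitrogen_mineralization(final$nh4_n, substrate$nh4_n, final$kjeldahl_n)
  else NA_real_

  structure(list(
    stages = per_stage, vol_red = vr, shrink = shrink,
    deg_overall = deg_overall, protein_deg_corrected = pcorr,
    vs_red_adj = vs_red, degraded_vs_conc = dvs,
    degraded_vs_rate = if (!is.na(vs_red))
      degraded_vs_rate(stages[[1]]$olr, vs_red) else NA_real_,
    y_prot = yp, protein_resid = presid, n_mineralization = nmin),
    class = "mass_balance_result")
}

#' @export
print.mass_balance_result <- function(x, ...) {
  cat("<mass_balance_result>", length(x$stages), "stage(s)\n")
  cat("  VS reduction (adj):", format(round(100 * x$vs_red_adj, 1)), "%\n")
  ok <- !is.na(x$deg_overall)
  if (any(ok)) {
    cat("  overall degradation efficiencies (%):\n")
    for (nm in names(x$deg_overall)[ok])
      cat(sprintf("    %-14s %6.1f\n", nm, 100 * x$deg_overall[[nm]]))
  }
  cat("  Y_prot:", format(signif(x$y_prot, 3)), "g/kg;  residual protein:",
      format(signif(x$protein_resid, 3)), "g/kg\n")
  invisible(x)
}
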