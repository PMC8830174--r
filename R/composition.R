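#' Construct a material stream composition
#'
#' A `stream_composition` describes one material stream of a biogas plant --
#' a substrate (mixture), a digester effluent, or a post-digester effluent --
#' on the canonical g per kg wet weight (ww) basis. All concentration fields
#' are optional; absent analytes are stored as `NA` and operations that need
#' them fail loudly rather than silently assuming zero.
#'
#' @param ts total solids, fraction of wet weight (0..1).
#' @param vs_of_ts volatile solids, fraction of TS (0..1).
#' @param ph pH, unitless.
#' @param kjeldahl_n total Kjeldahl nitrogen, g N/kg ww.
#' @param nh4_n ammonium nitrogen, g N/kg ww (must not exceed `kjeldahl_n`).
#' @param protein raw protein, g/kg ww.
#' @param crude_fat crude fat, g/kg ww.
#' @param sugar_monomers named numeric vector of total (bound + free) sugar
#'   monomers in g/kg ww (xylose, mannose, glucose, galactose, arabinose).
#' @param ndf,adf,adl neutral-detergent fiber, acid-detergent fiber and
#'   acid-detergent lignin, g/kg ww; the sequential assay implies
#'   `adl <= adf <= ndf`.
#' @param vfa named numeric vector of volatile fatty acids in mmol/L
#'   (see [supported_vfa()]).
#' @param density stream density, kg/L (liquids default to 1).
#' @param extra named list of carried-through optional fields (elements,
#'   EPS/SMP, viscosities, enzyme activities, DOC, C/N ratio, ...). These are
#'   data only; no operation interprets them.
#' @return An object of class `stream_composition`.
#' @examples
#' s <- stream_composition(ts = 0.12, vs_of_ts = 1, protein = 26.4,
#'                         crude_fat = 38.4, ndf = 36, adf = 24, adl = 9.6)
#' vs_g_per_kg(s)
#' @export
stream_composition <- function(ts = NA_real_, vs_of_ts = NA_real_,
                               ph = NA_real_,
                               kjeldahl_n = NA_real_, nh4_n = NA_real_,
                               protein = NA_real_, crude_fat = NA_real_,
                               sugar_monomers = NULL,
                               ndf = NA_real_, adf = NA_real_, adl = NA_real_,
                               vfa = NULL, density = 1,
                               extra = list()) {
  s <- structure(
    list(ts = as.numeric(ts), vs_of_ts = as.numeric(vs_of_ts),
         ph = as.numeric(ph),
         kjeldahl_n = as.numeric(kjeldahl_n), nh4_n = as.numeric(nh4_n),
         protein = as.numeric(protein), crude_fat = as.numeric(crude_fat),
         sugar_monomers = sugar_monomers,
         ndf = as.numeric(ndf), adf = as.numeric(adf), adl = as.numeric(adl),
         vfa = vfa, density = as.numeric(density), extra = extra),
    class = "stream_composition")
  validate_stream(s)
}

validate_stream <- function(s) {
  chk01 <- function(x, nm) {
    if (!is.na(x) && (x < 0 || x > 1))
      stop(nm, " must lie in [0, 1], got ", x)
  }
  chk01(s$ts, "ts"); chk01(s$vs_of_ts, "vs_of_ts")
  for (nm in c("kjeldahl_n", "nh4_n", "protein", "crude_fat",
               "ndf", "adf", "adl")) {
    v <- s[[nm]]
    if (!is.na(v) && v < 0) stop(nm, " must be non-negative, got ", v)
  }
  if (!is.na(s$nh4_n) && !is.na(s$kjeldahl_n) && s$nh4_n > s$kjeldahl_n) {
    stop("nh4_n (", s$nh4_n, ") exceeds kjeldahl_n (", s$kjeldahl_n, ")")
  }
  if (!is.null(s$vfa) && any(s$vfa < 0)) stop("VFA concentrations must be >= 0")
  if (!is.null(s$sugar_monomers) && any(s$sugar_monomers < 0))
    stop("sugar monomer concentrations must be >= 0")
  if (is.na(s$density) || s$density <= 0) stop("density must be > 0")
  s
}

#' @export
print.stream_composition <- function(x, ...) {
  cat("<stream_composition>  TS", format(x$ts), " VS/TS", format(x$vs_of_ts),
      " protein", format(x$protein), "g/kg  fat", format(x$crude_fat),
      "g/kg\n")
  invisible(x)
}

#' Volatile solids of a stream in g per kg wet weight
#'
#' @param stream a [stream_composition()].
#' @return VS concentration, g/kg ww (`ts * vs_of_ts * 1000`).
#' @export
vs_g_per_kg <- function(stream) {
  stream$ts * stream$vs_of_ts * 1000
}

#' Raw protein from Kjeldahl and ammonium nitrogen
#'
#' Raw protein is the organic nitrogen (Kjeldahl-N minus NH4-N) multiplied
#' by the conventional 6.25 g protein per g N.
#'
#' @param kjeldahl_n total Kjeldahl nitrogen, g N/kg.
#' @param nh4_n ammonium nitrogen, g N/kg.
#' @return Raw protein, g/kg.
#' @examples
#' raw_protein(6.0, 1.2)  # 30
#' @export
raw_protein <- function(kjeldahl_n, nh4_n) {
  if (any(nh4_n < 0) || any(kjeldahl_n < 0))
    stop("nitrogen concentrations must be non-negative")
  if (any(kjeldahl_n < nh4_n))
    stop("organic nitrogen is negative: kjeldahl_n = ", kjeldahl_n[1],
         " < nh4_n = ", nh4_n[1])
  (kjeldahl_n - nh4_n) * ad_config()$protein_n_factor
}

#' Fiber fractions container
#'
#' @param hemicellulose,cellulose,lignin_like,free_sugars g/kg ww.
#' @return Object of class `fiber_fractions`.
#' @export
fiber_fractions <- function(hemicellulose, cellulose, lignin_like,
                            free_sugars = NA_real_) {
  if (any(c(hemicellulose, cellulose, lignin_like) < 0, na.rm = TRUE))
    stop("fiber fractions must be non-negative")
  structure(list(hemicellulose = hemicellulose, cellulose = cellulose,
                 lignin_like = lignin_like, free_sugars = free_sugars),
            class = "fiber_fractions")
}

#' Partition sequential detergent-fiber measurements
#'
#' The sequential Van Soest assay measures NDF, then ADF, then ADL on the
#' same material, so hemicellulose = NDF - ADF, cellulose = ADF - ADL and
#' the ADL residue is lignin-like matter. Small ordering violations (within
#' the relative `tolerance`, lab noise) are clamped with a warning; larger
#' ones are treated as data corruption and raise an error.
#'
#' @param ndf,adf,adl g/kg ww, expected ordering `ndf >= adf >= adl >= 0`.
#' @param tolerance relative clamping tolerance (default from [ad_config()]).
#' @return A [fiber_fractions()] (without free sugars).
#' @examples
#' fiber_partition(36, 24, 9.6)
#' @export
fiber_partition <- function(ndf, adf, adl,
                            tolerance = ad_config()$clamp_tolerance) {
  if (any(is.na(c(ndf, adf, adl)))) stop("ndf, adf and adl must all be present")
  if (any(c(ndf, adf, adl) < 0)) stop("fiber measurements must be >= 0")
  fix_pair <- function(hi, lo, hi_nm, lo_nm) {
    if (lo > hi) {
      rel <- (lo - hi) / max(lo, .Machine$double.eps)
      if (rel > tolerance)
        stop(lo_nm, " (", lo, ") exceeds ", hi_nm, " (", hi,
             ") by more than ", 100 * tolerance, "% relative")
      warning(lo_nm, " (", lo, ") slightly exceeds ", hi_nm, " (", hi,
              "); clamped")
      lo <- hi
    }
    lo
  }
  adf <- fix_pair(ndf, adf, "ndf", "adf")
  adl <- fix_pair(adf, adl, "adf", "adl")
  fiber_fractions(hemicellulose = ndf - adf, cellulose = adf - adl,
                  lignin_like = adl)
}

#' Free (non-structural) sugars
#'
#' Estimated by subtracting hemicellulose and cellulose from the total
#' content of all sugar monomers; negative estimates are clamped to zero
#' with a warning.
#'
#' @param total_sugar_monomers total bound + free sugar monomers, g/kg.
#' @param hemicellulose,cellulose g/kg.
#' @return Free sugars, g/kg.
#' @export
free_sugars <- function(total_sugar_monomers, hemicellulose, cellulose) {
  if (any(c(total_sugar_monomers, hemicellulose, cellulose) < 0))
    stop("inputs must be non-negative")
  out <- total_sugar_monomers - hemicellulose - cellulose
  if (out < 0) {
    warning("free sugars estimate negative (", signif(out, 4),
            " g/kg); clamped to 0")
    out <- 0
  }
  out
}

#' Total carbohydrates of a fiber partition
#'
#' Free sugars + hemicellulose + cellulose. Lignin-like matter is excluded:
#' native lignin is essentially recalcitrant under anaerobic conditions and
#' carries no realistic methane potential.
#'
#' @param fiber a complete [fiber_fractions()] (free sugars present).
#' @return Carbohydrates, g/kg.
#' @export
total_carbohydrates <- function(fiber) {
  stopifnot(inherits(fiber, "fiber_fractions"))
  if (is.na(fiber$free_sugars))
    stop("fiber fractions are incomplete: free_sugars is missing")
  fiber$free_sugars + fiber$hemicellulose + fiber$cellulose
}

#' Full fiber/sugar partition of a stream
#'
#' Convenience wrapper: partitions NDF/ADF/ADL and estimates free sugars
#' from the stream's total sugar monomers.
#'
#' @param stream a [stream_composition()] with ndf/adf/adl and sugar
#'   monomers present.
#' @return A complete [fiber_fractions()].
#' @export
stream_fiber <- function(stream) {
  if (is.null(stream$sugar_monomers))
    stop("stream has no sugar monomer data; cannot estimate free sugars")
  f <- fiber_partition(stream$ndf, stream$adf, stream$adl)
  f$free_sugars <- free_sugars(sum(stream$sugar_monomers),
                               f$hemicellulose, f$cellulose)
  f
}

#' One component of a substrate mixture
#'
#' @param name component name.
#' @param volume_fraction fraction of ingoing volume (components of a
#'   mixture must sum to 1 within 0.01).
#' @param composition the component's [stream_composition()].
#' @param density kg/L, defaults to the composition's density.
#' @export
substrate_component <- function(name, volume_fraction, composition,
                                density = composition$density) {
  stopifnot(inherits(composition, "stream_composition"))
  if (volume_fraction < 0 || volume_fraction > 1)
    stop("volume_fraction must lie in [0, 1]")
  if (density <= 0) stop("density must be > 0")
  structure(list(name = name, volume_fraction = volume_fraction,
                 density = density, composition = composition),
            class = "substrate_component")
}

#' Mix substrate components into one stream
#'
#' Concentrations are mass-weighted with weights `volume_fraction * density`
#' so that total analyte mass is conserved. pH is combined as -log10 of the
#' weighted mean hydrogen-ion activity, and only when every component
#' reports a pH. Named analyte maps (sugars, VFAs) are merged over the union
#' of names when every component carries the map, treating names absent from
#' a component as zero.
#'
#' @param components list of [substrate_component()].
#' @param fraction_tolerance allowed deviation of the volume-fraction sum
#'   from 1 (default 0.01).
#' @return The mixture as a [stream_composition()].
#' @export
mix_streams <- function(components, fraction_tolerance = 0.01) {
  stopifnot(length(components) >= 1,
            all(vapply(components, inherits, TRUE, "substrate_component")))
  fr <- vapply(components, `[[`, 0, "volume_fraction")
  if (abs(sum(fr) - 1) > fraction_tolerance)
    stop("volume fractions sum to ", sum(fr), ", not 1 +/- ",
         fraction_tolerance)
  w <- fr * vapply(components, `[[`, 0, "density")
  w <- w / sum(w)
  comps <- lapply(components, `[[`, "composition")

  wmean <- function(field) {
    v <- vapply(comps, function(s) s[[field]], 0)
    if (any(is.na(v))) return(NA_real_)
    sum(w * v)
  }
  mix_map <- function(field) {
    maps <- lapply(comps, `[[`, field)
    if (any(vapply(maps, is.null, TRUE))) return(NULL)
    nms <- unique(unlist(lapply(maps, names)))
    out <- vapply(nms, function(nm) {
      sum(w * vapply(maps, function(m) if (nm %in% names(m)) m[[nm]] else 0, 0))
    }, 0)
    stats::setNames(out, nms)
  }
  ts  <- wmean("ts")
  vsg <- sum(w * vapply(comps, function(s) s$ts * s$vs_of_ts, 0))
  phs <- vapply(comps, `[[`, 0, "ph")
  ph  <- if (any(is.na(phs))) NA_real_ else -log10(sum(w * 10^(-phs)))
  stream_composition(
    ts = ts,
    vs_of_ts = if (!is.na(ts) && ts > 0) vsg / ts else NA_real_,
    ph = ph,
    kjeldahl_n = wmean("kjeldahl_n"), nh4_n = wmean("nh4_n"),
    protein = wmean("protein"), crude_fat = wmean("crude_fat"),
    sugar_monomers = mix_map("sugar_monomers"),
    ndf = wmean("ndf"), adf = wmean("adf"), adl = wmean("adl"),
    vfa = mix_map("vfa"),
    density = sum(fr * vapply(components, `[[`, 0, "density")))
}

#' Convert a concentration between reporting bases
#'
#' Exact conversion between the bases mixed freely in plant reporting:
#' g per kg wet weight (`"g_per_kg"`), percent of TS (`"pct_ts"`), percent
#' of VS (`"pct_vs"`) and mg per litre (`"mg_per_l"`, using the stream
#' density, default 1 kg/L).
#'
#' @param value numeric value(s) in the `from` basis.
#' @param from,to one of `"g_per_kg"`, `"pct_ts"`, `"pct_vs"`, `"mg_per_l"`.
#' @param ts,vs_of_ts solids fractions, required for the percent bases.
#' @param density kg/L, required for `"mg_per_l"`.
#' @return Value(s) in the `to` basis.
#' @examples
#' convert_basis(22, "pct_vs", "g_per_kg", ts = 0.12, vs_of_ts = 1)  # 26.4
#' @export
convert_basis <- function(value, from, to, ts = NA_real_,
                          vs_of_ts = NA_real_, density = 1) {
  bases <- c("g_per_kg", "pct_ts", "pct_vs", "mg_per_l")
  from <- match.arg(from, bases); to <- match.arg(to, bases)
  need <- function(x, nm) {
    if (any(is.na(x)) || any(x == 0))
      stop("conversion requires nonzero ", nm)
    x
  }
  # to canonical g/kg ww
  g_kg <- switch(from,
    g_per_kg = value,
    pct_ts   = value / 100 * need(ts, "ts") * 1000,
    pct_vs   = value / 100 * need(ts, "ts") * need(vs_of_ts, "vs_of_ts") * 1000,
    mg_per_l = value / 1000 / need(density, "density"))
  switch(to,
    g_per_kg = g_kg,
    pct_ts   = g_kg / (need(ts, "ts") * 1000) * 100,
    pct_vs   = g_kg / (need(ts, "ts") * need(vs_of_ts, "vs_of_ts") * 1000) * 100,
    mg_per_l = g_kg * 1000 * need(density, "density"))
}
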