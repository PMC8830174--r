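# Mean-preserving lognormal draw: E[X] = mean for every cv; cv = 0 is exact.
rlnorm_mean <- function(n, mean, cv) {
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) return(rep_len(mean, n))
  out <- numeric(n)
  pos <- mean > 0
  s2 <- log(1 + cv^2)
  out[pos] <- stats::rlnorm(sum(pos), log(mean[pos]) - s2 / 2, sqrt(s2))
  out
}

# Fixed split of total sugar monomers used by the generator.
.monomer_split <- c(glucose = 0.40, xylose = 0.25, mannose = 0.15,
                    galactose = 0.12, arabinose = 0.08)

#' Category template for synthetic plants
#'
#' Composition priors and stage plans for the four plant categories of the
#' survey: food waste (`FW`), plant-based agricultural waste (`AW`),
#' agricultural waste with manure (`AWM`) and sewage sludge (`WWTP`).
#' Means follow the printed full-scale compositions and operating tables
#' (e.g. FW: VS about 120 g/kg ww with 22% protein, 32% crude fat, 10%
#' hemicellulose, 12% cellulose, 16% free sugars and 8% lignin-like matter
#' of VS); the stage plans carry category-typical temperature, HRT, OLR and
#' true degradation fractions.
#'
#' @param category one of `"FW"`, `"AW"`, `"AWM"`, `"WWTP"`.
#' @return Object of class `plant_template`.
#' @export
plant_template <- function(category = c("FW", "AW", "AWM", "WWTP")) {
  category <- match.arg(category)
  tpl <- switch(category,
    FW = list(
      vs_mean = 120, vs_of_ts = 0.88, ph = 4.8, nh4_n = 0.5,
      macro = c(protein = 0.22, crude_fat = 0.32, hemicellulose = 0.10,
                cellulose = 0.12, free_sugars = 0.16, lignin_like = 0.08),
      vfa = c(acetic = 55),
      stages = list(
        list(name = "digester", temperature = 42, hrt = 35, olr = 4.2,
             ph_out = 7.8,
             truth = c(protein = 0.37, crude_fat = 0.91,
                       hemicellulose = 0.76, cellulose = 0.82,
                       free_sugars = 0.999, lignin_like = 0.30,
                       other = 0.50, vfa = 0.95)),
        list(name = "post-digester", temperature = 41, hrt = 20, olr = 2.0,
             ph_out = 7.8,
             truth = c(protein = 0.55, crude_fat = 0.50,
                       hemicellulose = 0.30, cellulose = 0.30,
                       free_sugars = 0.50, lignin_like = 0.10,
                       other = 0.30, vfa = 0.90)))),
    AW = list(
      vs_mean = 150, vs_of_ts = 0.92, ph = 5.5, nh4_n = 0.6,
      macro = c(protein = 0.15, crude_fat = 0.04, hemicellulose = 0.20,
                cellulose = 0.25, free_sugars = 0.15, lignin_like = 0.12),
      vfa = c(acetic = 20),
      stages = list(
        list(name = "digester", temperature = 38, hrt = 55, olr = 5.8,
             ph_out = 7.6,
             truth = c(protein = 0.50, crude_fat = 0.85,
                       hemicellulose = 0.60, cellulose = 0.65,
                       free_sugars = 0.95, lignin_like = 0.10,
                       other = 0.40, vfa = 0.90)),
        list(name = "post-digester", temperature = 38, hrt = 40, olr = 2.0,
             ph_out = 7.5,
             truth = c(protein = 0.35, crude_fat = 0.40,
                       hemicellulose = 0.35, cellulose = 0.40,
                       free_sugars = 0.60, lignin_like = 0.05,
                       other = 0.25, vfa = 0.85)))),
    AWM = list(
      vs_mean = 90, vs_of_ts = 0.80, ph = 6.5, nh4_n = 1.2,
      macro = c(protein = 0.18, crude_fat = 0.06, hemicellulose = 0.22,
                cellulose = 0.22, free_sugars = 0.10, lignin_like = 0.15),
      vfa = c(acetic = 25, propionic = 5),
      stages = list(
        list(name = "digester", temperature = 38, hrt = 55, olr = 3.4,
             ph_out = 7.9,
             truth = c(protein = 0.35, crude_fat = 0.80,
                       hemicellulose = 0.50, cellulose = 0.55,
                       free_sugars = 0.90, lignin_like = 0.05,
                       other = 0.30, vfa = 0.90)))),
    WWTP = list(
      vs_mean = 27, vs_of_ts = 0.75, ph = 6.0, nh4_n = 0.3,
      macro = c(protein = 0.29, crude_fat = 0.17, hemicellulose = 0.14,
                cellulose = 0.09, free_sugars = 0.20, lignin_like = 0.10),
      vfa = c(acetic = 10),
      stages = list(
        list(name = "digester", temperature = 37, hrt = 17, olr = 1.5,
             ph_out = 7.2,
             truth = c(protein = 0.55, crude_fat = 0.87,
                       hemicellulose = 0.48, cellulose = 0.61,
                       free_sugars = 0.85, lignin_like = 0.20,
                       other = 0.40, vfa = 0.90)))))
  if (sum(tpl$macro) > 1)
    stop("infeasible template: macromolecule fractions exceed total VS")
  tpl$category <- category
  tpl$composition_cv <- 0.08   # between-plant variation of analyte means
  structure(tpl, class = "plant_template")
}

#' Ground-truth record of a simulated plant
#'
#' @param stage_truth list (one element per stage) of named true degradation
#'   fractions.
#' @param noise_cv measurement-noise coefficient of variation.
#' @param seed RNG seed used for the plant.
#' @param yield,protein_fraction biomass model constants.
#' @return Object of class `synthetic_ground_truth`.
#' @export
synthetic_ground_truth <- function(stage_truth, noise_cv = 0, seed = NA,
                                   yield = 0.1, protein_fraction = 0.5) {
  for (tr in stage_truth) {
    if (any(tr < 0 | tr > 1)) stop("truth fractions must lie in [0, 1]")
  }
  structure(list(stage_truth = stage_truth, noise_cv = noise_cv,
                 seed = seed, yield = yield,
                 protein_fraction = protein_fraction),
            class = "synthetic_ground_truth")
}

#' Draw a substrate stream from a category template
#'
#' Analyte concentrations are drawn from mean-preserving lognormals around
#' the template means (CV = `cv`); the stream's VS and TS are reconstructed
#' from the drawn analytes so solids consistency holds by construction.
#'
#' @param template a [plant_template()].
#' @param seed optional RNG seed.
#' @param cv coefficient of variation of the draws (default: the template's
#'   `composition_cv`; 0 returns the template means exactly).
#' @return A [stream_composition()].
#' @export
sample_substrate <- function(template, seed = NULL,
                             cv = template$composition_cv) {
  stopifnot(inherits(template, "plant_template"))
  if (!is.null(seed)) set.seed(seed)
  means <- template$macro * template$vs_mean
  conc <- stats::setNames(rlnorm_mean(length(means), means, cv), names(means))
  other_mean <- (1 - sum(template$macro)) * template$vs_mean
  other <- rlnorm_mean(1, other_mean, cv)
  vfa <- stats::setNames(rlnorm_mean(length(template$vfa),
                                     unname(template$vfa), cv),
                         names(template$vfa))
  vfa_mass <- sum(vfa * .vfa_molar_mass[vapply(names(vfa),
                                               .normalize_acid, "")]) / 1000
  vs <- sum(conc) + other + vfa_mass
  ts <- vs / 1000 / template$vs_of_ts
  if (ts > 1) stop("infeasible template: TS above 1")
  nh4 <- rlnorm_mean(1, template$nh4_n, cv)
  monomers <- (conc[["free_sugars"]] + conc[["hemicellulose"]] +
                 conc[["cellulose"]]) * .monomer_split
  stream_composition(
    ts = ts, vs_of_ts = template$vs_of_ts, ph = template$ph,
    kjeldahl_n = conc[["protein"]] / 6.25 + nh4, nh4_n = nh4,
    protein = conc[["protein"]], crude_fat = conc[["crude_fat"]],
    sugar_monomers = monomers,
    ndf = conc[["hemicellulose"]] + conc[["cellulose"]] +
      conc[["lignin_like"]],
    adf = conc[["cellulose"]] + conc[["lignin_like"]],
    adl = conc[["lignin_like"]],
    vfa = vfa)
}

# Analyte masses (g per kg feed) seen by the simulator, incl. the
# unspeciated "other" VS pool and the VFA mass.
.sim_pools <- function(feed) {
  fib <- stream_fiber(feed)
  vfa <- if (is.null(feed$vfa)) numeric(0) else feed$vfa
  vfa_mass <- if (length(vfa))
    sum(vfa * .vfa_molar_mass[vapply(names(vfa), .normalize_acid, "")]) /
      1000 / feed$density else 0
  pools <- c(protein = feed$protein, crude_fat = feed$crude_fat,
             hemicellulose = fib$hemicellulose, cellulose = fib$cellulose,
             free_sugars = fib$free_sugars, lignin_like = fib$lignin_like)
  other <- vs_g_per_kg(feed) - sum(pools) - vfa_mass
  if (other < -1e-9)
    stop("infeasible stream: macromolecules + VFA exceed VS")
  list(pools = pools, other = max(other, 0), vfa = vfa,
       vfa_mass = vfa_mass)
}

#' Forward-simulate one digestion stage
#'
#' The stationary inverse of the mass-balance analysis. Per analyte, the
#' degraded mass is the feed mass times the true degradation fraction.
#' Methane is produced from degraded mass via the lumped Buswell
#' coefficients (and molar equivalents for VFAs); CO2 volume is set to 100%
#' of the CH4 volume for carbohydrate-like matter and protein and 43% for
#' fat (approximating Buswell CO2/CH4 ratios -- a documented simplification
#' used only to produce realistic volume reductions). New microbial biomass
#' is formed at `yield` g per g of net VS destroyed (so the generator is
#' exactly consistent with the Y_prot estimator applied to the measured VS
#' reduction), with half of it protein. Digestate concentrations are the
#' remaining masses divided by `1 - vol_red`; ammonium increases by the
#' nitrogen of net degraded protein.
#'
#' @param feed the feed [stream_composition()].
#' @param truth named true degradation fractions for `protein`,
#'   `crude_fat`, `hemicellulose`, `cellulose`, `free_sugars`,
#'   `lignin_like`, `other` and `vfa` (all in `[0,1]`).
#' @param name,temperature,hrt,olr,ph_out stage descriptors.
#' @param yield,protein_fraction biomass model constants.
#' @return List with elements `stage` (a [stage_record()] carrying gas data
#'   but no pre-set `vol_red`), `gas` (named NL/kg: ch4, co2), `vol_red`,
#'   and `degraded` (named net degraded masses, g per kg feed, satisfying
#'   exact per-analyte mass closure).
#' @export
simulate_digestion <- function(feed, truth, name = "digester",
                               temperature = 38, hrt = 30, olr = 3,
                               ph_out = 7.8, yield = 0.1,
                               protein_fraction = 0.5) {
  stopifnot(inherits(feed, "stream_composition"))
  need <- c("protein", "crude_fat", "hemicellulose", "cellulose",
            "free_sugars", "lignin_like", "other", "vfa")
  if (!all(need %in% names(truth)))
    stop("truth must name fractions for: ", paste(need, collapse = ", "))
  if (any(truth < 0 | truth > 1)) stop("truth fractions must lie in [0, 1]")
  p <- .sim_pools(feed)
  cfg <- ad_config()

  deg <- p$pools * truth[names(p$pools)]
  deg_other <- p$other * truth[["other"]]
  vfa_deg <- p$vfa * truth[["vfa"]]                     # mmol/L degraded
  vfa_deg_mass <- if (length(vfa_deg))
    sum(vfa_deg * .vfa_molar_mass[vapply(names(vfa_deg),
                                         .normalize_acid, "")]) /
      1000 / feed$density else 0
  gross <- sum(deg) + deg_other + vfa_deg_mass
  net <- gross / (1 + yield)          # net VS destruction D: B = yield * D
  biomass <- yield * net
  b_prot <- protein_fraction * biomass
  b_other <- biomass - b_prot

  carb_like <- sum(deg[c("hemicellulose", "cellulose", "free_sugars",
                         "lignin_like")]) + deg_other
  ch4_carbprot <- cfg$tmp_coefficients[["carbohydrate"]] * carb_like +
    cfg$tmp_coefficients[["protein"]] * deg[["protein"]]
  ch4_fat <- cfg$tmp_coefficients[["fat"]] * deg[["crude_fat"]]
  ch4_vfa <- if (length(vfa_deg))
    sum(vfa_deg * vapply(names(vfa_deg), vfa_ch4_equivalent, 0)) *
      cfg$molar_volume * 1e-3 / feed$density else 0
  ch4 <- ch4_carbprot + ch4_fat + ch4_vfa
  co2 <- 1.0 * (ch4_carbprot + ch4_vfa) + 0.43 * ch4_fat
  gas_mass <- ch4 * cfg$rho_ch4 + co2 * cfg$rho_co2
  vol_red <- gas_mass / 1000
  if (vol_red >= 1) stop("unphysical template: volume reduction >= 1")
  keep <- 1 - vol_red

  rem <- p$pools - deg
  rem[["protein"]] <- rem[["protein"]] + b_prot
  rem_other <- p$other - deg_other + b_other
  vfa_rem <- p$vfa - vfa_deg
  vfa_rem_mass <- p$vfa_mass - vfa_deg_mass
  vs_rem <- sum(rem) + rem_other + vfa_rem_mass
  ash <- feed$ts * 1000 - vs_g_per_kg(feed)
  ts_out <- (ash + vs_rem) / keep / 1000

  n_released <- (deg[["protein"]] - b_prot) / cfg$protein_n_factor
  kj_out <- feed$kjeldahl_n / keep
  nh4_out <- (feed$nh4_n + n_released) / keep
  if (!is.na(nh4_out) && nh4_out < 0) {
    warning("nitrogen immobilization exceeds the ammonium pool; ",
            "NH4-N floored at 0")
    nh4_out <- 0
  }

  monomers_total <- rem[["free_sugars"]] + rem[["hemicellulose"]] +
    rem[["cellulose"]]
  out <- stream_composition(
    ts = ts_out, vs_of_ts = vs_rem / (ash + vs_rem), ph = ph_out,
    kjeldahl_n = kj_out, nh4_n = nh4_out,
    protein = rem[["protein"]] / keep,
    crude_fat = rem[["crude_fat"]] / keep,
    sugar_monomers = monomers_total / keep * .monomer_split,
    ndf = (rem[["hemicellulose"]] + rem[["cellulose"]] +
             rem[["lignin_like"]]) / keep,
    adf = (rem[["cellulose"]] + rem[["lignin_like"]]) / keep,
    adl = rem[["lignin_like"]] / keep,
    vfa = if (length(vfa_rem)) vfa_rem / keep else NULL,
    density = feed$density)

  degraded_net <- c(deg, other = deg_other)
  degraded_net[["protein"]] <- degraded_net[["protein"]] - b_prot
  degraded_net[["other"]] <- degraded_net[["other"]] - b_other
  list(
    stage = stage_record(name = name, temperature = temperature, hrt = hrt,
                         olr = olr, out = out,
                         specific_gas = ch4 + co2,
                         ch4_fraction = if (ch4 + co2 > 0)
                           ch4 / (ch4 + co2) else 0),
    gas = c(ch4 = ch4, co2 = co2), vol_red = vol_red,
    degraded = degraded_net, net_vs_destroyed = net,
    biomass_protein = b_prot)
}

#' Add multiplicative measurement noise to a stream
#'
#' Applies mean-preserving lognormal noise (coefficient of variation `cv`)
#' independently to every measured analyte, then repairs invariants that
#' noise can break: the detergent-fiber ordering is re-clamped and ammonium
#' is capped at Kjeldahl nitrogen (each repair warns).
#'
#' @param stream a [stream_composition()].
#' @param cv noise coefficient of variation (0 returns the stream
#'   unchanged).
#' @param seed optional RNG seed.
#' @return A noisy [stream_composition()].
#' @export
add_noise <- function(stream, cv, seed = NULL) {
  stopifnot(inherits(stream, "stream_composition"))
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) return(stream)
  if (!is.null(seed)) set.seed(seed)
  jit <- function(x) {
    if (is.null(x)) return(NULL)
    bad <- is.na(x)
    x[!bad] <- rlnorm_mean(sum(!bad), x[!bad], cv)
    x
  }
  s <- stream
  s$ts <- min(jit(s$ts), 1)
  s$vs_of_ts <- min(jit(s$vs_of_ts), 1)
  for (nm in c("kjeldahl_n", "nh4_n", "protein", "crude_fat"))
    s[[nm]] <- jit(s[[nm]])
  s$vfa <- jit(s$vfa)
  # Fiber noise acts on the analytes (hemicellulose, cellulose, lignin,
  # free sugars), and the assay values NDF/ADF/ADL and total monomers are
  # recomposed from them, keeping the sequential-assay ordering intact.
  fib <- tryCatch(suppressWarnings(stream_fiber(stream)),
                  error = function(e) NULL)
  if (!is.null(fib)) {
    h <- jit(fib$hemicellulose); ce <- jit(fib$cellulose)
    l <- jit(fib$lignin_like); fs <- jit(fib$free_sugars)
    s$ndf <- h + ce + l; s$adf <- ce + l; s$adl <- l
    if (!is.null(s$sugar_monomers)) {
      old <- sum(s$sugar_monomers)
      tot <- fs + h + ce
      s$sugar_monomers <- if (old > 0) s$sugar_monomers / old * tot
        else s$sugar_monomers
    }
  } else {
    for (nm in c("ndf", "adf", "adl")) s[[nm]] <- jit(s[[nm]])
    s$sugar_monomers <- jit(s$sugar_monomers)
    if (!is.na(s$adf) && !is.na(s$ndf) && s$adf > s$ndf) {
      warning("noise broke ndf >= adf; clamped"); s$adf <- s$ndf
    }
    if (!is.na(s$adl) && !is.na(s$adf) && s$adl > s$adf) {
      warning("noise broke adf >= adl; clamped"); s$adl <- s$adf
    }
  }
  if (!is.na(s$nh4_n) && !is.na(s$kjeldahl_n) && s$nh4_n > s$kjeldahl_n) {
    warning("noise broke nh4_n <= kjeldahl_n; clamped")
    s$nh4_n <- s$kjeldahl_n
  }
  validate_stream(s)
}

#' A full plant record
#'
#' @param name plant identifier.
#' @param category substrate category.
#' @param substrate the ingoing [stream_composition()] (mixture).
#' @param stages list of [stage_record()]s in flow order.
#' @export
plant_record <- function(name, category, substrate, stages) {
  stopifnot(inherits(substrate, "stream_composition"),
            all(vapply(stages, inherits, TRUE, "stage_record")))
  structure(list(name = name, category = category, substrate = substrate,
                 stages = stages), class = "plant_record")
}

#' Generate a synthetic multi-plant survey
#'
#' Forward-simulates `n_plants` plants of the given categories: a substrate
#' is drawn from each category template, digested through the template's
#' stage plan with the template's true degradation fractions, and
#' (optionally) measurement noise is applied to every observed stream. The
#' generator's true fractions are returned alongside for parameter-recovery
#' tests.
#'
#' @param n_plants number of plants (>= 2).
#' @param categories character vector of categories, recycled to
#'   `n_plants`; default mirrors the nine-plant survey shape (4 FW, 2 AW,
#'   1 AWM, 2 WWTP).
#' @param noise_cv measurement-noise CV applied to observed streams.
#' @param seed RNG seed; the whole survey is reproducible from it.
#' @return List with `plants` (list of [plant_record()], observed = noisy),
#'   `truth` (list of [synthetic_ground_truth()]) and `tables` (the plant
#'   tables in the package's file dialect, see [plant_tables()]).
#' @export
generate_survey <- function(n_plants = 9,
                            categories = c("FW", "FW", "FW", "FW", "AW",
                                           "AW", "AWM", "WWTP", "WWTP"),
                            noise_cv = 0, seed = 1) {
  if (n_plants < 2) stop("n_plants must be >= 2")
  categories <- rep_len(categories, n_plants)
  set.seed(seed)
  plants <- vector("list", n_plants)
  truth <- vector("list", n_plants)
  for (i in seq_len(n_plants)) {
    tpl <- plant_template(categories[i])
    substrate <- sample_substrate(tpl)
    feed <- substrate
    stages <- vector("list", length(tpl$stages))
    st_truth <- vector("list", length(tpl$stages))
    for (k in seq_along(tpl$stages)) {
      sp <- tpl$stages[[k]]
      sim <- simulate_digestion(feed, sp$truth, name = sp$name,
                                temperature = sp$temperature, hrt = sp$hrt,
                                olr = sp$olr, ph_out = sp$ph_out)
      stages[[k]] <- sim$stage
      st_truth[[k]] <- sp$truth
      feed <- sim$stage$out
    }
    if (noise_cv > 0) {
      substrate <- suppressWarnings(add_noise(substrate, noise_cv))
      for (k in seq_along(stages))
        stages[[k]]$out <- suppressWarnings(add_noise(stages[[k]]$out,
                                                      noise_cv))
    }
    nm <- sprintf("%s%d", categories[i], sum(categories[seq_len(i)] ==
                                               categories[i]))
    plants[[i]] <- plant_record(nm, categories[i], substrate, stages)
    truth[[i]] <- synthetic_ground_truth(st_truth, noise_cv = noise_cv,
                                         seed = seed)
  }
  names(plants) <- vapply(plants, `[[`, "", "name")
  names(truth) <- names(plants)
  list(plants = plants, truth = truth, tables = plant_tables(plants))
}
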