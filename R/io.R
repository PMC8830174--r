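# Column dictionary of the plant-table dialect: canonical name -> unit.
.stream_columns <- c(
  plant = "text", stream_id = "text", role = "text",
  ts = "frac_ww", vs_of_ts = "frac_ts", ph = "-",
  kjeldahl_n = "g/kg_ww", nh4_n = "g/kg_ww",
  protein = "g/kg_ww", crude_fat = "g/kg_ww",
  ndf = "g/kg_ww", adf = "g/kg_ww", adl = "g/kg_ww",
  density = "kg/L")

.ops_columns <- c(
  plant = "text", stage = "index", name = "text",
  temperature = "C", hrt = "days", olr = "kgVS/m3.day",
  specific_gas = "NL/kg", ch4_fraction = "-", vol_red = "-")

.col_header <- function(dict) {
  ifelse(dict == "text" | dict == "index", names(dict),
         paste0(names(dict), "[", dict, "]"))
}

#' Plant tables in the package's file dialect
#'
#' Serializes a list of plants into three data frames: `streams` (one row
#' per stream, unit-suffixed wide columns), `analytes` (long format:
#' stream_id, analyte, value, unit; sugar monomers in g/kg_ww, VFAs in
#' mmol/L) and `operations` (one row per digestion stage). Units are
#' explicit in every header; silent unit guessing is forbidden on read.
#'
#' @param plants list of [plant_record()].
#' @return Named list of data frames `streams`, `analytes`, `operations`.
#' @export
plant_tables <- function(plants) {
  stopifnot(all(vapply(plants, inherits, TRUE, "plant_record")))
  srows <- list(); arows <- list(); orows <- list()
  for (p in plants) {
    streams <- c(list(substrate = p$substrate),
                 stats::setNames(lapply(p$stages, `[[`, "out"),
                                 vapply(p$stages, `[[`, "", "name")))
    for (role in names(streams)) {
      s <- streams[[role]]
      sid <- paste(p$name, role, sep = ":")
      srows[[sid]] <- data.frame(
        plant = p$name, stream_id = sid, role = role,
        ts = s$ts, vs_of_ts = s$vs_of_ts, ph = s$ph,
        kjeldahl_n = s$kjeldahl_n, nh4_n = s$nh4_n,
        protein = s$protein, crude_fat = s$crude_fat,
        ndf = s$ndf, adf = s$adf, adl = s$adl, density = s$density)
      if (!is.null(s$sugar_monomers))
        arows[[paste0(sid, ":sugar")]] <- data.frame(
          stream_id = sid, analyte = names(s$sugar_monomers),
          value = unname(s$sugar_monomers), unit = "g/kg_ww")
      if (!is.null(s$vfa))
        arows[[paste0(sid, ":vfa")]] <- data.frame(
          stream_id = sid, analyte = names(s$vfa),
          value = unname(s$vfa), unit = "mmol/L")
    }
    for (k in seq_along(p$stages)) {
      st <- p$stages[[k]]
      orows[[paste(p$name, k)]] <- data.frame(
        plant = p$name, stage = k, name = st$name,
        temperature = st$temperature, hrt = st$hrt, olr = st$olr,
        specific_gas = st$specific_gas, ch4_fraction = st$ch4_fraction,
        vol_red = st$vol_red)
    }
  }
  streams <- do.call(rbind, unname(srows))
  names(streams) <- .col_header(.stream_columns)
  operations <- do.call(rbind, unname(orows))
  names(operations) <- .col_header(.ops_columns)
  analytes <- if (length(arows)) do.call(rbind, unname(arows)) else
    data.frame(stream_id = character(0), analyte = character(0),
               value = numeric(0), unit = character(0))
  rownames(streams) <- rownames(analytes) <- rownames(operations) <- NULL
  list(streams = streams, analytes = analytes, operations = operations)
}

#' Write plant tables to a directory
#'
#' Writes `streams.csv`, `analytes.csv` and `operations.csv`; output is
#' deterministic (identical inputs give identical bytes).
#'
#' @param plants list of [plant_record()] (or a `plant_tables()` result).
#' @param dir output directory, created if needed.
#' @return The directory, invisibly.
#' @export
write_plant_table <- function(plants, dir) {
  tabs <- if (is.list(plants) && all(c("streams", "analytes", "operations")
                                     %in% names(plants))) plants
          else plant_tables(plants)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

.strip_units <- function(headers, dict, file) {
  expected <- .col_header(dict)
  # R's read.csv mangles "[" in headers; undo check on the mangled form
  mangled <- make.names(expected)
  missing <- setdiff(mangled, headers)
  if (length(missing))
    stop(file, ": missing or mis-united column(s): ",
         paste(expected[mangled %in% missing], collapse = ", "),
         " (units must be stated in headers)")
  extra <- setdiff(headers, mangled)
  if (length(extra))
    warning(file, ": unknown column(s) preserved but ignored: ",
            paste(extra, collapse = ", "))
  stats::setNames(mangled, names(dict))
}

#' Read plant tables from a directory
#'
#' Inverse of [write_plant_table()]: validates the unit-suffixed headers
#' (a wrong or absent unit is an error naming the column) and rebuilds
#' the [plant_record()] list on the canonical g/kg ww basis.
#'
#' @param dir directory containing `streams.csv`, `analytes.csv`,
#'   `operations.csv`.
#' @return Named list of [plant_record()].
#' @export
read_plant_table <- function(dir) {
  fs <- file.path(dir, c("streams.csv", "analytes.csv", "operations.csv"))
  for (f in fs) if (!file.exists(f)) stop("missing file: ", f)
  streams <- utils::read.csv(fs[1])
  analytes <- utils::read.csv(fs[2])
  ops <- utils::read.csv(fs[3])
  smap <- .strip_units(names(streams), .stream_columns, "streams.csv")
  omap <- .strip_units(names(ops), .ops_columns, "operations.csv")
  names(streams)[match(smap, names(streams))] <- names(smap)
  names(ops)[match(omap, names(ops))] <- names(omap)
  bad_unit <- !analytes$unit %in% c("g/kg_ww", "mmol/L")
  if (any(bad_unit))
    stop("analytes.csv: unknown unit '", analytes$unit[bad_unit][1],
         "' for analyte '", analytes$analyte[bad_unit][1], "' (stream ",
         analytes$stream_id[bad_unit][1], ")")

  build_stream <- function(row) {
    sid <- row$stream_id
    a <- analytes[analytes$stream_id == sid, , drop = FALSE]
    sug <- a[a$unit == "g/kg_ww", , drop = FALSE]
    vfa <- a[a$unit == "mmol/L", , drop = FALSE]
    stream_composition(
      ts = row$ts, vs_of_ts = row$vs_of_ts, ph = row$ph,
      kjeldahl_n = row$kjeldahl_n, nh4_n = row$nh4_n,
      protein = row$protein, crude_fat = row$crude_fat,
      sugar_monomers = if (nrow(sug)) stats::setNames(sug$value,
                                                      sug$analyte) else NULL,
      ndf = row$ndf, adf = row$adf, adl = row$adl,
      vfa = if (nrow(vfa)) stats::setNames(vfa$value, vfa$analyte) else NULL,
      density = row$density)
  }

  plants <- list()
  for (pl in unique(streams$plant)) {
    srows <- streams[streams$plant == pl, , drop = FALSE]
    sub_row <- srows[srows$role == "substrate", , drop = FALSE]
    if (nrow(sub_row) != 1)
      stop("plant '", pl, "': expected exactly one substrate stream")
    substrate <- build_stream(sub_row[1, ])
    orows <- ops[ops$plant == pl, , drop = FALSE]
    orows <- orows[order(orows$stage), , drop = FALSE]
    stages <- lapply(seq_len(nrow(orows)), function(k) {
      o <- orows[k, ]
      out_row <- srows[srows$role == o$name, , drop = FALSE]
      if (nrow(out_row) != 1)
        stop("plant '", pl, "': no stream for stage '", o$name, "'")
      stage_record(name = o$name, temperature = o$temperature, hrt = o$hrt,
                   olr = o$olr, out = build_stream(out_row[1, ]),
                   specific_gas = o$specific_gas,
                   ch4_fraction = o$ch4_fraction, vol_red = o$vol_red)
    })
    plants[[pl]] <- plant_record(pl, category = sub("[0-9]+$", "", pl),
                                 substrate = substrate, stages = stages)
  }
  plants
}

#' Feature matrix of a plant survey
#'
#' One row per plant: final-digestate concentrations and solids, free
#' ammonia, operating parameters and the mass-balance summaries, ready for
#' [scale_features()], [ward_cluster()] and [pca_survey()].
#'
#' @param plants list of [plant_record()].
#' @return Numeric matrix with plant names as row names.
#' @export
survey_features <- function(plants) {
  rows <- lapply(plants, function(p) {
    stn <- p$stages[[length(p$stages)]]
    fin <- stn$out
    st1 <- p$stages[[1]]
    mb <- suppressWarnings(chain_stages(p$substrate, p$stages))
    fib <- tryCatch(stream_fiber(fin), error = function(e) NULL)
    c(ts = fin$ts, vs_of_ts = fin$vs_of_ts, ph = fin$ph,
      nh4_n = fin$nh4_n, kjeldahl_n = fin$kjeldahl_n,
      nh3_n = if (!any(is.na(c(fin$nh4_n, fin$ph))))
        free_ammonia(fin$nh4_n, fin$ph, stn$temperature) else NA_real_,
      protein = fin$protein, crude_fat = fin$crude_fat,
      carbohydrates = if (is.null(fib)) NA_real_ else
        total_carbohydrates(fib),
      temperature = st1$temperature, hrt = st1$hrt, olr = st1$olr,
      vs_red_adj = mb$vs_red_adj,
      protein_deg = mb$deg_overall[["protein"]],
      fat_deg = mb$deg_overall[["crude_fat"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(plants, `[[`, "", "name")
  out
}

#' Write a survey mass-balance report
#'
#' Emits a tab-separated result table (one row per plant: adjusted VS
#' reduction, overall degradation efficiencies, Y_prot, residual protein,
#' nitrogen mineralization, free ammonia) and a human-readable text
#' summary. Both outputs are deterministic.
#'
#' @param balances named list of [chain_stages()] results.
#' @param plants the corresponding named list of [plant_record()].
#' @param path output stem; writes `<path>.tsv` and `<path>.txt`.
#' @return Invisibly, the result data frame.
#' @export
write_report <- function(balances, plants, path) {
  stopifnot(identical(names(balances), names(plants)))
  rows <- lapply(names(balances), function(nm) {
    b <- balances[[nm]]; p <- plants[[nm]]
    st1 <- p$stages[[1]]
    stn <- p$stages[[length(p$stages)]]
    nh3_d <- if (!any(is.na(c(st1$out$nh4_n, st1$out$ph))))
      free_ammonia(st1$out$nh4_n, st1$out$ph, st1$temperature)
    else NA_real_
    nh3 <- if (!any(is.na(c(stn$out$nh4_n, stn$out$ph))))
      free_ammonia(stn$out$nh4_n, stn$out$ph, stn$temperature)
    else NA_real_
    data.frame(plant = nm,
               vs_red_pct = round(100 * b$vs_red_adj, 1),
               protein_deg_pct = round(100 * b$deg_overall[["protein"]], 1),
               carb_deg_pct = round(100 * b$deg_overall[["carbohydrates"]], 1),
               fat_deg_pct = round(100 * b$deg_overall[["crude_fat"]], 1),
               y_prot_g_kg = round(b$y_prot, 2),
               protein_resid_g_kg = round(b$protein_resid, 2),
               n_mineralization_pct = round(100 * b$n_mineralization, 1),
               nh3_n_digester_g_kg = round(nh3_d, 2),
               nh3_n_final_g_kg = round(nh3, 2))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  con <- file(paste0(path, ".txt"), "w")
  on.exit(close(con))
  writeLines("Digestate mass-balance survey report", con)
  writeLines(strrep("-", 40), con)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    writeLines(sprintf(
      "%s: VS red (adj) %s%%; overall degradation protein %s%%, carbohydrates %s%%, fat %s%%; Y_prot %s g/kg; residual protein %s g/kg; NH3-N %s g/kg (digester), %s g/kg (final)",
      r$plant, r$vs_red_pct, r$protein_deg_pct, r$carb_deg_pct,
      r$fat_deg_pct, r$y_prot_g_kg, r$protein_resid_g_kg,
      r$nh3_n_digester_g_kg, r$nh3_n_final_g_kg),
      con)
  }
  invisible(df)
}

#' Bundled survey transcription fixtures
#'
#' Small plain-text transcriptions of the nine-plant survey's printed
#' process tables and worked compositions, shipped with the package:
#' `"table1_streams"` (digester/post-digester TS, VS, VS reduction, pH,
#' nitrogen and VFA), `"table2_operations"` (substrate mixtures, OLR, HRT,
#' temperature) and `"compositions"` (the worked macromolecule
#' compositions, percent of VS, for the three mass-balance plants).
#'
#' @param name fixture name.
#' @return A data.frame.
#' @export
survey_fixture <- function(name = c("table1_streams", "table2_operations",
                                    "compositions")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(name, ".csv"), package = "digestate",
                   mustWork = TRUE)
  utils::read.csv(f, check.names = FALSE)
}
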