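#!/usr/bin/env Rscript
# Worked mass balance of the FW1 food-waste plant.
#
# Rebuilds the plant from the bundled printed values (substrate VS
# 120 g/kg ww, protein 27 g/kg; digester 17 g/kg; post-digestate 7 g/kg
# substrate-derived protein) and runs the chained balance: per-stage and
# overall protein degradation, VS reduction, the biomass-protein
# correction Y_prot and the total residual protein.

library(digestate)

comp <- survey_fixture("compositions")
t1 <- survey_fixture("table1_streams")
fw1 <- comp[comp$plant == "FW1", ]

mk <- function(p, ts = NA, vs = NA)
  stream_composition(ts = ts, vs_of_ts = vs, protein = p)

substrate <- mk(fw1$protein_g_per_kg[fw1$role == "substrate"])
stages <- list(
  stage_record("digester", 42, 35, 4.2,
               mk(fw1$protein_g_per_kg[fw1$role == "digester"]),
               vol_red = 0),
  stage_record("post-digester", 41, 20, 0,
               mk(fw1$protein_g_per_kg[fw1$role == "post-digester"]),
               vol_red = 0))
mb <- suppressWarnings(chain_stages(substrate, stages))

vs <- fw1$vs_g_per_kg[fw1$role == "substrate"]
vs_red <- t1[t1$plant == "FW1" & t1$role == "post-digester",
             "vs_red_pct"] / 100
yp <- y_prot(degraded_vs_conc(vs / 1000, 1, vs_red))
resid <- fw1$protein_g_per_kg[fw1$role == "post-digester"]
total <- resid + yp

cat("FW1 protein balance (27 -> 17 -> 7 g/kg, no gas correction):\n")
cat(sprintf("  main digester reduction: %.0f%%\n",
            100 * mb$stages[[1]]$eff[["protein"]]))
cat(sprintf("  overall reduction (excl. biomass protein): %.0f%%\n",
            100 * mb$deg_overall[["protein"]]))
cat(sprintf("  degraded VS at %.0f%% VS reduction: %.1f g/kg\n",
            100 * vs_red, degraded_vs_conc(vs / 1000, 1, vs_red)))
cat(sprintf("  Y_prot: %.2f g/kg\n", yp))
cat(sprintf("  total residual protein incl. Y_prot: %.2f g/kg (~%d)\n",
            total, round(total)))
cat(sprintf("  overall reduction counting biomass as residual: %.0f%%\n",
            100 * (substrate$protein - total) / substrate$protein))

dir.create("results", showWarnings = FALSE)
df <- data.frame(
  quantity = c("main_digester_protein_deg_pct", "overall_protein_deg_pct",
               "degraded_vs_g_per_kg", "y_prot_g_per_kg",
               "residual_protein_total_g_per_kg"),
  value = c(round(100 * mb$stages[[1]]$eff[["protein"]], 1),
            round(100 * mb$deg_overall[["protein"]], 1),
            round(degraded_vs_conc(vs / 1000, 1, vs_red), 1),
            round(yp, 2), round(total, 2)))
write.table(df, "results/02_fw1_mass_balance.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote results/02_fw1_mass_balance.tsv\n")
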