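#!/usr/bin/env Rscript
# Parameter recovery on synthetic plants.
#
# Forward-simulates 50 plants across the four substrate categories with
# known true degradation fractions, then recovers the fractions with the
# mass-balance pipeline: exactly (to numerical precision) without
# measurement noise, and with quantified error at 5% analytical CV.

library(digestate)

analytes <- c("protein", "crude_fat", "hemicellulose", "cellulose",
              "free_sugars", "lignin_like")
cats <- rep(c("FW", "AW", "AWM", "WWTP"), length.out = 50)

recover <- function(noise_cv, seed = 2024) {
  sv <- generate_survey(n_plants = 50, categories = cats,
                        noise_cv = noise_cv, seed = seed)
  errs <- c()
  for (i in seq_along(sv$plants)) {
    p <- sv$plants[[i]]
    mb <- suppressWarnings(chain_stages(p$substrate, p$stages))
    truth <- sv$truth[[i]]$stage_truth
    overall <- vapply(analytes, function(nm)
      1 - prod(1 - vapply(truth, `[[`, 0, nm)), 0)
    rec <- c(mb$deg_overall[setdiff(analytes, "protein")],
             protein = mb$protein_deg_corrected)
    errs <- c(errs, abs(rec[names(overall)] - overall))
  }
  errs
}

e0 <- recover(0)
e5 <- recover(0.05)

cat("Noiseless recovery over 50 plants x", length(analytes), "analytes:\n")
cat("  max |recovered - true| =", format(max(e0), digits = 3),
    "(exact to numerical precision)\n")
cat("With 5% analytical CV:\n")
cat("  mean absolute error =", round(mean(e5), 4), "\n")
cat("  90th percentile error =", round(quantile(e5, 0.9), 4), "\n")

dir.create("results", showWarnings = FALSE)
write.table(data.frame(noise_cv = c(0, 0.05),
                       max_error = c(max(e0), max(e5)),
                       mae = c(mean(e0), mean(e5))),
            "results/04_recovery.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("wrote results/04_recovery.tsv\n")
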