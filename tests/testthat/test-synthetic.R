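test_that("substrate sampling is mean-exact at zero CV and seeded", {
  tpl <- plant_template("FW")
  s0 <- sample_substrate(tpl, seed = 1, cv = 0)
  expect_equal(s0$protein, 0.22 * 120)
  expect_equal(s0$crude_fat, 0.32 * 120)
  expect_equal(vs_g_per_kg(s0), 120 + 55 * 60.05 / 1000, tolerance = 1e-9)
  # determinism
  s1 <- sample_substrate(tpl, seed = 99, cv = 0.1)
  s2 <- sample_substrate(tpl, seed = 99, cv = 0.1)
  expect_identical(s1, s2)
})

test_that("sampled concentrations are unbiased around the template means", {
  tpl <- plant_template("WWTP")
  set.seed(123)
  draws <- replicate(1000, sample_substrate(tpl, cv = 0.1)$protein)
  mu <- 0.29 * 27
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("a zero-degradation stage is an identity with no gas", {
  tpl <- plant_template("FW")
  feed <- sample_substrate(tpl, seed = 2, cv = 0)
  zero <- setNames(rep(0, 8), c("protein", "crude_fat", "hemicellulose",
                                "cellulose", "free_sugars", "lignin_like",
                                "other", "vfa"))
  sim <- simulate_digestion(feed, zero)
  expect_equal(sim$vol_red, 0)
  expect_equal(unname(sim$gas), c(0, 0))
  expect_equal(sim$stage$out$protein, feed$protein)
  expect_equal(sim$stage$out$ts, feed$ts, tolerance = 1e-12)
})

test_that("pure fat degradation emits 1.01 NL CH4 per g", {
  feed <- stream_composition(ts = 0.02, vs_of_ts = 0.5, ph = 7,
                             kjeldahl_n = 0.1, nh4_n = 0.1,
                             protein = 0, crude_fat = 10,
                             sugar_monomers = c(glucose = 0),
                             ndf = 0, adf = 0, adl = 0)
  tr <- setNames(c(0, 1, 0, 0, 0, 0, 0, 0),
                 c("protein", "crude_fat", "hemicellulose", "cellulose",
                   "free_sugars", "lignin_like", "other", "vfa"))
  sim <- simulate_digestion(feed, tr)
  expect_equal(sim$gas[["ch4"]], 10.1)
})

test_that("per-analyte mass closes exactly through every simulated stage", {
  for (cat in c("FW", "AW", "AWM", "WWTP")) {
    tpl <- plant_template(cat)
    feed <- sample_substrate(tpl, seed = 5, cv = 0.05)
    for (sp in tpl$stages) {
      sim <- simulate_digestion(feed, sp$truth)
      keep <- 1 - sim$vol_red
      p_in <- digestate:::.sim_pools(feed)
      p_out <- digestate:::.sim_pools(sim$stage$out)
      gap <- p_in$pools -
        (p_out$pools * keep + sim$degraded[names(p_in$pools)])
      expect_lt(max(abs(gap)), 1e-12)
      gap_other <- p_in$other - (p_out$other * keep + sim$degraded[["other"]])
      expect_lt(abs(gap_other), 1e-12)
      feed <- sim$stage$out
    }
  }
})

test_that("noiseless parameter recovery is exact for a simulated chain", {
  tpl <- plant_template("FW")
  sub <- sample_substrate(tpl, seed = 3, cv = 0)
  feed <- sub
  stages <- list()
  for (k in seq_along(tpl$stages)) {
    sp <- tpl$stages[[k]]
    sim <- simulate_digestion(feed, sp$truth, name = sp$name,
                              temperature = sp$temperature, hrt = sp$hrt,
                              olr = sp$olr)
    stages[[k]] <- sim$stage
    feed <- sim$stage$out
  }
  mb <- suppressWarnings(chain_stages(sub, stages))
  plain <- c("crude_fat", "hemicellulose", "cellulose", "free_sugars",
             "lignin_like")
  for (k in 1:2) {
    tr <- tpl$stages[[k]]$truth
    for (nm in plain)
      expect_lt(abs(mb$stages[[k]]$eff[[nm]] - tr[[nm]]), 1e-9)
    expect_lt(abs(mb$stages[[k]]$protein_eff_corrected - tr[["protein"]]),
              1e-9)
  }
  # overall efficiencies compose multiplicatively
  for (nm in plain) {
    want <- 1 - prod(1 - vapply(tpl$stages, function(s) s$truth[[nm]], 0))
    expect_lt(abs(mb$deg_overall[[nm]] - want), 1e-9)
  }
  want_p <- 1 - prod(1 - vapply(tpl$stages, function(s) s$truth[["protein"]],
                                0))
  expect_lt(abs(mb$protein_deg_corrected - want_p), 1e-9)
})

test_that("TMP reduction of a noiseless plant equals the TMP-weighted efficiency mix", {
  tpl <- plant_template("FW")
  sub <- sample_substrate(tpl, seed = 4, cv = 0)
  sim <- simulate_digestion(sub, tpl$stages[[1]]$truth)
  out <- sim$stage$out
  t_sub <- stream_tmp(sub)
  t_out <- stream_tmp(out)
  red <- tmp_red(t_sub$tmp_total,
                 adjust_outflow(t_out$tmp_total, sim$vol_red))
  # independent weighting: substrate TMP shares times net removed fractions
  p_in <- digestate:::.sim_pools(sub)
  keep <- 1 - sim$vol_red
  p_out <- digestate:::.sim_pools(out)
  cfg <- ad_config()
  coef <- c(protein = 0.50, crude_fat = 1.01, hemicellulose = 0.42,
            cellulose = 0.42, free_sugars = 0.42)
  tmp_in <- sum(coef * p_in$pools[names(coef)]) + vfa_tmp(sub$vfa)
  tmp_rem <- sum(coef * p_out$pools[names(coef)]) * keep +
    vfa_tmp(out$vfa) * keep
  expect_equal(red, (tmp_in - tmp_rem) / tmp_in, tolerance = 1e-9)
})

test_that("measurement noise is calibrated and reproducible", {
  tpl <- plant_template("FW")
  s <- sample_substrate(tpl, seed = 6, cv = 0)
  expect_identical(add_noise(s, 0), s)
  n1 <- add_noise(s, 0.05, seed = 10)
  n2 <- add_noise(s, 0.05, seed = 10)
  expect_identical(n1, n2)
  set.seed(20)
  reps <- replicate(1000, add_noise(s, 0.05)$protein)
  rel_sd <- sd(reps) / mean(reps)
  expect_gt(rel_sd, 0.04)
  expect_lt(rel_sd, 0.06)
})

test_that("survey generation is seeded, structured and separable by category", {
  sv1 <- generate_survey(seed = 42)
  sv2 <- generate_survey(seed = 42)
  expect_identical(sv1$tables, sv2$tables)
  expect_length(sv1$plants, 9)
  expect_equal(sum(vapply(sv1$plants, function(p) length(p$stages), 0L) >= 1),
               9)
  # category separation: Ward on noiseless features recovers the categories
  feats <- suppressWarnings(survey_features(sv1$plants))
  feats <- drop_incomplete(feats)
  cl <- stats::cutree(ward_cluster(scale_features(feats)),
                      k = length(unique(vapply(sv1$plants, `[[`, "",
                                               "category"))))
  cats <- vapply(sv1$plants, `[[`, "", "category")
  expect_equal(length(unique(paste(cl, cats))), length(unique(cats)))
})
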