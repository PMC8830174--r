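test_that("macromolecule TMP applies the lumped Buswell coefficients", {
  expect_equal(macromolecule_tmp(0, 0, 0), 0)
  expect_equal(macromolecule_tmp(1, 0, 0), 0.42)
  expect_equal(macromolecule_tmp(0, 1, 0), 1.01)
  expect_equal(macromolecule_tmp(0, 0, 1), 0.50)
  # FW1 substrate macromolecules from the printed percent-of-VS figures
  expect_equal(macromolecule_tmp(46.8, 38.4, 26.4), 71.64)
})

test_that("VFA methane equivalents match the element-balance oracle", {
  acids <- supported_vfa()
  for (acid in acids) {
    f <- digestate:::.vfa_formula[[acid]]
    expect_equal(vfa_ch4_equivalent(acid),
                 buswell_oracle(f[["C"]], f[["H"]], f[["O"]]),
                 info = acid)
  }
  expect_equal(vfa_ch4_equivalent("acetate"), 1.0)
  expect_equal(vfa_ch4_equivalent("propionate"), 1.75)
  expect_equal(vfa_ch4_equivalent("isocaproic"), 4.0)
  expect_error(vfa_ch4_equivalent("citric"), "supported")
})

test_that("VFA TMP converts molar equivalents to normal litres", {
  expect_equal(vfa_tmp(NULL), 0)
  expect_equal(vfa_tmp(c(acetic = 55)), 0.055 * 1.0 * 22.414)
  expect_equal(vfa_tmp(c(propionic = 100)), 0.1 * 1.75 * 22.414)
  # mg/L profile converts through molar masses first
  mm <- vfa_mg_to_mmol(c(acetic = 60.05, propionic = 740.8))
  expect_equal(unname(mm), c(1, 10))
})

test_that("stream TMP reproduces the food-waste substrate figure", {
  tmp <- stream_tmp(fw1_substrate())
  expect_equal(tmp$tmp_macro, 71.64, tolerance = 1e-6)
  expect_equal(tmp$tmp_total, tmp$tmp_macro + tmp$tmp_vfa)
  expect_equal(round(tmp$tmp_total), 73)
  # per-VS basis
  expect_equal(tmp$tmp_vs_basis, tmp$tmp_total / 0.120, tolerance = 1e-9)
  zero <- stream_composition(ts = 0.1, vs_of_ts = 0.5, protein = 0,
                             crude_fat = 0, sugar_monomers = c(glucose = 0),
                             ndf = 0, adf = 0, adl = 0)
  expect_equal(stream_tmp(zero)$tmp_total, 0)
  expect_error(stream_tmp(stream_composition(crude_fat = 1)), "protein")
})

test_that("stream TMP is additive under mixing", {
  s1 <- fw1_substrate()
  s2 <- fw1_substrate()
  s2$protein <- 10; s2$crude_fat <- 5
  mixed <- mix_streams(list(substrate_component("a", 0.3, s1),
                            substrate_component("b", 0.7, s2)))
  t_mix <- stream_tmp(mixed)$tmp_total
  t_parts <- 0.3 * stream_tmp(s1)$tmp_total + 0.7 * stream_tmp(s2)$tmp_total
  expect_equal(t_mix, t_parts, tolerance = 1e-9)
})

test_that("TMP reduction behaves at its limits and matches FW1", {
  expect_equal(tmp_red(73, 73), 0)
  expect_equal(tmp_red(73, 0), 1)
  expect_equal(round(tmp_red(73, 8.3), 3), 0.886)
  expect_error(tmp_red(0, 1), "> 0")
})

test_that("gas volumes normalize to 273.2 K and 1.01325 bar", {
  expect_equal(normalize_gas_volume(100, 273.2, 1.01325), 100)
  expect_equal(normalize_gas_volume(100, 298.15, 1.01325),
               100 * 273.2 / 298.15)
  expect_equal(normalize_gas_volume(100, 273.2, 2.0265), 200)
})

test_that("specific RMP is reported per kg VS and per kg wet weight", {
  m <- rmp_measurement(1.82, vs_added = 200 * 0.116 * 0.666 * 1000 / 1000,
                       wet_mass_added = 0.2)
  # 200 g digestate at 11.6% TS, 66.6% VS -> 15.45 g VS
  r <- rmp_specific(m)
  expect_equal(round(r[["per_kg_vs"]], 1), 117.8)
  expect_equal(r[["per_kg_ww"]], 9.1)
  expect_equal(rmp_specific(rmp_measurement(1e-12, 10, 0.2))[["per_kg_ww"]],
               5e-12)
  # scale invariance: doubling sample and gas leaves specific RMP unchanged
  r2 <- rmp_specific(rmp_measurement(2 * 1.82, 2 * 15.4512, 0.4))
  expect_equal(r2, r)
})

test_that("RMP as a fraction of TMP matches the survey range logic", {
  expect_equal(rmp_fraction_of_tmp(9.1, 22.75), 0.4)
  expect_equal(rmp_fraction_of_tmp(0, 5), 0)
  expect_equal(rmp_fraction_of_tmp(5, 5), 1)
  expect_warning(over <- rmp_fraction_of_tmp(6, 5), "exceeds")
  expect_equal(over, 1.2)
  expect_error(rmp_fraction_of_tmp(1, 0), "> 0")
})

test_that("free ammonia reproduces the survey's digester values", {
  expect_equal(round(free_ammonia(3.4, 7.8, 42), 2), 0.34)  # FW1
  expect_equal(round(free_ammonia(2.4, 7.5, 38), 2), 0.10)  # FW3
  expect_equal(round(free_ammonia(2.4, 7.6, 38), 2), 0.12)  # AW1
  expect_equal(round(free_ammonia(0.8, 7.2, 37), 2), 0.02)  # WWTP2-A
  # speciation limits
  expect_lt(free_ammonia(3, 2.5, 38), 1e-5)
  expect_equal(free_ammonia(3, 12, 38), 3, tolerance = 1e-3)
  expect_error(free_ammonia(1, 13, 38), "ph")
  expect_error(free_ammonia(1, 7, 90), "temperature")
})

test_that("free ammonia is strictly increasing in pH and temperature", {
  ph_grid <- seq(6, 9, by = 0.25)
  t_grid <- seq(20, 60, by = 5)
  along_ph <- free_ammonia(3.4, ph_grid, 42)
  expect_true(all(diff(along_ph) > 0))
  along_t <- free_ammonia(3.4, 7.8, t_grid)
  expect_true(all(diff(along_t) > 0))
  grid <- expand.grid(ph = ph_grid, t = t_grid)
  vals <- free_ammonia(3.4, grid$ph, grid$t)
  expect_true(all(vals > 0 & vals < 3.4))
})
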