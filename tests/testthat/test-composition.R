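test_that("raw protein follows the 6.25 Kjeldahl convention", {
  expect_equal(raw_protein(6.0, 1.2), 30.0)
  expect_equal(raw_protein(5.2, 3.4), 11.25)
  expect_equal(raw_protein(3.3, 3.3), 0)         # fully mineralized N
  # linearity on the valid domain
  expect_equal(raw_protein(2 * 5.2, 2 * 3.4), 2 * raw_protein(5.2, 3.4))
  expect_error(raw_protein(2, 3), "kjeldahl")
})

test_that("sequential fiber assay partitions into hemicellulose, cellulose, lignin", {
  f <- fiber_partition(36, 24, 9.6)
  expect_equal(f$hemicellulose, 12)
  expect_equal(f$cellulose, 14.4)
  expect_equal(f$lignin_like, 9.6)
  # partition sums back to NDF exactly
  expect_equal(f$hemicellulose + f$cellulose + f$lignin_like, 36)
  expect_equal(unlist(fiber_partition(10, 10, 10)[1:3], use.names = FALSE),
               c(0, 0, 10))
  expect_equal(unlist(fiber_partition(0, 0, 0)[1:3], use.names = FALSE),
               c(0, 0, 0))
  # small ordering violations are clamped, large ones rejected
  expect_warning(fc <- fiber_partition(20, 20.5, 10), "clamped")
  expect_equal(fc$hemicellulose, 0)
  expect_error(suppressWarnings(fiber_partition(20, 30, 10)), "exceeds")
})

test_that("free sugars subtract structural carbohydrates with a clamp at zero", {
  expect_equal(free_sugars(45.6, 12, 14.4), 19.2)
  expect_equal(free_sugars(10, 6, 4), 0)
  expect_warning(z <- free_sugars(5, 6, 4), "clamped")
  expect_equal(z, 0)
})

test_that("carbohydrates sum sugars and structural fibers, excluding lignin", {
  f <- fiber_fractions(12, 14.4, 9.6, free_sugars = 19.2)
  expect_equal(total_carbohydrates(f), 45.6)
  expect_equal(total_carbohydrates(fiber_fractions(0, 0, 0, 0)), 0)
  expect_equal(total_carbohydrates(fiber_fractions(0, 5, 99, 0)), 5)
  expect_error(total_carbohydrates(fiber_fractions(1, 1, 1)), "free_sugars")
})

test_that("stream mixing is mass-conserving and density-weighted", {
  s1 <- stream_composition(ts = 0.10, vs_of_ts = 0.9, protein = 10, ph = 7)
  s2 <- stream_composition(ts = 0.20, vs_of_ts = 0.8, protein = 20, ph = 7)
  # identical halves reproduce the stream
  m <- mix_streams(list(substrate_component("a", 0.5, s1),
                        substrate_component("b", 0.5, s1)))
  expect_equal(m$protein, s1$protein)
  expect_equal(m$ts, s1$ts)
  # volume-fraction weighting at density 1
  m2 <- mix_streams(list(substrate_component("a", 0.6, s1),
                         substrate_component("b", 0.4, s2)))
  expect_equal(m2$protein, 14)
  # density weighting
  s2d <- stream_composition(protein = 20, density = 2)
  s1d <- stream_composition(protein = 10, density = 1)
  m3 <- mix_streams(list(substrate_component("a", 0.5, s1d),
                         substrate_component("b", 0.5, s2d)))
  expect_equal(m3$protein, (0.5 * 1 * 10 + 0.5 * 2 * 20) / (0.5 * 1 + 0.5 * 2))
  # total analyte mass is conserved: mixture conc * total weight = sum masses
  w <- c(0.6 * 1, 0.4 * 1)
  expect_equal(m2$protein * sum(w), 0.6 * 10 + 0.4 * 20)
  expect_error(mix_streams(list(substrate_component("a", 0.6, s1),
                                substrate_component("b", 0.2, s2))),
               "sum to")
})

test_that("basis conversions are exact and round-trip to identity", {
  expect_equal(convert_basis(22, "pct_vs", "g_per_kg", ts = 0.12,
                             vs_of_ts = 1), 26.4)
  expect_equal(convert_basis(1360, "mg_per_l", "g_per_kg"), 1.36)
  x <- 17.3
  rt <- convert_basis(convert_basis(x, "g_per_kg", "pct_ts", ts = 0.053),
                      "pct_ts", "g_per_kg", ts = 0.053)
  expect_equal(rt, x, tolerance = 1e-12)
  for (b in c("pct_vs", "mg_per_l")) {
    rt <- convert_basis(convert_basis(x, "g_per_kg", b, ts = 0.1,
                                      vs_of_ts = 0.8, density = 1.05),
                        b, "g_per_kg", ts = 0.1, vs_of_ts = 0.8,
                        density = 1.05)
    expect_equal(rt, x, tolerance = 1e-12)
  }
  expect_error(convert_basis(1, "g_per_kg", "pct_ts", ts = 0), "nonzero")
})

test_that("stream invariants are enforced at construction", {
  expect_error(stream_composition(ts = 1.2), "\\[0, 1\\]")
  expect_error(stream_composition(kjeldahl_n = 1, nh4_n = 2), "exceeds")
  expect_error(stream_composition(protein = -1), "non-negative")
  s <- stream_composition(ts = 0.12, vs_of_ts = 0.9)
  expect_equal(vs_g_per_kg(s), 0.12 * 0.9 * 1000)
})
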