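# Worked-example streams built in code (no stored binary fixtures).

# Food-waste substrate: VS 120 g/kg ww with 22% protein, 32% crude fat and
# 39% carbohydrates of VS (10% hemicellulose, 12% cellulose, remainder free
# sugars; the printed subfractions round to 38), plus 55 mmol/L acetate.
fw1_substrate <- function(vs_of_ts = 0.88) {
  vs <- 120
  stream_composition(
    ts = vs / 1000 / vs_of_ts, vs_of_ts = vs_of_ts, ph = 4.8,
    kjeldahl_n = 0.22 * vs / 6.25 + 0.5, nh4_n = 0.5,
    protein = 0.22 * vs, crude_fat = 0.32 * vs,
    sugar_monomers = c(glucose = 0.39 * vs),
    ndf = (0.10 + 0.12 + 0.08) * vs,
    adf = (0.12 + 0.08) * vs,
    adl = 0.08 * vs,
    vfa = c(acetic = 55))
}

# Protein-only chain 27 -> 17 -> 7 g/kg with no gas-volume correction.
fw1_protein_chain <- function() {
  mk <- function(p, ts = NA, vs = NA, nh4 = NA, kj = NA, ph = NA)
    stream_composition(ts = ts, vs_of_ts = vs, ph = ph, protein = p,
                       nh4_n = nh4, kjeldahl_n = kj)
  list(substrate = mk(27),
       stages = list(
         stage_record("digester", 42, 35, 4.2, mk(17), vol_red = 0),
         stage_record("post-digester", 41, 20, 2.0, mk(7), vol_red = 0)))
}

# Brute-force Ward clustering oracle: O(n^3) scan minimizing the increase
# in total within-cluster sum of squares, same active-slot bookkeeping and
# lowest-index tie-break as the implementation, heights sqrt(2 * dSSE).
ward_oracle <- function(x) {
  n <- nrow(x)
  members <- lapply(seq_len(n), identity)
  id <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  sse_inc <- function(a, b) {
    ca <- colMeans(x[a, , drop = FALSE]); cb <- colMeans(x[b, , drop = FALSE])
    (length(a) * length(b)) / (length(a) + length(b)) * sum((ca - cb)^2)
  }
  for (step in seq_len(n - 1)) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(members)[-length(members)]) {
      for (j in seq((i + 1), length(members))) {
        d <- sse_inc(members[[i]], members[[j]])
        if (d < best_d - 1e-14) { best <- c(i, j); best_d <- d }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- sqrt(2 * best_d)
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
    id[i] <- step
    id <- id[-j]
  }
  list(merge = merge, height = height)
}

# Buswell element-balance oracle: solve CcHhOo + a H2O -> b CH4 + c CO2
# from the three element balances, independent of the closed form.
buswell_oracle <- function(C, H, O) {
  # unknowns (a, b, c):  C: b + c = C;  H: 2a - 4b = -H;  O: a - 2c = -O
  A <- rbind(c(0, 1, 1), c(2, -4, 0), c(1, 0, -2))
  sol <- solve(A, c(C, -H, -O))
  sol[2]  # mol CH4
}
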