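test_that("OXPHOS defect sigmoid matches direct evaluation", {
  expect_equal(oxphos_defect(0), 0)
  expect_equal(oxphos_defect(0.75), 0.5)           # s(K) = 1/2 by definition
  expect_equal(oxphos_defect(0.6), 0.07910434, tolerance = 1e-6)
  expect_equal(oxphos_defect(1), 0.9594764, tolerance = 1e-6)
  expect_equal(oxphos_defect(0.9), 0.8813772, tolerance = 1e-6)
  expect_error(oxphos_defect(1.2), "\\[0, 1\\]")
  expect_error(oxphos_defect(-0.1), "\\[0, 1\\]")
})

test_that("defect midpoint property s(K) = 0.5 holds across (K, m)", {
  for (K in c(0.3, 0.6, 0.75, 0.9, 1)) {
    for (m in c(1, 4, 11, 25)) {
      expect_equal(oxphos_defect(K, K, m), 0.5)
      # strict monotonicity on a grid
      r <- seq(0, 1, by = 0.05)
      expect_true(all(diff(oxphos_defect(r, K, m)) > 0))
    }
  }
})

test_that("mitophagy propensity interpolates between basal and maximal rates", {
  p <- qc_params()
  expect_equal(mitophagy_propensity(0, p), 0.023)          # baseline k_D
  expect_equal(mitophagy_propensity(0.75, p), 0.023 * 3.5) # midpoint: 0.0805
  # bound: k_D (r_D_max + 1); approached but not attained at R = 1,
  # where s(1) = 0.9595 gives 5.797 k_D
  expect_lt(mitophagy_propensity(1, p), 0.023 * 6)
  expect_equal(mitophagy_propensity(1, p), 0.023 * (5 * 0.9594764 + 1),
               tolerance = 1e-6)
  # monotone in R; increments below ~0.3 are smaller than double eps of k_D
  expect_true(all(diff(mitophagy_propensity(seq(0, 1, 0.01), p)) >= 0))
  expect_true(all(diff(mitophagy_propensity(seq(0.4, 1, 0.01), p)) > 0))
})

test_that("replication rate reduces to a_R0/N_ss at reference and scales with k_R", {
  p <- qc_params()
  expect_equal(replication_propensity_per_nucleoid(FALSE, 0, p), 7.4 / 320)
  # retrograde amplification bound: 10x basal as s -> 1
  expect_equal(replication_propensity_per_nucleoid(FALSE, 1, p),
               (7.4 / 320) * (9 * oxphos_defect(1) + 1))
  p2 <- qc_params(k_R = 2)
  expect_equal(replication_propensity_per_nucleoid(TRUE, 0, p2),
               2 * 7.4 / 320)
})

test_that("fusion selectivity and pair propensity follow the printed formulas", {
  p <- qc_params()
  expect_equal(fusion_selectivity(0, p), 1)
  expect_equal(fusion_selectivity(0.75, p), 1 - 0.8 * 0.5)   # 0.6
  p_full <- qc_params(r_fusion_max = 1)
  # full selectivity asymptotically excludes dysfunctional partners
  expect_lt(fusion_selectivity(1, p_full), 0.05)
  healthy <- mitochondrion(W = 4)
  expect_equal(fusion_pair_propensity(healthy, healthy, p), 0.123)
  sick <- mitochondrion(W = 0, M = 4)
  expect_equal(fusion_pair_propensity(healthy, sick, p),
               0.123 * (1 - 0.8 * oxphos_defect(1)))
  # tau = 30 days scaling: both propensities x 0.25
  p30 <- scale_for_tau(30)
  expect_equal(fusion_pair_propensity(healthy, healthy, p30), 0.123 * 0.25)
})

test_that("fission propensity is a Hill function with a 2-nucleoid floor", {
  p <- qc_params()
  expect_equal(fission_propensity(mitochondrion(W = 30), p), 8.6e4 / 2)
  expect_equal(fission_propensity(mitochondrion(W = 4), p), 0.4832017,
               tolerance = 1e-6)
  # totals below 2 cannot divide: clamped to zero (raw Hill ~1.2e-4/day)
  expect_equal(fission_propensity(mitochondrion(W = 1), p), 0)
  expect_error(fission_propensity(mitochondrion(W = 1, M = 0), p), NA)
})

test_that("ff_scale rescales fusion and fission together, preserving their ratio", {
  m1 <- mitochondrion(W = 5); m2 <- mitochondrion(W = 3, M = 2)
  for (s in c(0.0625, 0.25, 1, 4)) {
    p <- qc_params(ff_scale = s)
    p1 <- qc_params()
    expect_equal(fusion_pair_propensity(m1, m2, p),
                 s * fusion_pair_propensity(m1, m2, p1))
    expect_equal(fission_propensity(m2, p), s * fission_propensity(m2, p1))
    expect_equal(fusion_pair_propensity(m1, m2, p) / fission_propensity(m2, p),
                 fusion_pair_propensity(m1, m2, p1) / fission_propensity(m2, p1))
  }
})

test_that("parameter constructor validates ranges and rejects unknown fields", {
  expect_error(qc_params(r_fusion_max = 1.5), "r_fusion_max")
  expect_error(qc_params(k_R = 0.5), "k_R")
  expect_error(qc_params(ff_scale = 0), "ff_scale")
  expect_error(qc_params(K_D = 0), "K_D")
  expect_error(qc_params_update(qc_params(), bogus = 1), "unknown")
  p <- qc_params_update(qc_params(), k_R = 2, r_D_max = 199)
  expect_equal(p$k_R, 2)
  expect_equal(p$r_D_max, 199)
})

test_that("scale_for_tau maps mixing times to rate scales", {
  expect_equal(scale_for_tau(7.5)$ff_scale, 1)
  expect_equal(scale_for_tau(30)$ff_scale, 0.25)
  expect_equal(scale_for_tau(120)$ff_scale, 0.0625)
  expect_error(scale_for_tau(-1), "positive")
  # calibrated anchor of the shipped geometry
  expect_equal(scale_for_tau(7.5, tau_at_unit_scale = tau_at_ff1())$ff_scale,
               tau_at_ff1() / 7.5)
})

test_that("compiled channel propensities agree with the R kinetics functions", {
  p <- qc_params(k_R = 2, r_D_max = 3, r_fusion_max = 0.5, ff_scale = 0.7)
  s <- chain_state(list(c(3, 1), 4, 2, 1), list(c(0, 2), 1, 0, 3),
                   comps = c(1L, 1L, 2L, 9L))
  ch <- enumerate_channels(s, p)
  R <- mito_mutant_fractions(s)
  expect_equal(ch$r_mito, R)
  expect_equal(ch$mitophagy, mitophagy_propensity(R, p))
  expect_equal(ch$fission,
               vapply(s$mitochondria, fission_propensity, numeric(1), p))
  expect_equal(ch$fusion_selectivity, fusion_selectivity(R, p))
  # replication: cell-level total a_R0 (r_R s(Rbar) + 1) allocated k_R:1
  W <- sum(vapply(s$mitochondria, function(m) sum(m$W), numeric(1)))
  M <- sum(vapply(s$mitochondria, function(m) sum(m$M), numeric(1)))
  tot <- p$a_R0 * (p$r_R_max * oxphos_defect(mean(R), p$K_R, p$m) + 1)
  expect_equal(ch$replication_rate_wt, tot / (W + p$k_R * M))
  expect_equal(ch$replication_rate_mut, p$k_R * tot / (W + p$k_R * M))
  expect_equal(unname(ch$total["replication"]), tot)
  # fusion channels: only feasible pairs, propensity = scaled r_i r_j
  pairs <- ch$fusion_pairs
  # mitos 1,2 share compartment 1; mito 3 in compartment 2 is adjacent;
  # mito 4 in compartment 9 is isolated from the rest
  expect_setequal(paste(pairs$i, pairs$j), c("1 2", "1 3", "2 3"))
  expect_equal(pairs$propensity,
               p$ff_scale * p$a_fusion0 *
                 fusion_selectivity(R[pairs$i], p) *
                 fusion_selectivity(R[pairs$j], p))
})

test_that("disabling channels removes their propensities", {
  s <- two_mito_state()
  ch <- enumerate_channels(s, qc_params(), channels = c("fusion", "fission"))
  expect_equal(unname(ch$total["replication"]), 0)
  expect_equal(unname(ch$total["mitophagy"]), 0)
  expect_gt(unname(ch$total["fusion"]), 0)
  expect_error(enumerate_channels(s, qc_params(), channels = "teleport"),
               "unknown channels")
})
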