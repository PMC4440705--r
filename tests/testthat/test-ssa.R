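test_that("identical seeds give bit-identical trajectories", {
  p <- qc_params()
  run <- function() {
    set.seed(1234)
    s <- premix(p)
    s <- relabel_random_mutant(s, 1)
    run_cell(s, p, t_end = 40, record = seq(0, 40, 1))
  }
  a <- run(); b <- run()
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final_state, b$final_state)
  expect_identical(a$counts, b$counts)
})

test_that("zero total propensity leaves the state constant on the grid", {
  s <- two_mito_state()
  out <- run_cell(s, qc_params(), t_end = 5, record = 0:5,
                  channels = character(0))
  expect_equal(out$n_events, 0)
  expect_equal(out$trajectory$r_cell, rep(1 / 8, 6))
  expect_equal(out$trajectory$n_mito, rep(2, 6))
  expect_identical(lapply(out$final_state$mitochondria, `[[`, "W"),
                   lapply(s$mitochondria, `[[`, "W"))
})

test_that("fusion-fission-only runs conserve the nucleoid total exactly", {
  set.seed(31)
  s <- initial_premix_state()
  out <- run_cell(s, qc_params(), t_end = 50, record = seq(0, 50, 1),
                  channels = c("fusion", "fission"))
  expect_true(all(out$trajectory$n_nucleoid == 320))
  expect_equal(total_nucleoids(out$final_state), 320)
  expect_equal(unname(out$counts["replication"] + out$counts["mitophagy"]), 0)
})

test_that("frozen-state waiting times are exponential and channel shares match propensities", {
  set.seed(32)
  s <- premix()
  s <- relabel_block_mutant(s, 60)
  p <- qc_params(k_R = 1.5)
  ch <- enumerate_channels(s, p)
  A <- sum(ch$total)
  n <- 1500
  dts <- numeric(n)
  kinds <- matrix(0, nrow = n, ncol = 4)
  for (i in seq_len(n)) {
    out <- run_cell(s, p, t_end = 1e6, record = numeric(0), max_events = 1)
    dts[i] <- out$t_final
    kinds[i, ] <- out$counts
  }
  # exact-SSA contract: first waiting time ~ Exp(total propensity)
  ks <- stats::ks.test(dts, "pexp", rate = A)
  expect_gt(ks$p.value, 0.001)
  expect_equal(mean(dts), 1 / A, tolerance = 0.1)
  # first-event class frequencies match propensity shares within ~4 sigma
  shares <- ch$total / A
  freq <- colMeans(kinds)
  for (k in 1:4) {
    tol <- 4 * sqrt(shares[k] * (1 - shares[k]) / n) + 1e-9
    expect_lt(abs(freq[k] - shares[k]), tol)
  }
})

test_that("mitophagy events occur at ~ k_D per mitochondrion in a healthy cell", {
  set.seed(33)
  s <- premix()
  out <- run_cell(s, qc_params(), t_end = 150, record = seq(0, 150, 1))
  n_bar <- mean(out$trajectory$n_mito)
  rate <- unname(out$counts["mitophagy"]) / 150
  expect_equal(rate, 0.023 * n_bar, tolerance = 0.2)
  # replication balances removal: nucleoid count stays near 320
  expect_equal(mean(out$trajectory$n_nucleoid), 320, tolerance = 0.1)
})

test_that("mutant-fraction statistics on the grid stay within [0, 1]", {
  set.seed(34)
  s <- relabel_random_mutant(premix(), 30)
  out <- run_cell(s, qc_params(k_R = 2), t_end = 60, record = seq(0, 60, 1))
  tr <- out$trajectory
  expect_true(all(tr$r_cell >= 0 & tr$r_cell <= 1, na.rm = TRUE))
  expect_true(all(tr$rbar_mito >= 0 & tr$rbar_mito <= 1, na.rm = TRUE))
  expect_true(all(is.na(tr$cov_rmito) | tr$cov_rmito >= 0))
})

test_that("homoplasmy absorption freezes the mutant fraction exactly", {
  set.seed(35)
  s <- relabel_random_mutant(premix(), 1)
  out <- run_cell(s, qc_params(), t_end = 300, record = seq(0, 300, 1),
                  stop_at_homoplasmy = TRUE)
  r <- out$trajectory$r_cell
  if (out$absorbed_homoplasmic) {
    expect_true(r[301] %in% c(0, 1))
    # once absorbed the recorded fraction never changes again
    k <- which(r %in% c(0, 1))[1]
    expect_true(all(r[k:301] == r[k]))
  }
})

test_that("event budget exhaustion is flagged and truncates gracefully", {
  set.seed(36)
  s <- initial_premix_state()
  expect_no_warning(
    run_cell(s, qc_params(), t_end = 50, record = seq(0, 50, 1),
             channels = c("fusion", "fission")))
  set.seed(36)
  out3 <- run_cell(s, qc_params(), t_end = 50, record = numeric(0),
                   channels = c("fusion", "fission"), max_events = 100)
  expect_true(out3$hit_max_events)
  expect_equal(out3$n_events, 100)
  expect_lt(out3$t_final, 50)
})
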