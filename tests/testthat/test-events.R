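test_that("mitophagy removes the whole target mitochondrion", {
  s <- chain_state(list(3, 4, c(2, 1)), list(1, 0, c(0, 2)))
  s2 <- execute_mitophagy(s, 1)
  expect_length(s2$mitochondria, 2)
  expect_equal(total_nucleoids(s2), total_nucleoids(s) - 4)
  # removing the only mutant-bearing mitochondria drives R_M^cell to 0
  s3 <- execute_mitophagy(execute_mitophagy(s, 3), 1)
  expect_equal(cell_mutant_fraction(s3), 0)
  # removing the last mitochondrion leaves a terminated-empty cell
  s4 <- chain_state(list(2), list(0))
  s5 <- execute_mitophagy(s4, 1)
  expect_length(s5$mitochondria, 0)
  expect_error(execute_mitophagy(s, 9), "out of range")
})

test_that("replication increments one nucleoid count in place", {
  s <- two_mito_state()
  s2 <- execute_replication(s, 1, subcompartment = 1, mutant = FALSE)
  expect_equal(s2$mitochondria[[1]]$W, 4L)
  expect_equal(s2$mitochondria[[1]]$M, 1L)
  s3 <- execute_replication(s, 1, subcompartment = 1, mutant = TRUE)
  expect_equal(s3$mitochondria[[1]]$M, 2L)
  expect_equal(s3$mitochondria[[1]]$W, 3L)
  expect_equal(total_nucleoids(s3), total_nucleoids(s) + 1)
})

test_that("fusion appends the donor chain and conserves nucleoids", {
  set.seed(4)
  s <- chain_state(list(2, c(3, 1)), list(0, c(1, 0)), comps = c(1L, 2L))
  s2 <- execute_fusion(s, 1, 2)
  expect_length(s2$mitochondria, 1)
  m <- s2$mitochondria[[1]]
  expect_length(m$W, 3)                       # 1 + 2 subcompartments
  expect_equal(sum(m$W) + sum(m$M), total_nucleoids(s))
  # chain is one of the two donor/acceptor orders, internal sites preserved
  ok <- identical(m$W, c(2L, 3L, 1L)) || identical(m$W, c(3L, 1L, 2L))
  expect_true(ok)
  # merged organelle resides in the acceptor compartment
  expect_true(m$compartment %in% c(1L, 2L))
  expect_error(execute_fusion(s, 1, 1), "itself")
})

test_that("two single-compartment mitochondria fuse into a two-subcompartment chain", {
  set.seed(5)
  s <- chain_state(list(3, 2), list(1, 0), comps = c(4L, 4L))
  s2 <- execute_fusion(s, 1, 2)
  expect_length(s2$mitochondria[[1]]$W, 2)    # one new fission site
  expect_equal(total_nucleoids(s2), 6)
})

test_that("fission conserves nucleoids and never creates an empty daughter", {
  set.seed(6)
  for (rep in 1:300) {
    L <- sample(1:4, 1)
    W <- sample(0:4, L, replace = TRUE)
    M <- sample(0:3, L, replace = TRUE)
    if (sum(W) + sum(M) < 2) next
    s <- chain_state(list(W), list(M), comps = sample(1:16, 1))
    s2 <- execute_fission(s, 1)
    expect_length(s2$mitochondria, 2)
    tots <- vapply(s2$mitochondria, function(m) sum(m$W) + sum(m$M), numeric(1))
    expect_true(all(tots >= 1))
    expect_equal(sum(tots), sum(W) + sum(M))
    expect_equal(total_mutants(s2), sum(M))
  }
  expect_error(execute_fission(chain_state(list(1), list(0)), 1), "fewer than 2")
})

test_that("fission cuts chains at a site: flanking subcompartments are untouched", {
  set.seed(7)
  # chain of 4 subcompartments: only the two pools at the chosen site change
  for (rep in 1:50) {
    s <- chain_state(list(c(3, 2, 4, 1)), list(c(0, 1, 0, 2)))
    s2 <- execute_fission(s, 1)
    lens <- vapply(s2$mitochondria, function(m) length(m$W), numeric(1))
    expect_equal(sum(lens), 4)        # subcompartment chains partition the parent
    expect_true(all(lens >= 1))
    # at most the two pools flanking the cut differ from the parent chain
    parent_pairs <- c("3.0", "2.1", "4.0", "1.2")
    daughter_pairs <- unlist(lapply(s2$mitochondria, function(m)
      paste(m$W, m$M, sep = ".")))
    changed <- length(parent_pairs) -
      sum(!is.na(match(parent_pairs, daughter_pairs)))
    expect_lte(changed, 2)
    expect_equal(sum(vapply(s2$mitochondria, function(m) sum(m$W), numeric(1))), 10)
    expect_equal(total_mutants(s2), 3)
  }
})

test_that("single-subcompartment fission: uniform split with hypergeometric identities", {
  set.seed(8)
  n <- 20000
  Wp <- 4L; Mp <- 3L; Tt <- Wp + Mp
  sizes <- integer(n); muts <- integer(n)
  s <- chain_state(list(Wp), list(Mp))
  for (i in seq_len(n)) {
    s2 <- execute_fission(s, 1)
    m1 <- s2$mitochondria[[1]]
    sizes[i] <- sum(m1$W) + sum(m1$M)
    muts[i] <- sum(m1$M)
  }
  # kept-daughter size uniform on 1..T-1 (the cut is uniform; sides symmetric)
  for (k in 1:(Tt - 1)) {
    pk <- mean(sizes == k)
    expect_lt(abs(pk - 1 / (Tt - 1)), 4 * sqrt((1 / 6) * (5 / 6) / n) + 0.01)
  }
  # identity assignment is hypergeometric given the size
  for (k in 1:(Tt - 1)) {
    idx <- sizes == k
    for (j in max(0, k - Wp):min(Mp, k)) {
      emp <- mean(muts[idx] == j)
      thr <- stats::dhyper(j, Mp, Wp, k)
      expect_lt(abs(emp - thr), 4 * sqrt(thr * (1 - thr) / sum(idx)) + 0.01)
    }
  }
  # mean mutants per daughter = Mp/2 by symmetry
  expect_equal(mean(muts), Mp / 2, tolerance = 0.05)
})

test_that("chain fission exchange is identity-blind (hypergeometric across the cut)", {
  set.seed(9)
  # chain of 2 -> single site; pools W=3, M=3 redistributed Binomial(1/2),
  # so conditional on the left total the mutant count is hypergeometric
  n <- 20000
  s <- chain_state(list(c(3, 0)), list(c(0, 3)))
  sizes <- integer(n); muts <- integer(n)
  for (i in seq_len(n)) {
    s2 <- execute_fission(s, 1)
    m1 <- s2$mitochondria[[1]]
    sizes[i] <- sum(m1$W) + sum(m1$M)
    muts[i] <- sum(m1$M)
  }
  for (k in 1:5) {
    idx <- sizes == k
    if (sum(idx) < 200) next
    for (j in max(0, k - 3):min(3, k)) {
      emp <- mean(muts[idx] == j)
      thr <- stats::dhyper(j, 3, 3, k)
      expect_lt(abs(emp - thr), 4 * sqrt(thr * (1 - thr) / sum(idx)) + 0.015)
    }
  }
})

test_that("fusion then fission at the junction redistributes the junction pools", {
  set.seed(10)
  for (rep in 1:100) {
    s <- chain_state(list(4, 2), list(0, 3), comps = c(2L, 2L))
    fused <- execute_fusion(s, 1, 2)
    expect_length(fused$mitochondria[[1]]$W, 2)
    split <- execute_fission(fused, 1)
    tots <- vapply(split$mitochondria, function(m) sum(m$W) + sum(m$M),
                   numeric(1))
    expect_equal(sum(tots), 9)
    expect_equal(total_mutants(split), 3)
    expect_true(all(tots >= 1))
  }
})

test_that("the displaced fission daughter lands in the original compartment or a neighbor", {
  set.seed(11)
  g <- build_default_geometry(16)
  allowed <- sort(c(5L, g$adjacency[[5]]))
  n <- 4000
  dests <- integer(n)
  s <- chain_state(list(8), list(4), comps = 5L)
  for (i in seq_len(n)) {
    s2 <- execute_fission(s, 1)
    expect_equal(s2$mitochondria[[1]]$compartment, 5L)  # one daughter stays
    dests[i] <- s2$mitochondria[[2]]$compartment
  }
  expect_true(all(dests %in% allowed))
  # destination approximately uniform over {original} + 4 neighbors
  for (d in allowed) {
    expect_lt(abs(mean(dests == d) - 0.2), 4 * sqrt(0.2 * 0.8 / n) + 0.01)
  }
})

test_that("population and nucleoid deltas per event kind", {
  set.seed(12)
  s <- chain_state(list(3, c(2, 2), 5), list(1, c(0, 1), 0),
                   comps = c(1L, 1L, 2L))
  n0 <- length(s$mitochondria); t0 <- total_nucleoids(s)
  expect_equal(length(execute_replication(s, 2, 1, FALSE)$mitochondria), n0)
  expect_equal(total_nucleoids(execute_replication(s, 2, 1, FALSE)), t0 + 1)
  expect_equal(length(execute_mitophagy(s, 2)$mitochondria), n0 - 1)
  expect_equal(total_nucleoids(execute_mitophagy(s, 2)), t0 - 5)
  expect_equal(length(execute_fusion(s, 1, 2)$mitochondria), n0 - 1)
  expect_equal(total_nucleoids(execute_fusion(s, 1, 2)), t0)
  expect_equal(length(execute_fission(s, 3)$mitochondria), n0 + 1)
  expect_equal(total_nucleoids(execute_fission(s, 3)), t0)
})
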