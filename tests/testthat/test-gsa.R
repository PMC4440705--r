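test_that("Latin hypercube samples stratify every marginal", {
  set.seed(61)
  d <- gsa_design(64)
  x <- latin_hypercube(d)
  expect_equal(nrow(x), 64)
  expect_named(x, c("k_R", "tau", "k_D", "r_D_max", "r_fusion_max",
                    "r_R_max", "K"))
  u <- attr(x, "unit")
  for (k in seq_len(ncol(u))) {
    bins <- floor(u[, k] * 64)
    expect_setequal(bins, 0:63)     # one point per equal-probability bin
  }
  for (nm in names(d$ranges)) {
    r <- d$ranges[[nm]]
    expect_true(all(x[[nm]] >= r[1] & x[[nm]] <= r[2]))
  }
})

test_that("design rows map to valid parameter sets with co-varying thresholds", {
  set.seed(62)
  x <- latin_hypercube(gsa_design(16))
  for (i in seq_len(8)) {
    p <- gsa_row_params(x[i, ])
    expect_s3_class(p, "qc_params")
    expect_equal(p$K_D, x$K[i])
    expect_equal(p$K_fusion, x$K[i])    # thresholds perturbed equally
    expect_equal(p$K_R, x$K[i])
    expect_equal(p$ff_scale, tau_at_ff1() / x$tau[i])
  }
})

test_that("sobol estimator recovers the additive analytic case", {
  set.seed(63)
  d <- gsa_design(512, ranges = list(k_R = c(0, 1), tau = c(0, 1)))
  x <- latin_hypercube(d)
  y <- x$k_R + x$tau           # only two active factors, no interaction
  s <- sobol_indices(y, x)
  expect_equal(unname(s$S1["k_R", 1]), 0.5, tolerance = 0.05)
  expect_equal(unname(s$S1["tau", 1]), 0.5, tolerance = 0.05)
  expect_lt(max(abs(s$S2[, 1])), 0.03)
  expect_lt(max(abs(s$S1[c("k_D", "r_D_max", "r_fusion_max", "r_R_max", "K"),
                        1])), 0.03)
})

test_that("sobol estimator recovers the product analytic case", {
  # Y = U1 * U2 on Uniform(0,1)^2: S1 = S2 = 3/7, S12 = 1/7 (exact
  # variance decomposition: V = 7/144, V1 = V2 = 1/48, V12 = 1/144)
  set.seed(64)
  d <- gsa_design(1024, ranges = list(k_R = c(0, 1), tau = c(0, 1)))
  x <- latin_hypercube(d)
  y <- x$k_R * x$tau
  s <- sobol_indices(y, x, degree = 3, degree2 = 2)
  expect_equal(unname(s$S1["k_R", 1]), 3 / 7, tolerance = 0.05)
  expect_equal(unname(s$S1["tau", 1]), 3 / 7, tolerance = 0.05)
  expect_equal(unname(s$S2["k_R:tau", 1]), 1 / 7, tolerance = 0.05)
})

test_that("sobol estimator matches the Ishigami benchmark", {
  # f = sin x1 + 7 sin^2 x2 + 0.1 x3^4 sin x1 on [-pi, pi]^3:
  # closed-form indices S1 = 0.3139, S2 = 0.4424, S3 = 0, S13 = 0.2437
  set.seed(65)
  n <- 3000
  u <- lhs::randomLHS(n, 3)
  colnames(u) <- c("x1", "x2", "x3")
  xx <- 2 * pi * u - pi
  y <- sin(xx[, 1]) + 7 * sin(xx[, 2])^2 + 0.1 * xx[, 3]^4 * sin(xx[, 1])
  x <- as.data.frame(u)
  attr(x, "unit") <- u
  s <- sobol_indices(y, x, degree = 9, degree2 = 5)
  expect_equal(unname(s$S1["x1", 1]), 0.3139, tolerance = 0.15)
  expect_equal(unname(s$S1["x2", 1]), 0.4424, tolerance = 0.15)
  expect_lt(abs(s$S1["x3", 1]), 0.03)
  expect_equal(unname(s$S2["x1:x3", 1]), 0.2437, tolerance = 0.2)
  expect_lt(abs(s$S2["x1:x2", 1]), 0.05)
})

test_that("indices are invariant to affine rescaling of the output", {
  set.seed(66)
  d <- gsa_design(256)
  x <- latin_hypercube(d)
  y <- 2 * x$k_R + x$r_D_max * x$K
  s1 <- sobol_indices(y, x)
  s2 <- sobol_indices(100 - 40 * y, x)
  expect_equal(s1$S1, s2$S1, tolerance = 1e-8)
  expect_equal(s1$S2, s2$S2, tolerance = 1e-8)
})

test_that("degenerate (zero-variance) outputs are flagged as undefined", {
  set.seed(67)
  x <- latin_hypercube(gsa_design(32))
  Y <- cbind(rep(0.5, 32), x$k_R)
  s <- sobol_indices(Y, x)
  expect_true(all(is.na(s$S1[, 1])))
  expect_false(anyNA(s$S1[, 2]))
})

test_that("rank table pools first- and second-order terms", {
  set.seed(68)
  x <- latin_hypercube(gsa_design(512))
  y <- 3 * x$k_R + x$r_D_max + 0.1 * x$K
  s <- sobol_indices(y, x)
  # variance contributions scale with (coef x range width)^2:
  # r_D_max spans [1,5] -> 16/12 beats k_R's 9/12 on [1,2]
  expect_equal(s$ranks$term[1], "r_D_max")
  expect_equal(s$ranks$term[2], "k_R")
  expect_true(all(c(1L, 2L) %in% s$ranks$order))
  expect_equal(nrow(s$ranks), 7 + choose(7, 2))
})
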