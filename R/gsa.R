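#' Global sensitivity analysis design
#'
#' Parameter ranges for the variance-based global sensitivity analysis of
#' the quality-control model.  The seven perturbed factors are the
#' replicative advantage `k_R` (1-2), the mixing time `tau` (7.5-30 days,
#' applied by scaling fusion and fission propensities with equal ratios),
#' the mitophagy rate `k_D` (0.0069-0.023/day, half-lives 30-100 days), the
#' mitophagy selectivity strength `r_D_max` (1-5), the fusion selectivity
#' `r_fusion_max` (0-0.8), the retrograde strength `r_R_max` (5-10), and the
#' shared OXPHOS defect threshold `K` (0.6-0.9) applied equally to `K_D`,
#' `K_fusion` and `K_R` so that all selectivity functions keep the same
#' midpoint.
#'
#' @param n_samples Number of Latin hypercube points (2048 at full scale).
#' @param ranges Optional named list of `c(lo, hi)` ranges overriding the
#'   defaults.
#' @return An object of class `gsa_design`.
#' @export
gsa_design <- function(n_samples = 2048, ranges = NULL) {
  default <- list(k_R = c(1, 2), tau = c(7.5, 30), k_D = c(0.0069, 0.023),
                  r_D_max = c(1, 5), r_fusion_max = c(0, 0.8),
                  r_R_max = c(5, 10), K = c(0.6, 0.9))
  if (!is.null(ranges)) {
    bad <- setdiff(names(ranges), names(default))
    if (length(bad) > 0)
      stop("unknown GSA factors: ", paste(bad, collapse = ", "),
           call. = FALSE)
    default[names(ranges)] <- ranges
  }
  for (nm in names(default))
    if (length(default[[nm]]) != 2 || diff(default[[nm]]) <= 0)
      stop("range for '", nm, "' must be c(lo, hi) with lo < hi",
           call. = FALSE)
  d <- list(n_samples = as.integer(n_samples), ranges = default)
  class(d) <- "gsa_design"
  d
}

#' Latin hypercube sample of a GSA design
#'
#' Stratified space-filling sample: each factor's marginal is divided into
#' `n_samples` equal-probability bins with exactly one point per bin,
#' uniform within bins.  Uses the current RNG state (`set.seed()` for
#' reproducibility).
#'
#' @param design A [gsa_design()].
#' @return data.frame with one column per factor plus the attribute
#'   `"unit"`, the sample on the unit hypercube (used by the index
#'   estimator).
#' @export
latin_hypercube <- function(design = gsa_design()) {
  stopifnot(inherits(design, "gsa_design"))
  p <- length(design$ranges)
  u <- lhs::randomLHS(design$n_samples, p)
  colnames(u) <- names(design$ranges)
  x <- as.data.frame(u)
  for (nm in names(design$ranges)) {
    r <- design$ranges[[nm]]
    x[[nm]] <- r[1] + (r[2] - r[1]) * u[, nm]
  }
  attr(x, "unit") <- u
  x
}

#' Build model parameters from one design row
#'
#' Maps one GSA sample row to a full [qc_params()] set: the sampled mixing
#' time `tau` is realized through the shipped geometry calibration
#' (`ff_scale = tau_at_ff1() / tau`) and `K` is applied equally to all
#' three defect thresholds.
#'
#' @param row Named list or one-row data.frame of GSA factor values.
#' @param base Base parameter set for the unperturbed fields.
#' @return A `qc_params` object.
#' @export
gsa_row_params <- function(row, base = qc_params()) {
  row <- as.list(row)
  qc_params_update(base,
                   k_R = row$k_R, k_D = row$k_D, r_D_max = row$r_D_max,
                   r_fusion_max = row$r_fusion_max, r_R_max = row$r_R_max,
                   K_D = row$K, K_fusion = row$K, K_R = row$K,
                   ff_scale = tau_at_ff1() / row$tau)
}

#' Evaluate the model over a GSA design
#'
#' Runs a clonal-expansion ensemble (premix, one de novo mutant, full
#' model) for every design point and records the ensemble-average cell
#' mutant fraction at the analysis times.
#'
#' @param table Design sample from [latin_hypercube()].
#' @param n_cells_per_point Cells averaged per design point.
#' @param times Analysis times in days.
#' @param master_seed Master seed; each design point gets an independent
#'   seed block.
#' @param progress Print progress every `progress` rows (0 = silent).
#' @return Matrix `n_samples x length(times)` of mean `R_M^cell` values,
#'   with the analysis times as column names.
#' @export
evaluate_model_over_design <- function(table, n_cells_per_point = 100,
                                       times = c(50, 100, 150, 200, 250),
                                       master_seed = 1, progress = 0) {
  n <- nrow(table)
  out <- matrix(NA_real_, nrow = n, ncol = length(times),
                dimnames = list(NULL, paste0("day", times)))
  t_end <- max(times)
  for (i in seq_len(n)) {
    p <- gsa_row_params(table[i, , drop = FALSE])
    sp <- scenario_spec(sprintf("gsa_%04d", i), p,
                        n_cells = n_cells_per_point, t_end = t_end)
    res <- run_scenario(sp, master_seed = child_seed(master_seed, i * 100003),
                        record_dt = min(times))
    out[i, ] <- res$summary$mean_r_cell[match(times, res$summary$time)]
    if (progress > 0 && i %% progress == 0)
      message(sprintf("  design point %d/%d", i, n))
  }
  out
}

# Orthonormal shifted Legendre polynomials on [0, 1], degrees 1..deg.
# Columns are orthonormal wrt the uniform measure: E[phi_k] = 0,
# E[phi_k phi_l] = delta_kl.
shifted_legendre <- function(x, deg) {
  P <- matrix(0, nrow = length(x), ncol = deg)
  z <- 2 * x - 1  # map to [-1, 1]
  Pm1 <- rep(1, length(x))  # P_0
  P0 <- z                   # P_1
  for (k in seq_len(deg)) {
    P[, k] <- sqrt(2 * k + 1) * P0
    Pnext <- ((2 * k + 1) * z * P0 - k * Pm1) / (k + 1)
    Pm1 <- P0
    P0 <- Pnext
  }
  P
}

#' Variance-based sensitivity indices by RS-HDMR
#'
#' Estimates first-order indices `S_i = V[E(Y|p_i)] / V(Y)` and second-order
#' indices `S_ij = (V[E(Y|p_i,p_j)] - V_i - V_j) / V(Y)` from a Latin
#' hypercube sample by random-sampling high dimensional model
#' representation: component functions are expanded in orthonormal shifted
#' Legendre polynomials, fitted jointly by least squares, and the index
#' variances are recovered from the squared expansion coefficients.
#' Parameters and pairs are ranked together by index magnitude at each
#' analysis time; the average rank summarizes importance over time.
#'
#' @param Y Output matrix (`n_samples x n_times`) or vector; e.g. the
#'   result of [evaluate_model_over_design()].
#' @param table Design sample from [latin_hypercube()] (its `"unit"`
#'   attribute is used), or a plain matrix/data.frame of samples on known
#'   ranges which are rescaled to the unit hypercube.
#' @param degree Polynomial degree of the first-order component functions.
#' @param degree2 Per-variable degree of the pairwise product terms.
#' @return A list of class `sensitivity_result`: `S1` (factors x times),
#'   `S2` (pairs x times), `ranks` (combined rank table with average rank,
#'   sorted), `variance` (output variance per time), `times`.
#' @examples
#' set.seed(1)
#' d <- gsa_design(512, ranges = NULL)
#' x <- latin_hypercube(d)
#' y <- x$k_R + x$r_D_max          # additive toy response
#' s <- sobol_indices(y, x)
#' round(s$S1[, 1], 2)
#' @export
sobol_indices <- function(Y, table, degree = 3, degree2 = 1) {
  u <- attr(table, "unit")
  if (is.null(u)) {
    u <- as.matrix(table)
    for (k in seq_len(ncol(u))) {
      rng <- range(u[, k])
      if (diff(rng) <= 0) stop("degenerate design column", call. = FALSE)
      u[, k] <- (u[, k] - rng[1]) / diff(rng)
    }
  }
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(u)) stop("Y and design are not row-aligned",
                               call. = FALSE)
  p <- ncol(u)
  factors <- colnames(u)
  if (is.null(factors)) factors <- paste0("p", seq_len(p))
  n_times <- ncol(Y)
  times <- colnames(Y)
  if (is.null(times)) times <- paste0("y", seq_len(n_times))

  # design matrix: first-order blocks then pairwise product blocks
  phi <- lapply(seq_len(p), function(k) shifted_legendre(u[, k], max(degree, degree2)))
  blocks <- list()
  block_id <- character(0)
  for (k in seq_len(p)) {
    blocks[[length(blocks) + 1]] <- phi[[k]][, seq_len(degree), drop = FALSE]
    block_id <- c(block_id, factors[k])
  }
  pairs <- utils::combn(p, 2)
  for (c2 in seq_len(ncol(pairs))) {
    a <- pairs[1, c2]; b <- pairs[2, c2]
    cols <- list()
    for (ka in seq_len(degree2)) for (kb in seq_len(degree2))
      cols[[length(cols) + 1]] <- phi[[a]][, ka] * phi[[b]][, kb]
    blocks[[length(blocks) + 1]] <- do.call(cbind, cols)
    block_id <- c(block_id, paste0(factors[a], ":", factors[b]))
  }
  X <- do.call(cbind, blocks)
  sizes <- vapply(blocks, ncol, integer(1))
  offsets <- cumsum(c(0, sizes[-length(sizes)]))

  S1 <- matrix(NA_real_, nrow = p, ncol = n_times,
               dimnames = list(factors, times))
  S2 <- matrix(NA_real_, nrow = ncol(pairs), ncol = n_times,
               dimnames = list(block_id[(p + 1):length(block_id)], times))
  vy <- numeric(n_times)
  for (tix in seq_len(n_times)) {
    y <- Y[, tix]
    v <- stats::var(y)
    vy[tix] <- v
    if (!is.finite(v) || v <= 0) next  # degenerate output: flagged as NA
    fit <- stats::lm.fit(cbind(1, X), y)
    coefs <- fit$coefficients[-1]
    coefs[is.na(coefs)] <- 0
    # orthonormal basis: component variance = sum of squared coefficients
    for (b in seq_along(blocks)) {
      idx <- offsets[b] + seq_len(sizes[b])
      vb <- sum(coefs[idx]^2)
      if (b <= p) S1[b, tix] <- vb / v else S2[b - p, tix] <- vb / v
    }
  }

  all_s <- rbind(S1, S2)
  ranks <- apply(-abs(all_s), 2, rank, ties.method = "average")
  avg_rank <- rowMeans(ranks)
  rank_table <- data.frame(term = rownames(all_s),
                           order = rep(c(1L, 2L), c(nrow(S1), nrow(S2))),
                           ranks, average_rank = avg_rank,
                           row.names = NULL, check.names = FALSE)
  rank_table <- rank_table[order(rank_table$average_rank), ]
  res <- list(S1 = S1, S2 = S2, ranks = rank_table,
              variance = stats::setNames(vy, times), times = times,
              degree = degree, degree2 = degree2)
  class(res) <- "sensitivity_result"
  res
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("sensitivity_result (RS-HDMR)\n")
  cat("top terms by average rank:\n")
  print(utils::head(x$ranks, 8), row.names = FALSE)
  invisible(x)
}

#' Run the full global sensitivity analysis
#'
#' Convenience wrapper: Latin hypercube sample, model evaluation over the
#' design, and RS-HDMR index estimation.
#'
#' @param design A [gsa_design()].
#' @param n_cells_per_point Cells averaged per design point.
#' @param times Analysis times (days).
#' @param master_seed Master seed (drives both the design sample and the
#'   simulations).
#' @param progress Print progress every `progress` design rows.
#' @return A list with `design`, `sample`, `Y` and `result`
#'   (a `sensitivity_result`).
#' @export
run_gsa <- function(design = gsa_design(256), n_cells_per_point = 100,
                    times = c(50, 100, 150, 200, 250), master_seed = 1,
                    progress = 0) {
  set.seed(child_seed(master_seed, 0))
  x <- latin_hypercube(design)
  Y <- evaluate_model_over_design(x, n_cells_per_point, times,
                                  master_seed = master_seed,
                                  progress = progress)
  list(design = design, sample = x, Y = Y,
       result = sobol_indices(Y, x))
}
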