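#' Premixing burn-in
#'
#' Runs the fusion-fission process alone (no turnover) from the uniform
#' 32-mitochondria / 320-nucleoid starting condition until the nucleoid
#' distribution among mitochondria and the spatial distribution of
#' mitochondria reach steady state.  Premixing removes any dependence of
#' downstream predictions on the unknown initial arrangement; the total
#' nucleoid count is conserved exactly.
#'
#' The default duration is 50 days, which suffices for mixing times up to
#' 30 days; for slower presets the horizon is extended proportionally
#' (`50 * tau / 30` days) so the burn-in always spans the same number of
#' mixing times (see [premix_duration()]).
#'
#' @param params A [qc_params()] object.
#' @param duration Burn-in length in days.
#' @param state Starting state; defaults to [initial_premix_state()].
#' @return The premixed `cell_state` (clock reset to 0).
#' @examples
#' set.seed(1)
#' s <- premix(qc_params(), duration = 5)  # short demonstration burn-in
#' @export
premix <- function(params = qc_params(), duration = premix_duration(params),
                   state = initial_premix_state()) {
  out <- run_cell(state, params, t_end = duration,
                  record = numeric(0), channels = c("fusion", "fission"))
  s <- out$final_state
  s$t <- 0
  s
}

#' @rdname premix
#' @param tau Mixing time (days) of the run the premix prepares; defaults to
#'   the value realized by `params$ff_scale` under the default geometry.
#' @export
premix_duration <- function(params = qc_params(),
                            tau = tau_at_ff1() / params$ff_scale) {
  if (tau <= 30) 50 else 50 * tau / 30
}

#' Relabel nucleoids as mutant
#'
#' `relabel_block_mutant()` converts `n_mutant` wild-type nucleoids to
#' mutant by whole mitochondria, walking the population in compartment order
#' (then storage order within a compartment) and splitting the remainder
#' within one organelle.  The labeled block is therefore spatially
#' contiguous: the two label populations start in disjoint regions of the
#' cell, as in the fused-cell mixing experiments the calibration emulates,
#' and the initial per-mitochondrion label heterogeneity is maximal.  This
#' is the labeling used for mixing-time estimation.
#' `relabel_random_mutant()` converts `n_mutant` uniformly chosen wild-type
#' nucleoids instead (with `n_mutant = 1`, the single de novo mutant of the
#' clonal-expansion experiments).  Both keep the total nucleoid count
#' unchanged.
#'
#' @param state A [cell_state()].
#' @param n_mutant Number of wild-type nucleoids to relabel.
#' @return The relabeled `cell_state`.
#' @export
relabel_block_mutant <- function(state, n_mutant) {
  remaining <- n_mutant
  total_w <- sum(vapply(state$mitochondria, function(m) sum(m$W), numeric(1)))
  if (total_w < n_mutant)
    stop("not enough wild-type nucleoids to relabel", call. = FALSE)
  comp <- vapply(state$mitochondria, function(m) m$compartment, numeric(1))
  for (i in order(comp)) {
    if (remaining <= 0) break
    m <- state$mitochondria[[i]]
    for (k in seq_along(m$W)) {
      take <- min(m$W[k], remaining)
      m$W[k] <- m$W[k] - take
      m$M[k] <- m$M[k] + take
      remaining <- remaining - take
      if (remaining <= 0) break
    }
    state$mitochondria[[i]] <- m
  }
  state
}

#' @rdname relabel_block_mutant
#' @export
relabel_random_mutant <- function(state, n_mutant = 1) {
  W <- lapply(state$mitochondria, function(m) m$W)
  flat <- unlist(W)
  if (sum(flat) < n_mutant)
    stop("not enough wild-type nucleoids to relabel", call. = FALSE)
  # index nucleoids by (mitochondrion, subcompartment) cell
  idx <- rep(seq_along(flat), flat)
  pick <- sample(idx, n_mutant, replace = FALSE)
  counts <- tabulate(pick, nbins = length(flat))
  pos <- 0
  for (i in seq_along(state$mitochondria)) {
    m <- state$mitochondria[[i]]
    for (k in seq_along(m$W)) {
      pos <- pos + 1
      if (counts[pos] > 0) {
        m$W[k] <- m$W[k] - counts[pos]
        m$M[k] <- m$M[k] + counts[pos]
      }
    }
    state$mitochondria[[i]] <- m
  }
  state
}

#' Estimate the nucleoid mixing time constant
#'
#' The mixing time constant `tau` is the time for the coefficient of
#' variation of the per-mitochondrion mutant fraction, averaged over a
#' population of cells, to complete 63.2% of its change from the initial
#' value to the steady-state plateau.  Each cell is premixed, half of its
#' nucleoids are relabeled as mutant (block labeling by whole mitochondria),
#' and the fusion-fission process alone is simulated with fusion
#' selectivity disabled - the labels are passive tracers.
#'
#' @param params A [qc_params()] object (its `ff_scale` sets the
#'   fusion-fission frequency under test).
#' @param n_cells Ensemble size (>= 2).
#' @param t_end Horizon of the labeled run in days.
#' @param master_seed Master seed; cell `k` runs on a derived child seed.
#' @param record_dt Sampling interval of the COV curve (days).
#' @param labeling `"block"` (default) or `"random"` assignment of the
#'   mutant labels after premixing.
#' @param plateau_fraction Final fraction of the time window averaged to
#'   estimate the steady-state plateau.
#' @return A list of class `mixing_curve`: `tau` (days), `curve` (data.frame
#'   `time, mean_cov, scaled` where `scaled` runs from 0% to -100% at the
#'   plateau), `plateau`, `cov0`, `n_cells`.
#' @examples
#' \donttest{
#' mt <- estimate_mixing_time(qc_params(), n_cells = 50, master_seed = 1)
#' mt$tau
#' }
#' @export
estimate_mixing_time <- function(params = qc_params(), n_cells = 500,
                                 t_end = NULL,
                                 master_seed = 1, record_dt = NULL,
                                 labeling = c("block", "random"),
                                 plateau_fraction = 0.2) {
  labeling <- match.arg(labeling)
  stopifnot(n_cells >= 2)
  tau_guess <- tau_at_ff1() / params$ff_scale
  # default horizon: ~8 expected mixing times, sampled at tau/20 resolution
  if (is.null(t_end)) t_end <- 8 * tau_guess
  if (is.null(record_dt)) record_dt <- tau_guess / 20
  record <- seq(0, t_end, by = record_dt)
  run_params <- qc_params_update(params, r_fusion_max = 0)
  half <- NULL
  covs <- matrix(NA_real_, nrow = n_cells, ncol = length(record))
  for (k in seq_len(n_cells)) {
    set.seed(child_seed(master_seed, k))
    s <- premix(run_params)
    if (is.null(half))
      half <- floor(sum(vapply(s$mitochondria, function(m) sum(m$W),
                               numeric(1))) / 2)
    s <- switch(labeling,
                block = relabel_block_mutant(s, half),
                random = relabel_random_mutant(s, half))
    out <- run_cell(s, run_params, t_end = t_end, record = record,
                    channels = c("fusion", "fission"))
    covs[k, ] <- out$trajectory$cov_rmito
  }
  mean_cov <- colMeans(covs, na.rm = TRUE)
  n_plateau <- max(2, ceiling(plateau_fraction * length(record)))
  plateau <- mean(mean_cov[(length(record) - n_plateau + 1):length(record)])
  cov0 <- mean_cov[1]
  if (plateau >= cov0)
    stop("COV did not decay within the horizon; increase 't_end'",
         call. = FALSE)
  target <- cov0 - 0.632 * (cov0 - plateau)
  below <- which(mean_cov <= target)
  below <- below[below > 1]
  if (length(below) == 0)
    stop("COV curve did not reach 63.2% of its steady-state change; ",
         "increase 't_end'", call. = FALSE)
  i <- below[1]
  # linear interpolation between the bracketing samples
  t_cross <- record[i - 1] + (record[i] - record[i - 1]) *
    (mean_cov[i - 1] - target) / (mean_cov[i - 1] - mean_cov[i])
  curve <- data.frame(time = record, mean_cov = mean_cov,
                      scaled = -100 * (cov0 - mean_cov) / (cov0 - plateau))
  out <- list(tau = t_cross, curve = curve, plateau = plateau, cov0 = cov0,
              n_cells = n_cells)
  class(out) <- "mixing_curve"
  out
}

#' @export
print.mixing_curve <- function(x, ...) {
  cat(sprintf("mixing_curve: tau = %.3g days (%d cells, plateau COV %.3g)\n",
              x$tau, x$n_cells, x$plateau))
  invisible(x)
}

#' @export
plot.mixing_curve <- function(x, ...) {
  plot(x$curve$time, x$curve$scaled, type = "l",
       xlab = "time (days)", ylab = "scaled mean COV change (%)", ...)
  graphics::abline(h = -63.2, lty = 2)
  graphics::abline(v = x$tau, lty = 3)
  invisible(x)
}

#' Write a mixing curve to CSV
#'
#' @param x A `mixing_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mixing_curve_csv <- function(x, path) {
  stopifnot(inherits(x, "mixing_curve"))
  utils::write.csv(x$curve, path, row.names = FALSE)
  invisible(path)
}
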