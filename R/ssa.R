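CHANNEL_NAMES <- c("replication", "mitophagy", "fusion", "fission")

channel_mask <- function(channels) {
  if (is.logical(channels)) {
    stopifnot(length(channels) == 4)
    return(channels)
  }
  bad <- setdiff(channels, CHANNEL_NAMES)
  if (length(bad) > 0)
    stop("unknown channels: ", paste(bad, collapse = ", "), call. = FALSE)
  CHANNEL_NAMES %in% channels
}

#' Enumerate reaction channels of a cell state
#'
#' Lists the propensities of every reaction channel of the current state:
#' one replication channel per nucleoid (aggregated per mitochondrion and
#' identity), one mitophagy channel per mitochondrion, one fission channel
#' per mitochondrion holding >= 2 nucleoids, and one fusion channel per
#' feasible pair (mitochondria in the same or adjacent compartments).
#'
#' @param state A [cell_state()].
#' @param params A [qc_params()] object.
#' @param channels Character subset of
#'   `c("replication", "mitophagy", "fusion", "fission")`.
#' @return A list with per-channel propensities and a `total` vector of
#'   per-class propensity sums.
#' @export
enumerate_channels <- function(state, params = qc_params(),
                               channels = CHANNEL_NAMES) {
  .mqc_enumerate_channels(state, params, channel_mask(channels))
}

#' Simulate one cell with the Gillespie direct method
#'
#' Exact stochastic simulation of the quality-control model: exponential
#' waiting times from the total propensity, channel choice proportional to
#' propensity, event execution, propensity refresh.  Per-cell statistics are
#' recorded on `record` times (the state at each grid time is the state
#' just before the first later event).
#'
#' @param state Initial [cell_state()].
#' @param params A [qc_params()] object.
#' @param t_end Duration in days (simulation runs from `state$t` to `t_end`).
#' @param record Sorted snapshot times within `[state$t, t_end]`.
#' @param channels Enabled reaction classes; the default enables all four.
#'   Fusion-fission-only runs (`c("fusion", "fission")`) conserve the total
#'   nucleoid count exactly.
#' @param episode_threshold When a fraction in `(0, 1]` is given, maximal
#'   time intervals during which a mitochondrion's mutant fraction exceeds
#'   the threshold ("mutant-rich episodes") are logged per organelle
#'   lineage: fusion ends an episode, fission creating a rich daughter
#'   starts one.  `NULL` disables tracking.
#' @param stop_at_homoplasmy Stop the event loop once the cell is
#'   homoplasmic (no mutant or no wild-type nucleoids left).  Homoplasmy is
#'   absorbing for the mutant fraction, so `r_cell` snapshots after the stop
#'   are exact; population-structure columns are frozen at the stop state.
#' @param max_events Safety cap on the number of executed events.
#' @return A list of class `cell_trajectory`:
#'   \describe{
#'     \item{trajectory}{data.frame `time, r_cell, n_mito, n_nucleoid,
#'       rbar_mito, cov_rmito` (rows after a terminated-empty cell are NA).}
#'     \item{final_state}{the `cell_state` at `t_end`.}
#'     \item{episodes}{data.frame `start, end, censored` (when tracking).}
#'     \item{episode_starts}{number of episode onsets observed.}
#'     \item{mito_days}{integral of the mitochondria count over time.}
#'     \item{counts}{executed events per reaction class.}
#'     \item{terminated_empty, absorbed_homoplasmic}{status flags.}
#'   }
#' @examples
#' set.seed(1)
#' s <- initial_premix_state()
#' out <- run_cell(s, qc_params(), t_end = 2, channels = c("fusion", "fission"))
#' tail(out$trajectory, 2)
#' @export
run_cell <- function(state, params = qc_params(), t_end,
                     record = seq(0, t_end, by = 1),
                     channels = CHANNEL_NAMES,
                     episode_threshold = NULL,
                     stop_at_homoplasmy = FALSE,
                     max_events = 1e8) {
  stopifnot(inherits(state, "cell_state"), t_end > state$t)
  if (is.unsorted(record, strictly = FALSE))
    stop("'record' must be sorted", call. = FALSE)
  thr <- if (is.null(episode_threshold)) -1 else {
    stopifnot(episode_threshold > 0, episode_threshold <= 1)
    episode_threshold
  }
  res <- .mqc_run_cell(state, params, channel_mask(channels),
                       t_end, as.numeric(record), thr, max_events,
                       isTRUE(stop_at_homoplasmy))
  out <- list(
    trajectory = as.data.frame(res$snapshots),
    final_state = res$final_state,
    episodes = as.data.frame(res$episodes),
    episode_starts = res$episode_starts,
    mito_days = res$mito_days,
    counts = res$counts,
    n_events = res$n_events,
    terminated_empty = res$terminated_empty,
    absorbed_homoplasmic = res$absorbed_homoplasmic,
    hit_max_events = res$hit_max_events,
    t_final = res$t_final)
  if (res$hit_max_events && max_events > 1e6)
    warning("event budget exhausted at t = ", signif(res$t_final, 4),
            " days; trajectory truncated", call. = FALSE)
  class(out) <- "cell_trajectory"
  out
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(sprintf("cell_trajectory: %d snapshots to t = %g days, %g events\n",
              nrow(x$trajectory), x$t_final, x$n_events))
  cat("  events:", paste(sprintf("%s=%g", names(x$counts), x$counts),
                         collapse = " "), "\n")
  if (x$terminated_empty) cat("  cell terminated empty\n")
  if (x$absorbed_homoplasmic) cat("  absorbed at homoplasmy\n")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' @param x A `cell_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "cell_trajectory"))
  utils::write.csv(x$trajectory, path, row.names = FALSE)
  invisible(path)
}
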