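#' Execute a single reaction event
#'
#' These wrappers apply one state transition of the model to a
#' [cell_state()] and return the updated state.  They share their mechanics
#' with the compiled simulation engine:
#'
#' * `execute_mitophagy()` removes the whole target mitochondrion (its
#'   entire chain and all nucleoids).  Removing the last mitochondrion is
#'   permitted; the returned state is then empty ("terminated-empty").
#' * `execute_replication()` increments the `W` or `M` count of one
#'   subcompartment by 1 (the "faithful nucleoid" model: a nucleoid is
#'   copied in place, producing an identical daughter).
#' * `execute_fusion()` picks donor and acceptor uniformly at random,
#'   appends the donor's subcompartment chain to the acceptor's (creating a
#'   new fission site at the junction and preserving the internal sites of
#'   both), and removes the donor; the merged organelle resides in the
#'   acceptor's compartment.
#' * `execute_fission()` divides a mitochondrion holding >= 2 nucleoids.
#'   Chains with more than one subcompartment are cut at a uniformly chosen
#'   fission site after the two adjacent pools are redistributed by
#'   Binomial(pool, 1/2) draws, identity-blind between wild-type and mutant;
#'   the exchange is redrawn if either daughter would be empty.  Chains of
#'   length one are split by a uniform cut with hypergeometric identity
#'   assignment.  One daughter keeps the original compartment; the other is
#'   placed uniformly over the original compartment and its neighbors.
#'
#' Randomness is drawn from R's RNG (`set.seed()` gives reproducibility).
#'
#' @param state A [cell_state()].
#' @param target,i,j 1-based index of the mitochondrion (pair) in
#'   `state$mitochondria`.
#' @param subcompartment 1-based chain position of the replicating nucleoid.
#' @param mutant Logical: replicate a mutant (`TRUE`) or wild-type nucleoid.
#' @param params A [qc_params()] object (used for internal bookkeeping).
#' @return The updated `cell_state`.
#' @name events
NULL

#' @rdname events
#' @export
execute_mitophagy <- function(state, target, params = qc_params()) {
  .mqc_execute_mitophagy(state, params, as.integer(target))
}

#' @rdname events
#' @export
execute_replication <- function(state, target, subcompartment = 1,
                                mutant = FALSE, params = qc_params()) {
  .mqc_execute_replication(state, params, as.integer(target),
                           as.integer(subcompartment), isTRUE(mutant))
}

#' @rdname events
#' @export
execute_fusion <- function(state, i, j, params = qc_params()) {
  .mqc_execute_fusion(state, params, as.integer(i), as.integer(j))
}

#' @rdname events
#' @export
execute_fission <- function(state, target, params = qc_params()) {
  .mqc_execute_fission(state, params, as.integer(target))
}
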