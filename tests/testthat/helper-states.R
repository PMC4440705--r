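# Small states used across tests; built in code, no stored fixtures.

two_mito_state <- function() {
  # (W=3,M=1) and (W=4,M=0) in adjacent compartments
  cell_state(build_default_geometry(16),
             list(mitochondrion(W = 3, M = 1, compartment = 1),
                  mitochondrion(W = 4, M = 0, compartment = 2)))
}

chain_state <- function(W_list, M_list, comps = NULL) {
  n <- length(W_list)
  if (is.null(comps)) comps <- rep(1L, n)
  mitos <- lapply(seq_len(n), function(i)
    mitochondrion(W = W_list[[i]], M = M_list[[i]], compartment = comps[i]))
  cell_state(build_default_geometry(16), mitos)
}

total_nucleoids <- function(state) {
  sum(vapply(state$mitochondria, function(m) sum(m$W) + sum(m$M), numeric(1)))
}

total_mutants <- function(state) {
  sum(vapply(state$mitochondria, function(m) sum(m$M), numeric(1)))
}
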