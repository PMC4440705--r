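#' Default compartment graph of the cell
#'
#' The cell interior is discretized into compartments whose width matches the
#' range of directed mitochondrial movements; fusion partners must reside in
#' the same or adjacent compartments and fission daughters disperse at most
#' one compartment away.  The default layout places `n_compartments`
#' compartments on a ring where each compartment is adjacent to its two ring
#' neighbors and the two next-nearest neighbors (degree 4 for `n >= 6`),
#' approximating the local connectivity of a 2D patchwork of a circular
#' cell.  Steady-state results are insensitive to the precise layout; any
#' symmetric irreflexive adjacency can be supplied to [cell_state()] instead.
#'
#' @param n_compartments Number of compartments (>= 2); default 16, which
#'   hosts the canonical premixing setup of two mitochondria per compartment.
#' @return An object of class `compartment_graph`: a list with
#'   `n_compartments` and `adjacency` (list of sorted 1-based neighbor
#'   index vectors).
#' @examples
#' g <- build_default_geometry(16)
#' lengths(g$adjacency)   # all 4
#' @export
build_default_geometry <- function(n_compartments = 16) {
  if (!is.numeric(n_compartments) || length(n_compartments) != 1 ||
      is.na(n_compartments) || n_compartments != round(n_compartments) ||
      n_compartments < 2)
    stop("'n_compartments' must be an integer >= 2", call. = FALSE)
  n <- as.integer(n_compartments)
  adjacency <- lapply(seq_len(n) - 1L, function(i) {
    nb <- unique((c(i - 2L, i - 1L, i + 1L, i + 2L)) %% n)
    sort(nb[nb != i]) + 1L
  })
  g <- list(n_compartments = n, adjacency = adjacency)
  class(g) <- "compartment_graph"
  validate_compartment_graph(g)
  g
}

validate_compartment_graph <- function(g) {
  n <- g$n_compartments
  adj <- g$adjacency
  if (length(adj) != n)
    stop("adjacency list must have one entry per compartment", call. = FALSE)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) < 1) stop("every compartment needs >= 1 neighbor",
                             call. = FALSE)
    if (any(nb < 1 | nb > n)) stop("neighbor index out of range", call. = FALSE)
    if (any(nb == i)) stop("adjacency must be irreflexive", call. = FALSE)
    if (anyDuplicated(nb)) stop("duplicated neighbor entries", call. = FALSE)
    for (j in nb)
      if (!(i %in% adj[[j]]))
        stop("adjacency must be symmetric", call. = FALSE)
  }
  invisible(g)
}

#' Construct a mitochondrion
#'
#' A mitochondrion is an ordered chain of subcompartments (nucleoid pools
#' inherited from past fusion events); a chain of length `L` has `L - 1`
#' fission sites.  `W` and `M` give the wild-type and mutant nucleoid counts
#' per subcompartment.
#'
#' @param W,M Nonnegative integer vectors of equal length (>= 1).
#' @param compartment 1-based compartment index the organelle resides in.
#' @return A list with fields `W`, `M`, `compartment`.
#' @export
mitochondrion <- function(W, M = rep(0L, length(W)), compartment = 1L) {
  W <- as.integer(W); M <- as.integer(M)
  if (length(W) != length(M) || length(W) < 1)
    stop("'W' and 'M' must be matched vectors of length >= 1", call. = FALSE)
  if (any(W < 0) || any(M < 0)) stop("nucleoid counts must be >= 0",
                                     call. = FALSE)
  if (sum(W) + sum(M) < 1)
    stop("a mitochondrion must hold at least one nucleoid", call. = FALSE)
  list(W = W, M = M, compartment = as.integer(compartment))
}

#' Construct a cell state
#'
#' @param graph A [build_default_geometry()] compartment graph.
#' @param mitochondria List of [mitochondrion()] objects.
#' @param t Simulation clock (days).
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(graph = build_default_geometry(),
                       mitochondria = list(), t = 0) {
  validate_compartment_graph(graph)
  for (m in mitochondria) {
    if (is.null(m$W) || is.null(m$M) || is.null(m$compartment))
      stop("each mitochondrion needs W, M and compartment fields",
           call. = FALSE)
    if (m$compartment < 1 || m$compartment > graph$n_compartments)
      stop("mitochondrion compartment index out of range", call. = FALSE)
  }
  s <- list(graph = graph, mitochondria = mitochondria, t = t)
  class(s) <- "cell_state"
  s
}

#' Uniform starting state for premixing
#'
#' Places `per_compartment` mitochondria in every compartment, each a single
#' subcompartment holding `nucleoids` wild-type nucleoids.  With the default
#' 16-compartment geometry this is the canonical 32-mitochondria,
#' 320-nucleoid initial condition.
#'
#' @param graph Compartment graph.
#' @param per_compartment Mitochondria per compartment.
#' @param nucleoids Wild-type nucleoids per mitochondrion.
#' @return A `cell_state`.
#' @export
initial_premix_state <- function(graph = build_default_geometry(),
                                 per_compartment = 2, nucleoids = 10) {
  mitos <- list()
  for (comp in seq_len(graph$n_compartments))
    for (k in seq_len(per_compartment))
      mitos[[length(mitos) + 1]] <-
        mitochondrion(W = nucleoids, compartment = comp)
  cell_state(graph, mitos, t = 0)
}

mito_totals <- function(state) {
  W <- vapply(state$mitochondria, function(m) sum(m$W), numeric(1))
  M <- vapply(state$mitochondria, function(m) sum(m$M), numeric(1))
  list(W = W, M = M)
}

#' Cell-level mutant fraction
#'
#' The fraction of mutant nucleoids in the cell,
#' `R_M^cell = sum(M_i) / sum(W_i + M_i)`; 0 and 1 indicate homoplasmic
#' wild-type and homoplasmic mutant cells respectively.
#'
#' @param state A `cell_state`.
#' @return A fraction in `[0, 1]`.
#' @export
cell_mutant_fraction <- function(state) {
  tot <- mito_totals(state)
  denom <- sum(tot$W) + sum(tot$M)
  if (denom < 1) stop("empty population: mutant fraction undefined",
                      call. = FALSE)
  sum(tot$M) / denom
}

#' Per-mitochondrion mutant fractions and their mean
#'
#' `mito_mutant_fractions()` returns `R_M,i^mito = M_i / (W_i + M_i)` for
#' every mitochondrion; `mean_mito_mutant_fraction()` is their unweighted
#' mean, the argument of the retrograde response.
#'
#' @param state A `cell_state`.
#' @return Numeric vector, or scalar mean.
#' @export
mito_mutant_fractions <- function(state) {
  if (length(state$mitochondria) < 1)
    stop("empty population: mutant fraction undefined", call. = FALSE)
  tot <- mito_totals(state)
  tot$M / (tot$W + tot$M)
}

#' @rdname mito_mutant_fractions
#' @export
mean_mito_mutant_fraction <- function(state) {
  mean(mito_mutant_fractions(state))
}

#' Coefficient of variation of per-mitochondrion mutant fractions
#'
#' Population (n-denominator) standard deviation of `R_M,i^mito` divided by
#' its mean; the dispersion statistic whose ensemble-mean relaxation defines
#' the nucleoid mixing time constant.  Undefined (NA) when the mean is zero;
#' such cells are excluded from ensemble averages.
#'
#' @param state A `cell_state`.
#' @return Nonnegative scalar, or `NA_real_` when the mean fraction is 0.
#' @export
cov_mito_mutant_fraction <- function(state) {
  R <- mito_mutant_fractions(state)
  if (length(R) < 2)
    stop("COV requires at least two mitochondria", call. = FALSE)
  mu <- mean(R)
  if (mu == 0) return(NA_real_)
  sqrt(mean((R - mu)^2)) / mu
}

#' Serialize a cell state to JSON
#'
#' Round-trip serialization for checkpointing and test fixtures.
#'
#' @param state A `cell_state`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `state_to_json`: JSON string (invisibly, if written to a file);
#'   `state_from_json`: a `cell_state`.
#' @export
state_to_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "cell_state"))
  doc <- list(
    n_compartments = state$graph$n_compartments,
    adjacency = lapply(state$graph$adjacency, as.integer),
    t = state$t,
    mitochondria = lapply(state$mitochondria, function(m)
      list(compartment = m$compartment,
           chain = mapply(function(w, mm) c(w, mm), m$W, m$M,
                          SIMPLIFY = FALSE))))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname state_to_json
#' @param json JSON string or file path to read from.
#' @export
state_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  graph <- list(n_compartments = as.integer(doc$n_compartments),
                adjacency = lapply(doc$adjacency,
                                   function(x) as.integer(unlist(x))))
  class(graph) <- "compartment_graph"
  mitos <- lapply(doc$mitochondria, function(m) {
    chain <- do.call(rbind, lapply(m$chain, function(p) as.integer(unlist(p))))
    mitochondrion(W = chain[, 1], M = chain[, 2],
                  compartment = as.integer(m$compartment))
  })
  cell_state(graph, mitos, t = as.numeric(doc$t))
}

#' @export
print.cell_state <- function(x, ...) {
  tot <- mito_totals(x)
  cat(sprintf(
    "cell_state: %d mitochondria, %d nucleoids (%d mutant), t = %g days\n",
    length(x$mitochondria), sum(tot$W) + sum(tot$M), sum(tot$M), x$t))
  invisible(x)
}
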