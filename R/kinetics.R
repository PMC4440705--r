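#' OXPHOS defect function
#'
#' Sigmoidal map from a mitochondrion's mutant fraction to its degree of
#' respiratory (OXPHOS) dysfunction, encoding the phenotypic threshold
#' effect of heteroplasmy: `s(R) = R^m / (K^m + R^m)`, with `s(0) = 0` and
#' `s(K) = 0.5`.  Note `s(1) = 1 / (1 + K^m) < 1`; statements that "s = 1"
#' for fully mutant mitochondria refer to the asymptotic bound.
#'
#' @param R Mutant fraction(s) in `[0, 1]` (vectorized).
#' @param K Threshold midpoint in `(0, 1]`.
#' @param m Sharpness exponent (> 0).
#' @return Defect level(s) in `[0, 1)`.
#' @examples
#' oxphos_defect(0.75)        # 0.5 at the midpoint
#' oxphos_defect(c(0.6, 0.9)) # the threshold region
#' @export
oxphos_defect <- function(R, K = 0.75, m = 11) {
  if (any(!is.finite(R)) || any(R < 0) || any(R > 1))
    stop("'R' must lie in [0, 1]", call. = FALSE)
  stopifnot(K > 0, K <= 1, m > 0)
  ifelse(R == 0, 0, R^m / (K^m + R^m))
}

#' Mitophagy propensity of one mitochondrion
#'
#' `a_D(R) = k_D * (r_D_max * s(R; K_D, m) + 1)`: healthy mitochondria are
#' autophagosized at the basal rate `k_D`; fully dysfunctional ones at up to
#' `(r_D_max + 1) * k_D`.
#'
#' @param R_mito Mutant fraction(s) of the mitochondrion.
#' @param params A [qc_params()] object.
#' @return Propensity in day^-1 (vectorized over `R_mito`).
#' @export
mitophagy_propensity <- function(R_mito, params = qc_params()) {
  params$k_D *
    (params$r_D_max * oxphos_defect(R_mito, params$K_D, params$m) + 1)
}

#' Per-nucleoid replication propensity
#'
#' Replication is retrograde-regulated and copy-number controlled: the
#' cell-level propensity `a_R(Rbar) = a_R0 * (r_R_max * s(Rbar; K_R, m) + 1)`
#' does not scale with the number of nucleoids (mtDNA content is tightly
#' regulated), and is allocated over individual nucleoids with the
#' replicative-advantage weight `k_R` on mutant copies: in a cell holding
#' `W` wild-type and `M` mutant nucleoids a wild-type copy replicates at
#' `a_R(Rbar) / (W + k_R * M)` and a mutant copy `k_R` times faster.  This
#' function returns the per-nucleoid rate at the reference steady-state
#' content (`W + k_R * M = N_ss`), where the wild-type rate is
#' `a_R0 / N_ss` — equal to the basal mitophagy rate `k_D`, so replication
#' balances turnover in a healthy cell.  `Rbar` is the average mutant
#' fraction among the mitochondria of the cell (the retrograde signal).
#'
#' @param is_mutant Logical: mutant (TRUE) or wild-type nucleoid.
#' @param Rbar Average per-mitochondrion mutant fraction of the cell.
#' @param params A [qc_params()] object.
#' @return Propensity in day^-1 per nucleoid (reference content).
#' @export
replication_propensity_per_nucleoid <- function(is_mutant, Rbar,
                                                params = qc_params()) {
  base <- (params$a_R0 / params$N_ss) *
    (params$r_R_max * oxphos_defect(Rbar, params$K_R, params$m) + 1)
  ifelse(is_mutant, params$k_R * base, base)
}

#' Fusion selectivity factor
#'
#' `r(R) = 1 - r_fusion_max * s(R; K_fusion, m)`: mitochondria with OXPHOS
#' defects are less likely to participate in fusion.  With
#' `r_fusion_max = 1` a fully dysfunctional mitochondrion is (asymptotically)
#' excluded from fusion.
#'
#' @param R_mito Mutant fraction(s).
#' @param params A [qc_params()] object.
#' @return Factor(s) in `[0, 1]`.
#' @export
fusion_selectivity <- function(R_mito, params = qc_params()) {
  1 - params$r_fusion_max *
    oxphos_defect(R_mito, params$K_fusion, params$m)
}

#' Pairwise fusion propensity
#'
#' For a feasible pair (two mitochondria in the same or adjacent
#' compartments): `a_fusion = ff_scale * a_fusion0 * r(R_i) * r(R_j)`.
#' Feasibility is the caller's contract; the simulation engine only
#' enumerates feasible pairs.
#'
#' @param mi,mj [mitochondrion()] objects (or any list with `W`, `M`).
#' @param params A [qc_params()] object.
#' @return Propensity in day^-1 for the pair.
#' @export
fusion_pair_propensity <- function(mi, mj, params = qc_params()) {
  ri <- fusion_selectivity(sum(mi$M) / (sum(mi$W) + sum(mi$M)), params)
  rj <- fusion_selectivity(sum(mj$M) / (sum(mj$W) + sum(mj$M)), params)
  params$ff_scale * params$a_fusion0 * ri * rj
}

#' Fission propensity
#'
#' Hill function of the total nucleoid content
#' `a_fission = ff_scale * V_F_max * T^n / (K_F^n + T^n)`, chosen to
#' reproduce a unimodal nucleoid-content distribution.  Mitochondria holding
#' fewer than 2 nucleoids cannot divide (both daughters must contain at
#' least one nucleoid), so their propensity is clamped to 0; the raw Hill
#' value at `T = 1` (~1.2e-4/day at nominal parameters) is negligible.
#'
#' @param mi A [mitochondrion()] object.
#' @param params A [qc_params()] object.
#' @return Propensity in day^-1.
#' @export
fission_propensity <- function(mi, params = qc_params()) {
  total <- sum(mi$W) + sum(mi$M)
  if (total < 1) stop("empty mitochondrion", call. = FALSE)
  if (total < 2) return(0)
  params$ff_scale * params$V_F_max *
    total^params$n / (params$K_F^params$n + total^params$n)
}
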