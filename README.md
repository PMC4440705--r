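# mitoqc

Stochastic simulation of mitochondrial quality control and the fate of
mtDNA mutations in a spatially compartmentalized cell.

## The problem

A cell maintains hundreds of mtDNA molecules, packaged into nucleoids and
distributed over a population of mitochondria that continuously fuse,
divide, and are turned over by mitophagy and replication.  Mutant mtDNA
can drift to high frequency (clonal expansion) and, past a threshold
fraction, cripple oxidative phosphorylation (OXPHOS).  Quality control
counteracts this: dysfunctional mitochondria fuse less (selective fusion)
and are degraded preferentially (selective mitophagy), while retrograde
signaling adjusts replication.  `mitoqc` is for computational biologists
who want to simulate this tug-of-war at single-nucleoid resolution and ask
when QC clears a de novo mutant and when the mutant expands.

## The model in brief

The cell state is a set of mitochondria on a 16-compartment graph; each
mitochondrion is a chain of subcompartments holding wild-type/mutant
nucleoid counts `(W_i, M_i)`, with mutant fraction
`R_i = M_i / (W_i + M_i)` and OXPHOS defect
`s(R) = R^m / (K^m + R^m)` (nominal `K = 0.75`, `m = 11`).  Four reaction
channels are simulated with the exact Gillespie direct method:

| process     | propensity                                        | effect |
|-------------|---------------------------------------------------|--------|
| replication | `a_R0 (r_R,max s(R̄) + 1)`, mutant copies weighted `k_R` | one nucleoid copied in place |
| mitophagy   | `k_D (r_D,max s(R_i) + 1)` per mitochondrion      | whole organelle removed |
| fusion      | `a_fusion,0 r(R_i) r(R_j)` per same/adjacent-compartment pair, `r(R) = 1 − r_fusion,max s(R)` | donor chain appended to acceptor |
| fission     | `V_F,max T^n / (K_F^n + T^n)` of total content `T` | chain cut at a random feasible site, Binomial(1/2) nucleoid exchange across the cut |

Cell-level summaries are the heteroplasmy `R_M^cell = ΣM_i / Σ(W_i+M_i)`
and the per-mitochondrion mean and COV of `R_i`.  The mixing time constant
τ (63.2% relaxation of the ensemble-mean COV under fusion-fission alone)
summarizes fusion-fission frequency; scaling both rates together moves τ
inversely while preserving the steady-state content distribution.  See
`vignette("mitoqc-methods")` for assumptions, calibration, and numerical
choices.

## Worked example

Premix a cell, introduce a single de novo mutant among its 320 nucleoids,
and simulate the full model for 300 days over a small ensemble:

```r
library(mitoqc)

sp  <- scenario_spec("nominal", scale_for_tau(7.5, tau_at_unit_scale = tau_at_ff1()),
                     n_cells = 200, t_end = 300)
res <- run_scenario(sp, master_seed = 1)
res
#> ensemble_result 'nominal': 200 cells to day 300
#>   final mean R_M^cell = 4.813e-05 (sd 0.000507), cleared 99.0%, fixed 0.0%
```

The ensemble mean starts at `1/320 = 0.003125` and decays as selective
fusion and mitophagy prune mutant-rich organelles; by day 300, 198 of the
200 cells are homoplasmic wild-type again and the population mean is
within one part in 10^4 of zero (a ~1% tail of cells carries the neutral
mutant slightly longer).  With a replicative advantage (`k_R = 2`) the
same call shows accumulation instead at fast fusion-fission.

Transient mutant-rich mitochondria — the objects QC must catch — can be
quantified directly:

```r
ep <- track_mutant_rich_episodes(
  scale_for_tau(7.5, tau_at_unit_scale = tau_at_ff1()),
  threshold = 0.9, n_cells = 100, t_end = 300, master_seed = 1)
ep
#> episode_stats (threshold 0.90): occurrence 0.000494 /day/mito, mean lifetime 1.1 days
#>   1435 episodes (1432 completed) over 2.906e+06 mitochondrion-days
```

About 4.9×10⁻⁴ mutant-rich organelles appear per mitochondrion-day and
live ~1 day at a 7.5-day mixing time; at τ = 30 days they appear ~4× less
often but live ~4× longer, so the fraction of time the mutant is exposed
to selective mitophagy is unchanged — the fusion-fission trade-off.

A variance-based global sensitivity analysis over the seven QC factors
(`run_gsa()`) ranks the replicative advantage `k_R` first and mitophagy
selectivity `r_D,max` ahead of the mitophagy rate at every analysis time.

A thin command-line front end over these functions ships in
`inst/cli/mitoqc.R` (subcommands `premix`, `mixtime`, `simulate`,
`episodes`, `gsa`).

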