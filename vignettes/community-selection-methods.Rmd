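---
title: "Breeding toxin-degrading communities in silico: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breeding toxin-degrading communities in silico: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commselect)
```

## The question the simulator addresses

Breeding whole microbial communities is harder than breeding organisms:
the unit of selection is a group whose composition shifts within and
between "generations", heritability is weak, and selection on individuals
(grow faster, contribute less) runs inside every round of selection on
communities. `commselect` implements an individual-based model of this
situation: communities of bacteria-like agents in well-mixed batch
culture are selected for degrading ten toxic compounds, under an explicit
trade-off — each lineage allocates a fraction $f_{i\cdot}=\sum_k f_{ik}$
of its consumed nutrients to degradation and the rest to growth. The
package exists to compare propagation schemes, chiefly the disassembly
family (re-assembling selected communities from isolated member species at
fixed inocula, with random composition changes) against the classical
propagule and migrant-pool schemes.

## Model structure and assumptions

**Species.** A species is a fixed parameter bundle (see
`sample_species()`): activation and replication probabilities $a, r \sim
\mathrm{Beta}(2,2)$ (mean 0.5, bell-shaped on (0,1): most species are
middling growers); nutrient preferences $n_{ij}$, per-toxin death rates
$m_{ik} \in \{0\}\cup[0.001, 0.02]$ per step, and the ancestral investment
vector $f_{ik}$. Sparsity — each coordinate masked out with probability
one half — is the engine of complementarity: a species consumes about
half the nutrients, is hurt by about half the toxins, and can degrade
about half of them, so full toxin coverage generally needs several
species. Masked coordinates are structural zeros and stay zero under
mutation. A species whose nutrient mask came out all-zero could never act
and its preference rescaling would be undefined, so that mask is redrawn;
all-zero death masks (immune species) and investment masks (non-degraders)
are legitimate phenotypes and kept.

**Within-round dynamics.** A round is 80 discrete time-steps in a batch
tube holding 4 nutrients (2000 units each) and 10 toxins (700 units
each). Cells are inactive ($p_0$) or active ($p_1$); division is
two-stage (pay to activate, divide for free into two inactive daughters),
which separates the nutrient cost of growth from its timing. The step
order is degradation → activation → replication/mutation → death. Death
follows a Hill function of toxin load with constant $K = 700$ — equal to
the initial toxin amount, so an untouched toxin kills at half its maximal
rate and degradation pays off immediately. All event counts are
$\min(\mathrm{Poisson}(p\,n),\,n)$ draws over the $n$ eligible cells;
truncation (rather than redraw) keeps the mean bias one-sided and
vanishing for small $p$.

**Mutation.** At each division the non-conserved daughter mutates with
probability $\mu = 0.01$, multiplying every unmasked $f_{ik}$ by an
independent lognormal$(0, \sigma^2 = 0.4)$ factor (median 1, so mutation
is directionless on the log scale); a total exceeding 1 is rescaled to
exactly 1, preserving relative allocation. Each mutant founds a new
lineage; lineages are the unit the propagation methods and the repository
track.

## Numerical and tie-break decisions

These points are underdetermined by the verbal description of such
models; the package fixes them as follows.

* **Resource competition within a step.** Lineages are processed in a
  freshly shuffled order each time-step, deducting nutrients and toxins
  sequentially with per-resource caps. Shuffling removes any systematic
  index advantage; caps guarantee $N_j, T_k \ge 0$ and monotone
  non-increase within a round.
* **Depleted toxins.** A lineage's degradation cost is charged only for
  the share of its investment aimed at toxins still present
  ($\sum_{k: T_k>0} f_{ik}$): degradation of an exhausted compound, and
  its nutrient cost, simply do not occur.
* **Reading $N_j(t)$ in the activation probability.** The nutrient
  fractions are read once per lineage-step after degradation, before
  maintenance deduction. Flagged-depleted nutrients contribute zero via
  $\hat n$, which makes the two possible readings (via $\hat n$ or via
  $N$) coincide.
* **Maintenance shortfall.** Active cells that cannot pay full
  maintenance revert to the inactive pool rather than dying (the mildest
  consistent interpretation of "consume to remain activated");
  `maint_revert = FALSE` disables reversion for sensitivity checks.
* **Death allocation.** Deaths are split between inactive and active
  cells hypergeometrically — the exchangeable-cells assumption.
* **Degrading cells.** Both active and inactive cells degrade
  ($C=\min(S_i, S_i^{max})$), since degradation is the community service
  being paid for by consumption, not a growth stage.
* **Ties in selection.** Top-$k$ selection breaks score ties towards the
  lower tube index; enumeration tables break score ties
  lexicographically on the canonical composition key. Both make ranking
  deterministic.

## Propagation design choices

* **Propagule parentage.** Each of the 7 selected parents founds exactly
  3 offspring by independent ~20-fold dilutions. A score-proportional
  parent assignment is available (`ps_score_proportional = TRUE`) but not
  default: the equal split is the cleaner control against the
  score-proportional disassembly family.
* **Migrant pool bottleneck.** The pooled parents are split so each of
  the 21 offspring receives Poisson($S_\ell/21$) cells per pooled
  lineage, drawn without replacement against the remaining pool. The
  division by the number of tubes (rather than a literal 20-fold
  dilution of the pool) keeps offspring tubes near-equal in expectation,
  which is the defining property of the scheme; the factor scales with
  `dilution_scale` in sweeps.
* **Disassembly inoculum.** Exactly 10 cells per member species by
  default, drawn with replacement across the species' repository
  lineages in proportion to their recorded abundances; a
  Poisson-with-floor-1 mode (`ds_fixed_inoculum = FALSE`) models pipette
  noise. The fixed mode is the default because the design's point is
  that the initial population is always 10 × richness.
* **Degenerate scores.** If every selected penalized score is zero,
  parent assignment falls back to uniform (the categorical distribution
  is undefined). A removal step that finds every member species unique
  to its tube removes none; an empty community scores $\hat D = 0$.
* **Invaders** (propagule/migrant-pool invasion variants) are ancestral
  genotypes at 10 cells — those schemes keep no repository — and are
  added even if the species is already present.

## Randomness and reproducibility

Every stochastic stage draws from a named substream: a splitmix-style
mixer (`mix_seed()`) turns (master seed, species set, run, round, tube,
process) into a 32-bit seed. Consequences: all propagation methods and
all mutation rates share bit-identical round-0 states for a given
(set, run), making paired method comparisons exact; and any recorded
tube-round can be replayed in isolation from the ledger. The compiled
engine and the pure-R reference engine consume the identical RNG
sequence, so `engine = "R"` and `engine = "cpp"` agree bit-for-bit — the
test suite asserts this, which guards the compiled code against silent
algorithmic drift.

## What the generator emulates, and what it does not

The species sampler *is* the study system: parameter distributions are
chosen so that communities, not single species, are the natural solution
(sparse complementary niches, growth–degradation trade-off, toxin
mortality on the same scale as the round length). It does not emulate
several properties of real communities: no spatial structure or clumping,
no cross-feeding (toxins are not nutrients), no parameter correlations
(e.g. fast growers are not systematically worse degraders beyond the
explicit trade-off), no phylogenetic structure, and mutation touches only
the investment vector. Passing tests therefore demonstrate the behaviour
of selection schemes under these idealized dynamics — exploration vs
exploitation of composition space, extinction penalties, inoculum
control — not quantitative predictions for any real consortium.

## Problem sizes used by the tests and the acceptance script

The full design (21 tubes, 15 species, 50 rounds, 10 replicate runs of 5
species sets per method) is what `experiment_config()` encodes. The
package's own replication battery runs 2 species sets × 5 runs × 50
rounds per method with shared round-0 states, release assays of 25
rounds × 5 replicates, and 10⁴-draw sampler checks; exhaustive
enumeration is oracle-verified on 4-species pools while the 15-species
enumeration (32 767 compositions) is exercised as bookkeeping plus
spot-scoring. These sizes keep the whole suite in the minutes range on a
single CPU while leaving the Monte-Carlo standard errors well inside the
spreads reported for the full-scale experiment.

## Known limitations

* The distinct-species count in a tube is capped by the pool (15); with
  richness-4 inoculation some assemblies collapse duplicates, so round-0
  richness is "at most 4", matching the sampling-with-replacement design.
* Bray–Curtis beta diversity uses raw counts; tubes that differ mainly
  in total population therefore register as dissimilar — intentional, as
  the bottlenecks under comparison differ exactly in how they control
  population size.
* At extreme mutation rates (μ ≫ 0.1) lineage bookkeeping, not the
  dynamics, dominates runtime; the engines are exact but not optimized
  for that regime.
* The pure-R engine exists for auditability and small fixtures; 50-round
  batteries should use the default compiled engine.
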