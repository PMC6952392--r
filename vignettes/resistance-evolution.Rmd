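---
title: "Simulating the evolution of drug-resistance mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the evolution of drug-resistance mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ever)
```

## The model

`ever` simulates the emergence of drug-resistance point mutations in a
drug-binding site as an evolutionary process on DNA. The model's central
assumptions are:

* **Resistance is local.** Only residues in direct contact with the drug
  are mutated; mutations in the pocket are assumed to affect drug binding
  directly and nothing else (no long-range conformational effects, no
  catalytic changes). This restricts the method to ATP-competitive
  inhibitors of targets whose backbone is not remodelled by mutation.
* **Mutation happens on codons, not amino acids.** Each offspring can
  acquire one uniformly placed single-nucleotide substitution in the
  binding-site DNA. Which amino acids are reachable in one generation is
  therefore dictated by the real codons of the gene — the reason
  methionine is reachable from an isoleucine codon (AUU→AUG) in one step
  but needs two steps from a threonine codon (ACU).
* **Fitness is docking-estimated binding.** A mutant is fit when it binds
  the drug more weakly than wild type does, while still binding ATP in
  the right place at near-wild-type energy (otherwise the kinase would
  not sustain the tumour). Docking scores are used directly as binding
  free-energy estimates in kcal/mol, with no correction terms.

A mutant that passes the ATP-preservation gates (pose RMSD ≤ 4 Å,
ATP-energy increase ≤ 0.3 kcal/mol) is scored

$$\mathrm{score} \;=\; \frac{\Delta E^{drug}_{mut}-\Delta E^{drug}_{wt}}
{\left|\Delta E^{ATP}_{mut}-\Delta E^{drug}_{mut}\right|\cdot
\mathrm{RMSD}_{ATP}\cdot \mathrm{Num}_{mut}}$$

and selection keeps the top 5% of mutation-bearing offspring, capped at
the population size, refilling any shortfall with the highest-ranking
original sequences.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_parents` | 1000 | sequences | full-scale population of the study design |
| `n_offspring_per_parent` | 10000 | offspring | brood size per individual per generation |
| `mutation_rate` | 1e-4 | per offspring | with the two values above, ≈10³ mutation-bearing offspring per generation, a computationally manageable proxy for the mutational load of a mid-stage tumour |
| `top_fraction` | 0.05 | – | eligible share of mutation-bearing offspring |
| `population_cap` | 1000 | individuals | post-selection population size |
| `rmsd_max` | 4.0 | Å | ATP must still occupy its site |
| `atp_dE_increase_max` | 0.3 | kcal/mol | ATP affinity must be essentially preserved |
| `max_generations` | 10 | – | hard stop |
| `convergence_share` / `convergence_generations` | 0.9 / 2 | – | dominance-based convergence (see below) |
| `seeds` | 1, 2, 3 | – | three independent replicates |

### Mutation-rate semantics

The stated study arithmetic — 10³ parents × 10⁴ offspring at rate 10⁻⁴
giving ≈10³ mutants — only balances if the rate is **per offspring**, not
per base. The default is therefore a per-offspring Bernoulli draw placing
one uniform substitution; a per-base mode (`per_base = TRUE`), in which
every base mutates independently and one offspring can carry several new
substitutions, is available for sensitivity analysis. Multi-site
genotypes still arise under the default semantics, by accumulation across
generations.

### Silent and nonsense mutants

Nonsense mutants are discarded outright: a truncated kinase cannot drive
the disease, so it is never a resistance outcome. Silent (synonymous)
DNA-level mutants are kept as genotypes — their DNA matters for what is
reachable next — but are ranked with score 0, so they never displace a
positively scored missense mutant and effectively persist only when
little else is eligible. This is one coherent reading of treating silent
changes as "mutation-bearing at the DNA level but wild-type at the
protein level".

### The selection rule

"Top 5% of individuals containing mutations" is implemented as: rank all
mutation-bearing offspring by score, keep the best 5% as the eligible
pool, then apply the cap/refill rule (keep at most `population_cap`; if
fewer are eligible, refill with the highest-ranking members of the
previous population). This is the only reading we found consistent with
both the 5% rule and the cap/refill rule; the fraction's denominator
(offspring, not unique mutants) is a package choice, configurable via
the pool helpers.

### Convergence

"The mutations have converged" is made precise as: the most frequent
amino-acid mutation among selected mutants holds a share ≥ 0.9 of the
mutation-bearing population for 2 consecutive generations (both
configurable). The primary endpoint, however, is energetic: the run stops
as soon as the top-ranked mutant binds the drug more weakly than ATP,
the point at which ATP outcompetes the inhibitor in the cell.

## Numerical choices

* **Denominator floors.** The score is singular at
  $\mathrm{RMSD}_{ATP}=0$ (an unmoved ATP pose) and at
  $\Delta E^{ATP}=\Delta E^{drug}$. Both factors are floored at
  `denominator_epsilon` (default 1e-6), keeping scores finite and
  order-preserving. Without the floor, wild-type-like ATP poses would
  dominate with infinite scores.
* **RMSD in the denominator is taken literally.** Smaller ATP
  displacement yields a *larger* score. Intuition might place it in the
  numerator; the literal form is the default and an `invert_rmsd` switch
  exists purely for sensitivity studies.
* **Gate before score.** The ATP constraints are a hard filter
  ("discarded"), not a soft penalty; their quantities additionally shape
  the score through the denominator. Both mechanisms are active, since
  the wording that introduced them supports either reading.
* **Deterministic ranking.** Ties break by fewer amino-acid mutations,
  then lexicographic genotype DNA, so runs are reproducible bit-for-bit
  from `(config, seed)` with the surrogate backend. Per-generation RNG
  streams are drawn once from the run seed.
* **Pose RMSD without superposition.** Mutant structures are built on the
  fixed wild-type backbone, so reference and docked poses share one
  frame; RMSD is computed over heavy atoms paired by PDB atom name. This
  frame convention replaces an external superposition step and is a
  package convention, not a claim about how any particular study computed
  it.
* **Degenerate inputs.** Mutation rate 0 is a fixed point (the engine
  provably selects nothing); rate 1 mutates every offspring; an empty
  residue selection yields an empty gene; an empty binding-site selection
  at a too-small cutoff warns rather than errors.

## What the surrogate landscape does and does not emulate

Repacking and docking thousands of mutants needs external tools and CPU
days, so the testable backend is a deterministic per-(position, amino
acid) table of energy offsets: mutant energies are the wild-type baseline
plus additive offsets, and the ATP displacement is the root-sum-square of
per-substitution displacements. The fixture generator draws background
offsets uniformly within ±0.3 kcal/mol (drug) and ±0.1 kcal/mol (ATP),
displacements in 0.3–2 Å, zero offsets for wild-type amino acids, and
baselines of −10.0 (drug) and −7.7 kcal/mol (ATP) — the ATP value chosen
to match the stable ATP-binding plateau of the ABL reference system. A
planted resistance substitution is always made single-nucleotide
accessible, so recovery experiments are fair.

The surrogate reproduces the *bookkeeping* a docking backend feeds the
engine — additive energetics, a dominant resistance site, ATP-preserving
versus ATP-disrupting substitutions — and therefore validates the
evolutionary machinery: mutation accessibility, caching, constraint
gating, scoring, selection, termination. It does **not** reproduce
epistasis between sites, docking-score noise, pose multiplicity, backbone
relaxation, or catalytic effects; passing surrogate tests says the engine
is correct, not that any particular real-target prediction is.

Tests and the acceptance script run the engine at reduced scale —
100 parents × 1000 offspring at rate 10⁻², population cap 100, 20
replicate recovery runs — sizes chosen so the whole suite exercises every
code path in seconds while the binomial mutant-count statistics remain
well separated from their acceptance bands. Scale is pure configuration;
no code path differs between desk scale and full scale.

## Replicate aggregation and triage

Final selected mutants are pooled across replicates by individual counts
(a `pool = "mean"` alternative averages per-replicate frequencies), with
amino-acid labels pooling synonymous DNA routes; labels occurring exactly
once across all replicates are collapsed into an `"other"` bucket, as
singletons carry no reproducible signal.

The downstream triage classifies a predicted mutant by comparing its
measured IC50 against the drug's clinical safety window converted to
molarity (ng/mL → g/L, divided by molecular weight; plasma protein
binding and tissue distribution are deliberately ignored). IC50 above the
window maximum ⇒ resistant; within ⇒ sensitive; missing ⇒ inconclusive.
Fold-change annotations mark the empirically observed regimes: ≥60-fold
IC50 increases are typical of clinically observed resistance mutations,
<15-fold of predicted-but-never-observed ones, and a >6-fold
catalytic-efficiency change flags an enzyme cells may not tolerate.

## A complete reduced-scale run

```{r run}
fx <- generate_fixture(seed = 42, n_residues = 10,
                       planted = list(aa = "M", drug_offset = 2.5,
                                      atp_offset = 0))
fx$gene
cfg <- ga_config(n_parents = 100, n_offspring_per_parent = 1000,
                 mutation_rate = 1e-2, population_cap = 100,
                 seeds = c(1, 2, 3))
reports <- ga_run(fx$gene, surrogate_backend(fx$landscape), cfg)
reports[[1]]
aggregate_runs(reports)
```

The planted substitution is recovered as the top-scoring mutant and the
run terminates on the energetic endpoint in the first generation (its
planted +2.5 kcal/mol drug offset immediately lifts drug binding above
the ATP level). Weaker planted effects converge over several generations
instead.

## Known limitations

* Single-site resistance only: compound mutations arise in the engine
  but the scoring deliberately down-weights them, and no epistasis model
  exists.
* Not applicable to allosteric or covalent inhibitors, or to resistance
  that acts through catalysis or expression rather than binding.
* The docking adapter inherits every limitation of the configured
  engine; with a rigid backbone, mutations acting through conformational
  change are invisible.
* The safety-window triage compares total plasma concentration with an
  in-vitro IC50; protein binding can shift the effective window
  substantially.
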