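# ever

Evolution-simulating prediction of drug-resistance point mutations.

## The problem

Point mutations in a drug's binding site are the main route by which
kinase-driven cancers escape targeted therapy: the classic example is the
BCR-ABL gatekeeper mutation T315I, which abolishes imatinib binding while
the kinase keeps phosphorylating its substrates with ATP. `ever` is for
computational chemists and structural biologists who want to ask, *before*
such mutations are observed in patients: which substitutions in this drug's
binding pocket would weaken drug binding, preserve ATP binding, and are
actually reachable by the mutational process?

The key design decision is that evolution is simulated at the **DNA
level**, on the real codons of the gene. Amino-acid-level mutagenesis
ignores codon degeneracy: the threonine codon ACU needs *two* nucleotide
substitutions to reach methionine (AUG), while the isoleucine codon AUU
needs only one — which is why T315M is essentially never seen arising from
wild type while I315M readily arises from T315I. Single-nucleotide
accessibility is a first-class citizen here.

## The method

A mutation-only genetic algorithm:

1. **Back-translation.** Binding-site residues (heavy-atom contact within a
   configurable cutoff of the bound drug) are mapped to their actual gene
   codons from the CDS.
2. **Offspring generation.** Each generation, every individual produces a
   large offspring brood; each offspring acquires, with probability equal
   to the mutation rate, one uniformly placed single-nucleotide
   substitution. Defaults: 10³ parents × 10⁴ offspring at rate 10⁻⁴, giving
   ≈10³ mutation-bearing offspring per generation.
3. **Evaluation.** Each *unique* missense genotype is evaluated once
   (results are cached): side chains are rebuilt on the fixed backbone and
   the drug and ATP are docked (external-tool adapter), or a deterministic
   surrogate energy landscape is used for desk-scale work and testing.
   Nonsense mutants are discarded as catalytically dead.
4. **Constraints and scoring.** Mutants whose docked ATP pose moves more
   than 4 Å from its reference position, or whose ATP binding energy rises
   by more than 0.3 kcal/mol, are discarded. Survivors are scored by

   ```
                         ΔE_mut^drug − ΔE_wt^drug
   resistance score = ─────────────────────────────────────
                      |ΔE_mut^ATP − ΔE_mut^drug| · RMSD_ATP · Num_mut
   ```

   — higher when drug binding weakens relative to wild type, normalised by
   the ATP/drug energy gap, the ATP pose displacement, and the number of
   amino-acid substitutions (single mutants are prioritised).
5. **Selection.** The top 5% of mutation-bearing offspring are eligible;
   at most 1000 (the population cap) are kept, and if fewer are eligible
   the highest-ranking original sequences refill the population.
6. **Termination.** Evolution stops when the top mutant binds the drug
   more weakly than ATP, when one mutation dominates the population for
   consecutive generations, or at the generation cap.

Replicate runs (three by default) are pooled into a mutation-frequency
distribution, and predicted mutants with measured IC50 values can be
triaged against the drug's clinical safety window: a mutant whose IC50
exceeds the highest safe plasma concentration cannot be rescued by dose
escalation and is classified resistant.

## Worked example

A reduced-scale run on a synthetic ten-residue binding site with one
planted resistance substitution (+2.5 kcal/mol drug-binding penalty, no
ATP effect) over a small random background:

```r
library(ever)
fx <- generate_fixture(seed = 42, n_residues = 10,
                       planted = list(aa = "M", drug_offset = 2.5, atp_offset = 0))
fx$gene
#> Binding-site gene (10 residues, synthetic-fixture-seed42)
#>   V301 [GTG] T302 [ACG] F303 [TTT] Q304 [CAG] R305 [AGG] T306 [ACA]
#>   P307 [CCT] G308 [GGT] V309 [GTG] V310 [GTC]

cfg <- ga_config(n_parents = 100, n_offspring_per_parent = 1000,
                 mutation_rate = 1e-2, population_cap = 100, seeds = c(1, 2, 3))
reports <- ga_run(fx$gene, surrogate_backend(fx$landscape), cfg)
reports[[1]]
#> Evolutionary run (seed 1): 1 generation(s), stopped: drug_weaker_than_atp
#>   top mutants: R305M (n=7, score=12.5), V310F (n=13, score=0.345),
#>   R305T (n=8, score=0.289), F303L (n=13, score=0.254), F303L (n=7, score=0.254)
```

The planted substitution (R305M, reachable from codon AGG by one
nucleotide change) is recovered as the top-scoring mutant — score 12.5
versus ≤0.35 for the background — and the run stops because its drug
binding (−7.5 kcal/mol) is now weaker than its ATP binding
(−7.7 kcal/mol), the intended endpoint. Pooling the three replicates:

```r
aggregate_runs(reports)
#>   label frequency
#> 1 F303L 0.3040541
#> 2 V310F 0.2702703
#> 3 R305M 0.2500000
#> 4 R305T 0.1756757
```

The scoring arithmetic and the triage conversion, on their worked
examples:

```r
ev <- energy_evaluation(dE_drug = -8.0, dE_atp = -7.7, rmsd_atp = 1.0)
resistance_score(ev, reference_state(-10.0, -7.7), num_mut = 1)
#> [1] 6.666667      # 2.0 / (0.3 * 1.0 * 1)

convert_safety_window(3000, 493.6) * 1e6   # imatinib upper bound, uM
#> [1] 6.077796
```

A thin command-line front end is provided at `exec/ever`
(`ever run --config run.yaml --backend surrogate --seed 1,2,3 --out DIR`).
Docking-backed runs use the adapter configured by `dock_backend()`, which
requires an external side-chain repacker and a Vina-compatible docking
engine on the PATH.

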