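# tcrshare

Tools for detecting **tumor-associated public TCR CDR3 clones** — amino-acid
CDR3 sequences that recur across subjects, and across species, despite the
quasi-random nucleotide rearrangement that generates them.

T-cell receptor repertoires are tables of clonotypes: a nucleotide (NT)
junction, its amino-acid (AA) translation, V/J gene calls and a copy number,
per sample. `tcrshare` takes such tables (AIRR Rearrangement-style TSV) and
implements the full comparative chain:

* **Publicness partition** — each AA CDR3 is *private* (one subject),
  *public-inclusive* (both study groups) or *public-exclusive* (≥ 2 subjects
  of exactly one group). Exclusive clones enriched in the tumor group are
  the candidate tumor-associated signature.
* **Convergent recombination (CR)** — `CR level = |{NT junctions encoding
  the AA}|`; high CR marks AA sequences that the rearrangement process
  converges on repeatedly.
* **Overlap indices** — Morisita–Horn for sample pairs (young/old,
  control/case averages) and a frequency-weighted Jaccard
  `Σ min(f_A, f_B) / Σ max(f_A, f_B)` for exclusive-set-vs-cohort sharing.
* **Cross-species metrics** — presence-quantified mouse∩human clone sets;
  the rank-area metric `1 / (rank_mouse × rank_human)` (1 when a clone tops
  both species, ≈ 0.000015 when ranked 258th of 258 in both); disease-stage
  similarity `shared / (clones_in_sample × cases_in_stage)`.
* **Sequence networks** — Levenshtein neighborhoods and networks over top-N
  abundance pools with seeded random baselines, plus the NT-origin bipartite
  graph showing that shared AA clones use species-disjoint NT encodings.
* **Single-cell α–β pairing** — per-cell chain assembly (multichain filter),
  matching pairs into bulk samples, and group-partitioned pair networks.
* **Synthetic-data generator** — planted-truth mouse/human/single-cell
  repertoires (power-law abundances, synonymous-codon CR, group-exclusive
  publics, stage gradients) used throughout the test suite.

All user-facing functions take a data frame first and return tibbles, so the
chain composes with the pipe; results have `autoplot()` methods and the
model-comparison object has `tidy()`/`glance()`.

## Worked example

Simulate a beta-chain study (5 control vs 5 case subjects, 4 monthly
timepoints, 10% planted case-exclusive vs 2% control-exclusive clones),
pool each subject, subsample to equal depth, and test for exclusive-clone
enrichment:

```r
library(tcrshare)
library(dplyr)

cfg    <- sim_config(clones_per_subject = 300, timepoints = 4,
                     chains = "beta", seed = 1)
study  <- simulate_mouse_study(cfg)
pooled <- pool_subjects(study$samples)
depth  <- floor(min(total_reads(pooled)$total_reads) * 0.9)   # 1706 reads
reps   <- subsample_repertoire(pooled, depth, seed = 1)

fr <- publicness_fractions(reps)
fr |>
  filter(label == "public_exclusive_case") |>
  group_by(group) |>
  summarise(mean_fraction = mean(fraction))
#> # A tibble: 2 × 2
#>   group   mean_fraction
#>   <chr>           <dbl>
#> 1 case            0.104
#> 2 control         0

ec <- filter(fr, label == "public_exclusive_case")
welch_ttest(ec$fraction[ec$group == "case"],
            ec$fraction[ec$group == "control"])
#> # A tibble: 1 × 3
#>   statistic    df    p.value
#>       <dbl> <dbl>      <dbl>
#> 1      38.8     4 0.00000263
```

Case subjects carry ~10% group-exclusive public clones against 0% in
controls — the planted tumor-associated signal, recovered with a Welch
p ≈ 2.6e-06. Convergent recombination and the rank-area metric:

```r
mean(cr_levels(reps)$cr_level > 1)   # fraction of AAs with >1 NT encoding
#> [1] 0.346

cross_rank_area(c(1, 258), c(1, 258))
#> [1] 1.000000e+00 1.502314e-05
```

`run_pipeline(pipeline_config())` executes the whole chain (load/simulate →
pool → subsample → publicness/CR → cross-species → networks → single-cell)
and writes per-stage TSVs plus a JSON summary; reruns with the same seed are
bit-identical.

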