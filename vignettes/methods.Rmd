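---
title: "Detecting tumor-associated public TCR clones: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tumor-associated public TCR clones: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrshare)
library(dplyr)
```

## The problem

A T-cell receptor (TCR) recognizes antigen through the CDR3 loop of its
alpha and beta chains. The CDR3 amino-acid (AA) sequence is produced by a
quasi-random V(D)J nucleotide (NT) rearrangement, so the prior probability
that two individuals — let alone two species — carry the *same* AA sequence
is minute. When the same AA CDR3 nevertheless recurs across subjects
("public" clones), and recurs preferentially in tumor-bearing subjects, that
recurrence is a signature of shared antigenic selection. `tcrshare`
implements the analysis chain for detecting such signatures in longitudinal
mouse repertoires and relating them to human cohorts:

1. **Publicness partition.** Over per-subject (pooled, equal-depth
   subsampled) repertoires, each AA CDR3 is *private* (one subject),
   *public-inclusive* (subjects of both groups) or *public-exclusive*
   (two or more subjects of exactly one group).
2. **Convergent recombination (CR).** The CR level of an AA sequence is the
   number of distinct NT junctions encoding it in scope. Summed over AAs, CR
   levels equal the distinct-NT count — a conservation law the tests check.
3. **Overlap indices.** Morisita–Horn for sample pairs; a frequency-weighted
   (Ruzicka) Jaccard, `sum(min)/sum(max)`, for exclusive-set versus cohort
   comparisons.
4. **Cross-species metrics.** A presence quantifier builds the
   mouse-and-human shared set; the rank-area metric
   `1/(rank_mouse x rank_human)` scores concordant abundance; stage
   similarity is `shared/(clones_in_sample x cases_in_stage)`.
5. **Sequence networks.** Levenshtein-distance neighborhoods and networks
   over top-N abundance pools, with a random-sequence baseline; the NT-origin
   bipartite graph showing species-disjoint encodings of one AA.
6. **Single-cell pairing.** Per-cell alpha–beta pairs (cells with more than
   one call of either chain are dropped), matched into bulk samples when
   both chains are present.

## Data model

Everything is a tibble with one row per clone: `sample_id`, `subject_id`,
`group` (`control`/`case`), `timepoint`, `chain`, `tissue`, `junction` (NT),
`junction_aa`, `v_call`, `j_call`, `duplicate_count`. Clone identity within
a sample is the NT junction alone; rows that differ only in V/J are merged
with summed counts and V/J kept as a comma-joined annotation set, because a
single CDR3 can arise from several V–J pairings and the analyses aggregate
across them. The stored AA junction is the full IMGT junction (conserved
C…F, as in `CASSLSYEQYF`), untrimmed.

Non-productive rows — NT length not divisible by three, or an in-frame stop —
are dropped at load and tallied in a skip report, since every analysis here
operates on translated AA CDR3s.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `min_count` (publicness) | 1 | copies needed to count as "present" in a subject |
| subsampling depth | per run | equal read depth per subject (multivariate hypergeometric, i.e. rarefaction without replacement) |
| `d_max` (networks) | 2 (3 for alpha-beta pairs, summed over chains) | maximum edit distance for "similar" |
| `n` (top-N pool) | 10,000 | fixed pool size removing sample-size bias |
| `min_samples` (abundant selection) | 10 | per-epoch presence threshold |
| `alpha` | 0.05 | two-sided Welch threshold for the young/old abundance filter |
| `n_iter` (resampling null) | 1000 | null draws; empirical p uses the +1 correction, so p >= 1/(n_iter+1) |
| young/old epochs | timepoints 1–4 / 5–8 | longitudinal binning for overlap and abundance contrasts |

Design choices made where the procedure was genuinely open:

* **Subsampling counts reads, not unique clones.** Equal-depth normalization
  is done at the read level (the standard rarefaction convention); the
  unique-clone alternative would change depth semantics for highly clonal
  samples.
* **Diversity and clonality.** Shannon entropy in nats over clone read
  frequencies, and clonality = 1 − Pielou evenness (0 for a single clone by
  convention). These are the standard repertoire summaries.
* **Morisita variant.** Morisita–Horn, the abundance-based form bounded in
  [0, 1], computed through `vegan`; the original count-only Morisita index is
  not used.
* **Rank ties.** Competition ranking with lexicographic AA tie-break, so
  ranks are a dense deterministic permutation and rank-areas are exactly
  reproducible.
* **Sharing-vs-CR comparison.** Per group, each AA contributes (CR level,
  number of carrying subjects); mean sharing per CR level enters nested
  Gaussian GLMs (`sharing ~ cr` vs `sharing ~ cr * group`) compared with a
  likelihood-ratio test (`lmtest::lrtest`), chi-squared reference with df =
  parameter difference.
* **Welch rather than Student.** All two-group mean comparisons use the
  unequal-variance t-test; when both groups are constant and equal the p is
  1 by convention.
* **Abundant-clone test values.** The young/old Welch test uses per-sample
  copy numbers over *all* samples of each epoch, zero when absent —
  candidates are required to be present in `min_samples` samples of each
  epoch anyway, and including zeros keeps the two epochs on the same footing.
* **Random baselines.** Neighborhood baselines draw uniformly from the top-N
  pool excluding the focal sequences; resampling nulls draw without
  replacement from the candidate set. Both are seeded and bit-reproducible.
* **Pair-network distance.** For alpha–beta pairs the default distance is
  the sum of the per-chain Levenshtein distances (`summed_chains`); a
  per-chain-capped mode (`single_chain`) is available, since "up to k AA
  differences between two pairs" admits either reading.
* **Cells both multichain and incomplete** are counted once, as multichain
  (that filter is applied first).

## The synthetic-data generator

No mouse sequencing accession accompanies the study design this package
addresses, so the generator is first-class, tested code that plants ground
truth with the statistical structure the analyses assume:

* two groups of subjects (5 control, 5 case) sampled at 8 monthly
  timepoints, both chains;
* Zipf (discrete power-law) clone abundances, exponent 1.2 — heavy-tailed
  copy numbers as observed in blood repertoires, which show no canonical
  parametric form;
* planted public AA clones: group-exclusive sets appearing in >= 2 subjects
  of one group and none of the other (defaults 10% of a case subject's
  clones vs 2% of a control subject's — the case-enriched exclusive signal),
  plus inclusive publics (15%) present in both groups;
* convergent recombination realized by synonymous-codon resampling of a
  reference NT encoding; the number of variants per AA is
  1 + Poisson(`cr_variants_mean` − 1). This is the minimal generative
  mechanism that produces many-NT-to-one-AA convergence; real rearrangement
  statistics (junctional insertions/deletions, gene-segment priors) are
  deliberately out of scope;
* public clone reads decay twofold at old timepoints, so young samples
  overlap more than old ones;
* human cohorts that share a fraction of the mouse public AAs through
  freshly drawn NT encodings rejection-sampled against the mouse set —
  shared AA, provably disjoint NT origins;
* a staged human cohort with a fourfold stage-i-over-stage-iv sharing
  gradient, and per-sequence synthetic score tables standing in for
  generation-probability and binding scores;
* single-cell chain calls with configurable multichain and planted-match
  fractions.

Everything flows from one seed; regeneration is byte-identical.

**What passing tests do and do not show.** The generator emulates the
*combinatorial* structure of repertoire sharing (who carries what, through
which encodings, at what abundance rank), so recovery tests demonstrate that
the chain detects planted signal of the stated effect sizes at desk scale.
It does not emulate sequencing error, PCR amplification bias, V(D)J
generation-probability structure, or HLA/MHC-driven selection; agreement on
synthetic data therefore validates the statistics, not any biological claim
about real repertoires.

## Problem sizes and numerical notes

The test suite runs the Monte-Carlo recovery checks at 120 clones per
subject, one timepoint, beta chain only, over 100 seeds — sizes at which a
full run of each check takes a couple of minutes while leaving the planted
effects (10% vs 2% exclusive fractions; 4x stage gradient) comfortably
detectable. Calibration uses 10,000 null replicates for the Welch test and
300 outer replicates (99 inner draws) for the resampling null. The pipeline
example in the README uses 3+3 subjects at 100 clones for speed.

Degenerate inputs are handled explicitly: empty samples are rejected by the
overlap indices; a stage with zero cases is excluded with a warning; a
fully constant Welch comparison returns p = 1; subsampling past a sample's
depth reports both numbers; few-codon AA sequences that admit fewer distinct
synonymous encodings than requested simply carry the encodings that exist.

## Limitations

* Clonotype tables are the input boundary: read alignment, UMI collapsing
  and V-D-J calling belong to upstream tools.
* Generation probabilities and binding scores are consumed as score tables
  (or a pluggable scorer function); the models that produce them are not
  re-implemented here.
* The publicness partition is presence/absence at a count threshold; no
  Bayesian sharing model or incidence-based richness estimation is provided.
* Edit-distance networks treat all substitutions equally; biochemically
  weighted TCR distances are out of scope.
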