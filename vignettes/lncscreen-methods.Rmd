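---
title: "Methods: pan-cancer screening of driver-mutation associated lncRNA expression"
author: "lncscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-cancer screening of driver-mutation associated lncRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the approach

Recurrent somatic driver mutations (TP53, KRAS, NFE2L2, ...) reshape tumour
transcriptomes, and long non-coding RNAs are candidate downstream effectors
of those programs. Testing mutation–expression associations within a single
cancer type produces an abundance of hits of questionable relevance, because
strong expression subtypes co-vary with driver-mutation frequencies. The
screen implemented here takes the replication route instead: an association
between a driver event and a feature's expression is only called when it
reaches significance *independently in at least two cancer types, in the
same direction*. Error control then comes not from per-cancer multiple-testing
correction but from the multiplicative rarity of replicated chance hits,
quantified by rerunning the whole screen on mutation labels permuted within
each cancer type.

The pipeline stages, each an exported function group:

1. **Annotation** (`load_gene_models`, `build_lnc_catalogue`,
   `classify_genic_intergenic`, `neighbours`): parse GENCODE-style GTF,
   keep loci whose transcript biotypes all belong to {antisense, lincRNA,
   processed_transcript, sense_intronic, sense_overlapping, miRNA} with a
   mature length (max over isoforms of summed exon lengths) of at least
   200 bp, and split them into *genic* (span gap to the nearest coding
   gene < 5 kb, overlap counting as 0) and *intergenic*.
2. **Quantification** (`size_factors`, `fpkm_matrix`, plus the
   cohort-overview statistics): FPKM with robust median-of-ratios size
   factors.
3. **Genomic inputs** (`read_maf`, `mutation_status`, `select_events`,
   `map_copy_number`, `pam50_assign`): per-sample driver status, driver
   eligibility, gene-level copy-number amplitudes, centroid-correlation
   subtype assignment.
4. **Association screen** (`driver_screen`, `rank_sum_p`,
   `consistent_associations`): per-cancer two-sided Wilcoxon rank-sum tests
   with detectability and fold-change filters, then cross-cancer
   replication.
5. **Permutation null** (`permute_within_cancer`, `permutation_fdr`).
6. **Neighbour analysis** (`neighbour_dependency`, `genic_fraction`):
   does a proximal coding gene explain an lncRNA hit?
7. **Synthetic cohorts** (`sim_config`, `simulate_annotation`,
   `simulate_cohort`, `plant_targets`, `worked_example`): seeded generators
   with planted ground truth, so every stage is testable without external
   data.

## The core statistic

For feature $g$, driver event $e$ and cancer type $c$, samples split into
mutated ($n_1$) and wild type ($n_2$, $N = n_1 + n_2$). With mid-ranks
$R_i$ of the pooled FPKM values and $W = \sum_{i \in \text{mut}} R_i$:

$$
\mu = \frac{n_1 (N+1)}{2}, \qquad
\sigma^2 = \frac{n_1 n_2}{12}\left( (N+1) - \frac{\sum_k (t_k^3 - t_k)}{N(N-1)} \right),
$$

where $t_k$ are tie-group sizes, and the two-sided p-value uses the
continuity-corrected normal approximation

$$
z = \frac{\max(|W - \mu| - \tfrac12,\, 0)}{\sigma}, \qquad
P = \min(2\,\Phi(-z),\, 1).
$$

This matches the classical "approximate method" of rank-sum implementations
(`stats::wilcox.test(exact = FALSE, correct = TRUE)` reproduces it to
machine precision; the test suite also compares it against exhaustive
permutation enumeration at small group sizes). If all pooled values are
identical, $\sigma^2 = 0$ and $P = 1$.

The effect size is the pseudo-counted group ratio
$\log_2\!\big((\bar{x}_{\text{mut}} + 0.1)/(\bar{x}_{\text{wt}} + 0.1)\big)$,
with the 0.1 FPKM pseudo-count guarding against division by zero and
deliberately shrinking ratios of barely-expressed features toward zero.

A record **passes** in one cancer iff it is *detectable* (FPKM $> 0$ in at
least 10% of samples of **both** groups), $P < 0.001$, and
$|\log_2 \text{ratio}| > 1$. A (feature, event) pair is a **consistent
association** when passing records span at least 2 cancer types with a
common direction. The permutation FDR is the consistent-association count
after one within-cancer label permutation divided by the observed count
(guarded denominator $\max(\cdot, 1)$, flagged when the observed count is
zero).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `p` | 0.001 | — | per-cancer significance (uncorrected, strict `<`) |
| `lfc` | 1 | log2 | minimum absolute expression change (strict `>`) |
| `detect_frac` | 0.10 | fraction | detectability in both groups (inclusive `>=`) |
| `pseudo` | 0.1 | FPKM | pseudo-count for group ratios and log transforms |
| `min_group` | 3 | samples | smallest mutated/wild-type group tested |
| `min_replication` | 2 | cancers | replication requirement |
| `same_direction` | TRUE | — | direction coherence across supporting cancers |
| genic threshold | 5000 | bp | genic vs intergenic split |
| neighbour window | 100000 | bp | proximal coding-gene candidates |
| `indep_p` | 0.01 | — | independence line for neighbour dependency |
| `min_segment` | 10000 | bp | smallest copy-number segment used (inclusive) |
| `min_mean_fpkm` | 5 | FPKM | expression filter for DNA–RNA correlation |

## Design decisions on genuinely open points

Several operational details are not fixed by the screen's published
description; the package resolves them as follows and exposes each as a
parameter where reasonable.

- **5 kb boundary side.** "Within 5 kb" is read as strict proximity: a gap
  of exactly 5,000 bp is intergenic (`genic` requires distance
  `< threshold`).
- **Distance definition.** Span gap, strand-agnostic, 0 on any overlap —
  not TSS-to-TSS. The genic set is meant to contain antisense and intronic
  overlaps, which a TSS distance would misclassify. The same gap definition
  drives the 100 kb neighbour window.
- **Direction coherence.** `same_direction = TRUE` by default: a hit that
  goes up in one cancer and down in another is not treated as replicated.
  The flag exists because the replication rule could be read either way.
- **Minimum group size.** Cancers with fewer than 3 mutated (or wild-type)
  samples are skipped for that event and logged: below that the rank
  approximation is meaningless. Note that a mutated group of 3 can never
  reach $P < 0.001$ anyway (complete separation against 97 wild types
  gives $P \approx 0.0034$ under the approximation), so in a 100-sample
  cancer the smallest mutated group that can contribute a passing record
  has 4 samples; powerless combinations still appear in the record table
  with their computed p-values.
- **Detectability boundary.** Inclusive ($\ge 10\%$), with "detected"
  operationalized as FPKM strictly positive.
- **FPKM denominator.** The effective library size is
  `size_factor * mean(raw library sizes)`: robust normalization that stays
  anchored to the familiar FPKM magnitude. Size factors take the median of
  count-to-geometric-mean ratios on the ratio scale, over genes detected
  in every sample.
- **Permutation scheme.** Labels (not expression columns) are permuted,
  independently per event within each cancer; a `joint` mode (one sample
  permutation per cancer applied to all events) is available since the
  published description does not specify event coupling. One permutation
  replicate is the default, matching the single-shuffle null; `replicates`
  generalizes the estimate to a mean null count.
- **Strength cancer.** For the neighbour analysis, the cancer with the
  lowest lncRNA p among its passing records; ties break by cancer label.
  Candidate coding genes failing detectability there contribute no p-value
  (they cannot be "strongly associated").
- **Variant classes.** MAF strings map to a closed vocabulary
  (`maf_class_table()`); missense, nonsense, any indel and splice-site
  records qualify as mutated, silent and unknown classes never do.
  Gain-of-function subsets are caller-supplied predicates on those records.

## The synthetic cohort generator

`simulate_cohort` emulates exactly the statistical structure the screen
assumes. Expression of gene $g$ in sample $s$ of cancer $c$:

$$
\log_2 \text{FPKM}_{gs} = \mu_g + \delta_{gc} + \beta\, a_{gs}
 + \Delta_{ge}\,[\text{mutated}] + \varepsilon_{gs},
$$

with baselines $\mu_g \sim N(3, 2^2)$ (log2-FPKM), per-cancer profile
offsets $\delta_{gc} \sim N(0, 0.5^2)$, dosage slope $\beta = 0.5$ per
copy-number log-ratio unit, planted effects $\Delta$, and noise
$\varepsilon \sim N(0, 0.5^2)$. Defaults describe the study conditions of
the test suite: 6 cancer types x 100 samples, 400 coding genes, 2,000
lncRNAs (half genic), 10 driver events mutated in 10% of each cancer's
samples (drawn as exactly `round(freq * n)` samples, so planted cohorts
meet their stated mutated-group sizes while realized frequencies stay at
the configured value).

Key generator choices:

- **Counts are derived by inverting the FPKM formula** at randomized
  log-normal library sizes (mean 2e7, CV 0.2) and rounding — the pipeline's
  normalization is exercised, not bypassed.
- **Dropout** (probability 0.1) applies *after* planted effects, and only
  to genes with baseline log2-FPKM below 1 (~2 FPKM): zeros in bulk
  RNA-seq counts are a property of weakly expressed genes, and this keeps
  the detectability filter genuinely stressed without imposing zeros on
  well-expressed loci.
- **Mediation modes.** `direct` targets shift the lncRNA itself;
  `via_host` targets shift the designated coding host and tie the (genic)
  lncRNA to it through a shared latent factor at correlation 0.9, so the
  neighbour-dependency classifier is tested in both directions. The
  latent coupling is defined on the expressed (pre-dropout) scale.
- **Copy number** is one whole-chromosome segment per sample
  ($a \sim N(0, 0.3^2)$) plus sub-10 kb decoy segments that the mapping
  rule must ignore; gene-level truth is therefore known exactly.
- **MAF records** for mutated samples draw qualifying classes (missense /
  nonsense / frameshift / splice-site); wild-type samples receive silent
  decoy records at rate 0.05, which the class filter must discard.

What the generator does **not** emulate: read-level noise (counts are
rounded expectations, not Poisson/NB draws), batch effects, clonal
heterogeneity, subtype structure within a cancer type beyond the smooth
per-cancer offsets, correlated co-expression modules among null genes, and
focal copy-number events. Passing tests therefore demonstrate the
pipeline's statistical behaviour under its own model assumptions — not
robustness to every artefact of real tumour data. In particular the
confounding-by-subtype problem that motivates cross-cancer replication is
represented only through the per-cancer offsets.

## Numerical choices and degenerate inputs

- Ranks use mid-ranks; tie correction enters the variance; the continuity
  correction is floored so $|W - \mu| \le 0.5$ gives $P = 1$ exactly.
- All-identical values (zero variance) give $P = 1$, not an error.
- Equidistant nearest/neighbour ties break by smaller start coordinate,
  then lexicographic gene id — classification is deterministic.
- An lncRNA on a chromosome without coding genes has distance `Inf` and is
  intergenic; an isolated lncRNA is trivially "independent" in the
  neighbour analysis with missing best-neighbour fields.
- `size_factors` refuses matrices with no gene detected in every sample
  (the caller must pre-filter) rather than silently switching method.
- Observed consistent count 0 in the FDR guard: denominator `max(., 1)`
  with an explicit `degenerate` flag.
- Internally all coordinates are 0-based half-open; GTF and SEG readers and
  writers convert at the file boundary (both formats are 1-based inclusive
  on disk); BED export passes coordinates through unchanged.

## Problem sizes used by the test suite

The packaged tests run the full screen at the generator's default scale
(6 x 100 samples, 2,000 lncRNAs + 400 coding genes, 10 events; about 10 s
per screen on one core): a null cohort and a within-cancer permutation must
produce zero consistent lncRNA associations; a cohort with 20 planted
targets (|log2| = 3, two cancers each) must keep the permutation FDR within
0.005; planted-recovery sensitivity (>= 0.9, no false lncRNA features) and
the direct/via-host separation of the neighbour classifier (independent
rates >= 0.9 / <= 0.1) are asserted at 15 mutated samples per cancer.
Rank-sum accuracy is checked exhaustively against full enumeration for all
tie-free configurations at group sizes 3–8. The interval operations are
compared to $O(n^2)$ brute-force oracles on fixtures of up to 200 genes.
The shipped worked example (2 cancers x 20 samples, 10 features; see
`inst/extdata/worked_example/derivation.md`) pins the whole screen to
hand-computed ranks, z, p and ratios, byte-identically.

## A traceable miniature run

```r
library(lncscreen)
we <- worked_example()
fpkm <- fpkm_matrix(we$counts, we$gene_lengths)
status <- mutation_status(as_mutation_records(we$maf), we$event,
                          colnames(we$counts))
scr <- driver_screen(fpkm, we$sample_map, cbind(DRIVER1 = status))
scr
summary(scr)
scr$consistent
```

## Known limitations

- The screen inherits the published design's limits: no covariate
  adjustment, no within-cancer multiple-testing correction (replication is
  the control), and no causal direction between an lncRNA and its coding
  host — `neighbour_dependency` annotates dependence, it does not resolve
  causality.
- The normal approximation is inaccurate in the extreme tail at very small
  group sizes (see the enumeration comparison above); with `min_group = 3`
  the smallest groups the screen tests are exactly the regime where exact
  tests would differ most. Hits supported only by minimal groups warrant
  scrutiny.
- FPKM magnitudes depend on the mean-library-size anchor; cross-cohort
  comparisons should re-quantify jointly rather than mix outputs of
  separate runs.
- `pam50_assign` is a generic centroid-correlation assigner; it does not
  implement the published PAM50 gene list or preprocessing, and ties or
  zero-variance samples are handled by explicit convention (first subtype
  in column order with a warning / unassigned).
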