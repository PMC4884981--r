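---
title: "Models, parameters and design choices in lncprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in lncprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncprofiler)
```

This vignette documents the statistical models behind each stage, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the design choices made where the analysis
recipe left the design open.

## The analysis model

The pipeline assumes a genes × samples matrix of log2-scale intensities
from paired tumor/normal samples in several tissue types. Stages:

**Normalization.** Quantile normalization forces all samples within a
group onto the cross-column mean of order statistics; the default grouping
is *per tissue*, since arrays of different tissues were normalized
separately. A global mode is available via `grouping`. Ties are assigned by
first-occurrence rank, which keeps the "identical sorted columns"
postcondition bit-exact.

**Differential expression.** Per gene and tissue, a two-tailed Student's
*t*-test compares tumor and normal samples. The default is the unpaired
pooled-variance test (df `n1 + n2 - 2`): the recipe names "Student's
t-test" without pairing, though samples are paired, so a paired mode
(one-sample *t* on per-patient differences) is provided and tested.
Fold change is the linear ratio `2^(mean_T - mean_N)`, i.e. the ratio of
geometric means on the intensity scale. Calls require `FDR < alpha`
(default 0.05) **and** `FC > fc` or `FC < 1/fc` (default 1.5), both
strict. BH adjustment is applied separately within the PCG and lncRNA
strata of each tissue by default — the two universes were designed and
reported separately — with a pooled mode behind `stratify = FALSE`.
Zero-variance genes are reported `ns` with a warning, never dropped.
Common up/down sets are strict all-tissue intersections by direction.

**Genomic context.** Coordinates are 0-based half-open everywhere (BED
convention); the distance between disjoint loci is the gap length.
Classification priority is antisense (any opposite-strand locus overlap)
→ sense-exonic (same-strand exon overlap) → intronic (same-strand locus
overlap without exon overlap) → intergenic. Antisense-first mirrors common
lncRNA taxonomies; the recipe gives no priority, so it is configurable
(`antisense_first`). Intronic does not require full containment. Neighbor
semantics per class: nearest by boundary distance (intergenic; a
TSS-distance mode was considered and rejected to keep distances symmetric
and strand-free), maximal locus overlap on the opposite strand
(antisense), maximal same-strand overlap (intronic host), maximal exon
overlap (sense-exonic). Ties break by smaller distance then lexicographic
id. Unstranded lncRNAs can never be antisense; they are classified by
exon/intron overlap only and flagged.

**Guilt-by-association enrichment.** For each lncRNA, Pearson correlations
with all PCGs over *all* samples (tumor and normal, every tissue) are the
ranking weights. The enrichment score of a gene set is the signed maximum
deviation of `P_hit - P_miss`, where hits advance by `|r|^p / N_R` and
misses by `1/(N - N_H)`; the weight exponent defaults to `p = 1` (the
weighted statistic), with `p = 0` giving the classic KS form. Significance
uses **gene-set label permutation** (random same-size sets), not sample
permutation: sample permutation would require recomputing every
correlation per permutation and per lncRNA, which is intractable at
transcriptome scale, and gene-set permutation matches the reference tool's
`gene_set` mode. The deviation risk — gene–gene correlation structure is
ignored under this null — is accepted and documented here. `NES = ES /
mean(|perm ES| of matching sign)`; the nominal p is the same-sign tail
fraction, reported as `1/n_perm` with a flag when no permutation matches
the sign. Set-size filters default to [10, 500] after universe
intersection (5 in the pipeline's synthetic smoke configuration, whose
sets are smaller).

**ceRNA network.** lncRNA nodes default to the common DE set; a
whole-transcriptome mode (`all_lnc`) exists because the generator's planted
ceRNA lncRNAs are deliberately *not* common-DE (roles are mutually
exclusive). Coexpression edges require `r > 0.45` and `p < 0.01`, both
strict, computed over all samples. A minimal motif requires all of: both
targeting edges, the neighbor edge, and the coexpression edge — the
correlated-pair requirement is an interpretation (the published examples
all display correlated pairs) and is noted as such. Node and edge tables
are kept in canonical (type, id) order so construction is
order-independent.

**SOM tissue specificity.** Genes are observations, samples features;
median-centered log2 values are the training input (matching the
clustering preprocessing), while unit/tissue summaries use the uncentered
values so absolute expression level is meaningful. The SOM is *batch*
(deterministic given the seeded initialization, which draws prototypes
from the data rows): each epoch assigns BMUs, then every prototype becomes
the Gaussian-neighborhood-weighted mean of all observations, with the
neighborhood width decaying linearly from `max(rows, cols)/2` to 0.5 over
50 epochs (defaults). The default grid is 13 × 9 = 117 hexagonal units,
consistent with unit numbering beyond 104 in the motivating analysis;
tests use smaller grids scaled to their gene-panel sizes. A unit is called
tissue-specific when its tissue mean exceeds every other tissue's mean by
`delta` (default 1.0 log2) **and** a one-sided Wilcoxon test of per-sample
unit means (tissue vs rest) has `p < alpha`; the margin-plus-rank-test
rule is this package's formalization of "higher overall expression in one
tissue" — the original selection was visual, so both knobs are exposed.

## The synthetic world

The generator states one fixed world; its defaults are not tuned to tests.

* **Design**: 4 tissues with 20/20/16/20 patient pairs (tumor + normal per
  patient), log2 baseline 8, homoscedastic Gaussian noise SD 0.5 (a
  per-gene SD hook exists because real arrays are heteroscedastic — the
  recipe is silent on this, so the default is the simpler model).
* **Annotation**: one synthetic chromosome; three-exon PCGs in regular
  slots (10 kb loci, 6 kb gaps) so that hosted and intergenic lncRNA
  placement is feasible by construction, with an explicit packing error
  otherwise. Class mix defaults to 45/25/15/15% with intergenic largest,
  matching the observed ordering of subgroup sizes.
* **Planted roles** (mutually exclusive per gene): common-DE genes shifted
  ±1.5 log2 in tumor samples of *all* tissues; tissue blocks elevated 2.0
  log2 in *all* samples (tumor and normal) of one tissue — tissue
  specificity is a property of the tissue, not the disease; cis pairs
  sharing a per-sample latent factor `f ~ N(0,1)` with loading
  `a = sd * sqrt(r/(1-r))`, so the model correlation is exactly
  `a^2/(a^2 + sd^2) = r` (target r defaults to 0.8; `r = 1` uses unit
  loading and converges to 1 as the noise vanishes); ceRNA triples are cis
  pairs whose two members are both targeted by a dedicated miRNA in the
  generated target table (background target edges are i.i.d. Bernoulli at
  rate 0.01 over a 100-miRNA universe).

The generator does **not** emulate probe-level spatial artifacts,
background subtraction, batch effects, heteroscedasticity (by default),
patient random effects, or sequence-level miRNA binding. A green recovery
test therefore establishes that each stage inverts its own generative
assumption at the stated effect and noise sizes — not that the pipeline is
robust to real-array pathologies upstream of its inputs.

One emergent (unplanted) property is worth knowing: common-DE lncRNAs
whose neighbor PCG is DE in the same direction acquire a genuine
expression correlation through the shared tumor shift, so coexpression
edges beyond the planted cis pairs are expected in DE-bearing worlds.

## Numerical choices

* Strict inequalities at every published threshold (`FC > 1.5`,
  `r > 0.45`, `p < 0.01`, `FDR < 0.05`).
* Quantile normalization resolves ties by first-occurrence rank; identical
  input columns are a fixed point.
* Even-length medians use the midpoint convention.
* Agglomeration is delegated to `stats::hclust` (complete linkage), which
  is deterministic for a fixed distance matrix; merge heights are verified
  against an O(n³) re-implementation in the tests.
* BMU ties go to the lowest unit id; degenerate t-tests (zero variance)
  return `t = 0, p = 1` with a warning.
* All randomness flows through per-stage seeds derived from one root seed
  and recorded in the run manifest; reruns are byte-identical.

## Known limitations

* Gene-set permutation understates between-gene correlation under the
  null; nominal p-values are calibrated against random sets, not against
  sample relabeling.
* The plain t-test has no variance moderation by design (the reference
  analysis used none); small-n tissues pay the usual power cost.
* Gene-level loci only; no transcript isoform resolution.
* The SOM grid size, epochs and selection margin are declared defaults,
  not inferred values — the original analysis did not state its training
  parameters.
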