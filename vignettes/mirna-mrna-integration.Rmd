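---
title: "Calling anticorrelated miRNA/mRNA pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling anticorrelated miRNA/mRNA pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpairs)
```

## The model

`mirpairs` operationalises a simple regulatory hypothesis: a miRNA that
is dysregulated in rheumatoid arthritis (RA) synovial fibroblasts
represses its target mRNAs, so a *bona fide* target should move in the
direction opposite its miRNA. With no paired per-sample miRNA/mRNA
measurements available, "negatively correlated" here means **direction
opposition**, not a sample-level correlation coefficient: a (miRNA,
gene) pair is called anticorrelated iff

> sign(gene log2 fold change in RA) = −direction(miRNA),

with direction(miRNA) ∈ {up = +1, down = −1} taken from a
literature-curated table of 14 RASF-dysregulated miRNAs (bundled, with
per-source predicted-target counts and legacy identifiers).

Candidate genes must clear four gates before pairing:

1. **Consensus prediction.** A gene counts as a predicted target only if
   both prediction sources call it. One curated miRNA has no record in
   the first source; for it the second source is used alone
   (`used_fallback` flag). The overlap of the two sources can be tested
   for significance with `overlap_significance()` (one-sided
   hypergeometric / Fisher; the universe is an explicit argument, since
   printed overlap p-values are unrecoverable without knowing the
   background the original computation used).
2. **Differential expression.** Per series, |logFC| ≥ 1 (2-fold,
   inclusive boundary) and p < 0.05 (strict inequality). The inclusive
   fold-change boundary matters: several published relaxed-tier records
   sit at 1.011–1.015.
3. **Control-vs-control removal.** Genes also differentially expressed
   between the two control groups (osteoarthritis vs healthy) are
   shared-arthritis signature, not RA biology, and are removed. This
   runs after DE filtering and before the consistency filters — the
   original protocol does not state the order; this placement removes
   confounders from exactly the set they could contaminate.
4. **Consistency across series.** Strict tier: every series; relaxed
   tier: at least one qualifying series, no sign conflict among
   qualifying series. Sub-threshold disagreement is ignored in the
   relaxed tier: a gene at +1.6 in one cohort and −0.4 in another still
   qualifies, matching the published record tables. p-values are *not*
   re-enforced inside the consistency filters (several published
   strict-tier rows carry p ≈ 0.13–0.29 in one series); when the
   pipeline runs from raw matrices, significance filtering happens
   upstream in gate 2, and `select_candidates(enforce_p = FALSE)` is the
   mode for curated record tables that were already filtered upstream.

Genes targeted by several miRNAs keep each concordant edge and drop each
discordant edge independently; a gene is dropped only when no concordant
miRNA remains.

## Statistical choices

* **Test statistic.** Welch's unequal-variance *t* with
  Welch–Satterthwaite degrees of freedom, two-sided, no direction prior.
  The original microarray analyses used a web-service moderated *t*;
  without the underlying raw cohorts those printed p-values are not
  reproducible, and the pipeline needs only a *calibrated* two-group
  test. The suite verifies type-I error ∈ [0.035, 0.065] at α = 0.05
  over ≥ 10 000 null gene-tests.
* **Multiple testing.** Benjamini–Hochberg step-up (`bh_adjust()`), the
  standard reading of "FDR-adjusted p-value".
* **RNA-seq fold change.** Ratio of group *mean* FPKM with pseudocount 0
  by default — this reproduces the published FPKM-based logFC values
  exactly from the printed group means (14 of 15 rows within one unit in
  the third decimal; the one exception was evidently computed upstream
  from unrounded FPKM). The Welch test on RNA-seq series runs on
  log2(FPKM + 1), which stabilises low-coverage genes without touching
  the reported fold change. For very sparse data pass a positive
  `pseudocount` to `run_de()`.
* **Enrichment.** Plain upper-tail hypergeometric over user-supplied GMT
  collections with BH across tested terms; terms with zero list overlap
  are untested and excluded from the BH denominator. The original
  annotation service's modified Fisher statistic (and its database
  versions) is out of scope, so published enrichment p-values are
  treated as fixtures, not reproduction targets.

## The synthetic cohorts

The generator emulates the study design the inference assumes, with
every parameter in `sim_config()`:

* **Microarray kind**: per-gene baseline log2 means ~ U(6, 12); i.i.d.
  Gaussian noise (`noise_sd`, default 0.5) per observation; true targets
  shifted by ±`effect_delta` (default 1.5) in RA only, sign opposite the
  miRNA's direction; a designated arthritis-signature subset
  (`n_fp_signature`, default 50) shifted by `shared_oa_hc_delta` in both
  RA and OA. Gaussian-on-log2 is the standard field model for arrays.
* **RNA-seq kind**: negative-binomial fragment counts
  (`size = 1/nb_dispersion`) around the exponentiated group means scaled
  by gene length and library size, converted to FPKM. Only RA and HC are
  generated, matching the sequencing cohort design (the published
  sequencing comparison had 2 RA vs 2 HC; the generator defaults to
  10/group so that recovery statements are about the method, not about
  an underpowered n = 2).
* **Prediction sources**: each true target enters each source with
  probability `db_sensitivity` (default 0.9); Poisson(`db_fp_rate`)
  decoys per miRNA per source; the curated miRNA lacking a first-source
  record is omitted from source A to exercise the fallback. Signature
  genes are deliberately planted in *both* sources — without this the
  control-vs-control filter would never face a confounder that survived
  the consensus gate, and the filter's efficacy would be untested.
* **Determinism**: every generator seeds its own RNG sub-stream from
  (master seed, label), so identical configurations are bit-identical
  and adding a generator never perturbs another's draws. The truth
  (target assignment, baselines, gene lengths) is its own sub-stream, so
  all series generated from one config share one ground truth.

Defaults are the conditions the validation suite runs under: 1000 genes,
10 samples/group, effect_delta 1.5, noise_sd 0.5, db_sensitivity 0.9.
`shared_oa_hc_delta` defaults to 2.0 (4-fold): the shared signature is
modelled as a *clearly detectable* confounder, which is the regime in
which the control-control filter is meaningful — at that effect size a
signature gene that passes the RA/HC filter fails to be removed with
probability ≈ 10⁻⁵, so "every detected confounder is removed" is a
property of the design, not of a lucky seed.

**What the simulation does not model:** batch effects, platform
differences within a series, correlated genes, paralogy, multi-miRNA
targets (truth target sets are disjoint; multi-miRNA genes are exercised
through the curated record fixtures instead), or read-level artefacts.
Passing recovery tests therefore show the cascade's logic is correct
under its own assumptions — not that real cohorts satisfy those
assumptions.

**Recovery metrics.** `evaluate_recovery()` reports sensitivity against
the *recoverable* truth — true targets present in the consensus map the
pipeline ran with. Targets the simulated catalogues failed to carry
(probability 1 − 0.9² = 0.19 per target per source pair at the default
sensitivity) are misses of the prediction step, which the cascade
consumes as given; counting them would measure the simulated databases,
not the selection logic. The false-discovery proportion counts all
called genes that are not true targets, with no such allowance.

## Numerical conventions and degenerate inputs

* Written tables round to 3 decimals, the precision of the curated
  records; readers reject any non-numeric cell, duplicate identifier or
  unlabelled sample by name (file + line), with no silent coercion.
* `fpkm_log_ratio(0, 0, pseudocount = 0)` is an error (undefined ratio);
  `welch_test()` rejects groups of fewer than 2 values and zero variance
  in both groups; `overlap_significance()` enforces the feasibility
  bounds of the 2×2 table.
* Ties and order: all outputs are sorted by gene (pair tables) or
  lexicographically (network serialisations), making every artefact
  byte-stable under permutation of the inputs; enrichment sorts by p
  with term-id tie-break.
* `select_candidates()` run with a single series degenerates the strict
  tier to the relaxed rule (with one series the two coincide);
  `strict_consistency()` itself requires ≥ 2 series.

## Problem sizes in the validation suite

The suite validates calibration on 5 × 2000 null genes (10 000 Welch
tests), exhaustively enumerates hypergeometric tails for universes up to
N = 15, compares BH against an independent step-up evaluation on 1000
random vectors, and runs the full simulated pipeline at the default
1000-gene configuration — sizes chosen so the whole suite runs in well
under a minute while keeping Monte-Carlo error far from every asserted
bound.

## Known limitations

* Direction opposition is a weak proxy for repression; without paired
  miRNA measurements, genuinely co-measured anticorrelation is out of
  reach.
* The published microarray p-values and DEG counts are not reproducible
  from the shipped fixtures (they require the raw cohort data and the
  original service's moderated test); the fixtures record them verbatim.
* Gene identifiers are matched exactly (official symbols, case
  sensitive, whitespace trimmed); no symbol-history service is included,
  and legacy symbols in the curated records are kept as printed.
* The consensus universe for overlap testing defaults to the union of
  both sources' genes; any claim about overlap significance is relative
  to that choice.
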