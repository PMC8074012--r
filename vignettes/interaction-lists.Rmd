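---
title: "Directional gene-list algebra for treatment-by-insult designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional gene-list algebra for treatment-by-insult designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirlists)
library(dplyr)
```

## The question the pipeline answers

A neuroprotectant such as magnesium sulfate (Mg) given before a neonatal
hypoxic-ischemic insult (HI) could act in several qualitatively different
ways on brain transcription: it may have its own effects that persist or
vanish under the insult, it may *reorient* the insult response (effects that
appear only in pretreated animals), it may *reverse* or *amplify* insult
effects, or it may leave parts of the insult response untouched. Telling
these apart requires more than one differential contrast — it requires a
bookkeeping algebra over *directional* gene lists from a factorial design:

* experiment 1 — Mg vs Ctrl, two-color arrays at 1.5 h, 3 h, 6 h, 12 h, 24 h;
* experiment 2 — MgHI vs HI, two-color arrays at 3 h and 12 h after insult;
* experiment 3 — HI vs Ctrl, two-color arrays at the same two timepoints;
* a one-color comparison of MgHI against the pooled control channels of
  experiments 1 and 3.

Three replicate arrays per contrast and timepoint. Each two-color array
yields one log~2~ ratio per probe; the one-color route compares normalized
single-channel intensities across arrays. All inputs are assumed LOWESS- or
equivalently normalized upstream; the package works at the normalized log~2~
scale throughout.

## From probes to calls

**Probe QC.** A spot cell (probe x contrast x timepoint) is discarded when
any replicate spot carries a non-uniformity flag. One-color cells must
additionally show signal *strictly* above `detection_factor` (default 2)
times the local background in at least `min_detected` (default 2) of the
replicates; boundary equality fails, a deliberate literal reading of
"above". Two-color ratio data carry no background and are filtered on
uniformity alone. Probes without a validated gene symbol (Riken clones,
array controls) are excluded before any statistics.

**Per-timepoint statistics.** Two-color contrasts use the classical
one-sample t against zero on the replicate log-ratios (df = n - 1,
two-sided). The one-color comparison uses a pooled-variance two-group t
(Welch switchable) on log~2~ intensities, MgHI (n = 3) against pooled Ctrl
(n = 6). Benjamini-Hochberg adjustment is applied across genes *within*
each contrast x timepoint, because lists are extracted per timepoint;
adjusting globally would couple unrelated test families. Zero-variance
degeneracies do not crash batch runs: a constant zero vector gives p = 1, a
constant nonzero vector p = 0 with a `degenerate` flag.

**Calling rule.** The default `union` rule calls an entity when
|FC| >= 2 *or* BH-adjusted p <= 0.05 (configurable to `intersection` or
`p_only`; the threshold p column is also configurable). The union rule is
the permissive historical convention for these designs; `intersection` is
provided because FC-alone calls at n = 3 carry no error control.

**Multi-probe genes.** Per gene x contrast x timepoint the probe with the
largest |mean log~2~ ratio| represents the gene; ties break to the
lexicographically smallest probe id so reruns are identical. Probe choice
is made per contrast x timepoint, not globally, consistent with
per-timepoint list extraction (the alternative global choice is not
implemented; a gene strongly responsive in one contrast would otherwise
impose a poorly measuring probe on another). When two significant probes of
one gene disagree in direction at one timepoint — the signature of
transcript-variant (splice) divergence — the gene is flagged and carried in
*both* direction lists.

**Merging over time.** A gene enters a contrast's merged list when called
at one or more timepoints, in either direction; genes called in opposite
directions at successive timepoints are flagged biphasic and keep both
entries. The peak timepoint (most called genes) and per-gene kinetics are
retained for reporting.

## The set algebra

Writing L1, L2, L3 for the merged two-color lists of experiments 1-3 and L7
for the merged one-color list, all directional:

* **A** = L1: every proper treatment effect.
* **A1** = same-direction overlap of L1 and L2: treatment effects unchanged
  by the insult.
* **B1** (de novo) = (L2 genes absent from L3) + (opposite directions in L1
  and L2) + L7, minus A1, minus the insult-confirmed list (below).
* **B2** (reversed) = (opposite directions in L3 and L2) + (L3 genes whose
  one-color comparison is *equivalent*), minus A1 — reported under the
  direction of the treatment modulation, i.e. opposite to the insult
  direction.
* **B3** (amplified) and **C** (insensitive) partition the
  "insult-confirmed" list L11 = same-direction overlap of L3 and L7: an
  entry is amplified when L2 is also called with the insult's sign (L2 is
  the only contrast that directly tests MgHI against HI, so it carries the
  amplification evidence), insensitive otherwise. B3 additionally removes
  A1 genes.
* **B** = B1 + B2 + B3, asserted disjoint.

Three constructions deserve justification because the design was genuinely
open:

*Equivalence, not non-significance.* "No difference in the one-color
comparison" is operationalized as a band — raw p > 0.05 **and**
|mean log~2~ difference| < log~2~(1.5) at *every* one-color timepoint, with
an incomplete timepoint record disqualifying the gene. Mere absence of
significance would label every noisy or undetected gene "unchanged";
absence of data is not evidence of absence of difference.

*A1 subtraction is gene-level.* B2 entries carry the flipped
(treatment-modulation) direction, so an entry-level match against A1's
(L1 = L2)-direction entries would silently fail to subtract. A gene whose
treatment response is insult-independent is excluded from B wholesale.
The L11 subtraction inside B1 stays entry-level since those directions are
commensurate.

*B1 is subordinate.* At finite noise a truly reversed gene occasionally
also picks up a spurious one-color call and would enter B1 via the
one-color route while sitting in B2 via the direct two-color evidence
(about 1 gene in 1000 at the default noise level). B2 and B3 rest on
direct two-color contrasts; B1's one-color route is the weakest evidence.
Entries claimed by B2 or B3 are therefore removed from B1 before
concatenation, which makes the sub-lists disjoint *by construction* and
lets `build_list_b()` keep disjointness as a hard assertion rather than a
hope.

Classification assigns each (gene, direction) entry one category with
precedence B1 > B2 > B3 > C > A1 > A (the B/C categories are asserted
pairwise disjoint first, so precedence only arbitrates the benign overlap
of a B entry with membership in A), and records every list that fired as
provenance. Genes in no list are `unaffected`.

## Enrichment and regulator statistics

Over-representation is direction-blind: a query list is flattened to genes
and each gene set scored by the hypergeometric right tail (Fisher exact),
the EASE score (the same tail with the overlap jackknifed by one — overlaps
of 0 or 1 score p = 1, so single-gene coincidences cannot drive a result),
and fold enrichment (k/n)/(K/N). Bonferroni is taken over the collection,
FDR is BH over the collection. Two filter profiles mirror common practice:
`keyword` (k >= 10 and Bonferroni p < 1e-4, or EASE p < 1e-4 with FE > 2)
and `pathway` (k >= 10, Bonferroni p < 0.05, FDR < 10%). The universe
defaults, in the pipeline, to the genes that survived QC — the detected
background — rather than the whole annotation; testing against genes that
could never have been called inflates enrichment.

The regulator statistic is the unweighted sign-consistency z-score on a
signed regulator-to-target network: with the gene's observed direction
coded +1/-1 and the edge sign +1/-1, an edge is consistent under
hypothesized activation when their product is positive, and
z = (n~consistent~ - n~inconsistent~) / sqrt(n~total~). z > 2 predicts
activation, z < -2 inhibition, strictly — z = -2 exactly is undetermined.
Genes carried under both directions are ambiguous and excluded from the
consistency count. A Fisher right tail on the target overlap accompanies
the z. Ontogeny concordance labels each effect `anticipating` when it
matches the gene's spontaneous developmental direction and `antagonistic`
otherwise.

## The synthetic generator

`simulate_experiment()` emulates the full design with a planted class per
gene: `null`, `mg_only` (treatment wave over the middle experiment-1
timepoints, vanishing under the insult), `hi_only` (single-timepoint insult
effect, unchanged by treatment), `de_novo`, `reversed`, `amplified`,
`insensitive`, `biphasic` (opposite directions at successive timepoints)
and `splice_discordant` (exactly two probes with opposite effects at one
timepoint). Effects are ±`effect_size_log2` (default 2, i.e. four-fold;
amplified genes reach twice that in MgHI vs Ctrl); signs alternate within a
class so both directions are exercised. Every spot is effect plus i.i.d.
normal noise (`noise_sd_log2`, default 0.25 — a typical replicate sd for
well-normalized two-color ratios). Class quotas are deterministic
largest-remainder allocations by default so recovery tests are exact; a
multinomial switch exists.

One-color intensities are a per-probe log~2~-uniform baseline between 10.5
and 14.5 shared across groups (so pooling control channels across
experiments is well-defined) plus the group effect plus noise. The baseline
floor sits far enough above twice the default background (30 linear units)
that even a four-fold repression cannot cross the detection threshold on
its own: which probes fail detection is controlled entirely by the artifact
model, not by an interaction between baseline and effect draws.

Artifacts: non-uniformity flags are Bernoulli per spot
(`frac_low_quality`, default 2%); detection failures are *probe-level* —
all one-color spots of a chosen fraction of probes (default 2%) are pushed
to at most twice their background — because lack of detection is a property
of a transcript's abundance, while a lone background-level spot on a bright
probe is a uniformity failure, which the spot-level flag already models.
Every altered spot is recorded so QC recovery is checkable exactly.

What the generator does *not* emulate: dye bias, spatial array effects,
intensity-dependent variance, cross-hybridization, correlated noise between
the two channels of one array (ratio and intensity noise are independent
draws), and pooling of biological material into arrays. Passing tests
therefore demonstrate the correctness of the statistics and the algebra
under clean factorial noise, not robustness to microarray pathology.

## Numerical conventions

* FC is signed: sign(mean log~2~ ratio) x 2^|mean|; |FC| >= 2 is
  equivalent to |mean log~2~| >= 1.
* Quartiles use linear interpolation (R type 7); amplitude summaries print
  repressions as negative values and compare |FC| distributions between
  directions with a two-sided Wilcoxon rank-sum test.
* Reported percentages are rounded half away from zero to one decimal.
* Reported distinct totals satisfy distinct = induced + repressed - dual.
* BH is `stats::p.adjust`; the t CDF is `stats::pt`; the hypergeometric
  tail is `stats::phyper`. Test oracles recompute tails by explicit
  binomial-coefficient summation, independent of `phyper`.
* All randomness flows from the single configuration seed
  (`withr::local_seed`); identical configurations reproduce identical TSV
  bytes.

## Problem sizes used by the test suite

The suite exercises: noiseless recovery on 600 genes across all nine
classes (must be exact); noisy recovery on 2,000 genes at the default
conditions (|log~2~ FC| = 2, sd 0.25, n = 3; at least 90% of planted
non-null genes must receive their class, with QC artifacts active);
false-discovery calibration on 100 seeded replicates of 2,000 genes with
10% non-null; and Fisher/EASE equivalence to exhaustive summation over
every (k, n, K, N) with N <= 60 (about one million tuples). These sizes
give binomial standard errors comfortably inside the asserted margins while
keeping the full suite around two minutes.

## Known limitations

* The equivalence band (p > 0.05, |mean| < log~2~ 1.5) is a pragmatic
  default, not a calibrated TOST procedure; its two knobs are exposed.
* Variance is estimated per probe at n = 3 with no moderation; the t at
  df = 2 is heavy-tailed, which the union rule partly compensates by the
  FC arm. Empirical-Bayes moderation is deliberately out of scope.
* The one-color pooling of control channels assumes the two experiments'
  one-color normalizations are comparable; nothing in the package checks
  that assumption.
* Enrichment treats gene sets as flat; no term hierarchy, redundancy
  clustering, or semantic grouping is attempted.
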