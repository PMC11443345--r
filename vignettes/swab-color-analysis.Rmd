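---
title: "Swab color as a proxy for rumen-microbiome capture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swab color as a proxy for rumen-microbiome capture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Oral swabs collect the remnants of regurgitated rumen contents from a cow's
mouth and can therefore stand in for invasive rumen sampling in herd-scale
microbiome studies. Swabs, however, vary visibly in color — from near-white to
dark brown — depending on how much rumen material was present at collection
time. swabshade implements the analysis chain needed to ask, quantitatively,
whether darker swabs capture the rumen community better: an objective
colorimetric darkness score for swab photographs, darkness-based
stratification of swabs, and the standard community-ecology comparison
battery against rumen solid- and liquid-fraction reference samples.

## Darkness scoring

A trimmed swab photograph is reduced to one number in three steps:

1. **Center crop.** The 100 × 100 px block centered on the image is
   extracted (top-left corner at `floor(H/2) - floor(size/2)`, so odd
   dimensions are handled deterministically). The block is assumed to be
   swab material; segmenting the swab out of a raw photo is out of scope and
   must happen upstream.
2. **Grayscale.** ITU-R BT.601 luma, `Y = 0.299 R + 0.587 G + 0.114 B`. Luma
   is kept in floating point rather than rounded to 8 bits: rounding shifts
   scores by less than 0.002 but would break exactness, and nothing
   downstream needs 8-bit luma.
3. **Darkness.** `1 - mean(Y)/255`, so 0 is pure white and 1 pure black.

The score is invariant under 180° rotation of the photograph, monotone
(non-increasing) under uniform brightening, and exactly `1 - v/255` on a flat
image of intensity `v` — the properties the test suite asserts.

## Normalization of the ASV table

The pipeline starts from a samples × ASVs count table. In order:

* **Taxon removal** — chloroplast (Order), mitochondrial (Family) and
  archaeal (Kingdom) ASVs are dropped, the usual 16S cleanup.
* **Rarefaction** — every sample is subsampled without replacement to a
  common depth (default 7,000 reads; 2,800 is the analogous choice for ITS
  fungal data). Samples below the depth are dropped and logged. Rarefaction
  precedes filtering because the minimum-count rule is defined on the
  rarefied scale.
* **Minimum-count filter** — any cell with fewer than 10 reads is set to
  zero. The rule is deliberately *cell-wise*: an ASV a sample cannot support
  with at least 10 reads is treated as absent from that sample, while the
  same ASV may remain present in deeper samples. A table-wide reading
  (drop an ASV everywhere unless some sample reaches 10) was considered and
  rejected; presence/absence-based statistics (prevalence, capture) need the
  per-sample interpretation to mean "detected with confidence in this
  sample". The filter is idempotent.
* **Relative abundance** — per-sample proportions, used for Bray-Curtis,
  SIMPER and the differential tests.

## Darkness groups

Two stratifications are built from the swab darkness ranks (ties broken
lexicographically by sample id, so assignment is deterministic and
auditable):

* **Deciles** — ranks split into 10 contiguous blocks as equal as possible;
  when `n mod 10 > 0` the extra members go to the lightest blocks. Labels
  run `Tenth` (lightest) to `Hundredth` (darkest).
* **Extremes** — the `k` lightest (`Low`), the `k` darkest (`High`), and the
  `k` swabs whose ranks are centered on the median rank
  (`floor((n-k)/2) + 1` through `floor((n-k)/2) + k`, `Mid`). The default
  `k = 13` pins the swab group size to the rumen reference group size so all
  compared groups are even. Mid is *rank*-centered, not centered on the
  midpoint of the darkness value range; with skewed score distributions the
  two differ, and the rank definition keeps group size exact by
  construction.

## Diversity, ordination and tests

Alpha diversity per sample: bias-corrected Chao1
(`S_obs + F1(F1-1) / (2(F2+1))`), Shannon entropy in nats, and inverse
Simpson. These satisfy the Hill-number ordering
`inv_simpson <= exp(shannon) <= S_obs <= chao1`, which the suite checks on
random tables.

Beta diversity: Bray-Curtis `sum|x-y| / sum(x+y)` (the default), quantitative
Jaccard `2B/(1+B)`, binary Jaccard on supports, and unweighted UniFrac
(fraction of branch length leading to leaves present in exactly one of the
two samples). Which Jaccard dialect a given study means is often
underspecified; both are provided and the quantitative form is the default,
matching the common ecology-toolchain behavior.

PCoA is the classical Gower double-centering of `-D²/2` with a symmetric
eigendecomposition. Negative eigenvalues (expected for Bray-Curtis, which is
not Euclidean-embeddable) are reported but excluded from the
variance-explained denominator and never scaled into coordinates. Axis signs
are fixed by making the largest-magnitude loading positive, so runs are
reproducible.

PERMANOVA uses the one-factor pseudo-F from total and within-group sums of
squared distances, with p-values from seeded label permutations and the
add-one rule (`p = (1 + #{F* >= F}) / (1 + n_perm)`), so p is never exactly
zero. For six or fewer samples an exhaustive mode enumerates all label
orderings and returns the exact permutation p. If every pairwise distance is
zero the statistic is undefined and the test returns `p = 1` with a message.

Relationships between darkness and community structure are tested three
ways, mirroring how such studies report them: an OLS regression
`darkness ~ Axis1 + Axis2` with per-axis t tests; Spearman correlations of
darkness against the mean Euclidean distance, in the first two PCoA axes,
from each swab to every rumen solid (or liquid) sample; and Kruskal-Wallis
with pairwise Wilcoxon/Benjamini-Hochberg follow-ups for group contrasts.
The distance-to-reference is measured in the plotted 2-axis plane by default
because that is the space in which the ordination is interpreted; the number
of axes is a parameter (`reference_distance_axes`) for users who want the
full embedding. All nonparametric tests are thin wrappers over the stats
package (`kruskal.test`, `pairwise.wilcox.test` with `fdr`, `cor.test`
Spearman with the t approximation, `p.adjust` BH); the pipeline always takes
the nonparametric branch rather than gating on a normality pre-test.

## Differential ASVs and core capture

SIMPER decomposes each between-group Bray-Curtis dissimilarity into exact
per-ASV terms `|x_ij - x_ik| / sum_i(x_ij + x_ik)` and averages over
between-group pairs; contributions are non-negative and sum to one, and the
pair-averaged total equals the mean between-group dissimilarity (asserted to
1e-10). ASVs contributing strictly more than 1% are tested per-ASV with
Kruskal-Wallis on relative abundances, BH-corrected *within the surviving
set of that comparison* — matching per-comparison reporting; correcting
globally across comparisons is a caller-side choice, since the gated sets
are assembled per contrast. Direction is the group with the higher median
relative abundance.

Core capture: an ASV is "highly prevalent" in a rumen fraction when its
prevalence there is strictly above the threshold (0.8 for bacteria; 0.5 is
the conventional relaxation for sparser fungal data). Presence means a
nonzero count in the rarefied, minimum-count-filtered table — i.e. at least
10 reads before filtering — so prevalence and capture inherit the filter's
"confidently detected" semantics. Each swab's capture percentage is the
share of the prevalent set it contains, and its Spearman correlation with
darkness is the headline statistic of the whole analysis. SIMPER and the
per-ASV tests run on relative abundances of the rarefied, filtered table;
the input scale is configurable because conventions differ, but proportions
are the default since Bray-Curtis decomposition is scale-sensitive.

## The synthetic-data generator

Because the analysis targets a sampling design (hundreds of swabs, ~a dozen
each of rumen solid/liquid references) whose raw data cannot be regenerated
at a desk, the package carries a generator that emulates the design's
statistical structure end to end:

* **Four source pools** (rumen solid, rumen liquid, oral, environmental)
  over a shared ASV universe, each with log-normally ranked base
  proportions (log-SD 1.5, a typical rank-abundance steepness). Solid and
  liquid share half their ASVs by default — overlapping but distinct
  communities — while oral/environmental pools are disjoint from them.
* **Swab mixtures.** Each swab has a rumen fraction `alpha ~ Beta(2, 2)`;
  its expected composition is
  `alpha (0.5 solid + 0.5 liquid) + (1 - alpha)(0.7 oral + 0.3 env)`;
  counts are Dirichlet-multinomial (concentration 100) at a log-normal
  depth around 30,000 reads with log-SD 1, so a realistic minority of
  samples falls under the 7,000-read rarefaction depth and is dropped.
  The 0.7/0.3 oral:environmental split is a modeling choice, not an
  empirically supported ratio; it is configurable.
* **Darkness link.** `darkness = clip(0.35 + 0.39 alpha + N(0, 0.02))`,
  spanning roughly 0.35–0.74 — the realistic range for TMR-fed cows — with
  noise small enough that darkness remains a faithful alpha proxy.
* **Matching photographs.** `render_swab_image()` produces a flat-gray
  image at `255(1 - darkness)` plus Gaussian texture (SD 10 by default),
  closing the loop so the colorimetry module is exercised by the same
  synthetic studies.
* **Ground truth.** Per-swab alpha, per-ASV source labels, and the planted
  differential set: ASVs whose expected relative abundance differs by at
  least 2 percentage points between the pure rumen mixture (`alpha = 1`)
  and the pure oral/environmental mixture (`alpha = 0`). The margin marks
  the effect size a 13-vs-13 rank test behind a 1% SIMPER gate is powered
  to detect. Because the pools are source-exclusive, *every* abundant ASV
  differs somewhat between light and dark swabs; ASVs with sub-margin but
  nonzero effects are therefore neither counted as planted (for
  sensitivity) nor as false discoveries (for FDR) — the standard
  three-zone convention in simulation benchmarks. FDR *control* of the
  differential caller is verified separately on label-permuted data, where
  the global null actually holds.

All randomness flows through explicit seeds; the same design and seed
reproduce every output file byte for byte, and each written TSV records the
seed in a header comment.

What the generator does **not** emulate: read-level error or chimera
structure, taxonomy-assignment uncertainty (its taxonomy labels are
synthetic, drawn from fixed rumen/oral/environmental genus pools so that
taxonomy-dependent code paths run), compositional correlations between ASVs
beyond the Dirichlet covariance, or time/cow-level covariates. Passing tests
therefore certify the statistical machinery and the planted-signal recovery,
not biological conclusions about any real herd.

## Validation problem sizes and numerical choices

The suite validates metrics against independent implementations (vegan, ape)
and brute-force oracles on 1,000 random tables of up to 10 × 12 and 100
random 8-leaf trees (agreement to 1e-10/1e-12); PCoA against exact
Euclidean configurations (1e-8); PERMANOVA type-I error over 1,000 null
simulations at 199 permutations (accepting 0.03–0.07 at nominal 0.05) and
against exhaustive enumeration at n = 6; and the full planted-signal
recovery on one default study of 402 swabs + 13 liquid + 12 solid over 525
ASVs. Degenerate inputs follow explicit conventions: all-tied values give
Kruskal-Wallis H = 0, p = 1; identical groups make SIMPER an error (the
decomposition is 0/0); an all-zero distance matrix makes PERMANOVA return
p = 1 with a message; Chao1 refuses non-integer counts; rarefaction refuses
depths no sample reaches.

## Known limitations

* The colorimetric score presumes pre-trimmed photographs under controlled
  lighting; no lighting normalization or swab segmentation is attempted.
* Bray-Curtis is not a metric; the triangle inequality is neither assumed
  nor asserted, and PCoA on it can produce negative eigenvalues (handled as
  described above).
* Wilcoxon tests always use the normal approximation with tie and
  continuity corrections — appropriate for the group sizes this design
  produces (>= 13), conservative for much smaller ones.
* The differential caller's per-comparison BH correction controls FDR
  within each contrast, not across all contrasts of a study.
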