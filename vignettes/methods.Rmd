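---
title: "Models and methods behind discoursemap"
author: "discoursemap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind discoursemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discoursemap)
```

## What the package models

`discoursemap` implements a validation-and-mapping workflow for spoken
discourse in post-stroke aphasia. Two measures of discourse informativeness
are computed from picture-description transcripts:

* **Content Word Fluency (CWF)** — a transcription-less score: one point
  each time the speaker produces an item from a pre-specified checklist of
  target content words, counting inflected forms and listed synonyms,
  excluding immediate repetitions and perseverations of the same item.
* **Correct Information Units (#CIU)** — a count of words that are
  intelligible, accurate, relevant and informative. The relevance and
  accuracy judgments require human (or simulated) annotation; the counter
  here is deterministic given per-token flags.

On top of the scores the package provides item-response-theory validation
of the checklist, a psycholinguistic item regression, and a suite of
lesion-symptom mapping (LSM) analyses: multivariate sparse
canonical-correlation mapping, streamline-template disconnection maps,
tract lesion-load partial correlations, and an AIC-based predictive
validity comparison (PVC) of two behaviours.

## Scoring rules and their edge cases

The CWF scorer resolves each token by a deterministic, auditable
lemmatizer: lower-casing, punctuation stripping, an extendable
irregular-form table, then ordered suffix rules (`-ies`→`-y`, `-es` after
sibilants, `-s`, `-ing` and `-ed` with e-restoration and consonant
undoubling). We deliberately avoid a statistical tagger: every match in the
audit trail can be traced to a rule. Synonyms pass through the same
normalizer, so inflected synonyms also match.

Two readings of the repetition rule were possible. The protocol wording
guarantees that re-use of a target *in a subsequent phrase* counts; it does
not say whether a within-phrase, non-adjacent re-use counts. We adopt the
more permissive reading: adjacency is evaluated after skipping
filler-flagged tokens only, so a repeat separated by any contentful token
counts again. Perseveration — named but not defined in the protocols we
follow — is operationalized as the third or later consecutive resolution to
one item within a phrase. Both choices are documented here because they
change scores on pathological repetition patterns, which are common in
non-fluent aphasia.

The per-token flags closed set is `{filler, unintelligible, off_topic,
inaccurate, non_word}`. CIU counting excludes all flagged tokens plus
immediate repetitions (same normalized form, adjacent after removing
flagged tokens); the word count excludes only unintelligible and non-word
tokens. These definitions make `CWF <= #CIU <= word count` a provable
property of generator output, and the test suite fuzzes it over a thousand
synthetic transcripts.

## Item response models

The checklist is validated by fitting one-, two- and three-parameter
logistic models to the persons-by-items production matrix (an item is 1 for
a person who produced it at least once). Items produced by everyone or by
no one carry no information for a dichotomous IRT model and are dropped —
with their identities reported — before fitting. The exclusion rule used
for the published 17-of-22-item analyses is not stated in the source
protocols; the no-variance drop is this package's reconstruction and is
flagged in the documentation.

Fitting is marginal maximum likelihood via Bock–Aitkin EM with fixed
Gauss–Hermite quadrature (41 nodes by default; results at 21 and 61 nodes
differ by less than 1e-3 in difficulty estimates on the test fixtures).
The identification convention fixes the latent variance at 1 and estimates
a *common slope* freely in the 1PL, giving `k + 1` free parameters for `k`
items — the convention under which the likelihood-ratio comparisons have
df 16 (1PL vs 2PL) and 33 (1PL vs 3PL) at `k = 17`, and the M2 statistic
has df `k(k+1)/2 - (k+1) = 135`. The 2PL warm-starts from the 1PL solution
and the 3PL from the 2PL, which guarantees the nested likelihood ordering
up to convergence tolerance. The 3PL lower asymptote is stabilized by a
weak `Beta(1, 9)` penalty that vanishes at `c = 0`; plain 3PL MML is
unstable at double-digit sample sizes, and the penalty (disclosed in the
fit object) can shave a numerically negligible amount off the raw
likelihood.

Goodness of fit uses the limited-information M2 statistic: a quadratic form
in the residuals of first- and second-order response margins, with the
weight matrix built from the model-implied covariance of the margin
indicators and a central-difference Jacobian in the free parameters.
Degrees of freedom are always reported analytically; when
`k(k+1)/2 <= n_params` the statistic cannot test the model and no p-value
is produced. A parametric bootstrap calibration of the margin-residual
quadratic form is available as a fallback. On null simulations (8 items,
300 persons, 200 replicates) the analytic M2 rejects at 3–7% at a nominal
5% level — the calibration the acceptance suite checks.

## Synthetic cohorts: what they emulate, and what they do not

The generator produces full study-shaped cohorts so every downstream stage
is testable offline:

* **Checklist**: items sampled from a packaged synthetic scene vocabulary
  (nouns:verbs near 15:7), difficulties drawn standard-normal, covariates
  spanning published ranges (phoneme length 2–7, log frequency 0.77–4.56,
  imageability 230–638), and up to three synonyms per item.
* **Lesions**: connected blobs emulating a vascular-territory stroke — the
  primary seed voxel is drawn around a territory centre (the critical
  region's centroid), a satellite seed nearby, and growth proceeds by
  randomized 6-neighbour accretion with 40% frontier acceptance, giving
  irregular boundaries. Target sizes are log-normal with median 1.5% of the
  grid — a desk-scale stand-in; real lesion volumes (tens to hundreds of
  cc in template space) scale down with the default 32x32x32, 2 mm grid.
* **Abilities and production**: latent ability is
  `theta = -beta * load + noise`, with `load` the lesioned fraction of the
  critical region; items are produced with probability
  `plogis(theta - b_j)` (a Rasch process). We do not re-standardize theta:
  leaving the location shift in place is what makes mean CWF provably
  non-increasing in the effect size at a fixed seed, and a location/scale
  change in theta is absorbed by the IRT fit anyway.
* **Transcripts**: produced items appear as the lemma, an inflected form,
  or a synonym, embedded among flagged fillers, occasional off-topic,
  unintelligible and non-word tokens, adjacent repetitions at the
  configured rate, and ability-linked relevant context words — so CIU
  counts exceed CWF scores and the two correlate strongly. The
  context-word rate (Poisson, mean 1.2 per produced item) was calibrated
  once so that the CWF–#CIU correlation lands in the strong range reported
  for real cohorts (around 0.85–0.95 at n = 100), then frozen.
* **Tract atlas and streamlines**: eight box-shaped tracts with the
  standard dorsal/ventral names, one of which (FAT) contains the default
  critical region; streamlines are shortest 6-connected paths between
  random tract voxels inside a one-step dilation of the tract.

The generator makes no claim of linguistic or anatomical realism: word
order is random within phrase chunks, there is no syntax, no discourse
structure, no grey/white matter distinction and no registration. Passing
tests on synthetic cohorts therefore demonstrate that the *algorithms*
implement their definitions and recover planted structure — not that the
pipeline's numbers would match any particular real dataset.

## Sparse canonical-correlation LSM

The multivariate LSM seeks a unit-norm voxel-weight vector `w` whose lesion
projection `Xw` maximally correlates with the (lesion-size-residualized)
behaviour. Three published conventions are honoured: voxels must be
lesioned in at least 10% of the cohort (inclusive comparison); total lesion
size is regressed out of the behaviour first; and sparseness is set to
-0.3, which we read — following the sign convention of the upstream
sparse-CCA tooling — as "retain at most 30% of voxels, signs
unconstrained" (a positive value constrains weights non-negative). The
parameter is nowhere defined in the source protocols, so this reading is a
documented package decision.

The optimizer is a proximal-gradient scheme: a least-squares fit step, an
optional 6-neighbour spatial smoothing of the iterate (weight 0.3),
soft-threshold shrinkage at `0.25 * max|X'y|`, and the hard top-`m`
sparseness cap. The smoothing and shrinkage follow the design of
established multivariate LSM tools, which regularize spatially precisely
because subjects-much-smaller-than-voxels problems have whole families of
equally-fitting diffuse solutions; shrinkage selects a compact,
reproducible cluster among them. With `n` in the tens and thousands of
mask voxels, the weight support is typically far below the 30% cap — the
cap is an upper bound, binding only for weakly regularized problems.

Significance is assessed by 4-fold cross-validation: held-out projections
are pooled and correlated with the behaviour, with a one-tailed t-test on
`n - 2` df (the upstream tool's exact procedure is unpublished, so a
permutation option `n_perm` is provided for verification; on permuted
behaviours the CV correlation centres near zero and the test stays
non-significant in ~95% of runs). Displayed voxels are those with negative
weights — damage predicting worse scores — whose weight magnitude on the
unit-norm vector exceeds 0.1 (voxels holding at least 1% of the squared
weight mass), stabilized by selection frequency over 25 subsample refits
(80% subsamples, threshold 0.4) and cleaned by a 3-voxel cluster-extent
floor. The stability step is standard stability selection; the display
constants were fixed by one recovery calibration on synthetic cohorts
(planted 20-voxel region, n = 40, 24-cube grid) and then frozen. On those
conditions the displayed set overlaps the planted region at Dice ≈ 0.5–0.7
with cross-validated correlations around 0.4–0.8 — honest numbers for
support recovery from 40 binary images, and the reason real studies report
region-level summaries rather than voxel-exact claims.

Disconnection LSM replaces each subject's lesion mask with its binarized
disconnection map: a template streamline is disconnected if any voxel on
its path is lesioned; each traversed voxel's disconnection fraction is the
disconnected share of streamlines passing through it, binarized inclusively
at 50%. Tract-level analysis computes per-tract lesion percentages
(`|lesion ∩ tract| / |tract|`) and partial correlations with the scores
controlling for total lesion size. Back-computing the t-transform from
published tract correlations (r = -0.22 at n = 63 yielding p = 0.04) is
consistent with one-tailed testing in the damage-worsens-performance
direction, so tract tests default to one-tailed; behavioural validation
correlations default to two-tailed. No multiple-testing correction is
applied by default, matching the uncorrected-p reporting convention;
`p.adjust`-style correction can be applied by the user on the returned
tables.

## Predictive validity comparison

PVC asks whether two behaviours need two lesion maps or share one. The
single-map model fits one sparse weight vector on the stacked data (both
behaviours, shared weights); the two-map model fits each separately.
Residuals come from cross-validated predictions, with a per-fold
intercept+slope calibration of the projection onto the behaviour scale.
Each model's fit is summarized as
`AIC = sum_behaviours n*ln(RSS/n) + 2k`, `k` counting fitted maps times
retained voxels, and the two-map verdict requires an AIC difference above
100. The exact AIC bookkeeping of the originating method is not restated
in the protocols we follow, so this Gaussian-residual operationalization
is validated through its structural properties — identical behaviours can
never favour two maps (the penalty is pure loss), and behaviours driven by
disjoint planted regions separate more than identical ones — rather than
against any published AIC value.

## Numerical and design choices

* Voxel indices are 1-based, grid-ordered (R array order) everywhere,
  including the JSON interchange formats; mixing conventions across
  formats is the classic source of off-by-one lesion analyses.
* All randomness flows from explicit integer seeds through per-stage child
  seeds; generators restore the caller's RNG state. Identical
  configurations reproduce byte-identical cohorts and reports.
* Ties in the sparsity projection are broken deterministically toward
  lower voxel indices.
* OLS solves use QR decompositions, never normal equations; rank-deficient
  psycholinguistic designs are refused with the offending columns named.
* The coverage filter, binarization threshold and verdict boundary are all
  inclusive comparisons, stated in their docstrings.
* Degenerate inputs fail loudly and early: empty checklists, constant
  behaviours, all-0/all-1 items, mismatched grids and collinear covariates
  all raise informative errors rather than propagating NaNs.
* Problem sizes used by the test suite (cohorts of 40–200 on 8- to 24-cube
  grids, 200 M2 replicates at 8 items x 300 persons, Rasch recovery at 500
  persons x 17 items) were chosen to exercise the asymptotics the methods
  rely on while keeping a full run in the low minutes on one core.

## Known limitations

* The lemmatizer is rule-based English with a finite irregular table;
  out-of-table irregulars normalize to themselves. Users can extend the
  table per call.
* CIU relevance/accuracy cannot be automated from text; the counter is
  only as good as the annotation flags it receives.
* The IRT module is strictly dichotomous and unidimensional — no
  polytomous models, no DIF.
* Voxel-exact recovery claims from cohorts of tens of subjects are
  intrinsically unstable; the displayed-voxel machinery reports compact
  stable clusters, and region-level summaries (label shares, tract
  correlations) are the intended unit of interpretation.
* The synthetic tract atlas is topological, not anatomical; real analyses
  should supply their own atlas and streamline template through the
  documented readers.
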