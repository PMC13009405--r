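# discoursemap

Transcription-less discourse scoring and lesion-symptom mapping for
post-stroke aphasia.

People with aphasia often lose the ability to produce informative connected
speech, and the standard way to measure it — transcribing a
picture-description sample and coding Correct Information Units (CIUs) —
can take an hour per minute of speech. Content Word Fluency (CWF) is a
transcription-less alternative: a clinician tallies, in real time,
productions of the words on a stimulus-specific checklist, counting
inflections and synonyms and skipping immediate repetitions. This package
implements, for researchers and methodologists working on discourse
assessment:

* the **CWF scorer** (rule-based lemmatizer, synonym matching, repetition
  and perseveration exclusions, full audit trail) and a flag-driven
  **CIU counter**;
* **item-response validation** of the checklist: 1PL/2PL/3PL logistic
  models by marginal maximum likelihood (Bock–Aitkin EM, Gauss–Hermite
  quadrature), likelihood-ratio model comparison, the limited-information
  **M2** goodness-of-fit statistic, and Wright-map tables. Under the
  common-slope convention a k-item 1PL has k+1 parameters, so at k = 17
  the comparisons have df 16 and 33 and M2 has df 135;
* **lesion analytics**: the 10%-coverage voxel filter, lesion-size
  residualization, sparse canonical-correlation LSM (sparseness −0.3
  retains at most 30% of voxels with unconstrained signs; 4-fold
  cross-validated significance; negative-weight display maps),
  streamline-template **disconnection maps** (50% binarization),
  per-tract **lesion-load partial correlations** (one-tailed, controlling
  total lesion size), and the AIC-based **predictive validity comparison**
  (two distinct maps only when the AIC difference exceeds 100);
* a **synthetic-cohort generator** (Rasch-driven item production, lesion
  blobs whose load in a critical region depresses ability, annotated
  transcripts, tract atlas, streamline template, behaviour table) and a
  **pipeline** that runs the whole analysis from one YAML config.

The model at the core of the psychometrics is the Rasch/1PL item-response
model: person *i* produces checklist item *j* with probability
`P(y_ij = 1) = logistic(a(theta_i − b_j))`, with latent ability `theta`,
item difficulty `b_j`, and a common slope `a`. The model at the core of
the lesion mapping is sparse canonical correlation between the
subjects-by-voxels binary lesion matrix `X` and a behaviour `y`: find
unit-norm sparse `w` maximizing `corr(Xw, y)`; negative entries of `w`
mark voxels where damage predicts worse scores.

## Worked example

Score one transcript against a three-item checklist in which *steal* has
the synonym *take*:

```r
library(discoursemap)

cl <- checklist(
  data.frame(item_id = c("cookie", "steal", "fall"),
             lemma = c("cookie", "steal", "fall"),
             word_class = c("noun", "verb", "verb"),
             length_phonemes = c(4, 4, 3),
             frequency = c(3.1, 2.2, 2.5),
             imageability = c(600, 410, 430)),
  synonyms = list(steal = "take"))

words <- c("the", "boy", "is", "stealing", "cookies", "and",
           "he", "took", "a", "cookie", "cookie")
tr <- transcript("p1", data.frame(position = seq_along(words),
                                  surface = words, flags = "",
                                  phrase_id = 1L))
res <- score_cwf(tr, cl)
print(res)
#> CWF score for p1: 4 (4 matches audited, 1 exclusions)
res$audit
#>   position item_id match_kind
#> 1        4   steal  inflected
#> 2        5  cookie  inflected
#> 3        8   steal    synonym
#> 4       10  cookie      lemma
count_cius(tr); word_count(tr)
#> [1] 10
#> [1] 11
```

"stealing" and "cookies" match as inflections, "took" matches *steal*
through the normalized synonym *take*, and the final "cookie" is excluded
as an immediate repetition — CWF 4, with every decision in the audit.

Run the full pipeline on a simulated cohort:

```r
bundle <- run_pipeline(list(simulate = list(n_participants = 60, seed = 3,
                                            grid_shape = c(24, 24, 24))))
print(bundle)
#> Discourse analysis report
#>   participants: 60
#>   r(CWF, CIU) = 0.97 (p = 1.344e-35)
#>   subtype t-test: t = 10.1 (df 44), p = 5.465e-13
#>   M2(230) = 242.8, p = 0.269
#>   PVC: AIC difference = -459.7 -> single_map
```

The CWF–CIU correlation is strongly positive (the convergent-validity
pattern the measure is built on), non-fluent subtypes score lower than
fluent ones, the 1PL model is consistent with the production margins (M2
p > 0.05), and the predictive validity comparison finds that CWF and CIU
deficits are adequately described by a single lesion map (AIC difference
far below the +100 two-map criterion).

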