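---
title: "The gene profile score: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gene profile score: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profscore)
```

## The problem

A qPCR gene panel reports, for each sample and each of G reporter genes, a
relative quantity RQ = 2^−ΔΔCT: expression normalised to a housekeeping gene
(ΔCT) and then to a calibrator sample (ΔΔCT). Panels assembled from
microarray discovery studies are attractive as diagnostics, but the raw
material is unfriendly: per-gene distributions overlap between cases and
controls, effect sizes vary widely across the panel, and a substantial
fraction of cells is simply missing (failed wells, undetermined CTs).
Standard clustering or margin-based classifiers degrade badly under that
missingness. The gene profile score is a deliberately minimal alternative: a
per-gene thresholded vote, summed across the panel.

## The metric

For gene $g$ with calibrated cut-off $c_g$, sample $i$ contributes digit

$$ b_{gi} = \mathbf{1}\{x_{gi} \text{ measured and } x_{gi} > c_g\} $$

(on the ΔCT scale the inequality flips, because lower cycle thresholds mean
more transcript). The profile score is $S_i = \sum_g b_{gi} \in \{0,\dots,G\}$
and the final call is *case* iff $S_i > s$ for a calibrated integer score
cut-off $s$. Missing measurements contribute 0 by definition — a sample with
no usable wells scores 0 and is always called a control.

Both calibrations use the same primitive. The empirical ROC curve sweeps
every *observed* score value as a candidate cut-off (plus an infinite
sentinel closing the curve at the all-positive point), counting a sample as
positive only when it is *strictly* beyond the cut-off. Among operating
points with training FPR at or below the target (5% by default, 10% as the
relaxed setting), the one maximising TPR is kept; ties resolve to the most
conservative cut-off, i.e. the one calling fewest positives. Consequences
worth knowing:

* every reported cut-off is an observed data value, so a frozen classifier
  is exactly reproducible from the serialized JSON artifact;
* values tied with the cut-off are negative calls;
* the achieved FPR can never exceed the target, because the all-negative
  operating point (FPR = TPR = 0) is always admissible;
* the trapezoidal AUC of this curve equals the tie-corrected Mann–Whitney
  probability $P(S_{case} > S_{ctrl}) + \frac12 P(=)$, so an uninformative
  constant score gives exactly 0.5. The test suite pins this equivalence
  against an all-pairs enumeration oracle and against pROC.

The score ROC treats the integer scores like any other score — candidate
cut-offs are the observed distinct scores, no interpolation — so the score
classifier inherits all of the above.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `target_fpr` | 0.05 (and 0.10) | per-gene and score-level training FPR ceiling; lower = more specific, fewer genes fire |
| `min_present` | off (study value 22) | drop samples with fewer measured genes before analysis |
| `scale` | `"RQ"` | `"DELTA_CT"` flips every comparison direction; same operating points, digit-identical profiles |
| `G` | 44 | panel size; anything ≥ 1 works, 44 matches the reference panel |

The ≥ `min_present` filter is optional and off by default: the reference
analysis used it only for its clustering experiments, and the profile score
itself already has a defined behaviour for missing cells.

## The synthetic generator

No patient data are deposited for the study this package re-examines, so
the generator is the package's data source. It draws log2(RQ) as
$N(\mu_g, \sigma_{0g}^2)$ for controls and $N(\mu_g + \delta_g, \sigma_{1g}^2)$
for cases — an upward shift in cases, matching how every reporter gene in the
training data behaved — and masks each cell missing-completely-at-random
with one global rate. Log2-normality makes the population AUC of each gene
available in closed form,

$$ \mathrm{AUC}_g = \Phi\!\left(\frac{\delta_g}{\sqrt{\sigma_{1g}^2 + \sigma_{0g}^2}}\right), $$

and monotone invariance of ROC analysis carries that value unchanged to the
RQ scale (2^x) and the ΔCT scale (−x). This is the parameter-recovery oracle
in the tests: at 500+500 samples the empirical per-gene AUC sits within
±0.03 of the closed form.

`paper_like_config()` freezes the study conditions the analyses use: 44
genes with population AUCs evenly spanning 0.67–0.94 (the span reported for
the real panel on its training set), unit log2 sds, baseline means varying
over the panel, 56 cases / 75 controls, 15% missingness. One seed drives
everything; per-gene substreams are derived from it so extending the panel
never changes existing genes' draws.

What the generator does **not** emulate: gene–gene correlation (real
reporter genes co-express; independent genes make panel aggregation look
*better* than reality, so the "score beats every single gene" property
should be read as a structural, not quantitative, reproduction), informative
missingness (low expression is likelier to drop out in practice), covariates
such as age or population stratification, and outlying RQ values from
plate artefacts. Passing tests therefore certify the algorithmic contracts
and the qualitative structure of the findings, not clinical performance.

## The generalization experiment

The study's central negative finding is that a metric calibrated on one
cohort carried little over to a blinded second population: per-gene
accuracies across the two datasets were essentially uncorrelated. The
analysis scripts reproduce this as a simulation contrast: a test population
with the *same* per-gene effects as training keeps a high training-vs-test
per-gene accuracy correlation, while one whose effects are redrawn
independently (same AUC span, new ranking) drives it to ≈ 0. Because the
redrawn effects stay positive, the aggregate score can remain accurate even
as the per-gene ranking dissolves — the simulation reproduces the loss of
*gene-level* transferability, not the full collapse seen with the real
blinded cohort, whose genes appear to have carried no effect at all.

## Numerical choices and edge cases

* FPR comparisons use a 1e−12 absolute slack so exact rational rates
  (e.g. 1/20 against a 0.05 target) are admitted regardless of binary
  representation.
* Percent summaries round half-up to integers for reporting (the convention
  of the published tables) and keep full precision alongside; a zero
  denominator yields `NA`, never an error or a silent 0/0.
* Welch t-tests delegate to `stats::t.test`; Pearson correlation to
  `stats::cor`. No multiple-testing correction is applied to the per-gene
  tests, matching the analysis being reproduced; treat the per-gene p-values
  as descriptive.
* A gene entirely absent from a dataset (column missing, not cells) is a
  hard error at binarization: silent zeros would bias every score downward
  invisibly.
* Degenerate inputs fail loudly with the offending entity named: a gene with
  no measured cases or controls at calibration, non-positive values on the
  RQ scale, duplicate identifiers, unknown labels at evaluation.

## Problem sizes

The test suite and scripts run on deliberately modest sizes: the study-shaped
panel (44 genes × 131 + 128 samples), 500+500 samples for parameter
recovery, and batches of ≤ 30-sample instances for the exact
oracle-equivalence properties. These sizes make every distributional claim
in the suite checkable in seconds while keeping sampling error well inside
the asserted tolerances.

## Limitations

The package evaluates a *given* panel; it does not select genes, model qPCR
efficiency, use multiple housekeeping genes, or weight votes. Those are
deliberate non-goals: the point of the profile score is that even a maximally
simple, missingness-tolerant voting metric can look excellent on its
training cohort and still fail to transfer — so its evaluation must rest on
an independent, ideally blinded, population.
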