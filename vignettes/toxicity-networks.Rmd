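---
title: "Predicting toxicity categories from gene partial-correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting toxicity categories from gene partial-correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggmtox)
```

## The problem and the model

Chemicals with different target-organ toxicities (neurotoxins,
hepatotoxins, cardiotoxins, glomerular and tubular nephrotoxins,
non-genotoxic carcinogens) perturb the transcriptional machinery of
pluripotent stem cells in category-characteristic ways. `ggmtox`
implements a pipeline that turns such dose-resolved expression
responses into per-chemical *gene networks* and classifies chemicals
into the six (overlapping) toxicity categories from the network edges:

1. **Dose setting.** An ATP viability assay per chemical is fitted with
   the three-parameter log-logistic model
   \(f(x) = d / (1 + e^{b(\ln x - \ln e)})\) (lower asymptote 0,
   upper asymptote \(d\), slope \(b\), inflection \(e\)); the inverse
   closed form \(x_p = e\,(q/(1-q))^{1/b}\), \(q = p/100\), yields the
   inhibitory concentrations IC\(_{0.1}\)–IC\(_{50}\) bracketing the
   maximum exposure dose, from which a two-fold dilution ladder
   (1/1 … 1/16 plus vehicle) is built.
2. **Expression preprocessing.** Gene counts are filtered
   (counts-per-million above the cutoff implied by `min_count = 30` at
   the median library size, in at least the smallest group size of the
   122 condition groups), transformed to
   \(\log_2((c + 0.5)/(L + 1)\cdot 10^6)\), batch-corrected by
   per-gene least-squares residualisation, and summarised per exposed
   condition as the log fold change (LFC) against the matched
   same-solvent vehicle. Differential expression uses a moderated t
   statistic with empirical-Bayes variance shrinkage
   \(\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)\), \((d_0, s_0^2)\)
   estimated by a moments fit on log sample variances, with
   Benjamini–Hochberg control (DEGs: FDR < 0.01 and |LFC| > 1).
3. **Feature genes.** PCA of the conditions × genes LFC panel; from
   each of the top five components the two most positive- and two most
   negative-loading genes are taken (20 genes). Eigenvector signs are
   fixed by orienting each component so its largest-magnitude loading
   is positive, making the panel deterministic; duplicated extremes
   fall through to the next-ranked gene.
4. **Networks.** For each chemical the five dose-level LFC vectors over
   the 20 genes give a sample covariance (n = 5). A Gaussian graphical
   model is estimated by L1-penalised maximum likelihood (graphical
   lasso) along a 1000-point log-spaced penalty path from
   \(\lambda_{max}\) (empty graph) down to \(0.01\,\lambda_{max}\),
   and the penalty is selected by (extended) BIC with \(\gamma = 0\),
   i.e. plain BIC, ties resolved toward the sparser graph. Edges are
   reported as partial correlations
   \(\rho_{ij} = -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}\) in a
   canonical order over the \(\binom{20}{2} = 190\) gene pairs.
5. **Classification.** Each category is a binary task over the
   24-chemical × 190-edge feature matrix, evaluated by leave-one-out
   cross-validation: in every fold, features are ranked by the
   two-sided Welch t statistic *on the training instances only*,
   standardised by training moments, and an SVM is fitted for every
   kernel configuration and every top-k cut (k = 1…190). The reported
   statistic is the maximum accuracy over the whole sweep with the AUC
   of the accuracy-maximising configuration.
6. **Transfer.** For a second cell line measured by qPCR
   (ΔΔCT-derived LFCs over the same 20 genes), the classifier is
   trained on the labeled first-domain instances and predicts the
   unlabeled second-domain instance of the held-out chemical
   (transductive standardisation over both domains in `stacked` mode;
   a 380-feature concatenation mode is also provided).
7. **Significance.** The observed maximum accuracy is compared against
   10 replicates of the identical sweep on uniform-random features via
   a one-sample, one-sided t test with 9 degrees of freedom.

## Tunable parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_count` | 30 | CPM filter anchor (counts at the median library size) |
| `fdr_cut`, `lfc_cut` | 0.01, 1 | DEG thresholds (BH FDR; log2 units) |
| `n_pcs`, `genes_per_sign` | 5, 2 | feature panel: 5 PCs × 2 signs × 2 genes = 20 |
| `nlambda`, `lambda_min_ratio` | 1000, 0.01 | penalty path resolution and span |
| `gamma` | 0 | EBIC weight; 0 = BIC |
| `n_obs` | 5 | observations behind each covariance (dose levels) |
| `cost`, `gamma_scale`, `degree` | grid | SVM hyperparameters (see `svm_grid()`) |
| `p_max` | 50 | percent inhibition defining the top exposure dose |
| `lfc_sign` | +1 | qPCR convention: ΔΔCT recorded as LFC as-is |

The qPCR sign convention deserves a note: ΔΔCT as computed here is
*positive* when expression goes down; the `lfc_sign = -1` flag gives
the conventional expression orientation. A classifier consuming both
domains is insensitive to a consistent global flip, and a test asserts
the round-trip under the matching convention.

## Numerical choices

* **Graphical lasso.** Block coordinate descent with an unpenalised
  diagonal, warm starts along the decreasing penalty path, and an
  active-set inner loop; convergence is declared when the mean
  absolute change of the working covariance falls below
  `1e-4 ×` mean |off-diagonal|. The solver operates on the correlation
  matrix by default (scale equivariance; with n = 5 the covariance is
  rank-deficient, which the solver accepts), mapping to partial
  correlations afterwards. A penalty value where the back-substitution
  turns non-positive is recorded as non-converged, refitted once with
  `1e-8` diagonal jitter, and otherwise skipped by the BIC scan —
  never aborting the path. At \(\lambda \ge \lambda_{max}\) the
  estimate is exactly diagonal; at \(\lambda \to 0\) on a well-posed
  input it converges to the unpenalised inverse (both are tested).
* **Dose-response fitting.** Multi-start Levenberg–Marquardt in
  log-concentration space (starts: \(d\) = max response, \(e\) =
  concentration nearest half-max, \(b \in \pm\{0.5, 1, 2, 4\}\));
  Wald 95% intervals from the asymptotic covariance. A fit explaining
  no variance beyond the mean is flagged non-converged and refuses IC
  inversion. Mean blank luminescence is subtracted before fitting.
* **Ranking ties** break deterministically by feature index;
  **sweep ties** resolve by higher AUC, then smaller k, then grid
  order.
* **Degenerate inputs.** Constant genes yield zero covariance rows
  (no edges); zero-variance features standardise to zero; single-batch
  data pass through batch removal unchanged.

## Leakage

Nothing inside a leave-one-out fold — feature ranking, standardisation
moments, the SVM fit — sees the held-out instance. The test suite
plants a label-revealing value in the held-out vector only and checks
that per-fold rankings are unchanged, that decision values are
bit-identical whenever the planted column is not selected, and that
paired accuracies do not rise. This matters for interpreting the
random baselines below: ranking on the *full* data before
cross-validation (a common protocol slip) inflates random-feature
accuracy dramatically.

## The maximum-accuracy statistic and the search grid

The reported "maximum accuracy" is an extreme-value statistic: its
expectation grows with the breadth of the kernel/k search even on pure
noise, which is exactly why the uniform-random baseline must be run
through the *identical* sweep. The full default grid
(`svm_grid()`: linear, polynomial, RBF over costs 0.01–100) is used
for single runs; for the ten-replicate baselines the package documents
a reduced protocol (`baseline_protocol()`) — fewer kernel
configurations and a top-k grid that is dense for small k and coarser
above, where neighbouring k values are nearly redundant — so that ten
full leave-one-out sweeps remain tractable on one CPU. Reports carry
the protocol used. Because a narrower search lowers the maximum on
random data, baseline levels are only comparable between runs of the
same protocol.

## What the synthetic generator emulates — and what it does not

`sim_truth()` + `gen_*()` reproduce the full study design: 24
chemicals with the packaged multi-label category table, 6 doses
(vehicle included), 2 replicates, 2 timepoints (576 samples), solvent
matched vehicles, batch shifts, negative-binomial counts, an ATP assay
per chemical and a qPCR CT table for the second domain. The planted
signal gives each category a 3-gene clique in its precision matrix
(partial correlations 0.45) and a category-specific mean dose response
on those genes. The dose profiles are sigmoidal with
category-specific thresholds spread over the five dose ranks: distinct
mechanisms switching on at different concentrations. This choice is
load-bearing — if every category shared one common dose ramp, the mean
shifts of a multi-label chemical would collapse into a single rank-one
direction of its covariance, and no estimator could attribute edges to
categories for chemicals carrying three or more labels. Effect sizes
(`mu = 5` log2 units, precision scale 36, isotropic noise SD 0.1) are
set so that the planted networks are strong and well separated, the
regime the recovery tests are about.

What the generator does *not* emulate: transcriptome-wide correlation
structure beyond the planted panel, library-size and GC biases,
dose-dependent cytotoxic global shutdown, or any relationship between
a chemical's real mechanism and its synthetic signature. Passing
recovery tests therefore demonstrates that the pipeline recovers the
kind of signal it assumes, at realistic noise — not that real
chemicals carry such signal.

## Problem sizes used by the test-suite simulations

The checks run at the study scale where the quantity depends on it
(576-sample design, 500 genes, 24 chemicals, 190 edges, 1000-point
penalty paths) and at reduced scale where it does not (shorter penalty
paths for small worked examples; the documented reduced sweep protocol
for the ten-replicate baselines; single-timepoint end-to-end runs).

## Known limitations

* With n = 5 dose vectors, per-edge partial-correlation estimates are
  intrinsically noisy; the classifier's power comes from pooling 190
  edges over 24 chemicals, not from any single edge being well
  estimated.
* The "maximum entropy" kernel of the predecessor protocol has no
  public definition; the fourth kernel family here is the sigmoid
  kernel, behind a flag.
* Six categories compete for five principal components; feature genes
  of the rarest category are the first to be crowded out when
  unrelated high-variance genes exist.
* Whether confidence intervals should be Wald or profile-likelihood is
  a judgment call; the package reports Wald intervals and says so.
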