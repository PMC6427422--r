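---
title: "Classifying seed viability from FT-NIR spectra with PLS-DA"
author: "seednir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying seed viability from FT-NIR spectra with PLS-DA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seednir)
```

## The problem

Naturally aged seed lots lose viability during storage, and for
thick-coated triploid (seedless) watermelon seed the loss cannot be judged
from the outside. The reference assay — a two-week germination test — is
destructive and slow. FT-NIR absorbance spectroscopy (4000–10,000 cm^-1^)
reads the embryo's chemistry (protein and bound-water overtone bands)
through the coat in seconds, so a calibrated classifier on single-seed
spectra can screen lots nondestructively. `seednir` implements the complete
chemometric workflow for this task: spectral preprocessing, PLS-DA
classification with a ±0.5 decision band, VIP wavelength selection, T²/Q
outlier screening, and confusion-matrix/ROC evaluation — together with a
synthetic spectra generator so every stage is testable end to end without
instrument data.

## The model

Viability is coded as a response $y_i \in \{0, 1\}$ (nonviable = 0,
viable = 1) and regressed on the preprocessed spectra by partial least
squares:

$$ Y = X b + E, \qquad X = T P^\top + E_X, \qquad Y = U Q^\top + E_Y $$

Components are extracted one at a time by NIPALS on mean-centered data:
the weight vector $w_a \propto X_{a-1}^\top u$ is normalized, scores
$t_a = X_{a-1} w_a$, loadings $p_a = X_{a-1}^\top t_a / t_a^\top t_a$ and
$q_a = y^\top t_a / t_a^\top t_a$ are computed, and $X$ and $y$ are
deflated. The collapsed coefficient vector is
$b = W (P^\top W)^{-1} q$, so prediction for a new spectrum $x$ is
$\hat y = (x - \bar x)^\top b + \bar y$. Columns are mean-centered but not
variance-scaled: absorbance channels share a unit, and autoscaling would
inflate the information-free channels.

The inner NIPALS iteration uses a convergence tolerance of $10^{-10}$ on
the weight vector and at most 500 iterations per component (for a
univariate response the loop converges immediately; the general loop is
retained for robustness).

**Decision rule.** A response within 0.5 of a class code is assigned to
that class: $\hat y \ge 0.5$ is viable, $\hat y < 0.5$ nonviable, with the
tie at exactly 0.5 going to the viable band's closed lower bound. Responses
outside $[-0.5, 1.5]$ belong to no band; they are assigned to the nearest
class and flagged `outsideBaseline`, so per-class tallies always sum to the
number of samples presented.

**Choosing the number of latent variables.** Stratified 10-fold
cross-validation on the calibration set, minimizing the misclassification
rate under the ±0.5 rule, with ties broken toward the smallest component
count. Ten-fold stratified CV is the conventional default when the
original protocol is unspecified; the fold assignment is drawn from a
dedicated seed stream so it is reproducible and independent of the
simulation and split streams.

## Preprocessing menu

All transforms are pure, per-spectrum and row-independent:

* **Normalization** — maximum ($x/\max x$), mean ($x/\bar x$), range
  ($(x - \min x)/(\max x - \min x)$).
* **SNV** — $(x - \bar x)/s_x$ with the sample (n−1) standard deviation,
  the common chemometrics convention; the choice affects rows only by a
  constant factor that the regression absorbs.
* **MSC** — each spectrum is regressed on a reference by OLS,
  $x \approx a + b\,\mathrm{ref}$, and corrected to $(x - a)/b$. The
  reference defaults to the *calibration-set* mean and is frozen inside
  the fitted chain, so validation and test spectra are corrected against
  the training reference and no information leaks across the split.
* **Savitzky–Golay derivatives** — local polynomial least-squares
  differentiation (degree 2 by default, the customary choice), computed
  with `signal::sgolayfilt`, which handles the terminal windows by the
  full polynomial fits at the edges. The derivative is taken per grid
  index; a flag rescales to per-cm^-1^ units. A toolbox-style "4-point"
  window specifies points per side, which maps to a full odd window of
  $2 \times 4 + 1 = 9$ points — the package default.
* **Region trimming** — a closed wavenumber interval is kept; the default
  pipeline keeps 4000–9000 cm^-1^, dropping the information-free noisy
  region above 9000 cm^-1^.

Candidate chains are compared as single-step alternatives (raw vs
SG-1st-derivative by default), mirroring the usual calibration/validation
comparison table.

## VIP wavelength selection

Variable importance in projection for wavelength $j$ is

$$ \mathrm{VIP}_j = \sqrt{ p \cdot \frac{\sum_{a=1}^{A} (w_{ja}/\lVert w_a
\rVert)^2\, \mathrm{SSY}_a }{ \sum_{a=1}^{A} \mathrm{SSY}_a } }, \qquad
\mathrm{SSY}_a = q_a^2\, t_a^\top t_a , $$

the explained-Y sum of squares of component $a$. The normalized-weight
convention is used because it preserves the identity
$\sum_j \mathrm{VIP}_j^2 = p$, which the test suite asserts on every fit
(unnormalized weights break it). The threshold scan examines a grid over
$[0.8, 1.5]$ (step 0.1), refits on each selected subset — re-running LV
selection on the reduced variables — and picks the threshold with the best
cross-validated accuracy, preferring fewer variables and then the smaller
threshold on ties.

## T²/Q outlier screening

For sample $i$ with scores $t_i$: $T^2_i = \sum_a t_{ia}^2 /
\mathrm{var}(t_a)$ (score variance with n−1), and $Q_i$ is the squared
norm of the spectral residual off the model plane. Limits at confidence
$1-\alpha$ (default 0.989, kept configurable):

* $T^2$: $\frac{A(n-1)}{n-A} F_{1-\alpha}(A,\, n-A)$.
* $Q$: the Jackson–Mudholkar approximation from the residual eigenvalues.
  Its power transform requires $h_0 > 0$; when a few dominant residual
  eigenvalues drive $h_0$ negative the implementation falls back to the
  moment-matched chi-square approximation $g\,\chi^2_h$ with
  $g = \theta_2/\theta_1$, $h = \theta_1^2/\theta_2$.

A sample is reported as an outlier only when it exceeds **both** limits;
single-statistic exceedances are kept as separate flags for inspection.

## Evaluation

With viable as the positive class: sensitivity $tp/(tp+fn)$, specificity
$tn/(tn+fp)$, non-error rate $\mathrm{NER} = (\mathrm{sens} +
\mathrm{spec})/2$ (the chemometric definition; on balanced sets it equals
overall accuracy, and both are reported), $\mathrm{ER} = 1 -
\mathrm{NER}$, precision $tp/(tp+fp)$ and FPR $fp/(fp+tn)$. Metrics with a
zero denominator are returned as `NA` rather than crashing. The ROC sweep
classifies $\hat y \ge$ threshold as viable over all unique responses plus
sentinels, computes AUC by the trapezoid rule over (FPR, sensitivity), and
locates the sensitivity/specificity crossing by linear interpolation
between adjacent sweep points.

## The synthetic generator

`simulateSpectra()` builds each spectrum as a variety baseline (offset +
slope), a sum of Gaussian absorption bands, and a global additive class
offset, then corrupts it with a per-sample affine scatter transform
$x' = a + b x$ ($a \sim N(0, \sigma_a)$, $b \sim N(1, \sigma_b)$ — exactly
the distortion MSC and SNV are designed to invert), a smooth random
baseline flex, and heteroscedastic noise. Gaussian band shapes are
sufficient for NIR's broad overlapping overtone bands; no radiative
transfer through the seed coat is modelled. The defaults encode the data
structure the workflow assumes:

* grid 4000–10,000 cm^-1^ at 4 cm^-1^ spacing (1501 points; the exact
  instrument point count is configurable);
* shared absorption bands near 4536, 4744, 4987, 5174, 5376 and
  6929 cm^-1^; class-discriminative bands at 4079, 5261 and 7416 cm^-1^
  (amplitude excess 0.005–0.006 AU for nonviable seeds) so that VIP
  recovery is a meaningful test;
* a global nonviable excess of 0.02 AU, making nonviable mean spectra sit
  above viable ones at every wavenumber;
* three varieties with distinct baseline offsets and slopes, and
  germination rates 0.87 / 0.89 / 0.84 used by `simulateLabelledLot()` to
  draw unbalanced field lots;
* an information-free region: channels at and above 9000 cm^-1^ carry
  10× the base noise (0.03 vs 0.003 AU);
* the baseline flex is a random combination of 40 broad Gaussian
  components (amplitude SD 0.04 AU). This is the deliberate difficulty
  knob: it is smooth enough that derivative preprocessing suppresses it,
  but of high enough dimension that a raw-spectra PLS model cannot project
  it all out with a realistic number of latent variables — reproducing the
  qualitative gap between raw and derivative-preprocessed models observed
  on real seed spectra.

What the generator does **not** emulate: correlated (pink) instrument
noise, nonlinear detector response, water-band temperature shifts,
variety-by-class interactions, and any real covariance structure between
neighbouring seeds in a lot. Passing tests therefore demonstrate that the
algorithms are implemented correctly and that the pipeline recovers
structure of this kind — not that any particular accuracy will transfer to
a given instrument or seed lot.

Wavenumber axes are stored ascending throughout (instruments often report
descending); readers canonicalize column order. `"unknown"` is a legal
label so prediction-only datasets use the same container.

## Reproducibility and problem sizes

Every stochastic stage draws from a named stream derived from one master
seed (simulation = seed, split = seed + 1000, CV folds = seed + 2000), so
identical configuration and seed give bit-identical spectra, splits,
models and reports; the model archive serializes doubles at 17 significant
digits so a reloaded model predicts bit-identically. The worked analyses
use the study-scale sizes: 744 pooled spectra (124 per variety per class),
a 520/224 calibration/validation split, 10-fold CV over up to 15 latent
variables, and 100-seed external lots; unit tests exercise the same code
paths on smaller instances.

## Known limitations

* Strictly two-class; no multi-class PLS2 variant.
* The ±0.5 rule leaves responses outside $[-0.5, 1.5]$ formally
  unassigned; nearest-class assignment plus a flag is this package's
  documented resolution so accounting always totals $n$.
* The FPR column of an external report uses the standard $fp/(fp+tn)$
  definition; some published tables appear to tabulate $1 -
  \mathrm{PREC}$ instead, so small discrepancies against literature
  values of FPR can occur.
* No bootstrap confidence intervals on evaluation metrics, and no
  alternative wavelength-selection schemes (sparse PLS, CARS, genetic
  algorithms) beyond VIP.
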