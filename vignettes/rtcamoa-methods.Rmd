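---
title: "Methods: wavelet-featurized MOA classification of RTCA response curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-featurized MOA classification of RTCA response curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcamoa)
```

## The problem

Impedance-based real-time cell analysis (RTCA) follows adherent cells
continuously: micro-electrodes at the bottom of each well report an
impedance that grows with cell number, spreading and adhesion. Exposing
a cell line to a chemical at a ladder of concentrations produces a
family of time–concentration response curves (TCRCs) whose shapes —
immediate kill, delayed kill, transient stimulation, recovery — carry a
signature of the chemical's mode of action (MOA). `rtcamoa` implements
a supervised pipeline that learns MOA cluster labels from TCRCs and
assigns new compounds to clusters.

The pipeline is: normalize and resample the raw signal; concatenate the
concentration curves into one input vector; compress that vector with a
multilevel discrete wavelet transform, keeping only the coarse blocks;
classify with a Gaussian-kernel SVM (or a small feedforward network);
estimate accuracy by repeated stratified random splits; extend to more
than two clusters with a binary tree of SVMs; and, for hard imbalanced
tasks, use dose–response-curve (DRC) profiles over time to select an
informative time window before featurizing.

## Preprocessing

The instrument-level signal is converted to the cell index
\(CI = \max_k\left[R_{cell}(f_k)/R_b(f_k) - 1\right]\), the largest
relative impedance increase over the cell-free background across the
measurement frequencies \(f_k\). Because seeding density varies between
wells, each series is normalized to the value right before treatment,
\(NCI[k] = CI[k]/CI[0]\), so every curve starts at 1. Logging intervals
are slightly irregular, and the wavelet transform needs a uniform grid,
so the post-treatment samples are interpolated with a cubic spline and
evaluated at whole hours.

Choices made here, and why:

* **Window 0–72 h at 1-h steps, 73 samples per curve.** Monitoring runs
  at least 72 h; the concatenated input sizes the rest of the pipeline
  relies on (803 = 11 × 73, 876 = 12 × 73) force 73 samples.
* **Not-a-knot end condition** for the spline. Nothing in the data
  motivates a clamped or natural end; not-a-knot reproduces cubic
  polynomials exactly, which makes the resampler verifiable against
  closed forms (the tests exercise exactly this).
* **Pre-treatment samples are discarded** — they contain seeding and
  attachment dynamics common to all wells, not compound response.
* **Negative NCI values are not clipped**; impedance can dip below the
  cell-free background after detachment.
* CI may be supplied directly (instruments export it); the impedance
  formula is retained for raw inputs.

## Wavelet featurization

A TCRC set is concatenated into TCRC(n): the \(n\) highest
concentrations in rank order, optionally followed by the negative
control (NC). Including the NC consistently helps — it encodes
plate-condition information shared by the treated wells. With all 11
concentrations plus NC the input has 876 points, which is large for a
classifier trained on a few dozen compounds.

The multilevel discrete wavelet transform splits a signal into an
approximation block and per-level detail blocks: level 1 yields CA\_1
and CD\_1, level 2 re-decomposes CA\_1, and after \(n\) levels the
blocks are CA\_n, CD\_n, …, CD\_1. Coarse blocks capture the slow
morphology of the curves; fine detail blocks mostly carry noise. The
pruned feature vector \(W_n(m)\) keeps the \(m\) coarsest blocks; it is
always a prefix of \(W_n(m+1)\), and \(W_n(n+1)\) is the complete
coefficient set.

Conventions, fixed by the published coefficient-count arithmetic:

* **Order-2 Daubechies filters (4 taps)** with **half-point symmetric
  boundary extension**, so each level maps a block of length \(L\) to
  blocks of length \(\lfloor (L+3)/2 \rfloor\). For the 876-point input
  at level 5 the cumulative coarse-to-fine counts are 30, 60, 117, 229,
  450, 889; for the 146-point input they are 7, 14, 25, 45, 83, 157.
  \(W_5(4)\) of the full input keeps 229 of 876 values (a 74 %
  reduction); \(W_5(1)\) keeps 30 (97 %).
* **The transform is applied to the whole concatenated vector**, not
  per curve — only whole-vector decomposition reproduces those counts.
* **Level 5 is the default operating point**; it is configurable.
* Coefficients are used unstandardized; scaling is a classifier-side
  option so that raw and wavelet inputs are treated uniformly.

Numerical notes: the analysis step takes the even-phase samples of the
valid convolution of the symmetrically extended block; the synthesis
step zero-stuffs at even positions, convolves with the reconstruction
pair and drops three leading samples. This pair reconstructs the input
to machine precision for any length (the test suite checks 1,000 random
lengths between 64 and 900 at a 1e-8 tolerance). Because the symmetric
extension duplicates boundary samples, the transform is a redundant
frame rather than an orthogonal map: Parseval equality holds exactly
only when the boundary neighbourhoods are zero, and the energy test is
stated that way rather than on arbitrary signals.

## Classifiers

**SVM.** A soft-margin binary SVM with Gaussian kernel
\(k(x, x') = \exp(-\lVert x - x'\rVert^2 / 2\sigma^2)\). The dual
quadratic program is solved exactly with `quadprog` (training sets here
are tens of compounds, so a dense solve is simple and reproducible; a
small ridge keeps the kernel matrix positive definite). Unstated
hyperparameters default to the stable choices: box constraint
\(C = 1\); bandwidth \(\sigma\) from the median heuristic on pairwise
training distances; features standardized with training-split
statistics (wavelet coefficients across blocks have very different
scales). The printed hard-margin constraint of the classical derivation
is implemented as the usual soft-margin \(y_i(w \cdot x_i - b) \ge 1 -
\xi_i\); real screening data are not separable. Decision-value ties
(exactly 0) resolve deterministically to the first class.

**ANN.** A feedforward network with hidden layers 24–12–6,
logistic-sigmoid activations, and one softmax output unit per cluster
with argmax readout (the output-layer size is a genuinely open choice;
one-unit-per-cluster extends unchanged to multi-cluster use). Training
is full-batch Adam, capped at 2000 epochs, with up to 5 random
restarts. A network is *accepted* once its training-set success rate
reaches 85 %; pushing the training target higher on small imbalanced
panels over-fits. A model that never reaches the threshold is returned
with `accepted = FALSE` rather than discarded, and evaluation counts
such repetitions while flagging them — silently dropping failed
repetitions would bias the reported success rate upward.

## Evaluation

The success rate (SR) of a task is the fraction of test compounds
assigned their correct cluster. Because per-cluster sample counts are
small, a single split is unreliable: the evaluator draws (by default)
100 independent 70/30 splits, stratified within each cluster with
round-half-up training counts (14 of 20, 9 of 13), and reports the mean
SR. Across a battery of binary tasks the summary is the average error
\(E = \operatorname{mean}(1 - SR)\). Two operating points are wired in
as presets: `svm11` (\(W_5(4)\) of TCRC(11)+NC, 229 inputs) and `svm1`
(\(W_5(6)\) of TCRC(1)+NC, 157 inputs); taking the better of the two
per task (`combine_best`) never increases any task's error.

## Multi-cluster trees

SVMs are binary, so multi-cluster tasks are arranged as a binary tree:
each internal node groups the clusters into two super-classes and
carries one SVM trained on its subtree's samples only. The grouping
matters when clusters are imbalanced — pairing a 4-compound cluster
against a 29-compound super-class trains a 3-vs-23 node at 70 %
training fraction, and the package warns when a node side has fewer
than 5 training samples. `enumerate_structures()` generates either
every full binary nesting (3 forms for 3 labels, 15 for 4, 105 for 5)
or a named shallow family: the pair-vs-pair forms plus, per label, one
one-vs-rest form peeling the remaining labels in their given order (7
forms for 4 labels). The package reports SR per structure rather than
asserting a universal winner; which structure is best depends on the
data.

## Dose–response curves and time-window selection

The toxicity effect at time \(t\) and concentration rank \(k\) is the
percentage deviation from the negative control, either pointwise,
\(TE_t(k) = 100\,(TCRC_t(k) - NC_t)/NC_t\), or through the area under
the curve from 0 to \(t\) (composite trapezoid on the hourly grid — the
quadrature rule is this package's choice). The 11-element TE vector at
a fixed time is the DRC profile: an 11-input classifier feature that is
far cheaper than any TCRC featurization. Scanning time and plotting the
repeated-split SR of a DRC-input SVM per hour shows *when* two clusters
become distinguishable; `select_time_interval()` keeps the longest
contiguous run of hours at or above a threshold (default: the profile
mean — the threshold is otherwise unconstrained by anything published,
and the longest-run rule resolves multi-segment profiles
deterministically), and `restrict_tcrc()` truncates the curves to that
window before the usual wavelet featurization. Hour 0 is excluded from
pointwise profiles (every curve is at its normalization anchor there),
and DRC features are used unstandardized since they are already
relative percentages.

## The synthetic world

Real screening panels of this kind are rarely deposited, so the
generator produces datasets with the structure the pipeline assumes —
it is a stated world, not a tuning dial. Each cluster is an *archetype*:
a maximal kill rate \(k_{max}\) (h⁻¹), Hill coefficient and EC50 for
the concentration response, an onset lag, an optional transient
stimulation (hormetic bump) and an optional recovery (kill stops after
a fixed duration). A compound draws its parameters log-normally
(sd 0.15) around its archetype; a curve is

\[ NCI(t, c) = g(t)\, s(t, c)\, e^{\varepsilon_m} + \varepsilon_a, \]

with \(g\) a logistic-style growth curve anchored at \(g(0) = 1\)
(plateau 8, rate 0.12 h⁻¹, half-time 24 h — typical proliferative
dynamics on the NCI scale), survival
\(s(t,c) = \exp(-k_{max}\, \frac{c^h}{c^h + EC50^h} \max(0, t -
\text{lag}))\) times the archetype's transient/recovery terms,
multiplicative log-normal noise \(\sigma_m = 0.05\) and additive noise
\(\sigma_a = 0.01\). The design is 11 concentrations in 1:3 serial
dilution from 100 (arbitrary molar-scale unit) plus a negative control,
hourly 0–72 h. The default `separable` preset has 7 clusters sized 20,
5, 4, 5, 6, 10, 13 (63 compounds), mirroring the skewed composition of
real MOA panels; `null` keeps the sizes but gives every cluster the
same archetype; `window` has two clusters identical (pure growth)
before hour 36 and divergent after.

What the generator does **not** emulate: replicate wells and well
position or edge effects; biophysically calibrated impedance;
compound-specific solubility artifacts; correlated (drift-like) noise;
clusters whose members genuinely straddle several dynamic shapes. A
green pipeline test on this world therefore establishes that the
machinery recovers cluster structure *when the generative story holds*,
not that any particular laboratory panel will classify at the same
rates.

## What the tests compute

The non-acceptance suite checks each operation against independent
oracles (closed-form cubics for the resampler, brute-force maxima,
analytic integrals, enumeration counts via the double factorial,
perfect reconstruction). The acceptance suite re-derives the
data-independent arithmetic exactly (coefficient counts, reductions,
worked SR/error examples) and runs the Monte-Carlo properties on the
stated worlds: the separable preset's two largest clusters reach mean
SR ≥ 0.90 under the `svm11` operating point with 100 × 70/30 splits;
the null preset stays within three Monte-Carlo standard errors of the
majority baseline; and DRC-guided window restriction loses no more
than 0.02 mean SR against the full window on the `window` preset.

## Known limitations

* The QP-based SVM is exact but dense: fine for panels of tens to a few
  hundred compounds, not for thousands (an SMO-style solver would be
  the next step).
* The ANN is a minimal reference implementation (full-batch Adam, fixed
  architecture); it exists to compare against the SVM, which is the
  recommended tool.
* Replicate wells are not merged; the reader expects one well per
  (chemical, concentration).
* Interval selection assumes a single contiguous informative window;
  profiles with two genuinely separated informative bands would be
  served by a multi-interval extension.
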