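---
title: "Fused texture and bispectral features for stroke severity classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused texture and bispectral features for stroke severity classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stroketex)
```

This vignette is the package's account of its science: the processing model
and its assumptions, the parameters that matter, the numerical conventions,
the design choices that were genuinely open, and the limits of what the
test suite can show.

## The classification problem

Ischaemic stroke severity is graded from brain imaging into three
syndromes: LACS (lacunar — small occlusions of vessels supplying deep brain
structures), PACS (partial anterior circulation — cortical,
middle/anterior cerebral territory) and TACS (total anterior circulation —
extensive anterior-territory damage). The three pathophysiologies leave
different *textural* signatures in a diffusion-weighted MRI slice: lesion
extent, contrast, and the spatial statistics of the surrounding tissue.
`stroketex` quantifies a slice with a fused feature catalog and measures,
via cross-validated classification, how much severity information that
texture carries.

## Preprocessing

Slices are loaded as grayscale intensities in $[0,1]$ (multi-channel
rasters are collapsed by channel averaging) and resized to a common
$200\times200$ working grid. Bilinear interpolation is the default because
it preserves constant regions and very nearly preserves the global mean;
nearest-neighbour is available for label-like images. Bicubic is not
offered — the underlying affine resampler supports bilinear and nearest
only, and nothing downstream is sensitive to the difference at this
resolution.

Contrast-limited adaptive histogram equalisation (CLAHE) then enhances
local contrast: the image is divided into non-overlapping tiles, each
tile's histogram is equalised towards uniform, histogram mass above a clip
limit is redistributed to prevent over-amplification in flat regions, and
the per-tile mappings are blended bilinearly to avoid tile-boundary
artefacts. Parameters:

* `tile` — tile side in **pixels**, default 8 (a $25\times25$ tile grid at
  the working resolution). Some CLAHE implementations parameterise the
  *grid*; the `grid` argument supports that reading directly.
* `clip` — normalised clip limit, default 0.01, interpreted as a fraction
  of the tile pixel count (the convention of the major image-processing
  toolboxes); it is converted to the per-bin relative limit
  `clip * bins` used by the underlying routine.
* `bins` — 256 histogram bins, the 8-bit convention.

Two behavioural notes, both visible in the tests: a constant image passes
through (up to one 8-bit gray level), because clipping makes the mapping
identity-like in flat regions; and the bilinear tile blending slightly
smooths a single hard step edge, so global contrast gains should be judged
on textured images, not on one ideal edge.

## Wavelet decomposition

Each preprocessed slice is decomposed with a separable 2D discrete wavelet
transform to three levels. Level $k$ yields an approximation image $A_k$
and *three* detail subbands (horizontal, vertical, diagonal); the pipeline
consumes one detail image $D_k$ per level, so the three subbands are fused
by a configurable rule — `mean_abs` (default; the mean of the absolute
subbands, which keeps energy from all orientations), `diagonal`, or
`max_abs`. The feature extractors therefore always see exactly
$1 + 3 + 3 = 7$ sub-images per slice.

Design choices made here:

* **Family.** Unconstrained by the method itself; `haar` is the default
  because it is the simplest orthonormal family and makes the energy
  invariants exact. `db2` and `db4` are available.
* **Boundaries.** Periodization (odd-length signals replicate their last
  sample) rather than symmetric reflection. This is deliberate: with
  periodization the subband shapes halve (ceiling) exactly at every level
  for every filter length, and orthonormal families conserve energy across
  the level-1 subbands to machine precision — both properties are asserted
  in the test suite, and both fail at the boundary for reflected
  convolution with filters longer than 2.
* **Renormalisation.** Sub-images are rescaled to $[0,1]$ before texture
  extraction so gray-level quantization is well defined per sub-image; a
  constant (e.g. zero-detail) sub-image rescales to all zeros.

## The fused feature catalog

Per sub-image, three extractor families run on an 8-level uniformly
quantized copy (GLCM/GLRLM) or on the continuous image (HOS):

**GLCM (14 features).** The gray-level co-occurrence matrix at distance 1
is accumulated over the four standard angles (0°, 45°, 90°, 135°),
symmetrised, angle-averaged and normalised — the standard rotation-robust
Haralick protocol. The default feature set holds autocorrelation, maximum
probability, dissimilarity, entropy, cluster shade, sum average, sum
entropy, sum variance, difference variance, difference entropy, the two
information measures of correlation, contrast and homogeneity. The
registry also implements cluster prominence, and `glcm_features()` accepts
any subset, so the fourteenth-feature choice is swappable rather than
baked in. Conventions: gray-level indices are 0-based, logarithms natural
with $0\log 0 = 0$, sum variance follows Haralick's original definition
(second moment of the level-sum distribution about the sum-entropy value),
and IMC1 returns 0 (with a message) when both marginal entropies vanish.
Eight gray levels keep the $L\times L$ matrix well populated on
$200\times200$ (and smaller subband) images; 16/32/256 are configurable.

**GLRLM (11 features).** Maximal runs of equal gray level are counted per
scan direction; features (short/long run emphasis, gray-level and
run-length non-uniformity, run percentage, low/high gray-level emphasis
and the four joint emphases) are computed per direction and averaged over
the four directions. Gray-level weights are 1-based so level 0 cannot
divide by zero. The conservation law "every pixel belongs to exactly one
run" is asserted against a pixel-walking oracle.

**HOS (5 features × angles).** For each projection angle
$\theta \in \{1^\circ,\dots,180^\circ\}$ the mean-subtracted image is
projected onto the detector axis (unit pixel spacing), and the direct
single-segment bispectrum
$B(f_1,f_2) = X(f_1)X(f_2)X^*(f_1+f_2)$ is evaluated from the zero-padded
FFT over the non-redundant region
$\Omega = \{0 \le f_2 \le f_1,\ f_1+f_2 \le f_s/2\}$. Five features
summarise each $B$: the normalised bispectral entropies of order 1–3
(Shannon entropy of $|B|^q/\sum|B|^q$, the convention of the HOS feature
literature), the phase entropy over 64 uniform bins of $\arg B$ on
$(-\pi,\pi]$, and the mean magnitude. An identically zero bispectrum maps
to all-zero features by convention. Estimator choices: `nfft = 256`,
rectangular window, single segment — projections are short
(under 300 samples), so segment averaging would leave too little data per
segment. A $200\times200$ image's diagonal projection spans 283 unit bins,
which exceeds `nfft`; the implementation trims all-zero tails and then
center-crops to `nfft`, discarding only the extreme image-corner bins
(background in brain-masked images). `nfft` and the bin count are
configurable if that trade-off is wrong for other data.

Catalog arithmetic, asserted at assembly time: $(14+11)\times 7 = 175$
texture features plus $5 \times 180 \times 7 = 6300$ HOS features, 6475
columns in total, in a fixed order (GLCM block, GLRLM block, HOS block;
sub-images ordered orig, A1–A3, D1–D3 within each block).

## Class imbalance: ADASYN

Severity classes are heavily imbalanced in clinical practice (the shipped
composition example is 222/18/27 — an 83.15% majority). ADASYN
oversamples each minority class one-vs-rest against the largest class:
class deficit $G = (m_{maj} - m_{min})\beta$, per-seed difficulty $r_i$ =
foreign fraction among the seed's $k=5$ nearest neighbours in the full
set, allocation $g_i$ proportional to normalised $r_i$, and synthetics
$x_i + \lambda(x_z - x_i)$, $\lambda\sim U[0,1)$, towards a random one of
the seed's $k$ nearest same-class neighbours. All originals are retained;
every synthetic is a convex combination of two same-class originals
(asserted geometrically in the tests). Two conventions worth noting:
allocation uses half-up rounding (round-to-even would allocate zero
synthetics whenever the uniform fallback gives every seed exactly half a
unit), and when no seed has any foreign neighbour the allocation falls
back to uniform so the class still balances. Balancing runs in
flattened-image space before feature extraction, matching the pipeline's
dataflow; `balance.space = "features"` offers the leakage-safer
alternative of balancing the feature table instead. Balancing before
cross-validation places synthetic/real pairs across folds; the package
implements this documented order and leaves per-fold balancing to the
caller via the feature-space mode.

## Ranking and model evaluation

Each feature is scored by the one-way ANOVA F statistic across the three
classes; features are ordered by descending $F$ (identical to ascending
$p$, since the F tail is monotone), ties broken by column position.
Degenerate conventions: zero within-class variance with non-zero
between-class variance scores $F=\infty$ ($p=0$); an entirely constant
feature scores $F=0$ ($p=1$). No multiple-testing correction is applied —
the statistic orders features, it does not test hypotheses. Inside
cross-validation the ranking is recomputed on each fold's training part by
default, which avoids selection leakage; passing a precomputed ranking
reproduces the "rank once globally" protocol.

Sequential forward selection walks the ranked list once, keeping a
candidate only if it strictly improves the internal validation accuracy (a
stratified 5-fold split of the training part), and stops after `patience`
consecutive non-improvements (default 5; 0 yields the longest
strictly-improving prefix) or `max_features` kept (default 50). The
stopping rule is a design choice — greedy selection needs one, and a
patience-bounded pass is cheap and deterministic given the seed.

Four SVM kernels are evaluated: linear, quadratic and cubic polynomial
(`coef0 = 1`), and RBF with $\gamma = 1/(p\,\mathrm{var}(X))$ computed on
the standardized training matrix; $C = 1$ throughout; features are
standardized with training-split statistics. Multiclass decisions use
one-vs-one voting. All hyperparameters are exposed in the configuration.

**Confusion collapse.** The three-class test outcome of each fold is
collapsed to binary TP/TN/FP/FN counts. The default rule designates a
*reference class* (the most frequent label unless specified) as the
negative class; every test sample then contributes exactly one count — TP
or FN for non-reference samples classified correctly or not, TN or FP for
reference samples. Two properties recommend this rule: the reported ACC
equals plain multiclass accuracy (so chance level for three balanced
classes is ~33%, and label-shuffling experiments land there), and the
positives-to-negatives ratio is about 2:1 for balanced three-class data,
matching the shape of the reference fold tables shipped with the package.
Micro-averaged one-vs-rest collapse is available (`collapse = "micro"`)
but inflates ACC to $\tfrac13 + \tfrac23 a$ for multiclass accuracy $a$,
which makes chance sit at 55.6% rather than 33%.

**Metric arithmetic.** ACC, PPV, SEN, SPE (percent) and Dice are computed
unrounded; any zero denominator yields `NA`, never a silent 0. The
per-fold summary averages the *unrounded* per-fold metrics and counts are
summed — averaging already-rounded values fails to reproduce standard
published averages by the last digit. Presentation rounding is half-up to
2 decimals (`round_half_up()`): banker's rounding turns a Dice of exactly
0.925 into 0.92 where the tabulated convention prints 0.93.

## The phantom generator

Clinical MRI slices cannot ship with a package, so the generator emulates
the *study conditions* rather than anatomy: a smoothed Gaussian
random-field background (class-specific correlation length: 3/5/8 px for
LACS/PACS/TACS) inside an elliptical brain mask, plus one elliptical
lesion whose defaults scale by class — LACS small (8 px), central, high
contrast (0.50); PACS medium (20 px), off-centre, 0.35; TACS large (55 px,
covering over a quarter of the mask), 0.30. Pixel noise sd 0.02. Class
identity is deliberately carried by texture statistics, not by global
intensity, so the GLCM/GLRLM/HOS extractors are what separates the
classes. Everything is deterministic per seed; per-image seeds are drawn
from the dataset seed.

What the phantoms do **not** emulate: anatomy, MRI physics (no
pulse-sequence, bias-field or partial-volume modelling), inter-patient
variability, or the subtlety of real lesion boundaries. Consequently a
perfect phantom classification (the end-to-end runs reach 100% with the
default separations, and chance under label shuffling) validates the
*pipeline machinery* — extraction correctness, leakage-free evaluation,
metric arithmetic — and says nothing about accuracy on real stroke MRI.
The published-table reproductions in the test suite cover the metric
arithmetic of the clinical experiment; the clinical images themselves are
out of reach by design.

## Problem sizes and numerical conventions

The end-to-end runs in the tests and the acceptance script use 60 phantoms
per class at $200\times200$ with an 18-angle HOS grid (10°,20°,…,180°) —
the full 180-angle catalog is exercised on single images, where the
6475-column arithmetic is asserted exactly. These sizes give stable
accuracy estimates (stratified 10-fold, ~18 test samples per fold) while
keeping a full run around a minute.

Other conventions collected in one place: intensities live in $[0,1]$ from
load to extraction; quantization bins $[0,1]$ uniformly with the top edge
closed; all entropies are natural-log with $0\log0=0$; stratified folds
stagger per-class remainders so test-set sizes differ by at most one; all
randomness flows from one run seed through named substreams (balance, cv,
per-fold sfs, phantom); and every "derived" expectation in the test suite
is computed by an independent oracle (double-loop GLCM, pixel-walking run
enumerator, two-pass ANOVA, full-plane bispectrum) rather than frozen from
the implementation under test.

## Known limitations

* The bispectral phase-coupling property is an *ensemble* property: the
  magnitude of a single-segment bispectrum at the coupled bin is
  phase-blind; only the ensemble-averaged complex bispectrum distinguishes
  coupled from uncoupled triples. The tests average over 50 realisations.
* CLAHE's clip-limit semantics differ between toolboxes (fraction of tile
  pixels vs per-bin multiplier); the conversion used here is documented
  above, but numeric outputs will not match a toolbox with different
  semantics bin-for-bin.
* ADASYN in flattened-image space measures difficulty with Euclidean
  pixel distance, which is a crude similarity for images; it matches the
  pipeline's documented dataflow, but the feature-space mode is the better
  default when leakage control matters more than fidelity to that flow.
* Greedy SFS with an internal 5-fold criterion is variance-prone on small
  folds; the patience bound and fixed seeds make it reproducible, not
  optimal.
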