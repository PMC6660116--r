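---
title: "Spectral geometry features for ultrasound tumor classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral geometry features for ultrasound tumor classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffgf)
```

## The problem and the model

Distinguishing benign from malignant tumors on B-mode ultrasound is
examiner-dependent; computer-aided pipelines aim to supply a
reproducible second reader.  This package implements one such pipeline
built on a deliberately low-dimensional descriptor of image texture: the
geometry of the central blob of the Fourier power spectrum.

The intuition is physical.  A smooth, fluid-filled benign cyst is close
to a piecewise-constant image: its spectrum is a narrow lobe around the
zero-frequency (DC) term.  A malignant mass carries papillary
projections, septa and irregular walls — geometric discontinuities whose
spectral signature is energy spread along rays through DC and into the
mid frequencies.  Thresholding the log-spectrum therefore yields a
central connected region that is small and slim for simple images and
large and round for structured ones.  The moment ellipse of that region
gives three numbers — major axis, minor axis, area — which act as an
aggressive but informative dimension reduction of the whole image.

Formally, for an `M x N` image `f` the package computes

$$F(u,v) = \frac{1}{MN}\sum_{x=0}^{M-1}\sum_{y=0}^{N-1}
  f(x,y)\, e^{-2\pi i (ux/M + vy/N)},$$

keeps the modulus $\|F\|$, shifts DC to the grid center, binarizes
$\log(1+\|F\|)$ at a trained threshold, and fits the moment ellipse to
the 8-connected component containing the DC cell.  Classification then
operates on the $(major, minor, area)$ triples with targets
$t_n \in \{+1, -1\}$ (+1 = benign, matching the problem's original
labeling; sensitivity is reported for the +1 class by default and can be
flipped with the `positive` argument, since the clinical convention
would call malignancy "positive").

## Threshold training: why the cut is global, not per image

The binarization threshold is the one genuinely trained ingredient of
the feature extractor.  Two designs were on the table:

* **Per-image quantile**: each image is cut at its own `q`-quantile of
  the log-modulus.  Robust to brightness differences, but it fixes the
  number of super-threshold cells at `(1 - q) * M * N` for *every*
  image.  On phantoms this inverts the method's premise: a smooth
  image's narrow spectral lobe absorbs the whole fixed budget into one
  compact central blob (measured area 407 at `q = 0.975`), while a
  textured image scatters the same budget across frequencies (area 199).
  Smooth images would systematically get the *larger* areas.
* **Pooled global cut** (the implemented default): the threshold is the
  `q`-quantile of the log-moduli pooled over the *training* images, one
  absolute value applied to all images.  Images with more spectral
  spread now grow genuinely larger central blobs; mean area rises
  strictly with the phantom texture density (255 → 494 → 773 → 951 over
  densities 0/5/15/30 at `q = 0.95`, 20 seeds each).

The quantile `q` itself is selected from the grid
`r paste(ffgf_quantile_grid(), collapse = ", ")` by maximizing the
Fisher ratio (between-class over within-class variance) of the area
feature on training data — the simplest supervised separability
criterion.  Ties break toward the smaller quantile; a candidate that
separates the classes with zero within-class variance is accepted
immediately.  Inside cross-validation the whole procedure — pooling,
quantile selection — reruns on each fold's training portion only
(`threshold_trainer()`), so the held-out case never influences its own
features' threshold; the hook records which cases it saw, and the test
suite audits that record.  `binarize_spectrum()` retains the per-image
quantile as a fallback when no trained cut is supplied, because it needs
no training data and its degenerate behavior is easy to reason about.

Raw spectra are not thresholded directly: the dynamic range is dominated
by DC, and `log(1 + x)` is the standard compression for both display and
thresholding.  The DC cell is always forced into the mask so a central
component exists even for constant images (which yield the degenerate
triple (1, 1, 1)).

## The moment ellipse

The central component is summarized by the ellipse with the same second
central moments: axis length equals $4\sqrt{\lambda}$ for each
eigenvalue $\lambda$ of the 2x2 covariance of the component's pixel
coordinates.  This convention reproduces the exact diameters of an ideal
filled ellipse (a filled disc of radius `r` has coordinate variance
$r^2/4$ per axis).  Axes are floored at 1 pixel so thin and single-pixel
components keep `major >= minor >= 1`; a single-pixel blob returns
(1, 1, 1).  Connectivity is 8-neighbor, and only the component
containing DC counts — distant speckle peaks above threshold are
deliberately ignored.

## Classifiers

All four families are implemented from first principles and expose a
real-valued decision score (`label = sign(score)`, with score exactly 0
mapped to +1 — a documented, reproducible tie rule).

* **KNN** (`knn_fit`): majority vote among the `K` nearest neighbors
  under the Minkowski metric $d(a,b) = (\sum_i |a_i - b_i|^p)^{1/p}$
  (`p = 1` city block, `p = 2` Euclidean).  Distance ties break toward
  the lower training index; the score `(votes_+ - votes_-)/K` feeds the
  ROC.
* **Linear discriminant** (`ld_fit`): minimizes the squared error of the
  affine score $w_0 + w \cdot x$ against the ±1 targets; solved through
  the SVD pseudoinverse of the bias-augmented design, so rank-deficient
  designs get the minimum-norm solution.
* **Linear SVM** (`svm_fit`): the SMO trainer solves the soft-margin
  dual with KKT tolerance `1e-3`, a deterministic first-violator outer
  scan, a second index chosen by maximal $|E_i - E_j|$ with fallback to
  the next candidate when a pair is blocked, and a pass budget of
  `10 N` (exceeding it raises an error carrying the duality gap).  The
  LS trainer solves the least-squares SVM system (equality-constrained
  form with ridge `1/C`).  `C` defaults to 1; the source study does not
  state its value.
* **ELM / OP-ELM** (`elm_fit`, `op_elm_fit`): random hidden layer
  (uniform `[-1, 1]` weights and biases for linear and sigmoid nodes;
  gaussian nodes centered on training points with widths uniform on
  `[0.2, 0.8]` times the median pairwise distance), output weights by
  pseudoinverse.  Mixed layers split nodes equally over the listed
  types, remainders to earlier types.  Inputs are standardized
  internally (training mean/sd, stored in the model): with `[-1, 1]`
  weights, a raw feature on the scale of blob areas (hundreds of pixels)
  saturates every sigmoid node, and on phantom features an
  unstandardized OP-ELM measurably collapses to chance.  OP-ELM ranks
  the hidden-layer columns by their LARS entry order against the
  targets, evaluates Allen's PRESS statistic
  $\mathrm{mean}_i\,[(t_i - \hat y_i)/(1 - h_{ii})]^2$ on every prefix,
  and keeps the PRESS-minimal prefix (ties toward fewer neurons).
  PRESS requires more cases than regressors, so the initial node count
  (default 100) is capped at `N - 2`; the "very high initial number"
  the OP-ELM literature suggests is incompatible with leverage-based
  leave-one-out and this cap is the package's resolution.  Every
  stochastic fit takes an explicit seed.

## Evaluation protocol

`loocv()` refits everything — classifier *and* threshold training — `N`
times, scoring one held-out case per fold, and computes ACC, rank-based
AUC (Mann-Whitney with ties counted 1/2, equivalent to trapezoidal ROC
integration), sensitivity and specificity once from the pooled
predictions.  For the randomly initialized ELMs, `repeat_elm_loocv()`
repeats the whole procedure `R = 30` times with consecutive seeds and
reports the best run (highest ACC, ties by AUC — the selection key for
"best" is not specified upstream and this one is the package's choice)
plus mean and sample (n−1) standard deviation of ACC, AUC and selected
neuron count.  A linear-node-only ELM has a seed-independent fit
whenever the hidden layer spans the full affine class, so its repetition
standard deviation is exactly zero — a property the acceptance suite
asserts.

## The phantom generator: what it does and does not emulate

`gen_phantom()` states the world the pipeline is tested in: a dark
background, a soft-walled elliptical "cyst" (edges blurred with a
Gaussian of sd 2 px — benign walls are smooth), `Poisson(lambda)` sharp
internal structures drawn uniformly inside the cyst (bright blobs,
septa, arcs), multiplicative exponential speckle
(`pixel * ((1 - s) + s * Exp(1))`), clipping to `[0, 255]`.  Defaults:
128x128 pixels (large enough for stable spectra, small enough for fast
tests), `lambda = 2` for benign, `25` for malignant, speckle `0.3` — a
moderate level for B-mode-like appearance.  The generator is a pure
function of its spec: same seed, same bytes.

What it deliberately does **not** model: the scanner point-spread
function, attenuation and depth-dependent gain, acoustic shadowing,
refraction artifacts, or the biological variety of real tumors.  A green
end-to-end test therefore establishes that the implementation separates
classes whose texture differs the way the method assumes — not that the
method reaches any particular accuracy on clinical images.  The
headline accuracies of the original clinical study (85–88%) were
measured on a 187-image hospital dataset that is not publicly available
and are out of scope here; the synthetic benchmark's accuracies
(~0.95+) are properties of the stated phantom world only.

`gen_feature_clusters()` provides the complementary classifier-only
world: two shared-covariance Gaussian classes in feature space, where
the linear discriminant is Bayes-optimal; at 6-sigma mean separation all
linear-family classifiers should exceed 95% LOO accuracy, and the
acceptance suite requires exactly that.

## Numerical conventions

* DFT normalization `1/(MN)` on both real and imaginary parts; under it
  Parseval reads $\sum \|F\|^2 = \frac{1}{MN}\sum f^2$ (asserted to
  1e-9 against a brute-force double-loop DFT).
* Spectrum centering puts DC at `(floor(M/2), floor(N/2))` (0-based),
  also for even sizes.
* Phase uses the four-quadrant `atan2` in $(-\pi, \pi]$, with
  `Re = Im = 0` mapping to 0; phase is computed for completeness but
  unused by the features (the modulus carries the geometry).
* Quantiles are R's default type-7 sample quantiles.
* PRESS leverages are clipped at `1 - 1e-10`; pseudoinverse tolerance is
  the usual `max(dim) * eps * max(singular value)`.
* LARS ranks standardized columns; zero-variance columns go last, and a
  numerically singular active Gram matrix falls back to ordering the
  remaining columns by current correlation.
* Tie rules throughout (score 0 → +1, distance ties → lower index,
  quantile ties → smaller q, PRESS ties → fewer neurons) are fixed so
  every run is bit-reproducible given seeds.

## Interfaces

Images are 8-bit grayscale PNG (color collapses by Rec. 601 luma; TIFF
is not supported because no reader is available in the supported
dependency set).  ROI masks are same-size PNGs, nonzero = inside; the
crop keeps the mask's bounding box and fills outside-mask pixels with
the masked mean, avoiding the sharp synthetic edge a zero fill would
inject into the spectrum.  Enhancement is a 3x3 median filter plus a
1st–99th percentile contrast stretch, each stage optional; on a constant
image the stretch is skipped with a warning.  In the
"roi-enhanced" setting the full image is enhanced first and cropped
second, mirroring the order the acquisition protocol describes.  Feature
tables are CSV (`image_id,major,minor,area,label`), configs YAML,
reports and serialized models flat JSON.

## Known limitations

* The trained threshold assumes training and test images share an
  intensity regime; the pooled absolute cut is not invariant to global
  brightness rescaling of a single test image (the per-image fallback
  is, but weakens class separation).
* SMO's pass budget can in principle be exhausted on pathological data;
  the error then reports the duality gap rather than returning a
  non-converged model.
* The phantom world is favorable: real clinical variability will lower
  every reported accuracy.
* KNN on these three features is implemented for completeness; on both
  the original clinical data and the phantom world it is the weakest
  family, and the package makes no attempt to tune it beyond `K` and
  `p`.
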