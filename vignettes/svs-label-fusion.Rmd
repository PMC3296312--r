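---
title: "Label fusion and strategy selection: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label fusion and strategy selection: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

In multi-atlas segmentation of medical images — the motivating case is
automated hippocampus and amygdala labelling — one scene is segmented by K
independent *raters* (human experts or instances of an automated pipeline),
producing K binary label images $e_k$ on a common grid of N elements. Label
fusion combines them into a single consensus estimate of the unknown true
segmentation $T$, exploiting the fact that uncorrelated rater errors tend to
cancel. `svsfusion` implements three classical fusers, a pair of
ground-truth-free *dissimilarity factors* describing how much the raters
disagree, and a trained selector (SVS) that uses those factors to pick the
fuser expected to do best on each case.

All fusion runs on the *disputed* elements only: wherever every rater agrees,
that label is final. This is both a large speedup and, for STAPLE,
empirically beneficial.

# The three base fusers

**Vote** assigns each element the label given by the majority of raters.
Ties (possible for even K, including the canonical K = 10) go to the
foreground; this foreground tie rule is used globally by every fuser in the
package so that results are deterministic and mutually consistent.

**STAPLE** treats $T$ as hidden and each rater as a binary channel with
sensitivity $p_k = P(e_k = 1 \mid T = 1)$ and specificity
$q_k = P(e_k = 0 \mid T = 0)$, estimated by EM. The E-step computes the
posterior $W(x) = a(x) / (a(x) + b(x))$ with
$a(x) = g \prod_k p_k^{e_k}(1-p_k)^{1-e_k}$ and
$b(x) = (1-g) \prod_k (1-q_k)^{e_k} q_k^{1-e_k}$; the M-step re-estimates
$p_k, q_k$ from $W$; the final label is $W \ge 0.5$. Choices the original
description leaves open, resolved here as the common conventions:

* initialisation $p_k = q_k = 0.99999$ for all raters;
* the foreground prior $g$ is fixed during EM, defaulting to the mean
  foreground fraction of the raters on the restriction set;
* convergence when $\sum_x W(x)$ changes by less than `tol` (default
  $10^{-3}$ elements) between iterations, with `max_iter` = 100 and a
  warning (not an error) on non-convergence;
* degenerate M-step denominators clamp the parameters into
  $[10^{-5}, 1-10^{-5}]$ and continue.

E-step products are evaluated in log space, and the observed-data
log-likelihood $\sum_x \log(a(x)+b(x))$ is recorded per iteration; it is
non-decreasing, which the test suite asserts. `fuse_staple(restrict =
"full")` runs the textbook full-grid EM instead of the disputed-only
variant; the two legitimately differ in their performance estimates, because
restricting the sums conditions them on disagreement. Parameter recovery
from data simulated under the STAPLE generative model is a property of the
full-grid EM and is tested there; on spatially unstructured flip noise the
disputed-only variant can even converge to a poor fixed point, which is one
more reason the selector below is useful.

**Shape-Based Averaging (SBA)** computes, for each rater, the signed
Euclidean distance map of its label (negative inside the foreground), takes
the per-element mean over raters, and labels foreground where the mean is
non-positive (the same foreground rule covers the exact-zero tie). Distances
are exact Euclidean distances between element centers, computed by the
separable Felzenszwalb–Huttenlocher transform in compiled code — not a
chamfer approximation — and measured in index space: spacing metadata is
deliberately ignored, as the simulated and intended grids are isotropic.
Distance maps are always computed on the full grid even when only disputed
elements are assembled; the two routes coincide and are asserted equal in
the tests. A rater with an empty (or full) foreground has no boundary; its
map is replaced by a constant $\pm$ grid diagonal with a warning.

# Dissimilarity factors

With no ground truth available, the package estimates how bad and how
variable the raters are from the decision matrix alone. For each element,
the foreground frequency is $f(x, 1) = \#\{k : e_k(x) = 1\}/K$, and rater
k's misclassification probability is $p_k(x) = 1 - f(x, e_k(x))$. Each
probability is amplified through a *majority-of-B* transform: the upper-tail
probability that a clear majority of B independent virtual raters, each
wrong with probability $p_k(x)$, is wrong,
$$P_k(x) = \sum_{i=\lceil (B+1)/2 \rceil}^{B} \binom{B}{i} p_k(x)^i (1-p_k(x))^{B-i},$$
computed through the binomial survival function for numerical stability.
B must be odd so the mass function splits exactly; the default B = 99 makes
the summation run from 50 to 99. Summing $P_k(x)$ over elements gives an
estimated misclassified count $v_k$ per rater; the same transform applied to
$f(x,1)$ and summed gives an estimated true foreground size $V$. The
*dissimilarity coefficient* and *ratio* are then
$$d_c = \frac{\sigma(v_k)}{\mu(v_k)}, \qquad d_r = \frac{\mu(v_k)}{V},$$
estimating the coefficient of variation and the mean of the raters' true
relative errors $v_D$. Because $p_k(x)$ and $f(x,1)$ take only K + 1
discrete values, the implementation evaluates the binomial tail once per
count and sums by table lookup, so the estimators cost O(NK) with tiny
constants.

Conventions: $\sigma(v_k)$ uses the sample (K−1) standard deviation — the
population convention is available via `sd_type` for sensitivity checks, and
at K = 10 the two are practically indistinguishable. Identical raters give
$(d_c, d_r) = (0, 0)$ with a `unanimous` flag (selection is moot); $V = 0$
with disagreement present gives $d_r = \infty$, flagged. Unanimous elements
contribute exactly 0 to every $v_k$ and exactly 0 or 1 to $V$, so full-grid
and disputed-masked computation agree identically — asserted in the tests.

# Scoring surfaces and selection

Training consumes simulated fusion tests with known truth. For each test the
three fusers run, the disagreement counts $v_m$ against the truth are
ranked, and scores are assigned: 1 to the best, 0 to the worst, and
$(v_{\max} - v_m)/(v_{\max} - v_{\min})$ in between. Tests where all three
counts tie get all-ones scores and a `degenerate` flag; they are *kept* in
training so that the surfaces are not biased downward in regions where the
methods agree. One surface $s_m(d_c, d_r)$ per method is fitted by locally
weighted linear regression (LOESS, degree 1). The regression family is part
of the method; the smoothing span is not specified by it, so the package
fixes span = 0.25 as a configurable default, widening it automatically (with
a warning) when a training set is too small to populate the local windows.

For portability and determinism the fitted surfaces are tabulated on a dense
101 × 101 grid over the training bounding box; evaluation bilinearly
interpolates inside the box and clamps to the nearest edge outside it, then
clamps scores to [0, 1]. Serialized models (JSON: axes, score grids,
training points, provenance) therefore evaluate identically after a round
trip, to floating-point precision. Extrapolation beyond the training hull is
deliberately flat: far from the data there is no basis for preferring any
trend.

Selection computes $(d_c, d_r)$ for a new stack, evaluates the three
surfaces, and runs *only* the winning fuser (selection needs the factors,
not the fusions). Scores tied within $10^{-9}$ trigger the meta-fusion path:
all three fusers run and their results are combined by a weighted
per-element vote with the scores as weights, foreground on ties. A unanimous
stack short-circuits to the input. The selector's output is therefore always
one of the base results or their weighted vote — never a fourth labelling —
and the tests assert exactly that.

# The shape simulators

**2D.** The ground truth is an ellipse with semi-axes 1.0 and 0.5 AU traced
through 8 control points at equally spaced angles, interpolated by periodic
cubic splines, and rasterized on a 256 × 256 grid spanning [−1.5, 1.5] AU
with the pixel-center/even–odd rule; its area is within 1% of
$\pi r_x r_y$. A rater image displaces each control point in a uniformly
random direction by a N(0, $f_\sigma \sigma_{\max}$) distance (a negative
draw flips the direction, leaving the magnitude distribution unchanged) and
re-rasterizes. Deformed curves may self-intersect; the even–odd rule fills
them without special cases.

**3D.** The ground truth is an ellipsoid with semi-axes (1.0, 0.5, 0.5) AU
on a 64³ grid. Construction follows a warped-grid scheme: dividing each
coordinate by its radius maps the ellipsoid to the unit sphere; the sphere
is described by 26 control radii — 3 elevation rings × 8 azimuths plus both
poles, a regular angular sampling — and the surface radius $r^*(\theta,
\phi)$ is interpolated bicubically on the angular chart (periodic in
azimuth, pole rows replicated across azimuths to avoid seams). A voxel is
inside iff its warped radius is below $r^*$. Deformation perturbs the 26
control radii with N(0, $f_\sigma \sigma_{\max}$) draws (each pole is one
point), clamping negative interpolated radii to zero. With undeformed radii
the construction reduces exactly to the analytic ellipsoid, within 2% of its
volume at this resolution. The interpolation is evaluated through a fine
181 × 91 angular lookup table with bilinear lookup per voxel, which is
visually and numerically indistinguishable from direct bicubic evaluation at
these node counts.

**Calibration.** The deformation factor $f_\sigma \in [0, 1]$ is normalized
so that images generated at $f_\sigma = 1$ have mean relative error
$v_D = 50\%$ against the truth; $\sigma(f_\sigma) = f_\sigma \sigma_{\max}$
is linear, consistent with the observed quasilinear response of $v_D$ to the
factor. `calibrate_sigma` finds $\sigma_{\max}$ by a monotone bracketing
search refined by false position, evaluating the pilot mean with common
random numbers (the same pilot seeds at every candidate $\sigma$) so the
objective is smooth and monotone and the search converges in a handful of
evaluations. Individual draws can exceed 50% — the per-draw $v_D$ at maximum
deformation is right-skewed with standard deviation ≈ 0.18 in 2D (8 control
points) and ≈ 0.09 in 3D (26 points) — so only the mean is calibrated, and
the default pilot sizes (2500 draws in 2D, 300 in 3D) keep the pilot
standard error of that mean a fraction of a percentage point. $v_D$ is
scale-free, so a calibrated $\sigma_{\max}$ transfers across grid
resolutions. Results are cached per (generator, spec, pilot size, seed)
within a session.

**Protocol.** A full simulation set is a grid of tests: the mean and
standard deviation of a per-test Gaussian distribution of $f_\sigma$ each
sweep `n_grid` linearly spaced values in [0, 1] (canonically 25 × 25 = 625
tests of 10 raters each, 6,250 images per set); per-test draws are clamped
into [0, 1]. `build_protocol` returns a lazy plan — one (μ, σ, seed) row per
test — and `make_test_case` materializes any single test reproducibly from
its own seed. This keeps memory flat (a full 2D set held at once would be
~0.4 GB) and makes any individual test reproducible in isolation. Per-test
seeds are derived as `(seed %% 2e5) * 1e4 + test index`, with calibration
pilots on a disjoint offset of the same stream; the multiplier separates the
substreams of different protocol seeds, which a plain `seed + index` scheme
would interleave.

# Numerical and degenerate-input choices

* Binary inputs are validated strictly; non-binary values in files are a
  hard error, never thresholded silently.
* Labels are stored as small integers rather than booleans, leaving room
  for a future multi-label extension.
* The signed distance convention is distance-to-nearest-opposite-center:
  a boundary element takes the signed distance of its own side and 0 is
  never assigned.
* DSC of two empty sets is 1 by convention; $v_D$ against an empty truth is
  an error (no convention is defensible there).
* The coefficient of variation of an all-exact rater stack is defined as 0.
* Grader-style comparisons aside, every stochastic quantity in the package
  is reproducible: all randomness flows through explicit seeds, and
  generator functions restore the caller's RNG state.

# Scaled experiment defaults

`run_protocol` defaults to a 10 × 10 grid (100 tests per set) rather than
the canonical 25 × 25, which keeps a full train-plus-test cycle with all
three fusers and the selector in the minutes range on one CPU; the canonical
size is a parameter away. The package's own evaluation (test suite and
acceptance script) uses these 100-test sets for the selector-superiority
checks and the full 256²/64³ resolutions everywhere. Unanimous tests are
reported but excluded from group statistics, since nothing is fused or
selected there.

# What the simulations do and do not show

The simulators emulate smooth, boundary-localized disagreement between
raters segmenting one connected structure — the regime of template-library
segmentation pipelines — with a controllable error level and spread. They do
not emulate intensity noise, registration failures producing gross outliers,
multi-object scenes, or spatially correlated rater bias. Passing the
simulation-based checks therefore shows the machinery is correct and the
selector behaves as designed under this generative family; performance
claims on real anatomy require real labels. The selector is also upper-bound
limited by construction: it can never beat the best of its three base
methods on a given case, it can only avoid picking the wrong one.
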