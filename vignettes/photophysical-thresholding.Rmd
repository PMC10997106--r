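---
title: "Photophysical thresholding of EMCCD images: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photophysical thresholding of EMCCD images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The noise model

An EMCCD camera converts photons into a stored integer count through four
stochastic stages. Photoelectrons arrive as a Poisson variable
$n_{ie} \sim \mathrm{Pois}(\lambda)$; the electron-multiplication register
amplifies them into $n_{oe} \sim \Gamma(\text{shape}=n_{ie},
\text{scale}=g)$ (with $n_{oe}=0$ when $n_{ie}=0$, and $n_{oe}=n_{ie}$ when
the gain is off); readout adds Gaussian noise and an offset,
$n_{ic} \sim \mathcal N(n_{oe}/f + \Delta,\ r^2)$; finally $n_{ic}$ is
rounded to the nearest integer. The four chip constants
$\{g, f, r, \Delta\}$ are static camera properties (apart from the gain
setting) and are held in a `chip_params` object.

The characteristic function of the stored count has a closed form,

$$\varphi(p) \;=\; e^{-p^2 r^2/2 + ip\Delta}\;
  \exp\!\Big\{\lambda\Big(\frac{1}{1 - ip\,g/f} - 1\Big)\Big\}\;
  \frac{\sin(p/2)}{p/2},$$

where the last factor is the rounding kernel (gain off, the middle factor
becomes $\exp\{\lambda(e^{ip/f}-1)\}$). `cf_emccd()` evaluates it;
`build_distribution()` inverts it numerically to the exact probability mass
function; `emccd_moments()` gives the closed-form mean
$\mu = \lambda g/f + \Delta$ and variance
$\sigma^2 = 2\lambda(g/f)^2 + r^2 + 1/12$, the $1/12$ being the
uniform-model variance of the rounding error.

## Numerical inversion

The PMF at integer $n$ is $(2\pi)^{-1}\int e^{-ipn}\varphi(p)\,dp$. We use
trapezoidal quadrature on a symmetric grid, exploiting
$\varphi(-p)=\overline{\varphi(p)}$ to integrate on $[0, P]$ only. The
cutoff $P$ is set where the modulus envelope of $\varphi$ falls below
$10^{-12}$; the Gaussian readout factor makes that quick ($P \approx 7.4/r$).
When $r=0$ only the $\sim 1/p$ rounding kernel decays and a fixed $P=64\pi$
is used. The grid spacing is chosen so that the aliasing period of the
discretised transform is at least four times the support width (minimum
1024 counts). Quadrature ripple can leave tiny negative PMF values; values
above $-10^{-9}$ are clipped to zero and the mass renormalised, anything
more negative aborts as a grid failure. The support starts at
$\mu \pm 8\sigma$ and is extended until the captured mass reaches
$1 - 10^{-9}$.

Everything downstream shares one precomputed "engine" per chip and support
(the $\lambda$-independent factors and the cosine/sine matrices), so a PMF
evaluation at a new $\lambda$ costs two matrix-vector products. This is
what keeps the truncated-likelihood scan below a second for a 64x64 tile.

The inversion is validated against an independent oracle: a $10^6$-draw
forward simulation of the physical chain agrees with the inverted PMF to a
total-variation distance of about $2\times 10^{-3}$ (sampling noise scale).

## Region sums

The p-value that a connected region of $k$ background pixels sums to at
least the observed total uses the $k$-th power of the characteristic
function, inverted exactly for $k \le 64$; above that a normal
approximation with mean $k\mu$, variance $k\sigma^2$ and a half-count
continuity correction takes over. At the switchover the two routes differ
by about $10^{-3}$ in p-value (the skewness of the Gamma stage), which is
negligible against the 0.01 decision level it feeds.

# Estimating the background strength

The background Poisson parameter $\lambda_{bg}$ is estimated from an image
that also contains signal, with no model for the signal: only counts below
a truncation point $N$ are fitted, with the truncated likelihood
$\prod_{n_j \le N}\mathrm{pmf}(n_j)/\mathrm{cdf}(N)$. A scan over candidate
truncations (from the 25% data quantile up to the maximum count, thinned to
at most 60 candidates evenly spaced in quantile space) fits
$\hat\lambda(N)$ by bounded golden-section search started from the moment
initialiser $(\mathrm{median} - \Delta)/(g/f)$, and scores each fit with a
$\chi^2$ test on five integer-edged bins holding as close to one fifth of
the truncated PMF mass as integer edges allow, with $5-1-1=3$ degrees of
freedom for the one estimated parameter. The accepted truncation
$N^{bg}_{icr}$ is the largest one whose p-value reaches $p_{GoF}=0.01$;
counts at or below it are "certain background".

Numerical details worth knowing:

* The truncated likelihood degenerates when $\lambda$ is so large that the
  model puts essentially no mass below $N$; the objective returns a
  $\lambda$-sloped penalty there so the search cannot stall on the
  degenerate plateau.
* The search interval is $[10^{-3}, 50\,\lambda_{init}]$; the likelihood is
  empirically unimodal in $\lambda$ on it.
* With five bins and an unbinned MLE the $\chi^2$ statistic is only
  asymptotically $\chi^2_3$ (it sits between 3 and 4 degrees of freedom);
  at $m = 4096$ pixels the p-values are uniform to within what a
  1000-replicate Kolmogorov-Smirnov test can see, at $m \approx 1000$ a
  slight miscalibration is already detectable. Tiles of 64x64 pixels are
  comfortably in the calibrated regime.
* When no truncation passes — which happens in a few percent of
  whole-image fits at low SNR, where the signal distribution leaks below
  every candidate — `fit_background()` raises a typed condition by
  default. In the tiled pipeline the failed tile borrows its threshold
  from the nearest passing tile; for single-image workflows
  `on_no_pass = "accept-best"` accepts the best-fitting truncation and
  flags the fit.

# Probabilistic thresholding

Given the fitted background model, the requested false-positive probability
$p_{binarize}$ is converted to the smallest integer threshold with
$1-\mathrm{cdf}(N^{thresh}) \le p_{binarize}$; pixels above it are white.
Because the count is discrete the achieved tail $p(\mathrm{white}|bg)$ is
typically below the request (0.005–0.009 at a nominal 0.01), never above.

The second error rate, $p(\mathrm{black}|s)$, needs the unknown number of
background pixels $n_{bg}$. For every level $N_j$ below $N^{bg}_{icr}$ the
expected number of pixels at or below $N_j$ is $n_{bg}\,\mathrm{cdf}(N_j)$,
so a least-squares line through the origin of observed cumulative counts
against model CDF values estimates $n_{bg}$; $n_s = m - n_{bg}$. Expected
black background pixels $n_{bg}\mathrm{cdf}(N^{thresh})$ are subtracted
from the observed black count to give black signal pixels, Laplace-smoothed
to $p(\mathrm{black}|s) = (n(\mathrm{black}|s)+1)/(n_s+2)$ and clipped into
$[0,1]$. The five confusion-matrix rates (white = positive, signal =
positive class) follow.

What the a priori rates can and cannot promise: the FPR estimate inherits
the exponential sensitivity of a tail probability to $\hat\lambda_{bg}$ — a
1% overestimate of $\lambda_{bg}$ (typical with 15% signal admixture, since
some low signal counts sit below every truncation) moves the predicted tail
by ~25% relative, though rarely more than 0.002 absolute at the 0.01 level.
The $n_{bg}$ slope fit absorbs whatever signal mass lies below
$N^{bg}_{icr}$, so at SNR $\lesssim 2$ (shot-noise definition) $n_s$ is
systematically underestimated and the FNR/accuracy/FDR/FOR predictions
degrade from ~10% relative error at SNR 3–4 to several tens of percent at
SNR 1.5. At the other end, when the true FNR is small, its prediction
hinges on $n_{bg}$ being right to a fraction of a percent, which the slope
fit cannot deliver. These are properties of the estimation problem, not of
the implementation; the test suite measures them explicitly.

# Segmentation

White components (8-connectivity) and black components (4-connectivity, the
complementary pair that avoids the both-colors-diagonally-connected
paradox) are labeled; each color's region sizes are sorted and the size
list is cut at the first gap exceeding `allowed_gap_length` (default 1);
regions at or below the cut are flipped, both colors simultaneously, in one
pass. Flipping is inclusive of the cut size: the sizes before the first gap
are read as the noise cluster. If a color has no qualifying gap, all its
regions are treated as noise ("keep no components"); a color with a single
region is left untouched — there is no list to walk, and flipping an
image's only background or only object region is never the intent.
Surviving white regions get a background p-value from their summed counts.

Two deliberate consequences: the pass is one-shot (simultaneous flips can
mint fresh noise-scale islands, so a second pass is neither guaranteed to
be a no-op nor supported — on a mask of near-equal-sized objects it would
flip everything, by the no-gap rule); and hole recovery in ring-shaped
objects relies on small black noise regions existing elsewhere, which any
realistic false-negative rate provides.

# The simulator and what passing tests mean

`render_scene()` draws every pixel through the exact physical chain with
hard-edged disk (or arbitrary-template) objects: background pixels carry
$\lambda_{bg}$, object pixels $\lambda_{bg}+\lambda_{sig}$. The
signal-to-noise ratio uses the shot-noise definition
$\mathrm{SNR} = \lambda_{sig}/\sqrt{\lambda_{sig}+\lambda_{bg}}$ (the plain
ratio $\lambda_{sig}/(\lambda_{sig}+\lambda_{bg})$, which is bounded by 1
and cannot express the usual working range, is available behind
`snr_literal = TRUE`). Default study conditions for scene tests: 256x256
pixels, $\lambda_{bg}=20$, radius-5 beads covering ~15% of the image, the
gain-100 reference chip $g=18.82$, $f=35.17$, $r=1.45$, $\Delta=26.37$.

The simulator emulates stationary, uniform illumination, independent
pixels, hard-edged objects and a single gain register. It does not emulate
optics (no point-spread function, so object edges are unrealistically
sharp), illumination gradients, pixel-to-pixel gain variation, clock-induced
charge structure, or temporal correlations. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
physical model, not robustness to those real-world effects; the tiled
pipeline (64-pixel tiles, per-tile backgrounds and thresholds) is the
mechanism that absorbs slow illumination drift in real images.

Calibration stacks are simulated at three illumination levels with 500
frames in the recovery tests (40x40 pixels, both gain modes); chip
parameters come back within 10% and the 1000-pixel subsampling
interquartile ranges cover the truth in well over half the repetitions.

# Known limitations

* At SNR 3 and below, a 0.01-tail threshold leaves roughly half of each
  object's pixels black. Object cores fragment, some objects are removed
  entirely by the size rule, and the pixelwise overlap with ground truth
  tops out far below what the rates themselves would suggest — segmentation
  at these settings finds and scores objects; it does not delineate them.
* The a priori rate predictions degrade at the SNR extremes, as quantified
  above.
* The gap rule is scale-free but assumes noise regions and objects have
  disjoint size ranges; densely packed small objects violate it.
* Problem sizes in the test suite (scene counts, replicate counts, stack
  sizes) are the package's own validation choices: large enough that
  sampling error is well below every asserted tolerance.
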