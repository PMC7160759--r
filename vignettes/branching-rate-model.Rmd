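---
title: "A state-space point-process model of dendritic branching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A state-space point-process model of dendritic branching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrogen)
```

## The problem

Network-scale simulations of the hippocampus need many more neuronal
morphologies than the public archives hold, and the reconstructions that do
exist cannot express systematic anatomical gradients (for example, the
thickness of the molecular layer at a cell's position). `dendrogen`
addresses this for dentate gyrus granule cells and similar neurons: it
measures how the *rate* of dendritic bifurcation varies with distance from
the soma in a training set of SWC reconstructions, and grows new trees
whose branching follows that spatially heterogeneous rate, terminated at an
anatomical boundary rather than by a diameter threshold.

## The branching-rate model

Every soma-to-tip path of a morphology is discretized into pathlength bins
of width $\Delta$ (bin $k$ covers $((k-1)\Delta,\,k\Delta]$). A bin gets a
1 when a bifurcation of that path falls in it, and the dendritic tip itself
is recorded as a final event, so every sequence ends in 1. Pooling all
paths of all training trees gives $R$ binary sequences $n_r(k)$.

The latent log branching rate follows a first-order autoregressive Gaussian
model driving a Poisson-type observation:

$$x_k = \rho\, x_{k-1} + \varepsilon_k,\quad
  \varepsilon_k \sim N(0, \sigma_\varepsilon^2),\qquad
  \lambda_k = \exp(\mu + \beta x_k),$$

with per-bin event probability $\lambda_k \Delta$. The forward filter is
the discrete point-process analogue of the Kalman filter: a one-step AR
prediction followed by a nonlinear update in which the filtered mean
$x_{k|k}$ solves

$$x_{k|k} = x_{k|k-1} + \sigma^2_{k|k-1}\sum_{r=1}^R
  \beta\left[n_r(k) - e^{\mu + \beta x_{k|k}}\Delta\right].$$

Because $x_{k|k}$ appears on both sides, the update is solved by damped
fixed-point iteration started at the prediction, falling back to Newton
with step halving on the (strictly concave) log-posterior. A fixed-interval
smoother then runs backward with gain
$A_k = \rho\,\sigma^2_{k|k}/\sigma^2_{k+1|k}$, and
expectation-maximization alternates this E-step with closed-form updates
of $\rho$ and $\sigma^2_\varepsilon$ from the smoothed second moments and
a closed-form update of $\mu$.

Numerical choices worth knowing:

* **Identifiability.** $(\beta, x)$ enter only through $\beta x$, so
  $\beta$ is fixed at 1 by default; `fit_beta = TRUE` estimates all four
  parameters.
* **Initial state.** The user-facing filter defaults to $x_{0|0} = 0$ with
  the stationary AR variance. Inside EM the initial state is estimated
  with a fixed prior variance $\sigma^2_\varepsilon$: tying the prior to
  the stationary variance makes it diverge as the M-step pushes
  $\rho \to 1$ and destroys the monotone-likelihood property.
* **Stopping.** EM stops when all parameter changes fall below `tol`
  (default `1e-5`), when the observed-data log-likelihood (Gauss–Hermite
  quadrature over the one-step predictive density) improves by less than
  `ll_tol`, or at `max_iter`. The E-step is a Gaussian approximation, so
  an update can occasionally *decrease* the exact likelihood slightly;
  such a step is rolled back and EM stops, which keeps the reported
  likelihood trace non-decreasing. The rate curve itself is insensitive
  to this, because the likelihood is nearly flat along the
  $(\mu, \bar{x})$ ridge where the drift happens.
* **Filter accuracy.** The update is a posterior-mode (Gaussian)
  approximation. It agrees with exact quadrature to $10^{-3}$ in the
  small-variance regimes the tests pin down; with a diffuse prior and a
  single binary observation the skewness of the true posterior makes the
  mode-mean gap larger. This is inherent to the filter, not a bug.

## Axis conventions and the tip event

Two pathlength axes are supported. The default is the normalized per-path
axis: each terminal path is rescaled to $[0,1]$ and divided into `bins`
(default 100) equal bins, so all sequences share one grid and the tip
event always lands in the final bin. The absolute axis (micrometres, bin
width `delta`) is also available; sequences then stop contributing beyond
their tip bin. Whether normalization should be per path or per morphology
is not settled by the source material; per path is the default and the
choice is a flag.

The forced tip event is a termination marker, not a bifurcation. On the
normalized axis it concentrates in the last bin, where the fitted rate
consequently spikes. The generator never uses that spike: an event whose
daughters could not fit a single compartment before the boundary is
discarded, which nulls exactly the region the tip convention contaminates.

## From path hazard to branch hazard

Encoding *every* terminal path recounts each shared bifurcation once per
downstream tip. A tree whose branches bifurcate independently with
per-bin probability $h$ therefore shows the event in a fraction
$q = 2h/(1+h) \approx 2h$ of its paths, because a bifurcation doubles the
number of tips that inherit it. The estimate produced from encoded
morphologies is the *path* hazard $q$. Growing branches directly at $q$
would double the branching rate on every estimate→generate cycle — an
error that compounds (in testing, mean bifurcation counts jumped from 21
to 164 in one cycle). `grow()` therefore inverts the relation and drives
each branch at $h = q/(2-q)$. With this convention the loop closes: a
population grown from a known curve, encoded, fitted, and regrown
reproduces the original per-bin event frequencies (this is tested at
3 Monte-Carlo standard errors on ≥90% of bins). The rate *estimate* is
left uncorrected; the inversion is a property of the generator.

## Growing a morphology

For each tree the generator samples a terminal boundary length from the
empirical terminal-pathlength distribution — the anatomical stand-in for
the hippocampal fissure or pial surface — and a stem count. One stem
points straight up (+y); several are spaced evenly around a cone about +y
with an empirically drawn half-angle. Each branch then advances in steps
of `delta` along a direction that accumulates Gaussian angular noise,
with its own thinned point process: a homogeneous Bernoulli process at
the maximal rate, events kept with probability $\lambda(d)/\lambda_\max$
evaluated at the branch's current distance from the soma on the
soma-anchored grid (the grid continues across bifurcations rather than
restarting). At an event the branch bifurcates: the primary daughter
continues the parent direction; the secondary is rotated away by an
amplitude and an azimuth drawn from the conditional angle table for the
(x, z) cell containing the bifurcation, falling back to the x-row
marginal and then the global marginal when cells are empty. Diameters
taper linearly within each branch (one taper draw per branch) and are
floored at `diam_floor`; the floor never terminates growth. Every branch
stops at the boundary, so all terminal pathlengths of a generated tree
lie within one step of the sampled boundary.

Branch angles are measured in a registered frame: soma at the origin, the
mean of the soma-to-tip unit vectors rotated onto +y (unit vectors, so
long paths do not dominate), and the smallest-area ellipse enclosing the
tip projections on the xz-plane rotated so its major axis lies along +x
(tie-broken toward the +x half-plane). Azimuth is the clockwise angle,
viewed from the parent's base along the parent vector, that carries the
secondary daughter onto the direction pointing at the central y-axis.
Default table resolution is 20 µm in x and z and 10° in angle; the
Gaussian orientation noise defaults to 10° for stems and 5° per
elongation step. None of these three values is stated by the source
material; they are package defaults chosen at granule-cell scale and all
are configurable.

Generated trees are screened on bifurcation count and on the major/minor
axes of the tip-projection ellipse; trees failing only the axis checks
are rescaled in x and z to the middle of the allowed ranges and
re-screened (rescale-on-fail is an interpretation; the source is
ambiguous about whether all or only failing morphologies were rescaled).
The homogeneous-rate control mode flattens the rate curve to its mean
over bins and is otherwise identical — it exists as the comparator that
shows why spatial heterogeneity matters: with the mean rate everywhere,
proximal branching is systematically underestimated.

## Validation machinery

`measure()` computes branch pathlengths, bifurcation amplitudes and
azimuths, bifurcation counts, total dendritic length (TDL), branch
orders, and the width (x-extent) and depth (z-extent) of the registered
tree — the last two follow the L-Measure reading of those terms.
`sholl()` counts exact segment–sphere crossings of concentric spheres.
`tdl_by_distance()` apportions segment lengths to distance bins (by
height above the soma or by pathlength) and returns the density and CDF;
`tdl_per_layer()` splits the soma-to-boundary span into layers (default
thirds, the molecular-layer convention). `distribution_rmse()` bins two
samples on shared edges (Freedman–Diaconis edges from the reference
pool) and returns the RMSE of per-bin probability mass — mass, not
density; the source does not say which it used.

The passive model treats every branch as one resistor of identical value
(a per-µm mode exists). For a point on the tree, `R_prox` is the series
resistance to the soma and `R_dist` the series/parallel reduction of the
distal subtree with all tips tied to a common node; the reported value is
the current divider `R_dist / (R_prox + R_dist)`, i.e. the fraction of
injected current flowing somatward. A literal "proportion of resistance
leading to the soma" reading is available behind `mode = "resistance"`
for sensitivity analysis. Points at tips return 1 (no distal material);
treating tips as sealed ends of infinite resistance would give the same
answer in the divider reading. Population samples (100 length-uniform
points per tree by default) are fitted with a quadratic in normalized
distance, and fits can be cross-scored against another population's
samples. `spine_weighted_current()` multiplies dendritic length per µm by
per-layer spine densities and by the fitted fraction; its curve
comparison uses range-normalized RMSE (the normalization constant is not
stated by the source; the range is this package's choice). Spine
densities are inputs — the package ships no literature values.

## The synthetic world, and what a green test shows

All tests run on synthetic data. The stand-in for a reconstruction
archive is `make_reference_population()`: trees grown from a known rate
curve — by default $\lambda_0 e^{-k/\tau}$ with $\lambda_0\Delta = 0.1$
and $\tau = K/4$ on the normalized axis, a proximally peaked shape of the
kind real granule cells show — with boundary lengths $N(300, 30)$ µm
(floored at 200), 1–3 stems, 5 µm growth steps, amplitudes spread over
20–70° and azimuths over the full circle. These are granule-cell-scale
magnitudes, not measurements. A green suite therefore establishes that
the estimator recovers known rates, that the generator's output has the
structure and boundary behaviour it promises, that the
estimate→generate loop is a fixed point, and that every measurement
agrees with an independent oracle — it does *not* establish that any
particular real population is reproduced, which would require the
archival reconstructions.

Known limitations, inherited from the modelled method: the estimate is a
path hazard with the recounting bias discussed above (acknowledged, not
corrected); branching history and neighbour interactions are not
modelled (no history-dependent intensity terms, no trophic factors);
bin-grid aliasing between the growth step and the encoding bins makes
adjacent-bin frequencies jagged at fine resolutions; and the filter's
Gaussian approximation is exact only in the near-Gaussian regime.
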