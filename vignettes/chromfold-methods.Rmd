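---
title: "chromfold: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromfold: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromfold)
```

## The model

`chromfold` reconstructs a chromosome's 3D organisation from two
complementary assays.  A Hi-C contact map gives interaction frequencies
$f_{ij}$ between genomic loci; a multiplexed-FISH experiment gives mean
spatial distances $F_{ij}$ (µm) between imaged TADs, averaged over
cells.  The reconstruction is divide-and-conquer: a TAD-level backbone,
independent intra-TAD models, and a rigid-body assembly.

### Backbone objective

One 3D point per TAD is embedded by minimising

$$C_g = C_1 + \lambda_E C_2 + \lambda_F C_3 .$$

$C_1$ is a stochastic-neighbour objective: contact frequencies are
normalised to affinities $p_{ij} = f_{ij} / \sum_{i \ne j} f_{ij}$ over
ordered off-diagonal pairs, model distances to probabilities $q_{ij}
\propto (1 + \lVert s_i - s_j \rVert)^{-1}$, and
$C_1 = \sum_{i \ne j} p_{ij} \log (p_{ij}/q_{ij})$.  We use the globally
normalised reading throughout: the row-wise decomposition sometimes
written for this objective is incompatible with a global denominator in
the definition of $p$, so the package treats $P$ and $Q$ as single
distributions over ordered pairs.  Because $p$ is scale-invariant in the
counts, raw and pre-normalised Hi-C are both accepted.

$C_2$ is a minimal polymer prior: harmonic stretching of consecutive
bonds toward a rest length $b$ plus a soft-sphere penalty for
non-adjacent points closer than a contact radius $r_c$,

$$C_2 = \sum_{i} k_s (\lVert y_{i+1} - y_i \rVert - b)^2 +
  \sum_{|i-j|>1} k_r \max(0,\, r_c - \lVert y_i - y_j \rVert)^2 .$$

This is the smallest standard prior enforcing chain connectivity and
non-self-intersection.  It is deliberately isolated behind
`polymer_params()`/`polymer_energy()` so richer forms (bending,
torsion) can be swapped without touching the fitting code.  The default
rest length is data-derived: the median FISH distance between
genomically adjacent TADs for backbones, and $c \cdot
(\text{bin size})^\beta$ from the FISH power law for intra-TAD models;
$r_c = b/2$ and $k_s = k_r = 1$, since their overall magnitude is
absorbed by $\lambda_E$.

$C_3 = \sum_{i \ne j} (\lVert s_i - s_j \rVert - F_{ij})^2$ anchors the
embedding to the imaged distances.  Missing FISH entries are excluded
from the sum (and from error averaging), never imputed.

### Intra-TAD objective

FISH provides no restraints inside a TAD, but the genomic-to-spatial
power law $d = c\,g^\beta$ fitted across TAD pairs
(`fit_distance_powerlaw()`, ordinary least squares in log–log space)
extrapolates a rough spatial extent for each TAD from its own genomic
length.  The package converts that end-to-end estimate to a target
radius of gyration by the ideal-chain relation $\hat R_g = c
L^\beta/\sqrt 6$ — a declared stand-in estimator; direct per-TAD
measurements override it when supplied.  Each TAD is then embedded at
bin resolution (default 5000 bp) under

$$C_t = C_1 + \lambda_E C_2 + \lambda_R C_4, \qquad
  C_4 = \lvert R_g^2 - \hat R_g^2 \rvert .$$

Bins with zero marginal contact are retained and positioned by chain
connectivity alone, because dropping them would break the junction
indexing used at assembly time.  Per-TAD fits are independent with
derived seeds (global seed + TAD ordinal), so parallel and sequential
execution are result-identical.

### Assembly

Each TAD model is translated so its centroid (our definition of its
"centre") sits on the backbone point, then TAD orientations are
optimised by rigid rotation about the centre to close the junction gaps
to the estimated linker distances

$$d_{i,i+1} = \begin{cases} f_{i,i+1}^{\alpha} & f_{i,i+1} \ne 0 \\
  c\, g_{i,i+1}^{\beta} & f_{i,i+1} = 0 \end{cases}$$

with $\alpha = -0.25$, $f$ the contact count between the junction bins
in the full-resolution map, and $g$ the genomic distance between their
centres.  Because $f^\alpha$ inherits the scale of the counts, a
documented option (`calibrate_scale`) rescales the contact-derived
linkers so their median matches the power-law median; it is off by
default so that pre-normalised counts pass through untouched.

The integration cost $C = \sum_{i=1}^{n-1} (\lVert y_{s_{i+1}} -
y_{e_i} \rVert - d_{i,i+1})^2$ sums over the $n-1$ existing junctions.
A gradient step on a junction endpoint is converted into a rotation:
the axis is the cross product of the centre-to-endpoint vector and the
centre-to-target vector, the angle the subtended angle capped at
$\pi/2$ per step (the cap prevents overshoot oscillation), with
backtracking halving of the angle so the cost never increases.  Sweeps
run in genomic order; an interior TAD has two constrained endpoints and
uses whichever carries the larger gradient that sweep — a deterministic
rule chosen because the update equation moves one endpoint at a time.
Once per sweep each TAD's mirror image (reflection through the plane
perpendicular to the current rotation axis, through the centre) is
evaluated and kept if strictly better, resolving chirality errors that
rotations cannot reach — e.g. an endpoint pointing exactly away from
its junction target, where the rotation axis is undefined.

### Weight selection

$\lambda$ pairs are chosen by grid search maximising

$$S = (1 - C_1)\, \frac{v}{\lvert v - v' \rvert},$$

with $v$ a prior volume and $v'$ the convex-hull volume of the fitted
model.  Three regularisations make the score well-defined: $C_1$ is
clamped to $[0,1]$ (the globally normalised divergence can exceed 1),
the denominator is floored at $\varepsilon v$ with $\varepsilon =
10^{-3}$ (the printed form diverges at $v' = v$), and ties break toward
the smaller first, then second, weight.  The hull volume is computed by
an incremental convex-hull construction implemented in the package;
degenerate (coplanar) models get volume 0 with a warning.  When no
measured volume is available, a fallback prior inflates the power-law
radius of gyration to a uniform-ball radius, $v = \tfrac43 \pi (1.29
\hat R_g)^3$.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `lambda_E`, `lambda_F` (backbone) | 5e12, 1e-8 | – | published defaults, tied to raw-count Hi-C magnitudes |
| `lambda_E`, `lambda_R` (intra-TAD) | 5e11, 1e-7 | – | same caveat; `lambda_R` must dominate to pin $R_g$ |
| `alpha_exponent` | −0.25 | – | contact→distance exponent; $f \propto d^{-4}$ |
| `rest_length` | data-derived | µm | see above |
| `learning_rate` | 0.05 (fits), 0.1 (assembly) | – | backtracking makes the exact value uncritical |
| `rel_tol` | 1e-7 (fits), 1e-9 (assembly) | – | relative cost-change stop |
| `init_scale` | mean(F)/2 | µm | Gaussian initialisation in the data's length scale |

The term weights multiply quantities whose magnitudes depend on the
scale of the contact counts ($C_1$ is scale-free, $C_2$–$C_4$ are in
µm²-derived units), so the published defaults are meaningful only for
inputs on the same count scale they were selected on.  All synthetic
analyses in this package use unit count scale and state their weights
explicitly (backbone $\lambda_E = 10^{-3}$, $\lambda_F = 1$; intra-TAD
$\lambda_R = 50$, the constraint-dominant regime).  For new data the
honest route is `tune_backbone()` / `tune_tad()`.

## Numerical choices

* **Ordered-pair sums.** All pairwise costs follow the printed
  ordered-pair form (each unordered pair counted twice), and every
  analytic gradient is the exact gradient of the cost as summed —
  the gradient of $C_3$ therefore carries a factor 4, not the factor 2
  of a single-counted sum.  This keeps finite-difference checks exact;
  constant factors are absorbed by the weights.  The distance-residual
  symbol in the printed gradient is read as $F_{ij}$ (an apparent
  typographical slip in the source derivation).
* **$C_4$ kink.** $C_4$ is non-differentiable at $R_g = \hat R_g$; the
  subgradient uses $\mathrm{sign}(0) = 0$.  Near the kink plain
  gradient descent stalls by design (the minimum sits at the kink);
  with $\lambda_R$ large the fitted $R_g$ pins to the target to high
  accuracy, at the price of the KL term converging more slowly.
* **Descent control.** Plain gradient descent with backtracking step
  halving (30 halvings maximum) guarantees monotone non-increasing
  trajectories everywhere, which the test suite asserts.
* **Zero distances.** Coincident points get zero-direction gradient
  contributions by convention in every term; zero junction gaps get a
  zero integration gradient.
* **Compartment calling.** TAD-centre distances → column-wise Pearson
  correlation → sign of the leading principal component; this
  transplants the classical correlation-matrix/first-eigenvector
  compartment call from contact space to distance space.  Zero scores
  map to +1; the sign convention fixes the largest-magnitude score
  positive; a degenerate leading eigenvalue (e.g. a regular simplex)
  triggers a warning and deterministic-but-arbitrary labels.  Labels
  carry no A/B identity without epigenetic tracks, so accuracies
  maximise over the two label permutations.
* **Consistency statistic.** Over all pairs of TAD pairs with defined
  entries, the fraction whose ordering by contact frequency opposes
  their ordering by FISH distance, ties dropped.
* **Configuration.** Run configuration is YAML; a resolved copy is
  echoed to the output directory, and one global seed determines every
  output bit-for-bit.

## The synthetic generator

`simulate_structure()` produces a confined, weakly self-avoiding
random walk: TAD centres step 0.4 µm inside a 1.5 µm sphere (the scale
of human chromosome territories in imaging studies), and each TAD is a
persistent local walk (step 0.07 µm, persistence 0.8, confined to
0.25 µm) around its centre, mimicking fibre stiffness at the 5 kb
scale.  In polarised mode, TADs form alternating five-TAD blocks whose
centres are confined to opposite half-spaces with a drift toward
per-compartment attractors — the spatially polarised A/B arrangement
seen in chromosome-scale imaging; inter-block linker steps may exceed
the within-block spacing.  `simulate_hic()` draws expected counts from
the inverse-power law $f = \text{scale} \cdot d^{-4}$ (optionally
Poisson-sampled); `simulate_fish()` returns exact backbone distances
with optional truncated Gaussian noise and missingness.

What passing tests on this generator show: the estimators and
optimizers are correct and self-consistent (gradients match finite
differences; noiseless inputs are inverted back to the planted
geometry; planted compartments are recovered).  What they do not show:
performance on real Hi-C/FISH data, whose counts are noisy,
normalisation-dependent and loop-structured, whose FISH tables average
heterogeneous cell populations, and whose TADs are neither equal-sized
nor genomically adjacent.  Claims about real chromosomes require the
real inputs.

## Problem sizes

The shipped analyses use 20 TADs for backbone recovery (20 seeds),
25–50-bead TADs for the radius-of-gyration checks, 30 TADs × 20 seeds
for compartment recovery, 5 × 25-bead TADs for assembly, and a
10-TAD × 12-bin bundle for the end-to-end pipeline — sizes at which
every property under test is already exercised while the whole suite
runs in well under a minute per module.

## Known limitations

* A single conformation is fitted, not an ensemble; population
  heterogeneity is averaged away, which is also why fitted distances
  and mean FISH distances can never match perfectly on real data.
* The assembly stage optimises junction gaps only: $n-1$ scalar
  constraints against $3n$ rotational degrees of freedom.  Its zero-cost
  set is high-dimensional, so TAD orientations are only weakly
  determined — the integration cost closes essentially to zero while
  substantial orientation freedom remains (the acceptance script
  reports the measured whole-model recovery alongside the closed
  cost).  Orientation recovery would need restraints the junction
  objective does not contain, e.g. inter-TAD contacts between interior
  bins.
* The radius-of-gyration estimator and the volume prior are declared
  stand-ins for calibration details that are not part of the published
  main text.
* Compartment labels are geometric; assigning A/B identity requires
  external epigenomic tracks, which are out of scope.
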