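---
title: "Negative binomial inference of 3D genome structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative binomial inference of 3D genome structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicstruct)
```

## The model

A Hi-C contact map is a symmetric matrix of counts $c_{ij}$ between $n$
genomic bins. We model each bin as a bead $x_i \in \mathbb{R}^3$ and each
count as an independent negative binomial draw

$$C_{ij} \sim \mathrm{NB}(\mu_{ij}, r_{ij}), \qquad
\mu_{ij} = \beta\, b_i b_j\, d_{ij}^{\alpha}, \qquad
r_{ij} = b_i b_j\, r,$$

with $d_{ij} = \lVert x_i - x_j \rVert$, decay exponent $\alpha < 0$,
per-locus multiplicative biases $b_i$, coverage scale $\beta$, and global
dispersion $r > 0$. The NB variance is
$\sigma^2_{ij} = \mu_{ij} + \mu_{ij}^2 / r_{ij}$: smaller $r$ means more
overdispersion, and $r \to \infty$ recovers the Poisson model, which the
package also provides as a baseline (`model = "poisson"`). The structure and
the exponent are inferred jointly by maximizing

$$L(X, \alpha) = \sum_{i<j} \log \Pr(C_{ij} = c_{ij})$$

over all pairs of usable loci, including pairs with $c_{ij} = 0$: under a
power-law mean, a zero count is evidence of a large distance, and discarding
zeros measurably degrades low-coverage reconstructions (the test suite
includes this ablation).

Key identifiability facts shape the interface:

* the likelihood depends on $X$ only through distances, so solutions are
  defined up to rotation, translation and reflection (distance data cannot
  fix chirality);
* $\beta$ trades off exactly against an overall rescaling of $X$
  ($\beta d^\alpha = (\beta^{1/\alpha} d)^\alpha$), so $\beta$ is fixed to 1
  during inference and absolute scale is restored afterwards with
  `rescale_structure()` when a nucleus size is known.

Assumptions worth keeping in mind: counts are treated as independent given
the structure (no polymer connectivity terms, no excluded volume), a single
consensus structure is assumed to explain a population-averaged map, and one
global $r$ is shared by all pairs, including inter-chromosomal ones.

## Normalization

Raw counts carry locus-specific visibility biases. `ice_normalize()`
estimates $b_i$ by iterative correction: repeat
$b_i \leftarrow b_i \cdot S_i / \bar S$, where $S_i$ is the current row sum
of $c_{ij}/(b_i b_j)$, until the relative row-sum spread falls below `tol`
(default $10^{-5}$, `max_iter = 300`; both are conventional settings for
this algorithm). Zero-marginal loci are always excluded; `filter_fraction`
optionally removes the sparsest remaining loci, which is conventional for
real Hi-C but defaults to 0 because the synthetic generator produces no
pathological bins. Biases are rescaled to arithmetic mean 1 over unfiltered
loci — some convention is needed because a common factor in $b$ can be
absorbed by $\beta$, and mean 1 keeps normalized counts on the raw-count
scale.

## Dispersion estimation

Estimating $r$ by joint maximum likelihood with $X$ is deliberately avoided;
instead `per_distance_stats()` pools, for each intra-chromosomal genomic
distance $l = |i - j|$ (in bins), the normalized counts $c_{ij}/(b_i b_j)$
and computes their empirical mean $\tilde\mu_l$ and sample variance
$\tilde\omega_l$. This rests on the assumption that pairs at the same
genomic distance have (approximately) the same spatial distance — used only
here, and relaxed entirely during coordinate optimization. The variance is
corrected for bias-induced inflation,

$$\tilde\sigma^2_l = \tilde\omega_l \Big/
\Big(\tfrac{1}{N_l}\textstyle\sum 1/(b_i b_j)\Big),$$

a direction one can verify by moment calculation: under the model,
$\mathrm{Var}(c_{ij}/(b_ib_j)) = \mu^N/(b_ib_j) + (\mu^N)^2/(b_i b_j r)$
with $\mu^N = d^\alpha_{(l)}$, so dividing by the mean inverse bias product
makes $\tilde\sigma^2_l$ estimate $\mu^N + (\mu^N)^2/r$ and the per-distance
dispersion $\tilde r_l = \tilde\mu_l^2 / (\tilde\sigma^2_l - \tilde\mu_l)$
unbiased for $r$ in expectation. With unit biases the correction is 1.

`estimate_dispersion()` then averages the $\tilde r_l$ with weights
$N_l$ (pair counts, so short distances dominate) over distances
$l < \tfrac{2}{3} l_{\max}$ (strict; $l_{\max}$ is the largest distance with
at least two pairs) and clamps at zero. Distances with zero mean or zero
variance are discarded; a distance with $\tilde\sigma^2_l = \tilde\mu_l$
exactly would divide by zero and is skipped. A clamped (near-zero) result
triggers a warning recommending the Poisson model, because $r = 0$ makes the
NB mass function undefined — the clamp value itself is never used as a
likelihood parameter.

**Limitation.** $\tilde r_l$ is a reciprocal of a noisy difference, so its
sampling distribution is heavy-tailed whenever the variance excess
$\tilde\mu_l^2/r$ is small relative to the sampling noise of
$\tilde\sigma^2_l$ — i.e. at genomic distances with small means or few
pairs. On chains of a few hundred beads, single long distances with
$\tilde\sigma^2_l$ slightly *below* $\tilde\mu_l$ can contribute large
negative $\tilde r_l$ and drag the weighted average far from the truth or
onto the zero clamp. On maps with thousands of pairs per distance the
estimator is stable. The test suite measures this honestly: the
constant-mean recovery property passes at $n = 200$, while factor-of-two
recovery on the 100-bead helix at reference coverage does not hold reliably
for $\gamma \ge 1$ and the corresponding acceptance test is expected to
fail there. Downstream inference is insulated by design: reconstruction
accuracy is robust to an order of magnitude of dispersion misestimation, and
the pipeline helpers fall back to a moderate default ($r = 1$) when the
estimate clamps to zero.

## Optimization

`infer_structure()` maximizes $L$ with L-BFGS-B using the analytic gradient
(chain rule through $\mu_{ij}$; $r$ is held fixed, so no digamma terms).
Choices that matter:

* **Negativity of $\alpha$** is enforced by the smooth reparameterization
  $\alpha = -e^a$ rather than a box constraint; the initial value is
  $\alpha_0 = -3$, the classic contact-decay exponent for chromatin at these
  scales.
* **Restarts.** The problem is non-convex, so `n_init = 5` independent
  optimizations start from i.i.d. standard Gaussian coordinates; the highest
  final log-likelihood wins, with exact ties broken by the lowest restart
  index. Restart $k$ seeds the generator with `seed + k - 1`, so a larger
  restart budget reuses the smaller budget's initializations (the best
  log-likelihood is monotone in `n_init`) and identical seeds give
  bit-identical results.
* **Warm start for the exponent.** Each restart first fits coordinates with
  $\alpha$ fixed at $\alpha_0$ and only then optimizes $(X, a)$ jointly.
  Started jointly from a random blob, the exponent otherwise collapses
  towards $0$ — a flat-mean local optimum in which all pairs share
  $\mu \approx 1$ regardless of geometry — and all restarts can land there.
  Fitting the structure first places the joint stage in the basin of a
  structured solution; the final stage is still a full joint optimization.
* **Distance floor.** $\mu_{ij}$ is evaluated at
  $\max(d_{ij}, 10^{-8})$ so transiently coincident beads cannot overflow
  the objective; with zeros included the likelihood itself repels coincident
  beads, so the floor is inactive at any optimum.
* **Convergence.** Projected-gradient tolerance $10^{-5}$ with a generous
  iteration cap; the defaults terminate well past the point where
  reconstruction metrics stop improving.
* **Unconstrained beads.** Loci that are bias-filtered or have zero marginal
  counts get `NA` coordinates rather than arbitrary positions.

Inter-chromosomal pairs enter the likelihood (with $r_{ij} = b_i b_j r$ as
everywhere) but not the dispersion estimate, where genomic distance is
undefined across chromosomes. No nucleus-envelope or bead-connectivity
constraints are applied. The diagonal is zeroed on load: $d_{ii} = 0$ with
$\alpha < 0$ gives an undefined self-contact mean, and self-ligation counts
carry no distance information anyway.

## The synthetic generator

`simulate_counts()` draws each pair independently from the *same* NB family
the inference assumes — mean $\beta b_i b_j d^\alpha_{ij}$, dispersion
$\gamma b_i b_j$ — via the gamma–Poisson mixture construction. Mapping the
tuning parameter $\gamma$ onto the model's dispersion slot makes simulated
overdispersion directly comparable to the estimated $r$. Ground truths are a
regular helix (radius 1, ten beads per turn, unit rise per turn; all
adjacent distances equal) or a unit-step random walk; biases are unit or
i.i.d. log-normal rescaled to mean 1. The reference coverage
($\beta_{\mathrm{rel}} = 1$) is calibrated so the mean nearest-neighbour
count is 100, a comfortably deep map at these sizes; coverage sweeps scale
this reference (e.g. 10% coverage = $\beta_{\mathrm{rel}} = 0.1$).

What this emulates: power-law contact decay, multiplicative locus biases,
tunable overdispersion and depth. What it does not: polymer connectivity
and excluded volume, a population of heterogeneous structures (the main
biological source of overdispersion), domain/compartment structure,
mappability gaps, and single-cell sparsity. Tests passing on these data
show the estimator and optimizer do their statistical job under the model;
they do not certify accuracy on real nuclei.

Test and acceptance runs use 50-bead (inference) and 100-bead (moment
estimation) chains with 5 restarts and 10-seed medians — sizes at which the
full pipeline completes in seconds per fit while leaving every phenomenon
of interest (coverage sweeps, ablations, model comparisons) measurable.

## Evaluation choices

* **RMSD** uses least-squares superposition (SVD); *reflection is allowed by
  default* because chirality is unidentifiable from distances — without
  this, accuracy distributions on simulated data are bimodal for no
  scientific reason. A strict proper-rotation mode is available.
* **Scaling.** Inferred coordinates are in arbitrary units, so accuracy
  against a ground truth uses similarity alignment (`allow_scaling = TRUE`).
  Scaled superposition is asymmetric, so the two directed RMSDs are
  averaged; rigid RMSD is already symmetric.
* **Replicate protocol.** `compare_structures()` masks beads with no
  contacts in either replicate (they were never constrained), rescales both
  structures so 99% of beads fit a diameter-100 sphere (quantile 1.0 for
  whole-nucleus normalization), and reports RMSD and distance Spearman.
* **Resolution coarsening** averages runs of `factor` beads anchored at
  each chromosome start; a trailing partial group averages what it has, and
  a group with no valid bead stays invalid.
* **Downsampling** is binomial thinning per upper-triangle entry, the exact
  analogue of discarding each read independently; thinning by $f_1$ then
  $f_2$ is distributed as thinning by $f_1 f_2$.

## Degenerate inputs and numerical notes

Asymmetric dense matrices, negative or fractional counts, out-of-range
triplet indices and malformed structure lines are rejected with pointed
error messages. An all-zero matrix has no informative loci and is an error
for balancing; a structure whose valid beads are all coincident cannot be
rescaled. Log-PMF evaluation goes through `lgamma` throughout; at
$r = 10^8$ the NB and Poisson objectives agree to $10^{-3}$ on typical
instances, which is also the regime where `lgamma(c + r) - lgamma(r)`
starts to lose precision — a reason the Poisson model is a separate code
path rather than a large-$r$ NB call.

## Known limitations

* The dispersion estimator's small-sample fragility described above.
* A single global $r$; per-distance or replicate-based dispersion is out of
  scope.
* Consensus models compress a heterogeneous cell population into one
  geometry and should be read as a summary, not a conformation.
* With many chromosomes, inter-chromosomal pairs can dominate the fit of
  $\alpha$; no mitigation is applied.
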