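# hicstruct

Infer a consensus 3D model of chromatin from a Hi-C contact map by maximum
likelihood under a negative binomial (NB) observation model.

Hi-C experiments produce a symmetric matrix of contact counts `c_ij` between
pairs of genomic bins. Consensus structure-inference methods place one bead
per bin in 3D so that the counts are explained by the bead geometry. A
natural statistical formulation models `c_ij` as Poisson with an intensity
that decays with the inter-bead distance — but Hi-C counts are strongly
overdispersed (variance well above the mean), which a Poisson model cannot
express. `hicstruct` instead models

    C_ij ~ NB(mean = mu_ij, dispersion = r_ij)
    mu_ij = beta * b_i * b_j * d_ij^alpha        (alpha < 0, beta fixed to 1)
    r_ij  = b_i * b_j * r
    var   = mu_ij + mu_ij^2 / r_ij

where `d_ij = ||x_i - x_j||` is the Euclidean distance between beads,
`alpha` is the count-to-distance exponent, `b_i` are per-locus multiplicative
biases estimated by ICE matrix balancing, and `r` is a global dispersion
estimated from the data. The coordinates `X` and the exponent `alpha` are
then found by maximizing the log-likelihood `L(X, alpha) = sum_ij log
P(C_ij = c_ij)` with L-BFGS from several random restarts; zero counts stay
in the objective (a zero is evidence of a large distance). As `r` grows the
model reduces to the Poisson formulation, which is also available as a
baseline.

The dispersion `r` is estimated from the data before the optimization: for
every genomic distance `l` the empirical mean and (bias-corrected) variance
of the normalized counts give a per-distance estimate
`r_l = mean^2 / (var - mean)`, and `r` is their pair-count-weighted average
over distances below two thirds of the maximum, clamped at zero.

The package is aimed at method developers and analysts who want a compact,
fully scriptable NB structure-inference pipeline with a matching synthetic
Hi-C generator and the standard evaluation metrics (superposition RMSD,
distance-matrix Spearman, nucleus rescaling, resolution coarsening,
binomial downsampling).

## Worked example

Simulate an overdispersed Hi-C map from a known 60-bead helix with
log-normal locus biases, then run the full pipeline:

```r
library(hicstruct)

truth <- generate_structure(60, "helix")
cfg <- simulation_config(60, "helix", alpha = -3, gamma = 0.5,
                         bias_spec = "lognormal:0.3", seed = 42)
hic <- simulate_dataset(cfg)
hic$counts
#> <contact_matrix> 60 bins, 1 chromosome(s), resolution 1 bp
#>   total counts: 10235, nonzero upper-triangle pairs: 891

ice <- ice_normalize(hic$counts)
est <- estimate_dispersion(per_distance_stats(hic$counts, ice$bias))
est
#> <dispersion_estimate> r = 0.782855 from 38 genomic distances (l < 0.667 * 58)

fit <- infer_structure(hic$counts, ice$bias, r = est$r, n_init = 5, seed = 1)
fit
#> <hic_fit> model=nb, 60/60 beads placed
#>   log-likelihood -3298.9746, alpha_hat -2.9041, r 0.7829, 5 restarts

100 * rmsd(fit$structure, truth, allow_scaling = TRUE) / max(dist(truth$coords))
#> [1] 7.76
distance_spearman(fit$structure, truth)
#> [1] 0.901
```

The estimated dispersion (0.78) recovers the simulated overdispersion
(`gamma = 0.5`, i.e. variance = mu + 2 mu^2 at unit bias) to well within a
factor of two, the fitted exponent (-2.90) recovers the simulated decay
(-3), and the inferred structure matches the ground truth up to a similarity
transform: RMSD is 7.8% of the true structure's diameter and the pairwise
distance matrices correlate at rho = 0.90. `tidy(fit)` returns the
per-restart table, `glance(fit)` a one-row fit summary, and
`autoplot(per_distance_stats(hic$counts, ice$bias))` draws the
mean-variance overdispersion diagnostic.

The same pipeline is scriptable from a shell through `exec/hicstruct`
(subcommands `simulate`, `normalize`, `dispersion`, `infer`, `evaluate`,
`downsample`), e.g.

```sh
exec/hicstruct simulate --n-beads 50 --gamma 0.5 --seed 1 --out-dir sim
exec/hicstruct infer --counts sim/counts.tsv --bias auto --dispersion auto \
    --seed 2 --out-structure fit.tsv
exec/hicstruct evaluate --structure-a fit.tsv --structure-b sim/true_structure.tsv
```

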