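# basin

Reference-based cell-type deconvolution for spot-resolution spatial
transcriptomics, for analysts who have a spot-level expression matrix with
coordinates (10x Visium and similar array platforms, or stitched
imaging-based data) plus an annotated scRNA-seq reference from matching
tissue, and who want *posterior distributions* of the per-spot cell-type
proportions rather than a single point estimate.

## The model

With `X` the n×p log1p expression matrix over p spots and `B` the n×c
per-cell-type mean profile matrix from the reference, basin models

    X = B V + E,    E ~ MN(0, σ² Iₙ, L⁻¹),    V_ij ~ Exp(η),

where `L = D − A` is the graph Laplacian of a Gaussian-kernel spot graph
(`A_ij = exp{−(‖s_i−s_j‖² + μ (I_i−I_j)²)/σ_A²}`, optionally using
histology-image intensities `I`), used as the error's column *precision* so
that nearby spots covary; the exponential prior on the proportion matrix
`V` enforces non-negativity and sparsity, and conjugate priors
`σ² ~ InvGamma(a₁, b₁)`, `η ~ Gamma(a₂, b₂)` complete the model. A Gibbs
sampler alternates the three closed-form conditionals — inverse-gamma for
σ², gamma for η, and a **truncated matrix normal** for V with mean
`(BᵀB)⁻¹(BᵀX − σ²η J L⁻¹)`, row covariance `σ²(BᵀB)⁻¹` and column
covariance `L⁻¹` — sampled coordinate-wise on its Kronecker-structured
precision at O(c+p) per entry, with a rectified matrix-normal approximation
above 10⁴ dimensions. Columns of the stored draws are normalized to the
simplex; posterior means, per-proportion standard deviations, cell-type
co-localization correlations and per-spot posterior histograms come out the
other end.

The package also ships the accompanying preprocessing (gene harmonization,
variance-to-mean-ratio filter, log-fold specificity filter, log1p),
fully synthetic simulation schemes with known ground truth, and the
standard evaluation metrics (RMSE, per-type global SSIM, per-spot
Jensen–Shannon distance).

## Worked example

```r
library(basin)

sim   <- simulate_dataset(grid_shape = c(20L, 20L), scheme = 1, seed = 2024)
graph <- build_spatial_graph(sim$geometry)
draws <- run_basin(sim$X, sim$B, graph,
                   control = basin_control(n_samples = 500, burn_in = 5),
                   seed = 2025)
smry  <- summary(draws)
smry
#> basin_summary over 500 draws: 3 cell types x 400 spots
#> mean proportion by cell type:
#>  type1  type2  type3
#> 0.3407 0.3099 0.3494
evaluate_deconvolution(smry, sim$truth)
#> $rmse 0.00919   $ssim 0.999   $jsd 0.013
mean(smry$sd_props)
#> 0.0099
```

The synthetic tissue has three regions, each dominated (proportion 0.7) by
one of three cell types; the run recovers the truth to RMSE 0.009 with
near-perfect structural similarity, and the mean posterior standard
deviation of ~0.01 quantifies the per-proportion uncertainty. Real data
enter through `read_st()` / `read_sc_reference()` / `basin_preprocess()`,
or through the CLI:

```sh
Rscript inst/exec/basin.R simulate   --scheme 1 --seed 3 --out sim/
Rscript inst/exec/basin.R deconvolve --counts sim/counts.csv --coords sim/coords.csv \
                                     --ref sim/B.csv --seed 4 --out run/
Rscript inst/exec/basin.R evaluate   --truth sim/V_true.csv --est run/mean_props.csv
```

See `vignettes/basin-methods.Rmd` for the model derivation, parameter
guidance and limitations.

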