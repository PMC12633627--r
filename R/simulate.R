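#' Lay out spots on a grid and partition them into regions
#'
#' Spots sit on a regular `grid_shape[1]` x `grid_shape[2]` integer grid
#' (x fastest). `style = "thirds"` splits the grid into `n_regions`
#' contiguous vertical bands of near-equal width; `style = "voronoi"`
#' assigns each spot to the nearest of `n_regions` randomly chosen seed
#' spots, giving irregular contiguous regions.
#'
#' @param grid_shape Integer vector `c(nx, ny)`.
#' @param n_regions Number of regions (default 3).
#' @param style `"thirds"` or `"voronoi"`.
#' @param seed Optional seed (only used by `"voronoi"`).
#' @return An object of class `basin_layout`: `coords` (p x 2), `region`
#'   (length-p integers in `1:n_regions`), `grid_shape`, `style`.
#' @export
make_region_layout <- function(grid_shape = c(20L, 20L), n_regions = 3L,
                               style = c("thirds", "voronoi"), seed = NULL) {
  style <- match.arg(style)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1L))
  nx <- as.integer(grid_shape[1]); ny <- as.integer(grid_shape[2])
  p <- nx * ny
  if (n_regions > p) stop("more regions than spots")
  if (!is.null(seed)) set.seed(as.integer(seed))
  coords <- cbind(x = rep(seq_len(nx), times = ny),
                  y = rep(seq_len(ny), each = nx))
  rownames(coords) <- paste0("spot", seq_len(p))
  if (style == "thirds") {
    band <- rep(seq_len(n_regions), times = diff(round(seq(0, nx, length.out = n_regions + 1))))
    region <- band[coords[, "x"]]
  } else {
    centers <- coords[sample.int(p, n_regions), , drop = FALSE]
    d <- outer(seq_len(p), seq_len(n_regions), function(i, k)
      (coords[i, 1] - centers[k, 1])^2 + (coords[i, 2] - centers[k, 2])^2)
    region <- max.col(-d, ties.method = "first")
  }
  structure(list(coords = coords, region = as.integer(region),
                 grid_shape = c(nx, ny), style = style),
            class = "basin_layout")
}

# separable Gaussian smoothing of a per-spot field on the layout grid,
# reflect boundary handling
.smooth_grid <- function(values, layout, kernel_size, kernel_sd) {
  nx <- layout$grid_shape[1]; ny <- layout$grid_shape[2]
  r <- floor(min(kernel_size, 2 * max(nx, ny)) / 2)
  off <- -r:r
  w <- exp(-off^2 / (2 * kernel_sd^2))
  w <- w / sum(w)
  reflect <- function(i, n) {
    # reflect indices into 1..n (mirror without repeating the edge twice)
    i <- ifelse(i < 1L, 2L - i, i)
    i <- ifelse(i > n, 2L * n - i, i)
    pmin(pmax(i, 1L), n)
  }
  m <- matrix(values, nx, ny)
  # along x
  m1 <- matrix(0, nx, ny)
  for (k in seq_along(off))
    m1 <- m1 + w[k] * m[reflect(seq_len(nx) + off[k], nx), , drop = FALSE]
  # along y
  m2 <- matrix(0, nx, ny)
  for (k in seq_along(off))
    m2 <- m2 + w[k] * m1[, reflect(seq_len(ny) + off[k], ny), drop = FALSE]
  as.numeric(m2)
}

#' Simulate ground-truth cell-type proportions
#'
#' One cell type per region, dominant where its region lies. Four schemes:
#' \describe{
#'   \item{1}{Piecewise constant: the dominant type has proportion
#'     `base_high` (0.7) and the others share `base_low` (0.15) each.}
#'   \item{2}{Scheme 1 smoothed with a Gaussian kernel (default size 40,
#'     sd 0.5 in spot-grid units).}
#'   \item{3}{Gaussian noise (sd `prop_noise_sd` = 0.05) added around the
#'     scheme-1 means, then smoothed with the same kernel.}
#'   \item{4}{Per-spot Dirichlet draws with concentration `dirichlet_main`
#'     (3) on the region's dominant type and `dirichlet_other` (1) on the
#'     rest.}
#' }
#' In every scheme the columns are clipped at zero and renormalized to the
#' simplex.
#'
#' @param layout A [make_region_layout()] result.
#' @param scheme Integer 1-4.
#' @param seed Optional seed.
#' @param base_high,base_low Dominant/minor base proportions.
#' @param kernel_size,kernel_sd Gaussian smoothing kernel (spot-grid units).
#' @param prop_noise_sd Proportion noise of scheme 3.
#' @param dirichlet_main,dirichlet_other Dirichlet concentrations of scheme 4.
#' @return An object of class `basin_truth`: `V_true` (c x p, simplex
#'   columns), `region`, `scheme`, `cell_types`.
#' @export
simulate_proportions <- function(layout, scheme = 1L, seed = NULL,
                                 base_high = 0.7, base_low = 0.15,
                                 kernel_size = 40L, kernel_sd = 0.5,
                                 prop_noise_sd = 0.05,
                                 dirichlet_main = 3, dirichlet_other = 1) {
  stopifnot(inherits(layout, "basin_layout"))
  scheme <- as.integer(scheme)
  if (!scheme %in% 1:4) stop("unknown simulation scheme: ", scheme)
  if (!is.null(seed)) set.seed(as.integer(seed))
  c_ <- max(layout$region)
  p <- nrow(layout$coords)
  Vb <- matrix(base_low, c_, p)
  Vb[cbind(layout$region, seq_len(p))] <- base_high
  V <- switch(scheme,
    Vb,
    t(apply(Vb, 1L, .smooth_grid, layout = layout,
            kernel_size = kernel_size, kernel_sd = kernel_sd)),
    {
      Vn <- Vb + matrix(rnorm(length(Vb), sd = prop_noise_sd), c_, p)
      t(apply(Vn, 1L, .smooth_grid, layout = layout,
              kernel_size = kernel_size, kernel_sd = kernel_sd))
    },
    {
      draws <- vapply(seq_len(p), function(j) {
        alpha <- rep(dirichlet_other, c_)
        alpha[layout$region[j]] <- dirichlet_main
        g <- rgamma(c_, shape = alpha)
        g / sum(g)
      }, numeric(c_))
      draws
    })
  V <- pmax(V, 0)
  V <- sweep(V, 2L, colSums(V), `/`)
  types <- paste0("type", seq_len(c_))
  dimnames(V) <- list(types, rownames(layout$coords))
  structure(list(V_true = V, region = layout$region, scheme = scheme,
                 cell_types = types, seed = seed),
            class = "basin_truth")
}

#' Simulate synthetic reference profiles
#'
#' A synthetic stand-in for profiles derived from real scRNA-seq: genes get a
#' common baseline drawn uniformly from `baseline_range` (log1p scale) and
#' the genes are partitioned into disjoint marker blocks, one per cell type,
#' whose entries in that type's column are elevated by exactly `separation`.
#' `B'B` is well conditioned for any `separation > 0` and singular at 0.
#'
#' @param n_genes Number of genes (default 5000, the order of magnitude of
#'   gene panels retained by the preprocessing filters on real data).
#' @param n_types Number of cell types.
#' @param separation Marker elevation on the log1p scale (default 2).
#' @param seed Optional seed.
#' @param baseline_range Range of the uniform baseline.
#' @return A `basin_profiles` object on the log1p scale.
#' @export
simulate_reference <- function(n_genes = 5000L, n_types = 3L, separation = 2,
                               seed = NULL, baseline_range = c(0.1, 1.5)) {
  stopifnot(separation >= 0, n_types >= 2L, n_genes >= n_types)
  if (!is.null(seed)) set.seed(as.integer(seed))
  baseline <- runif(n_genes, baseline_range[1], baseline_range[2])
  sizes <- diff(round(seq(0, n_genes, length.out = n_types + 1)))
  block <- rep(seq_len(n_types), times = sizes)
  B <- matrix(baseline, n_genes, n_types)
  B[cbind(seq_len(n_genes), block)] <- baseline + separation
  dimnames(B) <- list(paste0("gene", seq_len(n_genes)),
                      paste0("type", seq_len(n_types)))
  structure(list(B = B, cell_types = colnames(B), log_scale = TRUE),
            class = "basin_profiles")
}

#' Simulate spot expression from reference profiles and true proportions
#'
#' `X = pmax(B V_true + N(0, noise_sd^2), 0)`, returned as a log1p-scale
#' [expression_matrix()] (the synthetic profiles live on that scale already,
#' so no further transform applies).
#'
#' @param B A `basin_profiles` object or genes x cell types matrix.
#' @param truth A `basin_truth` from [simulate_proportions()].
#' @param noise_sd Gaussian noise standard deviation (default 0.5).
#' @param seed Optional seed.
#' @return An [expression_matrix()] with `log_scale = TRUE`.
#' @export
simulate_expression <- function(B, truth, noise_sd = 0.5, seed = NULL) {
  Bm <- .as_matrix_B(B)
  stopifnot(inherits(truth, "basin_truth"),
            ncol(Bm) == nrow(truth$V_true), noise_sd >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mu <- Bm %*% truth$V_true
  X <- pmax(mu + matrix(rnorm(length(mu), sd = noise_sd), nrow(mu), ncol(mu)), 0)
  expression_matrix(X, log_scale = TRUE)
}

#' Simulate a complete synthetic deconvolution dataset
#'
#' Convenience wrapper chaining [make_region_layout()],
#' [simulate_proportions()], [simulate_reference()] and
#' [simulate_expression()] under one seed.
#'
#' @inheritParams simulate_proportions
#' @inheritParams simulate_reference
#' @inheritParams simulate_expression
#' @param grid_shape Spot grid, default 20 x 20 (400 spots).
#' @param style Region layout style.
#' @return A list with `X`, `geometry`, `B`, `truth`, `layout`.
#' @export
simulate_dataset <- function(grid_shape = c(20L, 20L), scheme = 1L,
                             n_types = 3L, n_genes = 5000L, separation = 2,
                             noise_sd = 0.5, style = "thirds", seed = 1L) {
  set.seed(as.integer(seed))
  layout <- make_region_layout(grid_shape, n_regions = n_types, style = style)
  truth <- simulate_proportions(layout, scheme = scheme)
  B <- simulate_reference(n_genes = n_genes, n_types = n_types,
                          separation = separation)
  X <- simulate_expression(B, truth, noise_sd = noise_sd)
  geometry <- spot_geometry(layout$coords)
  list(X = X, geometry = geometry, B = B, truth = truth, layout = layout)
}
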