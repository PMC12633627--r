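# Shared in-code fixtures for the test suite.

# tiny raw-count ST matrix with coordinates
tiny_st <- function() {
  m <- matrix(c(1, 0, 3,
                2, 5, 0,
                0, 1, 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  list(expr = expression_matrix(m),
       geometry = spot_geometry(cbind(c(1, 2, 3), c(1, 1, 1)),
                                spot_ids = c("s1", "s2", "s3")))
}

# raw-count scRNA-seq reference: 2 types x 2 cells each
tiny_sc <- function() {
  m <- matrix(c(2, 4, 0, 0,
                1, 1, 6, 8,
                0, 0, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("c1", "c2", "c3", "c4")))
  sc_reference(m, cell_types = c("A", "A", "B", "B"))
}

# an identity-Laplacian graph on p spots (A = 0, ridge 1): L_pd = I
identity_graph <- function(p) {
  build_laplacian(matrix(0, p, p), ridge_eps = 1)
}

# a well-conditioned random graph on a grid of p spots
grid_graph <- function(nx, ny, sigma_A2 = 2) {
  lay <- make_region_layout(c(nx, ny), n_regions = 1L, style = "thirds")
  build_spatial_graph(spot_geometry(lay$coords),
                      graph_config(sigma_A2 = sigma_A2))
}

# small synthetic deconvolution problem on the log1p scale
small_problem <- function(n = 40, p = 12, c_ = 3, seed = 99, noise_sd = 0.1) {
  set.seed(seed)
  B <- matrix(runif(n * c_, 0.2, 1), n, c_,
              dimnames = list(paste0("g", 1:n), paste0("t", 1:c_)))
  B[cbind(1:n, rep(1:c_, length.out = n))] <- B[cbind(1:n, rep(1:c_, length.out = n))] + 2
  V <- matrix(rgamma(c_ * p, 2), c_, p)
  V <- sweep(V, 2, colSums(V), `/`)
  X <- pmax(B %*% V + matrix(rnorm(n * p, sd = noise_sd), n, p), 0)
  colnames(X) <- paste0("s", 1:p)
  list(X = X, B = B, V = V)
}
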