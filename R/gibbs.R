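#' Sampler run configuration
#'
#' @param n_samples Number of kept posterior draws (default 2000).
#' @param burn_in Discarded initial iterations; the reference-based chain
#'   converges within a few steps, so the default is 5.
#' @param sampler `"auto"` (dimension-based, see [choose_sampler()]),
#'   `"tmn"` or `"rectified"`.
#' @param sweeps Coordinate-Gibbs sweeps per V draw (default 1; the outer
#'   chain supplies the mixing).
#' @param random_scan Shuffle the coordinate scan order each sweep.
#' @param normalize_in_chain If `TRUE` the chain itself propagates the
#'   column-normalized V (the literal algorithm); by default the chain keeps
#'   the raw draw so the noise/sparsity conditionals stay consistent with the
#'   unnormalized model, and normalization applies to the stored copy only.
#' @param shape_mode Shape convention of the noise-scale conditional, see
#'   [sigma2_posterior_params()].
#' @param verbose Print a per-iteration log line (iteration, sigma2, eta,
#'   fraction of zero entries).
#' @return An object of class `basin_control`.
#' @export
basin_control <- function(n_samples = 2000L, burn_in = 5L,
                          sampler = c("auto", "tmn", "rectified"),
                          sweeps = 1L, random_scan = FALSE,
                          normalize_in_chain = FALSE,
                          shape_mode = c("paper", "likelihood_only"),
                          verbose = FALSE) {
  sampler <- match.arg(sampler)
  shape_mode <- match.arg(shape_mode)
  n_samples <- as.integer(n_samples); burn_in <- as.integer(burn_in)
  stopifnot(n_samples >= 1L, burn_in >= 0L, sweeps >= 1L)
  structure(list(n_samples = n_samples, burn_in = burn_in, sampler = sampler,
                 sweeps = as.integer(sweeps), random_scan = isTRUE(random_scan),
                 normalize_in_chain = isTRUE(normalize_in_chain),
                 shape_mode = shape_mode, verbose = isTRUE(verbose)),
            class = "basin_control")
}

.normalize_columns <- function(V, warn_env = NULL) {
  cs <- colSums(V)
  zero <- cs <= 0
  if (any(zero)) {
    if (!is.null(warn_env) && !isTRUE(warn_env$warned)) {
      warning("all-zero proportion column(s) encountered; set to uniform 1/c")
      warn_env$warned <- TRUE
    }
    V[, zero] <- 1 / nrow(V)
    cs[zero] <- 1
  }
  sweep(V, 2L, cs, `/`)
}

#' Run the deconvolution Gibbs sampler
#'
#' Iterates the three conditional draws: noise scale `sigma2` given V,
#' sparsity rate `eta` given V, then V given both from its truncated
#' matrix-normal conditional. V is initialized at the non-negative
#' least-squares fit `pmax((B'B)^{-1}B'X, 0)`. Stored draws are
#' column-normalized onto the simplex; the first `burn_in` draws are
#' discarded.
#'
#' @param X Log1p-scale expression ([expression_matrix()] or matrix,
#'   genes x spots), genes aligned with `B`.
#' @param B Reference profiles (`basin_profiles` or genes x cell types
#'   matrix) on the log1p scale.
#' @param graph A `basin_graph` built on the spots of `X`.
#' @param hyper A [basin_hyperparams()].
#' @param control A [basin_control()].
#' @param seed Optional integer seed; all randomness in the run derives from
#'   it.
#' @return An object of class `basin_draws`: `V` (c x p x n_samples array of
#'   normalized proportion draws), `sigma2`, `eta` (vectors), `cell_types`,
#'   `spot_ids`, and the configuration used.
#' @export
run_basin <- function(X, B, graph, hyper = basin_hyperparams(),
                      control = basin_control(), seed = NULL) {
  Xm <- .as_matrix_X(X); Bm <- .as_matrix_B(B)
  if (inherits(X, "basin_expression") && !X$log_scale)
    warning("X is flagged as raw counts; run_basin expects log1p-scale data")
  if (inherits(B, "basin_profiles") && !B$log_scale)
    warning("B is flagged as raw counts; run_basin expects log1p-scale profiles")
  stopifnot(inherits(graph, "basin_graph"),
            nrow(Xm) == nrow(Bm), ncol(Xm) == nrow(graph$L_pd))
  if (!is.null(rownames(Xm)) && !is.null(rownames(Bm)) &&
      !identical(rownames(Xm), rownames(Bm)))
    stop("gene identifiers of X and B do not match; run basin_preprocess()")
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- nrow(Xm); p <- ncol(Xm); c_ <- ncol(Bm)
  G <- crossprod(Bm)
  chG <- .chol_gram(G)
  Ginv <- chol2inv(chG)
  L <- graph$L_pd
  P <- crossprod(Bm, Xm)                       # B'X, c x p
  M0 <- Ginv %*% P                             # least-squares fit
  g1 <- as.numeric(Ginv %*% rep(1, c_))
  w <- as.numeric(.solve_lpd(graph, rep(1, p)))  # L_pd^{-1} 1
  # constant pieces of tr(L_pd E'E): tr(L X'X) and the c x p matrix (B'X L)'
  trXLX <- sum((Xm %*% L) * Xm)
  PLt <- P %*% L                               # (c x p): row i = (B'X L)_i.
  sampler <- control$sampler
  if (sampler == "auto") sampler <- choose_sampler(c_, p)
  Fr <- Fc <- NULL
  if (sampler == "rectified") {
    Fr <- backsolve(chG, diag(c_))             # Fr Fr' = (B'B)^{-1}
    Fc <- .lpd_inv_factor(graph)               # Fc Fc' = L_pd^{-1}
  }

  V <- pmax(M0, 0)
  V <- .normalize_columns(V)
  total <- control$n_samples + control$burn_in
  keep <- control$n_samples
  V_draws <- array(NA_real_, c(c_, p, keep),
                   dimnames = list(colnames(Bm), colnames(Xm), NULL))
  sigma2_draws <- numeric(keep); eta_draws <- numeric(keep)
  shape_s <- hyper$a1 + n * p / 2 +
    if (control$shape_mode == "paper") c_ * p / 2 else 0
  warn_env <- new.env(); warn_env$warned <- FALSE

  for (t in seq_len(total)) {
    trLEE <- trXLX - 2 * sum(PLt * V) + sum((G %*% V) * (V %*% L))
    if (trLEE < 0) trLEE <- 0                  # guard tiny negative roundoff
    sigma2 <- 1 / rgamma(1L, shape = shape_s, rate = hyper$b1 + trLEE / 2)
    eta <- rgamma(1L, shape = hyper$a2 + c_ * p,
                  rate = sum(V) + 1 / hyper$b2)
    M <- M0 - (sigma2 * eta) * tcrossprod(g1, w)
    if (sampler == "tmn") {
      V <- tmn_gibbs_sweeps_cpp(V, M, G, L, sigma2, control$sweeps,
                                control$random_scan)
    } else {
      Z <- matrix(rnorm(c_ * p), c_, p)
      V <- pmax(M + sqrt(sigma2) * Fr %*% Z %*% t(Fc), 0)
    }
    if (any(!is.finite(V)))
      stop("numerical failure in the V conditional at iteration ", t)
    V_store <- .normalize_columns(V, warn_env)
    if (control$normalize_in_chain) V <- V_store
    if (control$verbose)
      message(sprintf("iter %d: sigma2 = %.4g, eta = %.4g, zero frac = %.3f",
                      t, sigma2, eta, mean(V == 0)))
    if (t > control$burn_in) {
      k <- t - control$burn_in
      V_draws[, , k] <- V_store
      sigma2_draws[k] <- sigma2
      eta_draws[k] <- eta
    }
  }
  structure(list(V = V_draws, sigma2 = sigma2_draws, eta = eta_draws,
                 cell_types = colnames(Bm), spot_ids = colnames(Xm),
                 sampler = sampler, control = control, hyper = hyper,
                 seed = seed),
            class = "basin_draws")
}

#' @export
print.basin_draws <- function(x, ...) {
  d <- dim(x$V)
  cat(sprintf("basin_draws: %d cell types x %d spots, %d kept draws (%s sampler)\n",
              d[1], d[2], d[3], x$sampler))
  invisible(x)
}

#' Summarize posterior draws
#'
#' Per-entry posterior mean and standard deviation of the cell-type
#' proportions, and the Pearson correlation matrix of the mean proportion
#' profiles across spots (which cell types co-localize spatially).
#'
#' @param object A `basin_draws` object from [run_basin()].
#' @param ... Unused.
#' @return An object of class `basin_summary` with `mean_props` (c x p,
#'   columns on the simplex), `sd_props` (c x p) and `type_correlations`
#'   (c x c).
#' @export
summary.basin_draws <- function(object, ...) {
  d <- dim(object$V)
  if (d[3] < 2L) stop("need at least two kept draws to summarize")
  m <- rowMeans(object$V, dims = 2L)
  sq <- rowMeans(object$V^2, dims = 2L)
  sd_ <- sqrt(pmax(sq - m^2, 0) * d[3] / (d[3] - 1))
  dimnames(m) <- dimnames(sd_) <- dimnames(object$V)[1:2]
  corr <- suppressWarnings(cor(t(m)))
  structure(list(mean_props = m, sd_props = sd_, type_correlations = corr,
                 n_draws = d[3]),
            class = "basin_summary")
}

#' @export
print.basin_summary <- function(x, ...) {
  cat(sprintf("basin_summary over %d draws: %d cell types x %d spots\n",
              x$n_draws, nrow(x$mean_props), ncol(x$mean_props)))
  cat("mean proportion by cell type:\n")
  print(round(rowMeans(x$mean_props), 4))
  invisible(x)
}

#' Histogram data of the posterior proportions at one spot
#'
#' Bins the sampled proportions of every cell type at the given spot into a
#' long-format table ready for plotting.
#'
#' @param draws A `basin_draws` object.
#' @param spot Spot identifier or column index.
#' @param breaks Number of equal-width bins on `[0, 1]` (default 50).
#' @return A data frame with columns `cell_type`, `bin_lower`, `bin_mid`,
#'   `count`; counts of each type sum to the number of kept draws.
#' @export
spot_histogram <- function(draws, spot, breaks = 50L) {
  stopifnot(inherits(draws, "basin_draws"))
  j <- if (is.character(spot)) match(spot, draws$spot_ids) else as.integer(spot)
  if (is.na(j) || j < 1L || j > dim(draws$V)[2])
    stop("unknown spot: ", spot)
  edges <- seq(0, 1, length.out = breaks + 1L)
  out <- lapply(seq_len(dim(draws$V)[1]), function(i) {
    x <- draws$V[i, j, ]
    idx <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), breaks)
    counts <- tabulate(idx, nbins = breaks)
    data.frame(cell_type = draws$cell_types[i] %||% as.character(i),
               bin_lower = edges[-length(edges)],
               bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
               count = counts)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
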