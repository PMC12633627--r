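#' Model hyperparameters
#'
#' Shape/scale hyperparameters of the conjugate priors: inverse-gamma
#' `(a1, b1)` on the noise scale \eqn{\sigma^2} and gamma `(a2, b2)`
#' (shape-scale parameterization) on the sparsity rate \eqn{\eta}. The
#' defaults make all of `a1`, `a2`, `b1` and `1/b2` equal to `1e-4`, i.e.
#' essentially non-informative priors that let the data dominate.
#'
#' @param a1,b1 Inverse-gamma shape and scale for \eqn{\sigma^2}.
#' @param a2,b2 Gamma shape and scale for \eqn{\eta}.
#' @return An object of class `basin_hyper`.
#' @export
basin_hyperparams <- function(a1 = 1e-4, b1 = 1e-4, a2 = 1e-4, b2 = 1e4) {
  stopifnot(a1 > 0, b1 > 0, a2 > 0, b2 > 0)
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2), class = "basin_hyper")
}

.as_matrix_X <- function(X) if (inherits(X, "basin_expression")) X$values else as.matrix(X)
.as_matrix_B <- function(B) if (inherits(B, "basin_profiles")) B$B else as.matrix(B)

# Cholesky of B'B with an explicit conditioning check: exactly collinear
# columns can slip through chol() on the strength of rounding noise alone.
.chol_gram <- function(G) {
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < 1e-7 * max(diag(ch)))
    stop("B'B is singular: cell-type profiles are collinear; ",
         "consider removing or merging a cell type", call. = FALSE)
  ch
}

#' Conditional posterior of the proportion matrix V
#'
#' Given the noise scale and sparsity rate, the conditional posterior of V is
#' a truncated matrix normal on the non-negative orthant with mean
#' \deqn{M = (B^T B)^{-1}(B^T X - \sigma^2 \eta\, J\, L_{pd}^{-1}),}
#' row covariance \eqn{\sigma^2 (B^T B)^{-1}} and column covariance
#' \eqn{L_{pd}^{-1}}, where \eqn{J} is the all-ones c x p matrix. Under
#' column-major vectorization the precision of `vec(V)` is the Kronecker
#' product `L_pd %x% (B'B / sigma2)`.
#'
#' @param X Log1p-scale expression matrix (genes x spots) or
#'   [expression_matrix()].
#' @param B Reference profile matrix (genes x cell types) or `basin_profiles`.
#' @param graph A `basin_graph` built on the spots of `X`.
#' @param sigma2 Current noise scale (positive).
#' @param eta Current sparsity rate (non-negative).
#' @return An object of class `basin_vcond` with the mean `M`, the Gram
#'   matrix `G = B'B`, `sigma2`, the truncated-matrix-normal precision pieces
#'   `row_prec = G/sigma2` and `col_prec = L_pd`, and the row covariance
#'   `row_cov = sigma2 * solve(G)`.
#' @export
v_conditional <- function(X, B, graph, sigma2, eta) {
  X <- .as_matrix_X(X); B <- .as_matrix_B(B)
  stopifnot(inherits(graph, "basin_graph"), sigma2 > 0, eta >= 0,
            nrow(X) == nrow(B), ncol(X) == nrow(graph$L_pd))
  G <- crossprod(B)
  chG <- .chol_gram(G)
  Ginv <- chol2inv(chG)
  p <- ncol(X); c_ <- ncol(B)
  # J L_pd^{-1} is rank one: ones %*% t(w) with w = L_pd^{-1} ones
  w <- .solve_lpd(graph, rep(1, p))
  g1 <- Ginv %*% rep(1, c_)
  M <- Ginv %*% crossprod(B, X) - (sigma2 * eta) * tcrossprod(g1, w)
  dimnames(M) <- list(colnames(B), colnames(X))
  structure(list(M = M, G = G, Ginv = Ginv, sigma2 = sigma2, eta = eta,
                 row_prec = G / sigma2, col_prec = graph$L_pd,
                 row_cov = sigma2 * Ginv, graph = graph),
            class = "basin_vcond")
}

#' Parameters of the conditional posterior of the noise scale
#'
#' The conditional posterior of \eqn{\sigma^2} is inverse-gamma with shape
#' `a1 + n*p/2 + c*p/2` and scale `b1 + tr(L_pd E'E)/2`, `E = X - BV`. The
#' `c*p/2` term follows the model's stated conditional; with
#' `shape_mode = "likelihood_only"` the shape is `a1 + n*p/2`, which is what
#' the matrix-normal likelihood alone contributes.
#'
#' @inheritParams v_conditional
#' @param V Current proportion matrix (c x p, non-negative).
#' @param hyper A [basin_hyperparams()].
#' @param shape_mode `"paper"` (default) or `"likelihood_only"`.
#' @return List with `shape` and `scale`.
#' @export
sigma2_posterior_params <- function(X, B, V, graph, hyper = basin_hyperparams(),
                                    shape_mode = c("paper", "likelihood_only")) {
  shape_mode <- match.arg(shape_mode)
  X <- .as_matrix_X(X); B <- .as_matrix_B(B)
  E <- X - B %*% V
  tr <- sum(E * (E %*% graph$L_pd))
  n <- nrow(X); p <- ncol(X); c_ <- ncol(B)
  shape <- hyper$a1 + n * p / 2 + if (shape_mode == "paper") c_ * p / 2 else 0
  scale <- hyper$b1 + tr / 2
  stopifnot(scale > 0)
  list(shape = shape, scale = scale)
}

#' Draw the noise scale from its conditional posterior
#'
#' @inheritParams sigma2_posterior_params
#' @return One inverse-gamma draw of \eqn{\sigma^2}.
#' @export
sample_sigma2 <- function(X, B, V, graph, hyper = basin_hyperparams(),
                          shape_mode = c("paper", "likelihood_only")) {
  par <- sigma2_posterior_params(X, B, V, graph, hyper, shape_mode)
  1 / rgamma(1L, shape = par$shape, rate = par$scale)
}

#' Parameters of the conditional posterior of the sparsity rate
#'
#' The conditional posterior of \eqn{\eta} is gamma with shape `a2 + c*p` and
#' scale `1 / (sum(V) + 1/b2)` (shape-scale parameterization; `sum(V)` is
#' `tr(J'V)` for the all-ones matrix J).
#'
#' @param V Current proportion matrix (c x p, non-negative).
#' @param hyper A [basin_hyperparams()].
#' @return List with `shape` and `scale`.
#' @export
eta_posterior_params <- function(V, hyper = basin_hyperparams()) {
  stopifnot(all(V >= 0))
  list(shape = hyper$a2 + length(V),
       scale = 1 / (sum(V) + 1 / hyper$b2))
}

#' Draw the sparsity rate from its conditional posterior
#'
#' @inheritParams eta_posterior_params
#' @return One gamma draw of \eqn{\eta}.
#' @export
sample_eta <- function(V, hyper = basin_hyperparams()) {
  par <- eta_posterior_params(V, hyper)
  rgamma(1L, shape = par$shape, scale = par$scale)
}

#' Un-normalized log joint density of the model
#'
#' Sum of the matrix-normal log likelihood of `X` given `V` and `sigma2`
#' (column precision `L_pd`), the exponential prior on `V`, and the
#' inverse-gamma/gamma log priors on `sigma2` and `eta`. Returns `-Inf` for
#' any negative entry of `V`. Intended for validation: the conditionals
#' implemented in [v_conditional()], [sample_sigma2()] (likelihood-only mode)
#' and [sample_eta()] can be checked against finite differences or grids of
#' this density.
#'
#' @inheritParams sigma2_posterior_params
#' @param sigma2,eta Current scalar parameter values (positive).
#' @return Scalar log density (up to an additive constant).
#' @export
log_joint_density <- function(X, B, V, sigma2, eta, graph,
                              hyper = basin_hyperparams()) {
  X <- .as_matrix_X(X); B <- .as_matrix_B(B)
  V <- as.matrix(V)
  if (any(V < 0)) return(-Inf)
  stopifnot(sigma2 > 0, eta > 0)
  E <- X - B %*% V
  n <- nrow(X); p <- ncol(X)
  logdetL <- 2 * sum(log(diag(graph$chol_L_pd)))
  ll <- -(n * p / 2) * log(2 * pi * sigma2) + (n / 2) * logdetL -
    sum(E * (E %*% graph$L_pd)) / (2 * sigma2)
  lp_v <- length(V) * log(eta) - eta * sum(V)
  lp_s <- hyper$a1 * log(hyper$b1) - lgamma(hyper$a1) -
    (hyper$a1 + 1) * log(sigma2) - hyper$b1 / sigma2
  lp_e <- -hyper$a2 * log(hyper$b2) - lgamma(hyper$a2) +
    (hyper$a2 - 1) * log(eta) - eta / hyper$b2
  ll + lp_v + lp_s + lp_e
}
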