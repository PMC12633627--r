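#' Spatial graph configuration
#'
#' @param sigma_A2 Gaussian-kernel bandwidth \eqn{\sigma_A^2}. `NULL` selects
#'   a default from the coordinate magnitude when the graph is built: 0.1 for
#'   coordinates of magnitude up to a few hundred, 1e4 for coordinates in the
#'   thousands (see [default_sigma_a2()]).
#' @param mu Weight of the histology-intensity difference term (ignored when
#'   no intensities are supplied). Default 1, matching intensities normalized
#'   to `[0, 1]`.
#' @param ridge_eps Ridge added to the Laplacian diagonal to make it positive
#'   definite; `NULL` selects `1e-3 * mean(degree)` at build time.
#' @param knn Optional integer: keep only each spot's `knn` nearest neighbours
#'   in the weight matrix (symmetrized by the elementwise maximum).
#' @return An object of class `basin_graph_config`.
#' @export
graph_config <- function(sigma_A2 = NULL, mu = 1, ridge_eps = NULL, knn = NULL) {
  if (!is.null(sigma_A2) && sigma_A2 <= 0) stop("sigma_A2 must be positive")
  if (mu < 0) stop("mu must be non-negative")
  if (!is.null(ridge_eps) && ridge_eps < 0) stop("ridge_eps must be non-negative")
  if (!is.null(knn)) knn <- as.integer(knn)
  structure(list(sigma_A2 = sigma_A2, mu = mu, ridge_eps = ridge_eps, knn = knn),
            class = "basin_graph_config")
}

#' Default kernel bandwidth from coordinate magnitude
#'
#' Coordinates of magnitude 1e1 to 1e2 (typical array-based ST platforms) get
#' \eqn{\sigma_A^2 = 0.1}; coordinates of magnitude 1e3 to 1e4 (e.g. stitched
#' imaging-based data in pixel units) get \eqn{\sigma_A^2 = 10^4}.
#'
#' @param coords Numeric p x 2 coordinate matrix.
#' @return The default bandwidth.
#' @export
default_sigma_a2 <- function(coords) {
  m <- max(abs(coords))
  if (m < 1000) 0.1 else 1e4
}

#' Extract per-spot intensities from a histology image
#'
#' The image is min-max normalized to `[0, 1]`, optionally resized so its
#' longer side equals `resize_to` (aspect ratio preserved; requires the
#' EBImage package), and each spot's intensity is the mean over the
#' `window` x `window` pixel square centred on the spot's mapped pixel
#' coordinate, clipped at the image borders.
#'
#' The affine map is given as six numbers `(a, b, tx, c, d, ty)` mapping a
#' spot at `(x, y)` to pixel column `a*x + b*y + tx` and pixel row
#' `c*x + d*y + ty` of the *original* image; after resizing the mapped
#' coordinates are scaled by the resize factor.
#'
#' @param image Numeric matrix (rows = pixel rows) in arbitrary units, or a
#'   3-channel array which is converted to grayscale by luminance.
#' @param coords Numeric p x 2 spot coordinates.
#' @param affine Length-6 affine map, default identity.
#' @param resize_to Target length of the longer image side, or `NULL` to skip
#'   resizing.
#' @param window Odd side length of the averaging square (default 5).
#' @return Numeric length-p intensity vector in `[0, 1]`.
#' @export
extract_spot_intensity <- function(image, coords, affine = c(1, 0, 0, 0, 1, 0),
                                   resize_to = 1024, window = 5) {
  if (length(dim(image)) == 3L) {
    lum <- c(0.2126, 0.7152, 0.0722)[seq_len(dim(image)[3])]
    lum <- lum / sum(lum)
    image <- apply(sweep(image, 3L, lum, `*`), c(1L, 2L), sum)
  }
  image <- as.matrix(image)
  stopifnot(length(affine) == 6L, window >= 1, window %% 2 == 1)
  rng <- range(image)
  image <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) else
    pmin(pmax(image, 0), 1)
  scale <- 1
  if (!is.null(resize_to) && max(dim(image)) != resize_to) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("image resizing requires the EBImage package; pass resize_to = NULL")
    scale <- resize_to / max(dim(image))
    # EBImage images are x-by-y; transpose in and out
    img <- EBImage::resize(EBImage::Image(t(image)),
                           w = round(ncol(image) * scale),
                           h = round(nrow(image) * scale))
    image <- t(EBImage::imageData(img))
    image <- pmin(pmax(image, 0), 1)
  }
  coords <- as.matrix(coords)
  px <- (affine[1] * coords[, 1] + affine[2] * coords[, 2] + affine[3]) * scale
  py <- (affine[4] * coords[, 1] + affine[5] * coords[, 2] + affine[6]) * scale
  nr <- nrow(image); nc <- ncol(image)
  ci <- round(px); ri <- round(py)
  if (any(ci < 1 | ci > nc | ri < 1 | ri > nr))
    stop("some spots map outside the image; check the affine alignment")
  half <- (window - 1) / 2
  vapply(seq_len(nrow(coords)), function(i) {
    rows <- max(1, ri[i] - half):min(nr, ri[i] + half)
    cols <- max(1, ci[i] - half):min(nc, ci[i] + half)
    mean(image[rows, cols])
  }, numeric(1))
}

#' Build the Gaussian-kernel spot weight matrix
#'
#' \deqn{A_{ij} = \exp\{-(\|s_i - s_j\|^2 + \mu (I_i - I_j)^2)/\sigma_A^2\}}
#' for \eqn{i \ne j} and 0 on the diagonal. When the geometry carries no
#' intensity vector the \eqn{\mu} term is dropped. With `knn` set, entries
#' outside each spot's k nearest neighbours are zeroed and the result is
#' symmetrized by the elementwise maximum.
#'
#' @param geometry A [spot_geometry()].
#' @param config A [graph_config()].
#' @return Symmetric p x p weight matrix with zero diagonal.
#' @export
build_weight_matrix <- function(geometry, config = graph_config()) {
  stopifnot(inherits(geometry, "basin_geometry"))
  sigma_A2 <- config$sigma_A2
  if (is.null(sigma_A2)) sigma_A2 <- default_sigma_a2(geometry$coords)
  if (sigma_A2 <= 0) stop("sigma_A2 must be positive")
  d2 <- as.matrix(dist(geometry$coords))^2
  if (!is.null(geometry$intensity) && config$mu > 0) {
    di <- outer(geometry$intensity, geometry$intensity, `-`)^2
    d2 <- d2 + config$mu * di
  }
  A <- exp(-d2 / sigma_A2)
  diag(A) <- 0
  if (!is.null(config$knn)) {
    p <- nrow(A)
    k <- min(config$knn, p - 1L)
    keep <- matrix(FALSE, p, p)
    for (i in seq_len(p)) {
      nn <- order(A[i, ], decreasing = TRUE)[seq_len(k)]
      keep[i, nn] <- TRUE
    }
    A <- pmax(A * keep, t(A * keep))
  }
  dimnames(A) <- list(rownames(geometry$coords), rownames(geometry$coords))
  A
}

#' Build the (regularized) graph Laplacian
#'
#' Computes `L = D - A` with degree matrix `D = diag(rowSums(A))`, and the
#' positive-definite ridge form `L_pd = L + ridge_eps * I` actually used as
#' the column precision of the model. The Cholesky factor of `L_pd` is cached.
#'
#' @param A Symmetric non-negative weight matrix with zero diagonal.
#' @param ridge_eps Ridge; `NULL` gives `1e-3 * mean(rowSums(A))`.
#' @return An object of class `basin_graph` with elements `A`, `degrees`,
#'   `L`, `L_pd`, `chol_L_pd` (upper triangular), `ridge`.
#' @export
build_laplacian <- function(A, ridge_eps = NULL) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-8)) stop("A must be symmetric")
  if (any(diag(A) != 0)) stop("A must have a zero diagonal")
  if (any(A < 0)) stop("A must be non-negative")
  deg <- rowSums(A)
  L <- diag(deg, nrow(A)) - A
  if (is.null(ridge_eps)) ridge_eps <- 1e-3 * mean(deg)
  L_pd <- L + diag(ridge_eps, nrow(A))
  ch <- tryCatch(chol(L_pd), error = function(e)
    stop("Cholesky of the ridged Laplacian failed; increase ridge_eps ",
         "(current: ", format(ridge_eps), ")", call. = FALSE))
  dimnames(L) <- dimnames(L_pd) <- dimnames(A)
  structure(list(A = A, degrees = deg, L = L, L_pd = L_pd, chol_L_pd = ch,
                 ridge = ridge_eps),
            class = "basin_graph")
}

#' @export
print.basin_graph <- function(x, ...) {
  cat(sprintf("basin_graph: %d spots, mean degree %.3g, ridge %.3g\n",
              nrow(x$A), mean(x$degrees), x$ridge))
  invisible(x)
}

#' Build the spatial graph from geometry in one step
#'
#' Convenience wrapper: [build_weight_matrix()] then [build_laplacian()].
#'
#' @inheritParams build_weight_matrix
#' @return A `basin_graph`.
#' @export
build_spatial_graph <- function(geometry, config = graph_config()) {
  build_laplacian(build_weight_matrix(geometry, config),
                  ridge_eps = config$ridge_eps)
}

# solve L_pd x = b via the cached Cholesky factor
.solve_lpd <- function(graph, b) {
  backsolve(graph$chol_L_pd, backsolve(graph$chol_L_pd, b, transpose = TRUE))
}

# lazily computed factor F with F F' = L_pd^{-1}
.lpd_inv_factor <- function(graph) {
  backsolve(graph$chol_L_pd, diag(nrow(graph$L_pd)))
}

#' Export the weight matrix or Laplacian as MatrixMarket
#'
#' @param graph A `basin_graph`.
#' @param file Output path (`.mtx`).
#' @param what `"A"` or `"L"`.
#' @return The path, invisibly.
#' @export
export_graph_mtx <- function(graph, file, what = c("A", "L")) {
  what <- match.arg(what)
  m <- Matrix::Matrix(if (what == "A") graph$A else graph$L, sparse = TRUE)
  Matrix::writeMM(m, file)
  invisible(file)
}
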