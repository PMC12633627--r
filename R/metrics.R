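#' Root mean squared error
#'
#' `rmse(a, b) = ||a - b||_F / sqrt(N)` with `N` the number of entries.
#'
#' @param a,b Numeric vectors or matrices of identical shape.
#' @return Scalar RMSE.
#' @export
rmse <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("rmse: shape mismatch")
  sqrt(mean((a - b)^2))
}

#' Global structural similarity index
#'
#' Single-window SSIM of two proportion maps of one cell type: means,
#' (population) variances and covariance are taken over all spots, with the
#' standard stabilizers `c1 = (0.01 R)^2`, `c2 = (0.03 R)^2` for data range
#' `R = 1`. To score a full deconvolution, average the per-type values (see
#' [evaluate_deconvolution()]).
#'
#' @param a,b Numeric vectors/matrices of identical shape.
#' @param c1,c2 Stabilizing constants.
#' @return Scalar SSIM in `[-1, 1]` for inputs in `[0, 1]`.
#' @export
ssim <- function(a, b, c1 = 0.01^2, c2 = 0.03^2) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("ssim: shape mismatch")
  stopifnot(c1 > 0, c2 > 0)
  mua <- mean(a); mub <- mean(b)
  va <- mean(a^2) - mua^2; vb <- mean(b^2) - mub^2
  vab <- mean(a * b) - mua * mub
  ((2 * mua * mub + c1) * (2 * vab + c2)) /
    ((mua^2 + mub^2 + c1) * (va + vb + c2))
}

#' Jensen-Shannon distance between two probability vectors
#'
#' Square root of the Jensen-Shannon divergence
#' `0.5 KL(a || m) + 0.5 KL(b || m)`, `m = (a + b)/2`, with the convention
#' `0 log 0 = 0`. Base-2 logs (the default) bound the distance in `[0, 1]`.
#'
#' @param a,b Simplex vectors (non-negative, summing to 1 within 1e-6).
#' @param base Log base, 2 or `exp(1)`.
#' @return Scalar distance.
#' @export
jsd <- function(a, b, base = 2) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("jsd: shape mismatch")
  if (any(a < -1e-12) || any(b < -1e-12) ||
      abs(sum(a) - 1) > 1e-6 || abs(sum(b) - 1) > 1e-6)
    stop("jsd expects simplex vectors (non-negative, summing to 1)")
  m <- (a + b) / 2
  kl <- function(p, q) {
    i <- p > 0
    sum(p[i] * (log(p[i], base = base) - log(q[i], base = base)))
  }
  sqrt(max(0.5 * kl(a, m) + 0.5 * kl(b, m), 0))
}

#' Score an estimated proportion matrix against the truth
#'
#' RMSE over all entries, mean per-cell-type global SSIM, and mean per-spot
#' Jensen-Shannon distance.
#'
#' @param estimate,truth c x p proportion matrices (simplex columns); `truth`
#'   may also be a `basin_truth` object.
#' @param jsd_base Log base of the JSD, see [jsd()].
#' @return A list with `rmse`, `ssim`, `jsd`.
#' @export
evaluate_deconvolution <- function(estimate, truth, jsd_base = 2) {
  if (inherits(truth, "basin_truth")) truth <- truth$V_true
  if (inherits(estimate, "basin_summary")) estimate <- estimate$mean_props
  estimate <- as.matrix(estimate); truth <- as.matrix(truth)
  if (!all(dim(estimate) == dim(truth)))
    stop("estimate and truth have different shapes")
  list(rmse = rmse(estimate, truth),
       ssim = mean(vapply(seq_len(nrow(truth)), function(i)
         ssim(estimate[i, ], truth[i, ]), numeric(1))),
       jsd = mean(vapply(seq_len(ncol(truth)), function(j)
         jsd(estimate[, j], truth[, j], base = jsd_base), numeric(1))))
}

#' Correlation of overall mean proportions with the scRNA-seq composition
#'
#' Pearson correlation between the overall mean estimated proportion of each
#' cell type (mean over spots) and the frequency of that type among the
#' reference cells. High values indicate the deconvolution recovers the
#' tissue-level composition seen in the matched scRNA-seq data.
#'
#' @param mean_props c x p mean proportion matrix (or `basin_summary`).
#' @param reference A [sc_reference()], or a named numeric vector of
#'   cell-type frequencies.
#' @return Scalar Pearson correlation.
#' @export
reference_correlation <- function(mean_props, reference) {
  if (inherits(mean_props, "basin_summary")) mean_props <- mean_props$mean_props
  est <- rowMeans(as.matrix(mean_props))
  freqs <- if (inherits(reference, "basin_scref")) {
    tab <- table(reference$cell_types)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  } else reference
  if (!is.null(names(freqs)) && !is.null(names(est))) {
    if (!all(names(est) %in% names(freqs)))
      stop("cell types of the estimate and reference do not match")
    freqs <- freqs[names(est)]
  }
  if (length(est) != length(freqs)) stop("cell-type counts do not match")
  if (length(est) < 3L)
    warning("Pearson correlation over fewer than 3 cell types is uninformative")
  cor(est, as.numeric(freqs))
}
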