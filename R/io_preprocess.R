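#' Construct a spot-level expression matrix
#'
#' Lightweight container for a genes x spots ST expression table. Values must
#' be non-negative and finite; gene and spot identifiers must be unique.
#'
#' @param values Numeric genes x spots matrix (raw counts or log1p scale).
#' @param gene_ids Character vector of gene identifiers (defaults to rownames).
#' @param spot_ids Character vector of spot identifiers (defaults to colnames).
#' @param log_scale Logical; `TRUE` once values are log1p-transformed.
#' @return An object of class `basin_expression` with elements `values`
#'   (with dimnames set), and `log_scale`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              spot_ids = colnames(values), log_scale = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(spot_ids))
    stop("gene_ids and spot_ids are required (or set dimnames on `values`)")
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(spot_ids))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(spot_ids)) stop("spot_ids must be unique")
  if (nrow(values) < 1L || ncol(values) < 1L) stop("need at least one gene and one spot")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  dimnames(values) <- list(gene_ids, spot_ids)
  structure(list(values = values, log_scale = isTRUE(log_scale)),
            class = "basin_expression")
}

#' @export
print.basin_expression <- function(x, ...) {
  cat(sprintf("basin_expression: %d genes x %d spots (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log_scale) "log1p" else "raw count"))
  invisible(x)
}

#' Construct a labelled scRNA-seq reference
#'
#' @param values Numeric genes x cells matrix of non-negative expression.
#' @param cell_types Character vector, one cell-type label per cell.
#' @param gene_ids,cell_ids Identifiers (default from dimnames).
#' @param log_scale Logical scale flag as in [expression_matrix()].
#' @return An object of class `basin_scref`.
#' @export
sc_reference <- function(values, cell_types, gene_ids = rownames(values),
                         cell_ids = colnames(values), log_scale = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(values)))
  if (is.null(gene_ids)) stop("gene_ids are required")
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  cell_types <- as.character(cell_types)
  if (length(cell_types) != ncol(values))
    stop("need exactly one cell-type label per cell")
  if (anyNA(cell_types)) stop("cell-type labels must not be NA")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, cell_types = cell_types,
                 log_scale = isTRUE(log_scale)),
            class = "basin_scref")
}

#' @export
print.basin_scref <- function(x, ...) {
  cat(sprintf("basin_scref: %d genes x %d cells, %d cell types\n",
              nrow(x$values), ncol(x$values), length(unique(x$cell_types))))
  invisible(x)
}

#' Construct spot geometry
#'
#' @param coords Numeric p x 2 matrix of spot coordinates, rows ordered as the
#'   spots of the matching [expression_matrix()].
#' @param intensity Optional numeric vector of per-spot histology intensities
#'   in `[0, 1]`.
#' @param spot_ids Optional spot identifiers (default rownames of `coords`).
#' @return An object of class `basin_geometry`.
#' @export
spot_geometry <- function(coords, intensity = NULL, spot_ids = rownames(coords)) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stop("coords must have two columns")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (!is.null(intensity)) {
    intensity <- as.numeric(intensity)
    if (length(intensity) != nrow(coords))
      stop("intensity must have one value per spot")
    if (any(!is.finite(intensity)) || any(intensity < 0 | intensity > 1))
      stop("intensity values must lie in [0, 1]")
  }
  if (!is.null(spot_ids)) rownames(coords) <- as.character(spot_ids)
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, intensity = intensity),
            class = "basin_geometry")
}

.read_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)(\\.gz)?$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read spatial transcriptomics counts and coordinates
#'
#' Reads a genes x spots count table (first column gene identifiers, header =
#' spot identifiers) and a coordinate table (columns: spot identifier, x, y),
#' and aligns the coordinate rows to the count columns by spot identifier.
#' CSV and TSV are recognized by file extension; gzipped files are accepted.
#'
#' @param path_counts Path to the count table.
#' @param path_coords Path to the coordinate table.
#' @param transpose If `TRUE` the count table is spots x genes and is flipped.
#' @return A list with elements `expr` ([expression_matrix()]) and `geometry`
#'   ([spot_geometry()]), aligned by spot identifier.
#' @export
read_st <- function(path_counts, path_coords, transpose = FALSE) {
  if (!file.exists(path_counts)) stop("count table not found: ", path_counts)
  if (!file.exists(path_coords)) stop("coordinate table not found: ", path_coords)
  tab <- .read_table(path_counts)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  if (transpose) m <- t(m)
  co <- .read_table(path_coords)
  if (ncol(co) < 3L) stop("coordinate table needs columns: spot id, x, y")
  spot_ids <- colnames(m)
  idx <- match(spot_ids, as.character(co[[1]]))
  if (anyNA(idx)) {
    missing <- spot_ids[is.na(idx)]
    stop("spots missing from the coordinate table: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  coords <- as.matrix(co[idx, 2:3])
  rownames(coords) <- spot_ids
  list(expr = expression_matrix(m),
       geometry = spot_geometry(coords, spot_ids = spot_ids))
}

#' Read an annotated scRNA-seq reference
#'
#' @param path_counts Genes x cells count table (first column gene ids).
#' @param path_meta Two-column metadata table: cell identifier, cell type.
#' @param transpose If `TRUE` the count table is cells x genes.
#' @return A [sc_reference()] object with cells ordered as in the count table.
#' @export
read_sc_reference <- function(path_counts, path_meta, transpose = FALSE) {
  if (!file.exists(path_counts)) stop("count table not found: ", path_counts)
  if (!file.exists(path_meta)) stop("metadata table not found: ", path_meta)
  tab <- .read_table(path_counts)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  if (transpose) m <- t(m)
  meta <- .read_table(path_meta)
  idx <- match(colnames(m), as.character(meta[[1]]))
  if (anyNA(idx)) stop("cells missing from the metadata table: ",
                       paste(head(colnames(m)[is.na(idx)], 5L), collapse = ", "))
  sc_reference(m, cell_types = as.character(meta[idx, 2]))
}

#' Harmonize the gene sets of ST and scRNA-seq data
#'
#' Removes genes absent (all-zero) in either dataset and genes present in only
#' one of the two, then re-orders both objects to a common gene order (the ST
#' object's original order restricted to the retained set, so that already
#' harmonized inputs pass through unchanged). Idempotent.
#'
#' @param st An [expression_matrix()] on the raw-count scale.
#' @param sc A [sc_reference()] on the raw-count scale.
#' @return A list with the filtered, aligned `st` and `sc` objects.
#' @export
harmonize_genes <- function(st, sc) {
  stopifnot(inherits(st, "basin_expression"), inherits(sc, "basin_scref"))
  if (st$log_scale || sc$log_scale)
    stop("harmonize_genes expects raw-count inputs")
  common <- intersect(rownames(st$values), rownames(sc$values))
  if (length(common) == 0L) stop("no genes shared between ST and scRNA-seq data")
  keep <- common[rowSums(st$values[common, , drop = FALSE]) > 0 &
                 rowSums(sc$values[common, , drop = FALSE]) > 0]
  # preserve ST gene order for the retained set
  keep <- rownames(st$values)[rownames(st$values) %in% keep]
  if (length(keep) == 0L) stop("no genes remain after removing all-zero genes")
  list(st = expression_matrix(st$values[keep, , drop = FALSE],
                              log_scale = st$log_scale),
       sc = sc_reference(sc$values[keep, , drop = FALSE],
                         cell_types = sc$cell_types,
                         log_scale = sc$log_scale))
}

#' Build per-cell-type mean expression profiles
#'
#' Averages expression over all cells with each label, giving the n x c
#' reference matrix B of the deconvolution model.
#'
#' @param sc A [sc_reference()].
#' @return An object of class `basin_profiles` with elements `B` (genes x
#'   cell types, columns in sorted label order), `cell_types`, `log_scale`.
#' @export
build_reference_profiles <- function(sc) {
  stopifnot(inherits(sc, "basin_scref"))
  types <- sort(unique(sc$cell_types))
  if (length(types) < 2L) stop("reference must contain at least two cell types")
  B <- vapply(types, function(k) {
    rowMeans(sc$values[, sc$cell_types == k, drop = FALSE])
  }, numeric(nrow(sc$values)))
  dimnames(B) <- list(rownames(sc$values), types)
  structure(list(B = B, cell_types = types, log_scale = sc$log_scale),
            class = "basin_profiles")
}

#' @export
print.basin_profiles <- function(x, ...) {
  cat(sprintf("basin_profiles: %d genes x %d cell types (%s scale)\n",
              nrow(x$B), ncol(x$B), if (x$log_scale) "log1p" else "raw count"))
  invisible(x)
}

#' Flag genes with unstable within-type expression (VMR filter)
#'
#' For every gene and cell type the variance-to-mean ratio (VMR) over the
#' cells of that type is computed (defined as 0 when the type mean is 0, so
#' absent genes are never penalized; types with a single cell contribute 0).
#' Genes whose mean VMR across types falls in the top `top_fraction` are
#' flagged for removal: exactly `ceiling(top_fraction * n)` genes are removed,
#' ranked by mean VMR descending with ties broken by gene identifier so the
#' cut is deterministic.
#'
#' @param sc A [sc_reference()] on the raw-count scale.
#' @param top_fraction Fraction of genes to remove (default 0.10).
#' @return Named logical vector, `TRUE` for genes to keep; the per-gene mean
#'   VMR is attached as attribute `"mean_vmr"`.
#' @export
filter_vmr <- function(sc, top_fraction = 0.10) {
  stopifnot(inherits(sc, "basin_scref"))
  if (sc$log_scale) stop("filter_vmr expects raw-count input")
  stopifnot(top_fraction >= 0, top_fraction <= 1)
  types <- sort(unique(sc$cell_types))
  vmr <- vapply(types, function(k) {
    sub <- sc$values[, sc$cell_types == k, drop = FALSE]
    mu <- rowMeans(sub)
    v <- if (ncol(sub) > 1L) apply(sub, 1L, var) else rep(0, nrow(sub))
    out <- ifelse(mu > 0, v / mu, 0)
    out
  }, numeric(nrow(sc$values)))
  mean_vmr <- rowMeans(as.matrix(vmr))
  names(mean_vmr) <- rownames(sc$values)
  n_remove <- ceiling(top_fraction * length(mean_vmr))
  ord <- order(-mean_vmr, names(mean_vmr), method = "radix")
  keep <- rep(TRUE, length(mean_vmr))
  names(keep) <- names(mean_vmr)
  if (n_remove > 0L) keep[ord[seq_len(n_remove)]] <- FALSE
  attr(keep, "mean_vmr") <- mean_vmr
  keep
}

#' Keep genes with cell-type-specific expression (log-fold filter)
#'
#' A gene is kept when its highest mean expression across cell types exceeds
#' the mean of the remaining types by at least `log(threshold)` (natural log
#' by default, `log2(threshold)` with `base = "log2"`), evaluated on
#' log1p-scale profiles.
#'
#' @param profiles A [basin_profiles] object on the log1p scale.
#' @param threshold Fold-change threshold (default 1.25).
#' @param base `"natural"` or `"log2"`; base of the log-fold comparison.
#' @return Named logical keep vector.
#' @export
filter_logfold <- function(profiles, threshold = 1.25,
                           base = c("natural", "log2")) {
  stopifnot(inherits(profiles, "basin_profiles"))
  base <- match.arg(base)
  if (!profiles$log_scale)
    stop("filter_logfold expects log1p-scale profiles; see log1p_transform()")
  cut <- if (base == "natural") log(threshold) else log2(threshold)
  B <- profiles$B
  keep <- apply(B, 1L, function(row) {
    i <- which.max(row)
    max(row) - mean(row[-i]) >= cut
  })
  names(keep) <- rownames(B)
  keep
}

#' Apply the log1p transform
#'
#' Maps each entry x to log(1 + x) and flips the scale flag. Applying the
#' transform twice is an error.
#'
#' @param x An [expression_matrix()], [sc_reference()] or `basin_profiles`.
#' @return Object of the same class on the log1p scale.
#' @export
log1p_transform <- function(x) UseMethod("log1p_transform")

#' @export
log1p_transform.basin_expression <- function(x) {
  if (x$log_scale) stop("data are already on the log1p scale")
  expression_matrix(log1p(x$values), log_scale = TRUE)
}

#' @export
log1p_transform.basin_scref <- function(x) {
  if (x$log_scale) stop("data are already on the log1p scale")
  sc_reference(log1p(x$values), cell_types = x$cell_types, log_scale = TRUE)
}

#' @export
log1p_transform.basin_profiles <- function(x) {
  if (x$log_scale) stop("data are already on the log1p scale")
  structure(list(B = log1p(x$B), cell_types = x$cell_types, log_scale = TRUE),
            class = "basin_profiles")
}

.subset_genes <- function(obj, keep_ids) {
  if (inherits(obj, "basin_expression"))
    expression_matrix(obj$values[keep_ids, , drop = FALSE], log_scale = obj$log_scale)
  else if (inherits(obj, "basin_scref"))
    sc_reference(obj$values[keep_ids, , drop = FALSE], cell_types = obj$cell_types,
                 log_scale = obj$log_scale)
  else
    structure(list(B = obj$B[keep_ids, , drop = FALSE],
                   cell_types = obj$cell_types, log_scale = obj$log_scale),
              class = "basin_profiles")
}

#' Full preprocessing pipeline
#'
#' Runs, in order: gene-set harmonization, reference-profile construction,
#' the VMR filter (on raw counts), the log-fold specificity filter (on
#' log1p-scale profiles) and the final log1p transform of the retained ST
#' matrix and reference profiles.
#'
#' @param st An [expression_matrix()] on the raw-count scale.
#' @param sc A [sc_reference()] on the raw-count scale.
#' @param vmr_fraction Top fraction of mean-VMR genes to remove (default 0.10).
#' @param logfold_threshold Fold-change threshold of the specificity filter.
#' @param logfold_base Log base of the specificity filter, see [filter_logfold()].
#' @return A list with `X` (log1p [expression_matrix()]), `B` (log1p
#'   `basin_profiles`), `sc` (filtered raw reference) and `genes`, the
#'   retained gene identifiers.
#' @export
basin_preprocess <- function(st, sc, vmr_fraction = 0.10,
                             logfold_threshold = 1.25,
                             logfold_base = c("natural", "log2")) {
  logfold_base <- match.arg(logfold_base)
  h <- harmonize_genes(st, sc)
  keep1 <- filter_vmr(h$sc, top_fraction = vmr_fraction)
  ids1 <- names(keep1)[keep1]
  if (length(ids1) == 0L) stop("no genes remain after the VMR filter")
  st2 <- .subset_genes(h$st, ids1)
  sc2 <- .subset_genes(h$sc, ids1)
  prof <- build_reference_profiles(sc2)
  keep2 <- filter_logfold(log1p_transform(prof), threshold = logfold_threshold,
                          base = logfold_base)
  ids2 <- names(keep2)[keep2]
  if (length(ids2) == 0L) stop("no genes remain after the log-fold filter")
  list(X = log1p_transform(.subset_genes(st2, ids2)),
       B = log1p_transform(.subset_genes(prof, ids2)),
       sc = .subset_genes(sc2, ids2),
       genes = ids2)
}
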