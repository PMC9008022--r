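#' Quality-control filter for raw single-cell counts
#'
#' Removes poor-quality cells and then poor-quality genes. A cell is kept
#' when its detected-gene count (entries > 0) lies strictly inside the
#' `[min_genes, max_genes]` bounds interpreted as "lower than" / "higher
#' than" exclusions (a cell with exactly `min_genes` or `max_genes` detected
#' genes survives) and its mitochondrial count fraction does not exceed
#' `max_mito_frac`. A gene is then kept when it is detected in at least
#' `min_cells_per_gene` of the surviving cells. Row and column order is
#' preserved.
#'
#' @param m ExpressionMatrix with `layer = "raw_counts"`.
#' @param min_genes,max_genes detected-gene bounds per cell (default 200 and
#'   7500); cells below/above are removed, the boundary survives.
#' @param max_mito_frac maximum mitochondrial count fraction (default 0.20);
#'   cells strictly above are removed.
#' @param min_cells_per_gene minimum number of cells a gene must be detected
#'   in (default 3).
#' @param mito_prefix gene-id prefix marking mitochondrial genes,
#'   case-insensitive (default `"MT-"`).
#' @return filtered ExpressionMatrix (still `raw_counts`).
#' @export
qc_filter <- function(m, min_genes = 200L, max_genes = 7500L,
                      max_mito_frac = 0.20, min_cells_per_gene = 3L,
                      mito_prefix = "MT-") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "raw_counts") stop("qc_filter requires raw counts")
  v <- m$values
  detected <- Matrix::colSums(v > 0)
  mito <- startsWith(toupper(m$gene_ids), toupper(mito_prefix))
  tot <- Matrix::colSums(v)
  mito_frac <- if (any(mito)) {
    ifelse(tot > 0,
           Matrix::colSums(v[mito, , drop = FALSE]) / pmax(tot, 1), 0)
  } else rep(0, ncol(v))
  keep_obs <- detected >= min_genes & detected <= max_genes &
    mito_frac <= max_mito_frac
  if (!any(keep_obs)) stop("qc_filter removed every observation")
  v <- v[, keep_obs, drop = FALSE]
  keep_genes <- Matrix::rowSums(v > 0) >= min_cells_per_gene
  if (!any(keep_genes)) stop("qc_filter removed every gene")
  expression_matrix(v[keep_genes, , drop = FALSE], layer = "raw_counts")
}

#' Library-size normalization and log transform
#'
#' Scales every observation (column) to `scale_total` total counts, then
#' applies `log1p` — natural log by default, base-2 with `base = 2` for
#' bulk-style TPM conventions.
#'
#' @param m ExpressionMatrix with `layer = "raw_counts"`.
#' @param scale_total target column total (default `1e4`).
#' @param base log base; `exp(1)` (default) or `2`.
#' @return ExpressionMatrix with `layer = "lognorm"`.
#' @export
lognormalize <- function(m, scale_total = 1e4, base = exp(1)) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "raw_counts") stop("lognormalize requires raw counts")
  tot <- Matrix::colSums(m$values)
  if (any(tot <= 0)) {
    stop("observation(s) with zero total counts: ",
         paste(utils::head(m$obs_ids[tot <= 0], 5), collapse = ", "))
  }
  if (inherits(m$values, "sparseMatrix")) {
    v <- m$values %*% Matrix::Diagonal(x = scale_total / tot)
    v@x <- log1p(v@x) / log(base)
    dimnames(v) <- dimnames(m$values)
  } else {
    v <- log1p(sweep(m$values, 2, tot / scale_total, "/")) / log(base)
  }
  expression_matrix(v, gene_ids = m$gene_ids, obs_ids = m$obs_ids,
                    layer = "lognorm")
}
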