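#' One-vs-rest marker detection on log-normalized data
#'
#' For every group in `labels`, each gene detected (expression > 0) in at
#' least `min_pct` of the group or of its complement is tested with a
#' two-sided Wilcoxon rank-sum test (group vs all other observations).
#' Fold change is computed on the un-logged scale as
#' `ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))` (pseudocount 1);
#' base-2 fold changes are available via `logfc_base = 2`. P-values are
#' Benjamini-Hochberg adjusted within each group's tested genes. Only genes
#' with `log_fc >= min_logfc` and `p_adj < 0.05` are reported.
#'
#' The rank-sum p-value uses exact enumeration when both groups have fewer
#' than 20 observations and the combined sample has no ties, and otherwise
#' the normal approximation with tie and continuity correction.
#'
#' @param m ExpressionMatrix, `layer = "lognorm"` (or
#'   `external_normalized` bulk data on a log scale).
#' @param labels character/factor vector of group labels, one per
#'   observation (aligned with `m$obs_ids`), or a metadata data.frame with
#'   columns `obs_id` and the column named by `label_col`.
#' @param min_logfc minimum log fold change reported (default 0.25).
#' @param min_pct minimum detection fraction in group or complement for a
#'   gene to be tested (default 0.25).
#' @param logfc_base base of the reported fold change (default natural log).
#' @param label_col metadata column holding labels when `labels` is a
#'   data.frame (default `"subtype"`).
#' @return data.frame with columns `gene_id`, `group`, `log_fc`, `pct1`,
#'   `pct2`, `p_value`, `p_adj`, ordered by group then ascending p then
#'   descending log fold change.
#' @export
find_markers <- function(m, labels, min_logfc = 0.25, min_pct = 0.25,
                         logfc_base = exp(1), label_col = "subtype") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer == "raw_counts") {
    stop("find_markers expects normalized (log-scale) data")
  }
  if (is.data.frame(labels)) {
    labels <- labels[[label_col]][match(m$obs_ids, labels$obs_id)]
  }
  labels <- as.character(labels)
  if (length(labels) != length(m$obs_ids)) {
    stop("labels length does not match number of observations")
  }
  groups <- sort(unique(labels[!is.na(labels)]))
  if (length(groups) < 2) stop("need at least 2 groups")
  tab <- table(labels)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    stop("group(s) with fewer than 3 observations: ",
         paste(small, collapse = ", "))
  }

  keep <- !is.na(labels)
  x <- as.matrix(m$values[, keep, drop = FALSE])
  labels <- labels[keep]
  n <- ncol(x)
  g_ind <- vapply(groups, function(g) labels == g,
                  logical(n))                     # n x n_groups
  n_in <- colSums(g_ind)

  det <- x > 0
  det_in <- det %*% g_ind                         # genes x groups counts
  det_tot <- rowSums(det)
  pct1 <- sweep(det_in, 2, n_in, "/")
  pct2 <- sweep(-det_in + det_tot, 2, n - n_in, "/")

  e <- expm1(x)
  e_in <- e %*% g_ind
  e_tot <- rowSums(e)
  mean_in <- sweep(e_in, 2, n_in, "/")
  mean_out <- sweep(-e_in + e_tot, 2, n - n_in, "/")
  log_fc <- log((mean_in + 1) / (mean_out + 1)) / log(logfc_base)

  tested <- pmax(pct1, pct2) >= min_pct
  if (!any(tested)) stop("no gene passes the min_pct pre-filter")

  p_value <- matrix(NA_real_, nrow(x), length(groups))
  need <- which(rowSums(tested) > 0)
  for (gi in need) {
    xv <- x[gi, ]
    r <- rank(xv)
    nt <- table(r)
    tie_term <- sum(nt^3 - nt)
    has_ties <- tie_term > 0
    for (k in which(tested[gi, ])) {
      n1 <- n_in[[k]]
      p_value[gi, k] <- ranksum_p(sum(r[g_ind[, k]]), n1, n - n1,
                                  tie_term, has_ties)
    }
  }

  out <- do.call(rbind, lapply(seq_along(groups), function(k) {
    idx <- which(tested[, k])
    if (length(idx) == 0) return(NULL)
    data.frame(gene_id = rownames(x)[idx], group = groups[[k]],
               log_fc = log_fc[idx, k], pct1 = pct1[idx, k],
               pct2 = pct2[idx, k], p_value = p_value[idx, k],
               p_adj = stats::p.adjust(p_value[idx, k], method = "BH"),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$log_fc >= min_logfc & out$p_adj < 0.05, , drop = FALSE]
  out <- out[order(out$group, out$p_value, -out$log_fc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Two-sided rank-sum p from the group-1 rank sum. Exact Wilcoxon
# distribution when both groups < 20 and no ties; otherwise normal
# approximation with tie and continuity correction.
ranksum_p <- function(rank_sum, n1, n2, tie_term = 0, has_ties = FALSE) {
  w <- rank_sum - n1 * (n1 + 1) / 2               # Mann-Whitney U
  if (!has_ties && n1 < 20 && n2 < 20) {
    p <- if (w > n1 * n2 / 2) {
      stats::pwilcox(w - 1, n1, n2, lower.tail = FALSE)
    } else {
      stats::pwilcox(w, n1, n2)
    }
    return(min(2 * p, 1))
  }
  ntot <- n1 + n2
  z <- w - n1 * n2 / 2
  sigma <- sqrt((n1 * n2 / 12) *
                ((ntot + 1) - tie_term / (ntot * (ntot - 1))))
  if (sigma == 0) return(1)
  z <- (z - sign(z) * 0.5) / sigma
  2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE), 0.5)
}

#' Select a lineage signature from a marker table
#'
#' Keeps the group's markers whose out-group detection fraction is strictly
#' below `max_pct2`, ordered by descending log fold change.
#'
#' @param markers data.frame from [find_markers()].
#' @param group group whose signature to extract (e.g. `"BS"`).
#' @param max_pct2 strict upper bound on `pct2` (default 0.4).
#' @return [signature_set()] named after the group.
#' @export
select_lineage_signature <- function(markers, group, max_pct2 = 0.4) {
  if (NROW(markers) == 0) stop("empty marker table")
  sel <- markers[markers$group == group & markers$pct2 < max_pct2, ,
                 drop = FALSE]
  if (nrow(sel) == 0) {
    stop("no marker of group '", group, "' has pct2 < ", max_pct2)
  }
  sel <- sel[order(-sel$log_fc), , drop = FALSE]
  signature_set(group, sel$gene_id)
}

#' Stage-progression signature across cohorts
#'
#' Genes commonly upregulated (`log_fc > 0`, `p_adj < 0.05`) in stage II/III
#' versus stage I across every supplied cohort's marker table.
#'
#' @param markers_by_cohort list of marker data.frames (one per cohort),
#'   each a stage II/III-vs-I contrast; for tables carrying both contrast
#'   directions only rows with `group == up_group` are used.
#' @param up_group group label marking the stage II/III side
#'   (default `"II_III"`; ignored when a table has a single group).
#' @param name signature name (default `"progression"`).
#' @return SignatureSet; empty (with a warning) when the intersection is
#'   empty.
#' @export
progression_signature <- function(markers_by_cohort, up_group = "II_III",
                                  name = "progression") {
  if (length(markers_by_cohort) < 1) stop("need at least one cohort")
  up <- lapply(markers_by_cohort, function(mk) {
    if (length(unique(mk$group)) > 1) {
      mk <- mk[mk$group == up_group, , drop = FALSE]
    }
    unique(mk$gene_id[mk$log_fc > 0 & mk$p_adj < 0.05])
  })
  genes <- Reduce(intersect, up)
  if (length(genes) == 0) {
    warning("no gene is commonly upregulated across all cohorts")
    return(structure(list(name = name, genes = character(0),
                          description = ""),
                     class = "SignatureSet"))
  }
  signature_set(name, genes)
}
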