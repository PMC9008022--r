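# Independent reference implementations used as oracles. These deliberately
# take the slow, explicit route (loops, stats::wilcox.test, enumeration)
# and never share code with the package internals they check.

# Brute-force one-vs-rest marker calling; p-values from stats::wilcox.test
# with the same exactness rule the package documents (exact only below 20
# per group without ties).
oracle_markers <- function(x, labels, min_logfc = 0.25, min_pct = 0.25) {
  out <- NULL
  for (g in sort(unique(labels))) {
    rows <- NULL
    for (gi in seq_len(nrow(x))) {
      xin <- x[gi, labels == g]
      xout <- x[gi, labels != g]
      pct1 <- mean(xin > 0)
      pct2 <- mean(xout > 0)
      if (max(pct1, pct2) < min_pct) next
      lfc <- log((mean(expm1(xin)) + 1) / (mean(expm1(xout)) + 1))
      use_exact <- length(xin) < 20 && length(xout) < 20 &&
        !any(duplicated(c(xin, xout)))
      p <- suppressWarnings(
        stats::wilcox.test(xin, xout, exact = use_exact)$p.value)
      rows <- rbind(rows, data.frame(
        gene_id = rownames(x)[gi], group = g, log_fc = lfc,
        pct1 = pct1, pct2 = pct2, p_value = p,
        stringsAsFactors = FALSE))
    }
    if (is.null(rows)) next
    rows$p_adj <- stats::p.adjust(rows$p_value, method = "BH")
    out <- rbind(out, rows)
  }
  out <- out[out$log_fc >= min_logfc & out$p_adj < 0.05, , drop = FALSE]
  out[order(out$group, out$gene_id), , drop = FALSE]
}

# Exact upper-tail hypergeometric by enumerating every overlap value.
oracle_hyper <- function(universe_n, set_a, set_b, overlap) {
  ks <- max(overlap, set_a + set_b - universe_n):min(set_a, set_b)
  sum(choose(set_a, ks) * choose(universe_n - set_a, set_b - ks)) /
    choose(universe_n, set_b)
}

# Textbook log-rank: loop over distinct event times accumulating
# observed/expected/variance for the second group.
oracle_logrank <- function(time, event, high) {
  O <- 0; E <- 0; V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at <- time >= tt
    n <- sum(at); n1 <- sum(at & high)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & high)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(chisq = (O - E)^2 / V, z = (O - E) / sqrt(V))
}

# Small random lognorm matrix (counts -> library-size + log1p by explicit
# arithmetic, independent of lognormalize()).
random_lognorm <- function(n_genes, n_cells, seed, mu = 0.5) {
  set.seed(seed)
  counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu, size = 2),
                   n_genes, n_cells,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("c%03d", seq_len(n_cells))))
  counts[, colSums(counts) == 0] <- 1   # avoid empty cells in tiny fixtures
  norm <- log1p(t(t(counts) / colSums(counts)) * 1e4)
  expression_matrix(norm, layer = "lognorm")
}

rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * sum(!positive))
}
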