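#' Correlation between per-observation scores and signature expression
#'
#' Correlates a score vector (e.g. CCI) with the mean normalized expression
#' of a gene set in the same observations.
#'
#' @param scores named numeric vector (names = observation ids) or plain
#'   vector aligned with `m$obs_ids`.
#' @param m ExpressionMatrix (normalized layer).
#' @param s SignatureSet.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `n`, `method`.
#' @export
score_signature_correlation <- function(scores, m, s,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  expr <- signature_score(m, s)
  if (!is.null(names(scores))) {
    common <- intersect(names(scores), names(expr))
    scores <- scores[common]
    expr <- expr[common]
  }
  if (length(scores) != length(expr)) {
    stop("scores and observations do not align")
  }
  if (length(scores) < 10) stop("need at least 10 observations")
  if (stats::sd(scores) == 0 || stats::sd(expr) == 0) {
    stop("zero-variance input")
  }
  ct <- stats::cor.test(scores, expr, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(scores),
       method = method)
}

#' Two-group comparison
#'
#' Two-sided Wilcoxon rank-sum or unpaired t-test between the two label
#' groups, reported with group medians and means.
#'
#' @param values numeric vector.
#' @param labels two-level vector aligned with `values`.
#' @param test `"wilcoxon_ranksum"` or `"t_test"`.
#' @return list with `statistic`, `p`, `medians`, `means`, `n`.
#' @export
group_compare <- function(values, labels,
                          test = c("wilcoxon_ranksum", "t_test")) {
  test <- match.arg(test)
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("labels must have exactly 2 levels")
  g1 <- values[labels == lv[[1]]]
  g2 <- values[labels == lv[[2]]]
  if (length(g1) < 3 || length(g2) < 3) {
    stop("need at least 3 observations per group")
  }
  if (stats::sd(values) == 0) stop("constant values in both groups")
  ht <- if (test == "wilcoxon_ranksum") {
    stats::wilcox.test(g1, g2, exact = FALSE)
  } else {
    stats::t.test(g1, g2)
  }
  list(statistic = unname(ht$statistic), p = ht$p.value,
       medians = stats::setNames(c(stats::median(g1), stats::median(g2)), lv),
       means = stats::setNames(c(mean(g1), mean(g2)), lv),
       n = stats::setNames(c(length(g1), length(g2)), lv))
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of observing at least `overlap` shared genes when
#' `set_b` genes are drawn without replacement from a universe of
#' `universe_n` genes of which `set_a` are marked.
#'
#' @param universe_n universe size.
#' @param set_a,set_b sizes of the two sets.
#' @param overlap observed overlap.
#' @return p-value, `P(X >= overlap)`.
#' @export
hypergeom_overlap <- function(universe_n, set_a, set_b, overlap) {
  if (overlap > min(set_a, set_b) || set_a > universe_n ||
      set_b > universe_n || overlap < 0 ||
      overlap < set_a + set_b - universe_n) {
    stop("inconsistent overlap counts")
  }
  stats::phyper(overlap - 1, set_a, universe_n - set_a, set_b,
                lower.tail = FALSE)
}

#' Build a survival record table
#'
#' @param subject_id character ids.
#' @param time positive follow-up times (unit carried through verbatim).
#' @param event event indicator (0/1 or logical).
#' @param score continuous score (CCI or expression).
#' @param group optional `"low"`/`"high"` assignment.
#' @return validated data.frame of class `SurvivalRecord`.
#' @export
survival_records <- function(subject_id, time, event, score, group = NULL) {
  event <- as.integer(event)
  if (any(time <= 0)) stop("all times must be positive")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  df <- data.frame(subject_id = as.character(subject_id), time = time,
                   event = event, score = score,
                   stringsAsFactors = FALSE)
  if (!is.null(group)) {
    if (!all(group %in% c("low", "high"))) stop("group must be low/high")
    df$group <- group
  }
  class(df) <- c("SurvivalRecord", "data.frame")
  df
}

#' Maximally selected log-rank cut-point
#'
#' Scans every distinct score between the `qmin` and `qmax` score quantiles
#' as a candidate split, computes the standardized two-group log-rank
#' statistic at each, and returns the cut-point with the largest absolute
#' statistic (ties broken toward the median score). Records with
#' `score > cutpoint` form the high group. The naive log-rank p-value at the
#' selected cut-point is anti-conservative (the split was chosen to maximize
#' it), so it is reported as descriptive only.
#'
#' @param records [survival_records()] table (group column ignored).
#' @param qmin,qmax score-quantile window for candidates (defaults 0.1/0.9).
#' @return list with `cutpoint`, `max_statistic` (standardized, signed so
#'   positive means higher hazard in the high-score group), and the
#'   candidate `scan` table.
#' @export
maxstat_cutpoint <- function(records, qmin = 0.1, qmax = 0.9) {
  if (nrow(records) < 20) stop("need at least 20 records")
  if (sum(records$event) < 5) stop("need at least 5 events")
  qs <- stats::quantile(records$score, c(qmin, qmax), names = FALSE)
  cand <- sort(unique(records$score))
  cand <- cand[cand >= qs[[1]] & cand <= qs[[2]]]
  # a candidate equal to the max score puts everyone in the low group
  cand <- cand[cand < max(records$score)]
  if (length(cand) == 0) stop("no candidate cut-point inside the window")
  z <- vapply(cand, function(ct) logrank_z(records, ct), 0)
  ok <- is.finite(z)
  if (!any(ok)) stop("every candidate split is degenerate (all events on ",
                     "one side)")
  cand <- cand[ok]; z <- z[ok]
  best <- abs(z) == max(abs(z))
  med <- stats::median(records$score)
  pick <- which(best)[which.min(abs(cand[best] - med))]
  list(cutpoint = cand[[pick]], max_statistic = z[[pick]],
       scan = data.frame(cutpoint = cand, statistic = z))
}

# standardized log-rank statistic for the split score > ct, signed so that
# a positive value means more deaths than expected in the high group
logrank_z <- function(records, ct) {
  grp <- records$score > ct
  if (all(grp) || !any(grp)) return(NA_real_)
  sd_ <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ grp, data = records),
    error = function(e) NULL)
  if (is.null(sd_) || any(sd_$var == 0)) return(NA_real_)
  # element [2] is the high (score > ct) group
  (sd_$obs[[2]] - sd_$exp[[2]]) / sqrt(sd_$var[2, 2])
}

#' Dichotomize survival records at a cut-point
#' @param records survival_records table
#' @param cutpoint scores strictly above are `"high"`
#' @return records with the `group` column set
#' @export
assign_survival_groups <- function(records, cutpoint) {
  records$group <- ifelse(records$score > cutpoint, "high", "low")
  records
}

#' Kaplan-Meier medians and log-rank test for a two-group split
#'
#' @param records [survival_records()] with the `group` column set.
#' @param rho `survival::survdiff` rho parameter (0 = log-rank).
#' @return list with `median_low`, `median_high` (`NA` = median not
#'   reached), `chi2`, `p`, `n`, `events`, and the fitted
#'   `survival::survfit` object.
#' @export
km_logrank <- function(records, rho = 0) {
  if (!"group" %in% names(records)) stop("records need a group column")
  if (length(unique(records$group)) < 2) {
    stop("both groups must be non-empty")
  }
  records$group <- factor(records$group, levels = c("low", "high"))
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = records)
  med <- summary(fit)$table[, "median"]
  if (sum(records$event) == 0) {
    # no events at all: log-rank undefined, medians not reached
    return(list(median_low = NA_real_, median_high = NA_real_,
                chi2 = NA_real_, p = NA_real_,
                n = table(records$group), events = 0, fit = fit))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = records, rho = rho)
  chi2 <- sd_$chisq
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(median_low = unname(med[[1]]), median_high = unname(med[[2]]),
       chi2 = chi2, p = p, n = table(records$group),
       events = sum(records$event), fit = fit)
}
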