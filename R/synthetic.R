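#' Specification of a synthetic squamous-epithelium cohort
#'
#' Describes a desk-scale cohort with three transcriptionally distinct pure
#' epithelial populations (BS, BK, DK) occupying the corners of the ternary
#' identity map, plus a "confused" malignant population that co-expresses
#' all three lineage programs at a reduced level and additionally expresses
#' a malignant-only gene program. Counts are negative binomial
#' (variance = mu + mu^2 * dispersion) with a lognormal per-cell library
#' factor and independent Bernoulli dropout.
#'
#' @param n_bs,n_bk,n_dk pure-population sizes (default 200 each).
#' @param n_confused confused (malignant) population size (default 300).
#' @param n_genes total genes (default 2000).
#' @param sig_size planted genes per lineage signature (default 25).
#' @param n_cci_genes malignant-only genes (default 30).
#' @param effect log-scale mean lift of a population's own signature genes
#'   (default 1.5).
#' @param confusion fraction of each lineage effect expressed by confused
#'   cells, in (0, 1] (default 0.6: all three programs on, "at slightly
#'   lower levels").
#' @param confusion_jitter lognormal sd of the per-cell confusion multiplier
#'   (default 0.15); the per-cell draw also drives stage labels.
#' @param cci_effect_scale gain applied to `effect` for the malignant-only
#'   program (default 3), lifting those genes from a near-silent baseline to
#'   strong expression in confused cells only.
#' @param nb_dispersion negative-binomial dispersion (default 0.3, typical
#'   of droplet scRNA-seq).
#' @param dropout independent zeroing probability per entry (default 0.05).
#' @param libsize_sigma sd of the lognormal library-size factor
#'   (default 0.2).
#' @param stage_fraction fraction of confused cells labeled stage II/III
#'   (default 0.5), assigned to the cells with the largest confusion draws.
#' @param base_mean_log,base_mean_sdlog lognormal parameters of baseline
#'   gene means (defaults `log(0.3)` and 1).
#' @param sig_base_range uniform range of signature-gene baseline means
#'   (default `c(0.3, 0.6)`), low enough that out-group detection stays
#'   below the pct.2 < 0.4 selection bound.
#' @param cci_quiet_mean baseline mean of malignant-only genes outside the
#'   confused population (default 0.045, i.e. detected in < 5% of cells).
#' @param seed RNG seed (default 1).
#' @return a `CohortSpec` list.
#' @export
cohort_spec <- function(n_bs = 200L, n_bk = 200L, n_dk = 200L,
                        n_confused = 300L, n_genes = 2000L, sig_size = 25L,
                        n_cci_genes = 30L, effect = 1.5, confusion = 0.6,
                        confusion_jitter = 0.15, cci_effect_scale = 3,
                        nb_dispersion = 0.3, dropout = 0.05,
                        libsize_sigma = 0.2, stage_fraction = 0.5,
                        base_mean_log = log(0.3), base_mean_sdlog = 1,
                        sig_base_range = c(0.3, 0.6),
                        cci_quiet_mean = 0.045, seed = 1L) {
  spec <- as.list(environment())
  sizes <- c(n_bs, n_bk, n_dk, n_confused, n_genes, sig_size, n_cci_genes)
  if (any(sizes < 1)) stop("all sizes must be >= 1")
  if (3 * sig_size + n_cci_genes > n_genes) {
    stop("3 * sig_size + n_cci_genes exceeds n_genes")
  }
  if (effect < 0) stop("effect must be nonnegative")
  if (confusion <= 0 || confusion > 1) stop("confusion must be in (0, 1]")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(spec, class = "CohortSpec")
}

#' Generate a synthetic cohort
#'
#' Deterministic for a fixed spec (the spec's `seed` initializes the RNG).
#' Pure populations get their own signature genes lifted by `exp(effect)`;
#' confused cells get `exp(c_i * effect)` on all three signatures, where
#' `c_i` is the cell's jittered confusion level, plus
#' `exp(cci_effect_scale * effect)` on the malignant-only genes.
#'
#' @param spec a [cohort_spec()].
#' @return list with `matrix` (ExpressionMatrix, raw counts), `meta`
#'   (observation metadata data.frame) and `truth` (planted signatures,
#'   per-cell population, per-cell confusion draws).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  n_cells <- spec$n_bs + spec$n_bk + spec$n_dk + spec$n_confused
  pop <- rep(c("BS", "BK", "DK", "confused"),
             c(spec$n_bs, spec$n_bk, spec$n_dk, spec$n_confused))
  gene_ids <- sprintf("gene%04d", seq_len(spec$n_genes))
  obs_ids <- sprintf("cell%04d", seq_len(n_cells))

  sig_idx <- list(BS = seq_len(spec$sig_size),
                  BK = spec$sig_size + seq_len(spec$sig_size),
                  DK = 2L * spec$sig_size + seq_len(spec$sig_size))
  cci_idx <- 3L * spec$sig_size + seq_len(spec$n_cci_genes)

  base <- stats::rlnorm(spec$n_genes, spec$base_mean_log,
                        spec$base_mean_sdlog)
  base[unlist(sig_idx)] <- stats::runif(3L * spec$sig_size,
                                        spec$sig_base_range[[1]],
                                        spec$sig_base_range[[2]])
  base[cci_idx] <- spec$cci_quiet_mean
  lib <- stats::rlnorm(n_cells, 0, spec$libsize_sigma)

  conf_draw <- pmin(1, spec$confusion *
                      exp(stats::rnorm(spec$n_confused, 0,
                                       spec$confusion_jitter)))

  # per-cell multiplicative lift on each gene block
  lift <- matrix(1, spec$n_genes, n_cells)
  for (lineage in names(sig_idx)) {
    lift[sig_idx[[lineage]], pop == lineage] <- exp(spec$effect)
  }
  conf_cols <- which(pop == "confused")
  lift[unlist(sig_idx), conf_cols] <-
    rep(exp(conf_draw * spec$effect), each = 3L * spec$sig_size)
  lift[cci_idx, conf_cols] <- exp(spec$cci_effect_scale * spec$effect)

  mu <- (base * lift) * rep(lib, each = spec$n_genes)
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = 1 / spec$nb_dispersion),
                   spec$n_genes, n_cells)
  if (spec$dropout > 0) {
    counts[stats::runif(length(counts)) < spec$dropout] <- 0L
  }
  dimnames(counts) <- list(gene_ids, obs_ids)

  stage <- rep(NA_character_, n_cells)
  thr <- stats::quantile(conf_draw, 1 - spec$stage_fraction, names = FALSE)
  stage[conf_cols] <- ifelse(conf_draw >= thr, "II_III", "I")

  meta <- data.frame(
    obs_id = obs_ids, sample_id = "synthetic1",
    group = ifelse(pop == "confused", "malignant_SE", "normal_SE"),
    subtype = ifelse(pop == "confused", NA_character_, pop),
    stage = stage, stringsAsFactors = FALSE)

  truth <- list(
    signatures = list(
      BS = signature_set("BS", gene_ids[sig_idx$BS], "planted"),
      BK = signature_set("BK", gene_ids[sig_idx$BK], "planted"),
      DK = signature_set("DK", gene_ids[sig_idx$DK], "planted"),
      CCI = signature_set("CCI", gene_ids[cci_idx], "planted")),
    population = stats::setNames(pop, obs_ids),
    confusion_draw = stats::setNames(conf_draw, obs_ids[conf_cols]))

  list(matrix = expression_matrix(counts, layer = "raw_counts"),
       meta = validate_metadata(meta), truth = truth)
}

#' Generate synthetic survival records with a planted cut-point
#'
#' Scores are uniform(0, 1); event times are exponential with the baseline
#' rate multiplied by `hazard_ratio` for scores above `cutpoint`; censoring
#' is an independent exponential whose rate is chosen so that roughly
#' `censor_rate` of subjects are censored.
#'
#' @param n number of subjects (>= 10).
#' @param cutpoint planted score threshold (default 0.5).
#' @param hazard_ratio hazard multiplier above the cut-point (default 3).
#' @param censor_rate target censored fraction in [0, 1) (default 0.3).
#' @param baseline_rate event rate below the cut-point (default 0.1).
#' @param seed RNG seed.
#' @return [survival_records()] table with a `truth_high` column.
#' @export
generate_survival <- function(n, cutpoint = 0.5, hazard_ratio = 3,
                              censor_rate = 0.3, baseline_rate = 0.1,
                              seed = 1L) {
  if (n < 10) stop("n must be >= 10")
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  set.seed(seed)
  score <- stats::runif(n)
  high <- score > cutpoint
  rate <- baseline_rate * ifelse(high, hazard_ratio, 1)
  t_event <- stats::rexp(n, rate)
  if (censor_rate > 0) {
    c_rate <- censor_rate / (1 - censor_rate) * mean(rate)
    t_cens <- stats::rexp(n, c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  rec <- survival_records(subject_id = sprintf("subj%04d", seq_len(n)),
                          time = pmin(t_event, t_cens),
                          event = as.integer(t_event <= t_cens),
                          score = score)
  rec$truth_high <- high
  rec
}
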