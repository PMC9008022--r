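# The default synthetic cohort and its processed products are shared across
# test files (generation plus QC/normalization/scoring costs ~10 s; doing it
# once keeps the suite fast). Everything is deterministic for seed 1.

.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.cohort_cache$co)) {
    .cohort_cache$co <- generate_cohort(cohort_spec())
  }
  .cohort_cache$co
}

# QC -> lognorm -> score against the planted signatures -> cut-point
default_cci_run <- function() {
  if (is.null(.cohort_cache$run)) {
    co <- default_cohort()
    m <- lognormalize(qc_filter(co$matrix))
    tab <- cci_table(m, co$truth$signatures[c("BS", "BK", "DK")])
    pop <- co$truth$population[m$obs_ids]
    cut <- cci_cutpoint(tab$cci, transform = "log")
    .cohort_cache$run <- list(m = m, tab = tab, pop = pop,
                              cutpoint = cut$cutpoint,
                              positive = tab$cci > cut$cutpoint)
  }
  .cohort_cache$run
}

small_spec <- function(...) {
  # 1200 genes keeps typical per-cell detection above the 200-gene QC floor
  cohort_spec(n_bs = 60L, n_bk = 60L, n_dk = 60L, n_confused = 90L,
              n_genes = 1200L, sig_size = 15L, n_cci_genes = 15L, ...)
}
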