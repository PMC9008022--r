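#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values that parse as numbers become numeric.
#'
#' @param path config file
#' @return named list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) stop("malformed config line: ", lines[bad][[1]])
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, trimws(vapply(kv, `[[`, "", 1)))
}

pipeline_defaults <- function() {
  list(matrix_format = "mtx_triplet", f = 10, epsilon = 1e-6,
       sd_mode = "sample", min_logfc = 0.25, min_pct = 0.25,
       max_pct2 = 0.4, min_basemean = 0.8, min_pct1 = 0.8,
       scale_total = 1e4, seed = 1, outdir = ".")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full CCI pipeline
#'
#' QC -> log-normalization -> lineage-signature derivation (from the
#' metadata's normal-SE subtype labels, unless a GMT with BS/BK/DK is
#' supplied) -> per-observation scoring and CCI -> cohort cut-point ->
#' CCI signature genes. All tables are written under `outdir` with fixed
#' filenames (`cci_table.tsv`, `markers.tsv`, `signatures.gmt`,
#' `cci_signature.gmt`, `run_summary.json`).
#'
#' @param config named list (see [pipeline_defaults()] for optional keys) or
#'   path to a key=value config file. Required: `matrix` (path) and
#'   `metadata` (path), or pass ready objects via `matrix_obj` / `meta_obj`.
#' @return invisible list with the cci table, signatures, cut-point and
#'   summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(cfg$seed))

  m <- stage("read_matrix", {
    if (!is.null(cfg$matrix_obj)) cfg$matrix_obj
    else {
      if (is.null(cfg$matrix)) stop("config key 'matrix' is required")
      if (!file.exists(cfg$matrix)) stop("matrix path does not exist: ",
                                         cfg$matrix)
      read_matrix(cfg$matrix, cfg$matrix_format)
    }
  })
  meta <- stage("read_metadata", {
    if (!is.null(cfg$meta_obj)) validate_metadata(cfg$meta_obj)
    else {
      if (is.null(cfg$metadata)) stop("config key 'metadata' is required")
      read_metadata(cfg$metadata)
    }
  })

  n0 <- dim(m)
  if (m$layer == "raw_counts") {
    m <- stage("qc_filter", qc_filter(m))
    m <- stage("lognormalize", lognormalize(m, scale_total = cfg$scale_total))
  }
  meta <- meta[match(m$obs_ids, meta$obs_id), , drop = FALSE]

  sigs <- stage("signatures", {
    if (!is.null(cfg$gmt)) {
      read_gmt(cfg$gmt)
    } else {
      normal <- meta$group == "normal_SE" & !is.na(meta$subtype)
      mk <- find_markers(em_subset(m, obs = which(normal)),
                         meta$subtype[normal],
                         min_logfc = cfg$min_logfc, min_pct = cfg$min_pct)
      utils::write.table(mk, file.path(cfg$outdir, "markers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      s <- lapply(c("BS", "BK", "DK"), function(g) {
        select_lineage_signature(mk, g, max_pct2 = cfg$max_pct2)
      })
      names(s) <- c("BS", "BK", "DK")
      s
    }
  })
  write_gmt(sigs, file.path(cfg$outdir, "signatures.gmt"))

  tab <- stage("cci_score", cci_table(m, sigs, f = cfg$f,
                                      epsilon = cfg$epsilon,
                                      sd_mode = cfg$sd_mode))
  cut <- stage("cci_cutpoint",
               cci_cutpoint(tab$cci[!tab$degenerate], transform = "log"))
  tab$positive <- !tab$degenerate & tab$cci > cut$cutpoint
  tab$cutpoint <- cut$cutpoint
  utils::write.table(format(tab, digits = 10),
                     file.path(cfg$outdir, "cci_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cci_sig <- stage("cci_signature_genes", {
    pos <- tab$obs_id[tab$positive]
    bg <- tab$obs_id[!tab$positive & !tab$degenerate]
    if (identical(cfg$background, "malignant_only")) {
      bg <- intersect(bg, meta$obs_id[meta$group == "malignant_SE"])
    }
    cci_signature_genes(m, pos, bg, min_logfc = cfg$min_logfc,
                        min_basemean = cfg$min_basemean,
                        min_pct1 = cfg$min_pct1)
  })
  if (length(cci_sig$genes) > 0) {
    write_gmt(cci_sig, file.path(cfg$outdir, "cci_signature.gmt"))
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("cciscore")),
    seed = cfg$seed,
    parameters = cfg[c("f", "epsilon", "sd_mode", "min_logfc", "min_pct",
                       "max_pct2", "min_basemean", "min_pct1")],
    n_genes_input = n0[[1]], n_obs_input = n0[[2]],
    n_genes_used = dim(m)[[1]], n_obs_used = dim(m)[[2]],
    cutpoint = cut$cutpoint, n_cci_positive = sum(tab$positive),
    n_cci_signature_genes = length(cci_sig$genes))
  jsonlite::write_json(summary, file.path(cfg$outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cci = tab, signatures = sigs, cci_signature = cci_sig,
                 cutpoint = cut$cutpoint, summary = summary))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `pipeline`, `qc`, `signatures`, `score`,
#' `cutpoint`, `cci-genes`, `survival`, `report`. Flags are `--key value`
#' pairs; `pipeline` also accepts `--config file`. Also installed as the
#' executable script `exec/cciscore`.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
cci_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: cciscore <simulate|pipeline|qc|signatures|score|",
            "cutpoint|cci-genes|survival|report> [--key value ...]")
    return(invisible(1L))
  }
  cmd <- args[[1]]
  opts <- parse_flags(args[-1])
  status <- tryCatch({
    switch(cmd,
      simulate = cli_simulate(opts),
      pipeline = {
        cfg <- if (!is.null(opts$config)) {
          utils::modifyList(read_config(opts$config),
                            opts[names(opts) != "config"])
        } else opts
        run_pipeline(cfg)
        0L
      },
      qc = {
        m <- read_matrix(req(opts, "matrix"),
                         opts$matrix_format %||% "mtx_triplet")
        m <- qc_filter(m)
        write_matrix(m, req(opts, "outdir"))
        0L
      },
      signatures = ,
      score = ,
      cutpoint = ,
      `cci-genes` = {
        run_pipeline(opts)   # stages share the pipeline implementation
        0L
      },
      survival = cli_survival(opts),
      report = {
        f <- file.path(req(opts, "outdir"), "run_summary.json")
        if (!file.exists(f)) stop("no run_summary.json under outdir")
        cat(readLines(f), sep = "\n")
        0L
      },
      { message("unknown subcommand: ", cmd); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
req <- function(opts, key) {
  if (is.null(opts[[key]])) stop("missing required flag --", key)
  opts[[key]]
}

parse_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[[i]], "--")) stop("expected --flag, got ", args[[i]])
    key <- gsub("-", "_", substring(args[[i]], 3))
    if (i == length(args) || startsWith(args[[i + 1]], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      v <- args[[i + 1]]
      num <- suppressWarnings(as.numeric(v))
      opts[[key]] <- if (!is.na(num)) num else v
      i <- i + 2
    }
  }
  opts
}

cli_simulate <- function(opts) {
  outdir <- req(opts, "outdir")
  spec_args <- opts[names(opts) %in% names(formals(cohort_spec))]
  spec <- do.call(cohort_spec, spec_args)
  co <- generate_cohort(spec)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(co$matrix, file.path(outdir, "matrix"))
  utils::write.table(co$meta, file.path(outdir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  write_gmt(co$truth$signatures, file.path(outdir, "truth_signatures.gmt"))
  message("wrote synthetic cohort (", dim(co$matrix)[[1]], " genes x ",
          dim(co$matrix)[[2]], " cells) under ", outdir)
  0L
}

cli_survival <- function(opts) {
  tab <- utils::read.table(req(opts, "input"), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  rec <- survival_records(tab$subject_id, tab$time, tab$event, tab$score)
  ms <- maxstat_cutpoint(rec, qmin = opts$qmin %||% 0.1,
                         qmax = opts$qmax %||% 0.9)
  rec <- assign_survival_groups(rec, ms$cutpoint)
  km <- km_logrank(rec)
  out <- list(cutpoint = ms$cutpoint, max_statistic = ms$max_statistic,
              median_low = km$median_low, median_high = km$median_high,
              logrank_chi2 = km$chi2, logrank_p_post_selection = km$p)
  jsonlite::write_json(out, file.path(req(opts, "outdir"), "survival.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  0L
}
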