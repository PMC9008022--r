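#' Expression matrix container
#'
#' A thin S3 wrapper around a genes x observations matrix (dense base matrix
#' or a \pkg{Matrix} sparse matrix) carrying unique gene and observation
#' identifiers and a normalization-state flag.
#'
#' @param values numeric matrix (genes in rows, observations in columns);
#'   dense or sparse. Row and column names, if present, are used as
#'   identifiers unless `gene_ids` / `obs_ids` are given.
#' @param gene_ids character vector of unique gene identifiers.
#' @param obs_ids character vector of unique observation (cell/sample)
#'   identifiers.
#' @param layer one of `"raw_counts"`, `"lognorm"`,
#'   `"external_normalized"`. Raw counts must be nonnegative.
#' @return an `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              obs_ids = colnames(values),
                              layer = c("raw_counts", "lognorm",
                                        "external_normalized")) {
  layer <- match.arg(layer)
  if (is.null(gene_ids) || is.null(obs_ids)) {
    stop("gene_ids and obs_ids are required (as arguments or dimnames)")
  }
  gene_ids <- as.character(gene_ids)
  obs_ids <- as.character(obs_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(obs_ids)) {
    stop("dimensions of values do not match identifier lengths")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5),
               collapse = ", "))
  }
  if (anyDuplicated(obs_ids)) {
    stop("duplicate observation identifiers: ",
         paste(utils::head(unique(obs_ids[duplicated(obs_ids)]), 5),
               collapse = ", "))
  }
  if (layer == "raw_counts" && em_min(values) < 0) {
    stop("raw_counts layer must be nonnegative")
  }
  rownames(values) <- gene_ids
  colnames(values) <- obs_ids
  structure(list(values = values, gene_ids = gene_ids, obs_ids = obs_ids,
                 layer = layer),
            class = "ExpressionMatrix")
}

em_min <- function(values) {
  if (inherits(values, "sparseMatrix")) {
    x <- values@x
    if (length(x) == 0) 0 else min(0, min(x))
  } else {
    if (length(values) == 0) 0 else min(values)
  }
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d observations [%s]\n",
              length(x$gene_ids), length(x$obs_ids), x$layer))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by gene and/or observation ids or indices
#' @param x ExpressionMatrix
#' @param genes,obs index vectors (logical, integer or character ids)
#' @return ExpressionMatrix with the same layer
#' @export
em_subset <- function(x, genes = NULL, obs = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(obs)) v <- v[, obs, drop = FALSE]
  expression_matrix(v, layer = x$layer)
}

#' Read an expression matrix from disk
#'
#' Supports the 10x-style MatrixMarket triplet layout (`matrix.mtx` plus
#' `features.tsv` and `barcodes.tsv` companions, plain or gzipped) and dense
#' delimited tables with a header row of observation ids and gene ids in the
#' first column.
#'
#' @param path for `mtx_triplet`, either the `.mtx` file or the directory
#'   containing `matrix.mtx[.gz]`; for `dense_table`, the table file.
#' @param format `"mtx_triplet"` or `"dense_table"`.
#' @param layer normalization state of the data; defaults to `raw_counts`
#'   for triplet input and `external_normalized` for dense tables.
#' @param sep field separator for dense tables (guessed from the extension
#'   when `NULL`: `","` for `.csv`, tab otherwise).
#' @param genes_in_rows set `FALSE` to transpose a dense table whose rows
#'   are observations.
#' @return an [expression_matrix()] object.
#' @export
read_matrix <- function(path,
                        format = c("mtx_triplet", "dense_table"),
                        layer = NULL, sep = NULL, genes_in_rows = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "mtx_triplet") {
    files <- locate_10x_triplet(path)
    m <- tryCatch(Matrix::readMM(files$matrix),
                  error = function(e) stop("malformed MatrixMarket file: ",
                                           conditionMessage(e)))
    feats <- utils::read.table(files$features, sep = "\t",
                               stringsAsFactors = FALSE, quote = "",
                               comment.char = "")
    bcs <- utils::read.table(files$barcodes, sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
    if (nrow(feats) != nrow(m)) {
      stop("features table has ", nrow(feats), " rows but matrix has ",
           nrow(m), " genes")
    }
    if (nrow(bcs) != ncol(m)) {
      stop("barcodes table has ", nrow(bcs), " rows but matrix has ",
           ncol(m), " observations")
    }
    # 10x features.tsv: column 1 = id, column 2 = symbol; prefer symbol
    gene_ids <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
    if (anyDuplicated(gene_ids) && ncol(feats) >= 2) gene_ids <- feats[[1]]
    expression_matrix(methods::as(m, "CsparseMatrix"),
                      gene_ids = gene_ids, obs_ids = bcs[[1]],
                      layer = if (is.null(layer)) "raw_counts" else layer)
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                             check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids)) {
      stop("duplicate gene identifiers: ",
           paste(utils::head(unique(ids[duplicated(ids)]), 5),
                 collapse = ", "))
    }
    v <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(v) <- "double"
    rownames(v) <- ids
    if (!genes_in_rows) v <- t(v)
    expression_matrix(v,
                      layer = if (is.null(layer)) "external_normalized"
                              else layer)
  }
}

locate_10x_triplet <- function(path) {
  dir <- if (dir.exists(path)) path else dirname(path)
  pick <- function(stem) {
    for (f in file.path(dir, paste0(stem, c(".tsv", ".tsv.gz")))) {
      if (file.exists(f)) return(f)
    }
    stop("missing companion file ", stem, ".tsv[.gz] in ", dir)
  }
  mtx <- if (dir.exists(path)) {
    cand <- file.path(dir, c("matrix.mtx", "matrix.mtx.gz"))
    cand <- cand[file.exists(cand)]
    if (length(cand) == 0) stop("no matrix.mtx[.gz] in ", dir)
    cand[[1]]
  } else path
  list(matrix = mtx, features = pick("features"), barcodes = pick("barcodes"))
}

#' Write an expression matrix
#'
#' `format = "mtx_triplet"` writes `matrix.mtx`, `features.tsv` and
#' `barcodes.tsv` into the directory `path`; `"dense_table"` writes a single
#' TSV with gene ids in the first column.
#'
#' @param m ExpressionMatrix
#' @param path output directory (triplet) or file (dense table)
#' @param format output format
#' @export
write_matrix <- function(m, path,
                         format = c("mtx_triplet", "dense_table")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(m$values, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    utils::write.table(data.frame(id = m$gene_ids, symbol = m$gene_ids),
                       file.path(path, "features.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(bc = m$obs_ids),
                       file.path(path, "barcodes.tsv"),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    tab <- data.frame(gene_id = m$gene_ids,
                      as.matrix(m$values), check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read observation metadata
#'
#' A TSV with header and at least the columns `obs_id` and `group`
#' (`normal_SE`, `malignant_SE` or `other`); optional `sample_id`,
#' `subtype` (`BS`/`BK`/`DK`/`unknown`, only for `normal_SE` rows) and
#' `stage` (`I`/`II_III`).
#'
#' @param path TSV file
#' @return data.frame with one row per observation
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  validate_metadata(md)
}

validate_metadata <- function(md) {
  if (!all(c("obs_id", "group") %in% names(md))) {
    stop("metadata requires columns obs_id and group")
  }
  if (anyDuplicated(md$obs_id)) stop("duplicate obs_id in metadata")
  bad <- setdiff(unique(md$group), c("normal_SE", "malignant_SE", "other"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if ("subtype" %in% names(md)) {
    has_sub <- !is.na(md$subtype) & md$subtype != "" & md$subtype != "unknown"
    if (any(has_sub & md$group != "normal_SE")) {
      stop("subtype may only be set for normal_SE observations")
    }
  }
  md
}
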