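#' Gene-set (signature) constructor
#'
#' @param name signature name (e.g. `"BS"`, `"BK"`, `"DK"`, `"CCI"`).
#' @param genes non-empty character vector of gene ids, no duplicates.
#' @param description free-text description carried into GMT output.
#' @return a `SignatureSet` object.
#' @export
signature_set <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("signature '", name, "' has no genes")
  if (anyDuplicated(genes)) stop("signature '", name, "' has duplicate genes")
  structure(list(name = as.character(name), genes = genes,
                 description = as.character(description)),
            class = "SignatureSet")
}

#' @export
print.SignatureSet <- function(x, ...) {
  cat(sprintf("SignatureSet '%s': %d genes (%s%s)\n", x$name, length(x$genes),
              paste(utils::head(x$genes, 5), collapse = ", "),
              if (length(x$genes) > 5) ", ..." else ""))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file
#' @return named list of [signature_set()] objects
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields (name, description, ",
           ">=1 gene)")
    }
    signature_set(fields[[1]], fields[-(1:2)], fields[[2]])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#' @param sets list of SignatureSet (or a single one)
#' @param path output file
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "SignatureSet")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    desc <- if (nzchar(s$description)) s$description else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Match signature genes against a matrix, case-insensitively
#'
#' Unmatched genes are dropped with a message; fewer than `min_match_frac`
#' of the set matching is an error, since a mostly-missing signature makes
#' scores meaningless.
#'
#' @param m ExpressionMatrix
#' @param s SignatureSet
#' @param min_match_frac minimum matched fraction (default 0.5)
#' @return integer row indices of the matched genes in `m`
#' @export
match_signature <- function(m, s, min_match_frac = 0.5) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(s, "SignatureSet"))
  idx <- match(toupper(s$genes), toupper(m$gene_ids))
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    message("signature '", s$name, "': ", n_missing, "/", length(idx),
            " genes not in matrix, dropped")
  }
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) stop("no gene of signature '", s$name,
                             "' found in the matrix")
  if (length(idx) < min_match_frac * length(s$genes)) {
    stop("fewer than ", round(100 * min_match_frac),
         "% of signature '", s$name, "' matched the matrix")
  }
  idx
}
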