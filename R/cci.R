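#' Signature score per observation
#'
#' The score of observation i is the arithmetic mean of the normalized
#' values of the signature genes present in the matrix (matched
#' case-insensitively; unmatched genes are dropped).
#'
#' @param m ExpressionMatrix (`lognorm` or `external_normalized`).
#' @param s SignatureSet.
#' @param min_match_frac minimum fraction of the set that must match
#'   (default 0.5, see [match_signature()]).
#' @return named numeric vector of scores, one per observation.
#' @export
signature_score <- function(m, s, min_match_frac = 0.5) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer == "raw_counts") {
    stop("signature_score expects normalized data")
  }
  idx <- match_signature(m, s, min_match_frac)
  sc <- Matrix::colMeans(m$values[idx, , drop = FALSE])
  stats::setNames(as.numeric(sc), m$obs_ids)
}

#' Barycentric (ternary) projection of a score triple
#'
#' Negative components are clipped to zero, then each component is divided
#' by the sum. Triples that are all-zero after clipping are degenerate:
#' their coordinates are `NA` and they are flagged for exclusion from maps.
#'
#' @param a,b,c numeric vectors of BS, BK and DK scores (recycled to a
#'   common length).
#' @return data.frame with clipped `a`, `b`, `c`, barycentric `bary_a`,
#'   `bary_b`, `bary_c`, and logical `degenerate`.
#' @export
ternary_project <- function(a, b, c) {
  n <- max(length(a), length(b), length(c))
  a <- pmax(rep_len(as.numeric(a), n), 0)
  b <- pmax(rep_len(as.numeric(b), n), 0)
  c <- pmax(rep_len(as.numeric(c), n), 0)
  s <- a + b + c
  deg <- s <= 0
  s[deg] <- NA_real_
  data.frame(a = a, b = b, c = c,
             bary_a = a / s, bary_b = b / s, bary_c = c / s,
             degenerate = deg)
}

#' Cosine-law CCI score
#'
#' For a nonnegative score triple (a, b, c), the cosine of the angle between
#' each axis and the segment from the origin to the point is
#' `cos_k = coordinate_k / sqrt(a^2 + b^2 + c^2)`. The CCI score is the
#' constant `f` divided by the standard deviation of the three cosines: a
#' point near a corner has widely spread cosines (low CCI) while the
#' centroid direction has three equal cosines (sd 0, CCI capped at
#' `f / epsilon`).
#'
#' @param a,b,c nonnegative score vectors (negatives are clipped to 0, as in
#'   [ternary_project()]).
#' @param f scale constant (default 10); a display convention, not a fitted
#'   parameter.
#' @param epsilon floor on the cosine standard deviation (default `1e-6`),
#'   capping the score for exactly-central observations.
#' @param sd_mode `"sample"` (n-1 denominator over the 3 cosines, default)
#'   or `"population"` (n denominator; scores rescale by sqrt(3/2)).
#' @return data.frame with `cos1`, `cos2`, `cos3`, `sd_cos`, `cci`;
#'   all-zero triples yield `NA` rows.
#' @export
cci_score <- function(a, b, c, f = 10, epsilon = 1e-6,
                      sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  n <- max(length(a), length(b), length(c))
  a <- pmax(rep_len(as.numeric(a), n), 0)
  b <- pmax(rep_len(as.numeric(b), n), 0)
  c <- pmax(rep_len(as.numeric(c), n), 0)
  r <- sqrt(a^2 + b^2 + c^2)
  bad <- r <= 0
  if (all(bad) && n > 0) stop("all score triples are zero")
  r[bad] <- NA_real_
  cos1 <- a / r; cos2 <- b / r; cos3 <- c / r
  mu <- (cos1 + cos2 + cos3) / 3
  ss <- (cos1 - mu)^2 + (cos2 - mu)^2 + (cos3 - mu)^2
  sd_cos <- sqrt(ss / if (sd_mode == "sample") 2 else 3)
  cci <- f / pmax(sd_cos, epsilon)
  data.frame(cos1 = cos1, cos2 = cos2, cos3 = cos3,
             sd_cos = sd_cos, cci = cci)
}

#' Full per-observation CCI table
#'
#' Scores a matrix against the ordered (BS, BK, DK) signature triple and
#' combines [ternary_project()] and [cci_score()] into the standard
#' per-observation table. The axis order is fixed: a = BS, b = BK, c = DK.
#'
#' @param m ExpressionMatrix (normalized layer).
#' @param signatures list of three SignatureSet objects in (BS, BK, DK)
#'   order, or a named list with names `BS`, `BK`, `DK`.
#' @param f,epsilon,sd_mode passed to [cci_score()].
#' @return data.frame: `obs_id`, `a`, `b`, `c`, `bary_*`, `cos*`, `sd_cos`,
#'   `cci`, `degenerate`.
#' @export
cci_table <- function(m, signatures, f = 10, epsilon = 1e-6,
                      sd_mode = "sample") {
  if (all(c("BS", "BK", "DK") %in% names(signatures))) {
    signatures <- signatures[c("BS", "BK", "DK")]
  }
  if (length(signatures) != 3) stop("need exactly 3 signatures (BS, BK, DK)")
  a <- signature_score(m, signatures[[1]])
  b <- signature_score(m, signatures[[2]])
  c <- signature_score(m, signatures[[3]])
  tp <- ternary_project(a, b, c)
  cs <- cci_score(a, b, c, f = f, epsilon = epsilon, sd_mode = sd_mode)
  cbind(data.frame(obs_id = m$obs_ids, stringsAsFactors = FALSE),
        tp[c("a", "b", "c", "bary_a", "bary_b", "bary_c")], cs,
        degenerate = tp$degenerate)
}

#' CCI positivity cut-point from the score distribution
#'
#' Computes the empirical CDF of the scores on the sorted unique values,
#' fits a two-parameter logistic curve to (score, ECDF) by binomial-family
#' maximum likelihood, and returns the first score at which the ECDF
#' robustly crosses from above the fitted curve to below it. Over the low
#' component of a two-component mixture the empirical mass accumulates
#' faster than the single logistic predicts (ECDF > fitted); the first
#' drop below the fit marks the transition into the inter-component valley,
#' which is the cut. Scores strictly above the cut-point are CCI-positive.
#'
#' Crossings are only trusted where the deviation exceeds a noise band of
#' `max(min_dev, 1.36 / sqrt(n))` on both sides (the `1.36/sqrt(n)` term is
#' the large-sample 95% Kolmogorov-Smirnov band): an ECDF that is itself
#' logistic-shaped wiggles inside the band and yields no robust crossing,
#' which is reported as an error asking the caller to inspect the
#' distribution.
#'
#' `transform = "log"` fits the logistic on the log-score axis and maps the
#' cut-point back; because the CCI score is the reciprocal of a dispersion
#' it is strongly right-skewed, and on the log axis its two components have
#' comparable scale, which is what the logistic-fit construction assumes.
#' The pipeline uses the log axis for CCI scores; the identity axis is the
#' default for generic scores.
#'
#' @param scores numeric vector, at least 50 values with at least 2
#'   distinct (all positive when `transform = "log"`).
#' @param transform fitting axis, `"identity"` (default) or `"log"`.
#' @param min_dev lower floor of the noise band (default `1e-3`), ignoring
#'   boundary artifacts where ECDF and fit both approach 0 or 1.
#' @return list with `cutpoint` (original scale) and a data.frame `curve`
#'   of (`score`, `ecdf`, `fitted`) on the original scale.
#' @export
cci_cutpoint <- function(scores, transform = c("identity", "log"),
                         min_dev = 1e-3) {
  transform <- match.arg(transform)
  scores <- scores[is.finite(scores)]
  if (length(scores) < 50) stop("need at least 50 finite scores")
  if (transform == "log" && any(scores <= 0)) {
    stop("log transform requires positive scores")
  }
  x <- if (transform == "log") log(scores) else scores
  grid <- sort(unique(x))
  if (length(grid) < 2) stop("need at least 2 distinct scores")
  ec <- stats::ecdf(x)(grid)
  # binomial-family ML logistic fit of ECDF on score; quasi avoids the
  # non-integer-response warning, coefficients are identical
  fit <- stats::glm(ec ~ grid, family = stats::quasibinomial())
  fitted <- as.numeric(stats::fitted(fit))
  d <- ec - fitted
  tol <- max(min_dev, 1.36 / sqrt(length(scores)))
  s <- sign(d) * (abs(d) > tol)
  nz <- which(s != 0)
  cut_at <- NA_real_
  if (length(nz) >= 2) {
    run_sign <- s[nz]
    flips <- which(run_sign[-length(nz)] == 1 & run_sign[-1] == -1)
    if (length(flips) > 0) {
      i <- nz[flips[[1]]]; j <- nz[flips[[1]] + 1]
      # linear interpolation of the deviation between the bracketing
      # trusted points
      cut_at <- grid[[i]] + (grid[[j]] - grid[[i]]) * d[[i]] /
        (d[[i]] - d[[j]])
    }
  }
  if (!is.finite(cut_at)) {
    stop("no robust ECDF/logistic crossing found; inspect the score ",
         "distribution (it may be unimodal or logistic-shaped)")
  }
  if (transform == "log") {
    cut_at <- exp(cut_at)
    grid <- exp(grid)
  }
  list(cutpoint = cut_at,
       curve = data.frame(score = grid, ecdf = ec, fitted = fitted))
}

#' CCI signature genes
#'
#' Genes exclusively upregulated in CCI-positive cells relative to the
#' background squamous epithelium: log fold change (same convention as
#' [find_markers()]) strictly above `min_logfc`, mean normalized expression
#' across the union of both cell sets ("base-mean") strictly above
#' `min_basemean`, and detection fraction within CCI-positive cells (pct.1)
#' strictly above `min_pct1`.
#'
#' @param m ExpressionMatrix (`lognorm`).
#' @param cci_positive,background_SE disjoint non-empty character vectors of
#'   observation ids.
#' @param min_logfc fold-change threshold (default 0.25; the looser 0.2
#'   convention can be requested explicitly).
#' @param min_basemean base-mean threshold on the lognorm scale
#'   (default 0.8).
#' @param min_pct1 detection-fraction threshold in the positive set
#'   (default 0.8).
#' @param name name for the returned set (default `"CCI"`).
#' @return SignatureSet ordered by descending log fold change; empty with a
#'   warning when nothing passes.
#' @export
cci_signature_genes <- function(m, cci_positive, background_SE,
                                min_logfc = 0.25, min_basemean = 0.8,
                                min_pct1 = 0.8, name = "CCI") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer == "raw_counts") stop("expects normalized data")
  if (length(cci_positive) == 0 || length(background_SE) == 0) {
    stop("both observation sets must be non-empty")
  }
  if (length(intersect(cci_positive, background_SE)) > 0) {
    stop("cci_positive and background_SE must be disjoint")
  }
  pos <- match(cci_positive, m$obs_ids)
  bg <- match(background_SE, m$obs_ids)
  if (anyNA(pos) || anyNA(bg)) stop("unknown observation id(s)")
  xp <- m$values[, pos, drop = FALSE]
  xb <- m$values[, bg, drop = FALSE]
  mean_in <- Matrix::rowMeans(expm1_values(xp))
  mean_out <- Matrix::rowMeans(expm1_values(xb))
  log_fc <- log((mean_in + 1) / (mean_out + 1))
  base_mean <- (Matrix::rowSums(xp) + Matrix::rowSums(xb)) /
    (length(pos) + length(bg))
  pct1 <- Matrix::rowMeans(xp > 0)
  keep <- log_fc > min_logfc & base_mean > min_basemean & pct1 > min_pct1
  if (!any(keep)) {
    warning("no gene passes the CCI signature thresholds")
    return(structure(list(name = name, genes = character(0),
                          description = ""),
                     class = "SignatureSet"))
  }
  genes <- m$gene_ids[keep][order(-log_fc[keep])]
  signature_set(name, genes)
}

expm1_values <- function(v) {
  if (inherits(v, "sparseMatrix")) {
    v@x <- expm1(v@x)
    v
  } else {
    expm1(v)
  }
}

#' Kernel density of ternary points, for external plotting
#'
#' Embeds barycentric triples in the 2-D ternary plane (corners
#' BS = (0, 0), BK = (1, 0), DK = (1/2, sqrt(3)/2)), estimates a 2-D
#' Gaussian kernel density on a `bins` x `bins` grid, and returns the grid
#' nodes inside the simplex with their barycentric coordinates and density.
#'
#' @param bary matrix or data.frame with at least 10 rows of barycentric
#'   coordinates (columns a, b, c summing to 1); degenerate rows (`NA`)
#'   are dropped.
#' @param bins grid resolution per axis (default 500).
#' @return data.frame: `bary_a`, `bary_b`, `bary_c`, `x`, `y`, `density`.
#' @export
export_ternary_density <- function(bary, bins = 500) {
  bary <- as.matrix(bary[, 1:3, drop = FALSE])
  bary <- bary[stats::complete.cases(bary), , drop = FALSE]
  if (nrow(bary) < 10) stop("need at least 10 non-degenerate points")
  h <- sqrt(3) / 2
  x <- bary[, 2] + 0.5 * bary[, 3]
  y <- h * bary[, 3]
  bw <- c(ternary_bw(x), ternary_bw(y))
  kd <- MASS::kde2d(x, y, h = bw, n = bins, lims = c(0, 1, 0, h))
  gx <- rep(kd$x, times = bins)
  gy <- rep(kd$y, each = bins)
  dens <- as.vector(kd$z)
  bc <- gy / h
  bb <- gx - 0.5 * bc
  ba <- 1 - bb - bc
  eps <- 1e-9
  inside <- ba >= -eps & bb >= -eps & bc >= -eps
  data.frame(bary_a = pmax(ba[inside], 0), bary_b = pmax(bb[inside], 0),
             bary_c = pmax(bc[inside], 0),
             x = gx[inside], y = gy[inside], density = dens[inside])
}

# MASS::bandwidth.nrd collapses for near-constant coordinates; keep a floor
ternary_bw <- function(v) {
  bw <- tryCatch(MASS::bandwidth.nrd(v), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) 0.05 else bw
}
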