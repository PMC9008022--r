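test_that("signature_score is the mean of matched gene values", {
  v <- matrix(c(2, 4, 6, 0, 0, 0), 3, 2,
              dimnames = list(c("gA", "gB", "gC"), c("c1", "c2")))
  m <- expression_matrix(v, layer = "lognorm")
  s <- signature_set("S", c("gA", "gB", "gC"))
  expect_equal(unname(signature_score(m, s)), c(4, 0))
  s1 <- signature_set("one", "gB")
  expect_equal(unname(signature_score(m, s1)), c(4, 0))
  expect_error(suppressMessages(
    signature_score(m, signature_set("none", "nope"))), "no gene")
})

test_that("ternary projection normalizes, clips and flags degeneracy", {
  tp <- ternary_project(c(2, 1, 0, -1), c(1, 1, 0, -2), c(1, 1, 5, -3))
  expect_equal(unlist(tp[1, c("bary_a", "bary_b", "bary_c")]),
               c(bary_a = 0.5, bary_b = 0.25, bary_c = 0.25))
  expect_equal(unlist(tp[2, c("bary_a", "bary_b", "bary_c")]),
               rep(1 / 3, 3), ignore_attr = TRUE)
  expect_equal(unlist(tp[3, c("bary_a", "bary_b", "bary_c")]),
               c(bary_a = 0, bary_b = 0, bary_c = 1))
  expect_true(tp$degenerate[4])
  expect_true(all(is.na(tp[4, c("bary_a", "bary_b", "bary_c")])))
})

test_that("cci_score reproduces hand-computed corner and 3-4-5 cases", {
  corner <- cci_score(1, 0, 0)
  expect_equal(unlist(corner[c("cos1", "cos2", "cos3")]),
               c(cos1 = 1, cos2 = 0, cos3 = 0))
  expect_equal(corner$sd_cos, 0.57735026919, tolerance = 1e-10)
  expect_equal(corner$cci, 17.3205080757, tolerance = 1e-6)

  eq <- cci_score(1, 1, 1)
  expect_equal(unlist(eq[c("cos1", "cos2", "cos3")]),
               rep(1 / sqrt(3), 3), ignore_attr = TRUE)
  expect_equal(eq$sd_cos, 0)
  expect_equal(eq$cci, 10 / 1e-6)   # capped at f / epsilon

  tri <- cci_score(3, 4, 0)
  expect_equal(unlist(tri[c("cos1", "cos2", "cos3")]),
               c(cos1 = 0.6, cos2 = 0.8, cos3 = 0.0))

  # law-of-cosines cross-check: cos(theta1) from the segment geometry
  a <- 3; b <- 4; c <- 0
  hyp <- sqrt(a^2 + b^2 + c^2)
  opp <- sqrt(b^2 + c^2)
  expect_equal(tri$cos1, (a^2 + hyp^2 - opp^2) / (2 * a * hyp))

  expect_error(cci_score(0, 0, 0), "all score triples are zero")
})

test_that("population sd mode rescales scores by sqrt(3/2)", {
  s1 <- cci_score(2, 1, 0.5)
  s2 <- cci_score(2, 1, 0.5, sd_mode = "population")
  expect_equal(s2$cci / s1$cci, sqrt(3 / 2), tolerance = 1e-12)
})

test_that("cci invariances: scale, permutation, normalization, centrality", {
  set.seed(31)
  n <- 2000
  a <- runif(n); b <- runif(n); c <- runif(n)
  base <- cci_score(a, b, c)
  # sum of squared cosines is 1
  expect_true(all(abs(base$cos1^2 + base$cos2^2 + base$cos3^2 - 1) < 1e-9))
  # scale invariance
  for (k in c(1e-3, 0.5, 7, 1e4)) {
    expect_equal(cci_score(k * a, k * b, k * c)$cci, base$cci,
                 tolerance = 1e-9)
  }
  # permutation symmetry
  perm <- cci_score(c, a, b)
  expect_equal(perm$cci, base$cci, tolerance = 1e-12)
  expect_equal(perm$cos2, base$cos1, tolerance = 1e-12)
  # corner-to-centroid monotonicity on a 100-point grid
  t <- seq(0, 1, length.out = 100)
  path <- cci_score(1 - t * 2 / 3, t / 3, t / 3)
  expect_true(all(diff(path$cci) >= -1e-9))
})

test_that("cutpoint finds the valley of a bimodal mixture", {
  set.seed(32)
  scores <- c(rnorm(1000, 15, 3), rnorm(1000, 40, 5))
  cut <- cci_cutpoint(scores)
  expect_gt(cut$cutpoint, qnorm(0.95, 15, 3))
  expect_lt(cut$cutpoint, qnorm(0.05, 40, 5))
  # translation equivariance on the identity axis
  cut2 <- cci_cutpoint(scores + 100)
  expect_equal(cut2$cutpoint, cut$cutpoint + 100, tolerance = 1e-8)
})

test_that("cutpoint errors on logistic-shaped and invalid input", {
  set.seed(33)
  expect_error(cci_cutpoint(rlogis(5000, 30, 4)), "no robust")
  expect_error(cci_cutpoint(rnorm(20)), "at least 50")
  expect_error(cci_cutpoint(rep(c(1, 1), 50)), "distinct")
  expect_error(cci_cutpoint(rnorm(100), transform = "log"), "positive")
})

test_that("log-axis cutpoint agrees with identity axis on mild data and
           handles skewed mixtures", {
  set.seed(34)
  scores <- c(rnorm(1000, 15, 3), rnorm(1000, 40, 5))
  cl <- cci_cutpoint(scores, transform = "log")
  expect_gt(cl$cutpoint, qnorm(0.95, 15, 3))
  expect_lt(cl$cutpoint, qnorm(0.05, 40, 5))
  # reciprocal-dispersion style mixture: log axis splits it, and the
  # cut-point lies between the components
  skew <- c(10 / abs(rnorm(800, 0.45, 0.08)), 10 / abs(rnorm(800, 0.08, 0.03)))
  cs <- cci_cutpoint(skew, transform = "log")
  expect_gt(cs$cutpoint, quantile(10 / abs(rnorm(1e4, 0.45, 0.08)), 0.5))
})

test_that("cci_signature_genes applies strict triple thresholds", {
  set.seed(35)
  n_pos <- 30; n_bg <- 40
  v <- matrix(runif((n_pos + n_bg) * 5, 0.1, 0.4), 5, n_pos + n_bg,
              dimnames = list(paste0("g", 1:5),
                              sprintf("c%02d", 1:(n_pos + n_bg))))
  pos <- colnames(v)[1:n_pos]; bg <- colnames(v)[-(1:n_pos)]
  v["g1", pos] <- 3          # clean positive marker: high, 100% detected
  v["g2", ] <- 5             # uniform everywhere: fails fold change only
  v["g3", pos] <- c(rep(3, 24), rep(0, 6))  # pct1 = 0.8 exactly -> excluded
  v["g4", pos] <- 0.5        # fails base-mean
  m <- expression_matrix(v, layer = "lognorm")
  sig <- cci_signature_genes(m, pos, bg)
  expect_equal(sig$genes, "g1")

  # brute-force triple-threshold filter agrees on random instances
  set.seed(36)
  v2 <- matrix(rexp(20 * 70, 1), 20, 70,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:70)))
  m2 <- expression_matrix(v2, layer = "lognorm")
  pos2 <- colnames(v2)[1:25]; bg2 <- colnames(v2)[26:70]
  got <- suppressWarnings(cci_signature_genes(m2, pos2, bg2))
  want <- character(0)
  for (g in rownames(v2)) {
    xin <- v2[g, pos2]; xout <- v2[g, bg2]
    lfc <- log((mean(expm1(xin)) + 1) / (mean(expm1(xout)) + 1))
    bm <- mean(c(xin, xout))
    if (lfc > 0.25 && bm > 0.8 && mean(xin > 0) > 0.8) want <- c(want, g)
  }
  expect_setequal(got$genes, want)

  expect_error(cci_signature_genes(m, pos, pos), "disjoint")
  expect_error(cci_signature_genes(m, character(0), bg), "non-empty")
})

test_that("ternary density grid is nonnegative, finite and centroid-peaked", {
  pts <- matrix(rep(1 / 3, 3 * 50), ncol = 3) +
    matrix(rnorm(150, 0, 1e-3), ncol = 3)
  pts <- pts / rowSums(pts)
  d <- export_ternary_density(pts, bins = 41)
  expect_true(all(d$density >= 0 & is.finite(d$density)))
  top <- d[which.max(d$density), ]
  expect_equal(unlist(top[c("bary_a", "bary_b", "bary_c")]),
               rep(1 / 3, 3), tolerance = 0.05, ignore_attr = TRUE)
  expect_error(export_ternary_density(pts[1:5, ]), "at least 10")
})

test_that("uniform simplex sample gives a flat interior density", {
  set.seed(37)
  e <- matrix(rexp(3 * 10000), ncol = 3)
  bary <- e / rowSums(e)   # uniform on the simplex
  d <- export_ternary_density(bary, bins = 61)
  interior <- d$bary_a > 0.15 & d$bary_b > 0.15 & d$bary_c > 0.15
  ratio <- max(d$density[interior]) / min(d$density[interior])
  expect_lt(ratio, 3)
})
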