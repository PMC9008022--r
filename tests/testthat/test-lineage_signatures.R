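test_that("perfectly separated and null genes behave as expected", {
  # gene g1: lognorm 2 in every A cell, 0 elsewhere; g2 identical everywhere
  set.seed(21)
  n <- 40
  labels <- rep(c("A", "B"), each = n / 2)
  v <- rbind(g1 = ifelse(labels == "A", 2, 0),
             g2 = rep(1.3, n),
             g3 = runif(n, 0, 2))
  colnames(v) <- sprintf("c%02d", 1:n)
  m <- expression_matrix(v, layer = "lognorm")
  mk <- find_markers(m, labels)
  a <- mk[mk$group == "A" & mk$gene_id == "g1", ]
  expect_equal(nrow(a), 1)
  expect_equal(a$pct1, 1.0)
  expect_equal(a$pct2, 0.0)
  expect_gt(a$log_fc, 0.25)
  expect_false("g2" %in% mk$gene_id)   # identically distributed gene
})

test_that("find_markers equals the brute-force oracle gene for gene", {
  # 30 genes x 3 groups synthetic matrix, including planted shifts
  set.seed(22)
  m <- random_lognorm(30, 60, seed = 22)
  labels <- rep(c("A", "B", "C"), each = 20)
  v <- as.matrix(m$values)
  v[1:5, labels == "A"] <- v[1:5, labels == "A"] + 1.5
  v[6:10, labels == "B"] <- v[6:10, labels == "B"] + 1.5
  m <- expression_matrix(v, layer = "lognorm")
  got <- find_markers(m, labels)
  want <- oracle_markers(v, labels)
  got <- got[order(got$group, got$gene_id), ]
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$group, want$group)
  expect_equal(got$log_fc, want$log_fc, tolerance = 1e-12)
  expect_equal(got$pct1, want$pct1)
  expect_equal(got$pct2, want$pct2)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  expect_equal(got$p_adj, want$p_adj, tolerance = 1e-12)
})

test_that("find_markers matches the oracle on the exact-test path", {
  # tiny groups without ties exercise the exact Wilcoxon branch
  set.seed(23)
  v <- matrix(rnorm(8 * 14, mean = 2), 8, 14,
              dimnames = list(paste0("g", 1:8), paste0("c", 1:14)))
  labels <- rep(c("A", "B"), c(6, 8))
  v[1:2, labels == "A"] <- v[1:2, labels == "A"] + 3
  m <- expression_matrix(abs(v), layer = "lognorm")
  got <- find_markers(m, labels, min_logfc = 0, min_pct = 0)
  want <- oracle_markers(abs(v), labels, min_logfc = 0, min_pct = 0)
  got <- got[order(got$group, got$gene_id), ]
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
})

test_that("find_markers is invariant to observation and gene order", {
  set.seed(24)
  m <- random_lognorm(25, 45, seed = 24)
  labels <- rep(c("A", "B", "C"), each = 15)
  v <- as.matrix(m$values)
  v[1:4, labels == "A"] <- v[1:4, labels == "A"] + 2
  base <- find_markers(expression_matrix(v, layer = "lognorm"), labels)
  po <- sample(ncol(v)); pg <- sample(nrow(v))
  perm <- find_markers(expression_matrix(v[pg, po], layer = "lognorm"),
                       labels[po])
  key <- function(d) d[order(d$group, d$gene_id),
                       c("gene_id", "group", "log_fc", "pct1", "pct2",
                         "p_value")]
  expect_equal(key(perm), key(base), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("duplicating every cell never flips a log_fc sign", {
  set.seed(25)
  m <- random_lognorm(20, 30, seed = 25)
  labels <- rep(c("A", "B"), each = 15)
  v <- as.matrix(m$values)
  v[1:3, labels == "A"] <- v[1:3, labels == "A"] + 1
  mk1 <- find_markers(expression_matrix(v, layer = "lognorm"), labels,
                      min_logfc = -Inf, min_pct = 0)
  mk2 <- find_markers(expression_matrix(cbind(v, v), layer = "lognorm",
                                        obs_ids = sprintf("c%03d", 1:60),
                                        gene_ids = rownames(v)),
                      rep(labels, 2), min_logfc = -Inf, min_pct = 0)
  shared <- merge(mk1, mk2, by = c("gene_id", "group"))
  expect_true(all(sign(shared$log_fc.x) == sign(shared$log_fc.y)))
})

test_that("find_markers validates inputs", {
  m <- random_lognorm(10, 10, seed = 26)
  expect_error(find_markers(m, rep("A", 10)), "at least 2 groups")
  expect_error(find_markers(m, c(rep("A", 8), "B", "B")),
               "fewer than 3")
  expect_error(find_markers(m, rep(c("A", "B"), 5), min_pct = 2),
               "pre-filter")
})

test_that("pct2 selection is strict and ordered by fold change", {
  mk <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   group = "BS",
                   log_fc = c(0.3, 1.2, 0.8, 2.0),
                   pct1 = 1, pct2 = c(0.39, 0.4, 0.0, 0.41),
                   p_value = 1e-6, p_adj = 1e-5,
                   stringsAsFactors = FALSE)
  sig <- select_lineage_signature(mk, "BS")
  expect_equal(sig$genes, c("g3", "g1"))   # 0.4 and 0.41 excluded, desc lfc
  mk$pct2 <- 0
  expect_equal(length(select_lineage_signature(mk, "BS")$genes), 4)
  expect_error(select_lineage_signature(mk, "DK"), "DK")
})

test_that("planted lineage signatures are recovered from the cohort", {
  co <- default_cohort()
  run <- default_cci_run()
  meta <- co$meta[match(run$m$obs_ids, co$meta$obs_id), ]
  normal <- which(meta$group == "normal_SE")
  mk <- find_markers(em_subset(run$m, obs = normal), meta$subtype[normal])
  for (g in c("BS", "BK", "DK")) {
    sig <- select_lineage_signature(mk, g)
    hit <- length(intersect(sig$genes, co$truth$signatures[[g]]$genes))
    expect_gte(hit, 20)   # >= 20 of the 25 planted genes
  }
})

test_that("progression signature is the cross-cohort intersection", {
  mk <- function(genes, lfc = 1) {
    data.frame(gene_id = genes, group = "II_III", log_fc = lfc,
               pct1 = 1, pct2 = 0, p_value = 1e-6, p_adj = 1e-5,
               stringsAsFactors = FALSE)
  }
  two <- progression_signature(list(mk(c("X", "Y", "Z")), mk(c("X", "Y"))))
  expect_setequal(two$genes, c("X", "Y"))
  one <- progression_signature(list(mk(c("A", "B"))))
  expect_setequal(one$genes, c("A", "B"))
  expect_warning(none <- progression_signature(list(mk("A"), mk("B"))),
                 "commonly upregulated")
  expect_length(none$genes, 0)
  # downregulated genes never enter
  down <- progression_signature(list(mk(c("U", "D")), mk(c("U", "D"), lfc = c(1, -1))))
  expect_equal(down$genes, "U")
})
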