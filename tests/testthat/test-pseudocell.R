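test_that("pseudo-cells of size one are the original cells", {
  X <- matrix(rpois(50, 5), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
  pc <- make_pseudocells(X, rep("A", 10), k = 1, seed = 1)
  expect_equal(ncol(pc$profiles), 10)
  reordered <- pc$profiles[, order(unlist(pc$members))]
  expect_equal(unname(reordered), unname(X[, order(colnames(X))]))
})

test_that("identical cells average to the common profile", {
  X <- matrix(rep(c(1, 2, 3, 4, 5), 40), 5, 40,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:40)))
  pc <- make_pseudocells(X, rep("A", 40), k = 20, seed = 2)
  expect_equal(ncol(pc$profiles), 2)
  expect_equal(unname(pc$profiles[, 1]), c(1, 2, 3, 4, 5))
  expect_equal(unname(pc$profiles[, 2]), c(1, 2, 3, 4, 5))
})

test_that("pseudo-cell averaging conserves the grand mean", {
  set.seed(6)
  X <- matrix(rpois(20 * 53, 4), 20, 53,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:53)))
  labels <- rep(c("A", "B"), c(33, 20))
  pc <- make_pseudocells(X, labels, k = 10, seed = 3)
  used <- unlist(pc$members)
  grand_pc <- as.numeric(pc$profiles %*% pc$size / sum(pc$size))
  grand_cells <- rowMeans(X[, used])
  expect_equal(grand_pc, unname(grand_cells), tolerance = 1e-12)
  # remainder handling: 33 cells at k=10 -> 3 groups of 10, remainder 3 < k/2
  expect_equal(sum(pc$cluster == "A"), 3)
  # 20 cells -> 2 groups
  expect_equal(sum(pc$cluster == "B"), 2)
})

test_that("top-detected mode picks the deepest cells first", {
  X <- matrix(0, 4, 10, dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  ng <- 1:10
  X[1, ] <- ng  # marker of depth
  pc <- make_pseudocells(X, rep("A", 10), k = 5, mode = "top_detected",
                         n_gene = ng, seed = 1)
  # first pseudo-cell = cells with most genes detected (c10..c6)
  expect_setequal(pc$members[[1]], paste0("c", 10:6))
  # 10 cells at k = 16: remainder group of 10 >= k/2 is kept
  small <- make_pseudocells(X, rep("A", 10), k = 16, seed = 1)
  expect_equal(ncol(small$profiles), 1)
  # 10 cells at k = 25: below k/2, skipped entirely
  expect_error(suppressWarnings(make_pseudocells(X, rep("A", 10), k = 25,
                                                 seed = 1)),
               "no pseudo-cells")
})

test_that("correlation network applies a strict threshold", {
  p <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  et <- corr_network(p, r_threshold = 0.65)
  expect_equal(nrow(et), 1)
  expect_equal(et$weight, 1)
  # r exactly at the threshold is excluded (strict ">")
  p2 <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 5, 4))
  r_ab <- cor(p2)["a", "b"]
  expect_equal(nrow(corr_network(p2, r_threshold = r_ab)), 0)
  # zero-variance profile dropped with warning
  expect_warning(corr_network(cbind(p, d = rep(1, 4)), 0.5), "zero-variance")
})

test_that("independent random profiles stay below the edge threshold", {
  set.seed(8)
  p <- matrix(rnorm(500 * 10), 500, 10,
              dimnames = list(NULL, paste0("p", 1:10)))
  et <- corr_network(p, r_threshold = 0.65)
  expect_equal(nrow(et), 0)
})

test_that("reference mapping is exact for reference profiles and flags
           orthogonal queries", {
  atl <- simulate_reference_atlas(n_types = 3, markers_per_type = 8,
                                  n_genes = 200, seed = 13)
  ref <- build_reference(atl$counts, top_k = 8)
  # a query equal to a reference profile maps to it with r = 1
  q <- ref$profiles[, "type01", drop = FALSE]
  rownames(q) <- rownames(ref$profiles)
  colnames(q) <- "q1"
  mp <- map_cells(q, ref)
  expect_equal(mp$best_type, "type01")
  expect_equal(mp$max_r, 1, tolerance = 1e-12)
  # simulated cells map back to their true types accurately
  expr <- normalize_cpm1e5(atl$counts, log1p = TRUE)
  mp2 <- map_cells(expr, ref)
  expect_gte(mean(mp2$best_type == atl$counts$cell_meta$type), 0.95)
  # shuffled profile fails to match
  set.seed(1)
  qshuf <- matrix(sample(q), ncol = 1,
                  dimnames = list(rownames(q), "shuffled"))
  mp3 <- map_cells(qshuf, ref, unmatched_threshold = 0.6)
  expect_true(mp3$unmatched)
  expect_error(map_cells(q[1:3, , drop = FALSE], ref), "fewer than 5")
})

test_that("AUROC linkage agrees with exact pairwise enumeration", {
  set.seed(17)
  genes <- sprintf("g%02d", 1:30)
  # batch A: two types with distinct signatures; batch B: small type sets
  base <- matrix(rnorm(30 * 24, 5), 30, 24, dimnames = list(genes, NULL))
  typeA <- rep(c("t1", "t2"), each = 6)
  typeB <- rep(c("t1", "t2"), each = 6)
  base[1:10, c(typeA == "t1", typeB == "t1")] <-
    base[1:10, c(typeA == "t1", typeB == "t1")] + 4
  batch <- rep(c("A", "B"), each = 12)
  labels <- c(typeA, typeB)
  colnames(base) <- sprintf("c%02d", 1:24)
  res <- cluster_auroc(base, batch, labels, genes, threshold = 0.7)
  # oracle: recompute each entry by brute-force pair counting
  cc <- cor(base[, batch == "B"], base[, batch == "A"])
  for (ta in rownames(res$auroc)) {
    score <- rowMeans(cc[, typeA == ta])
    for (tb in colnames(res$auroc)) {
      expect_equal(res$auroc[ta, tb], auroc_enum(score, typeB == tb),
                   tolerance = 1e-12)
    }
  }
  # matched types link, crossed types do not
  expect_equal(res$auroc["t1", "t1"], 1)
  expect_lt(res$auroc["t1", "t2"], 0.7)
  # shuffled labels give chance-level AUROC
  set.seed(3)
  resn <- cluster_auroc(base, batch, sample(labels), genes)
  expect_lt(abs(mean(resn$auroc) - 0.5), 0.25)
})

test_that("specificity screen removes reference markers and keeps order", {
  mk <- data.frame(gene = c("amlA", "sharedB", "amlC", "sharedD"),
                   score = c(9, 8, 7, 6), stringsAsFactors = FALSE)
  refs <- list(t1 = c("sharedB", "x1"), t2 = c("sharedD", "x2"))
  out <- specificity_screen(mk, refs)
  expect_equal(out$gene, c("amlA", "amlC"))
  expect_warning(specificity_screen(mk[2, ], refs), "no markers")
})

test_that("gene correlation network ranks a duplicated gene first", {
  set.seed(23)
  P <- matrix(rpois(30 * 40, 5), 30, 40)
  rownames(P) <- sprintf("g%02d", 1:30)
  P <- rbind(P, twin = P["g01", ])
  et <- gene_corr_network(P, "g01", top_m = 3)
  expect_true("twin" %in% c(et$node_a, et$node_b))
  w_twin <- et$weight[et$node_a == "g01" & et$node_b == "twin" |
                        et$node_b == "g01" & et$node_a == "twin"]
  expect_equal(w_twin, 1)
  expect_warning(gene_corr_network(P, "absent", top_m = 3), "skipped")
})

test_that("correlation is symmetric and affine-invariant", {
  set.seed(29)
  for (i in 1:5) {
    a <- rnorm(50); b <- rnorm(50)
    expect_equal(cor(a, b), cor(b, a))
    expect_equal(cor(2 * a + 3, b), cor(a, b), tolerance = 1e-12)
  }
})
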