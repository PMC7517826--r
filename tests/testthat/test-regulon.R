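test_that("mutual information is symmetric and maximal for copies", {
  set.seed(61)
  for (i in 1:5) {
    x <- rnorm(60); y <- rnorm(60)
    expect_equal(mutual_information(x, y), mutual_information(y, x),
                 tolerance = 1e-12)
  }
  x <- rnorm(100)
  expect_gt(mutual_information(x, x), mutual_information(x, rnorm(100)) + 0.5)
})

test_that("a copied TF target survives DPI with maximal MI", {
  set.seed(67)
  n <- 80
  tf <- rnorm(n)
  X <- rbind(tf1 = tf, copy = tf, noise1 = rnorm(n), noise2 = rnorm(n),
             tf2 = rnorm(n))
  reg <- infer_regulons(X, c("tf1", "tf2"), seed = 1)
  expect_true("copy" %in% reg$tf1$target)
  expect_equal(reg$tf1$weight[reg$tf1$target == "copy"],
               max(reg$tf1$weight))
  expect_equal(reg$tf1$mode[reg$tf1$target == "copy"], 1)
})

test_that("independent noise yields essentially no regulon edges", {
  set.seed(71)
  X <- matrix(rnorm(40 * 100), 40, 100,
              dimnames = list(sprintf("g%02d", 1:40), NULL))
  reg <- infer_regulons(X, c("g01", "g02"), seed = 2)
  n_edges <- sum(vapply(reg, nrow, 0L))
  expect_lte(n_edges, 4)  # ~1% of 76 possible at the 99% null threshold
})

test_that("DPI removes the indirect edge of a planted chain", {
  set.seed(73)
  n <- 200
  tf <- rnorm(n)
  g1 <- tf + rnorm(n, 0, 0.3)   # direct target (also a TF)
  g2 <- g1 + rnorm(n, 0, 0.3)   # downstream of g1 only
  X <- rbind(tf = tf, g1 = g1, g2 = g2)
  reg <- infer_regulons(X, c("tf", "g1"), mi_threshold = 0.05, seed = 3)
  expect_true("g1" %in% reg$tf$target)
  expect_true("g2" %in% reg$g1$target)
  expect_false("g2" %in% reg$tf$target)
})

test_that("DPI agrees with brute-force triangle pruning on random networks", {
  set.seed(79)
  for (rep in 1:3) {
    n_genes <- 20; n <- 60
    X <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(sprintf("g%02d", 1:n_genes), NULL))
    # add some real structure so edges exist
    X[2, ] <- X[1, ] + rnorm(n, 0, 0.5)
    X[3, ] <- X[2, ] + rnorm(n, 0, 0.5)
    X[12, ] <- X[11, ] + rnorm(n, 0, 0.4)
    tfs <- c("g01", "g02", "g11")
    thr <- 0.15
    reg <- infer_regulons(X, tfs, mi_threshold = thr, dpi_epsilon = 0,
                          seed = rep)
    # oracle: full symmetric MI matrix, threshold, then the triangle rule
    MI <- matrix(0, n_genes, n_genes, dimnames = list(rownames(X), rownames(X)))
    for (i in 1:(n_genes - 1)) for (j in (i + 1):n_genes) {
      MI[i, j] <- MI[j, i] <- mutual_information(X[i, ], X[j, ])
    }
    adj <- MI >= thr
    edge_in_graph <- function(a, b)
      adj[a, b] && (a %in% tfs || b %in% tfs)
    drop <- matrix(FALSE, n_genes, n_genes, dimnames = dimnames(MI))
    nodes <- rownames(X)
    for (a in nodes) for (b in nodes) for (g in nodes) {
      if (a >= b || g == a || g == b) next
      if (!(edge_in_graph(a, b) && edge_in_graph(a, g) && edge_in_graph(b, g)))
        next
      e <- c(MI[a, b], MI[a, g], MI[b, g])
      w <- which.min(e)
      if (e[w] < min(e[-w])) {
        if (w == 1) drop[a, b] <- drop[b, a] <- TRUE
        if (w == 2) drop[a, g] <- drop[g, a] <- TRUE
        if (w == 3) drop[b, g] <- drop[g, b] <- TRUE
      }
    }
    for (tf in tfs) {
      expected <- nodes[adj[tf, ] & !drop[tf, ] & nodes != tf]
      # restrict to candidate targets with defined variance
      expect_setequal(reg[[tf]]$target, expected)
    }
    # the strongest edge of any triangle is never removed
    for (tf in tfs) {
      if (nrow(reg[[tf]])) {
        strongest <- nodes[which.max(MI[tf, ] * adj[tf, ])]
        if (adj[tf, strongest]) expect_true(strongest %in% reg[[tf]]$target ||
                                              !edge_in_graph(tf, strongest))
      }
    }
  }
})

test_that("NES reduces to the z-score for a single unit-weight target", {
  reg <- list(tfX = data.frame(target = "gA", mi = 1, mode = 1, weight = 1))
  enr <- nes_enrichment(c(gA = 2.0), reg, min_targets = 1)
  expect_equal(enr$nes, 2.0)
  expect_equal(enr$p, 2 * pnorm(-2))
  # flipping all modes negates NES, p unchanged
  reg2 <- list(tfX = data.frame(target = letters[1:5], mi = 1,
                                mode = -1, weight = 1))
  reg1 <- list(tfX = data.frame(target = letters[1:5], mi = 1,
                                mode = 1, weight = 1))
  sig <- setNames(c(1, 2, -1, 0.5, 3), letters[1:5])
  e1 <- nes_enrichment(sig, reg1)
  e2 <- nes_enrichment(sig, reg2)
  expect_equal(e2$nes, -e1$nes)
  expect_equal(e2$p, e1$p)
  # too few usable targets: skipped with warning
  expect_warning(out <- nes_enrichment(c(gA = 1), reg2), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("NES is standard normal under a random signature", {
  set.seed(83)
  n_tf <- 400
  regs <- lapply(seq_len(n_tf), function(i)
    data.frame(target = sample(sprintf("g%03d", 1:500), 20),
               mi = 1, mode = sample(c(-1, 1), 20, replace = TRUE),
               weight = runif(20)))
  names(regs) <- paste0("tf", seq_len(n_tf))
  sig <- setNames(rnorm(500), sprintf("g%03d", 1:500))
  enr <- nes_enrichment(sig, regs)
  expect_gt(ks.test(enr$nes, "pnorm")$p.value, 0.01)
})

test_that("regulon pruning applies the FDR removal rule and is idempotent", {
  reg <- data.frame(target = c("a", "b", "c"), mi = 1, mode = 1,
                    weight = c(0.2, 0.5, 1))
  de <- data.frame(gene = c("a", "b", "c"), fdr = c(0.04, 0.06, 0.05))
  pr <- prune_regulon(reg, de)
  expect_setequal(pr$target, c("a", "c"))  # 0.06 removed (> 0.05), 0.05 kept
  expect_identical(prune_regulon(pr, de), pr)
  expect_warning(empty <- prune_regulon(reg, data.frame(gene = "z", fdr = 1)),
                 "empty")
  expect_equal(nrow(empty), 0)
})

test_that("Wilcoxon selection p matches rank-permutation enumeration", {
  # borderline case: {4,4,4} vs {1,1,1} -> p = 1/C(6,3) = 0.05, not < 0.05
  p <- wilcoxon_greater_p(c(4, 4, 4), c(1, 1, 1))
  expect_equal(p, 0.05)
  set.seed(89)
  for (i in 1:10) {
    x <- sample(1:5, sample(3:6, 1), replace = TRUE)
    y <- sample(1:5, sample(3:6, 1), replace = TRUE)
    # oracle: enumerate all assignments of the pooled mid-ranks
    r <- rank(c(x, y)); n1 <- length(x)
    W <- sum(r[seq_len(n1)])
    all_w <- combn(length(r), n1, function(ix) sum(r[ix]))
    expect_equal(wilcoxon_greater_p(x, y), mean(all_w >= W))
  }
})

test_that("attractor TF selection keeps planted regulators", {
  set.seed(97)
  n <- 120
  genes <- sprintf("g%03d", 1:60)
  de <- data.frame(gene = genes,
                   log2fc = c(rep(2, 20), rep(0.2, 40)),
                   fdr = c(rep(1e-6, 20), rep(0.04, 40)))
  regs <- list(
    good = data.frame(target = genes[1:10], mi = 1, mode = 1, weight = 1),
    weak = data.frame(target = genes[41:50], mi = 1, mode = 1, weight = 1))
  enr <- data.frame(tf = c("good", "weak"), n_targets = 10,
                    nes = c(3, 2.5), p = 0.001, fdr = c(0.001, 0.001))
  sel <- select_attractor_tfs(regs, de, enr)
  expect_true(sel$selected[sel$tf == "good"])
  expect_false(sel$selected[sel$tf == "weak"])
  # gene score arithmetic: |log2FC| = 2, FDR = 0.01 -> 2 * 2 = 4
  sc <- abs(2) * -log10(0.01)
  expect_equal(sc, 4)
  # under-powered TFs are flagged unselectable
  regs$tiny <- data.frame(target = genes[1], mi = 1, mode = 1, weight = 1)
  enr2 <- rbind(enr, data.frame(tf = "tiny", n_targets = 1, nes = 2,
                                p = 0.001, fdr = 0.001))
  sel2 <- select_attractor_tfs(regs, de, enr2)
  expect_false(sel2$selected[sel2$tf == "tiny"])
  expect_true(is.na(sel2$wilcoxon_p[sel2$tf == "tiny"]))
})

test_that("attractor network applies the strict r > 0.3 rule", {
  set.seed(101)
  n <- 50
  a <- rnorm(n); b <- a + rnorm(n, 0, 0.4); c_ <- rnorm(n)
  X <- rbind(tfA = a, tfB = b, tfC = c_)
  et <- attractor_network(X, c("tfA", "tfB", "tfC"), r_threshold = 0.3)
  pair <- paste(et$node_a, et$node_b)
  expect_true("tfA tfB" %in% pair)
  expect_false("tfA tfC" %in% pair)
  # exactly at the threshold: excluded
  p2 <- cbind(x = c(1, 2, 3, 4, 5), y = c(1, 2, 3, 5, 4))
  r_xy <- cor(p2)["x", "y"]
  et2 <- attractor_network(t(p2), c("x", "y"), r_threshold = r_xy)
  expect_equal(nrow(et2), 0)
  expect_warning(attractor_network(X, "tfA"), "fewer than 2")
})

test_that("planted active TFs are recovered end to end", {
  set.seed(103)
  n_pc <- 100
  genes <- sprintf("g%03d", 1:80)
  tfs <- paste0("tf", 1:6)
  active <- tfs[1:3]
  X <- matrix(rnorm(length(c(genes, tfs)) * n_pc), ncol = n_pc,
              dimnames = list(c(genes, tfs), NULL))
  targets <- split(genes[1:60], rep(tfs, each = 10))
  for (tf in tfs) X[targets[[tf]], ] <-
    X[targets[[tf]], ] + matrix(X[tf, ], 10, n_pc, byrow = TRUE) * 0.9
  # DE signature: targets of active TFs strongly shifted
  de <- data.frame(gene = c(genes, tfs), log2fc = 0.1, fdr = 0.04)
  act_t <- unlist(targets[active])
  de$log2fc[de$gene %in% act_t] <- 2
  de$fdr[de$gene %in% act_t] <- 1e-8
  z <- setNames(sign(de$log2fc) * qnorm(pmax(de$fdr, 1e-15) / 2,
                                        lower.tail = FALSE), de$gene)
  regs <- infer_regulons(X, tfs, seed = 4)
  enr <- nes_enrichment(z, regs)
  pruned <- lapply(regs, prune_regulon, de_table = de)
  sel <- select_attractor_tfs(pruned, de, enr)
  picked <- sel$tf[sel$selected]
  precision <- length(intersect(picked, active)) / max(1, length(picked))
  recall <- length(intersect(picked, active)) / length(active)
  expect_gte(precision, 0.8)
  expect_gte(recall, 0.8)
})
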