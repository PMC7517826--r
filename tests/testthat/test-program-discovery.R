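test_that("per-patient subgroups never span patients", {
  pp <- pp_small()
  meta <- pp$counts$cell_meta
  mal <- meta$lineage == "malignant"
  sub <- subcluster_per_patient(pp$scaled[, mal], meta$patient_id[mal],
                                resolution = 3, seed = 2)
  pat_of_sub <- tapply(meta$patient_id[mal], sub, function(x) length(unique(x)))
  expect_true(all(pat_of_sub == 1))
  expect_true(all(startsWith(names(pat_of_sub), "P0")))
  # homogeneous cells at high resolution: profiles of sizeable subgroups
  # are mutually near-identical
  prof <- subgroup_profiles(pp$expr[pp$hvg, mal], sub)
  big <- prof$patient == "P01" & prof$size >= 15
  if (sum(big) >= 2) {
    cc <- cor(prof$profiles[, big, drop = FALSE])
    expect_gt(min(cc[upper.tri(cc)]), 0.95)
  }
  # determinism
  sub2 <- subcluster_per_patient(pp$scaled[, mal], meta$patient_id[mal],
                                 resolution = 3, seed = 2)
  expect_identical(sub, sub2)
  # undersized patients are excluded with a warning each
  ws <- capture_warnings(
    s3 <- subcluster_per_patient(pp$scaled[, mal], meta$patient_id[mal],
                                 min_cells = 1e5, seed = 1))
  expect_true(all(grepl("excluded", ws)))
  expect_true(all(is.na(s3)))
})

test_that("single-patient and excluded modules are discarded", {
  set.seed(33)
  # two planted programs across 3 patients, plus one patient-private profile
  genes <- 60
  mk_prof <- function(center) center + rnorm(genes, 0, 0.05)
  progA <- rnorm(genes); progB <- rnorm(genes); privC <- rnorm(genes) * 3
  profiles <- cbind(
    sapply(1:3, function(i) mk_prof(progA)),   # P1..P3 program A
    sapply(1:3, function(i) mk_prof(progB)),   # P1..P3 program B
    mk_prof(privC))                            # P3 only
  colnames(profiles) <- c(paste0("P", 1:3, "_s0"), paste0("P", 1:3, "_s1"),
                          "P3_s2")
  prof <- list(profiles = profiles,
               patient = sub("_s[0-9]+$", "", colnames(profiles)),
               size = rep(10L, 7),
               members = setNames(vector("list", 7), colnames(profiles)))
  mods <- ward_modules(prof, k_modules = 3, center_patients = FALSE)
  kept <- mods[mods$kept, ]
  expect_equal(length(unique(kept$module)), 2)
  n_pat <- tapply(kept$patient, kept$module, function(x) length(unique(x)))
  expect_true(all(n_pat == 3))
  expect_true(any(mods$reason == "single-patient"))
  # explicit exclusion overrides keeping
  excl <- unique(kept$module)[1]
  mods2 <- ward_modules(prof, k_modules = 3, exclusion_list = excl,
                        center_patients = FALSE)
  expect_true(all(!mods2$kept[mods2$module == excl]))
  expect_true(all(mods2$reason[mods2$module == excl] == "excluded"))
  expect_error(ward_modules(prof, k_modules = 10), "exceeds")
})

test_that("module signatures rank planted program genes at the top", {
  sim <- sim_small()
  pp <- pp_small()
  meta <- pp$counts$cell_meta
  use <- meta$lineage %in% c("malignant", "HSPC")
  # hand-made module structure: the malignant program vs the HSPC state
  sub <- paste0(meta$patient_id[use], "_", meta$lineage[use])
  names(sub) <- pp$counts$cell_barcodes[use]
  usub <- unique(sub)
  mt <- data.frame(subgroup = usub, patient = sub("_.*$", "", usub),
                   size = as.integer(table(sub)[usub]),
                   module = ifelse(grepl("malignant", usub), "M1", "M2"),
                   reason = "", kept = TRUE, stringsAsFactors = FALSE)
  sig <- module_signatures(pp$expr[, use], mt, sub, n_total = 100)
  prog <- sim$truth$program_sets[[1]]
  expect_gte(length(intersect(sig$signature, prog)), 40)
  # two identical modules give near-identical signatures
  m1 <- head(sig$per_module[["M1"]]$gene, 50)
  # empty module table errors
  expect_error(module_signatures(pp$expr[, use], mt[0, ], sub), "no kept")
  expect_error(module_signatures(pp$expr[, use], mt, sub, n_total = 0),
               "n_total")
})

test_that("signature reclustering beats naive pooled clustering under batch", {
  sim <- memo("sim_batch", function()
    simulate_bmmc(n_patients = 3, cells_per_patient = 300, n_genes = 800,
                  program_size = 60, rp_size = 30, batch_sd = 0.5,
                  n_programs = 2, seed = 19))
  pp <- memo("pp_batch", function()
    preprocess(sim$counts, n_hvg = 500, seed = 4))
  meta <- pp$counts$cell_meta
  mal <- meta$lineage == "malignant"
  truth <- meta$program[mal]
  naive <- cluster_cells(pp$scaled[, mal], resolution = 1, seed = 5)
  disc <- discover_programs(pp$expr, pp$scaled, meta$patient_id, mal,
                            min_cells = 30, seed = 6)
  ari_naive <- adjusted_rand_index(naive, truth)
  ari_disc <- adjusted_rand_index(disc$labels, truth)
  expect_gt(ari_disc, ari_naive)
  expect_gte(ari_disc, 0.8)
  # no kept module is single-patient (assertable post-condition)
  kept <- disc$modules[disc$modules$kept, ]
  n_pat <- tapply(kept$patient, kept$module, function(x) length(unique(x)))
  expect_true(all(n_pat > 1))
})

test_that("gene-set scoring flags the set-high cluster only", {
  X <- matrix(0, 4, 30, dimnames = list(paste0("g", 1:4), NULL))
  labels <- rep(c("A", "B", "C"), each = 10)
  X[c("g1", "g2"), labels == "A"] <- 5
  sc <- score_gene_set(X, labels, c("g1", "g2"))
  expect_true(sc$high[sc$cluster == "A"])
  expect_false(any(sc$high[sc$cluster != "A"]))
  # uniform expression: no flags
  sc2 <- score_gene_set(matrix(1, 4, 30, dimnames = list(paste0("g", 1:4),
                                                         NULL)),
                        labels, c("g1", "g2"))
  expect_false(any(sc2$high))
  expect_warning(score_gene_set(X, labels, c("g1", "nope")), "unknown")
  expect_error(score_gene_set(X, labels, "nope"), "no gene-set genes")
})

test_that("cluster grouping follows arg-max with RP precedence", {
  X <- matrix(0, 8, 30, dimnames = list(paste0("g", 1:8), NULL))
  labels <- rep(c("c0", "c1", "c2"), each = 10)
  sets <- list(rp = c("g1", "g2"), neutrophil = c("g3", "g4"),
               monocyte = c("g5", "g6"), myeloid = c("g7", "g8"))
  # c0 high on neutrophil set; c1 high on rp AND monocyte (rp wins);
  # c2 weakly myeloid
  X[c("g3", "g4"), labels == "c0"] <- 5
  X[c("g1", "g2"), labels == "c1"] <- 4
  X[c("g5", "g6"), labels == "c1"] <- 6
  X[c("g7", "g8"), labels == "c2"] <- 1
  grp <- group_clusters(X, labels, sets)
  expect_equal(grp$group[grp$cluster == "c0"], "neutrophil-like")
  expect_equal(grp$group[grp$cluster == "c1"], "RP-high")
  expect_error(group_clusters(X, labels,
                              list(rp = "g1", neutrophil = "g1",
                                   monocyte = "g5", myeloid = "g7")),
               "disjoint")
})

test_that("planted RP module flags exactly its recluster label", {
  sim <- sim_small()
  pp <- pp_small()
  meta <- pp$counts$cell_meta
  rp <- sim$truth$rp_genes
  # RP genes ride on program 1 cells (all malignant cells here, 1 program)
  sc <- score_gene_set(pp$expr, meta$lineage, rp)
  expect_true(sc$high[sc$cluster == "malignant"])
  expect_false(any(sc$high[sc$cluster != "malignant"]))
})
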