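#' Subcluster malignant cells within each patient
#'
#' The first step of shared-program discovery: each patient's malignant cells
#' are clustered independently at high resolution into many small subgroups,
#' so that no subgroup can span patients and patient-specific batch structure
#' cannot leak into the subgroup definition.
#'
#' @param expr gene x cell scaled matrix (all malignant cells)
#' @param patients per-cell patient ids
#' @param resolution Louvain resolution for the fine subclustering (default 3)
#' @param min_cells patients with fewer malignant cells are excluded
#' @param n_pcs,seed passed to [cluster_cells()]
#' @return character vector of subgroup ids ("P01_s0", ...), named by cell;
#'   NA for cells of excluded patients
#' @export
subcluster_per_patient <- function(expr, patients, resolution = 3,
                                   min_cells = 50, n_pcs = NULL, seed = 1) {
  stopifnot(ncol(expr) == length(patients))
  out <- rep(NA_character_, ncol(expr))
  names(out) <- colnames(expr)
  for (p in unique(patients)) {
    idx <- which(patients == p)
    if (length(idx) < min_cells) {
      aml_warn("patient ", p, " has ", length(idx),
               " malignant cells (< ", min_cells, "); excluded")
      next
    }
    lab <- cluster_cells(expr[, idx, drop = FALSE], n_pcs = n_pcs,
                         resolution = resolution, seed = seed)
    out[idx] <- paste0(p, "_s", lab)
  }
  out
}

#' Average expression profiles of subgroups
#'
#' @param expr gene x cell matrix (log scale)
#' @param subgroups per-cell subgroup ids (NAs skipped)
#' @return list: `profiles` (gene x subgroup matrix of arithmetic means),
#'   `patient` (patient of each subgroup), `size` (member counts),
#'   `members` (list of cell barcodes)
#' @export
subgroup_profiles <- function(expr, subgroups) {
  keep <- !is.na(subgroups)
  ids <- sort(unique(subgroups[keep]))
  X <- as.matrix(expr)
  prof <- vapply(ids, function(s)
    rowMeans(X[, which(subgroups == s), drop = FALSE]), numeric(nrow(X)))
  colnames(prof) <- ids
  members <- lapply(ids, function(s) colnames(expr)[which(subgroups == s)])
  names(members) <- ids
  list(profiles = prof, patient = sub("_s[0-9]+$", "", ids),
       size = vapply(members, length, 0L), members = members)
}

#' Aggregate subgroups into cross-patient modules by Ward clustering
#'
#' Subgroup mean profiles are clustered with Ward linkage on Euclidean
#' distance. Modules contributed by a single patient are flagged discarded
#' (they carry no shared-program evidence), as are modules named in an
#' explicit exclusion list (for analyst-curated removals). When `k_modules`
#' is not given the tree cut is chosen by maximum mean silhouette width over
#' k in [2, 12].
#'
#' @param prof output of [subgroup_profiles()]
#' @param k_modules fixed number of modules, or `NULL` for silhouette choice
#' @param exclusion_list module ids (e.g. "M2") to discard regardless
#' @param center_patients subtract each patient's mean profile before
#'   computing distances (default TRUE): the linear batch-effect elimination
#'   step, without which Ward groups subgroups by patient rather than by
#'   shared program
#' @return data.frame: subgroup, patient, size, module, kept, reason
#' @export
ward_modules <- function(prof, k_modules = NULL, exclusion_list = character(),
                         center_patients = TRUE) {
  P <- prof$profiles
  if (ncol(P) < 2) aml_stop("need at least 2 subgroup profiles")
  if (center_patients) {
    for (p in unique(prof$patient)) {
      j <- prof$patient == p
      P[, j] <- P[, j, drop = FALSE] - rowMeans(P[, j, drop = FALSE])
    }
  }
  d <- dist(t(P))
  hc <- hclust(d, method = "ward.D2")
  if (is.null(k_modules)) {
    ks <- 2:min(12L, ncol(P) - 1L)
    sil <- vapply(ks, function(k)
      mean_silhouette(cutree(hc, k), as.matrix(d)), 0)
    k_modules <- ks[which.max(sil)]
  }
  if (k_modules > ncol(P)) aml_stop("k_modules exceeds number of subgroups")
  cl <- cutree(hc, k_modules)
  module <- paste0("M", cl)
  df <- data.frame(subgroup = colnames(P), patient = prof$patient,
                   size = prof$size, module = module,
                   stringsAsFactors = FALSE)
  n_pat <- tapply(df$patient, df$module, function(x) length(unique(x)))
  df$reason <- ""
  df$reason[n_pat[df$module] == 1] <- "single-patient"
  df$reason[df$module %in% exclusion_list] <- "excluded"
  df$kept <- df$reason == ""
  df
}

# mean silhouette width of a labeling given a distance matrix
mean_silhouette <- function(labels, dmat) {
  n <- length(labels)
  if (length(unique(labels)) < 2) return(-1)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(dmat[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(dmat[i, labels == l]), 0))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Signature genes of the kept modules
#'
#' One-vs-rest Wilcoxon over the member cells of each kept module (against
#' all other malignant cells), pooled across modules into a single signature
#' list of `n_total` unique genes. The per-module quota is proportional to
#' module size; ties broken by (p, -log2FC, gene id).
#'
#' @param expr gene x cell log-expression matrix over malignant cells
#' @param modules output of [ward_modules()]
#' @param subgroups per-cell subgroup ids (links cells to modules)
#' @param n_total total signature genes (default 500)
#' @param sig_fdr only genes whose one-vs-rest marker test reaches this BH
#'   FDR may enter a signature (default 0.05); modules without significant
#'   markers contribute nothing, so the pooled signature can fall short of
#'   `n_total`
#' @return list: `signature` (character), `per_module` (marker tables of
#'   significant genes only)
#' @export
module_signatures <- function(expr, modules, subgroups, n_total = 500,
                              sig_fdr = 0.05) {
  if (n_total < 1) aml_stop("n_total must be >= 1")
  kept <- modules[modules$kept, , drop = FALSE]
  if (nrow(kept) == 0) aml_stop("no kept modules")
  mod_of_cell <- kept$module[match(subgroups, kept$subgroup)]
  in_mod <- !is.na(mod_of_cell)
  X <- expr[, in_mod, drop = FALSE]
  labs <- mod_of_cell[in_mod]
  if (n_total > nrow(expr)) {
    aml_warn("n_total capped at number of genes")
    n_total <- nrow(expr)
  }
  mk <- rank_sum_markers(X, labs)
  mk$fdr <- stats::ave(mk$p, mk$group,
                       FUN = function(p) p.adjust(p, method = "BH"))
  mk <- mk[mk$fdr < sig_fdr, , drop = FALSE]
  mods <- sort(unique(labs))
  sizes <- table(labs)[mods]
  quota <- pmax(1L, round(n_total * as.numeric(sizes) / sum(sizes)))
  per_module <- split(mk, factor(mk$group, levels = mods))
  sig <- character(0)
  for (i in seq_along(mods)) {
    sig <- union(sig, head(per_module[[mods[i]]]$gene, quota[i]))
  }
  # fill remaining slots round-robin down the per-module rankings
  depth <- max(quota) + 1L
  max_depth <- max(vapply(per_module, nrow, 0L))
  while (length(sig) < n_total && depth <= max_depth) {
    for (m in mods) {
      if (length(sig) >= n_total) break
      cand <- per_module[[m]]$gene[depth]
      if (!is.na(cand)) sig <- union(sig, cand)
    }
    depth <- depth + 1L
  }
  if (length(sig) == 0)
    aml_stop("no module has significant signature genes at FDR < ", sig_fdr)
  if (length(sig) < n_total)
    aml_log("module_signatures", "only ", length(sig),
            " significant signature genes available (requested ", n_total, ")")
  list(signature = head(sig, n_total), per_module = per_module)
}

#' Recluster all malignant cells on the shared signature
#'
#' Pooled clustering of malignant cells from all patients restricted to the
#' module signature genes: the signature carries the shared-program contrast
#' while diluting patient-specific variation, so the pooled clusters align
#' with programs rather than patients.
#'
#' @param expr gene x cell log-expression matrix (malignant cells)
#' @param signature_genes character vector of signature genes
#' @param covariates optional per-cell covariates for [regress_scale()]
#' @param resolution,n_pcs,seed passed to [cluster_cells()]
#' @return integer cluster labels (0..K-1), named by cell
#' @export
recluster_on_signature <- function(expr, signature_genes, covariates = NULL,
                                   resolution = 0.5, n_pcs = NULL, seed = 1) {
  sig <- intersect(signature_genes, rownames(expr))
  if (length(sig) == 0) aml_stop("no signature genes present in matrix")
  scaled <- regress_scale(expr[sig, , drop = FALSE], covariates)
  cluster_cells(scaled, n_pcs = n_pcs, resolution = resolution, seed = seed)
}

#' Score clusters on a gene set and flag set-high clusters
#'
#' The cluster score is the mean over member cells of the mean log
#' expression of the set genes; clusters are flagged "high" when their score
#' exceeds the across-cluster mean by `sd_mult` standard deviations.
#'
#' @param expr gene x cell log-expression matrix
#' @param labels per-cell cluster labels
#' @param gene_set character vector of genes (unknown ones dropped with a
#'   warning; error if none remain)
#' @param sd_mult flag threshold in SD units (default 1)
#' @return data.frame: cluster, score, high
#' @export
score_gene_set <- function(expr, labels, gene_set, sd_mult = 1) {
  if (length(gene_set) == 0) aml_stop("empty gene set")
  present <- intersect(gene_set, rownames(expr))
  if (length(present) == 0) aml_stop("no gene-set genes present in matrix")
  if (length(present) < length(gene_set))
    aml_warn(length(gene_set) - length(present), " unknown gene(s) dropped")
  cell_score <- Matrix::colMeans(expr[present, , drop = FALSE])
  cl <- sort(unique(labels))
  score <- vapply(cl, function(c) mean(cell_score[labels == c]), 0)
  thr <- mean(score) + sd_mult * sd(score)
  data.frame(cluster = cl, score = score,
             high = !is.na(thr) & score > thr, row.names = NULL)
}

#' Assign shared clusters to the four phenotype groups
#'
#' Each cluster goes to the arg-max of its four set scores (RP,
#' neutrophil, monocyte, myeloid); a cluster flagged RP-high by
#' [score_gene_set()] is assigned "RP-high" regardless (the prognostic
#' category takes precedence). Ties follow the fixed priority RP >
#' neutrophil > monocyte > myeloid and are logged.
#'
#' @param expr gene x cell log-expression matrix
#' @param labels per-cell cluster labels
#' @param gene_sets named list with elements `rp`, `neutrophil`, `monocyte`,
#'   `myeloid` (disjoint gene sets)
#' @param sd_mult passed to [score_gene_set()] for the RP-high flag
#' @return data.frame: cluster, scores per set, rp_high, group
#' @export
group_clusters <- function(expr, labels, gene_sets, sd_mult = 1) {
  need <- c("rp", "neutrophil", "monocyte", "myeloid")
  stopifnot(all(need %in% names(gene_sets)))
  if (any(duplicated(unlist(gene_sets[need]))))
    aml_stop("the four gene sets must be disjoint")
  tabs <- lapply(need, function(s) score_gene_set(expr, labels, gene_sets[[s]],
                                                  sd_mult = sd_mult))
  scores <- vapply(tabs, function(t) t$score, numeric(nrow(tabs[[1]])))
  scores <- matrix(scores, ncol = 4, dimnames = list(NULL, need))
  group_names <- c(rp = "RP-high", neutrophil = "neutrophil-like",
                   monocyte = "monocyte-like", myeloid = "myeloid-like")
  grp <- character(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    best <- which(scores[i, ] == max(scores[i, ]))
    if (length(best) > 1)
      aml_log("group_clusters", "tie for cluster ", tabs[[1]]$cluster[i],
              "; priority order applied")
    grp[i] <- group_names[need[best[1]]]
  }
  rp_high <- tabs[[1]]$high
  grp[rp_high] <- "RP-high"
  out <- data.frame(cluster = tabs[[1]]$cluster, scores,
                    rp_high = rp_high, group = grp, row.names = NULL)
  out
}

#' Seed-to-seed stability of discovered modules
#'
#' Runs the subcluster -> Ward -> signature stages under two different
#' seeds and matches each kept (multi-patient) module of the first run to
#' its best counterpart in the second by Jaccard similarity of the top
#' per-module marker genes. Real shared programs reappear with high overlap;
#' modules carved out of batch noise do not, so the count of kept modules
#' with Jaccard at or above 0.5 estimates the number of genuine programs.
#'
#' @param expr,scaled,patients,malignant as in [discover_programs()]
#' @param seeds integer vector of length 2
#' @param per_module_n marker genes per module used for the overlap (100)
#' @param ... passed to [subcluster_per_patient()] / [ward_modules()]
#' @return data.frame: module (run 1), n_patients, best_jaccard, stable
#' @export
program_stability <- function(expr, scaled, patients, malignant,
                              seeds = c(1, 2), per_module_n = 100, ...) {
  stopifnot(length(seeds) == 2)
  run <- function(seed) {
    mal <- which(malignant)
    sub <- subcluster_per_patient(scaled[, mal, drop = FALSE], patients[mal],
                                  seed = seed, ...)
    hvg <- intersect(rownames(scaled), rownames(expr))
    prof <- subgroup_profiles(expr[hvg, mal, drop = FALSE], sub)
    modules <- ward_modules(prof)
    kept <- modules[modules$kept, , drop = FALSE]
    if (nrow(kept) == 0) return(list(modules = modules, sigs = list()))
    sig <- tryCatch(
      module_signatures(expr[, mal, drop = FALSE], modules, sub,
                        n_total = per_module_n *
                          length(unique(kept$module))),
      error = function(e) NULL)
    if (is.null(sig)) return(list(modules = modules, sigs = list()))
    sigs <- lapply(sig$per_module, function(df) head(df$gene, per_module_n))
    sigs <- sigs[names(sigs) %in% kept$module]
    list(modules = modules, sigs = sigs)
  }
  a <- run(seeds[1]); b <- run(seeds[2])
  if (length(a$sigs) == 0)
    return(data.frame(module = character(), n_patients = integer(),
                      best_jaccard = numeric(), stable = logical()))
  jac <- function(x, y) {
    u <- length(union(x, y))
    if (u == 0) 0 else length(intersect(x, y)) / u
  }
  out <- do.call(rbind, lapply(names(a$sigs), function(m) {
    best <- if (length(b$sigs)) max(vapply(b$sigs, jac, 0, x = a$sigs[[m]]))
    else 0
    n_pat <- length(unique(a$modules$patient[a$modules$module == m]))
    data.frame(module = m, n_patients = n_pat, best_jaccard = best,
               stable = best >= 0.5, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Full shared-program discovery pipeline
#'
#' Per-patient high-resolution subclustering, subgroup profile averaging,
#' Ward module aggregation with single-patient discard, pooled signature
#' selection, and reclustering of all malignant cells on the signature.
#'
#' @param expr gene x cell log-expression matrix (all cells)
#' @param scaled gene x cell scaled matrix used for subclustering (HVG rows)
#' @param patients per-cell patient ids
#' @param malignant logical mask of malignant cells
#' @param subcluster_resolution,recluster_resolution Louvain resolutions
#' @param k_modules,exclusion_list passed to [ward_modules()]
#' @param n_signature signature size (default 500)
#' @param min_cells minimum malignant cells per patient
#' @param regress_patient include a patient indicator when rescaling for the
#'   pooled signature reclustering (default TRUE), mirroring the linear
#'   regression that eliminates batch effects before pooled maps
#' @param seed integer seed
#' @return list: `subgroups`, `modules`, `signature`, `labels` (shared
#'   cluster labels over malignant cells)
#' @export
discover_programs <- function(expr, scaled, patients, malignant,
                              subcluster_resolution = 3,
                              recluster_resolution = 0.5,
                              k_modules = NULL, exclusion_list = character(),
                              n_signature = 500, min_cells = 50,
                              regress_patient = TRUE, seed = 1) {
  stopifnot(ncol(expr) == length(patients), length(patients) == length(malignant))
  mal <- which(malignant)
  sub <- subcluster_per_patient(scaled[, mal, drop = FALSE], patients[mal],
                                resolution = subcluster_resolution,
                                min_cells = min_cells, seed = seed)
  hvg <- intersect(rownames(scaled), rownames(expr))
  prof <- subgroup_profiles(expr[hvg, mal, drop = FALSE], sub)
  modules <- ward_modules(prof, k_modules = k_modules,
                          exclusion_list = exclusion_list)
  sig <- module_signatures(expr[, mal, drop = FALSE], modules, sub,
                           n_total = n_signature)
  cov <- if (regress_patient) data.frame(patient = patients[mal]) else NULL
  labels <- recluster_on_signature(expr[, mal, drop = FALSE], sig$signature,
                                   covariates = cov,
                                   resolution = recluster_resolution,
                                   seed = seed)
  list(subgroups = sub, modules = modules, signature = sig$signature,
       labels = labels)
}
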