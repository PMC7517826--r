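#' Normalize counts to CPM x 0.1 (counts per 100,000)
#'
#' The correlation analyses operate on expression normalized to the total
#' number of transcripts and multiplied by 100,000; optionally log1p'd.
#'
#' @param cm CountMatrix
#' @param log1p apply log(1 + x) after scaling
#' @return sparse gene x cell matrix
#' @export
normalize_cpm1e5 <- function(cm, log1p = FALSE) {
  stopifnot(is(cm, "CountMatrix"))
  nUMI <- cm$cell_meta$nUMI
  if (any(nUMI == 0)) aml_stop("cells with zero counts present")
  m <- methods::as(cm$counts %*% Matrix::Diagonal(ncol(cm$counts), 1e5 / nUMI),
                   "CsparseMatrix")
  if (log1p) m@x <- log1p(m@x)
  dimnames(m) <- dimnames(cm$counts)
  attr(m, "expr_kind") <- if (log1p) "log_cpm1e5" else "cpm1e5"
  m
}

#' Build pseudo-cells by averaging cells within clusters
#'
#' In `random` mode each cluster's cells are partitioned (seeded shuffle)
#' into disjoint groups of `k`; the terminal remainder forms its own
#' pseudo-cell when it holds at least `k/2` cells and is dropped otherwise.
#' In `top_detected` mode cells are taken in decreasing order of detected
#' gene count, so the first pseudo-cell averages the k most informative
#' cells. Clusters smaller than `k/2` are skipped with a warning. The
#' size-weighted average of pseudo-cell profiles equals the average of the
#' member cells (conservation of the grand mean).
#'
#' @param expr gene x cell expression matrix (typically CPM x 1e5 scale)
#' @param labels per-cell cluster labels
#' @param k cells per pseudo-cell (20 for random sampling, 50 for
#'   top-detected, matching their respective uses)
#' @param mode "random" or "top_detected"
#' @param n_gene per-cell detected gene counts (required for top_detected)
#' @param seed integer seed (random mode)
#' @return list: `profiles` (gene x pseudo-cell matrix), `cluster`, `size`,
#'   `members` (list of member cell names)
#' @export
make_pseudocells <- function(expr, labels, k = 20,
                             mode = c("random", "top_detected"),
                             n_gene = NULL, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(k >= 1, ncol(expr) == length(labels))
  if (mode == "top_detected" && is.null(n_gene))
    aml_stop("top_detected mode needs per-cell n_gene")
  X <- expr
  cells <- colnames(X) %||% as.character(seq_len(ncol(X)))
  members <- list(); cluster <- character(0)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < k / 2) {
        aml_warn("cluster ", cl, " has ", length(idx),
                 " cells (< k/2); skipped")
        next
      }
      ord <- if (mode == "random") sample(idx)
      else idx[order(-n_gene[idx], cells[idx])]
      n_full <- length(ord) %/% k
      splits <- if (n_full > 0) split(ord[seq_len(n_full * k)],
                                      rep(seq_len(n_full), each = k))
      else list()
      rem <- if (n_full * k < length(ord)) ord[(n_full * k + 1):length(ord)]
      else integer(0)
      if (length(rem) >= k / 2) splits <- c(splits, list(rem))
      for (s in splits) {
        members[[length(members) + 1L]] <- cells[s]
        cluster <- c(cluster, as.character(cl))
      }
    }
  })
  if (length(members) == 0) aml_stop("no pseudo-cells could be formed")
  prof <- vapply(members, function(m)
    as.numeric(Matrix::rowMeans(X[, m, drop = FALSE])), numeric(nrow(X)))
  rownames(prof) <- rownames(X)
  ids <- paste0(cluster, "_pc", stats::ave(seq_along(cluster), cluster,
                                           FUN = seq_along))
  colnames(prof) <- ids
  names(members) <- ids
  list(profiles = prof, cluster = cluster,
       size = vapply(members, length, 0L), members = members)
}

#' Pairwise Pearson correlation network
#'
#' All pairwise Pearson correlations between profiles; edges with r strictly
#' above the threshold are retained (r exactly at the threshold is excluded).
#' Zero-variance profiles have undefined correlations and are dropped with a
#' warning.
#'
#' @param profiles gene x profile matrix
#' @param r_threshold correlation threshold, strict (default 0.65)
#' @return EdgeTable
#' @export
corr_network <- function(profiles, r_threshold = 0.65) {
  stopifnot(r_threshold > -1, r_threshold < 1)
  if (ncol(profiles) < 2) aml_stop("need at least 2 profiles")
  v <- apply(profiles, 2, var)
  if (any(v == 0)) {
    aml_warn(sum(v == 0), " zero-variance profile(s) dropped")
    profiles <- profiles[, v > 0, drop = FALSE]
  }
  if (ncol(profiles) < 2) return(edge_table(namespace = "profile"))
  r <- cor(profiles)
  idx <- which(upper.tri(r) & r > r_threshold, arr.ind = TRUE)
  edge_table(colnames(r)[idx[, 1]], colnames(r)[idx[, 2]],
             r[idx], namespace = "profile")
}

#' Build a reference atlas from labeled counts
#'
#' Per-type one-vs-rest Wilcoxon markers; the gene panel is the union of the
#' top `top_k` markers of every type, and each type's profile is its mean
#' log1p(CPM x 1e5) expression over the panel.
#'
#' @param cm CountMatrix whose metadata has a `type` column (or pass labels)
#' @param labels per-cell type labels (default `cm$cell_meta$type`)
#' @param top_k markers per type (default 20)
#' @return list of class `ReferenceAtlas`: `types`, `panel`,
#'   `profiles` (panel gene x type matrix), `markers` (per-type top lists)
#' @export
build_reference <- function(cm, labels = NULL, top_k = 20) {
  stopifnot(is(cm, "CountMatrix"))
  if (top_k < 1) aml_stop("top_k must be >= 1")
  labels <- labels %||% cm$cell_meta$type
  if (length(unique(labels)) < 2) aml_stop("need at least 2 types")
  expr <- normalize_cpm1e5(cm, log1p = TRUE)
  mk <- rank_sum_markers(expr, labels)
  marker_lists <- top_markers(mk, top_k)
  panel <- unique(unlist(marker_lists, use.names = FALSE))
  types <- sort(unique(labels))
  prof <- vapply(types, function(t)
    as.numeric(Matrix::rowMeans(expr[panel, labels == t, drop = FALSE])),
    numeric(length(panel)))
  rownames(prof) <- panel
  structure(list(types = types, panel = panel, profiles = prof,
                 markers = marker_lists), class = "ReferenceAtlas")
}

#' Map query cells onto a reference atlas by correlation
#'
#' Pearson correlation of every query cell against every reference type
#' profile over the shared panel genes; the best-correlated type is
#' reported, and cells whose maximum correlation falls below
#' `unmatched_threshold` are flagged unmatched — the operational analogue of
#' a malignant state that matches no normal cell type.
#'
#' @param query gene x cell expression matrix on the same scale the
#'   reference was built on (log1p CPM x 1e5)
#' @param ref ReferenceAtlas
#' @param unmatched_threshold max-r below which a cell is unmatched (0.6)
#' @return data.frame: cell, best_type, max_r, unmatched; attribute
#'   `cor_matrix` holds the full cell x type correlation matrix
#' @export
map_cells <- function(query, ref, unmatched_threshold = 0.6) {
  stopifnot(is(ref, "ReferenceAtlas"))
  shared <- intersect(ref$panel, rownames(query))
  if (length(shared) < 5) aml_stop("fewer than 5 panel genes shared with query")
  Q <- as.matrix(query[shared, , drop = FALSE])
  R <- ref$profiles[shared, , drop = FALSE]
  cc <- suppressWarnings(cor(Q, R))
  cc[is.na(cc)] <- 0
  best <- max.col(cc, ties.method = "first")
  max_r <- cc[cbind(seq_len(nrow(cc)), best)]
  out <- data.frame(cell = colnames(query) %||% as.character(seq_len(ncol(query))),
                    best_type = ref$types[best], max_r = max_r,
                    unmatched = max_r < unmatched_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "cor_matrix") <- cc
  out
}

#' Cross-batch cluster similarity by neighbour-voting AUROC
#'
#' For each type in batch A, every batch-B cell is scored by its mean
#' Pearson correlation (over the given genes) to the A-cells of that type;
#' for each B type the AUROC of its membership against that score is
#' computed (Mann-Whitney U / n1 n2, mid-ranks for ties). Pairs at or above
#' the threshold form the linkage table.
#'
#' @param expr gene x cell expression matrix containing both batches
#' @param batch per-cell batch labels (exactly 2 levels)
#' @param labels per-cell type labels
#' @param genes gene panel (typically HVGs)
#' @param threshold linkage threshold on AUROC (default 0.7, inclusive)
#' @param min_cells types with fewer cells are skipped
#' @return list: `auroc` (typeA x typeB matrix), `links` (data.frame)
#' @export
cluster_auroc <- function(expr, batch, labels, genes = rownames(expr),
                          threshold = 0.7, min_cells = 3) {
  bs <- unique(batch)
  if (length(bs) != 2) aml_stop("exactly 2 batches required")
  genes <- intersect(genes, rownames(expr))
  X <- as.matrix(expr[genes, , drop = FALSE])
  a_cells <- which(batch == bs[1]); b_cells <- which(batch == bs[2])
  types_a <- names(which(table(labels[a_cells]) >= min_cells))
  types_b <- names(which(table(labels[b_cells]) >= min_cells))
  if (!length(types_a) || !length(types_b))
    aml_stop("no types with >= min_cells cells in one of the batches")
  cc <- suppressWarnings(cor(X[, b_cells, drop = FALSE],
                             X[, a_cells, drop = FALSE]))
  cc[is.na(cc)] <- 0
  M <- matrix(NA_real_, length(types_a), length(types_b),
              dimnames = list(types_a, types_b))
  for (ta in types_a) {
    score <- rowMeans(cc[, labels[a_cells] == ta, drop = FALSE])
    r <- rank(score)
    for (tb in types_b) {
      pos <- labels[b_cells] == tb
      n1 <- sum(pos); n2 <- sum(!pos)
      M[ta, tb] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
    }
  }
  idx <- which(M >= threshold, arr.ind = TRUE)
  links <- data.frame(type_a = rownames(M)[idx[, 1]],
                      type_b = colnames(M)[idx[, 2]],
                      auroc = M[idx], stringsAsFactors = FALSE)
  list(auroc = M, links = links[order(-links$auroc), , drop = FALSE])
}

#' Screen markers for disease specificity against a reference
#'
#' Removes from a ranked disease marker list every gene appearing in any of
#' the reference types' top marker lists, leaving genes specifically
#' expressed in the disease population, in their original score order.
#'
#' @param markers data.frame with `gene` and `score` columns, ranked
#' @param ref_marker_lists list of character vectors (top markers per
#'   reference type), e.g. the `markers` element of a ReferenceAtlas
#' @return data.frame of retained markers, ranked by score
#' @export
specificity_screen <- function(markers, ref_marker_lists) {
  stopifnot(is.data.frame(markers), all(c("gene", "score") %in% names(markers)))
  block <- unique(unlist(ref_marker_lists, use.names = FALSE))
  out <- markers[!markers$gene %in% block, , drop = FALSE]
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) aml_warn("no markers survive the specificity screen")
  out
}

#' Gene-gene correlation network around seed genes
#'
#' Genes expressed in fewer than `min_cells` profiles are removed, Pearson
#' correlations of every remaining gene with each seed gene are computed and
#' absolute values taken; each seed contributes its `top_m` strongest
#' partners as edges weighted by |r|.
#'
#' @param profiles gene x pseudo-cell expression matrix
#' @param seed_genes character vector of seed genes
#' @param top_m partners per seed gene (default 10)
#' @param min_cells expression filter (default 3 profiles)
#' @return EdgeTable with namespace "gene"
#' @export
gene_corr_network <- function(profiles, seed_genes, top_m = 10, min_cells = 3) {
  expressed <- Matrix::rowSums(profiles > 0) >= min_cells
  P <- as.matrix(profiles[expressed, , drop = FALSE])
  a <- character(0); b <- character(0); w <- numeric(0)
  for (s in seed_genes) {
    if (!s %in% rownames(P)) {
      aml_warn("seed gene ", s, " filtered out or absent; skipped")
      next
    }
    r <- abs(suppressWarnings(cor(P[s, ], t(P))))[1, ]
    r[is.na(r)] <- 0
    r <- r[names(r) != s]
    top <- head(order(-r, names(r)), top_m)
    a <- c(a, rep(s, length(top)))
    b <- c(b, names(r)[top])
    w <- c(w, unname(r[top]))
  }
  edge_table(a, b, w, namespace = "gene")
}
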