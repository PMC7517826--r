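#' Mutual information with equal-frequency binning
#'
#' Both vectors are discretized into `n_bins` equal-frequency bins
#' (rank-based) and the plug-in mutual information of the joint histogram is
#' returned, in nats. Symmetric by construction.
#'
#' @param x,y numeric vectors of equal length
#' @param n_bins number of bins (default 8)
#' @return scalar MI >= 0
#' @export
mutual_information <- function(x, y, n_bins = 8) {
  stopifnot(length(x) == length(y))
  bx <- ef_bin(x, n_bins); by <- ef_bin(y, n_bins)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

# equal-frequency binning on mid-ranks (deterministic random-free ties)
ef_bin <- function(x, n_bins) {
  r <- rank(x, ties.method = "average")
  pmin(n_bins, ceiling(r / length(x) * n_bins))
}

#' Infer TF regulons by mutual information and DPI pruning
#'
#' A simplified accurate-cellular-network reconstruction, at desk scale:
#' pairwise MI (equal-frequency binning) between every transcription factor
#' and every gene; edges below an MI threshold (permutation-calibrated when
#' not given) are removed; then the data-processing inequality is applied —
#' in every triangle (tf1, tf2, g) the weakest edge is presumed indirect and
#' dropped when it falls below both others by more than `dpi_epsilon`.
#' Interaction mode is the sign of the Spearman correlation; weight is the
#' MI rank-normalized within each TF's regulon.
#'
#' @param expr gene x pseudo-cell expression matrix (>= 30 pseudo-cells
#'   recommended)
#' @param tf_list transcription-factor gene ids (must be rows of `expr`)
#' @param n_bins MI bins (default 8)
#' @param dpi_epsilon DPI tolerance (default 0 = classic rule)
#' @param mi_threshold minimum MI to keep an edge; `NULL` calibrates it as
#'   the 99th percentile of MI between permuted gene pairs
#' @param seed seed for the permutation calibration
#' @return named list of regulons; each is a data.frame (target, mi, mode,
#'   weight)
#' @export
infer_regulons <- function(expr, tf_list, n_bins = 8, dpi_epsilon = 0,
                           mi_threshold = NULL, seed = 1) {
  X <- as.matrix(expr)
  if (ncol(X) < 30)
    aml_warn("fewer than 30 pseudo-cells; MI estimates will be noisy")
  missing_tf <- setdiff(tf_list, rownames(X))
  if (length(missing_tf)) aml_stop("TFs absent from matrix: ",
                                   paste(missing_tf, collapse = ", "))
  keep <- apply(X, 1, var) > 0
  if (any(!keep)) aml_warn(sum(!keep), " constant gene(s) dropped")
  X <- X[keep, , drop = FALSE]
  tf_list <- intersect(tf_list, rownames(X))
  genes <- rownames(X)
  B <- t(apply(X, 1, ef_bin, n_bins = n_bins))

  if (is.null(mi_threshold)) {
    mi_threshold <- with_seed(seed, {
      null_mi <- replicate(500, {
        i <- sample(nrow(X), 2)
        mutual_information(X[i[1], ], sample(X[i[2], ]), n_bins)
      })
      quantile(null_mi, 0.99, names = FALSE)
    })
  }

  mi_pair <- function(a, b) {
    joint <- table(factor(B[a, ], levels = 1:n_bins),
                   factor(B[b, ], levels = 1:n_bins)) / ncol(B)
    px <- rowSums(joint); py <- colSums(joint)
    nz <- joint > 0
    sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  }
  MI <- matrix(0, length(tf_list), length(genes),
               dimnames = list(tf_list, genes))
  for (tf in tf_list) for (g in genes)
    if (tf != g) MI[tf, g] <- mi_pair(tf, g)

  adj <- MI >= mi_threshold
  ## DPI: in every triangle whose three edges are all present (which needs
  ## two TFs), the weakest edge is presumed indirect and dropped when it is
  ## below both others by more than epsilon; drops are marked first and
  ## applied together, so the strongest edge of a triangle is never removed
  if (length(tf_list) >= 2) {
    drop <- matrix(FALSE, nrow(MI), ncol(MI), dimnames = dimnames(MI))
    is_tf <- setNames(genes %in% tf_list, genes)
    has <- function(a, b) (is_tf[a] && adj[a, b]) || (is_tf[b] && adj[b, a])
    miv <- function(a, b) if (is_tf[a]) MI[a, b] else MI[b, a]
    mark <- function(a, b) {
      if (is_tf[a]) drop[a, b] <<- TRUE
      if (is_tf[b]) drop[b, a] <<- TRUE
    }
    for (pr in combn(tf_list, 2, simplify = FALSE)) {
      t1 <- pr[1]; t2 <- pr[2]
      if (!has(t1, t2)) next
      cand <- genes[adj[t1, ] & adj[t2, ] & genes != t1 & genes != t2]
      for (g in cand) {
        if (!has(t1, g) || !has(t2, g)) next
        e <- c(miv(t1, t2), miv(t1, g), miv(t2, g))
        w <- which.min(e)
        if (e[w] < min(e[-w]) - dpi_epsilon) {
          if (w == 1) mark(t1, t2)
          else if (w == 2) mark(t1, g)
          else mark(t2, g)
        }
      }
    }
    adj <- adj & !drop
  }

  sp <- suppressWarnings(cor(t(X[tf_list, , drop = FALSE]), t(X),
                             method = "spearman"))
  out <- lapply(tf_list, function(tf) {
    tg <- genes[adj[tf, ] & genes != tf]
    if (length(tg) == 0)
      return(data.frame(target = character(), mi = numeric(),
                        mode = numeric(), weight = numeric()))
    mi <- MI[tf, tg]
    w <- rank(mi, ties.method = "average") / length(mi)
    data.frame(target = tg, mi = unname(mi),
               mode = sign(sp[tf, tg]), weight = unname(w),
               stringsAsFactors = FALSE)
  })
  names(out) <- tf_list
  out
}

#' Normalized enrichment score of regulons against a DE signature
#'
#' `NES = sum(w m z) / sqrt(sum(w^2))` over the regulon's targets present in
#' the signature, where w is the confidence weight, m the interaction mode
#' and z the signature z-score; under a null signature NES is standard
#' normal, so the two-sided p comes from the normal tail; BH FDR over TFs.
#'
#' @param signature named numeric vector of per-gene z-scores (e.g. signed
#'   z-transform of DE p-values)
#' @param regulons named list of regulons from [infer_regulons()]
#' @param min_targets TFs with fewer usable targets are skipped (default 5)
#' @return data.frame: tf, n_targets, nes, p, fdr
#' @export
nes_enrichment <- function(signature, regulons, min_targets = 5) {
  rows <- lapply(names(regulons), function(tf) {
    reg <- regulons[[tf]]
    use <- reg$target %in% names(signature)
    if (sum(use) < min_targets) {
      aml_warn("TF ", tf, " has < ", min_targets, " usable targets; skipped")
      return(NULL)
    }
    reg <- reg[use, , drop = FALSE]
    z <- signature[reg$target]
    nes <- sum(reg$weight * reg$mode * z) / sqrt(sum(reg$weight^2))
    data.frame(tf = tf, n_targets = nrow(reg), nes = nes,
               p = 2 * pnorm(-abs(nes)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(tf = character(), n_targets = integer(),
                                      nes = numeric(), p = numeric(),
                                      fdr = numeric()))
  out$fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Prune a regulon to differentially expressed targets
#'
#' Targets whose FDR in the differential-expression table exceeds the cutoff
#' are removed (non-DE downstream targets carry no evidence for the
#' attractor state). Idempotent.
#'
#' @param regulon data.frame regulon (one element of [infer_regulons()])
#' @param de_table [de_test()] table covering the target genes
#' @param fdr removal rule: drop targets with FDR strictly above this (0.05)
#' @return pruned regulon; zero-row regulons are flagged with a warning
#' @export
prune_regulon <- function(regulon, de_table, fdr = 0.05) {
  g_fdr <- setNames(de_table$fdr, de_table$gene)
  tf_fdr <- g_fdr[regulon$target]
  keep <- !is.na(tf_fdr) & tf_fdr <= fdr
  out <- regulon[keep, , drop = FALSE]
  if (nrow(out) == 0) aml_warn("all targets pruned: empty regulon")
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum p-value with exact small-sample enumeration
#'
#' One-sided (x greater) rank-sum p. When both groups have at most
#' `enum_max` observations the p-value is computed by complete enumeration
#' of group assignments (exact even under ties); otherwise the tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y numeric samples
#' @param enum_max enumeration limit per group (default 8)
#' @return one-sided p-value for the alternative "x shifted up"
#' @export
wilcoxon_greater_p <- function(x, y, enum_max = 8) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (n1 <= enum_max && n2 <= enum_max) {
    idx <- combn(n1 + n2, n1)
    stats_all <- colSums(matrix(r[idx], nrow = n1))
    return(mean(stats_all >= W))
  }
  suppressWarnings(wilcox.test(x, y, alternative = "greater",
                               exact = FALSE, correct = TRUE)$p.value)
}

#' Select attractor transcription factors
#'
#' Candidates are the TFs with enrichment FDR < 0.05 and NES > 0. For each,
#' the gene score s(g) = |log2FC(g)| * (-log10 FDR(g)) of its pruned targets
#' is compared with the scores of all other differentially expressed genes
#' by a one-sided Wilcoxon rank-sum test; the TF is selected iff its targets
#' score significantly higher (p < alpha, strict).
#'
#' @param regulons named list of pruned regulons
#' @param de_table [de_test()] table (defines the DEG universe at `de_fdr`)
#' @param enrichment [nes_enrichment()] table
#' @param alpha Wilcoxon significance level (default 0.05)
#' @param de_fdr DEG universe cutoff (default 0.05)
#' @param min_target_degs TFs with fewer target DEGs are not selectable (3)
#' @return data.frame: tf, nes, fdr, n_target_degs, wilcoxon_p, selected
#' @export
select_attractor_tfs <- function(regulons, de_table, enrichment,
                                 alpha = 0.05, de_fdr = 0.05,
                                 min_target_degs = 3) {
  deg <- de_table[de_table$fdr < de_fdr, , drop = FALSE]
  score <- setNames(abs(deg$log2fc) * -log10(pmax(deg$fdr, 1e-300)), deg$gene)
  cand <- enrichment[enrichment$fdr < 0.05 & enrichment$nes > 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    tf <- cand$tf[i]
    targets <- intersect(regulons[[tf]]$target, names(score))
    others <- setdiff(names(score), targets)
    if (length(targets) < min_target_degs || length(others) == 0)
      return(data.frame(tf = tf, nes = cand$nes[i], fdr = cand$fdr[i],
                        n_target_degs = length(targets), wilcoxon_p = NA_real_,
                        selected = FALSE, stringsAsFactors = FALSE))
    p <- wilcoxon_greater_p(score[targets], score[others])
    data.frame(tf = tf, nes = cand$nes[i], fdr = cand$fdr[i],
               n_target_degs = length(targets), wilcoxon_p = p,
               selected = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tf = character(), nes = numeric(), fdr = numeric(),
                      n_target_degs = integer(), wilcoxon_p = numeric(),
                      selected = logical())
  rownames(out) <- NULL
  out
}

#' Attractor network over selected TFs
#'
#' Pairwise Pearson correlation of the selected TFs' expression over
#' pseudo-cells; edges strictly above the threshold (default r > 0.3) are
#' significant.
#'
#' @param expr gene x pseudo-cell expression matrix
#' @param selected_tfs character vector of selected TF ids
#' @param r_threshold strict edge threshold (default 0.3)
#' @return EdgeTable with namespace "tf"
#' @export
attractor_network <- function(expr, selected_tfs, r_threshold = 0.3) {
  tfs <- intersect(selected_tfs, rownames(expr))
  if (length(tfs) < 2) {
    aml_warn("fewer than 2 selected TFs: empty attractor network")
    return(edge_table(namespace = "tf"))
  }
  profiles <- t(as.matrix(expr[tfs, , drop = FALSE]))  # pseudo-cells x TFs
  et <- corr_network(profiles, r_threshold = r_threshold)
  attr(et, "namespace") <- "tf"
  et
}
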