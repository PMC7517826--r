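#' Quality-control filter on cells
#'
#' Retains cells in which more than `min_transcripts` transcripts were
#' detected (strict inequality) and whose mitochondrial count fraction does
#' not exceed `max_mito_frac`. Genes are untouched. Idempotent.
#'
#' @param cm CountMatrix
#' @param min_transcripts minimum UMI count, exclusive (default 500)
#' @param max_mito_frac maximum tolerated mitochondrial fraction in (0, 1];
#'   the threshold for a "high proportion" of mitochondrial content is not a
#'   universal constant, so it is an explicit parameter (default 0.2)
#' @return filtered CountMatrix
#' @export
qc_filter <- function(cm, min_transcripts = 500, max_mito_frac = 0.2) {
  stopifnot(is(cm, "CountMatrix"))
  if (!(max_mito_frac > 0 && max_mito_frac <= 1))
    aml_stop("max_mito_frac must lie in (0, 1]")
  if (ncol(cm$counts) == 0) aml_stop("qc_filter: empty input")
  keep <- cm$cell_meta$nUMI > min_transcripts &
    cm$cell_meta$mito_frac <= max_mito_frac
  if (!any(keep)) aml_stop("qc_filter removed every cell")
  aml_log("qc_filter", sprintf("%d of %d cells removed (nUMI <= %d or mito > %.2f)",
                               sum(!keep), length(keep), min_transcripts,
                               max_mito_frac))
  subset_cells(cm, keep)
}

#' log2(TPM/100 + 1) normalization
#'
#' Transforms UMI counts to `log2(count / nUMI * 1e6 / 100 + 1)`, i.e.
#' log2(TP10K + 1): counts-per-million at gene level scaled by 1/100, with no
#' transcript-length correction (appropriate for 3' UMI data). Zero counts
#' map to zero, so sparsity is preserved; values are invariant to per-cell
#' rescaling of counts.
#'
#' @param cm CountMatrix (every cell must have nUMI > 0)
#' @return sparse gene x cell matrix with attribute `expr_kind = "log_tpm"`
#' @export
normalize_log_tpm <- function(cm) {
  stopifnot(is(cm, "CountMatrix"))
  nUMI <- cm$cell_meta$nUMI
  if (any(nUMI == 0))
    aml_stop("cells with zero counts present; run qc_filter first")
  m <- cm$counts
  expr <- methods::as(m %*% Matrix::Diagonal(ncol(m), 1e4 / nUMI),
                      "CsparseMatrix")
  expr@x <- log2(expr@x + 1)
  dimnames(expr) <- dimnames(m)
  attr(expr, "expr_kind") <- "log_tpm"
  expr
}

#' Select highly variable genes
#'
#' Genes are ranked by standardized dispersion: the log dispersion
#' (variance/mean) is compared against a smooth mean-dispersion trend
#' (loess over all genes), so lowly and highly expressed genes compete
#' fairly and a cluster of co-varying genes cannot hide inside its own
#' mean stratum. Ties are broken by gene id, and the selected set is
#' invariant to gene order.
#'
#' @param expr gene x cell log-expression matrix (sparse or dense)
#' @param n_genes number of genes to return (default 2000)
#' @param span loess span for the mean-dispersion trend
#' @return character vector of gene ids, ranked
#' @export
select_hvg <- function(expr, n_genes = 2000, span = 0.3) {
  if (n_genes > nrow(expr)) aml_stop("n_genes exceeds number of genes")
  mu <- Matrix::rowMeans(expr)
  ex2 <- Matrix::rowMeans(expr^2)
  v <- pmax(ex2 - mu^2, 0) * ncol(expr) / max(1, ncol(expr) - 1)
  if (all(v == 0)) aml_stop("constant expression matrix: no variable genes")
  disp <- ifelse(mu > 0, v / mu, 0)
  ldisp <- log1p(disp)
  z <- if (nrow(expr) >= 50) {
    fit <- stats::loess(ldisp ~ mu, span = span, degree = 1,
                        family = "symmetric")
    stats::residuals(fit)
  } else {
    ldisp - stats::median(ldisp)
  }
  ids <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  ord <- order(-z, ids)
  ids[ord][seq_len(n_genes)]
}

#' Regress out covariates and scale
#'
#' Per gene, ordinary least squares of expression on the given per-cell
#' covariates (typically nUMI and mitochondrial fraction; optionally a
#' patient indicator for pooled maps); residuals are centered, scaled to unit
#' variance, and clipped. Collinear covariate columns are dropped with a
#' warning. With no informative covariates the result is the z-scored input.
#'
#' @param expr gene x cell matrix (rows typically restricted to HVGs first)
#' @param covariates data.frame or matrix of per-cell covariates (numeric
#'   columns; factors/characters are expanded to indicators)
#' @param clip residuals clipped to `[-clip, clip]` after scaling
#' @return dense gene x cell matrix, attribute `expr_kind = "scaled"`;
#'   per-gene variance 1 for non-degenerate genes (before clipping)
#' @export
regress_scale <- function(expr, covariates = NULL, clip = 10) {
  X <- as.matrix(expr)
  n <- ncol(X)
  if (n < 2) aml_stop("need at least 2 cells")
  design <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates, stringsAsFactors = FALSE)
    for (j in names(cv)) {
      col <- cv[[j]]
      if (is.numeric(col)) design <- cbind(design, col)
      else design <- cbind(design, stats::model.matrix(~ f - 1,
        data.frame(f = factor(col)))[, -1, drop = FALSE])
    }
    if (any(!is.finite(design))) aml_stop("non-finite covariates")
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aml_warn(ncol(design) - qrd$rank, " collinear covariate column(s) dropped")
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design)
  }
  res <- t(qr.resid(qrd, t(X)))
  s <- apply(res, 1, sd)
  # perfectly fitted genes have numerically-zero residual spread; leave them
  # at zero rather than amplifying rounding noise to unit variance
  s[s < sqrt(.Machine$double.eps)] <- 1
  res <- res / s
  res[res > clip] <- clip
  res[res < -clip] <- -clip
  dimnames(res) <- dimnames(expr)
  attr(res, "expr_kind") <- "scaled"
  res
}

#' Choose the number of principal components by the elbow criterion
#'
#' Picks the component after which the largest drop in explained variance
#' occurs, with a floor (default 10) so fine structure is not lost.
#'
#' @param sdev vector of PC standard deviations
#' @param floor minimum number of PCs
#' @return integer number of PCs
#' @export
choose_n_pcs <- function(sdev, floor = 10) {
  v <- sdev^2 / sum(sdev^2)
  if (length(v) <= floor) return(length(v))
  drops <- -diff(v)
  elbow <- which.max(drops)
  max(min(elbow, length(v)), min(floor, length(v)))
}

#' Cluster cells by PCA + shared-nearest-neighbour Louvain
#'
#' PCA on the scaled residual matrix, a k-nearest-neighbour graph in PC
#' space with Jaccard shared-neighbour edge weights, then Louvain community
#' detection (delegated to igraph) at the given resolution. Labels are
#' 0-based, ordered by decreasing cluster size, and deterministic under a
#' fixed seed.
#'
#' @param expr gene x cell scaled matrix
#' @param n_pcs number of PCs (`NULL` = elbow criterion via [choose_n_pcs()])
#' @param resolution Louvain resolution; higher gives more clusters
#' @param k neighbours per cell for the kNN graph
#' @param seed integer seed
#' @param prune drop shared-neighbour edges with Jaccard below this
#' @return integer vector of cluster labels (0..K-1), named by cell
#' @export
cluster_cells <- function(expr, n_pcs = NULL, resolution = 1, k = 20,
                          seed = 1, prune = 1 / 15) {
  X <- as.matrix(expr)
  n <- ncol(X)
  if (n < 3) aml_stop("need at least 3 cells to cluster")
  max_pcs <- min(dim(X)) - 1L
  if (!is.null(n_pcs) && n_pcs > max_pcs)
    aml_stop("n_pcs must be <= min(genes, cells) - 1")
  with_seed(seed, {
    pc <- prcomp(t(X), center = TRUE, scale. = FALSE,
                 rank. = min(50L, max_pcs))
    np <- n_pcs %||% choose_n_pcs(pc$sdev[seq_len(ncol(pc$x))])
    emb <- pc$x[, seq_len(np), drop = FALSE]
    kk <- min(k, n - 1L)
    nn <- knn_index(emb, kk)
    adj <- snn_jaccard(nn, prune)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    com <- igraph::cluster_louvain(g, resolution = resolution)
    lab <- as.integer(igraph::membership(com))
    sizes <- sort(table(lab), decreasing = TRUE)
    relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
    out <- relabel[as.character(lab)]
    names(out) <- colnames(X)
    out
  })
}

# k nearest neighbours by Euclidean distance (self excluded); n x k index matrix
knn_index <- function(emb, k) {
  d2 <- as.matrix(dist(emb))^2
  diag(d2) <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

# shared-nearest-neighbour Jaccard weights over the union kNN graph
snn_jaccard <- function(nn, prune) {
  n <- nrow(nn); k <- ncol(nn)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)             # |N(i) intersect N(j)|
  shared <- methods::as(shared, "CsparseMatrix")
  jac <- shared
  jac@x <- shared@x / (2 * k - shared@x)      # Jaccard of k-sets
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  Matrix::drop0(jac)
}

#' Run the standard preprocessing chain
#'
#' [qc_filter()] -> [normalize_log_tpm()] -> [select_hvg()] ->
#' [regress_scale()] (on nUMI and mitochondrial fraction, plus a patient
#' indicator if requested) -> [cluster_cells()].
#'
#' @param cm CountMatrix
#' @param n_hvg number of highly variable genes
#' @param regress_patient include a patient indicator in the regression
#' @param resolution,n_pcs,seed passed to [cluster_cells()]
#' @param min_transcripts,max_mito_frac passed to [qc_filter()]
#' @return list: `counts` (filtered), `expr` (log), `hvg`, `scaled`
#'   (HVG x cells), `labels`
#' @export
preprocess <- function(cm, n_hvg = 1000, regress_patient = FALSE,
                       resolution = 1, n_pcs = NULL, seed = 1,
                       min_transcripts = 500, max_mito_frac = 0.2) {
  cmf <- qc_filter(cm, min_transcripts, max_mito_frac)
  expr <- normalize_log_tpm(cmf)
  hvg <- select_hvg(expr, min(n_hvg, nrow(expr)))
  cov <- data.frame(nUMI = cmf$cell_meta$nUMI,
                    mito_frac = cmf$cell_meta$mito_frac)
  if (regress_patient && "patient_id" %in% names(cmf$cell_meta))
    cov$patient <- cmf$cell_meta$patient_id
  scaled <- regress_scale(expr[hvg, , drop = FALSE], cov)
  labels <- cluster_cells(scaled, n_pcs = n_pcs, resolution = resolution,
                          seed = seed)
  list(counts = cmf, expr = expr, hvg = hvg, scaled = scaled, labels = labels)
}
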