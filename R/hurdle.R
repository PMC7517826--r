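#' Fit the hurdle model for one gene
#'
#' The two-part model used for single-cell differential expression: a
#' logistic regression for the zero process, `P(y > 0) ~ nGene + group`, and
#' a Gaussian linear regression for the continuous process among expressing
#' cells, `E(y | y > 0) ~ nGene + group`. Each component is compared with
#' its group-free null by a likelihood-ratio test (1 df each); the combined
#' statistic is their sum (chi-square, df = number of components fitted).
#' Perfect separation in the logistic part triggers a small ridge-penalized
#' refit (flagged); genes never expressed are skipped with p = 1.
#'
#' @param y non-negative log-expression vector (log2(TPM/100 + 1))
#' @param group binary group indicator (logical or 0/1; TRUE/1 = group A)
#' @param ngene per-cell detected-gene covariate
#' @param ridge ridge penalty used for the separation fallback
#' @return one-row data.frame: log2fc (difference of group means including
#'   zeros), coef_disc, coef_cont, lrt_disc, lrt_cont, lrt, df, p, flagged
#' @export
fit_hurdle <- function(y, group, ngene, ridge = 1e-4) {
  group <- as.numeric(group)
  stopifnot(length(y) == length(group), length(y) == length(ngene),
            all(y >= 0))
  if (length(unique(group)) < 2)
    return(hurdle_row(0, NA, NA, 0, 0, 0, 0, 1, FALSE))
  log2fc <- mean(y[group == 1]) - mean(y[group == 0])
  z <- as.numeric(y > 0)
  has_ng <- sd(ngene) > 0
  ng <- if (has_ng) as.numeric(scale(ngene)) else rep(0, length(y))
  if (all(z == 0)) return(hurdle_row(log2fc, NA, NA, 0, 0, 0, 0, 1, FALSE))

  ## discrete component
  flagged <- FALSE
  lrt_disc <- 0; coef_disc <- NA_real_; df <- 0L
  if (var(z) > 0) {
    X1 <- if (has_ng) cbind(1, ng, group) else cbind(1, group)
    X0 <- if (has_ng) cbind(1, ng) else matrix(1, length(z), 1)
    f1 <- ridge_logit(X1, z, 0)
    f0 <- ridge_logit(X0, z, 0)
    if (f1$separated || f0$separated) {
      flagged <- TRUE
      f1 <- ridge_logit(X1, z, ridge)
      f0 <- ridge_logit(X0, z, ridge)
    }
    lrt_disc <- max(0, 2 * (f1$loglik - f0$loglik))
    coef_disc <- f1$coef[ncol(X1)]
    df <- df + 1L
  }

  ## continuous component
  lrt_cont <- 0; coef_cont <- NA_real_
  pos <- y > 0
  if (sum(pos) >= 3 && length(unique(group[pos])) == 2 && var(y[pos]) > 0) {
    yp <- y[pos]; n <- length(yp)
    X1 <- if (has_ng) cbind(1, ng[pos], group[pos]) else cbind(1, group[pos])
    X0 <- if (has_ng) cbind(1, ng[pos]) else matrix(1, n, 1)
    r1 <- qr(X1); r0 <- qr(X0)
    rss1 <- sum(qr.resid(r1, yp)^2)
    rss0 <- sum(qr.resid(r0, yp)^2)
    if (rss1 > 0) {
      lrt_cont <- max(0, n * log(rss0 / rss1))
      coef_cont <- qr.coef(r1, yp)[ncol(X1)]
      df <- df + 1L
    }
  }

  lrt <- lrt_disc + lrt_cont
  p <- if (df > 0) pchisq(lrt, df = df, lower.tail = FALSE) else 1
  hurdle_row(log2fc, coef_disc, coef_cont, lrt_disc, lrt_cont, lrt, df, p,
             flagged)
}

hurdle_row <- function(log2fc, coef_disc, coef_cont, lrt_disc, lrt_cont,
                       lrt, df, p, flagged) {
  data.frame(log2fc = log2fc, coef_disc = coef_disc, coef_cont = coef_cont,
             lrt_disc = lrt_disc, lrt_cont = lrt_cont, lrt = lrt,
             df = df, p = p, flagged = flagged)
}

# logistic regression by IRLS with optional ridge penalty on all but the
# intercept; reports perfect separation (fitted probabilities at 0/1)
ridge_logit <- function(X, z, lambda, max_iter = 50, tol = 1e-9) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    zwork <- eta + (z - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      solve(XtW %*% X + pen, XtW %*% zwork),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  eps <- 1e-10
  loglik <- sum(z * log(pmax(mu, eps)) + (1 - z) * log(pmax(1 - mu, eps))) -
    lambda / 2 * sum(beta[-1]^2)
  separated <- any(mu > 1 - 1e-6 & z == 1) && any(mu < 1e-6 & z == 0) ||
    max(abs(beta)) > 1e3
  list(coef = beta, loglik = loglik, separated = separated)
}

#' Hurdle-model differential expression between two groups
#'
#' Cells are evenly downsampled (seeded) so at most `max_cells` per group
#' enter the test, then [fit_hurdle()] is applied gene-wise and p-values are
#' Benjamini-Hochberg adjusted over all tested genes. The combined LRT p is
#' the default ranking; discrete-component statistics are also reported.
#'
#' @param expr gene x cell log-expression matrix
#' @param cells_a,cells_b disjoint cell index/name vectors for the 2 groups
#' @param ngene per-cell detected-gene covariate for ALL columns of `expr`
#' @param max_cells downsampling cap per group (default 10000)
#' @param seed integer seed for the downsampling
#' @return data.frame (one row per gene): gene, log2fc, coef_disc,
#'   coef_cont, lrt_disc, lrt_cont, lrt, df, p, fdr, direction
#' @export
de_test <- function(expr, cells_a, cells_b, ngene = NULL, max_cells = 10000,
                    seed = 1) {
  cols <- colnames(expr) %||% as.character(seq_len(ncol(expr)))
  ia <- if (is.character(cells_a)) match(cells_a, cols) else as.integer(cells_a)
  ib <- if (is.character(cells_b)) match(cells_b, cols) else as.integer(cells_b)
  if (length(ia) == 0 || length(ib) == 0) aml_stop("empty group")
  if (length(intersect(ia, ib)) > 0) aml_stop("groups must be disjoint")
  with_seed(seed, {
    if (length(ia) > max_cells) ia <- sample(ia, max_cells)
    if (length(ib) > max_cells) ib <- sample(ib, max_cells)
  })
  X <- as.matrix(expr[, c(ia, ib), drop = FALSE])
  grp <- rep(c(1, 0), c(length(ia), length(ib)))
  ng <- if (is.null(ngene)) colSums(X > 0) else ngene[c(ia, ib)]
  res <- do.call(rbind, lapply(seq_len(nrow(X)), function(g)
    fit_hurdle(X[g, ], grp, ng)))
  res <- cbind(gene = rownames(X) %||% as.character(seq_len(nrow(X))), res,
               stringsAsFactors = FALSE)
  res$fdr <- p.adjust(res$p, method = "BH")
  res$direction <- ifelse(res$log2fc > 0, "up", ifelse(res$log2fc < 0,
                                                       "down", "none"))
  rownames(res) <- NULL
  res
}

#' Common and unique significant genes between two comparisons
#'
#' Set algebra over the significant genes (FDR below the cutoff) of two
#' differential-expression tables sharing a gene universe, split by
#' direction. Genes from a supplied ribosomal-protein list are sub-flagged.
#'
#' @param de_a,de_b [de_test()] tables (e.g. A-vs-control, B-vs-control)
#' @param fdr significance cutoff (default 0.05)
#' @param rp_genes optional character vector of ribosomal-protein gene ids
#' @return list: `common_up`, `common_down`, `unique_a`, `unique_b`
#'   (character vectors) and `rp_flag` (named logical over common_up)
#' @export
common_unique <- function(de_a, de_b, fdr = 0.05, rp_genes = character()) {
  if (!setequal(de_a$gene, de_b$gene))
    aml_stop("the two tables must share a gene universe")
  sig <- function(de, dir) de$gene[de$fdr < fdr & de$direction == dir]
  a_up <- sig(de_a, "up"); b_up <- sig(de_b, "up")
  a_dn <- sig(de_a, "down"); b_dn <- sig(de_b, "down")
  common_up <- intersect(a_up, b_up)
  common_down <- intersect(a_dn, b_dn)
  sig_a <- union(a_up, a_dn); sig_b <- union(b_up, b_dn)
  list(common_up = common_up, common_down = common_down,
       unique_a = setdiff(sig_a, sig_b), unique_b = setdiff(sig_b, sig_a),
       rp_flag = setNames(common_up %in% rp_genes, common_up))
}
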