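#' Classify patients into type I / type II
#'
#' A patient is type I when the progenitor cluster holds strictly more than
#' 50% of the patient's cells; a fraction of exactly 0.5 is type II.
#'
#' @param patients per-cell patient ids
#' @param labels per-cell cluster labels
#' @param progenitor_cluster_id the cluster counting toward the fraction
#' @return data.frame: patient_id, n_cells, c1_fraction, type
#' @export
classify_patients <- function(patients, labels, progenitor_cluster_id) {
  stopifnot(length(patients) == length(labels))
  if (!progenitor_cluster_id %in% labels)
    aml_stop("progenitor cluster '", progenitor_cluster_id,
             "' absent from labels")
  ids <- sort(unique(patients))
  frac <- vapply(ids, function(p) {
    i <- patients == p
    mean(labels[i] == progenitor_cluster_id)
  }, 0)
  data.frame(patient_id = ids,
             n_cells = as.integer(table(patients)[ids]),
             c1_fraction = frac,
             type = ifelse(frac > 0.5, "I", "II"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Lower tail of the hypergeometric distribution
#'
#' P(X <= k) for X ~ Hypergeometric(N population, K successes, n draws), by
#' direct summation of the point masses.
#'
#' @param k observed successes in the draw
#' @param K successes in the population
#' @param n draws
#' @param N population size
#' @return lower-tail probability
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (!(K <= N && n <= N && k >= 0 && k <= min(K, n)))
    aml_stop("invalid hypergeometric margins")
  sum(dhyper(0:k, m = K, n = N - K, k = n))
}

#' Complete-remission rates by patient type
#'
#' CR rate = CR / (CR + non-CR) per type, as a percentage rounded half-up
#' to two decimals; patients lost to follow-up are excluded from the
#' denominators. The accompanying p-value is the one-sided hypergeometric
#' lower tail for the observed CR count among type I patients given the
#' margins (the natural alternative: a deficit of remissions in type I).
#'
#' @param calls data.frame with `type` ("I"/"II") and `remission` ("CR",
#'   "non-CR", "lost") columns, one row per patient
#' @return list: `rates` (data.frame type, cr, total, rate_percent), `p`
#' @export
remission_rates <- function(calls) {
  stopifnot(all(c("type", "remission") %in% names(calls)))
  kept <- calls[calls$remission != "lost", , drop = FALSE]
  rates <- do.call(rbind, lapply(c("I", "II"), function(ty) {
    sub <- kept[kept$type == ty, , drop = FALSE]
    cr <- sum(sub$remission == "CR"); tot <- nrow(sub)
    if (tot == 0) {
      aml_warn("type ", ty, " empty after exclusions; rate undefined")
      return(data.frame(type = ty, cr = 0L, total = 0L,
                        rate_percent = NA_real_))
    }
    data.frame(type = ty, cr = cr, total = tot,
               rate_percent = round_half_up(100 * cr / tot, 2))
  }))
  n1 <- rates$total[rates$type == "I"]
  k1 <- rates$cr[rates$type == "I"]
  N <- sum(rates$total); K <- sum(rates$cr)
  p <- if (n1 > 0 && N > n1) hypergeom_tail(k1, K, n1, N) else NA_real_
  list(rates = rates, p = p)
}

#' Dominant progenitor group per patient and its outcome association
#'
#' Each patient's dominant group is the plurality group of its progenitor
#' cells over the four phenotype groups (ties follow the fixed priority
#' RP-high > neutrophil-like > monocyte-like > myeloid-like, logged). The
#' association between RP-high dominance and remission is summarized as a
#' 2x2 table with Fisher's exact and one-sided hypergeometric p-values.
#'
#' @param patients per-progenitor-cell patient ids
#' @param groups per-progenitor-cell phenotype group (from
#'   [group_clusters()] applied to the cell's cluster)
#' @param remission named remission status per patient ("CR"/"non-CR"/"lost")
#' @return list: `dominant` (per patient), `table` (2x2), `fisher_p`,
#'   `hypergeom_p`
#' @export
rp_prognosis_table <- function(patients, groups, remission) {
  stopifnot(length(patients) == length(groups))
  ids <- sort(unique(patients))
  if (length(ids) < 2) aml_stop("need at least 2 patients")
  priority <- c("RP-high", "neutrophil-like", "monocyte-like", "myeloid-like")
  dominant <- vapply(ids, function(p) {
    tab <- table(groups[patients == p])
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1) {
      aml_log("rp_prognosis_table", "dominance tie for ", p,
              "; priority order applied")
      best <- priority[priority %in% best][1]
    }
    best
  }, "")
  status <- remission[ids]
  kept <- status %in% c("CR", "non-CR")
  tab <- table(factor(ifelse(dominant[kept] == "RP-high", "RP-high", "other"),
                      levels = c("RP-high", "other")),
               factor(status[kept], levels = c("CR", "non-CR")))
  fisher_p <- fisher.test(tab)$p.value
  # deficit of CR among RP-high-dominant patients
  hg <- hypergeom_tail(tab["RP-high", "CR"], sum(tab[, "CR"]),
                       sum(tab["RP-high", ]), sum(tab))
  list(dominant = setNames(dominant, ids), table = tab,
       fisher_p = fisher_p, hypergeom_p = hg)
}
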