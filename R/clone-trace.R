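#' Filter circular-consensus reads on predicted accuracy
#'
#' Keeps reads whose predicted accuracy is strictly above the cutoff.
#' Reads lacking an accuracy value are kept with a single warning
#' (instrument-filtered input is assumed for such files).
#'
#' @param reads data.frame from [read_reads()]
#' @param min_accuracy strict lower cutoff (default 0.9)
#' @return filtered data.frame
#' @export
filter_ccs <- function(reads, min_accuracy = 0.9) {
  if (nrow(reads) == 0) return(reads)
  na <- is.na(reads$predicted_accuracy)
  if (any(na))
    aml_warn(sum(na), " read(s) lack predicted accuracy; kept unfiltered")
  keep <- na | reads$predicted_accuracy > min_accuracy
  reads[keep, , drop = FALSE]
}

# mismatches between two equal-length strings
str_mismatch <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Parse the microwell barcode/linker structure of one long read
#'
#' Scans the forward strand and then the reverse complement for the layout
#' `ACGT` + CB1(6) + linker1(15) + CB2(6) + linker2(15) + CB3(6) + UMI(6) +
#' polyT(12) + cDNA. Candidate anchors are every exact `ACGT` occurrence
#' plus the read start; at a candidate the anchor may carry at most one
#' mismatch (long reads are error-prone even at the very first bases), each
#' linker at most `max_mm`, and at least 8 of the 12 polyT positions must be
#' T. The leftmost passing window wins; the 12-nt block between linker2 and
#' the polyT is split CB3 = first 6 nt, UMI = last 6 nt.
#'
#' @param seq read sequence (uppercase ACGTN)
#' @param linker1,linker2 fixed linker sequences
#' @param max_mm per-linker mismatch budget (default 2)
#' @param min_polyt minimum T count in the 12-nt polyT block (default 8)
#' @return list with `cb1`, `cb2`, `cb3`, `umi`, `barcode` (18 nt, raw),
#'   `orientation` ("fwd"/"rc"), `mm` (per-linker mismatches), `cdna`;
#'   or `NULL` attributes with `reason` when rejected
#' @export
parse_read <- function(seq, linker1 = "CGACTCACTACAGGG",
                       linker2 = "TCGGTGACACGATCG", max_mm = 2,
                       min_polyt = 8) {
  for (orient in c("fwd", "rc")) {
    s <- if (orient == "fwd") seq else revcomp(seq)
    hit <- parse_one_strand(s, linker1, linker2, max_mm, min_polyt)
    if (!is.null(hit)) {
      hit$orientation <- orient
      return(hit)
    }
  }
  structure(list(reason = attr(parse_one_strand(seq, linker1, linker2,
                                                max_mm, min_polyt,
                                                want_reason = TRUE),
                               "reason") %||% "no-anchor"),
            class = "parse_rejection")
}

parse_one_strand <- function(s, linker1, linker2, max_mm, min_polyt,
                             want_reason = FALSE) {
  need <- 70L  # 4+6+15+6+15+6+6+12
  n <- nchar(s)
  if (n < need) {
    if (want_reason) return(structure(list(), reason = "too-short"))
    return(NULL)
  }
  anchors <- unique(c(1L, as.integer(gregexpr("ACGT", s, fixed = TRUE)[[1]])))
  anchors <- sort(anchors[anchors > 0 & anchors <= n - need + 1L])
  reason <- "no-anchor"
  for (a in anchors) {
    if (str_mismatch(substr(s, a, a + 3L), "ACGT") > 1L) next
    mm1 <- str_mismatch(substr(s, a + 10L, a + 24L), linker1)
    if (mm1 > max_mm) { reason <- "linker1"; next }
    mm2 <- str_mismatch(substr(s, a + 31L, a + 45L), linker2)
    if (mm2 > max_mm) { reason <- "linker2"; next }
    polyt <- substr(s, a + 58L, a + 69L)
    n_t <- nchar(gsub("[^T]", "", polyt))
    if (n_t < min_polyt) { reason <- "polyT"; next }
    cb1 <- substr(s, a + 4L, a + 9L)
    cb2 <- substr(s, a + 25L, a + 30L)
    cb3 <- substr(s, a + 46L, a + 51L)
    umi <- substr(s, a + 52L, a + 57L)
    return(list(cb1 = cb1, cb2 = cb2, cb3 = cb3, umi = umi,
                barcode = paste0(cb1, cb2, cb3),
                mm = c(linker1 = mm1, linker2 = mm2),
                cdna = substr(s, a + 70L, n)))
  }
  if (want_reason) return(structure(list(), reason = reason))
  NULL
}

#' Correct a raw 18-nt barcode against a whitelist
#'
#' Each 6-nt segment is corrected independently: a whitelist segment within
#' `max_seg_mm` mismatches is accepted only when it is unique at the minimal
#' distance; ambiguity (two or more equally close) yields no correction.
#'
#' @param barcode raw 18-nt barcode (or a parse hit's `barcode`)
#' @param whitelist character vector of valid 18-nt barcodes
#' @param max_seg_mm per-segment mismatch budget (default 1)
#' @return corrected 18-nt barcode, or `NA_character_`
#' @export
correct_barcode <- function(barcode, whitelist, max_seg_mm = 1) {
  if (length(whitelist) == 0) aml_stop("empty whitelist")
  segs <- whitelist_segments(whitelist)
  out <- character(3)
  for (i in 1:3) {
    q <- substr(barcode, (i - 1) * 6 + 1, i * 6)
    d <- vapply(segs[[i]], str_mismatch, 0L, a = q)
    best <- min(d)
    if (best > max_seg_mm || sum(d == best) > 1) return(NA_character_)
    out[i] <- segs[[i]][which.min(d)]
  }
  corrected <- paste0(out, collapse = "")
  if (!corrected %in% whitelist) NA_character_ else corrected
}

# per-slot unique segments of an 18-nt whitelist (cached on the vector)
whitelist_segments <- function(whitelist) {
  lapply(1:3, function(i) unique(substr(whitelist, (i - 1) * 6 + 1, i * 6)))
}

#' Parse and demultiplex a set of long reads
#'
#' [parse_read()] applied to every read, followed by [correct_barcode()]
#' against the whitelist. Vectorized bookkeeping of rejection reasons.
#'
#' @param reads data.frame from [read_reads()] (after [filter_ccs()])
#' @param whitelist 18-nt cell barcodes from the short-read experiment
#' @param max_mm,min_polyt passed to [parse_read()]
#' @param max_seg_mm passed to [correct_barcode()]
#' @return data.frame: read_id, parsed, reason, orientation, barcode (raw),
#'   corrected, umi, cdna
#' @export
demux_reads <- function(reads, whitelist, max_mm = 2, min_polyt = 8,
                        max_seg_mm = 1) {
  n <- nrow(reads)
  out <- data.frame(read_id = reads$read_id, parsed = FALSE,
                    reason = NA_character_, orientation = NA_character_,
                    barcode = NA_character_, corrected = NA_character_,
                    umi = NA_character_, cdna = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    hit <- parse_read(reads$sequence[i], max_mm = max_mm,
                      min_polyt = min_polyt)
    if (inherits(hit, "parse_rejection")) {
      out$reason[i] <- hit$reason
      next
    }
    out$parsed[i] <- TRUE
    out$orientation[i] <- hit$orientation
    out$barcode[i] <- hit$barcode
    out$umi[i] <- hit$umi
    out$cdna[i] <- hit$cdna
    out$corrected[i] <- correct_barcode(hit$barcode, whitelist, max_seg_mm)
  }
  aml_log("demux_reads", sprintf("%d/%d reads parsed, %d barcodes corrected",
                                 sum(out$parsed), n, sum(!is.na(out$corrected))))
  out
}

#' Align a cDNA fragment to a single-gene target reference
#'
#' K-mer seeded gapless extension, suited to consensus long reads whose
#' residual errors are substitutions: exact k-mer seeds locate the diagonal
#' on either strand, the full overlap along that diagonal is scored, and the
#' best diagonal is reported. "Well-mapped" means aligned fraction >=
#' `min_frac` of the cDNA and identity >= `min_ident` over the overlap.
#'
#' @param cdna query sequence
#' @param target target transcript sequence (length >= 50)
#' @param k seed length (default 12)
#' @param seed_stride try seeds every this many bases (default 8)
#' @param min_frac minimum aligned fraction of the cDNA (default 0.8)
#' @param min_ident minimum identity over the aligned span (default 0.9)
#' @param index precomputed [kmer_index()] of the target (built when NULL)
#' @return list: `mapped`, and for mapped queries `strand` ("+"/"-"),
#'   `target_start` (0-based), `target_end` (half-open), `identity`,
#'   `aligned_frac`, `offset` (target minus query position, 0-based) and
#'   `query` (the strand-adjusted query sequence)
#' @export
align_target <- function(cdna, target, k = 12, seed_stride = 8,
                         min_frac = 0.8, min_ident = 0.9, index = NULL) {
  if (nchar(target) < 50) aml_stop("target must be >= 50 bases")
  idx <- index %||% kmer_index(target, k)
  for (strand in c("+", "-")) {
    q <- if (strand == "+") cdna else revcomp(cdna)
    nq <- nchar(q)
    if (nq < k) next
    starts <- unique(c(seq(1L, nq - k + 1L, by = seed_stride), nq - k + 1L))
    diags <- integer(0)
    for (s in starts) {
      hits <- idx[[substr(q, s, s + k - 1L)]]
      if (!is.null(hits)) diags <- c(diags, hits - s)
    }
    if (length(diags) == 0) next
    diags <- sort(unique(diags))
    best <- NULL
    qv <- charToRaw(q)
    tv <- charToRaw(target)
    nt <- length(tv)
    for (d in diags) {
      q_lo <- max(1L, 1L - d); q_hi <- min(nq, nt - d)
      if (q_hi - q_lo + 1L < k) next
      qs <- qv[q_lo:q_hi]
      ts <- tv[(q_lo + d):(q_hi + d)]
      matches <- sum(qs == ts)
      ident <- matches / length(qs)
      frac <- length(qs) / nq
      if (is.null(best) || matches > best$matches)
        best <- list(matches = matches, ident = ident, frac = frac, d = d,
                     q_lo = q_lo, q_hi = q_hi)
    }
    if (!is.null(best) && best$ident >= min_ident && best$frac >= min_frac) {
      return(list(mapped = TRUE, strand = strand,
                  target_start = best$q_lo + best$d - 1L,
                  target_end = best$q_hi + best$d,
                  identity = best$ident, aligned_frac = best$frac,
                  offset = best$d, query = q))
    }
  }
  list(mapped = FALSE, reason = "unaligned")
}

#' Hash of all k-mer start positions (1-based) in a sequence
#' @param seq character scalar
#' @param k k-mer length
#' @return named list mapping k-mer to start positions
#' @export
kmer_index <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  kmers <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  split(seq_len(n), kmers)
}

#' Call heteroplasmic variants from demultiplexed, aligned reads
#'
#' Reads sharing a (cell, UMI) pair are collapsed to a per-UMI consensus
#' base at every covered target position (majority; ties give N, which is
#' ignored downstream). Per cell, the UMI consensus bases form a pileup; a
#' site is reported for a cell when depth >= `min_cell_depth`, the
#' alternate count >= `min_alt` and the alternate fraction (alt/depth) >=
#' `min_frac`. Heteroplasmy is that fraction.
#'
#' @param demux data.frame from [demux_reads()] (corrected barcodes needed)
#' @param target target transcript sequence
#' @param min_cell_depth minimum UMI depth at the site (default 20)
#' @param min_frac minimum alternate fraction (default 0.05)
#' @param min_alt minimum alternate UMI count (default 3)
#' @param align_args list of extra arguments for [align_target()]
#' @return list: `calls` (data.frame: barcode, pos (0-based), ref, alt,
#'   depth, alt_count, het) and `site_summary` (per-site totals)
#' @export
call_variants <- function(demux, target, min_cell_depth = 20,
                          min_frac = 0.05, min_alt = 3,
                          align_args = list()) {
  ok <- demux$parsed & !is.na(demux$corrected)
  d <- demux[ok, , drop = FALSE]
  tlen <- nchar(target)
  tvec <- strsplit(toupper(target), "")[[1]]
  base_levels <- c("A", "C", "G", "T")
  if (is.null(align_args$index))
    align_args$index <- kmer_index(target, align_args$k %||% 12)

  ## per-(cell,UMI) consensus: base votes per molecule
  key <- paste(d$corrected, d$umi, sep = "|")
  umi_ids <- unique(key)
  # votes[base, pos] accumulated per UMI, then a consensus base per position
  cell_of_umi <- d$corrected[match(umi_ids, key)]
  per_cell <- list()
  for (u in seq_along(umi_ids)) {
    rows <- which(key == umi_ids[u])
    votes <- matrix(0L, 4, tlen)
    covered <- rep(FALSE, tlen)
    for (i in rows) {
      aln <- do.call(align_target, c(list(d$cdna[i], target), align_args))
      if (!aln$mapped) next
      qpos <- (aln$target_start - aln$offset + 1L):(aln$target_end - aln$offset)
      bases <- strsplit(aln$query, "")[[1]][qpos]
      tpos <- (aln$target_start + 1L):aln$target_end
      bi <- match(bases, base_levels)
      keep <- !is.na(bi)
      votes[cbind(bi[keep], tpos[keep])] <-
        votes[cbind(bi[keep], tpos[keep])] + 1L
      covered[tpos[keep]] <- TRUE
    }
    if (!any(covered)) next
    cons <- rep(NA_integer_, tlen)
    cov_idx <- which(covered)
    vm <- votes[, cov_idx, drop = FALSE]
    top <- apply(vm, 2, function(v) {
      m <- max(v)
      w <- which(v == m)
      if (length(w) > 1) NA_integer_ else w  # tie -> N
    })
    cons[cov_idx] <- top
    cell <- cell_of_umi[u]
    if (is.null(per_cell[[cell]]))
      per_cell[[cell]] <- matrix(0L, 4, tlen, dimnames = list(base_levels, NULL))
    hit <- which(!is.na(cons))
    per_cell[[cell]][cbind(cons[hit], hit)] <-
      per_cell[[cell]][cbind(cons[hit], hit)] + 1L
  }

  calls <- list()
  for (cell in names(per_cell)) {
    pile <- per_cell[[cell]]
    depth <- colSums(pile)
    ref_i <- match(tvec, base_levels)
    for (pos in which(depth >= min_cell_depth)) {
      if (is.na(ref_i[pos])) next
      alt_counts <- pile[, pos]
      alt_counts[ref_i[pos]] <- 0L
      ai <- which.max(alt_counts)
      ac <- alt_counts[ai]
      if (ac >= min_alt && ac / depth[pos] >= min_frac)
        calls[[length(calls) + 1L]] <-
          data.frame(barcode = cell, pos = pos - 1L, ref = tvec[pos],
                     alt = base_levels[ai], depth = depth[pos],
                     alt_count = ac, het = ac / depth[pos],
                     stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls)
  else data.frame(barcode = character(), pos = integer(), ref = character(),
                  alt = character(), depth = integer(), alt_count = integer(),
                  het = numeric(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  site <- if (nrow(calls))
    aggregate(list(n_cells = calls$barcode),
              by = list(pos = calls$pos, ref = calls$ref, alt = calls$alt),
              FUN = length)
  else data.frame(pos = integer(), ref = character(), alt = character(),
                  n_cells = integer())
  list(calls = calls, site_summary = site)
}

#' Filter per-cell variant calls to clone-informative sites
#'
#' Sequencing error produces sporadic low-fraction calls that are private to
#' single cells; clone-defining heteroplasmic variants recur across cells at
#' substantial fractions. Sites are therefore kept only when called in at
#' least `min_cells_per_site` cells with mean heteroplasmy at least
#' `min_site_het`, and individual cell-level calls below `min_cell_het` are
#' dropped — the usual practice before mitochondrial lineage inference.
#'
#' @param calls `$calls` data.frame from [call_variants()]
#' @param min_cells_per_site minimum cells carrying the site (default 3)
#' @param min_site_het minimum mean heteroplasmy over carriers (default 0.2)
#' @param min_cell_het minimum per-cell heteroplasmy (default 0.1)
#' @return filtered calls data.frame
#' @export
filter_variant_calls <- function(calls, min_cells_per_site = 3,
                                 min_site_het = 0.2, min_cell_het = 0.1) {
  if (nrow(calls) == 0) return(calls)
  keep_cell <- calls$het >= min_cell_het
  calls <- calls[keep_cell, , drop = FALSE]
  if (nrow(calls) == 0) return(calls)
  site <- paste0(calls$pos, calls$ref, ">", calls$alt)
  n_cells <- tapply(calls$barcode, site, length)
  mean_het <- tapply(calls$het, site, mean)
  good <- names(n_cells)[n_cells >= min_cells_per_site &
                           mean_het >= min_site_het]
  out <- calls[site %in% good, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign cells to clones by their variant intersection pattern
#'
#' Each cell's set of detected variants defines its pattern; every distinct
#' pattern is a clone (the variant-free pattern is the wild-type clone).
#' Clones carried by fewer than `min_cells` cells are merged into
#' "unassigned". The intersection table — pattern against cell count,
#' sorted descending — is the tabular form of an UpSet plot.
#'
#' @param calls data.frame from [call_variants()] (`$calls`), or any
#'   data.frame with `barcode` and variant id columns `pos`/`alt`
#' @param all_cells optional vector of all genotyped cell barcodes (cells
#'   with no calls then appear as wild-type)
#' @param min_cells minimum clone size (default 3)
#' @return list: `assignment` (data.frame barcode, clone, pattern),
#'   `clones` (clone, pattern, n_cells), `intersections` (pattern, n_cells)
#' @export
assign_clones <- function(calls, all_cells = NULL, min_cells = 3) {
  if (nrow(calls) == 0 && is.null(all_cells)) {
    aml_warn("no variant calls and no cell list: empty assignment")
    return(list(assignment = data.frame(barcode = character(),
                                        clone = character(),
                                        pattern = character()),
                clones = data.frame(), intersections = data.frame()))
  }
  var_id <- if (nrow(calls)) paste0(calls$pos, calls$ref, ">", calls$alt)
  else character(0)
  cells <- unique(c(all_cells, calls$barcode))
  pattern <- vapply(cells, function(cb) {
    v <- sort(unique(var_id[calls$barcode == cb]))
    if (length(v) == 0) "WT" else paste(v, collapse = "+")
  }, "")
  tab <- sort(table(pattern), decreasing = TRUE)
  clone_of_pattern <- setNames(paste0("clone", seq_along(tab)), names(tab))
  clone_of_pattern[names(tab)[tab < min_cells]] <- "unassigned"
  if ("WT" %in% names(clone_of_pattern) &&
      clone_of_pattern[["WT"]] != "unassigned")
    clone_of_pattern[["WT"]] <- "WT"
  assignment <- data.frame(barcode = cells,
                           clone = unname(clone_of_pattern[pattern]),
                           pattern = unname(pattern),
                           stringsAsFactors = FALSE)
  clones <- data.frame(clone = unname(clone_of_pattern[names(tab)]),
                       pattern = names(tab),
                       n_cells = as.integer(tab), stringsAsFactors = FALSE)
  inter <- data.frame(pattern = names(tab), n_cells = as.integer(tab),
                      stringsAsFactors = FALSE)
  list(assignment = assignment, clones = clones, intersections = inter)
}

#' Association between clones and transcriptomic clusters
#'
#' Cramér's V of the clone-by-cluster contingency table with a permutation
#' p-value (clone labels shuffled `n_perm` times; p = (1 + #perm >= obs) /
#' (1 + n_perm)). Low V with a flat p indicates clones decoupled from cell
#' phenotype.
#'
#' @param clones named clone labels (names = barcodes)
#' @param clusters named cluster labels (names = barcodes)
#' @param n_perm permutations (default 1000)
#' @param seed integer seed
#' @return list: `table`, `cramers_v`, `p`, `n_shared`, `low_power` flag
#' @export
clone_phenotype_assoc <- function(clones, clusters, n_perm = 1000, seed = 1) {
  shared <- intersect(names(clones), names(clusters))
  cl <- clones[shared]; cu <- clusters[shared]
  if (length(unique(cl)) < 2 || length(unique(cu)) < 2)
    aml_stop("need >= 2 clones and >= 2 clusters among shared cells")
  low_power <- length(shared) < 20
  if (low_power) aml_warn("fewer than 20 shared cells; association is ",
                          "estimated with wide uncertainty")
  v_obs <- cramers_v(table(cl, cu))
  perm <- with_seed(seed, replicate(n_perm, cramers_v(table(sample(cl), cu))))
  p <- (1 + sum(perm >= v_obs)) / (1 + n_perm)
  list(table = table(cl, cu), cramers_v = v_obs, p = p,
       n_shared = length(shared), low_power = low_power)
}

#' Cramér's V of a contingency table
#' @param tab a table or matrix of counts
#' @return scalar in `[0, 1]`
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected, na.rm = TRUE)
  k <- min(nrow(tab), ncol(tab)) - 1
  if (k < 1) return(0)
  sqrt(chi2 / (n * k))
}
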