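test_that("CCS filter is strict and tolerates missing accuracy", {
  rd <- data.frame(read_id = c("a", "b", "c"), sequence = "ACGT",
                   quality = NA, predicted_accuracy = c(0.89, 0.90, 0.95))
  kept <- filter_ccs(rd)
  expect_equal(kept$read_id, "c")  # 0.90 dropped: strictly above 0.9
  rd$predicted_accuracy <- NA
  expect_warning(all_kept <- filter_ccs(rd), "lack predicted accuracy")
  expect_equal(nrow(all_kept), 3)
  expect_equal(nrow(filter_ccs(rd[0, ])), 0)
})

test_that("the constructed pattern read parses into its segments", {
  cdna <- rand_dna(120, seed = 7)
  read <- build_read(cdna = cdna)
  hit <- parse_read(read)
  expect_equal(hit$cb1, "AAAAAA")
  expect_equal(hit$cb2, "CCCCCC")
  expect_equal(hit$cb3, "GGGGGG")
  expect_equal(hit$umi, "TTTTTT")
  expect_equal(hit$orientation, "fwd")
  expect_equal(hit$cdna, cdna)
  # strand symmetry: the reverse complement parses identically as rc
  hit_rc <- parse_read(revcomp(read))
  expect_equal(hit_rc$barcode, hit$barcode)
  expect_equal(hit_rc$umi, hit$umi)
  expect_equal(hit_rc$cdna, hit$cdna)
  expect_equal(hit_rc$orientation, "rc")
})

test_that("reads failing a linker budget are rejected with a reason", {
  bad1 <- build_read(cdna = rand_dna(50, 8))
  substr(bad1, 11, 13) <- "TTT"  # 3 mismatches into linker1
  rej <- parse_read(bad1, max_mm = 2)
  expect_s3_class(rej, "parse_rejection")
  expect_equal(rej$reason, "linker1")
  short <- "ACGTACGT"
  expect_s3_class(parse_read(short), "parse_rejection")
})

test_that("parse tolerates within-budget errors anywhere in the layout", {
  read <- build_read(cdna = rand_dna(80, 9))
  substr(read, 12, 12) <- "A"   # 1 error in linker1
  substr(read, 33, 33) <- "A"   # 1 error in linker2
  substr(read, 60, 61) <- "CA"  # 2 errors in polyT (10/12 T remain)
  hit <- parse_read(read)
  expect_false(inherits(hit, "parse_rejection"))
  expect_equal(unname(hit$mm["linker1"]), 1)
})

test_that("barcode correction is exact, 1-mm tolerant, and ambiguity-safe", {
  wl <- c("AAAAAACCCCCCGGGGGG", "TTTTTTGGGGGGAAAAAA")
  expect_equal(correct_barcode(wl[1], wl), wl[1])
  mut <- wl[1]
  substr(mut, 8, 8) <- "A"  # one substitution in CB2
  expect_equal(correct_barcode(mut, wl), wl[1])
  # two whitelist segments both at distance 1: ambiguous, no correction
  wl2 <- c("AAAAAACCCCCCGGGGGG", "AAAAAGCCCCCCGGGGGG")
  q <- "AAAAACCCCCCCGGGGGG"  # distance 1 from segment1 of both
  expect_true(is.na(correct_barcode(q, wl2, max_seg_mm = 1)))
  expect_error(correct_barcode(wl[1], character(0)), "empty whitelist")
})

test_that("alignment is exact for substrings and rejects random queries", {
  target <- rand_dna(400, seed = 10)
  q <- substr(target, 101, 250)
  aln <- align_target(q, target)
  expect_true(aln$mapped)
  expect_equal(aln$identity, 1)
  expect_equal(aln$target_start, 100L)
  expect_equal(aln$target_end, 250L)
  expect_equal(aln$strand, "+")
  # the reverse complement maps on the minus strand
  aln2 <- align_target(revcomp(q), target)
  expect_true(aln2$mapped)
  expect_equal(aln2$strand, "-")
  # ~5% substitutions still map with about 0.95 identity
  set.seed(11)
  qv <- strsplit(q, "")[[1]]
  pos <- sample(length(qv), 8)
  for (i in pos) qv[i] <- setdiff(c("A", "C", "G", "T"), qv[i])[1]
  aln3 <- align_target(paste(qv, collapse = ""), target)
  expect_true(aln3$mapped)
  expect_equal(aln3$identity, 1 - 8 / 150, tolerance = 0.02)
  # an unrelated sequence does not map
  expect_false(align_target(rand_dna(150, 12), target)$mapped)
})

test_that("variant calling arithmetic honors depth and count thresholds", {
  # synthetic demux table: 1 cell, 100 UMIs covering a 60-base target
  target <- rand_dna(60, seed = 13)
  ref30 <- substr(target, 31, 31)
  alt <- setdiff(c("A", "C", "G", "T"), ref30)[1]
  mk_cdna <- function(has_alt) {
    s <- target
    if (has_alt) substr(s, 31, 31) <- alt
    s
  }
  n_alt <- 30
  demux <- data.frame(read_id = sprintf("r%03d", 1:100), parsed = TRUE,
                      reason = NA, orientation = "fwd",
                      barcode = "B", corrected = "AAAAAACCCCCCGGGGGG",
                      umi = sprintf("U%03d", 1:100),
                      cdna = vapply(1:100, function(i) mk_cdna(i <= n_alt), ""),
                      stringsAsFactors = FALSE)
  vc <- call_variants(demux, target, min_cell_depth = 20)
  expect_equal(nrow(vc$calls), 1)
  expect_equal(vc$calls$pos, 30L)  # 0-based
  expect_equal(vc$calls$het, 0.30)
  expect_equal(vc$calls$depth, 100L)
  # 2 alt / 100 with min_alt = 3: not reported
  demux$cdna <- vapply(1:100, function(i) mk_cdna(i <= 2), "")
  vc2 <- call_variants(demux, target, min_cell_depth = 20, min_alt = 3)
  expect_equal(nrow(vc2$calls), 0)
})

test_that("per-UMI consensus outvotes a minority read error", {
  target <- rand_dna(60, seed = 14)
  ref10 <- substr(target, 11, 11)
  alt <- setdiff(c("A", "C", "G", "T"), ref10)[1]
  err <- target
  substr(err, 11, 11) <- alt
  # 3 reads on one UMI: 2 clean, 1 with the error -> consensus clean
  demux <- data.frame(read_id = c("r1", "r2", "r3"), parsed = TRUE,
                      reason = NA, orientation = "fwd", barcode = "B",
                      corrected = "AAAAAACCCCCCGGGGGG", umi = "U1",
                      cdna = c(target, target, err), stringsAsFactors = FALSE)
  vc <- call_variants(demux, target, min_cell_depth = 1, min_alt = 1)
  expect_equal(nrow(vc$calls), 0)
})

test_that("clone assignment groups distinct variant patterns", {
  calls <- data.frame(barcode = c("c1", "c2", "c3", "c3"),
                      pos = c(5, 5, 5, 9), ref = "A", alt = "T",
                      depth = 50, alt_count = 25, het = 0.5)
  cl <- assign_clones(calls, min_cells = 1)
  expect_equal(nrow(cl$clones), 2)
  expect_equal(sort(cl$clones$n_cells, decreasing = TRUE), c(2, 1))
  # pattern-free cells form a wild-type clone
  cl2 <- assign_clones(calls[0, ], all_cells = c("x", "y", "z"))
  expect_equal(unique(cl2$assignment$clone), "WT")
  # intersection table is sorted descending
  expect_true(!is.unsorted(rev(cl$intersections$n_cells)))
})

test_that("variant-call filtering removes sporadic error calls", {
  good <- data.frame(barcode = sprintf("c%02d", 1:10), pos = 5, ref = "A",
                     alt = "T", depth = 50, alt_count = 25, het = 0.5)
  noise <- data.frame(barcode = "c01", pos = 17, ref = "G", alt = "C",
                      depth = 50, alt_count = 3, het = 0.06)
  fc <- filter_variant_calls(rbind(good, noise))
  expect_true(all(fc$pos == 5))
  expect_equal(nrow(fc), 10)
})

test_that("clone-phenotype association separates coupling from independence", {
  set.seed(15)
  n <- 200
  clusters <- setNames(sample(c("k1", "k2"), n, TRUE),
                       sprintf("c%03d", 1:n))
  coupled <- setNames(ifelse(clusters == "k1", "m1", "m2"), names(clusters))
  a <- clone_phenotype_assoc(coupled, clusters, n_perm = 200, seed = 1)
  expect_equal(a$cramers_v, 1)
  expect_lte(a$p, 1 / 201 + 1e-12)
  indep <- setNames(sample(c("m1", "m2"), n, TRUE), names(clusters))
  b <- clone_phenotype_assoc(indep, clusters, n_perm = 200, seed = 2)
  expect_lt(b$cramers_v, 0.2)
  expect_gt(b$p, 0.05)
  expect_error(clone_phenotype_assoc(setNames(rep("m1", n), names(clusters)),
                                     clusters), "2 clones")
})
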