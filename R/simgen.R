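#' Simulate a multi-patient bone-marrow mononuclear cell (BMMC) cohort
#'
#' Generates gene-by-cell UMI counts with the statistical structure the
#' analysis pipeline assumes: discrete normal lineages (HSPC-like, neutrophil,
#' monocyte, erythroid, lymphoid) each with exclusive marker genes, plus a
#' malignant-progenitor population that shares the HSPC-like base profile and
#' additionally expresses one of `n_programs` shared transcriptional programs
#' and (for the first program) a ribosomal-protein-like module. Per-patient
#' batch effects are log-normal per-gene factors, the simplest structure that
#' makes naive pooled clustering split by patient. Counts follow a
#' gamma-Poisson (negative binomial) model with configurable dispersion.
#'
#' Malignant cells also carry a clone label (for mitochondrial lineage
#' tracing) drawn independently of the expression program, emulating the
#' observed decoupling of genetic subclones from cell phenotype.
#'
#' @param n_patients number of patients
#' @param cells_per_patient cells per patient before QC
#' @param n_genes total genes (includes `n_mito` mitochondrial genes)
#' @param program_size genes per shared malignant program
#' @param rp_size genes in the ribosomal-protein-like module
#' @param batch_sd SD of per-patient per-gene log2 batch factors
#' @param malignant_frac fraction of each patient's cells that are malignant
#'   (scalar or one value per patient)
#' @param program_log2fc log2 fold elevation of program genes in their cells
#' @param rp_log2fc log2 fold elevation of RP-like genes in RP-high cells
#' @param n_programs number of shared malignant programs (RP module rides on
#'   program 1)
#' @param markers_per_type exclusive marker genes per normal lineage
#' @param marker_log2fc log2 fold elevation of lineage markers
#' @param dispersion gamma-Poisson dispersion (1/size); 0 gives pure Poisson
#' @param depth_meanlog,depth_sdlog log-normal library-size parameters
#' @param n_mito number of mitochondria-encoded genes (ids prefixed `MT-`)
#' @param mito_base_frac expected fraction of a healthy cell's UMIs from
#'   mitochondrial genes
#' @param low_quality_frac fraction of cells simulated as dying/low-depth
#'   (shallow library, inflated mitochondrial content) for QC to remove
#' @param n_clones mitochondrial clones per patient (malignant cells only)
#' @param seed integer seed; same seed gives bit-identical output
#' @return list with `counts` (CountMatrix; metadata carries `patient_id`,
#'   `lineage`, `program`, `clone_id`) and `truth` (list: `cells` data.frame,
#'   `genes` data.frame with role/log2fc, and the parameter set)
#' @export
simulate_bmmc <- function(n_patients = 3, cells_per_patient = 1000,
                          n_genes = 2000, program_size = 100, rp_size = 50,
                          batch_sd = 0.5, malignant_frac = 0.5,
                          program_log2fc = 2, rp_log2fc = 2, n_programs = 2,
                          markers_per_type = 20, marker_log2fc = 3,
                          dispersion = 0.3, depth_meanlog = log(2500),
                          depth_sdlog = 0.35, n_mito = 10,
                          mito_base_frac = 0.05, low_quality_frac = 0.02,
                          n_clones = 3, seed = 1) {
  stopifnot(n_patients >= 1, cells_per_patient >= 1, n_genes >= 1,
            program_size >= 1, rp_size >= 0, n_programs >= 1,
            all(malignant_frac >= 0), all(malignant_frac <= 1),
            length(malignant_frac) %in% c(1L, n_patients))
  malignant_frac <- rep_len(malignant_frac, n_patients)
  lineages <- c("HSPC", "neutrophil", "monocyte", "erythroid", "lymphoid")
  n_marker <- markers_per_type * length(lineages)
  n_special <- n_programs * program_size + rp_size + n_marker + n_mito
  if (n_special > n_genes)
    aml_stop("program, RP, marker and mito genes exceed n_genes (",
             n_special, " > ", n_genes, ")")

  with_seed(seed, {
    ## ---- gene roles ----
    gene_ids <- sprintf("gene%05d", seq_len(n_genes - n_mito - rp_size))
    rp_ids <- if (rp_size > 0) sprintf("RPL-like%03d", seq_len(rp_size)) else character()
    mito_ids <- sprintf("MT-gene%02d", seq_len(n_mito))
    gene_ids <- c(gene_ids, rp_ids, mito_ids)
    role <- rep("background", n_genes)
    names(role) <- gene_ids
    idx <- 1L
    prog_sets <- list()
    for (p in seq_len(n_programs)) {
      prog_sets[[p]] <- gene_ids[idx:(idx + program_size - 1L)]
      role[prog_sets[[p]]] <- paste0("program", p)
      idx <- idx + program_size
    }
    marker_sets <- list()
    for (t in lineages) {
      marker_sets[[t]] <- gene_ids[idx:(idx + markers_per_type - 1L)]
      role[marker_sets[[t]]] <- paste0("marker:", t)
      idx <- idx + markers_per_type
    }
    role[rp_ids] <- "rp"
    role[mito_ids] <- "mito"

    ## ---- cells ----
    n_cells <- n_patients * cells_per_patient
    patient <- rep(sprintf("P%02d", seq_len(n_patients)), each = cells_per_patient)
    lineage <- character(n_cells)
    program <- rep(NA_integer_, n_cells)
    clone <- rep(NA_character_, n_cells)
    for (pi in seq_len(n_patients)) {
      p <- unique(patient)[pi]
      cells_p <- which(patient == p)
      n_mal <- round(malignant_frac[pi] * length(cells_p))
      mal <- cells_p[seq_len(n_mal)]
      lineage[mal] <- "malignant"
      if (n_mal > 0) {
        program[mal] <- sample(rep_len(seq_len(n_programs), n_mal))
        clone_probs <- (n_clones:1) / sum(n_clones:1)
        clone[mal] <- paste0(p, "_clone", sample(n_clones, n_mal, replace = TRUE,
                                                 prob = clone_probs))
      }
      normal <- setdiff(cells_p, mal)
      lineage[normal] <- sample(rep_len(lineages, length(normal)))
    }
    barcodes <- make_cell_barcodes(n_cells)
    low_q <- runif(n_cells) < low_quality_frac

    ## ---- log2 rate model ----
    base <- rnorm(n_genes, 0, 1.5)          # log2 relative abundance
    base[role == "mito"] <- log2(mito_base_frac * 2^mean(base) * n_genes / n_mito)
    L2 <- matrix(base, n_genes, n_cells)    # genes x cells log2 rates
    batch <- matrix(rnorm(n_genes * n_patients, 0, batch_sd), n_genes, n_patients)
    L2 <- L2 + batch[, match(patient, unique(patient)), drop = FALSE]
    for (t in lineages) {
      cols <- lineage == t
      if (any(cols)) L2[gene_ids %in% marker_sets[[t]], cols] <-
        L2[gene_ids %in% marker_sets[[t]], cols] + marker_log2fc
    }
    mal_cols <- lineage == "malignant"
    if (any(mal_cols)) {
      # progenitors keep a dampened HSPC-like identity plus their program
      L2[gene_ids %in% marker_sets[["HSPC"]], mal_cols] <-
        L2[gene_ids %in% marker_sets[["HSPC"]], mal_cols] + marker_log2fc / 2
      for (p in seq_len(n_programs)) {
        cols <- mal_cols & !is.na(program) & program == p
        if (any(cols)) L2[gene_ids %in% prog_sets[[p]], cols] <-
          L2[gene_ids %in% prog_sets[[p]], cols] + program_log2fc
      }
      rp_cols <- mal_cols & !is.na(program) & program == 1L
      if (rp_size > 0 && any(rp_cols)) L2[role == "rp", rp_cols] <-
        L2[role == "rp", rp_cols] + rp_log2fc
    }

    ## ---- gamma-Poisson sampling ----
    depth <- exp(rnorm(n_cells, depth_meanlog, depth_sdlog))
    depth[low_q] <- depth[low_q] * 0.15
    rate <- 2^L2
    if (any(low_q))  # dying cells leak cytoplasmic RNA, mito fraction rises
      rate[role == "mito", low_q] <- rate[role == "mito", low_q] * 8
    rate <- sweep(rate, 2, colSums(rate), "/")
    lambda <- sweep(rate, 2, depth, "*")
    if (dispersion > 0)
      lambda <- lambda * matrix(rgamma(length(lambda), shape = 1 / dispersion,
                                       scale = dispersion), n_genes, n_cells)
    counts <- matrix(rpois(length(lambda), lambda), n_genes, n_cells)

    meta <- data.frame(barcode = barcodes, patient_id = patient,
                       lineage = lineage, program = program, clone_id = clone,
                       stringsAsFactors = FALSE)
    cm <- CountMatrix(counts, gene_ids, barcodes, cell_meta = meta)
    truth <- list(
      cells = meta,
      genes = data.frame(gene_id = gene_ids, role = unname(role),
                         stringsAsFactors = FALSE),
      marker_sets = marker_sets, program_sets = prog_sets, rp_genes = rp_ids,
      params = list(n_patients = n_patients, batch_sd = batch_sd,
                    program_log2fc = program_log2fc, rp_log2fc = rp_log2fc,
                    marker_log2fc = marker_log2fc, dispersion = dispersion,
                    seed = seed))
    list(counts = cm, truth = truth)
  })
}

# 18-nt (3 x 6-nt) cell barcodes whose per-slot segment sets have pairwise
# Hamming distance >= 4, emulating designed microwell bead barcode sets;
# segments come from the hexacode (a [6,3,4] linear code over GF(4))
make_cell_barcodes <- function(n) {
  per_slot <- ceiling(n^(1 / 3)) + 2L
  if (per_slot > 64L)
    aml_stop("barcode space exhausted: at most ", 62L^3, " cells supported")
  segs <- lapply(1:3, function(s) sample(hexacode_segments(), per_slot))
  grid <- expand.grid(a = segs[[1]], b = segs[[2]], c = segs[[3]],
                      stringsAsFactors = FALSE)
  grid <- grid[sample(nrow(grid)), , drop = FALSE]
  paste0(grid$a, grid$b, grid$c)[seq_len(n)]
}

# the 64 hexacode words as 6-mers: (a, b, c, f(1), f(w), f(w^2)) with
# f(x) = a x^2 + b x + c over GF(4); minimum pairwise distance 4
hexacode_segments <- function() {
  add <- function(x, y) bitwXor(x, y)
  mul_tab <- matrix(c(0, 0, 0, 0,
                      0, 1, 2, 3,
                      0, 2, 3, 1,
                      0, 3, 1, 2), 4, 4, byrow = TRUE)
  mul <- function(x, y) mul_tab[x + 1, y + 1]
  f <- function(a, b, c, x) add(add(mul(a, mul(x, x)), mul(b, x)), c)
  words <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(nrow(words)), function(i) {
    a <- words$a[i]; b <- words$b[i]; c <- words$c[i]
    code <- c(a, b, c, f(a, b, c, 1), f(a, b, c, 2), f(a, b, c, 3))
    paste(bases[code + 1], collapse = "")
  }, "")
}

#' Simulate PacBio-like targeted long reads with microwell barcodes
#'
#' Each read follows the microwell bead layout: `ACGT` anchor, three 6-nt
#' barcode segments separated by two fixed linkers, a 6-nt UMI, a 12-nt polyT
#' stretch, then the cDNA (reverse complement of the target transcript, as a
#' 3'-primed cDNA reads back from the polyA). A cell's planted heteroplasmic
#' variants appear on each cDNA molecule independently with the variant's
#' heteroplasmy fraction; i.i.d. substitution errors are applied to the whole
#' read; a configurable fraction of reads is flipped to the opposite strand.
#'
#' @param cell_barcodes character vector of 18-nt cell barcodes
#' @param clone_map named character vector mapping barcode -> clone id
#' @param target character target transcript sequence (length >= 50)
#' @param variants data.frame with `pos` (0-based on target), `alt` base,
#'   `clones` (list column or ";"-separated clone ids carrying the variant),
#'   `het` heteroplasmy fraction in carriers
#' @param n_reads_per_cell reads (one UMI each) per cell
#' @param sub_error_rate per-base substitution error probability
#' @param rc_fraction fraction of reads emitted reverse-complemented
#' @param accuracy predicted CCS accuracy written as an `rq=` header tag
#' @param fastq_path optional path; when given, reads are written as FASTQ
#' @param linker1,linker2 fixed linker sequences
#' @param seed integer seed
#' @return list with `reads` (data.frame: read_id, sequence, quality,
#'   predicted_accuracy) and `truth` (per-read cell, UMI, variant alleles)
#' @export
simulate_long_reads <- function(cell_barcodes, clone_map, target, variants,
                                n_reads_per_cell = 50, sub_error_rate = 0.02,
                                rc_fraction = 0.5, accuracy = 0.99,
                                fastq_path = NULL,
                                linker1 = "CGACTCACTACAGGG",
                                linker2 = "TCGGTGACACGATCG", seed = 1) {
  if (any(nchar(cell_barcodes) != 18L))
    aml_stop("cell barcodes must be 18 nt (three 6-nt segments)")
  target <- toupper(target)
  if (nrow(variants) > 0 && any(variants$pos < 0 | variants$pos >= nchar(target)))
    aml_stop("variant positions outside target")
  carr <- variants_carriers(variants)

  with_seed(seed, {
    n_reads <- length(cell_barcodes) * n_reads_per_cell
    if (n_reads == 0) {
      if (!is.null(fastq_path)) writeLines(character(0), fastq_path)
      return(list(reads = data.frame(read_id = character(),
                                     sequence = character(),
                                     quality = character(),
                                     predicted_accuracy = numeric()),
                  truth = data.frame(read_id = character(),
                                     barcode = character(), umi = character(),
                                     clone = character())))
    }
    bc <- rep(cell_barcodes, each = n_reads_per_cell)
    clone <- unname(clone_map[bc])
    umi <- vapply(seq_len(n_reads), function(i)
      paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = ""), "")
    tvec <- strsplit(target, "")[[1]]
    has_var <- matrix(FALSE, n_reads, max(1L, nrow(variants)))
    cdna <- character(n_reads)
    for (i in seq_len(n_reads)) {
      tv <- tvec
      if (nrow(variants) > 0) for (v in seq_len(nrow(variants))) {
        if (!is.na(clone[i]) && clone[i] %in% carr[[v]] &&
            runif(1) < variants$het[v]) {
          tv[variants$pos[v] + 1L] <- variants$alt[v]
          has_var[i, v] <- TRUE
        }
      }
      cdna[i] <- revcomp(paste(tv, collapse = ""))
    }
    seqs <- paste0("ACGT", substr(bc, 1, 6), linker1, substr(bc, 7, 12),
                   linker2, substr(bc, 13, 18), umi,
                   strrep("T", 12), cdna)
    seqs <- add_sub_errors(seqs, sub_error_rate)
    flip <- runif(n_reads) < rc_fraction
    seqs[flip] <- vapply(seqs[flip], revcomp, "", USE.NAMES = FALSE)
    ids <- sprintf("read%06d", seq_len(n_reads))
    reads <- data.frame(read_id = ids, sequence = seqs,
                        quality = strrep("I", nchar(seqs)),
                        predicted_accuracy = rep(accuracy, n_reads),
                        stringsAsFactors = FALSE)
    if (!is.null(fastq_path)) {
      hdr <- sprintf("@%s rq=%g", ids, accuracy)
      writeLines(rbind(hdr, seqs, "+", reads$quality), fastq_path)
    }
    truth <- data.frame(read_id = ids, barcode = bc, umi = umi, clone = clone,
                        stringsAsFactors = FALSE)
    if (nrow(variants) > 0)
      for (v in seq_len(nrow(variants)))
        truth[[paste0("var", v)]] <- has_var[, v]
    list(reads = reads, truth = truth)
  })
}

variants_carriers <- function(variants) {
  if (nrow(variants) == 0) return(list())
  if (is.list(variants$clones)) variants$clones
  else strsplit(as.character(variants$clones), ";", fixed = TRUE)
}

#' Reverse complement of a DNA string
#' @param s character scalar over A,C,G,T,N
#' @return reverse-complemented string
#' @export
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

add_sub_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    hit <- which(runif(length(v)) < rate)
    if (length(hit)) {
      for (i in hit) v[i] <- sample(setdiff(bases, v[i]), 1)
      s <- paste(v, collapse = "")
    }
    s
  }, "", USE.NAMES = FALSE)
}

#' Simulate a reference atlas of well-separated cell types
#'
#' Emulates a normal bone-marrow / cell-landscape reference: `n_types` types,
#' each with `markers_per_type` exclusive high-expression marker genes over a
#' shared background, `cells_per_type` cells each (mirroring random sampling
#' of 50 cells per cluster when building a reference).
#'
#' @param n_types number of cell types (>= 2)
#' @param markers_per_type exclusive markers per type
#' @param n_genes total genes
#' @param cells_per_type cells per type
#' @param marker_log2fc marker elevation (log2); 0 gives indistinguishable types
#' @param dispersion gamma-Poisson dispersion
#' @param depth expected library size
#' @param seed integer seed
#' @return list with `counts` (CountMatrix; metadata carries `type`) and
#'   `truth` (marker sets per type)
#' @export
simulate_reference_atlas <- function(n_types = 5, markers_per_type = 10,
                                     n_genes = 500, cells_per_type = 50,
                                     marker_log2fc = 3, dispersion = 0.3,
                                     depth = 2000, seed = 1) {
  stopifnot(n_types >= 2)
  if (markers_per_type * n_types > n_genes)
    aml_stop("markers_per_type x n_types exceeds n_genes")
  with_seed(seed, {
    gene_ids <- sprintf("ref_gene%04d", seq_len(n_genes))
    types <- sprintf("type%02d", seq_len(n_types))
    marker_sets <- split(gene_ids[seq_len(markers_per_type * n_types)],
                         rep(types, each = markers_per_type))
    n_cells <- n_types * cells_per_type
    type_of <- rep(types, each = cells_per_type)
    base <- rnorm(n_genes, 0, 1.5)
    L2 <- matrix(base, n_genes, n_cells)
    for (t in types) {
      cols <- type_of == t
      L2[gene_ids %in% marker_sets[[t]], cols] <-
        L2[gene_ids %in% marker_sets[[t]], cols] + marker_log2fc
    }
    rate <- sweep(2^L2, 2, colSums(2^L2), "/")
    lambda <- rate * depth
    if (dispersion > 0)
      lambda <- lambda * matrix(rgamma(length(lambda), 1 / dispersion,
                                       scale = dispersion), n_genes, n_cells)
    counts <- matrix(rpois(length(lambda), lambda), n_genes, n_cells)
    barcodes <- sprintf("refcell%04d", seq_len(n_cells))
    meta <- data.frame(barcode = barcodes, type = type_of,
                       stringsAsFactors = FALSE)
    cm <- CountMatrix(counts, gene_ids, barcodes, cell_meta = meta)
    list(counts = cm, truth = list(marker_sets = marker_sets,
                                   types = types, seed = seed))
  })
}
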