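#' Read long reads from FASTQ or FASTA
#'
#' Sequences are returned uppercase. For PacBio-style CCS input the per-read
#' predicted accuracy is parsed from a `key=value` tag in the read header
#' (default key `"rq"`, as written by CCS tooling); reads without the tag get
#' `NA` accuracy and are passed through quality filters with a warning
#' downstream (instrument-filtered input is assumed).
#'
#' @param path FASTQ or FASTA file (optionally gzipped); format auto-detected
#'   from the first character (`@` vs `>`)
#' @param accuracy_tag header key carrying predicted read accuracy
#' @return data.frame with `read_id`, `sequence`, `quality` (NA for FASTA),
#'   `predicted_accuracy`
#' @export
read_reads <- function(path, accuracy_tag = "rq") {
  con <- gzfile(path, "rt"); first <- readLines(con, n = 1L); close(con)
  if (length(first) == 0L) {
    aml_warn("empty reads file: ", path)
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), predicted_accuracy = numeric(),
                      stringsAsFactors = FALSE))
  }
  fmt <- if (startsWith(first, "@")) "fastq" else if (startsWith(first, ">"))
    "fasta" else aml_stop("file is neither FASTQ nor FASTA: ", path)
  if (fmt == "fastq") {
    validate_fastq(path)
    ss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq",
                                                with.qualities = TRUE),
                   error = function(e)
                     aml_stop("malformed FASTQ record: ", conditionMessage(e)))
    qual <- as.character(S4Vectors::mcols(ss)$qualities)
  } else {
    ss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                   error = function(e)
                     aml_stop("malformed FASTA record: ", conditionMessage(e)))
    qual <- rep(NA_character_, length(ss))
  }
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  patt <- paste0(accuracy_tag, "=([0-9.eE+-]+)")
  acc <- rep(NA_real_, length(ss))
  hit <- regexpr(patt, headers)
  has <- hit > 0
  if (any(has)) {
    m <- regmatches(headers[has], regexpr(patt, headers[has]))
    acc[has] <- as.numeric(sub(patt, "\\1", m))
  }
  data.frame(read_id = ids, sequence = toupper(as.character(ss)),
             quality = qual, predicted_accuracy = acc,
             stringsAsFactors = FALSE)
}

# structural validation of a (4-line-record) FASTQ before parsing, so a
# truncated or shifted file fails loudly with the offending record named
validate_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0)
    aml_stop("malformed FASTQ: truncated record ",
             length(lines) %/% 4 + 1, " in ", path)
  idx <- seq(1L, length(lines), by = 4L)
  bad_h <- which(!startsWith(lines[idx], "@"))
  bad_p <- which(!startsWith(lines[idx + 2L], "+"))
  bad_q <- which(nchar(lines[idx + 1L]) != nchar(lines[idx + 3L]))
  bad <- c(bad_h, bad_p, bad_q)
  if (length(bad))
    aml_stop("malformed FASTQ: record ", min(bad), " in ", path)
  invisible(TRUE)
}

# one CIGAR string -> number of target bases consumed
cigar_target_span <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(NA_integer_)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

#' Import externally produced alignments (SAM or PAF)
#'
#' Accepts minimap2-style output so that long reads aligned outside the
#' package can feed the variant caller. Unmapped records are dropped and the
#' drop count logged. Positions are converted to 0-based half-open internally.
#'
#' @param path SAM (with `@` headers) or PAF file; format auto-detected
#' @return data.frame with `read_id`, `target`, `target_start` (0-based),
#'   `target_end`, `strand`, `cigar` (NA for PAF rows without cg tag)
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    aml_warn("empty alignment file: ", path)
    return(data.frame(read_id = character(), target = character(),
                      target_start = integer(), target_end = integer(),
                      strand = character(), cigar = character(),
                      stringsAsFactors = FALSE))
  }
  body <- lines[!startsWith(lines, "@")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  is_sam <- any(startsWith(lines, "@")) ||
    (all(nf >= 11) && !anyNA(suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))) &&
       all(vapply(fields, `[`, "", 6L) %in% c("*", "") |
             grepl("^[0-9MIDNSHP=X]+$", vapply(fields, `[`, "", 6L))))
  is_paf <- all(nf >= 12) && all(vapply(fields, `[`, "", 5L) %in% c("+", "-"))
  if (is_paf && !any(startsWith(lines, "@"))) {
    tname <- vapply(fields, `[`, "", 6L)
    mapped <- tname != "*"
    cg <- vapply(fields, function(f) {
      tag <- grep("^cg:Z:", f, value = TRUE)
      if (length(tag)) sub("^cg:Z:", "", tag[1]) else NA_character_
    }, "")
    out <- data.frame(read_id = vapply(fields, `[`, "", 1L),
                      target = tname,
                      target_start = as.integer(vapply(fields, `[`, "", 8L)),
                      target_end = as.integer(vapply(fields, `[`, "", 9L)),
                      strand = vapply(fields, `[`, "", 5L),
                      cigar = cg, stringsAsFactors = FALSE)[mapped, , drop = FALSE]
  } else if (is_sam) {
    flag <- as.integer(vapply(fields, `[`, "", 2L))
    rname <- vapply(fields, `[`, "", 3L)
    mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
    cigar <- vapply(fields, `[`, "", 6L)
    pos0 <- as.integer(vapply(fields, `[`, "", 4L)) - 1L
    span <- vapply(cigar, cigar_target_span, 1L)
    out <- data.frame(read_id = vapply(fields, `[`, "", 1L),
                      target = rname, target_start = pos0,
                      target_end = pos0 + span,
                      strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                      cigar = cigar, stringsAsFactors = FALSE)[mapped, , drop = FALSE]
  } else {
    aml_stop("unrecognized alignment format (expected SAM or PAF): ", path)
  }
  n_drop <- length(body) - nrow(out)
  if (n_drop > 0) aml_log("read_alignments", n_drop, " unmapped records dropped")
  rownames(out) <- NULL
  out
}
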