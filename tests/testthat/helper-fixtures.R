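# shared fixtures, built in code and memoized for the session
options(amlscape.quiet = TRUE)

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, .fixture_env)) assign(key, build(), .fixture_env)
  get(key, .fixture_env)
}

# small 2-patient cohort, no batch, one program: fast lineage-level fixture
sim_small <- function() memo("sim_small", function()
  simulate_bmmc(n_patients = 2, cells_per_patient = 300, n_genes = 600,
                program_size = 50, rp_size = 25, batch_sd = 0,
                n_programs = 1, seed = 42))

pp_small <- function() memo("pp_small", function()
  preprocess(sim_small()$counts, n_hvg = 300, seed = 7))

# tiny dense CountMatrix built by hand
toy_counts <- function() {
  m <- matrix(c(3, 0, 0, 1,
                0, 2, 5, 0,
                1, 1, 1, 1), nrow = 3, byrow = TRUE)
  CountMatrix(m, c("MT-g1", "g2", "g3"), paste0("cell", 1:4))
}

# exact AUROC by pairwise enumeration (Mann-Whitney definition)
auroc_enum <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# exact hypergeometric lower tail by enumerating all draws
hyper_enum <- function(k, K, n, N) {
  pop <- c(rep(1, K), rep(0, N - K))
  draws <- combn(N, n)
  mean(colSums(matrix(pop[draws], nrow = n)) <= k)
}

# BH from the definition: p_(i) * n / i, cumulative min from the largest
bh_enum <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# random DNA string
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# layout constants for constructing long reads by hand
LINKER1 <- "CGACTCACTACAGGG"
LINKER2 <- "TCGGTGACACGATCG"
build_read <- function(cb1 = "AAAAAA", cb2 = "CCCCCC", cb3 = "GGGGGG",
                       umi = "TTTTTT", cdna = "") {
  paste0("ACGT", cb1, LINKER1, cb2, LINKER2, cb3, umi, strrep("T", 12), cdna)
}
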