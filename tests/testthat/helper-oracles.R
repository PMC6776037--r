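# Shared fixtures and independent oracles used across the suite.

ACGT <- c("A", "C", "G", "T")

rand_dna <- function(n, gc = 0.5, n_frac = 0) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chars <- sample(ACGT, n, replace = TRUE, prob = probs)
  if (n_frac > 0) {
    idx <- which(runif(n) < n_frac)
    chars[idx] <- "N"
  }
  paste(chars, collapse = "")
}

rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Naive sliding-window motif counting oracle: per-window Hamming distance to
# the core and its reverse complement, windows with non-ACGT excluded.
brute_count_motif <- function(seq, core) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- nchar(core)
  n <- length(chars)
  if (L > n) return(c(exact = 0L, one_mismatch = 0L))
  cm <- strsplit(core, "")[[1]]
  rm_ <- strsplit(rc_chr(core), "")[[1]]
  starts <- seq_len(n - L + 1)
  dist_f <- integer(length(starts))
  dist_r <- integer(length(starts))
  bad <- logical(length(starts))
  for (j in seq_len(L)) {
    cj <- chars[starts + j - 1]
    dist_f <- dist_f + (cj != cm[j])
    dist_r <- dist_r + (cj != rm_[j])
    bad <- bad | !(cj %in% ACGT)
  }
  c(exact = sum((dist_f == 0 | dist_r == 0) & !bad),
    one_mismatch = sum((dist_f <= 1 | dist_r <= 1) & !bad))
}

# Fraction of identical sites between two equal-length sequences.
site_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

# Reduced pipeline configuration for fast end-to-end tests.
small_pipeline_config <- function(seed = 11) {
  cfg <- default_pipeline_config(seed)
  cfg$synthetic$clades <- list(
    list(name = "CladeA", species = "species_A", gc = 0.38,
         hin_density = 700, apl_density = 30, genome_length = 30000, n_genomes = 2),
    list(name = "CladeB", species = "species_B", gc = 0.42,
         hin_density = 60, apl_density = 500, genome_length = 30000, n_genomes = 2))
  cfg$synthetic$superclusters <- list(list(name = "SC1", gc = 0.39),
                                      list(name = "SC2", gc = 0.42))
  cfg$synthetic$phage_genome_length <- 20000
  cfg$synthetic$clusters <- list(
    list(name = "C01", supercluster = "SC1", host_clade = "CladeA",
         hin_density = 400, apl_density = 20, n_members = 3, divergence = 0.03),
    list(name = "C02", supercluster = "SC2", host_clade = "CladeB",
         hin_density = 30, apl_density = 350, n_members = 3, divergence = 0.03))
  cfg$synthetic$decoys <- list(n_low_score = 2, n_low_orf = 2, n_duplicates = 1)
  cfg$synthetic$lysogeny <- list(
    n_per_clade = 8,
    prevalence = list(CladeA = c(C01 = 0.9, C02 = 0.1),
                      CladeB = c(C01 = 0.1, C02 = 0.8)))
  cfg$synthetic$metagenome <- list(
    sites = c("tongue", "gingiva"), samples_per_site = 2,
    contigs_per_sample = 10, contig_len = c(1500, 2500),
    marker_length_aa = 160,
    site_cluster_weights = list(tongue = c(C01 = 0.7, C02 = 0.3),
                                gingiva = c(C01 = 0.3, C02 = 0.7)))
  cfg$ordination$n_restarts <- 5
  cfg
}
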