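test_that("sketches are canonical, bounded and deterministic", {
  set.seed(301)
  seq <- rand_dna(10000)
  s1 <- minhash_sketch(seq, k = 21, s = 1000)
  s2 <- minhash_sketch(seq, k = 21, s = 1000)
  expect_identical(s1$hashes, s2$hashes)
  expect_true(all(diff(s1$hashes) > 0))  # strictly increasing
  # reverse complement gives the identical sketch (canonical k-mers)
  s3 <- minhash_sketch(rc_chr(seq), k = 21, s = 1000)
  expect_identical(s1$hashes, s3$hashes)
  expect_lte(length(s1$hashes), 1000)
  expect_error(minhash_sketch(rand_dna(10), k = 21), "shorter than k")
})

test_that("sketch size equals min(s, distinct canonical k-mers)", {
  set.seed(302)
  seq <- rand_dna(300)
  # direct enumeration of distinct canonical 7-mers
  kmers <- substring(seq, 1:(300 - 6), 7:300)
  canon <- pmin(kmers, vapply(kmers, rc_chr, character(1)))
  s <- minhash_sketch(seq, k = 7, s = 10000)
  expect_equal(length(s$hashes), length(unique(canon)))
  s2 <- minhash_sketch(seq, k = 7, s = 50)
  expect_equal(length(s2$hashes), 50)
})

test_that("mash_distance obeys its boundary rules", {
  a <- minhash_sketch(rand_dna(5000), k = 21)
  expect_equal(mash_distance(a, a)$jaccard_est, 1)
  expect_equal(mash_distance(a, a)$mash_distance, 0)
  b <- minhash_sketch(rand_dna(5000), k = 15)
  expect_error(mash_distance(a, b), "different k")
  # unrelated genomes: j approximately 0, distance capped at 1
  c1 <- minhash_sketch(rand_dna(5000), k = 21)
  d <- mash_distance(a, c1)
  expect_equal(d$mash_distance, 1.0)
})

test_that("sketch Jaccard estimates track the exact k-mer Jaccard", {
  fam <- generate_family(family_spec(genome_spec(50000, 0.4, seed = 31), 2,
                                     0.01, seed = 303))
  a <- fam$records$sequence[1]
  b <- fam$records$sequence[2]
  jx <- exact_kmer_jaccard(a, b, 21)
  est <- mash_distance(minhash_sketch(a), minhash_sketch(b))$jaccard_est
  expect_lt(abs(est - jx), max(3 * sqrt(jx * (1 - jx) / 1000), 0.05))
})

test_that("mash distance increases with substitution rate", {
  rates <- seq(0, 0.10, by = 0.02)
  d <- vapply(seq_along(rates), function(i) {
    fam <- generate_family(family_spec(genome_spec(20000, 0.4, seed = 40 + i),
                                       2, rates[i], seed = 304 + i))
    mash_distance(minhash_sketch(fam$records$sequence[1]),
                  minhash_sketch(fam$records$sequence[2]))$mash_distance
  }, numeric(1))
  expect_gt(cor(rates, d, method = "spearman"), 0.95)
})

test_that("fragment ANI recovers identity and flags unrelated pairs", {
  g <- generate_genome(genome_spec(10000, 0.4, seed = 305), "g")
  expect_equal(as.numeric(fragment_ani(g, g)), 1.0)

  fam <- generate_family(family_spec(genome_spec(50000, 0.4, seed = 32), 2,
                                     0.05, seed = 306))
  ani <- fragment_ani(fam$records[1, ], fam$records[2, ])
  expect_lt(abs(as.numeric(ani) - fam$truth$expected_identity[1]), 0.02)

  u1 <- genome_records("u1", rand_dna(5000))
  u2 <- genome_records("u2", rand_dna(5000))
  expect_true(is.na(fragment_ani(u1, u2)))
  expect_error(fragment_ani(genome_records("s", rand_dna(100)), g), "fragment_len")
})

test_that("dotplot reports exact forward word matches in 0-based coordinates", {
  set.seed(307)
  w <- rand_dna(20)
  d <- dotplot_matrix(w, w, word_len = 10)
  expect_equal(nrow(d), 11)
  expect_equal(d$x_pos, 0:10)
  expect_equal(d$y_pos, 0:10)
  # symmetric under coordinate swap for self-comparison
  x <- rand_dna(100)
  dx <- dotplot_matrix(x, x, word_len = 10)
  expect_true(all(paste(dx$y_pos, dx$x_pos) %in% paste(dx$x_pos, dx$y_pos)))
  # disjoint sequences share no 10-mer
  expect_equal(nrow(dotplot_matrix(strrep("A", 50), strrep("C", 50), 10)), 0)
})

test_that("threshold clustering produces nested cluster/supercluster labels", {
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  ca <- cluster_genomes(d0, 0.1, 0.2)
  expect_equal(unique(ca$cluster_label), 1)
  expect_equal(unique(ca$supercluster_label), 1)

  # two families: within <= 0.08, between >= 0.3
  ids <- c("f1a", "f1b", "f2a", "f2b")
  d <- matrix(0.3, 4, 4, dimnames = list(ids, ids))
  d[1, 2] <- d[2, 1] <- 0.05
  d[3, 4] <- d[4, 3] <- 0.08
  diag(d) <- 0
  ca <- cluster_genomes(d, 0.1, 0.2)
  expect_equal(length(unique(ca$cluster_label)), 2)
  expect_equal(length(unique(ca$supercluster_label)), 2)
  ca2 <- cluster_genomes(d, 0.1, 0.35)
  expect_equal(length(unique(ca2$cluster_label)), 2)
  expect_equal(length(unique(ca2$supercluster_label)), 1)
  # clusters nest within superclusters
  nest <- tapply(ca2$supercluster_label, ca2$cluster_label,
                 function(x) length(unique(x)))
  expect_true(all(nest == 1))

  d2 <- d; d2[1, 3] <- d2[3, 1] <- NA
  expect_error(cluster_genomes(d2, 0.1, 0.2), "missing")
})

test_that("clustering at extreme thresholds gives duplicates or one component", {
  set.seed(308)
  ids <- sprintf("g%d", 1:5)
  d <- matrix(runif(25, 0.1, 0.5), 5, 5, dimnames = list(ids, ids))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0  # exact duplicates
  ca0 <- cluster_genomes(d, 0, 0)
  expect_equal(ca0$cluster_label[1], ca0$cluster_label[2])
  expect_equal(length(unique(ca0$cluster_label)), 4)
  ca1 <- cluster_genomes(d, max(d), max(d))
  expect_equal(length(unique(ca1$cluster_label)), 1)
})

test_that("mash-ANI correlation behaves on constructed inputs", {
  lin <- data.frame(mash_distance = seq(0.01, 0.3, length.out = 10),
                    ani = 1 - seq(0.01, 0.3, length.out = 10))
  expect_equal(mash_ani_correlation(lin), 1.0)
  anti <- lin
  anti$ani <- 1 - rev(lin$mash_distance)
  expect_equal(mash_ani_correlation(anti), -1.0)
  expect_error(mash_ani_correlation(lin[1:2, ]), "at least 3")
  flat <- data.frame(mash_distance = rep(0.1, 5), ani = runif(5))
  expect_error(mash_ani_correlation(flat), "zero variance")
})
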