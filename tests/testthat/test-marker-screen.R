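test_that("six-frame translation follows the standard code", {
  expect_equal(six_frame_translate("ATGGCC")[["F1"]], "MA")
  expect_equal(six_frame_translate("TAA")[["F1"]], "*")
  # reverse-complementing a contig swaps forward and reverse frames
  set.seed(501)
  x <- rand_dna(300)
  fx <- six_frame_translate(x)
  fr <- six_frame_translate(rc_chr(x))
  expect_equal(unname(fx[c("R1", "R2", "R3")]), unname(fr[c("F1", "F2", "F3")]))
  expect_equal(unname(fx[c("F1", "F2", "F3")]), unname(fr[c("R1", "R2", "R3")]))
})

test_that("the local aligner matches the reference implementation", {
  skip_if_not_installed("Biostrings")
  data("BLOSUM62", package = "Biostrings")
  mat <- BLOSUM62
  alphabet <- paste(rownames(mat), collapse = "")
  set.seed(502)
  for (i in 1:10) {
    q <- random_protein(60, seed = 600 + i)
    s <- mutate_protein(paste0(random_protein(30, seed = 700 + i), q,
                               random_protein(30, seed = 800 + i)),
                        0.1, seed = 900 + i)
    mine <- phagediv:::sw_align_cpp(q, s, mat, alphabet, 11, 1)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s), Biostrings::AAString(q), type = "local",
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1)
    expect_equal(mine$score, Biostrings::score(ref))
    score_only <- phagediv:::sw_score_cpp(q, s, mat, alphabet, 11, 1)
    expect_equal(score_only, mine$score)
  }
})

test_that("a verbatim planted marker is found at full identity and coverage", {
  aa <- random_protein(160, seed = 503)
  mk <- marker_proteins("m1", "C01", aa)
  g <- genome_records("g", rand_dna(2000))
  g <- embed_marker(g, aa, at = 601, seed = 504)
  h <- search_markers(mk, g)
  expect_equal(nrow(h), 1)
  expect_equal(h$percent_identity, 100)
  expect_equal(h$aligned_query_span, h$query_len)
  expect_equal(identity_score(h), 100)
})

test_that("marker search is invariant under contig reverse-complementation", {
  aa <- random_protein(160, seed = 505)
  mk <- marker_proteins("m1", "C01", aa)
  g <- embed_marker(genome_records("g", rand_dna(1500)), aa, at = 301, seed = 506)
  g_rc <- genome_records("g_rc", rc_chr(g$sequence))
  h1 <- search_markers(mk, g)
  h2 <- search_markers(mk, g_rc)
  expect_equal(h1$score, h2$score)
  expect_equal(h1$percent_identity, h2$percent_identity)
})

test_that("random contigs almost never produce hits", {
  set.seed(507)
  mk <- marker_proteins("m1", "C01", random_protein(160, seed = 508))
  contigs <- genome_records(sprintf("c%03d", 1:100),
                            replicate(100, rand_dna(1000)))
  h <- search_markers(mk, contigs)
  expect_lte(nrow(h), 1)  # >= 99% of random contigs yield no hit
})

test_that("a 10% diverged marker scores near 90% identity", {
  aa <- random_protein(160, seed = 509)
  mut <- mutate_protein(aa, 0.10, seed = 510)
  mk <- marker_proteins("m1", "C01", aa)
  g <- embed_marker(genome_records("g", rand_dna(1500)), mut, at = 301, seed = 511)
  h <- search_markers(mk, g)
  expect_equal(nrow(h), 1)
  expect_lt(abs(h$percent_identity - 90), 7.5)  # 3 binomial sd at n = 160
})

test_that("identity score is coverage times identity on a 0-100 scale", {
  hit <- data.frame(query_len = c(100, 100, 100),
                    aligned_query_span = c(100, 90, 100),
                    percent_identity = c(96, 100, 95))
  expect_equal(identity_score(hit), c(96, 90, 95))
  # inclusive retention at exactly 95; 90 is dropped
  expect_equal(identity_score(hit) >= 95, c(TRUE, FALSE, TRUE))
  # identity_score never exceeds percent_identity
  expect_true(all(identity_score(hit) <= hit$percent_identity))
})

test_that("prevalence profiling counts positive samples per site", {
  meta <- sample_metadata(sprintf("s%02d", 1:10), "tongue")
  markers <- marker_proteins("m1", "C01", random_protein(40, seed = 512),
                             supercluster_label = "SC1")
  hit <- data.frame(marker_id = "m1", contig_id = "c1", sample_id = "s01",
                    query_len = 100L, aligned_query_span = 100L,
                    percent_identity = 100, e_value = 1e-100,
                    stringsAsFactors = FALSE)
  res <- profile_prevalence(hit, meta, markers)
  prev <- res$prevalence[res$prevalence$level == "cluster", ]
  expect_equal(prev$prevalence, 0.1)
  expect_equal(prev$n_samples, 10)

  # E-value above cutoff is excluded
  weak <- hit; weak$e_value <- 1e-50
  res2 <- profile_prevalence(weak, meta, markers)
  expect_equal(res2$prevalence$n_positive, c(0, 0))

  # unknown sample id errors
  bad <- hit; bad$sample_id <- "nope"
  expect_error(profile_prevalence(bad, meta, markers), "unknown sample")
})

test_that("supercluster prevalence is the union over member clusters", {
  meta <- sample_metadata(sprintf("s%02d", 1:10), "tongue")
  markers <- marker_proteins(c("m1", "m2"), c("C01", "C02"),
                             c(random_protein(40, seed = 513),
                               random_protein(40, seed = 514)),
                             supercluster_label = "SC1")
  hits <- data.frame(marker_id = c("m1", "m2"), contig_id = c("c1", "c2"),
                     sample_id = c("s01", "s02"),
                     query_len = 100L, aligned_query_span = 100L,
                     percent_identity = 100, e_value = 1e-100,
                     stringsAsFactors = FALSE)
  res <- profile_prevalence(hits, meta, markers)
  sc <- res$prevalence[res$prevalence$level == "supercluster", ]
  expect_equal(sc$prevalence, 0.2)  # disjoint positives add up
})

test_that("raising either cutoff never increases prevalence", {
  set.seed(515)
  meta <- sample_metadata(sprintf("s%02d", 1:20), rep(c("tongue", "gingiva"), 10))
  markers <- marker_proteins("m1", "C01", random_protein(40, seed = 516))
  hits <- data.frame(marker_id = "m1",
                     contig_id = sprintf("c%02d", 1:40),
                     sample_id = sample(meta$sample_id, 40, replace = TRUE),
                     query_len = 100L,
                     aligned_query_span = sample(80:100, 40, replace = TRUE),
                     percent_identity = runif(40, 85, 100),
                     e_value = 10^runif(40, -120, -60),
                     stringsAsFactors = FALSE)
  base <- profile_prevalence(hits, meta, markers,
                             evalue_cutoff = 1e-70, score_cutoff = 85)
  stricter_e <- profile_prevalence(hits, meta, markers,
                                   evalue_cutoff = 1e-90, score_cutoff = 85)
  stricter_s <- profile_prevalence(hits, meta, markers,
                                   evalue_cutoff = 1e-70, score_cutoff = 95)
  expect_true(all(stricter_e$prevalence$prevalence <= base$prevalence$prevalence))
  expect_true(all(stricter_s$prevalence$prevalence <= base$prevalence$prevalence))
})

test_that("species presence uses a strict threshold", {
  ab <- matrix(c(0.2, 0.1, 0), 3, 1,
               dimnames = list(c("sp1", "sp2", "sp3"), "s1"))
  pres <- species_presence(ab)
  expect_equal(unname(pres[, 1]), c(TRUE, FALSE, FALSE))
  expect_error(species_presence(ab * 1000), "percentages")
})

test_that("external tabular hits feed the same identity score", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame("m1", "c1", 96.0, 100, 4, 0, 1, 100, 1, 300,
                         1e-90, 500, 100),
              f, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  h <- read_tabular_hits(f)
  expect_equal(h$query_len, 100)
  expect_equal(identity_score(h), 96)
})
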