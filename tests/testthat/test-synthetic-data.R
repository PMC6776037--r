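test_that("generated genomes hit the target GC within binomial tolerance", {
  spec <- genome_spec(1e6, 0.40, seed = 101)
  g <- generate_genome(spec)
  counts <- table(strsplit(g$sequence, "")[[1]])
  gc <- (counts[["G"]] + counts[["C"]]) / 1e6
  expect_lt(abs(gc - 0.40), 3 * sqrt(0.4 * 0.6 / 1e6))
})

test_that("planted motif counts match the requested density exactly", {
  spec <- genome_spec(200000, 0.40, hin_density = 500, apl_density = 250, seed = 102)
  g <- generate_genome(spec)
  planted <- attr(g, "planted")
  expect_equal(sum(planted$motif == "Hin-USS"), round(500 * 0.2))
  expect_equal(sum(planted$motif == "Apl-USS"), round(250 * 0.2))
  expect_equal(nchar(g$sequence), 200000)  # overwrite, not insert
  # every planted copy is present at its recorded position/orientation
  m <- default_motifs()
  for (i in seq_len(nrow(planted))) {
    core <- if (planted$motif[i] == "Hin-USS") m$hin$core else m$apl$core
    expected <- if (planted$strand[i] == "+") core else rc_chr(core)
    expect_equal(substr(g$sequence, planted$start[i], planted$start[i] + 8), expected)
  }
})

test_that("generators are pure functions of their spec", {
  spec <- genome_spec(50000, 0.45, hin_density = 300, seed = 103)
  expect_identical(generate_genome(spec)$sequence, generate_genome(spec)$sequence)
  fs <- family_spec(genome_spec(20000, 0.4, seed = 1), 3, 0.05, seed = 104)
  expect_identical(generate_family(fs)$records$sequence,
                   generate_family(fs)$records$sequence)
})

test_that("infeasible motif placement raises an error naming the density", {
  spec <- genome_spec(100, 0.5, hin_density = 2e5, seed = 105)
  expect_error(generate_genome(spec), "hin_density=2e\\+05|hin_density=200000")
})

test_that("family members match the closed-form expected identity", {
  fam0 <- generate_family(family_spec(genome_spec(10000, 0.4, seed = 2), 3, 0,
                                      seed = 106))
  expect_true(all(fam0$records$sequence == fam0$records$sequence[1]))
  expect_equal(unique(fam0$truth$expected_identity), 1.0)

  fam <- generate_family(family_spec(genome_spec(50000, 0.4, seed = 3), 5, 0.05,
                                     seed = 107))
  expect_equal(nrow(fam$truth), 10)  # choose(5, 2)
  expected <- 0.95^2 + 0.05^2 / 3
  expect_equal(unique(fam$truth$expected_identity), expected)
  sd3 <- 3 * sqrt(expected * (1 - expected) / 50000)
  for (k in seq_len(nrow(fam$truth))) {
    a <- fam$records$sequence[fam$records$id == fam$truth$id_a[k]]
    b <- fam$records$sequence[fam$records$id == fam$truth$id_b[k]]
    expect_lt(abs(site_identity(a, b) - expected), sd3)
  }
})

test_that("lysogeny tables realize degenerate probabilities exactly", {
  des <- lysogeny_design(c("X", "Y"), c("c1", "c2"),
                         matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE),
                         n_per_clade = 10, seed = 108)
  tab <- generate_lysogeny_table(des)
  expect_true(all(tab$c1[tab$group == "X"]))
  expect_false(any(tab$c2))
  expect_false(any(tab$c1[tab$group == "Y"]))
})

test_that("a strong clade effect is detectable by Fisher in >=95% of replicates", {
  reject <- vapply(seq_len(200), function(i) {
    des <- lysogeny_design(c("A", "B"), "c1", matrix(c(0.9, 0.1), 2, 1),
                           n_per_clade = 50, seed = 1000 + i)
    tab <- generate_lysogeny_table(des)
    carriers <- tapply(tab$c1, tab$group, sum)
    m <- rbind(c(carriers[["A"]], 50 - carriers[["A"]]),
               c(carriers[["B"]], 50 - carriers[["B"]]))
    fisher_exact_2x2(m) < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})

test_that("metagenome contigs are substrings with faithful truth labels", {
  phage <- generate_genome(genome_spec(10000, 0.4, seed = 109), id = "phA")
  mg <- generate_metagenome(phage, list(phA = c(4000, 4500)),
                            c(phA = 1), n_contigs = 50,
                            contig_len = c(800, 1200), seed = 110)
  expect_true(all(mg$truth$source_id == "phA"))
  for (i in seq_len(5)) {
    expect_equal(mg$contigs$sequence[i],
                 substr(phage$sequence, mg$truth$start[i], mg$truth$end[i]))
  }
  # truth positivity: overlap >= half the marker length (501 nt here -> >= 251)
  expect_equal(mg$truth$marker_positive, mg$truth$marker_overlap >= 0.5 * 501)
})

test_that("contig sources follow abundances within binomial tolerance", {
  phages <- genome_records(c("p1", "p2"),
                           c(rand_dna(5000), rand_dna(5000)))
  mg <- generate_metagenome(phages, list(p1 = NULL, p2 = NULL),
                            c(p1 = 0.9, p2 = 0.1), n_contigs = 1000,
                            contig_len = 500, seed = 111)
  n1 <- sum(mg$truth$source_id == "p1")
  expect_lt(abs(n1 - 900), 3 * sqrt(1000 * 0.9 * 0.1))
})

test_that("contigs longer than the genome are rejected", {
  phage <- genome_records("p1", rand_dna(1000))
  expect_error(generate_metagenome(phage, list(p1 = NULL), c(p1 = 1),
                                   n_contigs = 5, contig_len = 2000, seed = 1),
               "exceeds")
})

test_that("marker embedding reverse-translates faithfully", {
  aa <- random_protein(60, seed = 112)
  dna <- reverse_translate(aa, seed = 113)
  expect_equal(nchar(dna), 180)
  back <- six_frame_translate(dna)[["F1"]]
  expect_equal(back, aa)
  g <- genome_records("g", rand_dna(1000))
  g2 <- embed_marker(g, aa, at = 101, seed = 114)
  expect_equal(attr(g2, "marker_interval"), c(101, 280))
  expect_equal(six_frame_translate(substr(g2$sequence, 101, 280))[["F1"]], aa)
})
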