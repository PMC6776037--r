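make_profiles <- function(gc, hin, apl, entity = NULL) {
  n <- length(gc)
  data.frame(record_id = sprintf("r%d", seq_len(n)), length_acgt = 1e6,
             gc_percent = gc, hin_per_mb = hin, apl_per_mb = apl,
             hin_per_mb_1mm = hin, apl_per_mb_1mm = apl,
             stringsAsFactors = FALSE)
}

test_that("feature building subtracts minimum GC and scales to max 100", {
  prof <- make_profiles(gc = c(40, 50), hin = c(750, 375), apl = c(0, 0))
  feat <- build_features(prof, c("e1", "e2"))
  expect_equal(unname(feat[, "delta_gc"]), c(0, 100))
  expect_equal(unname(feat[, "hin_per_mb"]), c(100, 50))
  expect_equal(unname(feat[, "apl_per_mb"]), c(0, 0))
  expect_equal(attr(feat, "flagged_columns"), "apl_per_mb")
  expect_true(all(feat >= 0 & feat <= 100))
})

test_that("entities aggregate as the mean of member profiles", {
  prof <- make_profiles(gc = c(40, 44, 50), hin = c(700, 800, 375),
                        apl = c(10, 30, 20))
  feat <- build_features(prof, c("e1", "e1", "e2"))
  expect_equal(nrow(feat), 2)
  expect_equal(unname(feat["e1", "hin_per_mb"]), 100)   # mean 750 is the max
  expect_equal(unname(feat["e2", "hin_per_mb"]), 50)
})

test_that("feature standardization is idempotent", {
  prof <- make_profiles(gc = c(38, 42, 45), hin = c(700, 300, 100),
                        apl = c(20, 50, 200))
  feat <- build_features(prof, c("a", "b", "c"))
  prof2 <- make_profiles(gc = feat[, "delta_gc"], hin = feat[, "hin_per_mb"],
                         apl = feat[, "apl_per_mb"])
  feat2 <- build_features(prof2, rownames(feat))
  expect_equal(unname(feat2), unname(feat))
})

test_that("Bray-Curtis matches hand-computed values and its bounds", {
  f <- rbind(a = c(100, 0, 0), b = c(0, 100, 0), c = c(50, 0, 0))
  d <- bray_curtis(f)
  expect_equal(d["a", "b"], 1.0)
  expect_equal(d["a", "c"], 1 / 3)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  # all-zero pair convention
  z <- rbind(a = c(0, 0), b = c(0, 0))
  expect_equal(bray_curtis(z)["a", "b"], 0)
  expect_error(bray_curtis(rbind(c(-1, 0), c(0, 1))), "non-negative")
  # random matrices stay within [0, 1]
  set.seed(701)
  r <- matrix(runif(40, 0, 100), 8, 5)
  expect_true(all(bray_curtis(r) >= 0 & bray_curtis(r) <= 1))
})

test_that("Bray-Curtis agrees with vegan on positive matrices", {
  skip_if_not_installed("vegan")
  set.seed(702)
  m <- matrix(runif(30, 1, 100), 6, 5)
  expect_equal(as.vector(as.dist(bray_curtis(m))),
               as.vector(vegan::vegdist(m, method = "bray")),
               tolerance = 1e-12)
})

test_that("nMDS recovers exactly embeddable planar configurations", {
  set.seed(703)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- sprintf("p%d", 1:6)
  ord <- nmds(d, dims = 2, n_restarts = 5, seed = 704)
  expect_lt(ord$stress, 0.01)
  # recovered distance ranks match the input ranks
  rec <- as.vector(dist(ord$points))
  expect_equal(order(rec), order(as.vector(as.dist(d))))
})

test_that("nMDS is deterministic, monotone in stress, and validates input", {
  set.seed(705)
  d <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
  o1 <- nmds(d, n_restarts = 4, seed = 706)
  o2 <- nmds(d, n_restarts = 4, seed = 706)
  expect_identical(o1$points, o2$points)
  expect_true(all(diff(o1$stress_trace) <= 1e-12))
  # more restarts never increase the best stress
  o3 <- nmds(d, n_restarts = 8, seed = 706)
  expect_lte(o3$stress, o1$stress + 1e-12)
  bad <- d; bad[1, 2] <- bad[1, 2] + 0.5
  expect_error(nmds(bad, seed = 1), "symmetric")
  # four mutually equidistant entities embed at negligible stress
  d4 <- matrix(1, 4, 4); diag(d4) <- 0
  expect_lt(nmds(d4, n_restarts = 10, seed = 707)$stress, 0.05)
})

test_that("nMDS stress is comparable to vegan's monoMDS", {
  skip_if_not_installed("vegan")
  set.seed(708)
  feat <- matrix(runif(36, 0, 100), 9, 4)
  rownames(feat) <- sprintf("e%d", 1:9)
  d <- bray_curtis(feat)
  ord <- nmds(d, n_restarts = 10, seed = 709)
  ref <- vegan::monoMDS(as.dist(d), k = 2)
  expect_lt(ord$stress, ref$stress + 0.02)
})

test_that("vector fitting returns axis correlations and multiple R", {
  set.seed(710)
  pts <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- sprintf("p%d", 1:8)
  ord <- nmds(d, n_restarts = 5, seed = 711)
  x <- ord$points
  z1 <- as.vector(scale(x[, 1]))
  z2 <- as.vector(scale(x[, 2]))
  feat <- cbind(ax1 = x[, 1], diag = z1 + z2, const = rep(5, 8))
  rownames(feat) <- rownames(x)
  suppressWarnings(v <- fit_vectors(ord, feat))
  expect_equal(v$axis1_r[v$variable == "ax1"], 1)
  expect_equal(abs(v$axis2_r[v$variable == "ax1"]), 0, tolerance = 1e-6)
  expect_equal(v$multiple_r[v$variable == "ax1"], 1)
  expect_equal(abs(v$axis1_r[v$variable == "diag"]), 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(v$multiple_r[v$variable == "diag"], 1, tolerance = 1e-9)
  expect_true(is.na(v$multiple_r[v$variable == "const"]))
})
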