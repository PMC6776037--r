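test_that("Fisher's exact test matches hand-enumerated cases", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2, 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2)), 2 / 252)
  expect_equal(fisher_exact_2x2(matrix(c(10, 10, 0, 0), 2, 2)), 1.0)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2, 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "positive")
})

test_that("Fisher p-values agree with the reference implementation", {
  set.seed(601)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Bonferroni multiplies, caps at 1 and never drops below raw p", {
  out <- bonferroni(c(0.01, 0.5), family_size = 10)
  expect_equal(out$p_adjusted, c(0.10, 1.0))
  out3 <- bonferroni(0.5, family_size = 3)
  expect_equal(out3$p_adjusted, 1.0)
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni(rep(0.1, 5), family_size = 3), "at least")
  set.seed(602)
  p <- runif(20)
  out <- bonferroni(p, 40)
  expect_true(all(out$p_adjusted >= out$p_value))
  # star codes on adjusted values; '#' marks raw-only significance
  s <- bonferroni(c(1e-5, 0.002, 0.01, 0.04, 0.5), family_size = 5)
  expect_equal(s$significance, c("***", "*", "#", "#", ""))
})

test_that("one-way ANOVA with Tukey flags the shifted group only", {
  g_equal <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res <- anova_tukey(g_equal)
  expect_equal(res$anova$F, 0)
  expect_equal(res$anova$p_value, 1)

  set.seed(603)
  strong <- list(a = rnorm(10, 0, 0.1), b = rnorm(10, 10, 0.1))
  res2 <- anova_tukey(strong)
  expect_lt(res2$anova$p_value, 0.001)
  expect_lt(res2$tukey$p_adjusted, 0.001)

  three <- list(a = rnorm(10, 0, 1), b = rnorm(10, 0, 1), c = rnorm(10, 8, 1))
  res3 <- anova_tukey(three)
  sig <- res3$tukey$p_adjusted < 0.05
  expect_equal(sig[res3$tukey$comparison == "b-a"], FALSE)
  expect_true(all(sig[res3$tukey$comparison %in% c("c-a", "c-b")]))

  expect_error(anova_tukey(list(a = c(1, 1), b = c(1, 1))), "zero variance")
})

test_that("rarefaction realizes forced outcomes and flat curves", {
  tab <- data.frame(id = c("g1", "g2"), group = "x",
                    A = c(TRUE, FALSE), B = c(FALSE, TRUE))
  rc <- rarefy(tab, replicates = 5, seed = 604)
  expect_equal(rc$mean_richness, c(1, 2))

  flat <- data.frame(id = sprintf("g%d", 1:6), group = "x", A = TRUE)
  rcf <- rarefy(flat, replicates = 5, seed = 605)
  expect_equal(rcf$mean_richness, rep(1, 6))
  expect_error(rarefy(tab[0, ], replicates = 5, seed = 1), "empty")
})

test_that("every rarefaction replicate curve is non-decreasing", {
  set.seed(606)
  tab <- data.frame(id = sprintf("g%02d", 1:30), group = "x",
                    matrix(runif(30 * 8) < 0.3, 30, 8,
                           dimnames = list(NULL, paste0("c", 1:8))))
  rc <- rarefy(tab, replicates = 20, seed = 607)
  reps <- attr(rc, "replicates")
  expect_true(all(apply(reps, 1, function(x) all(diff(x) >= 0))))
  # curve ends at the total observed cluster count
  expect_equal(rc$mean_richness[30], sum(colSums(tab[, -(1:2)]) > 0))
})

test_that("rarefaction means converge to the analytic hypergeometric form", {
  set.seed(608)
  m <- matrix(runif(25 * 10) < 0.25, 25, 10)
  colnames(m) <- paste0("c", 1:10)
  rownames(m) <- paste0("g", 1:25)
  expected <- rarefaction_expectation(m)
  rc <- rarefy(m, replicates = 400, seed = 609)
  expect_lt(max(abs(rc$mean_richness - expected) / pmax(expected, 1)), 0.05)
})

test_that("the analytic curve matches vegan's exact accumulation", {
  skip_if_not_installed("vegan")
  set.seed(610)
  m <- matrix(runif(20 * 6) < 0.3, 20, 6)
  colnames(m) <- paste0("c", 1:6)
  sp <- vegan::specaccum(m * 1, method = "exact")
  expect_equal(rarefaction_expectation(m), unname(sp$richness), tolerance = 1e-10)
})

test_that("prevalence summaries use Wilson intervals", {
  tab <- data.frame(id = sprintf("g%d", 1:5), group = "x",
                    full = TRUE, partial = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  s <- prevalence_summary(tab)
  expect_equal(s$prevalence[s$cluster == "full"], 1.0)
  p35 <- s[s$cluster == "partial", ]
  expect_equal(p35$prevalence, 0.6)
  # Wilson score interval closed form for 3 of 5 at z = qnorm(0.975)
  z <- qnorm(0.975)
  center <- (0.6 + z^2 / 10) / (1 + z^2 / 5)
  half <- z * sqrt(0.6 * 0.4 / 5 + z^2 / 100) / (1 + z^2 / 5)
  expect_equal(p35$ci_lower, center - half, tolerance = 1e-9)
  expect_equal(p35$ci_upper, center + half, tolerance = 1e-9)
  expect_gt(p35$ci_lower, 0.23)
  expect_lt(p35$ci_upper, 0.89)

  none <- data.frame(id = sprintf("g%d", 1:7), group = "d", c1 = FALSE)
  s0 <- prevalence_summary(none)
  expect_equal(s0$prevalence, 0.0)
})

test_that("per-cluster Fisher panels decompose and correct correctly", {
  set.seed(611)
  tab <- data.frame(id = sprintf("g%02d", 1:40),
                    group = rep(c("A", "B"), each = 20),
                    c1 = c(runif(20) < 0.9, runif(20) < 0.1),
                    c2 = runif(40) < 0.3)
  res <- prevalence_tests(tab)
  expect_equal(nrow(res), 4)  # 2 groups x 2 clusters
  expect_true(all(res$p_adjusted >= res$p_value))
  # the clade-enriched cluster is significant after correction
  expect_lt(res$p_adjusted[res$group == "A" & res$cluster == "c1"], 0.05)
  # hand check one decomposed 2x2 against the scalar test
  row <- res[res$group == "A" & res$cluster == "c1", ]
  m <- matrix(c(row$carriers_in, row$noncarriers_in,
                row$carriers_out, row$noncarriers_out), 2, 2, byrow = TRUE)
  expect_equal(row$p_value, fisher_exact_2x2(m))
})

test_that("presence tables round-trip through TSV", {
  tab <- data.frame(id = c("g1", "g2"), group = c("A", "B"),
                    c1 = c(TRUE, FALSE), c2 = c(FALSE, FALSE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_presence_table(tab, f)
  back <- read_presence_table(f)
  expect_equal(back, tab)
})
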