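# Prevalence and richness statistics: two-sided Fisher's exact test with
# Bonferroni correction, one-way ANOVA with Tukey HSD, rarefaction of phage
# cluster richness, and prevalence summaries with Wilson intervals.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Direct hypergeometric enumeration: the two-sided p-value is the sum of the
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (within relative
#' tolerance 1e-7, the conventional guard against floating-point ties).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0)) stop("counts must be non-negative")
  if (sum(table) == 0) stop("at least one count must be positive")
  a <- table[1, 1]
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Bonferroni correction
#'
#' Each p-value is multiplied by the family size and capped at 1.
#' Significance codes on the adjusted values follow the usual convention
#' (`***` < 0.001, `**` < 0.01, `*` < 0.05); `#` marks values significant at
#' 0.05 before but not after correction. The family is all tests of one
#' analysis panel (clusters x group comparisons) and is an explicit argument
#' so alternative conventions remain testable.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param family_size Number of tests in the family (at least
#'   `length(p_values)`; defaults to it).
#' @return Data frame with `p_value`, `p_adjusted`, `significance`.
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (family_size < length(p_values)) {
    stop("family_size must be at least the number of p-values")
  }
  adj <- pmin(1, p_values * family_size)
  stars <- ifelse(adj < 0.001, "***",
           ifelse(adj < 0.01, "**",
           ifelse(adj < 0.05, "*",
           ifelse(p_values < 0.05, "#", ""))))
  data.frame(p_value = p_values, p_adjusted = adj, significance = stars,
             stringsAsFactors = FALSE)
}

#' One-way ANOVA with post hoc Tukey HSD
#'
#' @param values Numeric vector of per-genome prophage counts (or any
#'   response), or a named list of group vectors.
#' @param group Group labels (ignored when `values` is a list). At least two
#'   groups with n >= 2 each are required.
#' @return A list: `anova` (one-row data frame with `F` and `p_value`) and
#'   `tukey` (data frame of pairwise comparisons with Tukey-adjusted
#'   p-values).
#' @export
anova_tukey <- function(values, group = NULL) {
  if (is.list(values) && is.null(group)) {
    group <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  group <- factor(group)
  stopifnot(nlevels(group) >= 2, all(tabulate(group) >= 2))
  if (var(values) == 0) stop("response has zero variance; ANOVA undefined")
  fit <- aov(values ~ group)
  tab <- summary(fit)[[1]]
  hsd <- TukeyHSD(fit)$group
  list(anova = data.frame(F = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1]),
       tukey = data.frame(comparison = rownames(hsd), diff = hsd[, "diff"],
                          p_adjusted = hsd[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

# Coerce a presence table (id, group, logical columns) to its logical matrix.
presence_matrix <- function(table) {
  stopifnot(is.data.frame(table), ncol(table) >= 3)
  m <- as.matrix(table[, -(1:2), drop = FALSE])
  storage.mode(m) <- "logical"
  rownames(m) <- table[[1]]
  m
}

#' Rarefaction of phage-cluster richness
#'
#' Individual-based rarefaction over genomes, sampled without replacement:
#' each replicate draws a random genome order and the curve reports, for each
#' sample size n, the number of distinct phage clusters present among the
#' first n genomes. Nested (prefix) sampling makes every replicate curve
#' non-decreasing in n. The 95% CI across replicates is t-based.
#'
#' @param table Presence table data frame (`id`, `group`, logical cluster
#'   columns) or a logical matrix (genomes x clusters).
#' @param replicates Number of replicates (default 10, minimum 2).
#' @param seed Integer seed.
#' @return Data frame with `n`, `mean_richness`, `ci_lower`, `ci_upper`,
#'   `n_replicates`; attribute `replicates` holds the replicate x n richness
#'   matrix.
#' @export
rarefy <- function(table, replicates = 10, seed) {
  m <- if (is.matrix(table)) table else presence_matrix(table)
  if (nrow(m) == 0 || ncol(m) == 0) stop("presence table is empty")
  stopifnot(replicates >= 2)
  G <- nrow(m)
  curves <- with_seed(seed, {
    t(vapply(seq_len(replicates), function(rep) {
      ord <- sample.int(G)
      # first position at which each cluster appears along the permutation
      first <- apply(m[ord, , drop = FALSE], 2, function(col) {
        w <- which(col)
        if (length(w) == 0) G + 1L else w[1]
      })
      cumsum(tabulate(first, nbins = G))
    }, numeric(G)))
  })
  means <- colMeans(curves)
  sds <- apply(curves, 2, sd)
  half <- qt(0.975, replicates - 1) * sds / sqrt(replicates)
  out <- data.frame(n = seq_len(G), mean_richness = means,
                    ci_lower = means - half, ci_upper = means + half,
                    n_replicates = replicates)
  attr(out, "replicates") <- curves
  out
}

#' Analytic expected rarefaction curve
#'
#' Closed-form expectation of the number of distinct clusters among n genomes
#' drawn without replacement:
#' `E[S_n] = sum_i (1 - choose(G - g_i, n) / choose(G, n))`, where `g_i` is
#' the number of genomes carrying cluster i.
#'
#' @param table Presence table or logical matrix.
#' @return Numeric vector of expected richness for n = 1..G.
#' @export
rarefaction_expectation <- function(table) {
  m <- if (is.matrix(table)) table else presence_matrix(table)
  G <- nrow(m)
  g <- colSums(m)
  vapply(seq_len(G), function(n) {
    sum(1 - exp(lchoose(G - g, n) - lchoose(G, n)))
  }, numeric(1))
}

#' Per-group prevalence with Wilson 95% intervals
#'
#' @param table Presence table data frame (`id`, `group`, logical cluster
#'   columns).
#' @return Data frame per group x cluster: `group`, `cluster`, `n`,
#'   `carriers`, `prevalence`, `ci_lower`, `ci_upper` (Wilson score interval).
#' @export
prevalence_summary <- function(table) {
  m <- presence_matrix(table)
  groups <- split(seq_len(nrow(m)), table[[2]])
  rows <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    for (cl in colnames(m)) {
      x <- sum(m[idx, cl]); n <- length(idx)
      ci <- if (n >= 1) {
        suppressWarnings(prop.test(x, n, correct = FALSE)$conf.int)
      } else c(NA, NA)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, cluster = cl, n = n, carriers = x, prevalence = x / n,
        ci_lower = ci[1], ci_upper = ci[2], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cluster Fisher tests of group association
#'
#' Decomposes a groups x clusters presence table into per-cluster, per-group
#' 2x2 tables (carriers vs non-carriers, group vs rest), applies the
#' two-sided Fisher test to each, and Bonferroni-corrects over the panel
#' family (clusters x groups by default).
#'
#' @param table Presence table data frame.
#' @param family_size Bonferroni family size; defaults to the number of
#'   tests in the panel.
#' @return Data frame: `group`, `cluster`, counts, `p_value`, `p_adjusted`,
#'   `significance`.
#' @export
prevalence_tests <- function(table, family_size = NULL) {
  m <- presence_matrix(table)
  groups <- unique(table[[2]])
  rows <- list()
  for (g in groups) {
    in_g <- table[[2]] == g
    for (cl in colnames(m)) {
      tab <- matrix(c(sum(m[in_g, cl]), sum(!m[in_g, cl]),
                      sum(m[!in_g, cl]), sum(!m[!in_g, cl])),
                    nrow = 2, byrow = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, cluster = cl,
        carriers_in = tab[1, 1], noncarriers_in = tab[1, 2],
        carriers_out = tab[2, 1], noncarriers_out = tab[2, 2],
        p_value = fisher_exact_2x2(tab), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  fam <- family_size %||% nrow(out)
  adj <- bonferroni(out$p_value, fam)
  out$p_adjusted <- adj$p_adjusted
  out$significance <- adj$significance
  rownames(out) <- NULL
  out
}

#' Read / write presence tables
#'
#' Tab-separated: first column id, second column group, remaining columns
#' boolean carriage flags.
#'
#' @param path File path.
#' @return For the reader, a presence table data frame.
#' @export
read_presence_table <- function(path) {
  df <- read_tsv_stable(path)
  for (j in seq(3, ncol(df))) df[[j]] <- as.logical(df[[j]])
  df
}

#' @rdname read_presence_table
#' @param table Presence table data frame.
#' @export
write_presence_table <- function(table, path) {
  write_tsv_stable(table, path)
}
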