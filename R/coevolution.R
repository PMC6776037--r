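# Phage-host coevolution ordination: the three-variable feature matrix
# (delta-GC, Hin-USS, Apl-USS frequencies), max-standardization, Bray-Curtis
# dissimilarities, non-metric multidimensional scaling (Kruskal stress-1),
# and vector fitting of the variables onto the ordination axes.

#' Build the coevolution feature matrix
#'
#' Entities (bacterial clades and phage clusters) enter as the mean profile
#' of their members. `delta_gc` is the entity mean GC% minus the minimum mean
#' GC% over entities; each of the three columns is then rescaled so its
#' maximum is 100 (per-variable standardization). A column whose maximum is
#' 0 is left all-zero and flagged.
#'
#' @param profiles USS profile data frame (see [uss_profile_table()]).
#' @param grouping Entity label per profile row.
#' @return Numeric matrix (entities x `delta_gc`, `hin_per_mb`,
#'   `apl_per_mb`), values in `[0, 100]`; attribute `flagged_columns` names
#'   degenerate all-zero columns.
#' @export
build_features <- function(profiles, grouping) {
  stopifnot(nrow(profiles) == length(grouping))
  agg <- function(col) tapply(profiles[[col]], grouping, mean)
  gc <- agg("gc_percent")
  if (length(gc) < 2) stop("need at least 2 entities")
  feat <- cbind(delta_gc = gc - min(gc),
                hin_per_mb = agg("hin_per_mb"),
                apl_per_mb = agg("apl_per_mb"))
  flagged <- character(0)
  for (j in colnames(feat)) {
    mx <- max(feat[, j])
    if (mx > 0) {
      feat[, j] <- 100 * feat[, j] / mx
    } else {
      flagged <- c(flagged, j)
    }
  }
  attr(feat, "flagged_columns") <- flagged
  feat
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`; a pair of all-zero rows has
#' dissimilarity 0 by convention.
#'
#' @param features Non-negative numeric matrix (entities x variables).
#' @return Symmetric dissimilarity matrix in `[0, 1]` with zero diagonal.
#' @export
bray_curtis <- function(features) {
  features <- as.matrix(features)
  if (any(features < 0)) stop("Bray-Curtis requires non-negative features")
  n <- nrow(features)
  d <- matrix(0, n, n, dimnames = list(rownames(features), rownames(features)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      denom <- sum(features[i, ] + features[j, ])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else
        sum(abs(features[i, ] - features[j, ])) / denom
    }
  }
  d
}

# Kruskal stress-1 given configuration distances and disparities.
stress1 <- function(dhat, dstar) {
  sqrt(sum((dhat - dstar)^2) / sum(dhat^2))
}

# Monotone (isotonic) disparities of configuration distances on the input
# dissimilarity order; primary approach to ties (tied input dissimilarities
# are ordered by current configuration distance, leaving them free).
disparities <- function(dvec, dhat) {
  ord <- order(dvec, dhat)
  dstar <- numeric(length(dhat))
  dstar[ord] <- isoreg(dhat[ord])$yf
  dstar
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1,
#' `sqrt(sum((dhat_ij - d*_ij)^2) / sum(dhat_ij^2))`, where `dhat` are
#' configuration distances and `d*` the isotonic regression of `dhat` on the
#' input dissimilarity ranks. Each restart alternates isotonic regression
#' with Guttman (majorization) configuration updates; a step-halving
#' safeguard makes the recorded stress trace monotone non-increasing. The
#' first restart starts from classical (metric) scaling, the rest from
#' seeded random configurations; the best (lowest-stress) restart is
#' returned. Coordinates are centered, rotated to principal axes, and
#' sign-canonicalized (the first entity gets non-negative coordinates).
#'
#' @param dissimilarities Symmetric matrix with zero diagonal; at least
#'   `dims + 2` entities.
#' @param dims Embedding dimension (default 2).
#' @param n_restarts Number of starts (default 20).
#' @param max_iter Iteration cap per restart (default 300).
#' @param tol Stop when the stress change falls below this (default 1e-7).
#' @param seed Integer seed (required; local minima make restarts and
#'   reproducibility essential).
#' @return An object of class `nmds_result`: `points` (entities x dims),
#'   `stress`, `stress_trace` (per accepted iteration of the best restart),
#'   `n_restarts`, `seed`, `converged`.
#' @export
nmds <- function(dissimilarities, dims = 2, n_restarts = 20, max_iter = 300,
                 tol = 1e-7, seed) {
  d <- as.matrix(dissimilarities)
  n <- nrow(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)) || any(diag(d) != 0)) {
    stop("dissimilarity matrix must be symmetric with zero diagonal")
  }
  if (n < dims + 2) stop("need at least dims + 2 entities")
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  dvec <- d[cbind(pair_i, pair_j)]

  run_restart <- function(x0) {
    x <- x0
    dh <- as.vector(dist(x))
    dh[dh == 0] <- 1e-12
    ds <- disparities(dvec, dh)
    s <- stress1(dh, ds)
    trace <- s
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # Guttman transform with the current disparities
      b <- matrix(0, n, n)
      ratio <- ds / dh
      b[cbind(pair_i, pair_j)] <- -ratio
      b[cbind(pair_j, pair_i)] <- -ratio
      diag(b) <- -rowSums(b)
      x_new <- (b %*% x) / n
      # step-halving safeguard: accept only non-increasing stress
      step <- 1
      accepted <- FALSE
      for (h in seq_len(20)) {
        x_try <- x + step * (x_new - x)
        dh_try <- as.vector(dist(x_try))
        dh_try[dh_try == 0] <- 1e-12
        ds_try <- disparities(dvec, dh_try)
        s_try <- stress1(dh_try, ds_try)
        if (s_try <= s) { accepted <- TRUE; break }
        step <- step / 2
      }
      if (!accepted) { converged <- TRUE; break }
      delta <- s - s_try
      x <- x_try; dh <- dh_try; ds <- ds_try; s <- s_try
      trace <- c(trace, s)
      if (delta < tol) { converged <- TRUE; break }
    }
    list(x = x, stress = s, trace = trace, converged = converged)
  }

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      x0 <- if (r == 1) {
        cmd <- cmdscale(d, k = dims)
        if (ncol(cmd) < dims) cbind(cmd, matrix(rnorm(n * (dims - ncol(cmd)), sd = 1e-4), n)) else cmd
      } else {
        matrix(rnorm(n * dims), n, dims)
      }
      res <- run_restart(x0)
      if (is.null(best) || res$stress < best$stress) best <- res
    }
  })

  # center, rotate to principal axes, canonicalize signs
  x <- scale(best$x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  x <- sv$u %*% diag(sv$d, dims)
  for (j in seq_len(dims)) {
    nz <- which(abs(x[, j]) > 1e-12)
    if (length(nz) > 0 && x[nz[1], j] < 0) x[, j] <- -x[, j]
  }
  rownames(x) <- rownames(d)
  colnames(x) <- sprintf("axis%d", seq_len(dims))
  structure(list(points = x, stress = best$stress, stress_trace = best$trace,
                 n_restarts = n_restarts, seed = seed,
                 converged = best$converged),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("nMDS ordination: %d entities, %d dims, stress-1 = %.4f (%d restarts)\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_restarts))
  invisible(x)
}

#' Fit variable vectors onto an ordination
#'
#' For each feature-matrix variable: the vector direction is the pair of
#' Pearson correlations of the variable with the two ordination axes, and
#' the vector length is the multiple correlation coefficient of the linear
#' regression of the variable on the ordination coordinates. Zero-variance
#' variables are flagged with `NA`.
#'
#' @param result An `nmds_result`.
#' @param features Feature matrix sharing the ordination's entities.
#' @return Data frame: `variable`, `axis1_r`, `axis2_r`, `multiple_r`.
#' @export
fit_vectors <- function(result, features) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(result$points))
  features <- features[rownames(result$points), , drop = FALSE]
  x <- result$points
  rows <- lapply(colnames(features), function(v) {
    val <- features[, v]
    if (sd(val) == 0) {
      return(data.frame(variable = v, axis1_r = NA_real_, axis2_r = NA_real_,
                        multiple_r = NA_real_, stringsAsFactors = FALSE))
    }
    r1 <- cor(val, x[, 1]); r2 <- cor(val, x[, 2])
    fit <- lm(val ~ x[, 1] + x[, 2])
    data.frame(variable = v, axis1_r = r1, axis2_r = r2,
               multiple_r = sqrt(summary(fit)$r.squared),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
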