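# Genome comparison and clustering: MinHash sketches with Mash distances,
# simplified fragment-based average nucleotide identity (ANI), exact-word
# dotplot coordinates, and single-linkage threshold clustering into clusters
# and superclusters.

#' MinHash sketch of a genome
#'
#' Canonical k-mers (the lexicographic minimum of a k-mer and its reverse
#' complement on the 2-bit encoding) are hashed with a fixed 64-bit mix
#' (splitmix64, fixed seed, truncated to 53 bits so values are exactly
#' representable as R numerics); the sketch keeps the `s` smallest distinct
#' hash values. K-mers containing non-ACGT characters are skipped.
#'
#' @param record One-row genome record data frame, or a bare sequence string.
#' @param k K-mer size (default 21).
#' @param s Sketch size (default 1000).
#' @return A `minhash_sketch` list: `record_id`, `k`, `s`, `hashes` (sorted,
#'   strictly increasing numeric).
#' @export
minhash_sketch <- function(record, k = 21, s = 1000) {
  if (is.character(record)) record <- list(id = "seq", sequence = record)
  seq <- toupper(record$sequence)
  if (nchar(seq) < k) stop("sequence shorter than k; cannot sketch")
  structure(list(record_id = record$id, k = as.integer(k), s = as.integer(s),
                 hashes = sketch_hashes_cpp(seq, as.integer(k), as.integer(s))),
            class = "minhash_sketch")
}

#' Mash distance between two sketches
#'
#' The Jaccard index `j` is estimated from the merged bottom-`s` sketch (the
#' fraction of the `s'` smallest hash values of the union found in both
#' sketches, `s' = min(s, |union|)`); the Mash distance is
#' `d = -(1/k) * log(2j / (1 + j))`, with `j = 0` reported as `d = 1`.
#'
#' @param a,b `minhash_sketch` objects with equal `k`.
#' @return A one-row data frame: `id_a`, `id_b`, `jaccard_est`,
#'   `mash_distance`, `ani` (`NA`, filled by [fragment_ani()] callers).
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$k != b$k) stop("sketches have different k-mer sizes")
  merged <- sort(unique(c(a$hashes, b$hashes)))
  s_prime <- min(min(a$s, b$s), length(merged))
  bottom <- merged[seq_len(s_prime)]
  shared <- sum(bottom %in% a$hashes & bottom %in% b$hashes)
  j <- if (s_prime == 0) 0 else shared / s_prime
  d <- if (j <= 0) 1.0 else max(0, -(1 / a$k) * log(2 * j / (1 + j)))
  data.frame(id_a = a$record_id, id_b = b$record_id, jaccard_est = j,
             mash_distance = d, ani = NA_real_, stringsAsFactors = FALSE)
}

#' Exact Jaccard index over full canonical k-mer sets
#'
#' Reference quantity for MinHash calibration: the Jaccard index of the
#' complete canonical k-mer sets of two sequences.
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param k K-mer size.
#' @return Numeric in `[0, 1]`.
#' @export
exact_kmer_jaccard <- function(seq_a, seq_b, k = 21) {
  kmer_jaccard_cpp(toupper(seq_a), toupper(seq_b), as.integer(k))
}

#' Fragment-based average nucleotide identity
#'
#' A simplified fragment ANI: the first genome is cut into consecutive
#' fragments (default 1020 nt), each fragment is placed on the other genome
#' at its best ungapped offset (located by exact seed-word voting) and scored
#' by per-site identity; the same is done reciprocally, and ANI is the mean
#' identity of reciprocal best fragment pairs with identity at or above
#' `min_identity`. Returns `NA` (flagged) when no pair qualifies, e.g. for
#' unrelated genomes.
#'
#' @param a,b Genome record rows or sequence strings.
#' @param fragment_len Fragment length (default 1020 nt).
#' @param min_identity Qualifying identity fraction (default 0.35; ungapped
#'   full-fragment placement makes fragment coverage all-or-none, so the
#'   coverage rule is subsumed).
#' @return Numeric ANI in `[0, 1]` or `NA`; attribute `n_fragment_pairs`
#'   holds the number of qualifying reciprocal pairs.
#' @export
fragment_ani <- function(a, b, fragment_len = 1020, min_identity = 0.35) {
  sa <- toupper(if (is.character(a)) a else a$sequence)
  sb <- toupper(if (is.character(b)) b else b$sequence)
  if (nchar(sa) < fragment_len || nchar(sb) < fragment_len) {
    stop("sequence shorter than fragment_len")
  }
  res <- fragment_ani_cpp(sa, sb, as.integer(fragment_len), min_identity)
  structure(res$ani, n_fragment_pairs = res$n_pairs)
}

#' Exact-word dotplot coordinates
#'
#' All 0-based coordinate pairs `(x_pos, y_pos)` where the `word_len`-mer of
#' `x` starting at `x_pos` equals the one of `y` at `y_pos` (forward strand,
#' exact matching). With `both_strands = TRUE`, reverse-complement word
#' matches of `y` are appended with `strand = "-"`.
#'
#' @param x,y Genome record rows or sequence strings.
#' @param word_len Word length (default 10).
#' @param both_strands Also report reverse-strand matches (default `FALSE`).
#' @return Data frame with `x_pos`, `y_pos` (0-based) and `strand`.
#' @export
dotplot_matrix <- function(x, y, word_len = 10, both_strands = FALSE) {
  sx <- toupper(if (is.character(x)) x else x$sequence)
  sy <- toupper(if (is.character(y)) y else y$sequence)
  if (nchar(sx) < word_len || nchar(sy) < word_len) {
    stop("sequences must be at least word_len long")
  }
  words <- function(s) {
    n <- nchar(s) - word_len + 1L
    substring(s, seq_len(n), seq_len(n) + word_len - 1L)
  }
  match_words <- function(wx, wy, strand) {
    ix <- split(seq_along(wx) - 1L, wx)
    iy <- split(seq_along(wy) - 1L, wy)
    common <- intersect(names(ix), names(iy))
    if (length(common) == 0) {
      return(data.frame(x_pos = integer(0), y_pos = integer(0),
                        strand = character(0), stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, lapply(common, function(w) {
      expand.grid(x_pos = ix[[w]], y_pos = iy[[w]], KEEP.OUT.ATTRS = FALSE)
    }))
    out$strand <- strand
    out
  }
  res <- match_words(words(sx), words(sy), "+")
  if (both_strands) {
    wy_rc <- words(revcomp(sy))
    rc <- match_words(words(sx), wy_rc, "-")
    if (nrow(rc) > 0) {
      # report reverse-strand matches in original y coordinates (word start)
      rc$y_pos <- nchar(sy) - word_len - rc$y_pos
      res <- rbind(res, rc)
    }
  }
  res <- res[order(res$x_pos, res$y_pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' All-pairs Mash distance matrix
#'
#' @param records Genome record data frame.
#' @param k,s Sketch parameters.
#' @return A symmetric numeric matrix of Mash distances with record ids as
#'   dimnames; attribute `pairs` holds the long-format pair table.
#' @export
mash_distance_matrix <- function(records, k = 21, s = 1000) {
  sketches <- lapply(seq_len(nrow(records)), function(i) {
    minhash_sketch(records[i, , drop = FALSE], k = k, s = s)
  })
  n <- nrow(records)
  m <- matrix(0, n, n, dimnames = list(records$id, records$id))
  pairs <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        r <- mash_distance(sketches[[i]], sketches[[j]])
        m[i, j] <- m[j, i] <- r$mash_distance
        pairs[[length(pairs) + 1]] <- r
      }
    }
  }
  attr(m, "pairs") <- if (length(pairs) > 0) do.call(rbind, pairs) else NULL
  m
}

# Connected components of the graph joining pairs at distance <= threshold,
# labelled in order of the smallest member id.
threshold_components <- function(d, threshold) {
  n <- nrow(d)
  parent <- uf_new(n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (d[i, j] <= threshold) parent <- uf_union(parent, i, j)
      }
    }
  }
  comp <- uf_components(parent)
  ids <- rownames(d)
  min_id <- vapply(split(ids, comp), min, character(1))
  order_of <- rank(min_id, ties.method = "first")
  unname(order_of[as.character(comp)])
}

#' Threshold clustering of genomes into clusters and superclusters
#'
#' Single-linkage connected components at `mash_distance <=
#' cluster_threshold` define genus-like clusters; components at `<=
#' supercluster_threshold` define subfamily-like superclusters. Clusters nest
#' within superclusters by construction, and labels are assigned in order of
#' each component's smallest member id. The defaults (0.09 and 0.25) are
#' reproducible surrogates for curated cluster definitions: within-cluster
#' Mash distances in this phage collection ranged up to ~0.08.
#'
#' @param distances Complete symmetric matrix of Mash distances with id
#'   dimnames (missing entries are an error).
#' @param cluster_threshold,supercluster_threshold Distance thresholds with
#'   `cluster_threshold <= supercluster_threshold`.
#' @return Data frame: `record_id`, `cluster_label`, `supercluster_label`.
#' @export
cluster_genomes <- function(distances, cluster_threshold = 0.09,
                            supercluster_threshold = 0.25) {
  distances <- as.matrix(distances)
  stopifnot(nrow(distances) == ncol(distances),
            cluster_threshold <= supercluster_threshold)
  if (anyNA(distances)) stop("distance matrix has missing entries")
  if (is.null(rownames(distances))) {
    rownames(distances) <- colnames(distances) <- sprintf("g%d", seq_len(nrow(distances)))
  }
  data.frame(record_id = rownames(distances),
             cluster_label = threshold_components(distances, cluster_threshold),
             supercluster_label = threshold_components(distances, supercluster_threshold),
             stringsAsFactors = FALSE)
}

#' Correlation between Mash distance and 1 - ANI
#'
#' Pearson correlation between `mash_distance` and `1 - ani` over pairs with
#' a defined ANI; the coherence check between the k-mer and the
#' fragment-alignment views of genome distance.
#'
#' @param results Data frame with `mash_distance` and `ani` columns.
#' @return Pearson r.
#' @export
mash_ani_correlation <- function(results) {
  ok <- !is.na(results$ani)
  if (sum(ok) < 3) stop("need at least 3 pairs with defined ANI")
  x <- results$mash_distance[ok]
  y <- 1 - results$ani[ok]
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance; correlation undefined")
  cor(x, y)
}
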