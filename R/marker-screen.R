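# Marker-protein screening of metagenome contigs: six-frame translation,
# protein local alignment against each frame, the coverage-times-identity
# score used to retain hits, and prevalence profiling by body site.

#' Construct marker protein records
#'
#' @param marker_id Marker identifiers.
#' @param cluster_label Phage cluster each marker diagnoses.
#' @param sequence Amino-acid sequences (20-letter alphabet plus X, length
#'   >= 30).
#' @param supercluster_label Optional supercluster each cluster belongs to.
#' @return A `data.frame`.
#' @export
marker_proteins <- function(marker_id, cluster_label, sequence,
                            supercluster_label = NA_character_) {
  sequence <- toupper(as.character(sequence))
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence))) {
    stop("marker sequences must use the 20-letter amino-acid alphabet plus X")
  }
  if (any(nchar(sequence) < 30)) stop("marker sequences must be >= 30 residues")
  data.frame(marker_id = as.character(marker_id),
             cluster_label = rep_len(as.character(cluster_label), length(marker_id)),
             supercluster_label = rep_len(as.character(supercluster_label), length(marker_id)),
             sequence = sequence, stringsAsFactors = FALSE)
}

#' Six-frame translation of a contig
#'
#' Plain codon translation under the standard genetic code (no start-codon
#' handling); frames +1, +2, +3 and the three frames of the reverse
#' complement. Stop codons are rendered as `*`; trailing partial codons are
#' dropped.
#'
#' @param contig One-row genome record data frame or a sequence string.
#' @return Named character vector of six amino-acid strings
#'   (`F1`, `F2`, `F3`, `R1`, `R2`, `R3`).
#' @export
six_frame_translate <- function(contig) {
  seq <- if (is.character(contig)) contig else contig$sequence
  stopifnot(nchar(seq) >= 3)
  translate_six_frames(seq)[[1]]
}

# Vectorized six-frame translation of many sequences in one call (the per-call
# overhead of S4 translation dominates otherwise).
translate_six_frames <- function(seqs) {
  n <- length(seqs)
  d <- Biostrings::DNAStringSet(toupper(seqs))
  rc <- Biostrings::reverseComplement(d)
  frames <- list()
  for (f in 1:3) {
    for (set in list(fwd = d, rev = rc)) {
      w <- pmax(Biostrings::width(set) - f + 1L, 0L)
      len <- 3L * (w %/% 3L)
      frames[[length(frames) + 1]] <-
        Biostrings::subseq(set, start = pmin(f, Biostrings::width(set) + 1L),
                           width = len)
    }
  }
  # frame order after interleaving: F1, R1, F2, R2, F3, R3
  all6 <- do.call(c, frames)
  aa <- as.character(Biostrings::translate(all6, if.fuzzy.codon = "X"))
  lapply(seq_len(n), function(i) {
    c(F1 = aa[i], F2 = aa[2 * n + i], F3 = aa[4 * n + i],
      R1 = aa[n + i], R2 = aa[3 * n + i], R3 = aa[5 * n + i])
  })
}

# Karlin-Altschul-style constants for BLOSUM62 with gap costs 11/1; the
# resulting E-values are approximate and flagged as such.
EVALUE_LAMBDA <- 0.267
EVALUE_K <- 0.041

# BLOSUM62 with the alignment sentinels used by six-frame translation
# (* for stops, X for fuzzy codons), cached per session.
blosum62_env <- new.env(parent = emptyenv())
blosum62_matrix <- function() {
  if (is.null(blosum62_env$mat)) {
    data("BLOSUM62", package = "Biostrings", envir = blosum62_env)
    blosum62_env$mat <- blosum62_env$BLOSUM62
  }
  blosum62_env$mat
}

#' Search marker proteins against metagenome contigs
#'
#' Each marker is locally aligned (BLOSUM62, affine gaps; a plain
#' Smith-Waterman with NCBI-style gap costs `open + L * extend`) against all
#' six reading frames of each contig; the best-scoring frame yields at most
#' one hit record per (marker, contig) pair. Percent identity is counted
#' over all alignment columns including gaps. E-values follow the
#' `K * m * n * exp(-lambda * S)` form with fixed documented constants and
#' are approximate; downstream filtering should rely primarily on the
#' identity score. Alternatively, externally produced tabular hits can be
#' ingested with [read_tabular_hits()]; both paths feed [identity_score()].
#'
#' @param markers Marker protein data frame (see [marker_proteins()]).
#' @param contigs Genome record data frame; an optional `sample_id` column is
#'   carried into the hits.
#' @param gap_open,gap_extend Affine gap penalties (defaults 11 and 1).
#' @param max_evalue Emission threshold for the approximate E-value
#'   (default 1e-6); weaker alignments are dropped.
#' @return Data frame of hit records: `marker_id`, `contig_id`, `sample_id`,
#'   `query_len`, `aligned_query_span`, `percent_identity`, `e_value`,
#'   `score`, `frame`.
#' @export
search_markers <- function(markers, contigs, gap_open = 11, gap_extend = 1,
                           max_evalue = 1e-6) {
  stopifnot(nrow(markers) > 0, nrow(contigs) > 0)
  mat <- blosum62_matrix()
  alphabet <- paste(rownames(mat), collapse = "")
  sample_ids <- if ("sample_id" %in% names(contigs)) contigs$sample_id else
    rep("", nrow(contigs))

  frames <- translate_six_frames(contigs$sequence)

  hits <- lapply(seq_len(nrow(markers)), function(mi) {
    query <- markers$sequence[mi]
    qlen <- nchar(query)
    out <- lapply(seq_len(nrow(contigs)), function(ci) {
      # score-only pass over the six frames, then traceback on the best one
      best_fr <- NULL
      best_score <- 0
      for (fr in names(frames[[ci]])) {
        aa <- frames[[ci]][[fr]]
        if (nchar(aa) < 1) next
        s <- sw_score_cpp(query, aa, mat, alphabet, gap_open, gap_extend)
        if (is.null(best_fr) || s > best_score) { best_fr <- fr; best_score <- s }
      }
      if (is.null(best_fr) || best_score <= 0) return(NULL)
      n_aa <- nchar(contigs$sequence[ci]) / 3
      ev <- EVALUE_K * qlen * n_aa * exp(-EVALUE_LAMBDA * best_score)
      if (ev > max_evalue) return(NULL)
      best <- sw_align_cpp(query, frames[[ci]][[best_fr]], mat, alphabet,
                           gap_open, gap_extend)
      best$frame <- best_fr
      data.frame(marker_id = markers$marker_id[mi],
                 contig_id = contigs$id[ci],
                 sample_id = sample_ids[ci],
                 query_len = qlen,
                 aligned_query_span = best$qend - best$qstart + 1L,
                 percent_identity = 100 * best$identical / best$columns,
                 e_value = ev,
                 score = best$score,
                 frame = best$frame,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  })
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(marker_id = character(0), contig_id = character(0),
                       sample_id = character(0), query_len = integer(0),
                       aligned_query_span = integer(0),
                       percent_identity = numeric(0), e_value = numeric(0),
                       score = numeric(0), frame = character(0),
                       stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  hits
}

#' Identity score of a hit
#'
#' The retention statistic for translated-search hits: the fraction of the
#' query (marker) covered by the hit, multiplied by the hit's percent
#' identity, on a 0-100 scale. A hit covering the full marker at 96%
#' identity scores 96; a full-identity hit covering 90% of the marker scores
#' 90 and is dropped by the standard 95 threshold.
#'
#' @param hit Hit record data frame (vectorized over rows).
#' @return Numeric score(s) in `[0, 100]`.
#' @export
identity_score <- function(hit) {
  stopifnot(all(hit$aligned_query_span <= hit$query_len))
  (hit$aligned_query_span / hit$query_len) * hit$percent_identity
}

#' Read external tabular hits (12-column format)
#'
#' Standard tabular output of a translated search tool: query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore, plus a 13th `qlen` column (or a side
#' table mapping query to length).
#'
#' @param path Path to the tab-separated hits file (no header).
#' @param query_lengths Optional named vector of query lengths, required when
#'   the file has only 12 columns.
#' @param sample_from_contig Function mapping a contig/subject id to a sample
#'   id (default: identity).
#' @return Hit record data frame compatible with [identity_score()].
#' @export
read_tabular_hits <- function(path, query_lengths = NULL,
                              sample_from_contig = identity) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("tabular hits must have at least 12 columns")
  qlen <- if (ncol(df) >= 13) df[[13]] else {
    if (is.null(query_lengths)) stop("12-column hits need query_lengths")
    unname(query_lengths[df[[1]]])
  }
  span <- abs(df[[8]] - df[[7]]) + 1L
  data.frame(marker_id = df[[1]], contig_id = df[[2]],
             sample_id = vapply(df[[2]], function(x) as.character(sample_from_contig(x)), character(1)),
             query_len = as.integer(qlen),
             aligned_query_span = pmin(as.integer(span), as.integer(qlen)),
             percent_identity = df[[3]], e_value = df[[11]],
             score = df[[12]], frame = NA_character_,
             stringsAsFactors = FALSE)
}

#' Prevalence of phage clusters across samples and body sites
#'
#' A sample is positive for a phage cluster when it has at least one retained
#' hit (E-value at or below `evalue_cutoff` and identity score at or above
#' `score_cutoff`, both inclusive) from any marker of that cluster.
#' Prevalence is positive samples over samples per body site; supercluster
#' prevalence is the union over member clusters.
#'
#' @param hits Hit record data frame.
#' @param metadata Sample metadata (see [sample_metadata()]); every hit's
#'   `sample_id` must be present.
#' @param markers Marker protein data frame mapping markers to clusters (and
#'   optionally superclusters).
#' @param evalue_cutoff E-value retention cutoff (default 1e-80).
#' @param score_cutoff Identity-score retention cutoff (default 95,
#'   inclusive).
#' @return A list: `presence` (sample x cluster logical presence table with
#'   the body site as group), `prevalence` (long data frame per site x
#'   cluster and, when superclusters are defined, per site x supercluster).
#' @export
profile_prevalence <- function(hits, metadata, markers,
                               evalue_cutoff = 1e-80, score_cutoff = 95) {
  unknown <- setdiff(hits$sample_id, metadata$sample_id)
  if (length(unknown) > 0) {
    stop(sprintf("hits reference unknown sample ids: %s",
                 paste(unique(unknown), collapse = ", ")))
  }
  clusters <- sort(unique(markers$cluster_label))
  retained <- hits[hits$e_value <= evalue_cutoff &
                     identity_score(hits) >= score_cutoff, , drop = FALSE]
  retained$cluster <- markers$cluster_label[match(retained$marker_id, markers$marker_id)]

  presence <- data.frame(id = metadata$sample_id, group = metadata$body_site,
                         stringsAsFactors = FALSE)
  for (cl in clusters) {
    pos <- unique(retained$sample_id[retained$cluster == cl])
    presence[[cl]] <- presence$id %in% pos
  }

  site_split <- split(seq_len(nrow(presence)), presence$group)
  prev_rows <- list()
  for (site in names(site_split)) {
    idx <- site_split[[site]]
    for (cl in clusters) {
      npos <- sum(presence[[cl]][idx])
      prev_rows[[length(prev_rows) + 1]] <- data.frame(
        body_site = site, label = cl, level = "cluster",
        n_samples = length(idx), n_positive = npos,
        prevalence = npos / length(idx), stringsAsFactors = FALSE)
    }
    sc_map <- unique(markers[, c("cluster_label", "supercluster_label")])
    sc_map <- sc_map[!is.na(sc_map$supercluster_label), , drop = FALSE]
    for (sc in unique(sc_map$supercluster_label)) {
      members <- sc_map$cluster_label[sc_map$supercluster_label == sc]
      pos_any <- Reduce(`|`, lapply(members, function(cl) presence[[cl]][idx]))
      npos <- sum(pos_any)
      prev_rows[[length(prev_rows) + 1]] <- data.frame(
        body_site = site, label = sc, level = "supercluster",
        n_samples = length(idx), n_positive = npos,
        prevalence = npos / length(idx), stringsAsFactors = FALSE)
    }
  }
  list(presence = presence, prevalence = do.call(rbind, prev_rows))
}

#' Species presence from a relative-abundance table
#'
#' A species is regarded as present in a sample when its relative abundance
#' is strictly greater than the threshold (default 0.1%).
#'
#' @param abundance Numeric matrix (species x samples) of relative abundance
#'   percentages in `[0, 100]`.
#' @param threshold_percent Presence threshold (strict), default 0.1.
#' @return Logical matrix of the same shape.
#' @export
species_presence <- function(abundance, threshold_percent = 0.1) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0 | abundance > 100)) {
    stop("abundances must be percentages in [0, 100]")
  }
  abundance > threshold_percent
}
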