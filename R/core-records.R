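#' Construct a collection of genome records
#'
#' The unit flowing through every stage of the analysis: an identifier, a
#' nucleotide sequence over the IUPAC alphabet, and optional host metadata
#' (species, clade, niche). Stored as a plain data frame with one row per
#' record.
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param sequence Character vector of nucleotide sequences (uppercased on
#'   construction; IUPAC letters only, length >= 1).
#' @param species,clade,niche Optional metadata, recycled to length.
#' @return A `data.frame` with columns `id`, `sequence`, `species`, `clade`,
#'   `niche`.
#' @examples
#' genome_records("g1", "ACGT", species = "H. influenzae")
#' @export
genome_records <- function(id, sequence, species = "", clade = "", niche = "") {
  id <- as.character(id)
  sequence <- as.character(sequence)
  stopifnot(length(id) == length(sequence))
  if (any(!nzchar(id))) stop("record ids must be non-empty")
  if (anyDuplicated(id)) stop("record ids must be unique within a collection")
  if (any(nchar(sequence) < 1)) stop("sequences must have length >= 1")
  sequence <- vapply(seq_along(sequence), function(i) {
    check_iupac(sequence[i], what = sprintf("sequence of record '%s'", id[i]))
  }, character(1))
  data.frame(id = id, sequence = sequence,
             species = rep_len(as.character(species), length(id)),
             clade = rep_len(as.character(clade), length(id)),
             niche = rep_len(as.character(niche), length(id)),
             stringsAsFactors = FALSE)
}

# Pre-parse line scan used to attach line numbers to FASTA format errors.
validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) stop(sprintf("'%s': empty FASTA file", path), call. = FALSE)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("'%s' line %d: malformed header (expected '>')",
                 path, nonblank[1]), call. = FALSE)
  }
  pat <- sprintf("[^%s%s]", paste(IUPAC_CHARS, collapse = ""),
                 tolower(paste(IUPAC_CHARS, collapse = "")))
  for (i in nonblank) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      if (nchar(ln) < 2) {
        stop(sprintf("'%s' line %d: malformed header (empty id)", path, i),
             call. = FALSE)
      }
      next
    }
    if (grepl(pat, ln)) {
      stop(sprintf("'%s' line %d: non-IUPAC character in sequence", path, i),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a FASTA file into a genome record collection
#'
#' Sequences are uppercased and record order is preserved; the identifier is
#' the first whitespace-delimited token of the header. A malformed header or
#' a non-IUPAC character raises a format error naming the offending line.
#'
#' @param path Path to a FASTA file (multi-record, line wrapping allowed).
#' @return A genome record data frame (see [genome_records()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  validate_fasta_lines(path)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  genome_records(id = ids, sequence = toupper(as.character(set)))
}

#' Write genome records to FASTA
#'
#' Sequences are wrapped at 70 columns. `read_fasta(write_fasta(x))` is the
#' identity on record id and sequence.
#'
#' @param records Genome record data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Construct prophage annotation records
#'
#' One row per predicted prophage: the completeness score and ORF count from
#' upstream prophage prediction (inputs here, not recomputed), the host genome
#' link and host species used by deduplication, and optionally the prophage
#' nucleotide sequence.
#'
#' @param prophage_id,host_genome_id Character identifiers.
#' @param completeness_score Integer in 0-150.
#' @param orf_count Non-negative integer.
#' @param sequence Optional nucleotide sequences (`NA` allowed).
#' @param host_species Host species metadata used by [deduplicate()].
#' @return A `data.frame` with an `is_duplicate` logical column (all `FALSE`).
#' @export
prophage_annotations <- function(prophage_id, host_genome_id,
                                 completeness_score, orf_count,
                                 sequence = NA_character_, host_species = "") {
  n <- length(prophage_id)
  completeness_score <- as.integer(completeness_score)
  orf_count <- as.integer(orf_count)
  if (any(completeness_score < 0 | completeness_score > 150)) {
    stop("completeness_score must be within 0-150")
  }
  if (any(orf_count < 0)) stop("orf_count must be >= 0")
  data.frame(prophage_id = as.character(prophage_id),
             host_genome_id = rep_len(as.character(host_genome_id), n),
             completeness_score = completeness_score,
             orf_count = orf_count,
             sequence = rep_len(as.character(sequence), n),
             host_species = rep_len(as.character(host_species), n),
             is_duplicate = FALSE,
             stringsAsFactors = FALSE)
}

#' Prophage inclusion filter
#'
#' Keeps putatively intact prophages: completeness score strictly greater
#' than `min_score`, at least `min_orfs` predicted ORFs, and not flagged as a
#' duplicate. The score comparison is strict and the ORF comparison
#' inclusive, matching the ">90 score, at least 40 ORFs" convention for
#' intact prophage calls.
#'
#' @param annotations Prophage annotation data frame.
#' @param min_score Score threshold (kept if strictly greater). Default 90.
#' @param min_orfs ORF threshold (kept if greater or equal). Default 40.
#' @return The subset of rows passing the filter (possibly empty).
#' @export
filter_prophages <- function(annotations, min_score = 90, min_orfs = 40) {
  stopifnot(nrow(annotations) > 0, min_score >= 0, min_orfs >= 0)
  keep <- annotations$completeness_score > min_score &
    annotations$orf_count >= min_orfs &
    !annotations$is_duplicate
  annotations[keep, , drop = FALSE]
}

# Minimal union-find used for duplicate groups and threshold clustering.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}
uf_components <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

#' Flag duplicated prophage entries
#'
#' Automates the manual duplicate screen: within every group of records at
#' pairwise distance `<= max_distance` (groups formed transitively) that share
#' identical host species metadata, all but the first record in id sort order
#' are flagged as duplicates. The default distance cap of 0.001 with a
#' Mash-style distance is a reproducible proxy for "the same phage
#' re-sequenced under a different name".
#'
#' @param annotations Prophage annotation data frame with sequences.
#' @param distance_fn Symmetric non-negative function of two sequences.
#' @param max_distance Distance at or below which two same-species records are
#'   considered duplicates.
#' @return `annotations` with the `is_duplicate` column set.
#' @export
deduplicate <- function(annotations, distance_fn, max_distance = 0.001) {
  stopifnot(is.function(distance_fn), max_distance >= 0)
  n <- nrow(annotations)
  annotations$is_duplicate <- FALSE
  if (n < 2) return(annotations)
  parent <- uf_new(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (!identical(annotations$host_species[i], annotations$host_species[j])) next
      d <- distance_fn(annotations$sequence[i], annotations$sequence[j])
      if (is.finite(d) && d <= max_distance) parent <- uf_union(parent, i, j)
    }
  }
  comp <- uf_components(parent)
  for (g in unique(comp)) {
    members <- which(comp == g)
    if (length(members) < 2) next
    first <- members[order(annotations$prophage_id[members])][1]
    annotations$is_duplicate[setdiff(members, first)] <- TRUE
  }
  annotations
}

#' Read / write prophage annotation tables
#'
#' Tab-separated with a header row (`prophage_id`, `host_genome_id`,
#' `completeness_score`, `orf_count`, optional `host_species`), UTF-8.
#'
#' @param path File path.
#' @return For the reader, a prophage annotation data frame.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_stable(path)
  need <- c("prophage_id", "host_genome_id", "completeness_score", "orf_count")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop(sprintf("annotation table '%s' lacks columns: %s", path,
                 paste(missing, collapse = ", ")))
  }
  prophage_annotations(df$prophage_id, df$host_genome_id,
                       df$completeness_score, df$orf_count,
                       sequence = df$sequence %||% NA_character_,
                       host_species = df$host_species %||% "")
}

#' @rdname read_annotations
#' @param annotations Prophage annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  cols <- intersect(c("prophage_id", "host_genome_id", "completeness_score",
                      "orf_count", "host_species", "is_duplicate"),
                    names(annotations))
  write_tsv_stable(annotations[, cols, drop = FALSE], path)
}

#' Construct sample metadata
#'
#' @param sample_id Unique sample identifiers.
#' @param body_site Body-site label per sample (e.g. tongue, gingiva).
#' @param subject_group Optional grouping label.
#' @return A `data.frame`.
#' @export
sample_metadata <- function(sample_id, body_site, subject_group = "") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample_id must be unique")
  data.frame(sample_id = sample_id,
             body_site = rep_len(as.character(body_site), length(sample_id)),
             subject_group = rep_len(as.character(subject_group), length(sample_id)),
             stringsAsFactors = FALSE)
}
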