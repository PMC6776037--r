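# Per-megabase profiling of DNA uptake signal sequences (USSs). Naturally
# competent Pasteurellaceae preferentially take up DNA carrying short uptake
# signal motifs; two dialects exist, the H. influenzae-like (Hin) and the
# A. pleuropneumoniae-like (Apl) core. Phages that have coevolved with such
# hosts accumulate these motifs, so their genomic density (per Mb, both
# orientations) separates Pasteurellaceae-lysogenizing phages from others.

#' Specification of a USS motif
#'
#' @param name Motif label, e.g. `"Hin-USS"`.
#' @param core Core nucleotide string (A/C/G/T only, length >= 4, and not its
#'   own reverse complement, since counting in both orientations assumes the
#'   two strands are distinguishable).
#' @param max_mismatch 0 or 1; the single-mismatch profile is reported
#'   alongside the exact profile, never instead of it.
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(name, core, max_mismatch = 1) {
  core <- toupper(core)
  stopifnot(nchar(core) >= 4, max_mismatch %in% c(0, 1))
  if (grepl("[^ACGT]", core)) stop("motif core must contain only A, C, G, T")
  if (identical(core, revcomp(core))) {
    stop("motif core must not be its own reverse complement")
  }
  structure(list(name = name, core = core, max_mismatch = as.integer(max_mismatch)),
            class = "motif_spec")
}

#' Default USS motif pair
#'
#' The canonical 9-mer cores of the two USS dialects: Hin-USS `AAGTGCGGT`
#' and Apl-USS `ACAAGCGGT`. Both are overridable wherever a motif pair is
#' accepted.
#'
#' @return A list with elements `hin` and `apl`.
#' @export
default_motifs <- function() {
  list(hin = motif_spec("Hin-USS", "AAGTGCGGT"),
       apl = motif_spec("Apl-USS", "ACAAGCGGT"))
}

# Window starts whose window of width w contains a non-ACGT character.
bad_window_starts <- function(seq, w) {
  bad <- gregexpr("[^ACGT]", seq)[[1]]
  if (length(bad) == 1 && bad[1] == -1) return(integer(0))
  starts <- unlist(lapply(bad, function(p) max(1L, p - w + 1L):p))
  unique(starts[starts <= nchar(seq) - w + 1L])
}

#' Count motif occurrences in both orientations
#'
#' Occurrences of the core and of its reverse complement as substrings of the
#' uppercased sequence; overlapping occurrences are counted, and windows
#' containing a non-ACGT character are excluded. The one-mismatch count is
#' the number of windows within Hamming distance 1 of either orientation
#' (a superset of the exact count).
#'
#' @param sequence Nucleotide string.
#' @param motif A [motif_spec()].
#' @return Named integer vector `c(exact, one_mismatch)`. A motif longer than
#'   the sequence yields zero counts.
#' @export
count_motif <- function(sequence, motif) {
  stopifnot(inherits(motif, "motif_spec"), nchar(sequence) > 0)
  seq <- toupper(sequence)
  w <- nchar(motif$core)
  if (w > nchar(seq)) return(c(exact = 0L, one_mismatch = 0L))
  subj <- Biostrings::DNAString(gsub("[^ACGT]", "N", seq))
  bad <- bad_window_starts(seq, w)
  starts_at <- function(pattern, mm) {
    m <- Biostrings::matchPattern(pattern, subj, max.mismatch = mm, fixed = TRUE)
    s <- IRanges::start(m)
    # drop boundary matches hanging off the sequence ends
    s <- s[s >= 1 & s <= nchar(seq) - w + 1]
    setdiff(s, bad)
  }
  fwd <- motif$core
  rev <- revcomp(motif$core)
  exact <- length(starts_at(fwd, 0)) + length(starts_at(rev, 0))
  one_mm <- length(union(starts_at(fwd, 1), starts_at(rev, 1)))
  c(exact = as.integer(exact), one_mismatch = as.integer(one_mm))
}

#' USS / GC profile of a genome record
#'
#' GC% is `100 * (G + C) / (A + C + G + T)`; each motif frequency is
#' `count * 1e6 / length_acgt`. N and ambiguity codes are excluded from both
#' numerator and denominator, so padding cannot deflate densities.
#'
#' @param record One-row genome record data frame (or a list with `id` and
#'   `sequence`).
#' @param motifs Motif pair as from [default_motifs()].
#' @return A one-row data frame: `record_id`, `length_acgt`, `gc_percent`,
#'   `hin_per_mb`, `apl_per_mb`, `hin_per_mb_1mm`, `apl_per_mb_1mm`.
#' @export
uss_profile <- function(record, motifs = default_motifs()) {
  seq <- toupper(record$sequence)
  counts <- Biostrings::letterFrequency(Biostrings::BString(seq),
                                        c("A", "C", "G", "T"))
  length_acgt <- sum(counts)
  if (length_acgt == 0) stop("sequence has no A/C/G/T bases; profile undefined")
  gc_percent <- 100 * (counts[["C"]] + counts[["G"]]) / length_acgt
  hin <- count_motif(seq, motifs$hin)
  apl <- count_motif(seq, motifs$apl)
  per_mb <- function(x) x * 1e6 / length_acgt
  data.frame(record_id = record$id, length_acgt = as.integer(length_acgt),
             gc_percent = gc_percent,
             hin_per_mb = per_mb(hin[["exact"]]),
             apl_per_mb = per_mb(apl[["exact"]]),
             hin_per_mb_1mm = per_mb(hin[["one_mismatch"]]),
             apl_per_mb_1mm = per_mb(apl[["one_mismatch"]]),
             stringsAsFactors = FALSE)
}

#' Profile a collection of genome records
#'
#' @param records Genome record data frame.
#' @param motifs Motif pair.
#' @param cutoff_per_mb Classifier cutoff passed to [classify_lysogenizer()];
#'   the resulting `classified` column is appended.
#' @return Data frame of per-record profiles.
#' @export
uss_profile_table <- function(records, motifs = default_motifs(),
                              cutoff_per_mb = 100) {
  profiles <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    uss_profile(records[i, , drop = FALSE], motifs)
  }))
  profiles$classified <- classify_lysogenizer(profiles, cutoff_per_mb)
  profiles
}

#' Classify a phage as Pasteurellaceae-lysogenizing from its USS profile
#'
#' A phage is classified positive when either exact USS frequency reaches the
#' cutoff: `hin_per_mb >= cutoff` or `apl_per_mb >= cutoff` (inclusive
#' boundary). The default cutoff of 100 per Mb cleanly separates phages that
#' lysogenize Pasteurellaceae from other tailed phages.
#'
#' @param profile USS profile data frame (one or more rows).
#' @param cutoff_per_mb Non-negative frequency cutoff per Mb.
#' @return Logical vector, one element per profile row.
#' @export
classify_lysogenizer <- function(profile, cutoff_per_mb = 100) {
  if (cutoff_per_mb < 0) stop("cutoff_per_mb must be non-negative")
  profile$hin_per_mb >= cutoff_per_mb | profile$apl_per_mb >= cutoff_per_mb
}
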