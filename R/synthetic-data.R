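# Seeded generators emulating the statistical structure of the study inputs:
# genomes with controlled GC%, planted uptake-signal motifs, diverged phage
# families, lysogeny presence tables with clade effects, and fragmented
# metagenome contigs. All generators are pure functions of their spec (seed
# included).

#' Specification for a synthetic genome
#'
#' @param length Genome length in nucleotides.
#' @param gc_target Target GC fraction in `[0, 1]`; bases are drawn i.i.d.
#'   with `P(G) = P(C) = gc_target / 2`.
#' @param hin_density,apl_density Planted motifs per Mb (non-negative reals);
#'   `round(density * length / 1e6)` copies of each motif are planted at
#'   uniformly chosen non-overlapping positions, each independently in
#'   forward or reverse-complement orientation with probability 1/2.
#' @param seed Integer seed (required; generators never touch global RNG
#'   state).
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(length, gc_target, hin_density = 0, apl_density = 0, seed) {
  stopifnot(length >= 1, gc_target >= 0, gc_target <= 1,
            hin_density >= 0, apl_density >= 0)
  structure(list(length = as.integer(length), gc_target = gc_target,
                 hin_density = hin_density, apl_density = apl_density,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# i.i.d. background bases at a target GC fraction.
random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic genome with planted USS motifs
#'
#' Background bases are i.i.d. at the target GC; then the requested number of
#' copies of each motif core is planted at non-overlapping positions
#' (overwriting background bases, so the genome length stays exact), each in
#' a random orientation. Placement uses rejection sampling with a retry cap;
#' an infeasible density raises an error naming it. Deterministic given the
#' spec (seed included).
#'
#' @param spec A [genome_spec()].
#' @param id Record identifier.
#' @param motifs List with elements `hin` and `apl` (see [motif_spec()]);
#'   defaults to the canonical Hin/Apl 9-mers.
#' @return A one-row genome record data frame with attribute `planted`, a
#'   data frame of (motif, start, strand) for every planted copy.
#' @export
generate_genome <- function(spec, id = "synthetic_genome", motifs = default_motifs()) {
  stopifnot(inherits(spec, "genome_spec"))
  n_hin <- round(spec$hin_density * spec$length / 1e6)
  n_apl <- round(spec$apl_density * spec$length / 1e6)
  cores <- c(rep(motifs$hin$core, n_hin), rep(motifs$apl$core, n_apl))
  names(cores) <- c(rep(motifs$hin$name, n_hin), rep(motifs$apl$name, n_apl))
  if (length(cores) > 0 && spec$length < max(nchar(cores))) {
    stop("genome length shorter than motif length with positive density")
  }
  with_seed(spec$seed, {
    bases <- random_bases(spec$length, spec$gc_target)
    res <- tryCatch(plant_motif_copies(bases, cores), error = function(e) {
      stop(sprintf("infeasible motif placement at hin_density=%g, apl_density=%g per Mb: %s",
                   spec$hin_density, spec$apl_density, conditionMessage(e)),
           call. = FALSE)
    })
    rec <- genome_records(id, paste(res$bases, collapse = ""))
    attr(rec, "planted") <- res$planted
    rec
  })
}

# Plant named motif copies (a character vector of cores, names = motif
# labels) at uniformly chosen non-overlapping positions, each in a random
# orientation, overwriting background bases. Uses the active RNG stream;
# callers are responsible for seeding. Rejection sampling with a retry cap.
plant_motif_copies <- function(bases, cores, max_retry = 10000L) {
  len <- length(bases)
  occupied_start <- integer(0)
  occupied_end <- integer(0)
  planted <- vector("list", length(cores))
  for (m in seq_along(cores)) {
    w <- nchar(cores[m])
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      pos <- sample.int(len - w + 1L, 1L)
      if (!any(pos <= occupied_end & (pos + w - 1L) >= occupied_start)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("could not place motif %s (copy %d of %d in %d nt): density infeasible",
                   names(cores)[m], m, length(cores), len))
    }
    strand <- if (runif(1) < 0.5) "+" else "-"
    seq_m <- if (strand == "+") cores[m] else revcomp(cores[m])
    bases[pos:(pos + w - 1L)] <- strsplit(seq_m, "", fixed = TRUE)[[1]]
    occupied_start <- c(occupied_start, pos)
    occupied_end <- c(occupied_end, pos + w - 1L)
    planted[[m]] <- data.frame(motif = names(cores)[m], start = pos,
                               strand = strand, stringsAsFactors = FALSE)
  }
  list(bases = bases,
       planted = if (length(planted) > 0) do.call(rbind, planted) else
         data.frame(motif = character(0), start = integer(0),
                    strand = character(0)))
}

#' Plant USS motifs into an existing sequence
#'
#' Overwrites background bases of `sequence` with `n_hin` copies of the Hin
#' core and `n_apl` copies of the Apl core at non-overlapping uniform
#' positions (random orientation each). Deterministic given the seed.
#'
#' @param sequence Nucleotide string.
#' @param n_hin,n_apl Number of copies of each motif core.
#' @param seed Integer seed.
#' @param motifs Motif pair (see [default_motifs()]).
#' @return The sequence with motifs planted; attribute `planted` lists the
#'   placements.
#' @export
plant_uss <- function(sequence, n_hin, n_apl, seed, motifs = default_motifs()) {
  cores <- c(rep(motifs$hin$core, n_hin), rep(motifs$apl$core, n_apl))
  names(cores) <- c(rep(motifs$hin$name, n_hin), rep(motifs$apl$name, n_apl))
  with_seed(seed, {
    res <- plant_motif_copies(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], cores)
    structure(paste(res$bases, collapse = ""), planted = res$planted)
  })
}

#' Specification for a diverged genome family
#'
#' @param ancestor A [genome_spec()] for the shared ancestor.
#' @param n_members Number of family members (each derived independently from
#'   the ancestor).
#' @param substitution_rate Per-site substitution rate in `[0, 0.5)`;
#'   substituted bases are drawn uniformly among the three alternatives
#'   (Jukes-Cantor-like), giving the closed-form expected pairwise identity
#'   `(1 - r)^2 + r^2 / 3`.
#' @param seed Integer seed.
#' @return A `family_spec` list.
#' @export
family_spec <- function(ancestor, n_members, substitution_rate, seed) {
  stopifnot(inherits(ancestor, "genome_spec"), n_members >= 1,
            substitution_rate >= 0, substitution_rate < 0.5)
  structure(list(ancestor = ancestor, n_members = as.integer(n_members),
                 substitution_rate = substitution_rate, seed = as.integer(seed)),
            class = "family_spec")
}

# Substitute bases i.i.d. at rate r, uniformly among the 3 alternatives.
mutate_sequence <- function(seq, r) {
  if (r <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(chars)) < r)
  if (length(idx) > 0) {
    alphabet <- c("A", "C", "G", "T")
    code <- match(chars[idx], alphabet)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    chars[idx] <- alphabet[((code - 1L + shift) %% 4L) + 1L]
  }
  paste(chars, collapse = "")
}

#' Generate a family of diverged genomes with an identity truth table
#'
#' @param spec A [family_spec()].
#' @param id_prefix Identifier prefix for members.
#' @return A list with `records` (genome record data frame) and `truth`
#'   (data frame of all member pairs with the expected pairwise identity
#'   `(1 - r)^2 + r^2 / 3`).
#' @export
generate_family <- function(spec, id_prefix = "member") {
  stopifnot(inherits(spec, "family_spec"))
  ancestor <- generate_genome(spec$ancestor, id = "ancestor")
  r <- spec$substitution_rate
  members <- with_seed(spec$seed, {
    vapply(seq_len(spec$n_members), function(i) {
      mutate_sequence(ancestor$sequence, r)
    }, character(1))
  })
  ids <- sprintf("%s_%02d", id_prefix, seq_len(spec$n_members))
  records <- genome_records(ids, members)
  expected <- (1 - r)^2 + r^2 / 3
  pairs <- if (spec$n_members >= 2) t(combn(ids, 2)) else matrix(character(0), ncol = 2)
  truth <- data.frame(id_a = pairs[, 1], id_b = pairs[, 2],
                      expected_identity = rep(expected, nrow(pairs)),
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Design for a synthetic lysogeny presence table
#'
#' @param clade_names,cluster_names Row-group and column labels.
#' @param prevalence_matrix Matrix of carriage probabilities, clades in rows
#'   and clusters in columns, values in `[0, 1]`.
#' @param n_per_clade Number of genomes per clade (recycled).
#' @param seed Integer seed.
#' @return A `lysogeny_design` list.
#' @export
lysogeny_design <- function(clade_names, cluster_names, prevalence_matrix,
                            n_per_clade, seed) {
  prevalence_matrix <- as.matrix(prevalence_matrix)
  stopifnot(nrow(prevalence_matrix) == length(clade_names),
            ncol(prevalence_matrix) == length(cluster_names),
            all(prevalence_matrix >= 0), all(prevalence_matrix <= 1),
            all(n_per_clade >= 1))
  structure(list(clade_names = clade_names, cluster_names = cluster_names,
                 prevalence_matrix = prevalence_matrix,
                 n_per_clade = rep_len(as.integer(n_per_clade), length(clade_names)),
                 seed = as.integer(seed)),
            class = "lysogeny_design")
}

#' Generate a lysogeny presence table
#'
#' Each genome's carriage of each phage cluster is drawn
#' `Bernoulli(prevalence_matrix[clade, cluster])`; clade labels are attached
#' as the group column.
#'
#' @param design A [lysogeny_design()].
#' @return A presence table data frame: `id`, `group`, then one logical
#'   column per cluster.
#' @export
generate_lysogeny_table <- function(design) {
  stopifnot(inherits(design, "lysogeny_design"))
  with_seed(design$seed, {
    rows <- lapply(seq_along(design$clade_names), function(ci) {
      n <- design$n_per_clade[ci]
      carriage <- vapply(seq_along(design$cluster_names), function(cl) {
        as.logical(rbinom(n, 1, design$prevalence_matrix[ci, cl]))
      }, logical(n))
      carriage <- matrix(carriage, nrow = n)
      df <- data.frame(id = sprintf("%s_g%02d", design$clade_names[ci], seq_len(n)),
                       group = design$clade_names[ci], stringsAsFactors = FALSE)
      cbind(df, setNames(as.data.frame(carriage), design$cluster_names))
    })
    do.call(rbind, rows)
  })
}

#' Generate fragmented metagenome contigs from phage genomes
#'
#' Contigs are uniformly placed substrings of the phage genomes, with source
#' phages sampled proportionally to abundance. Truth labels record which
#' contigs overlap a phage's marker interval by at least half the marker
#' length.
#'
#' @param phages Genome record data frame of source phages.
#' @param marker_positions Named list mapping phage id to a `c(start, end)`
#'   marker interval (1-based, inclusive) or `NULL` when the phage carries no
#'   marker.
#' @param abundance Named non-negative numeric of relative abundances (sum
#'   must be positive).
#' @param n_contigs Number of contigs to draw.
#' @param contig_len Either a single length or `c(min, max)` for uniform
#'   integer lengths.
#' @param seed Integer seed.
#' @param id_prefix Contig identifier prefix.
#' @return A list with `contigs` (genome records) and `truth` (data frame:
#'   contig_id, source_id, start, end, marker_overlap, marker_positive).
#' @export
generate_metagenome <- function(phages, marker_positions, abundance,
                                n_contigs, contig_len, seed,
                                id_prefix = "contig") {
  stopifnot(sum(abundance) > 0, n_contigs >= 1)
  abundance <- abundance[phages$id]
  if (any(is.na(abundance))) stop("abundance must be named by phage id")
  lens <- nchar(phages$sequence)
  max_len <- if (length(contig_len) == 1) contig_len else max(contig_len)
  if (any(max_len > lens[abundance > 0])) {
    stop("contig length exceeds length of a sampled phage genome")
  }
  with_seed(seed, {
    src <- sample.int(nrow(phages), n_contigs, replace = TRUE,
                      prob = abundance / sum(abundance))
    clen <- if (length(contig_len) == 1) {
      rep_len(as.integer(contig_len), n_contigs)
    } else {
      sample(seq(contig_len[1], contig_len[2]), n_contigs, replace = TRUE)
    }
    start <- vapply(seq_len(n_contigs), function(i) {
      sample.int(lens[src[i]] - clen[i] + 1L, 1L)
    }, integer(1))
    end <- start + clen - 1L
    seqs <- substring(phages$sequence[src], start, end)
    ids <- sprintf("%s_%04d", id_prefix, seq_len(n_contigs))
    overlap <- vapply(seq_len(n_contigs), function(i) {
      mk <- marker_positions[[phages$id[src[i]]]]
      if (is.null(mk)) return(0L)
      as.integer(max(0L, min(end[i], mk[2]) - max(start[i], mk[1]) + 1L))
    }, integer(1))
    marker_len <- vapply(seq_len(n_contigs), function(i) {
      mk <- marker_positions[[phages$id[src[i]]]]
      if (is.null(mk)) return(NA_integer_)
      as.integer(mk[2] - mk[1] + 1L)
    }, integer(1))
    truth <- data.frame(contig_id = ids, source_id = phages$id[src],
                        start = start, end = end, marker_overlap = overlap,
                        marker_positive = !is.na(marker_len) &
                          overlap >= 0.5 * marker_len,
                        stringsAsFactors = FALSE)
    list(contigs = genome_records(ids, seqs), truth = truth)
  })
}

# Inverted genetic code for reverse translation (standard code, stops omitted).
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Reverse-translate an amino-acid sequence to DNA
#'
#' Codons are drawn uniformly among synonymous codons of the standard genetic
#' code; deterministic given the seed.
#'
#' @param aa Amino-acid string (20-letter alphabet).
#' @param seed Integer seed.
#' @return A DNA string of length `3 * nchar(aa)`.
#' @export
reverse_translate <- function(aa, seed) {
  tab <- codons_by_aa()
  chars <- strsplit(toupper(aa), "", fixed = TRUE)[[1]]
  if (!all(chars %in% names(tab))) {
    stop("amino-acid sequence contains letters without codons")
  }
  with_seed(seed, {
    paste(vapply(chars, function(a) {
      cods <- tab[[a]]
      cods[sample.int(length(cods), 1L)]
    }, character(1)), collapse = "")
  })
}

#' Substitute amino acids at a fixed per-site rate
#'
#' Substituted residues are drawn uniformly among the 19 alternatives.
#'
#' @param aa Amino-acid string.
#' @param rate Per-site substitution probability.
#' @param seed Integer seed.
#' @return The mutated amino-acid string.
#' @export
mutate_protein <- function(aa, rate, seed) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
  chars <- strsplit(toupper(aa), "", fixed = TRUE)[[1]]
  with_seed(seed, {
    idx <- which(runif(length(chars)) < rate)
    for (i in idx) chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
    paste(chars, collapse = "")
  })
}

#' Embed a protein-coding marker into a genome record
#'
#' The protein is reverse-translated and the encoding DNA overwrites the
#' genome at the given position (no insertion, so length is preserved).
#'
#' @param record One-row genome record data frame.
#' @param protein Amino-acid string.
#' @param at 1-based start position.
#' @param seed Integer seed for codon choice.
#' @return The record with the marker embedded; attribute `marker_interval`
#'   holds `c(start, end)`.
#' @export
embed_marker <- function(record, protein, at, seed) {
  dna <- reverse_translate(protein, seed)
  w <- nchar(dna)
  if (at < 1 || at + w - 1 > nchar(record$sequence)) {
    stop("marker does not fit in the genome at the given position")
  }
  substr(record$sequence, at, at + w - 1) <- dna
  attr(record, "marker_interval") <- c(at, at + w - 1)
  record
}

#' Generate a random protein sequence
#'
#' @param length Number of residues.
#' @param seed Integer seed.
#' @return An amino-acid string.
#' @export
random_protein <- function(length, seed) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
  with_seed(seed, paste(sample(alphabet, length, replace = TRUE), collapse = ""))
}
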