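# Configuration-driven end-to-end orchestration over the synthetic study:
# simulate -> filter -> cluster -> profile USS -> screen metagenomes ->
# prevalence/richness statistics -> coevolution ordination, with a
# reproducibility manifest. Stage outputs are plain files, so any stage can
# be rerun in isolation, and a rerun with the same config is byte-identical.

#' Default pipeline configuration
#'
#' All thresholds carry their standard defaults (prophage score > 90, >= 40
#' ORFs, Mash k = 21 / sketch 1000, dotplot word 10, E-value 1e-80, identity
#' score 95, USS cutoff 100 per Mb, species presence > 0.1%), and the
#' synthetic section fully specifies the emulated study: four host clades
#' with dialect-specific USS densities, six phage clusters in three
#' superclusters, a lysogeny design with clade-specific enrichment, and a
#' three-site metagenome. The config fully serializes a run; unknown keys
#' are rejected by [validate_config()].
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 20170301) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, filter = TRUE, cluster = TRUE,
                  profile_uss = TRUE, screen = TRUE, stats = TRUE,
                  ordinate = TRUE),
    thresholds = list(
      min_score = 90, min_orfs = 40,
      k = 21, sketch_size = 1000, word_length = 10,
      evalue_cutoff = 1e-80, identity_score_cutoff = 95,
      uss_cutoff_per_mb = 100, presence_threshold_percent = 0.1,
      cluster_threshold = 0.09, supercluster_threshold = 0.25,
      dedup_max_distance = 0.001),
    motifs = list(hin = "AAGTGCGGT", apl = "ACAAGCGGT"),
    rarefaction = list(replicates = 10),
    ordination = list(dims = 2, n_restarts = 20, max_iter = 300, tol = 1e-7),
    synthetic = list(
      clades = list(
        list(name = "Hinf", species = "H_influenzae", gc = 0.38,
             hin_density = 750, apl_density = 30, genome_length = 150000, n_genomes = 4),
        list(name = "Hpar", species = "H_parainfluenzae", gc = 0.40,
             hin_density = 600, apl_density = 50, genome_length = 150000, n_genomes = 4),
        list(name = "Aact", species = "A_actinomycetemcomitans", gc = 0.44,
             hin_density = 500, apl_density = 40, genome_length = 150000, n_genomes = 4),
        list(name = "Hhae", species = "H_parahaemolyticus", gc = 0.41,
             hin_density = 60, apl_density = 550, genome_length = 150000, n_genomes = 4)),
      superclusters = list(
        list(name = "SC1", gc = 0.39),
        list(name = "SC2", gc = 0.43),
        list(name = "SC3", gc = 0.41)),
      sc_divergence = 0.08,
      phage_genome_length = 40000,
      clusters = list(
        list(name = "C01", supercluster = "SC1", host_clade = "Hinf",
             hin_density = 450, apl_density = 20, n_members = 4, divergence = 0.03),
        list(name = "C02", supercluster = "SC1", host_clade = "Hinf",
             hin_density = 380, apl_density = 25, n_members = 4, divergence = 0.03),
        list(name = "C03", supercluster = "SC2", host_clade = "Hpar",
             hin_density = 350, apl_density = 30, n_members = 4, divergence = 0.03),
        list(name = "C04", supercluster = "SC2", host_clade = "Aact",
             hin_density = 300, apl_density = 25, n_members = 4, divergence = 0.03),
        list(name = "C05", supercluster = "SC3", host_clade = "Hhae",
             hin_density = 40, apl_density = 350, n_members = 4, divergence = 0.03),
        list(name = "C06", supercluster = "SC3", host_clade = "Hhae",
             hin_density = 30, apl_density = 300, n_members = 4, divergence = 0.03)),
      decoys = list(n_low_score = 6, n_low_orf = 4, n_duplicates = 2),
      lysogeny = list(
        n_per_clade = 12,
        prevalence = list(
          Hinf = c(C01 = 0.90, C02 = 0.70, C03 = 0.20, C04 = 0.05, C05 = 0.05, C06 = 0.05),
          Hpar = c(C01 = 0.30, C02 = 0.20, C03 = 0.70, C04 = 0.10, C05 = 0.05, C06 = 0.05),
          Aact = c(C01 = 0.05, C02 = 0.05, C03 = 0.05, C04 = 0.50, C05 = 0.02, C06 = 0.02),
          Hhae = c(C01 = 0.05, C02 = 0.05, C03 = 0.10, C04 = 0.05, C05 = 0.80, C06 = 0.70))),
      metagenome = list(
        sites = c("buccal_mucosa", "gingiva", "tongue"),
        samples_per_site = 3,
        contigs_per_sample = 40,
        contig_len = c(2000, 3600),
        marker_length_aa = 160,
        site_cluster_weights = list(
          buccal_mucosa = c(C01 = 0.35, C02 = 0.25, C03 = 0.05, C04 = 0.25, C05 = 0.05, C06 = 0.05),
          gingiva       = c(C01 = 0.10, C02 = 0.10, C03 = 0.40, C04 = 0.30, C05 = 0.05, C06 = 0.05),
          tongue        = c(C01 = 0.40, C02 = 0.10, C03 = 0.10, C04 = 0.05, C05 = 0.30, C06 = 0.05))))
  )
}

# Recursively collect dotted key paths of a nested config list.
config_keys <- function(x, prefix = "") {
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x)))) return(prefix)
  unlist(lapply(names(x), function(nm) {
    config_keys(x[[nm]], if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm)
  }))
}

#' Validate a pipeline configuration
#'
#' Key sets are compared against [default_pipeline_config()]; unknown keys
#' are errors (no silent typos). List-of-entry sections (clades, clusters,
#' superclusters) are validated per entry against the template entry.
#'
#' @param config Configuration list.
#' @return `config`, invisibly, on success.
#' @export
validate_config <- function(config) {
  template <- default_pipeline_config()
  strip_entries <- function(x) {
    for (s in c("clades", "superclusters", "clusters")) {
      x$synthetic[[s]] <- NULL
    }
    x$synthetic$lysogeny$prevalence <- NULL
    x$synthetic$metagenome$site_cluster_weights <- NULL
    x
  }
  unknown <- setdiff(config_keys(strip_entries(config)),
                     config_keys(strip_entries(template)))
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration keys: %s", paste(unknown, collapse = ", ")))
  }
  entry_template <- list(clades = template$synthetic$clades[[1]],
                         superclusters = template$synthetic$superclusters[[1]],
                         clusters = template$synthetic$clusters[[1]])
  for (s in names(entry_template)) {
    for (entry in config$synthetic[[s]]) {
      bad <- setdiff(names(entry), names(entry_template[[s]]))
      if (length(bad) > 0) {
        stop(sprintf("unknown key(s) in synthetic$%s entry: %s", s,
                     paste(bad, collapse = ", ")))
      }
    }
  }
  invisible(config)
}

#' Read / write pipeline configurations (YAML)
#'
#' @param path File path.
#' @return For the reader, a validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML maps become lists; coerce the numeric-vector sections back
  cfg$synthetic$lysogeny$prevalence <-
    lapply(cfg$synthetic$lysogeny$prevalence, function(x) unlist(x))
  cfg$synthetic$metagenome$site_cluster_weights <-
    lapply(cfg$synthetic$metagenome$site_cluster_weights, function(x) unlist(x))
  cfg$synthetic$metagenome$sites <- unlist(cfg$synthetic$metagenome$sites)
  cfg$synthetic$metagenome$contig_len <- unlist(cfg$synthetic$metagenome$contig_len)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  # named numeric vectors serialize as YAML maps (write_yaml drops names of
  # atomic vectors otherwise); read_config unlists them back
  config$synthetic$lysogeny$prevalence <-
    lapply(config$synthetic$lysogeny$prevalence, as.list)
  config$synthetic$metagenome$site_cluster_weights <-
    lapply(config$synthetic$metagenome$site_cluster_weights, as.list)
  yaml::write_yaml(config, path)
  invisible(path)
}

pipeline_motifs <- function(config) {
  list(hin = motif_spec("Hin-USS", config$motifs$hin),
       apl = motif_spec("Apl-USS", config$motifs$apl))
}

# ---- stages -----------------------------------------------------------------

stage_simulate <- function(config, dir) {
  syn <- config$synthetic
  motifs <- pipeline_motifs(config)
  seed0 <- config$seed
  counts <- list()

  # bacterial genomes per clade
  bact <- list()
  si <- 0
  for (cl in syn$clades) {
    for (g in seq_len(cl$n_genomes)) {
      si <- si + 1
      spec <- genome_spec(cl$genome_length, cl$gc,
                          hin_density = cl$hin_density,
                          apl_density = cl$apl_density,
                          seed = derive_seed(seed0, si))
      rec <- generate_genome(spec, id = sprintf("%s_g%02d", cl$name, g),
                             motifs = motifs)
      rec$species <- cl$species
      rec$clade <- cl$name
      bact[[length(bact) + 1]] <- rec
    }
  }
  bacteria <- do.call(rbind, bact)
  write_fasta(bacteria, file.path(dir, "bacteria.fasta"))
  write_tsv_stable(bacteria[, c("id", "species", "clade")],
                   file.path(dir, "bacteria_metadata.tsv"))
  counts$bacterial_genomes <- nrow(bacteria)

  # phage clusters: supercluster ancestor -> cluster ancestor (+ planted USS)
  # -> diverged members; markers embedded mid-genome
  sc_gc <- setNames(vapply(syn$superclusters, function(s) s$gc, numeric(1)),
                    vapply(syn$superclusters, function(s) s$name, character(1)))
  sc_anc <- lapply(seq_along(sc_gc), function(i) {
    generate_genome(genome_spec(syn$phage_genome_length, sc_gc[[i]],
                                seed = derive_seed(seed0, 1000 + i)),
                    id = names(sc_gc)[i])$sequence
  })
  names(sc_anc) <- names(sc_gc)

  clade_species <- setNames(vapply(syn$clades, function(x) x$species, character(1)),
                            vapply(syn$clades, function(x) x$name, character(1)))
  clade_n_genomes <- setNames(vapply(syn$clades, function(x) as.integer(x$n_genomes), integer(1)),
                              vapply(syn$clades, function(x) x$name, character(1)))
  phage_rows <- list()
  marker_rows <- list()
  marker_positions <- list()
  ann_rows <- list()
  member_cluster <- character(0)
  L <- syn$phage_genome_length
  for (ci in seq_along(syn$clusters)) {
    cc <- syn$clusters[[ci]]
    n_hin <- round(cc$hin_density * L / 1e6)
    n_apl <- round(cc$apl_density * L / 1e6)
    anc <- with_seed(derive_seed(seed0, 2000 + ci), {
      mutate_sequence(sc_anc[[cc$supercluster]], syn$sc_divergence)
    })
    anc <- plant_uss(anc, n_hin, n_apl, seed = derive_seed(seed0, 2100 + ci),
                     motifs = motifs)
    marker_aa <- random_protein(syn$metagenome$marker_length_aa,
                                seed = derive_seed(seed0, 2200 + ci))
    marker_rows[[ci]] <- data.frame(marker_id = sprintf("marker_%s", cc$name),
                                    cluster_label = cc$name,
                                    supercluster_label = cc$supercluster,
                                    sequence = marker_aa, stringsAsFactors = FALSE)
    mk_at <- as.integer(L / 2)
    for (m in seq_len(cc$n_members)) {
      id <- sprintf("%s_p%02d", cc$name, m)
      seq_m <- with_seed(derive_seed(seed0, 3000 + 100 * ci + m), {
        mutate_sequence(as.character(anc), cc$divergence)
      })
      rec <- genome_records(id, seq_m, species = clade_species[[cc$host_clade]],
                            clade = cc$host_clade)
      rec <- embed_marker(rec, marker_aa, at = mk_at,
                          seed = derive_seed(seed0, 4000 + 100 * ci + m))
      marker_positions[[id]] <- attr(rec, "marker_interval")
      phage_rows[[length(phage_rows) + 1]] <- rec
      member_cluster <- c(member_cluster, cc$name)
      ann_rows[[length(ann_rows) + 1]] <- with_seed(
        derive_seed(seed0, 5000 + 100 * ci + m), {
          data.frame(prophage_id = id,
                     host_genome_id = sprintf("%s_g%02d", cc$host_clade,
                                              sample.int(clade_n_genomes[[cc$host_clade]], 1)),
                     completeness_score = sample(95:150, 1),
                     orf_count = sample(40:70, 1),
                     host_species = clade_species[[cc$host_clade]],
                     stringsAsFactors = FALSE)
        })
    }
  }
  phages <- do.call(rbind, phage_rows)
  write_fasta(phages, file.path(dir, "phages.fasta"))
  write_tsv_stable(cbind(phages[, c("id", "species", "clade")],
                         true_cluster = member_cluster),
                   file.path(dir, "phage_truth.tsv"))
  counts$phage_genomes <- nrow(phages)

  markers <- do.call(rbind, marker_rows)
  write_tsv_stable(markers, file.path(dir, "markers.tsv"))
  mk_df <- do.call(rbind, lapply(names(marker_positions), function(id) {
    data.frame(phage_id = id, marker_start = marker_positions[[id]][1],
               marker_end = marker_positions[[id]][2], stringsAsFactors = FALSE)
  }))
  write_tsv_stable(mk_df, file.path(dir, "marker_positions.tsv"))

  # prophage annotation funnel: intact members plus decoys and duplicates
  ann <- do.call(rbind, ann_rows)
  ann$sequence <- phages$sequence[match(ann$prophage_id, phages$id)]
  dec <- syn$decoys
  decoy_rows <- with_seed(derive_seed(seed0, 6000), {
    first_clade <- syn$clades[[1]]
    low_score <- data.frame(
      prophage_id = sprintf("decoy_s%02d", seq_len(dec$n_low_score)),
      host_genome_id = sprintf("%s_g01", first_clade$name),
      completeness_score = sample(10:90, dec$n_low_score, replace = TRUE),
      orf_count = sample(40:70, dec$n_low_score, replace = TRUE),
      host_species = first_clade$species, stringsAsFactors = FALSE)
    second_clade <- syn$clades[[min(2, length(syn$clades))]]
    low_orf <- data.frame(
      prophage_id = sprintf("decoy_o%02d", seq_len(dec$n_low_orf)),
      host_genome_id = sprintf("%s_g01", second_clade$name),
      completeness_score = sample(95:150, dec$n_low_orf, replace = TRUE),
      orf_count = sample(5:39, dec$n_low_orf, replace = TRUE),
      host_species = second_clade$species, stringsAsFactors = FALSE)
    rbind(low_score, low_orf)
  })
  decoy_rows$sequence <- NA_character_
  dup_rows <- ann[seq_len(min(dec$n_duplicates, nrow(ann))), , drop = FALSE]
  if (nrow(dup_rows) > 0) {
    dup_rows$prophage_id <- sprintf("zz_dup_%02d", seq_len(nrow(dup_rows)))
  }
  annotations <- prophage_annotations(
    c(ann$prophage_id, decoy_rows$prophage_id, dup_rows$prophage_id),
    c(ann$host_genome_id, decoy_rows$host_genome_id, dup_rows$host_genome_id),
    c(ann$completeness_score, decoy_rows$completeness_score, dup_rows$completeness_score),
    c(ann$orf_count, decoy_rows$orf_count, dup_rows$orf_count),
    sequence = c(ann$sequence, decoy_rows$sequence, dup_rows$sequence),
    host_species = c(ann$host_species, decoy_rows$host_species, dup_rows$host_species))
  write_tsv_stable(annotations[, c("prophage_id", "host_genome_id",
                                   "completeness_score", "orf_count",
                                   "host_species")],
                   file.path(dir, "annotations.tsv"))
  counts$prophage_annotations <- nrow(annotations)

  # lysogeny presence table
  lys <- syn$lysogeny
  clade_names <- vapply(syn$clades, function(x) x$name, character(1))
  cluster_names <- vapply(syn$clusters, function(x) x$name, character(1))
  prev <- t(vapply(clade_names, function(cn) lys$prevalence[[cn]][cluster_names],
                   numeric(length(cluster_names))))
  design <- lysogeny_design(clade_names, cluster_names, prev,
                            n_per_clade = lys$n_per_clade,
                            seed = derive_seed(seed0, 7000))
  lys_table <- generate_lysogeny_table(design)
  write_presence_table(lys_table, file.path(dir, "lysogeny.tsv"))
  counts$lysogeny_genomes <- nrow(lys_table)

  # metagenome: per site, per sample
  mg <- syn$metagenome
  contig_rows <- list()
  truth_rows <- list()
  meta_rows <- list()
  sidx <- 0
  for (site in mg$sites) {
    w_cluster <- mg$site_cluster_weights[[site]]
    abund <- setNames(w_cluster[member_cluster] /
                        table(member_cluster)[member_cluster], phages$id)
    abund <- unname_to_named(abund, phages$id)
    for (sm in seq_len(mg$samples_per_site)) {
      sidx <- sidx + 1
      sample_id <- sprintf("%s_s%02d", site, sm)
      gm <- generate_metagenome(phages, marker_positions, abund,
                                n_contigs = mg$contigs_per_sample,
                                contig_len = mg$contig_len,
                                seed = derive_seed(seed0, 8000 + sidx),
                                id_prefix = sample_id)
      gm$contigs$sample_id <- sample_id
      gm$truth$sample_id <- sample_id
      contig_rows[[sidx]] <- gm$contigs
      truth_rows[[sidx]] <- gm$truth
      meta_rows[[sidx]] <- data.frame(sample_id = sample_id, body_site = site,
                                      subject_group = "", stringsAsFactors = FALSE)
    }
  }
  contigs <- do.call(rbind, contig_rows)
  write_fasta(contigs, file.path(dir, "contigs.fasta"))
  write_tsv_stable(contigs[, c("id", "sample_id")],
                   file.path(dir, "contig_samples.tsv"))
  write_tsv_stable(do.call(rbind, truth_rows), file.path(dir, "contig_truth.tsv"))
  write_tsv_stable(do.call(rbind, meta_rows), file.path(dir, "sample_metadata.tsv"))
  counts$metagenome_contigs <- nrow(contigs)
  counts$metagenome_samples <- sidx
  counts
}

# named-vector hygiene helper for abundance construction
unname_to_named <- function(x, ids) setNames(as.numeric(x), ids)

stage_filter <- function(config, dir) {
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  phages <- read_fasta(file.path(dir, "phages.fasta"))
  ann$sequence <- phages$sequence[match(ann$prophage_id, phages$id)]
  # duplicates duplicate an original member's sequence
  dup_ids <- grepl("^zz_dup_", ann$prophage_id)
  if (any(dup_ids)) {
    truth <- read_tsv_stable(file.path(dir, "phage_truth.tsv"))
    originals <- truth$id[seq_len(sum(dup_ids))]
    ann$sequence[dup_ids] <- phages$sequence[match(originals, phages$id)]
  }
  th <- config$thresholds
  with_seq <- !is.na(ann$sequence)
  dist_fn <- mash_distance_fn(k = th$k, s = th$sketch_size)
  ann[with_seq, ] <- deduplicate(ann[with_seq, , drop = FALSE], dist_fn,
                                 max_distance = th$dedup_max_distance)
  kept <- filter_prophages(ann, min_score = th$min_score, min_orfs = th$min_orfs)
  write_annotations(ann, file.path(dir, "annotations_flagged.tsv"))
  write_annotations(kept, file.path(dir, "prophages_kept.tsv"))
  list(annotations_in = nrow(ann), flagged_duplicates = sum(ann$is_duplicate),
       prophages_kept = nrow(kept))
}

stage_cluster <- function(config, dir) {
  kept <- read_tsv_stable(file.path(dir, "prophages_kept.tsv"))
  phages <- read_fasta(file.path(dir, "phages.fasta"))
  recs <- phages[phages$id %in% kept$prophage_id, , drop = FALSE]
  th <- config$thresholds
  dm <- mash_distance_matrix(recs, k = th$k, s = th$sketch_size)
  assign <- cluster_genomes(dm, cluster_threshold = th$cluster_threshold,
                            supercluster_threshold = th$supercluster_threshold)
  pairs <- attr(dm, "pairs")
  pairs$ani <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- recs$sequence[recs$id == pairs$id_a[i]]
    b <- recs$sequence[recs$id == pairs$id_b[i]]
    as.numeric(fragment_ani(a, b))
  }, numeric(1))
  dist_df <- cbind(data.frame(record_id = rownames(dm), stringsAsFactors = FALSE),
                   as.data.frame(dm))
  write_tsv_stable(dist_df, file.path(dir, "mash_distances.tsv"))
  write_tsv_stable(pairs, file.path(dir, "distance_pairs.tsv"))
  write_tsv_stable(assign, file.path(dir, "clusters.tsv"))
  defined <- !is.na(pairs$ani)
  r <- if (sum(defined) >= 3 && sd(pairs$mash_distance[defined]) > 0 &&
           sd(pairs$ani[defined]) > 0) mash_ani_correlation(pairs) else NA_real_
  list(genomes_clustered = nrow(assign),
       n_clusters = length(unique(assign$cluster_label)),
       n_superclusters = length(unique(assign$supercluster_label)),
       mash_ani_pearson_r = r)
}

stage_profile_uss <- function(config, dir) {
  motifs <- pipeline_motifs(config)
  bacteria <- read_fasta(file.path(dir, "bacteria.fasta"))
  phages <- read_fasta(file.path(dir, "phages.fasta"))
  meta <- read_tsv_stable(file.path(dir, "bacteria_metadata.tsv"))
  truth <- read_tsv_stable(file.path(dir, "phage_truth.tsv"))
  all_recs <- rbind(bacteria, phages)
  prof <- uss_profile_table(all_recs, motifs,
                            cutoff_per_mb = config$thresholds$uss_cutoff_per_mb)
  prof$kind <- ifelse(prof$record_id %in% bacteria$id, "bacterium", "phage")
  prof$entity <- ifelse(prof$kind == "bacterium",
                        meta$clade[match(prof$record_id, meta$id)],
                        truth$true_cluster[match(prof$record_id, truth$id)])
  write_tsv_stable(prof, file.path(dir, "uss_profiles.tsv"))
  list(profiles = nrow(prof),
       phages_classified_positive = sum(prof$classified[prof$kind == "phage"]))
}

stage_screen <- function(config, dir) {
  markers <- read_tsv_stable(file.path(dir, "markers.tsv"))
  contigs <- read_fasta(file.path(dir, "contigs.fasta"))
  contig_samples <- read_tsv_stable(file.path(dir, "contig_samples.tsv"))
  contigs$sample_id <- contig_samples$sample_id[match(contigs$id, contig_samples$id)]
  metadata <- read_tsv_stable(file.path(dir, "sample_metadata.tsv"))
  th <- config$thresholds
  hits <- search_markers(markers, contigs)
  hits$identity_score <- identity_score(hits)
  res <- profile_prevalence(hits, metadata, markers,
                            evalue_cutoff = th$evalue_cutoff,
                            score_cutoff = th$identity_score_cutoff)
  write_tsv_stable(hits, file.path(dir, "marker_hits.tsv"))
  write_presence_table(res$presence, file.path(dir, "sample_presence.tsv"))
  write_tsv_stable(res$prevalence, file.path(dir, "site_prevalence.tsv"))
  list(hits = nrow(hits),
       retained_hits = sum(hits$e_value <= th$evalue_cutoff &
                             hits$identity_score >= th$identity_score_cutoff),
       positive_sample_clusters = sum(res$prevalence$n_positive[res$prevalence$level == "cluster"]))
}

stage_stats <- function(config, dir) {
  lys <- read_presence_table(file.path(dir, "lysogeny.tsv"))
  tests <- prevalence_tests(lys)
  summ <- prevalence_summary(lys)
  curve <- rarefy(lys, replicates = config$rarefaction$replicates,
                  seed = derive_seed(config$seed, 9000))
  counts <- rowSums(presence_matrix(lys))
  av <- anova_tukey(counts, lys$group)
  write_tsv_stable(tests, file.path(dir, "prevalence_tests.tsv"))
  write_tsv_stable(summ, file.path(dir, "prevalence_summary.tsv"))
  write_tsv_stable(curve, file.path(dir, "rarefaction.tsv"))
  write_tsv_stable(av$tukey, file.path(dir, "tukey.tsv"))
  write_tsv_stable(av$anova, file.path(dir, "anova.tsv"))
  list(fisher_tests = nrow(tests),
       significant_after_bonferroni = sum(tests$p_adjusted < 0.05),
       anova_p = av$anova$p_value)
}

stage_ordinate <- function(config, dir) {
  prof <- read_tsv_stable(file.path(dir, "uss_profiles.tsv"))
  feat <- build_features(prof, prof$entity)
  d <- bray_curtis(feat)
  ord <- nmds(d, dims = config$ordination$dims,
              n_restarts = config$ordination$n_restarts,
              max_iter = config$ordination$max_iter,
              tol = config$ordination$tol,
              seed = derive_seed(config$seed, 9500))
  vec <- fit_vectors(ord, feat)
  feat_df <- cbind(data.frame(entity = rownames(feat), stringsAsFactors = FALSE),
                   as.data.frame(feat))
  coord_df <- cbind(data.frame(entity = rownames(ord$points), stringsAsFactors = FALSE),
                    as.data.frame(ord$points))
  write_tsv_stable(feat_df, file.path(dir, "ordination_features.tsv"))
  write_tsv_stable(coord_df, file.path(dir, "ordination_coordinates.tsv"))
  write_tsv_stable(vec, file.path(dir, "ordination_vectors.tsv"))
  jsonlite::write_json(list(stress = ord$stress, n_restarts = ord$n_restarts,
                            converged = ord$converged,
                            n_entities = nrow(ord$points)),
                       file.path(dir, "ordination_summary.json"),
                       auto_unbox = TRUE, digits = 10)
  list(entities = nrow(feat), stress = ord$stress)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order (simulate, filter,
#' cluster, profile_uss, screen, stats, ordinate) into a run directory,
#' writing per-stage plain-file outputs and a reproducibility manifest
#' (config hash, seed, package version, per-stage record counts, skipped
#' stages). Reruns with the same config are byte-identical for deterministic
#' stages. A disabled upstream stage whose outputs are missing raises an
#' error naming the stage.
#'
#' @param config Configuration list (see [default_pipeline_config()]).
#' @param out_dir Run directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)

  requires <- list(
    simulate = character(0),
    filter = c("annotations.tsv", "phages.fasta"),
    cluster = c("prophages_kept.tsv", "phages.fasta"),
    profile_uss = c("bacteria.fasta", "phages.fasta"),
    screen = c("markers.tsv", "contigs.fasta", "sample_metadata.tsv"),
    stats = "lysogeny.tsv",
    ordinate = "uss_profiles.tsv")
  stage_fns <- list(simulate = stage_simulate, filter = stage_filter,
                    cluster = stage_cluster, profile_uss = stage_profile_uss,
                    screen = stage_screen, stats = stage_stats,
                    ordinate = stage_ordinate)

  stages <- list()
  for (nm in names(stage_fns)) {
    if (!isTRUE(config$stages[[nm]])) {
      message(sprintf("[%s] skipped", nm))
      stages[[nm]] <- list(skipped = TRUE)
      next
    }
    missing <- requires[[nm]][!file.exists(file.path(out_dir, requires[[nm]]))]
    if (length(missing) > 0) {
      stop(sprintf("stage '%s' is missing upstream output(s): %s",
                   nm, paste(missing, collapse = ", ")))
    }
    counts <- stage_fns[[nm]](config, out_dir)
    message(sprintf("[%s] %s", nm,
                    paste(sprintf("%s=%s", names(counts),
                                  vapply(counts, function(x) format(x, digits = 6),
                                         character(1))),
                          collapse = ", ")))
    stages[[nm]] <- c(list(skipped = FALSE), counts)
  }

  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("phagediv")),
    stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}

#' Mash-distance closure for deduplication
#'
#' @param k,s Sketch parameters.
#' @return A function of two sequences returning their Mash distance.
#' @export
mash_distance_fn <- function(k = 21, s = 1000) {
  function(seq_a, seq_b) {
    mash_distance(minhash_sketch(seq_a, k = k, s = s),
                  minhash_sketch(seq_b, k = k, s = s))$mash_distance
  }
}
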