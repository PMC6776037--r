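# Pipeline configuration schema:
#   seed: integer master seed; every stage seed derives from it
#   stages: logical toggles, executed in the order simulate, filter, cluster,
#           profile_uss, screen, stats, ordinate
#   thresholds: all analysis cutoffs (prophage completeness score and ORF count,
#           Mash k/sketch size, dotplot word length, E-value and identity-score
#           retention cutoffs, USS per-Mb classifier cutoff, species presence
#           threshold, cluster/supercluster Mash thresholds, dedup distance)
#   motifs: Hin-USS and Apl-USS core sequences (A/C/G/T, not self-revcomp)
#   rarefaction: replicates for the richness curve
#   ordination: nMDS dimensions, restarts, iteration cap, tolerance
#   synthetic: the emulated study -- host clades (GC, USS densities, genome
#           length, genomes per clade), phage superclusters and clusters
#           (host clade, USS densities, members, divergence), annotation decoys,
#           lysogeny prevalence design, and the fragmented metagenome

seed: 20170301
stages:
  simulate: yes
  filter: yes
  cluster: yes
  profile_uss: yes
  screen: yes
  stats: yes
  ordinate: yes
thresholds:
  min_score: 90.0
  min_orfs: 40.0
  k: 21.0
  sketch_size: 1000.0
  word_length: 10.0
  evalue_cutoff: 1.0e-80
  identity_score_cutoff: 95.0
  uss_cutoff_per_mb: 100.0
  presence_threshold_percent: 0.1
  cluster_threshold: 0.09
  supercluster_threshold: 0.25
  dedup_max_distance: 0.001
motifs:
  hin: AAGTGCGGT
  apl: ACAAGCGGT
rarefaction:
  replicates: 10.0
ordination:
  dims: 2.0
  n_restarts: 20.0
  max_iter: 300.0
  tol: 1.0e-07
synthetic:
  clades:
  - name: Hinf
    species: H_influenzae
    gc: 0.38
    hin_density: 750.0
    apl_density: 30.0
    genome_length: 150000.0
    n_genomes: 4.0
  - name: Hpar
    species: H_parainfluenzae
    gc: 0.4
    hin_density: 600.0
    apl_density: 50.0
    genome_length: 150000.0
    n_genomes: 4.0
  - name: Aact
    species: A_actinomycetemcomitans
    gc: 0.44
    hin_density: 500.0
    apl_density: 40.0
    genome_length: 150000.0
    n_genomes: 4.0
  - name: Hhae
    species: H_parahaemolyticus
    gc: 0.41
    hin_density: 60.0
    apl_density: 550.0
    genome_length: 150000.0
    n_genomes: 4.0
  superclusters:
  - name: SC1
    gc: 0.39
  - name: SC2
    gc: 0.43
  - name: SC3
    gc: 0.41
  sc_divergence: 0.08
  phage_genome_length: 40000.0
  clusters:
  - name: C01
    supercluster: SC1
    host_clade: Hinf
    hin_density: 450.0
    apl_density: 20.0
    n_members: 4.0
    divergence: 0.03
  - name: C02
    supercluster: SC1
    host_clade: Hinf
    hin_density: 380.0
    apl_density: 25.0
    n_members: 4.0
    divergence: 0.03
  - name: C03
    supercluster: SC2
    host_clade: Hpar
    hin_density: 350.0
    apl_density: 30.0
    n_members: 4.0
    divergence: 0.03
  - name: C04
    supercluster: SC2
    host_clade: Aact
    hin_density: 300.0
    apl_density: 25.0
    n_members: 4.0
    divergence: 0.03
  - name: C05
    supercluster: SC3
    host_clade: Hhae
    hin_density: 40.0
    apl_density: 350.0
    n_members: 4.0
    divergence: 0.03
  - name: C06
    supercluster: SC3
    host_clade: Hhae
    hin_density: 30.0
    apl_density: 300.0
    n_members: 4.0
    divergence: 0.03
  decoys:
    n_low_score: 6.0
    n_low_orf: 4.0
    n_duplicates: 2.0
  lysogeny:
    n_per_clade: 12.0
    prevalence:
      Hinf:
        C01: 0.9
        C02: 0.7
        C03: 0.2
        C04: 0.05
        C05: 0.05
        C06: 0.05
      Hpar:
        C01: 0.3
        C02: 0.2
        C03: 0.7
        C04: 0.1
        C05: 0.05
        C06: 0.05
      Aact:
        C01: 0.05
        C02: 0.05
        C03: 0.05
        C04: 0.5
        C05: 0.02
        C06: 0.02
      Hhae:
        C01: 0.05
        C02: 0.05
        C03: 0.1
        C04: 0.05
        C05: 0.8
        C06: 0.7
  metagenome:
    sites:
    - buccal_mucosa
    - gingiva
    - tongue
    samples_per_site: 3.0
    contigs_per_sample: 40.0
    contig_len:
    - 2000.0
    - 3600.0
    marker_length_aa: 160.0
    site_cluster_weights:
      buccal_mucosa:
        C01: 0.35
        C02: 0.25
        C03: 0.05
        C04: 0.25
        C05: 0.05
        C06: 0.05
      gingiva:
        C01: 0.1
        C02: 0.1
        C03: 0.4
        C04: 0.3
        C05: 0.05
        C06: 0.05
      tongue:
        C01: 0.4
        C02: 0.1
        C03: 0.1
        C04: 0.05
        C05: 0.3
        C06: 0.05
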