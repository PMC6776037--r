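# Shared setup for the numbered analysis drivers: one run directory under
# results/, one configuration, and a helper to execute a single pipeline
# stage. Run the scripts in order from the repository root:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_filter_prophages.R
#   ...

suppressPackageStartupMessages(library(phagediv))

run_dir <- "results/study"
dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)

study_config <- function() {
  read_config(system.file("extdata", "default_config.yaml", package = "phagediv"))
}

run_stage <- function(stage) {
  cfg <- study_config()
  cfg$stages <- lapply(cfg$stages, function(x) FALSE)
  cfg$stages[[stage]] <- TRUE
  suppressMessages(run_pipeline(cfg, run_dir))
}

tsv <- function(name) {
  read.delim(file.path(run_dir, name), check.names = FALSE)
}
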