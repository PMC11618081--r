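# Shared settings for the numbered analysis scripts. Every script can be run
# on its own from the repository root:
#
#   Rscript analysis/01_simulate_world.R [seed]
#
# Later scripts re-derive deterministic inputs (fields, ensembles) from the
# same seed and read tabular intermediates from results/.

library(pelagicshift)

args <- commandArgs(trailingOnly = TRUE)
SEED <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

# the stated analysis world: 0.25-degree grid, 2005-2019 baseline months,
# a 50 x 90 degree east-Atlantic-like basin with a western coast, 30 animals
# tracked ~120 days each
CFG <- pipeline_config(
  seed = SEED,
  tracks = list(n_animals = 30, mean_duration = 120),
  ensemble = list(n_models = 8),
  scenarios = c("ssp126", "ssp370", "ssp585"),
  decades = c("2046-2055", "2086-2095"),
  n_regions = 24)   # EEZ-scale tiles rather than whole-basin quadrants

world_of <- function(cfg) do.call(world_spec, c(cfg$world, list(seed = cfg$seed)))
fields_of <- function(cfg) gen_env_fields(world_of(cfg))
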