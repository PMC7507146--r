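#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study panels.
#
# Two panels emulate the structure of a continental water-quality record:
#   - a spatial panel (200 sites x 20 samples) for the land-use and
#     homeostasis analyses;
#   - a temporal panel (13 densely sampled sites x 150 samples) for the
#     per-site homeostasis fits, mirroring a ">100 sequential samples"
#     subset.
# Ground truth is written alongside so later stages can be checked against
# the generating parameters.

suppressMessages(library(streamstoich))

seed <- 20260929L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

spatial_cfg <- synthetic_config(seed = seed)
lu <- generate_landscape(spatial_cfg)
gen <- generate_samples(lu, spatial_cfg)
rec <- inject_censoring(gen$records, spatial_cfg)
write_synthetic_tables(rec, lu, "results/data/samples_spatial.csv",
                       "results/data/landuse_spatial.csv")
utils::write.csv(gen$truth$records, "results/data/truth_spatial.csv",
                 row.names = FALSE)

n_lt <- sum(vapply(c("nh3n", "nh4n", "no3no2n", "dip"),
                   function(a) sum(rec[[paste0(a, "_qual")]] == "less_than"),
                   0L))
cat(sprintf("spatial panel: %d records at %d sites; %d less-than values injected\n",
            nrow(rec), nrow(lu), n_lt))

temporal_cfg <- synthetic_config(n_sites = 13L, obs_per_site = 150L,
                                 seed = seed + 1L)
lu_t <- generate_landscape(temporal_cfg)
gen_t <- generate_samples(lu_t, temporal_cfg)
rec_t <- inject_censoring(gen_t$records, temporal_cfg)
write_synthetic_tables(rec_t, lu_t, "results/data/samples_temporal.csv",
                       "results/data/landuse_temporal.csv")
utils::write.csv(gen_t$truth$records, "results/data/truth_temporal.csv",
                 row.names = FALSE)
cat(sprintf("temporal panel: %d records at %d sites (dense time series)\n",
            nrow(rec_t), nrow(lu_t)))
cat(sprintf("imposed homeostasis truth: 1/H = %.3f, log10 c = %.3f\n",
            spatial_cfg$true_inv_h, spatial_cfg$true_log_c))
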