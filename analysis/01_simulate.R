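#!/usr/bin/env Rscript
# Stage 1 — synthetic survey inputs.
#
# Generates everything the downstream stages consume, with planted ground
# truth: a strain panel (3 species x 3 strains, within-species divergence
# 0.5%, between-species 8%), an antiSMASH-style BGC collection (120 regions,
# survey-like product-type weights, 37.2% contig-edge rate), a reference
# library with planted compound families, a hit table with planted links
# over sub-threshold noise, and BiG-SLiCE-style GCF assignment tables for
# three "environments".

library(bgcmine)

out_dir <- file.path("results", "pipeline")
cfg <- pipeline_config(seed = 1L)
run_stage("simulate", cfg, out_dir)

truth <- read.delim(file.path(out_dir, "truth_species.tsv"))
message(sprintf("simulated %d genomes in %d planted species; inputs under %s",
                nrow(truth), length(unique(truth$species_id)), out_dir))
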