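#!/usr/bin/env Rscript
# Stage 6 — chemical-space-guided molecular families.
#
# Fingerprints the reference compounds (Morgan-style, radius 2, 2048 bits),
# links references at Tanimoto >= 0.5, joins those chemical edges with the
# genomic links from stage 4, and extracts molecular families (connected
# components holding both query and reference nodes). Finally compares the
# MF grouping against the GCF partition: which query BGCs and references
# each scheme co-groups, and how large the overlap is.

library(bgcmine)

out_dir <- file.path("results", "pipeline")
cfg <- pipeline_config(seed = 1L)
run_stage("molfam", cfg, out_dir)
run_stage("compare-grouping", cfg, out_dir)

rep <- jsonlite::read_json(file.path(out_dir, "mf_report.json"))
message(sprintf(
  "%d MFs (%d after the size-%d display filter): %d query BGCs grouped with %d references; %d queries unlinked",
  rep$n_mfs, rep$n_mfs_reported, rep$min_size, rep$n_query_in_mfs,
  rep$n_reference_in_mfs, rep$n_isolated_query))
truth <- read.delim(file.path(out_dir, "truth_families.tsv"))
message(sprintf("planted compound families: %d",
                length(unique(truth$family_id))))
cmp <- jsonlite::read_json(file.path(out_dir, "grouping_comparison.json"))
message(sprintf(
  "grouped queries: MF %d vs GCF %d (both: %d); references: MF %d vs GCF %d (both: %d)",
  cmp$n_query_mf, cmp$n_query_gcf, cmp$n_query_both,
  cmp$n_reference_mf, cmp$n_reference_gcf, cmp$n_reference_both))
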