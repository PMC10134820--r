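#!/usr/bin/env Rscript
# Stage 5 — GCF membership analytics.
#
# Classifies the BiG-SLiCE-style distances into core (d <= 900), putative
# (900 < d <= 1800) and orphan (d > 1800) strata, summarizes them overall
# and per chemical class, ranks the most prevalent GCFs by genome count,
# and compares GCF content across the three simulated environments
# (Venn counts and unique fractions).

library(bgcmine)

out_dir <- file.path("results", "pipeline")
cfg <- pipeline_config(seed = 1L)
run_stage("membership", cfg, out_dir)
run_stage("compare-datasets", cfg, out_dir)

s <- read.delim(file.path(out_dir, "membership_summary.tsv"))
overall <- s[s$group == "all", ]
message(sprintf(
  "memberships: %d core (%.2f%%), %d putative (%.2f%%), %d orphan (%.2f%%)",
  overall$core, overall$pct_core, overall$putative, overall$pct_putative,
  overall$orphan, overall$pct_orphan))
venn <- jsonlite::read_json(file.path(out_dir, "gcf_venn.json"))
message(sprintf("three-way shared GCFs: %s; unique fractions: %s",
                venn$intersections[["lichen&insect&marine"]],
                paste(sprintf("%s=%.2f", names(venn$unique_fraction),
                              unlist(venn$unique_fraction)),
                      collapse = ", ")))
print(read.delim(file.path(out_dir, "prevalent_gcfs.tsv")))
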