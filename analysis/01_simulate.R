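#!/usr/bin/env Rscript

# Simulate the study inputs: a reference atlas of 112 somatic tissues plus
# germline/placenta/embryonic-stem tissues with 30 restricted and 40
# predominant planted genes, and a 3-case vs 3-control cohort in which all
# planted genes are ectopically activated 10 control-SDs above baseline.
# Writes the TSV inputs the downstream steps consume, plus the ground truth.

suppressPackageStartupMessages(library(offcontext))

seed <- 1L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = seed)
atlas <- generate_atlas(cfg)
cohort <- generate_cohort(cfg, atlas$truth)

write_expression(atlas$expr, file.path(out, "atlas.tsv"))
write_tissue_annotation(atlas$annotation, file.path(out, "atlas_annotation.tsv"))
write_expression(cohort$cases, file.path(out, "cases.tsv"))
write_expression(cohort$controls, file.path(out, "controls.tsv"))
utils::write.table(atlas$truth$genes, file.path(out, "truth_genes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(gene = rownames(cohort$truth_calls), cohort$truth_calls),
  file.path(out, "truth_calls.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
jsonlite::write_json(
  list(seed = seed, rng = "Mersenne-Twister (R default)",
       config = unclass(cfg)),
  file.path(out, "simulation.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

message(sprintf("atlas: %d genes x %d samples (%d tissues); cohort: %d cases, %d controls",
                nrow(atlas$expr), ncol(atlas$expr),
                length(unique(atlas$annotation$tissue_label)),
                ncol(cohort$cases), ncol(cohort$controls)))
message(sprintf("planted: %d restricted, %d predominant, %d activated genes",
                cfg$n_restricted_planted, cfg$n_predominant_planted,
                cfg$n_activated_genes))
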