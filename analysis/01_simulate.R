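#!/usr/bin/env Rscript
# Step 1 -- generate the synthetic study: 19 farmland plots at 4 sites,
# paired fresh / air-dried 16S-like OTU tables with a known drying
# perturbation, plus plot metadata and ground truth.
suppressMessages(library(soilNDEP))

seed <- 20260924L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
ds <- generate_dataset(cfg)

write_community_table(ds$table, "results/data/community_table.tsv",
                      taxonomy_path = "results/data/taxonomy.tsv")
write.table(ds$frame, "results/data/sample_metadata.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(config = unclass(cfg),
       responders = ds$truth$responders,
       sensitive = ds$truth$sensitive,
       lfc = as.list(ds$truth$lfc[ds$truth$lfc != 0]),
       site_of_plot = as.list(ds$truth$site_of_plot)),
  "results/data/ground_truth.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

message(sprintf("wrote %d samples x %d OTUs at depth %d (seed %d)",
                nrow(ds$table$counts), ncol(ds$table$counts), cfg$depth,
                seed))
message(sprintf("drying truth: %d responder OTUs (LFC ~ +%.1f), %d sensitive (LFC ~ %.1f)",
                cfg$n_responders, cfg$responder_lfc, cfg$n_sensitive,
                cfg$sensitive_lfc))
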