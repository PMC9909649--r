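#!/usr/bin/env Rscript
# Step 1 — simulate a national ED transfer dataset.
#
# The real national referral registry is restricted, so the workflow runs on
# synthetic data from the package's calibrated hub-and-spoke generator:
# 14 regions, one base (hub) hospital each, in-degree linear in served
# population, planted dyadic reciprocity 0.21, heavy-tailed tie weights, and
# year-on-year growth over 2014-2016. The ground-truth ledger is kept so
# later steps can be checked against what was planted.

suppressPackageStartupMessages(library(edtransfernet))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 20140209L
out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(seed = seed)
registry <- generate_registry(cfg)
gt <- generate_transfers(registry, cfg)

write_registry(registry, file.path(out_dir, "registry.csv"))
write_transfers(gt$records, file.path(out_dir, "transfers.csv"))
jsonlite::write_json(gt$ledger, file.path(out_dir, "ground_truth_ledger.json"),
                     auto_unbox = TRUE, digits = NA, dataframe = "columns")

cat(sprintf("Simulated %d hospitals (%d hubs) in %d regions; %d transfers over %s.\n",
            nrow(registry), sum(registry$is_base),
            length(unique(registry$region_id)), nrow(gt$records),
            paste(range(names(gt$ledger$per_year_counts)), collapse = "-")))
cat(sprintf("Planted: slope %.1f in-degrees/million, reciprocity %.2f, distributor discharge %.3f vs %.3f.\n",
            gt$ledger$true_slope, gt$ledger$true_reciprocity,
            gt$ledger$true_discharge_rates[["distributor"]],
            gt$ledger$true_discharge_rates[["other"]]))
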