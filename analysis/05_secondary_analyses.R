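#!/usr/bin/env Rscript
# Step 5 — secondary analyses.
#
# (a) OLS of in-degree on served population: does a bigger catchment attract
#     more transfer-in partners? (b) Do patients sent by the top 5%
#     "distributor" hospitals get discharged directly from the receiving ED
#     more often? (c) How do the yearly network statistics move over time?

suppressPackageStartupMessages(library(edtransfernet))

registry <- read_registry("results/data/registry.csv")
records <- read_transfers("results/data/transfers.csv")$records
overall <- read_edgelist("results/networks/overall_edgelist.csv", registry)
nodes <- degree_metrics(overall)

fit <- degree_population_regression(nodes, registry)
print(fit)
jsonlite::write_json(unclass(fit), "results/population_regression.json",
                     auto_unbox = TRUE, digits = NA)

cmp <- distributor_discharge_comparison(records, nodes, quantile = 0.05)
print(cmp)
jsonlite::write_json(unclass(cmp), "results/distributor_comparison.json",
                     auto_unbox = TRUE, digits = NA)

yearly <- lapply(slice_by_year(records, registry), network_metrics)
trend <- temporal_report(yearly)
print(trend)
utils::write.csv(trend, "results/table3_temporal_trends.csv", row.names = FALSE)
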