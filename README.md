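# edtransfernet

Social network analysis of interhospital emergency department (ED) transfers.

When an ED transfers a patient, the sending and receiving hospitals form a
directed tie; the whole pattern of transfers across a country forms a directed
valued network whose structure reveals how well regionalized emergency care is
working — whether patients flow toward designated hub hospitals, how
concentrated that flow is, and how it changes over time. `edtransfernet` is a
pipeline for health-services researchers and emergency-care policymakers to
run that analysis on patient-level transfer registries: it ingests and cleans
one-row-per-transfer records, builds directed valued hospital networks,
computes the node- and network-level social-network statistics used to monitor
referral regionalization, and renders geographic sociograms. Because national
transfer registries are typically access-restricted, the package ships a
calibrated hub-and-spoke synthetic data generator with a ground-truth ledger,
so the complete workflow is runnable and testable out of the box.

## The statistics

For a directed network of `N` hospital EDs in which an arc `i -> j` means at
least one transfer from `i` to `j` (valued by the number of transfers):

- **in-degree / out-degree** — distinct transfer-in / transfer-out partners;
  **net connectivity** = in-degree − out-degree separates "receiver" hubs
  (positive) from "distributor" hospitals (negative);
- **standardized betweenness** — shortest-path (Brandes) betweenness divided
  by `(N−1)(N−2)`;
- **standardized closeness** — `(N−1) / farness`, farness being the summed
  geodesic distances to the other nodes (unreachable targets follow a
  documented, configurable convention);
- **local clustering** — directed arcs observed among a node's neighbors over
  the maximum `k(k−1)`;
- **density** — arcs / `N(N−1)`;
- **Freeman in-degree centralization** — `Σ(d_max − d_i) / (N−1)²`, exactly 1
  for a single-hub inward star;
- **dyad census and reciprocity** — unordered pairs classified
  mutual/asymmetric/null; reciprocity = mutual / (mutual + asymmetric);
- **skeleton networks** — tie-strength filters (≥ 36 transfers per 3 years =
  ≥ 1/month; 36–365 medium; > 365 strong ties).

Secondary analyses: OLS regression of in-degree on served population
(in-degrees per million residents) and a two-proportion z-test comparing
direct-discharge rates for patients sent by the top 5% distributor EDs.

All graph statistics are implemented natively and verified in the test suite
against exhaustive brute-force enumeration and against igraph.

## Worked example

The `analysis/` directory is a numbered workflow. Step 1 simulates a
national-scale dataset (14 regions, one base hospital each, ~200 EDs, planted
population/in-degree slope +5.5 per million, dyadic reciprocity 0.21, a
+0.02 discharge-probability boost on distributor-sent transfers):

```sh
Rscript analysis/01_simulate.R        # writes results/data/
Rscript analysis/02_descriptives.R    # cleaning report + descriptive tables
Rscript analysis/03_build_networks.R  # overall / skeleton / yearly networks
Rscript analysis/04_network_statistics.R
Rscript analysis/05_secondary_analyses.R
Rscript analysis/06_sociograms.R      # geographic sociograms + manifests
```

With the default seed this prints, among other output:

```
Simulated 201 hospitals (14 hubs) in 14 regions; 19294 transfers over 2014-2016.
Network [overall]: 201 nodes, 714 arcs
  density                  0.02
  in-degree centralization 0.11
  average clustering       0.04
  asymmetric/mutual dyads  466/124
  reciprocity              0.21
14 hospitals have >= 15 transfer-in partners; 14 of them are designated hubs.
In-degree vs population: beta = +5.3 in-degrees per million residents (SE 0.10), p = 3.28e-121, n = 201
Direct ED discharge: 7.9% (179/2261) among top-distributor transfers vs 5.5% (938/17033) elsewhere; z = 4.61, p = 4.02e-06
 year n_nodes n_arcs density in_degree_centralization reciprocity
 2014     199    508  0.0129                   0.0886      0.0972
 2015     200    544  0.0137                   0.1024      0.0837
 2016     200    603  0.0152                   0.1110      0.1229
non-decreasing over the period: n_nodes, n_arcs, density, in_degree_centralization
```

Reading the output: the realized network recovers what the generator planted —
the reciprocity (0.21) matches the target; the regression slope (+5.3 ± 0.2)
matches the planted +5.5; exactly the 14 designated hub hospitals sit in the
in-degree long tail (≥ 15 transfer-in partners); transfers sent by the top 5%
distributor EDs are discharged directly from the receiving ED more often
(7.9% vs 5.5%), recovering the planted outcome difference; and ties, density
and in-degree centralization all rise year on year, the signature of a
network consolidating around its hubs.

The same functions run on real data: point `read_transfers()` (with a column
mapping) and `read_registry()` at your registry extracts and proceed from
step 2.

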