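---
title: "Methods: network statistics and synthetic transfer data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network statistics and synthetic transfer data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edtransfernet)
```

# The model

An interhospital ED transfer system is modelled as a directed valued graph:
each hospital-based emergency department is a node, and a transfer from
hospital $i$ to hospital $j$ contributes to the arc $i \to j$, whose value is
the number of transfers it carries over the study window. Self-transfers are
invalid and removed at ingest. The node universe defaults to hospitals
incident to at least one transfer; registry isolates can be retained
(`include_isolates = TRUE`) when one wants the density denominator to reflect
all designated EDs rather than the active ones.

Two views of the network matter:

* the **valued** view, used for thresholding: the *skeleton* keeps arcs with
  at least 36 transfers per 3-year window (one per month on average), split
  further into *medium* (36–365) and *strong* (> 365) ties. Thresholding is
  an arc-weight filter; a node survives if and only if it keeps an incident
  arc. This reading (rather than a node-throughput filter) is what makes the
  skeleton's node count fall below the overall network's.
* the **binary** view, used for every statistic: degrees count distinct
  partners, and path-based statistics treat the graph as directed and
  unweighted. Tie values carry no distance semantics here — a
  weighted-geodesic rule would need an arbitrary weight-to-length transform,
  and the printed standardizations $(N-1)(N-2)$ and $(N-1)$ presuppose unit
  steps.

# Node-level statistics

For $N$ nodes, writing $d^{in}_v$, $d^{out}_v$ for distinct-partner counts:

* net connectivity $d^{in}_v - d^{out}_v$: positive values mark "receiver"
  hospitals, negative values "distributors".
* betweenness: $b_v = \sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$ over
  directed geodesics, computed by Brandes' dependency accumulation;
  standardized by $(N-1)(N-2)$, the number of ordered pairs $v$ could
  intermediate, so $b^{std}_v \in [0,1]$. Standardization requires $N \ge 3$.
* closeness: farness $f_v$ is the summed geodesic distance from $v$ to the
  other nodes (direction `"out"`, the default, measures spreading capacity;
  `"in"` measures accessibility); the standardized value is $(N-1)/f_v$.
* local clustering: with neighborhood the union of in- and out-neighbors of
  size $k$, the coefficient is the count of directed arcs among neighbors
  over $k(k-1)$; nodes with $k < 2$ score 0 and are *included* in the
  network average (excluding them would inflate sparse networks' clustering).

**Unreachable targets.** Transfer networks are rarely strongly connected, so
closeness needs a convention. The default (`"penalized"`) counts each
unreachable target as distance $N$ — one more than any possible geodesic —
and scores 0 for a node that reaches no one; it is continuous in the graph
(adding a long path recovers nearly the same value as removing it) and keeps
the standardized value in $[0,1]$. The alternative (`"reachable_only"`), the
Wasserman–Faust correction $\frac{r}{N-1}\cdot\frac{r}{f_r}$ over the $r$
reached nodes, is also available because sources differ on this point and the
choice materially changes the mean closeness of fragmented networks. Both
ship; results should state which was used.

# Network-level statistics

* density $= A/(N(N-1))$ for $A$ arcs.
* Freeman in-degree centralization
  $\sum_v (d^{in}_{max} - d^{in}_v) / (N-1)^2$. The denominator $(N-1)^2$ is
  chosen because it is the exact maximum of the numerator over directed
  graphs — attained by the inward star, which therefore scores exactly 1 (the
  anchor case); the undirected-style $(N-1)(N-2)$ denominator fails that
  anchor and is not used.
* dyad census: each unordered pair is mutual, asymmetric or null; the
  identities $m + a + n = N(N-1)/2$ and $2m + a = A$ are asserted in code.
* reciprocity is the **dyadic** form $m/(m+a)$. The arc-wise alternative
  ($2m/A$) is not used: only the dyadic form reproduces published reciprocity
  values from their printed dyad censuses.
* average clustering is the plain mean of local coefficients over all nodes.

# Secondary analyses

*Population regression.* OLS of in-degree on served population in millions
(`lm()`), slope reported as in-degrees per million residents with its
two-sided t-test p-value. At least 3 hospitals with known population and
non-degenerate population variance are required.

*Distributor outcome comparison.* Sender hospitals are ranked by net
connectivity; the bottom `quantile` (default 5%, type-1 quantile so boundary
ties are all included — a hospital cannot be half a distributor) defines the
distributor group. Transfers they sent are compared with all other transfers
on the proportion directly discharged from the receiving ED, by a two-sided
two-proportion z-test without continuity correction (identical groups give
$z = 0$, $p = 1$). The quantile is taken over hospitals, not transfers, so a
single high-volume distributor cannot swallow the group.

# The synthetic data generator

The restricted national registry cannot be redistributed, so the package
generates regionalized transfer data with known ground truth. The generator
is **receiver-driven**: every hospital receives a planned number of distinct
in-partners

$$d^{in}_v = \mathrm{round}\!\left(\alpha + \beta\,\mathrm{pop}_v/10^6 +
\varepsilon_v\right),\qquad \varepsilon_v \sim N(0, \sigma^2),$$

with $\beta$ = `target_slope` (default 5.5 per million) and $\alpha$ = 0.5.
Base hospitals are planted with large served populations (2.5–4.5 million vs
0.05–0.35 million for spokes), so hub status and the population/in-degree
slope arise from one mechanism rather than competing ones — this is what
makes the planted slope recoverable by the pipeline's own regression while
still putting the hubs in the in-degree long tail. Senders for each arc are
drawn with same-region affinity (weight $1 + 2\cdot\mathrm{same\ region} +
8\cdot\mathrm{same\ region \times hub\ receiver}$), producing the
hub-and-spoke regional clusters.

Other planted features:

* **reciprocity** is planted exactly: after the forward arcs are drawn, the
  number of mutual dyads is set to `round(target * non-null dyads)` by adding
  weak reverse arcs (weight 1–3) or demoting surplus mutual pairs; a target
  of 0 therefore yields exactly zero mutual dyads.
* **arc weights** are discretized log-normal; arcs from spokes into their
  own region's hub use a heavier parameterization (meanlog 3.8 vs 2.2), so
  the weight distribution naturally spans the medium (36) and strong (365)
  tie thresholds.
* **temporal growth**: arcs activate over calendar years at a rate tied to
  `yearly_growth` and persist once active, with per-year volumes growing at
  the same rate — so both transfer counts and distinct tie counts rise,
  reproducing the increasing-density, increasing-centralization trend the
  temporal report flags.
* **outcome difference**: transfers sent by the planted distributor
  hospitals (bottom 5% of senders by realized net connectivity) have their
  direct-discharge probability raised by `distributor_discharge_boost`
  (default 0.02; other disposition probabilities are renormalized).
* **record attributes** (sex, time of day, reason with a 2.2% missing rate,
  condition category, surgery, disposition) are sampled from the categorical
  tables in `inst/extdata/generator_defaults.yaml`, which follow the
  published national frequency profile of ED transfers; ages are truncated
  normal (mean 55.7, SD 23.8, range 0–111).

All calibration defaults live in that single YAML file, not in code, and the
generator emits a ground-truth ledger (planned arc weights, per-year counts,
hub and distributor identities, planted slope/reciprocity/discharge rates)
that the tests compare against.

**Scale.** The defaults produce ~200 hospitals and ~2 × 10⁴ transfers over
three years — a skeleton-scale network (a few hundred distinct ties), not the
~10⁴-tie overall national network. The simulation sizes were chosen so the
full workflow and test suite run in seconds while every planted parameter
remains comfortably recoverable; the outcome-difference boost (0.02) is
likewise larger than the sub-percentage-point differences seen in national
data so that its direction is reliably detectable at this scale.

**What passing tests do and do not show.** The generator emulates the
*structural* features the statistics respond to: regionalized hub-and-spoke
topology, heavy-tailed in-degree, mostly one-way ties, growth over time, and
a planted outcome difference. It does not emulate the density of a real
national 3-year network (where almost every ED has transferred to dozens of
partners at least once), geographic barriers, seasonal or weekday volume
cycles, hospital closures/openings mid-window, or correlated patient-mix
differences between hospitals. Parameter recovery on this synthetic data
validates the pipeline's arithmetic and plumbing, not the epidemiology of
any real system.

# Numerical and degenerate-input choices

* Time-of-day bands assign a boundary instant to the band it opens
  (15:00 is evening); weekend is Saturday/Sunday of the local departure
  date; seasons are meteorological (Mar–May spring, etc.). Records crossing
  midnight or year boundaries are classified by *departure* time throughout
  (arrival times may be missing or cross borders).
* Cleaning nullifies rather than drops wherever the row remains usable: an
  out-of-range age or a backwards arrival time becomes missing and is
  counted; only a missing/self-looped endpoint or an unparseable departure
  drops the row. Duplicate record ids keep the first occurrence.
* Percentages in descriptive tables use each variable's non-missing
  denominator, rounded to one decimal.
* `dyad_census` asserts its two count identities at run time; the network
  container rejects self-loops, dangling endpoints and duplicate ordered
  pairs at construction.
* The temporal report flags monotone non-decreasing columns with `>=`
  comparisons on exact doubles; ties (equal densities in consecutive years)
  count as non-decreasing, matching how plateaus are read in practice.
* Sociogram tests assert on the emitted JSON manifest (counts, filtered
  arcs, rounded coordinates), never on pixels, because raster output is
  device-dependent; force-directed layouts are seeded.

# Known limitations

* Betweenness and closeness are computed in pure R; the overall-network
  statistics on a ~200-node, ~10⁴-arc graph take well under a minute, but
  the implementation is not tuned for networks orders of magnitude larger.
* The skeleton of the synthetic network is sparser than a real national
  skeleton (its yearly medians of transfer-in/-out partners sit below the
  published 2/5), because the generator targets the planted slope,
  reciprocity and hub structure first; analyses of skeleton degree medians
  on synthetic data should read them as ordering (out > in) rather than
  calibrated levels.
* The regression treats hospitals as independent observations; no
  within-region correlation structure is modelled, matching the simple OLS
  formulation being reproduced.
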