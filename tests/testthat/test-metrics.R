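# Node- and network-level statistics on hand-checkable networks.

test_that("degrees count distinct partners, ignoring arc weights", {
  hub <- toy_network(sprintf("S%d->HUB", 1:5))
  deg <- degree_metrics(hub)
  h <- deg[deg$hospital_id == "HUB", ]
  expect_equal(h$in_degree, 5)
  expect_equal(h$out_degree, 0)
  expect_equal(h$net_connectivity, 5)
  expect_equal(h$total_degree, 5)

  heavy <- toy_network("A->B:100")
  expect_equal(degree_metrics(heavy)$out_degree,
               c(1, 0))  # weight does not inflate the binary degree
})

test_that("in- and out-degree totals both equal the arc count", {
  set.seed(12)
  for (i in 1:20) {
    net <- matrix_network(random_digraph(sample(3:12, 1), stats::runif(1, 0.1, 0.7)))
    deg <- degree_metrics(net)
    expect_equal(sum(deg$in_degree), nrow(net$arcs))
    expect_equal(sum(deg$out_degree), nrow(net$arcs))
  }
})

test_that("betweenness credits intermediaries on directed geodesics", {
  path <- toy_network(c("A->B", "B->C"))
  expect_equal(unname(betweenness(path, standardized = FALSE)["B"]), 1)
  expect_equal(unname(betweenness(path)["B"]), 0.5)  # 1 / ((3-1)(3-2))

  n <- 5
  complete <- matrix_network(1 - diag(n))
  expect_equal(unname(betweenness(complete)), rep(0, n))

  expect_error(betweenness(toy_network("A->B")), "at least 3")
})

test_that("closeness follows the documented unreachable conventions", {
  path <- toy_network(c("A->B", "B->C"))
  cl <- closeness(path)
  expect_equal(unname(cl["A"]), 2 / 3)        # farness 1 + 2
  expect_equal(unname(cl["B"]), 2 / 4)        # C at 1, A unreachable counts as N=3
  expect_equal(unname(cl["C"]), 0)            # reaches no one
  cl_in <- closeness(path, direction = "in")
  expect_equal(unname(cl_in["C"]), 2 / 3)

  iso <- toy_network("A->B", extra_nodes = "Z")
  expect_equal(unname(closeness(iso)["Z"]), 0)
  expect_equal(unname(closeness(iso, unreachable = "reachable_only")["Z"]), 0)

  # reachable-only correction: A reaches only B at distance 1 among N=3
  ro <- closeness(iso, unreachable = "reachable_only")
  expect_equal(unname(ro["A"]), (1 / 2) * (1 / 1))
})

test_that("local clustering uses the union neighborhood and directed arc counting", {
  tri <- matrix_network(1 - diag(3))  # all 6 directed arcs
  expect_equal(unname(local_clustering(tri)), rep(1, 3))

  star <- toy_network(sprintf("S%d->HUB", 1:4))
  expect_equal(unname(local_clustering(star)["HUB"]), 0)

  # two neighbors joined one way: 1 arc of the 2 possible
  vee <- toy_network(c("A->C", "B->C", "A->B"))
  expect_equal(unname(local_clustering(vee)["C"]), 0.5)
})

test_that("network metrics reproduce the closed-form anchors", {
  # inward star: all ties converge on one hub, centralization exactly 1
  star <- toy_network(sprintf("S%02d->HUB", 1:19))
  m <- network_metrics(star)
  expect_equal(m$in_degree_centralization, 1)
  expect_equal(m$density, 19 / (20 * 19))

  # any in-regular digraph (directed cycle) has centralization exactly 0
  cyc <- toy_network(c("A->B", "B->C", "C->D", "D->A"))
  expect_equal(network_metrics(cyc)$in_degree_centralization, 0)
  expect_equal(network_metrics(cyc)$reciprocity, 0)

  pair <- toy_network(c("A->B", "B->A"))
  expect_equal(network_metrics(pair)$reciprocity, 1)
  expect_error(network_metrics(toy_network(character(0), extra_nodes = "A")),
               "at least 2")
})

test_that("all normalized statistics stay within [0, 1] on random digraphs", {
  set.seed(44)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    net <- matrix_network(random_digraph(n, stats::runif(1, 0.1, 0.8)))
    m <- network_metrics(net)
    vals <- c(m$density, m$in_degree_centralization, m$avg_clustering,
              betweenness(net), closeness(net), local_clustering(net))
    if (!is.na(m$reciprocity)) vals <- c(vals, m$reciprocity)
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("population regression recovers exact lines and guards degeneracy", {
  nodes <- data.frame(hospital_id = c("A", "B", "C"),
                      in_degree = c(5, 10, 15))
  reg <- small_registry(c("A", "B", "C"))
  reg$population_served <- c(1e6, 2e6, 3e6)
  fit <- suppressWarnings(degree_population_regression(nodes, reg))
  expect_equal(fit$slope, 5)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$n_points, 3)

  nodes$in_degree <- c(7, 7, 7)
  expect_equal(suppressWarnings(degree_population_regression(nodes, reg))$slope, 0)

  reg$population_served <- 1e6
  expect_error(degree_population_regression(nodes, reg), "variance")
  expect_error(degree_population_regression(nodes[1:2, ], reg[1:2, ]),
               "at least 3")
})

test_that("distributor comparison reproduces printed-style percentages and a null case", {
  # two senders, one a strong distributor; 62/1000 vs 54/1000 discharges
  nodes <- data.frame(hospital_id = c("D", "E", "R"),
                      net_connectivity = c(-10, 4, 6))
  rec <- rbind(make_records(1000, "D", "R"), make_records(1000, "E", "R"))
  rec$record_id <- sprintf("r%04d", 1:2000)
  rec$disposition <- "ward_admission"
  rec$disposition[c(1:62, 1000 + 1:54)] <- "discharged_outpatient"
  cmp <- distributor_discharge_comparison(rec, nodes, quantile = 0.5)
  expect_equal(cmp$percent_a, 6.2)
  expect_equal(cmp$percent_b, 5.4)
  expect_true(cmp$p_value < 1)

  # identical groups: z = 0, two-sided p = 1
  rec$disposition <- rep(rep(c("discharged_outpatient", "ward_admission"),
                             c(54, 946)), 2)
  cmp0 <- distributor_discharge_comparison(rec, nodes, quantile = 0.5)
  expect_equal(cmp0$z, 0)
  expect_equal(cmp0$p_value, 1)
})

test_that("boundary ties in the distributor quantile are all included", {
  nodes <- data.frame(hospital_id = c("A", "B", "C", "D"),
                      net_connectivity = c(-5, -5, 2, 3))
  rec <- do.call(rbind, lapply(c("A", "B", "C", "D"), function(s) {
    x <- make_records(10, s, "Z"); x$record_id <- paste0(s, 1:10); x
  }))
  cmp <- distributor_discharge_comparison(rec, nodes, quantile = 0.25)
  expect_setequal(cmp$distributor_ids, c("A", "B"))
})

test_that("degree distributions report histogram, median and IQR", {
  nodes <- data.frame(hospital_id = letters[1:4], in_degree = c(1, 2, 2, 9),
                      out_degree = 0, total_degree = c(1, 2, 2, 9))
  dd <- degree_distribution(nodes, "in")
  expect_equal(dd$median, 2)
  expect_equal(dd$table$n_hospitals[dd$table$degree == 2], 2)
  single <- degree_distribution(
    data.frame(hospital_id = "a", in_degree = 0, out_degree = 0,
               total_degree = 0), "total")
  expect_equal(single$table, data.frame(degree = 0L, n_hospitals = 1L))
})
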