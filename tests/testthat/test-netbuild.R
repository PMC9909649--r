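# Network construction, skeleton thresholding, dyad census, yearly slices, IO.

test_that("build_network aggregates ordered pairs into weighted arcs", {
  rec <- rbind(make_records(2, "A", "B"), make_records(1, "B", "A"))
  rec$record_id <- c("a", "b", "c")
  net <- build_network(rec, small_registry(c("A", "B", "C")))
  expect_equal(nrow(net$nodes), 2)  # C is an isolate and excluded by default
  expect_equal(net$arcs[net$arcs$sender == "A", "weight"], 2L)
  expect_equal(net$arcs[net$arcs$sender == "B", "weight"], 1L)

  with_iso <- build_network(rec, small_registry(c("A", "B", "C")),
                            include_isolates = TRUE)
  expect_equal(nrow(with_iso$nodes), 3)

  cyc <- do.call(rbind, Map(function(s, r) {
    x <- make_records(1, s, r); x$record_id <- paste0(s, r); x
  }, c("A", "B", "C", "D"), c("B", "C", "D", "A")))
  cnet <- build_network(cyc, small_registry(c("A", "B", "C", "D")))
  expect_equal(nrow(cnet$arcs), 4)
  expect_true(all(cnet$arcs$weight == 1))
})

test_that("weight conservation: arc weights sum to contributing records under any period filter", {
  cfg <- generator_config(seed = 5, n_regions = 4, hospitals_per_region = c(5, 8))
  reg <- generate_registry(cfg)
  gt <- generate_transfers(reg, cfg)
  net <- build_network(gt$records, reg)
  expect_equal(sum(net$arcs$weight), nrow(gt$records))

  p <- c("2015-01-01 00:00:00", "2015-12-31 23:59:59")
  net15 <- build_network(gt$records, reg, period = p, period_label = "2015")
  in_period <- sum(gt$records$depart_datetime >= edtransfernet:::parse_dt(p[1]) &
                     gt$records$depart_datetime <= edtransfernet:::parse_dt(p[2]))
  expect_equal(sum(net15$arcs$weight), in_period)
})

test_that("unresolvable hospital ids error by default and can be dropped leniently", {
  rec <- make_records(3, c("A", "A", "ZZZ"), c("B", "B", "B"))
  rec$record_id <- c("a", "b", "c")
  reg <- small_registry(c("A", "B"))
  expect_error(build_network(rec, reg), "ZZZ")
  expect_message(net <- build_network(rec, reg, on_unknown = "drop"), "dropping 1")
  expect_equal(sum(net$arcs$weight), 2)
})

test_that("skeleton extraction filters by arc weight and drops isolated nodes", {
  net <- toy_network(c("A->B:40", "B->C:10"))
  sk <- extract_skeleton(net, 36)
  expect_equal(sk$arcs$weight, 40L)
  expect_setequal(sk$nodes$hospital_id, c("A", "B"))

  # medium-tie band excludes strong ties
  strong <- toy_network(c("A->B:400"))
  medium <- extract_skeleton(strong, 36, 365)
  expect_equal(nrow(medium$arcs), 0)

  # min_weight 1 is the identity transform
  expect_equal(extract_skeleton(net, 1)$arcs, net$arcs)
  expect_error(extract_skeleton(net, 36, 10), "max_weight")
})

test_that("skeleton extraction is idempotent and monotone in the threshold", {
  set.seed(31)
  A <- random_digraph(12, 0.4)
  net <- matrix_network(A, weights = sample(1:500, sum(A), replace = TRUE))
  sk36 <- extract_skeleton(net, 36)
  expect_equal(extract_skeleton(sk36, 36)$arcs, sk36$arcs)
  prev_arcs <- nrow(net$arcs); prev_nodes <- nrow(net$nodes)
  for (thr in c(10, 36, 100, 365)) {
    sk <- extract_skeleton(net, thr)
    expect_lte(nrow(sk$arcs), prev_arcs)
    expect_lte(nrow(sk$nodes), prev_nodes)
    prev_arcs <- nrow(sk$arcs); prev_nodes <- nrow(sk$nodes)
  }
})

test_that("dyad census classifies mutual, asymmetric and null pairs", {
  net <- toy_network(c("A->B:1", "B->A:5"), extra_nodes = "C")
  cen <- dyad_census(net)
  expect_equal(cen$mutual, 1)
  expect_equal(cen$asymmetric, 0)
  expect_equal(cen$null_pairs, 2)
})

test_that("dyad census matches exhaustive pair enumeration on random digraphs", {
  set.seed(97)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    A <- random_digraph(n, stats::runif(1, 0.1, 0.6))
    cen <- dyad_census(matrix_network(A))
    orc <- oracle_dyad_census(A)
    expect_equal(cen$mutual, orc$mutual)
    expect_equal(cen$asymmetric, orc$asymmetric)
    expect_equal(cen$null_pairs, orc$null_pairs)
    expect_equal(2 * cen$mutual + cen$asymmetric, sum(A))
  }
})

test_that("yearly slices partition the records by departure year", {
  rec <- rbind(
    make_records(2, "A", "B", as.POSIXct("2014-05-01 10:00:00", tz = "UTC")),
    make_records(3, "A", "C", as.POSIXct("2016-05-01 10:00:00", tz = "UTC")))
  rec$record_id <- sprintf("r%d", 1:5)
  nets <- slice_by_year(rec, small_registry(c("A", "B", "C")))
  expect_equal(names(nets), c("2014", "2016"))
  expect_equal(sum(nets[["2014"]]$arcs$weight) + sum(nets[["2016"]]$arcs$weight),
               nrow(rec))
  # yearly arcs are subsets of the overall arc set
  overall <- build_network(rec, small_registry(c("A", "B", "C")))
  all_keys <- paste(overall$arcs$sender, overall$arcs$receiver)
  for (nt in nets)
    expect_true(all(paste(nt$arcs$sender, nt$arcs$receiver) %in% all_keys))
})

test_that("yearly node and tie counts match the generator ledger years", {
  cfg <- generator_config(seed = 8, n_regions = 4, hospitals_per_region = c(5, 8))
  reg <- generate_registry(cfg)
  gt <- generate_transfers(reg, cfg)
  nets <- slice_by_year(gt$records, reg)
  expect_setequal(names(nets), names(gt$ledger$per_year_counts))
  for (y in names(nets))
    expect_equal(sum(nets[[y]]$arcs$weight),
                 unname(gt$ledger$per_year_counts[y]))
})

test_that("edge-list CSV round-trips bit-exactly and GraphML preserves attributes", {
  cfg <- generator_config(seed = 3, n_regions = 3, hospitals_per_region = c(4, 6))
  reg <- generate_registry(cfg)
  gt <- generate_transfers(reg, cfg)
  net <- build_network(gt$records, reg)

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_edgelist(net, p1)
  back <- read_edgelist(p1, registry = reg)
  expect_equal(back$arcs, net$arcs)
  write_edgelist(back, p2)
  expect_identical(readLines(p1), readLines(p2))  # bit-exact dialect

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  gback <- read_graphml(gml)
  gb <- gback$arcs[order(gback$arcs$sender, gback$arcs$receiver), ]
  rownames(gb) <- NULL
  expect_equal(gb, net$arcs)
  expect_setequal(gback$nodes$hospital_id, net$nodes$hospital_id)
  m <- merge(gback$nodes, net$nodes, by = "hospital_id")
  expect_equal(m$is_base.x, m$is_base.y)
  expect_equal(m$longitude.x, m$longitude.y)
})
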