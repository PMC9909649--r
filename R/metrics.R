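# Node- and network-level statistics for directed valued transfer networks.
#
# All path-based statistics treat the network as directed and UNWEIGHTED:
# an arc of weight 400 and an arc of weight 1 contribute the same geodesic
# step. Weights enter only through skeleton thresholding.

# adjacency index: integer out-/in-neighbor lists over nodes 1..N
adjacency_index <- function(net) {
  ids <- net$nodes$hospital_id
  n <- length(ids)
  out_adj <- rep(list(integer(0)), n)
  in_adj <- rep(list(integer(0)), n)
  if (nrow(net$arcs)) {
    s <- match(net$arcs$sender, ids)
    r <- match(net$arcs$receiver, ids)
    out_split <- split(r, factor(s, levels = seq_len(n)))
    in_split <- split(s, factor(r, levels = seq_len(n)))
    out_adj <- lapply(out_split, as.integer)
    in_adj <- lapply(in_split, as.integer)
  }
  list(ids = ids, n = n, out_adj = out_adj, in_adj = in_adj)
}

bfs_distances <- function(adj, s, n) {
  dist <- rep(-1L, n)
  dist[s] <- 0L
  queue <- integer(n)
  queue[1] <- s
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        tail <- tail + 1L
        queue[tail] <- w
      }
    }
  }
  dist
}

#' Degree-based node statistics
#'
#' Degrees count distinct transfer partners (the binary view of the valued
#' network): `in_degree` is the number of distinct hospitals a node receives
#' transfers from, `out_degree` the number it sends to, and net connectivity
#' `in_degree - out_degree` separates "receiver" hospitals (positive) from
#' "distributor" hospitals (negative).
#'
#' @param net A `transfer_network`.
#' @return Data frame with `hospital_id`, `in_degree`, `out_degree`,
#'   `total_degree`, `net_connectivity`.
#' @export
degree_metrics <- function(net) {
  ix <- adjacency_index(net)
  data.frame(
    hospital_id = ix$ids,
    in_degree = lengths(ix$in_adj),
    out_degree = lengths(ix$out_adj),
    total_degree = lengths(ix$in_adj) + lengths(ix$out_adj),
    net_connectivity = lengths(ix$in_adj) - lengths(ix$out_adj),
    stringsAsFactors = FALSE)
}

#' Betweenness centrality (directed, unweighted)
#'
#' Brandes' accumulation of shortest-path dependencies: the betweenness of a
#' node is the number of geodesics between ordered pairs of other nodes that
#' pass through it, with fractional credit when several geodesics tie.
#' The standardized value divides by `(N-1)(N-2)`, the number of ordered
#' pairs a node could possibly intermediate, giving a value in [0, 1].
#'
#' @param net A `transfer_network`.
#' @param standardized Divide by `(N-1)(N-2)` (requires at least 3 nodes).
#' @return Named numeric vector over `hospital_id`.
#' @export
betweenness <- function(net, standardized = TRUE) {
  ix <- adjacency_index(net)
  n <- ix$n
  if (standardized && n < 3)
    stop("standardized betweenness requires at least 3 nodes")
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- rep(list(integer(0)), n)
    queue <- integer(n); queue[1] <- s
    head <- 1L; tail <- 1L
    order_popped <- integer(n); npop <- 0L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      npop <- npop + 1L; order_popped[npop] <- v
      dv1 <- dist[v] + 1L
      for (w in ix$out_adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dv1
          tail <- tail + 1L; queue[tail] <- w
        }
        if (dist[w] == dv1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (i in rev(seq_len(npop))) {
      w <- order_popped[i]
      coef <- (1 + delta[w]) / sigma[w]
      for (p in preds[[w]]) delta[p] <- delta[p] + sigma[p] * coef
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  if (standardized) bc <- bc / ((n - 1) * (n - 2))
  stats::setNames(bc, ix$ids)
}

#' Closeness centrality (directed, unweighted)
#'
#' Farness is the sum of geodesic distances from (direction `"out"`) or to
#' (direction `"in"`) all other nodes; closeness is its inverse, and the
#' standardized value multiplies by `N-1` so a node adjacent to everyone
#' scores 1. Real transfer networks are rarely strongly connected, so two
#' unreachable-target conventions are available: `"penalized"` (default)
#' counts each unreachable target as distance `N` (one more than any possible
#' geodesic) and assigns 0 to a node that reaches no one; `"reachable_only"`
#' uses the Wasserman--Faust correction `(r/(N-1)) * (r/farness_r)` over the
#' `r` reachable targets. Both stay within [0, 1].
#'
#' @param net A `transfer_network`.
#' @param direction `"out"` (distances from the node) or `"in"` (to it).
#' @param standardized Return the `N-1`-standardized value (default) rather
#'   than raw `1/farness`.
#' @param unreachable Convention for unreachable targets.
#' @return Named numeric vector over `hospital_id`.
#' @export
closeness <- function(net, direction = c("out", "in"), standardized = TRUE,
                      unreachable = c("penalized", "reachable_only")) {
  direction <- match.arg(direction)
  unreachable <- match.arg(unreachable)
  ix <- adjacency_index(net)
  n <- ix$n
  adj <- if (direction == "out") ix$out_adj else ix$in_adj
  vals <- vapply(seq_len(n), function(s) {
    if (n < 2) return(0)
    d <- bfs_distances(adj, s, n)
    d <- d[-s]
    reached <- d >= 0L
    r <- sum(reached)
    if (r == 0) return(0)
    if (unreachable == "penalized") {
      farness <- sum(d[reached]) + n * (n - 1 - r)
      if (standardized) (n - 1) / farness else 1 / farness
    } else {
      farness <- sum(d[reached])
      if (standardized) (r / (n - 1)) * (r / farness) else 1 / farness
    }
  }, numeric(1))
  stats::setNames(vals, ix$ids)
}

#' Local clustering coefficient (directed)
#'
#' A node's neighborhood is the union of its in- and out-neighbors (binary
#' view, excluding itself). The coefficient is the number of directed arcs
#' observed among the `k` neighbors divided by the maximum possible
#' `k(k-1)`; nodes with fewer than two neighbors score 0.
#'
#' @param net A `transfer_network`.
#' @return Named numeric vector over `hospital_id`.
#' @export
local_clustering <- function(net) {
  ix <- adjacency_index(net)
  n <- ix$n
  A <- matrix(FALSE, n, n)
  if (nrow(net$arcs)) {
    A[cbind(match(net$arcs$sender, ix$ids), match(net$arcs$receiver, ix$ids))] <- TRUE
  }
  vals <- vapply(seq_len(n), function(v) {
    nb <- union(ix$out_adj[[v]], ix$in_adj[[v]])
    nb <- nb[nb != v]
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  stats::setNames(vals, ix$ids)
}

#' All node-level statistics in one table
#'
#' @param net A `transfer_network`.
#' @return Data frame with the degree fields plus `betweenness_std`,
#'   `closeness_std`, `clustering_local` (betweenness is `NA` for networks
#'   with fewer than 3 nodes).
#' @export
node_metrics <- function(net) {
  out <- degree_metrics(net)
  n <- nrow(net$nodes)
  out$betweenness_std <- if (n >= 3) unname(betweenness(net)) else NA_real_
  out$closeness_std <- unname(closeness(net))
  out$clustering_local <- unname(local_clustering(net))
  out
}

#' Write per-node statistics to CSV
#'
#' @param nodes Data frame from [node_metrics()].
#' @param path Output path.
#' @export
write_node_metrics <- function(nodes, path) {
  utils::write.csv(nodes, path, row.names = FALSE)
  invisible(path)
}

#' Network-level statistics
#'
#' Computes the whole-network summary: density `arcs / (N(N-1))`; Freeman
#' in-degree centralization `sum(d_max - d_i) / (N-1)^2`, which equals 1 when
#' every other node sends into a single hub and 0 for any in-regular network;
#' average local clustering over all nodes; the dyad census and dyadic
#' reciprocity `mutual / (mutual + asymmetric)`; and mean/SD of standardized
#' betweenness and (outgoing) closeness.
#'
#' @param net A `transfer_network` with at least 2 nodes.
#' @return A `network_metrics` list.
#' @export
network_metrics <- function(net) {
  n <- nrow(net$nodes)
  if (n < 2) stop("network metrics require at least 2 nodes")
  deg <- degree_metrics(net)
  census <- dyad_census(net)
  nonnull <- census$mutual + census$asymmetric
  btw <- if (n >= 3) betweenness(net) else NULL
  cls <- closeness(net)
  clust <- local_clustering(net)
  structure(list(
    period_label = net$period_label,
    n_nodes = n,
    n_arcs = nrow(net$arcs),
    n_transfers = sum(net$arcs$weight),
    density = nrow(net$arcs) / (n * (n - 1)),
    in_degree_centralization = sum(max(deg$in_degree) - deg$in_degree) / (n - 1)^2,
    avg_clustering = mean(clust),
    reciprocity = if (nonnull > 0) census$mutual / nonnull else NA_real_,
    census = census,
    betweenness_mean = if (is.null(btw)) NA_real_ else mean(btw),
    betweenness_sd = if (is.null(btw)) NA_real_ else stats::sd(btw),
    closeness_mean = mean(cls),
    closeness_sd = stats::sd(cls)
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("Network%s: %d nodes, %d arcs\n",
              if (nzchar(x$period_label)) paste0(" [", x$period_label, "]") else "",
              x$n_nodes, x$n_arcs))
  cat(sprintf("  density                  %.2f\n", x$density))
  cat(sprintf("  in-degree centralization %.2f\n", x$in_degree_centralization))
  cat(sprintf("  average clustering       %.2f\n", x$avg_clustering))
  cat(sprintf("  asymmetric/mutual dyads  %d/%d\n", x$census$asymmetric, x$census$mutual))
  cat(sprintf("  reciprocity              %.2f\n", x$reciprocity))
  cat(sprintf("  betweenness, mean (SD)   %.3f (%.3f)\n",
              x$betweenness_mean, x$betweenness_sd))
  cat(sprintf("  closeness, mean (SD)     %.2f (%.2f)\n",
              x$closeness_mean, x$closeness_sd))
  invisible(x)
}

#' @export
as.data.frame.network_metrics <- function(x, ...) {
  data.frame(period_label = x$period_label, n_nodes = x$n_nodes,
             n_arcs = x$n_arcs, n_transfers = x$n_transfers,
             density = x$density,
             in_degree_centralization = x$in_degree_centralization,
             avg_clustering = x$avg_clustering,
             mutual_dyads = x$census$mutual,
             asymmetric_dyads = x$census$asymmetric,
             reciprocity = x$reciprocity,
             betweenness_mean = x$betweenness_mean,
             betweenness_sd = x$betweenness_sd,
             closeness_mean = x$closeness_mean,
             closeness_sd = x$closeness_sd,
             stringsAsFactors = FALSE)
}

#' Regression of in-degree on served population
#'
#' Ordinary least squares of a hospital's in-degree (distinct transfer-in
#' partners) on the population its region serves, in millions of residents,
#' testing whether bigger catchments attract more transfer-in partners.
#'
#' @param nodes Data frame from [degree_metrics()] or [node_metrics()].
#' @param registry Hospital registry with `population_served` (persons).
#' @return An `indegree_regression` list: `slope` (in-degrees per million
#'   residents), `intercept`, `slope_se`, `p_value`, `n_points`.
#' @export
degree_population_regression <- function(nodes, registry) {
  df <- merge(nodes[c("hospital_id", "in_degree")],
              registry[c("hospital_id", "population_served")],
              by = "hospital_id")
  df <- df[!is.na(df$population_served), , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 hospitals with known population")
  df$pop_millions <- df$population_served / 1e6
  if (stats::var(df$pop_millions) == 0) stop("population has zero variance")
  fit <- stats::lm(in_degree ~ pop_millions, data = df)
  coefs <- summary(fit)$coefficients
  structure(list(slope = unname(coefs["pop_millions", "Estimate"]),
                 intercept = unname(coefs["(Intercept)", "Estimate"]),
                 slope_se = unname(coefs["pop_millions", "Std. Error"]),
                 p_value = unname(coefs["pop_millions", "Pr(>|t|)"]),
                 n_points = nrow(df)),
            class = "indegree_regression")
}

#' @export
print.indegree_regression <- function(x, ...) {
  cat(sprintf(
    "In-degree vs population: beta = %+.1f in-degrees per million residents (SE %.2f), p = %.3g, n = %d\n",
    x$slope, x$slope_se, x$p_value, x$n_points))
  invisible(x)
}

# two-proportion z-test, two-sided, no continuity correction
two_proportion_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Outcome comparison for top "distributor" hospitals
#'
#' Ranks sending hospitals by net connectivity (in-degree minus out-degree;
#' the most negative values are the strongest distributors), takes the bottom
#' `quantile` of sender hospitals (boundary ties included), and compares the
#' proportion of their transferred patients discharged directly from the
#' receiving ED against all other transfers with a two-sided two-proportion
#' z-test (no continuity correction).
#'
#' @param records Transfer records with a `disposition` column.
#' @param nodes Data frame from [degree_metrics()] or [node_metrics()].
#' @param quantile Fraction of sender hospitals forming the distributor group
#'   (default 0.05).
#' @return A `proportion_comparison` list with group numerators/denominators,
#'   percentages, the z statistic, p-value and the distributor hospital IDs.
#' @export
distributor_discharge_comparison <- function(records, nodes, quantile = 0.05) {
  senders <- nodes[nodes$hospital_id %in% unique(records$sender_id), , drop = FALSE]
  if (nrow(senders) < 2) stop("need at least 2 sender hospitals")
  cutoff <- stats::quantile(senders$net_connectivity, probs = quantile,
                            names = FALSE, type = 1)
  distributors <- senders$hospital_id[senders$net_connectivity <= cutoff]
  rec <- records[!is.na(records$disposition), , drop = FALSE]
  in_a <- rec$sender_id %in% distributors
  if (!any(in_a) || all(in_a)) stop("distributor comparison has an empty group")
  num_a <- sum(rec$disposition[in_a] == "discharged_outpatient")
  num_b <- sum(rec$disposition[!in_a] == "discharged_outpatient")
  den_a <- sum(in_a); den_b <- sum(!in_a)
  zt <- two_proportion_z(num_a, den_a, num_b, den_b)
  structure(list(group_a_numerator = num_a, group_a_denominator = den_a,
                 group_b_numerator = num_b, group_b_denominator = den_b,
                 percent_a = 100 * num_a / den_a,
                 percent_b = 100 * num_b / den_b,
                 z = zt$z, p_value = zt$p_value,
                 distributor_ids = distributors),
            class = "proportion_comparison")
}

#' @export
print.proportion_comparison <- function(x, ...) {
  cat(sprintf(
    "Direct ED discharge: %.1f%% (%d/%d) among top-distributor transfers vs %.1f%% (%d/%d) elsewhere; z = %.2f, p = %.3g\n",
    x$percent_a, x$group_a_numerator, x$group_a_denominator,
    x$percent_b, x$group_b_numerator, x$group_b_denominator, x$z, x$p_value))
  invisible(x)
}

#' Degree distribution with median and IQR
#'
#' @param nodes Data frame from [degree_metrics()] or [node_metrics()].
#' @param direction `"in"`, `"out"` or `"total"`.
#' @return A `degree_distribution` list: `table` (data frame `degree`,
#'   `n_hospitals`), `median`, `q25`, `q75`, `direction`.
#' @export
degree_distribution <- function(nodes, direction = c("in", "out", "total")) {
  direction <- match.arg(direction)
  if (nrow(nodes) == 0) stop("no nodes")
  deg <- nodes[[paste0(direction, "_degree")]]
  tab <- table(deg)
  q <- stats::quantile(deg, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(
    table = data.frame(degree = as.integer(names(tab)),
                       n_hospitals = as.integer(tab)),
    median = q[2], q25 = q[1], q75 = q[3], direction = direction),
    class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("%s-degree: median %g (IQR %g-%g)\n",
              x$direction, x$median, x$q25, x$q75))
  print(x$table, row.names = FALSE)
  invisible(x)
}
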