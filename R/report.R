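# Sociograms and temporal comparison tables.
#
# Tests and downstream checks never assert on pixels: every rendering call
# emits a JSON manifest (node/arc counts, filtered arcs, layout) next to the
# image, and that manifest is the assertable surface.

#' Sociogram specification
#'
#' @param layout `"geographic"` (node positions are longitude/latitude) or
#'   `"force_directed"` (Fruchterman--Reingold, seeded).
#' @param node_size_by Node radius metric: `"in_degree"`, `"total_degree"` or
#'   `"constant"`.
#' @param hub_color,nonhub_color Colors for base and non-base hospitals.
#' @param min_weight,max_weight Arc-weight filter applied before drawing
#'   (e.g. 36--365 for the medium-tie view).
#' @param title Plot title.
#' @return A `sociogram_spec` list.
#' @export
sociogram_spec <- function(layout = c("geographic", "force_directed"),
                           node_size_by = c("in_degree", "total_degree", "constant"),
                           hub_color = "red", nonhub_color = "steelblue",
                           min_weight = 1, max_weight = NULL, title = "") {
  if (!is.null(max_weight) && max_weight < min_weight)
    stop("max_weight must be >= min_weight")
  structure(list(layout = match.arg(layout),
                 node_size_by = match.arg(node_size_by),
                 hub_color = hub_color, nonhub_color = nonhub_color,
                 min_weight = min_weight, max_weight = max_weight,
                 title = title),
            class = "sociogram_spec")
}

#' Render a sociogram
#'
#' Draws the transfer network with node radius monotone in the chosen degree
#' metric and base hospitals in the hub color. In geographic mode, node
#' positions are (longitude, latitude); in force-directed mode the layout is
#' seeded and reproducible. Arcs outside the spec's weight band are filtered
#' out before drawing. A JSON manifest (`<out_path>.manifest.json`) records
#' what was drawn.
#'
#' @param net A `transfer_network`.
#' @param spec A `sociogram_spec`.
#' @param out_path Image path; `.png` and `.pdf` extensions are supported.
#' @param seed Layout seed for force-directed mode.
#' @return The manifest list, invisibly.
#' @export
render_sociogram <- function(net, spec, out_path, seed = 1) {
  n_before <- nrow(net$arcs)
  shown <- if (spec$min_weight > 1 || !is.null(spec$max_weight)) {
    extract_skeleton(net, spec$min_weight, spec$max_weight)
  } else net
  nodes <- shown$nodes
  arcs <- shown$arcs

  if (spec$layout == "geographic") {
    if (any(is.na(nodes$longitude)) || any(is.na(nodes$latitude)))
      stop("geographic layout requires coordinates on all nodes")
    xy <- cbind(nodes$longitude, nodes$latitude)
  } else {
    set.seed(seed)
    xy <- igraph::layout_with_fr(as_igraph(shown))
  }

  deg <- degree_metrics(shown)
  size_metric <- switch(spec$node_size_by,
                        in_degree = deg$in_degree,
                        total_degree = deg$total_degree,
                        constant = rep(1, nrow(nodes)))
  radius <- 0.6 + 1.8 * sqrt(size_metric / max(1, max(size_metric)))

  ext <- tolower(tools::file_ext(out_path))
  if (ext == "pdf") grDevices::pdf(out_path, width = 7, height = 7)
  else grDevices::png(out_path, width = 1400, height = 1400, res = 200)
  op <- graphics::par(mar = c(1, 1, if (nzchar(spec$title)) 3 else 1, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                 main = spec$title, asp = 1)
  if (nrow(arcs)) {
    si <- match(arcs$sender, nodes$hospital_id)
    ri <- match(arcs$receiver, nodes$hospital_id)
    graphics::segments(xy[si, 1], xy[si, 2], xy[ri, 1], xy[ri, 2],
                       col = grDevices::adjustcolor("grey40", alpha.f = 0.35),
                       lwd = 0.5 + log1p(arcs$weight) / 4)
  }
  graphics::points(xy, pch = 21,
                   bg = ifelse(!is.na(nodes$is_base) & nodes$is_base,
                               spec$hub_color, spec$nonhub_color),
                   cex = radius, lwd = 0.4)

  manifest <- list(
    layout = spec$layout,
    node_size_by = spec$node_size_by,
    min_weight = spec$min_weight,
    max_weight = if (is.null(spec$max_weight)) NA else spec$max_weight,
    n_nodes_drawn = nrow(nodes),
    n_arcs_drawn = nrow(arcs),
    n_arcs_filtered_out = n_before - nrow(arcs),
    n_hubs_drawn = sum(nodes$is_base, na.rm = TRUE),
    node_ids = nodes$hospital_id,
    coords = round(unname(as.matrix(xy)), 6),
    seed = if (spec$layout == "force_directed") seed else NA)
  jsonlite::write_json(manifest, paste0(out_path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Temporal comparison of yearly network statistics
#'
#' One row per calendar year with the headline statistics, flagging which
#' columns changed monotonically (non-decreasing) over the period — the
#' signature of a network becoming denser and more hub-centred over time.
#'
#' @param yearly Named list of `network_metrics`, one per year (e.g. from
#'   [slice_by_year()] + [network_metrics()]), in chronological order.
#' @return A `temporal_report` data frame (`year`, `n_nodes`, `n_arcs`,
#'   `density`, `in_degree_centralization`, `reciprocity`) with a
#'   `monotone_nondecreasing` attribute, a named logical over the statistic
#'   columns.
#' @export
temporal_report <- function(yearly) {
  if (length(yearly) < 2) stop("temporal report needs at least 2 years")
  rows <- do.call(rbind, lapply(names(yearly), function(y) {
    m <- yearly[[y]]
    data.frame(year = y, n_nodes = m$n_nodes, n_arcs = m$n_arcs,
               density = m$density,
               in_degree_centralization = m$in_degree_centralization,
               reciprocity = m$reciprocity, stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$year), , drop = FALSE]
  rownames(rows) <- NULL
  stat_cols <- c("n_nodes", "n_arcs", "density", "in_degree_centralization",
                 "reciprocity")
  attr(rows, "monotone_nondecreasing") <- vapply(
    stat_cols, function(cl) all(diff(rows[[cl]]) >= 0), logical(1))
  class(rows) <- c("temporal_report", "data.frame")
  rows
}

#' @export
print.temporal_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 3)
  mono <- attr(x, "monotone_nondecreasing")
  up <- names(mono)[mono]
  cat("non-decreasing over the period:",
      if (length(up)) paste(up, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
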