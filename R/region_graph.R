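# Region-level directed graph over a section: edges point from earlier to
# later median pseudotime between spatially adjacent regions, and planar
# trajectories are the simple root-to-sink paths of that DAG.

#' Infer the centre-to-centre grid spacing of a section
#'
#' @param section a [section_dataset].
#' @return the smallest non-zero spot-to-spot distance, micrometres.
#' @export
grid_spacing <- function(section) {
  xy <- as.matrix(section$spots[, c("x_um", "y_um")])
  n <- nrow(xy)
  take <- if (n > 600) sort(sample.int(n, 600)) else seq_len(n)
  d <- dist(xy[take, , drop = FALSE])
  min(d[d > 0])
}

#' Build the directed region graph of a section
#'
#' An edge A -> B is drawn iff (a) at least `min_adjacent` spot pairs lie
#' within `adjacency_radius_um` across the A/B border and (b) the median
#' pseudotime of B exceeds that of A by at least `min_delta` (strictly
#' positive; equal medians give no edge). Directions follow the median
#' ordering, so the graph is acyclic by construction; a defensive
#' cycle-breaking pass (dropping the smallest-delta edge on a cycle) is kept.
#'
#' @param section a [section_dataset].
#' @param pseudotime output of [compute_pseudotime()] for that section.
#' @param adjacency_radius_um radius defining spatial adjacency; default
#'   1.5 x the inferred grid spacing.
#' @param min_delta minimum median-pseudotime increase for an edge.
#' @param min_adjacent minimum adjacent spot pairs across the border.
#' @return object of class `region_graph`: list with `section_id`,
#'   `timepoint`, `z_um`, `nodes`, `edges` (tibble: from, to, n_adjacent,
#'   delta_pt), `medians` (named numeric) and `spots` (pseudotime tibble).
#' @export
build_region_graph <- function(section, pseudotime,
                               adjacency_radius_um = NULL,
                               min_delta = 0.05, min_adjacent = 1) {
  if (is.null(adjacency_radius_um)) {
    adjacency_radius_um <- 1.5 * grid_spacing(section)
  }
  spots <- section$spots |>
    left_join(pseudotime[, c("barcode", "pseudotime")], by = "barcode")
  regions <- sort(unique(spots$region))
  med <- vapply(regions, function(r) {
    v <- spots$pseudotime[spots$region == r]
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  }, numeric(1))

  edges <- list()
  for (i in seq_along(regions)) for (j in seq_along(regions)) {
    if (i >= j) next
    a <- regions[i]; b <- regions[j]
    if (is.na(med[a]) || is.na(med[b])) next
    npairs <- count_cross_pairs(
      as.matrix(spots[spots$region == a, c("x_um", "y_um")]),
      as.matrix(spots[spots$region == b, c("x_um", "y_um")]),
      adjacency_radius_um)
    if (npairs < min_adjacent) next
    delta <- med[b] - med[a]
    if (abs(delta) < min_delta || delta == 0) next
    edges[[length(edges) + 1L]] <- tibble(
      from = if (delta > 0) a else b, to = if (delta > 0) b else a,
      n_adjacent = npairs, delta_pt = abs(delta))
  }
  edges <- if (length(edges)) bind_rows(edges) else
    tibble(from = character(), to = character(),
           n_adjacent = integer(), delta_pt = numeric())

  # defensive: drop smallest-delta edge until acyclic (unreachable in
  # practice because directions follow a total order of medians)
  repeat {
    if (nrow(edges) == 0L) break
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       vertices = regions)
    if (igraph::is_dag(g)) break
    edges <- edges |> arrange(.data$delta_pt) |> dplyr::slice(-1)
  }

  structure(list(section_id = section$section_id,
                 timepoint = section$timepoint, z_um = section$z_um,
                 nodes = regions, edges = edges, medians = med,
                 spots = spots[, c("barcode", "region", "pseudotime")]),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat(sprintf("<region_graph> %s: %d regions, %d edges\n",
              x$section_id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Enumerate planar trajectories of a section
#'
#' Every simple path of the region DAG from the root region to a sink
#' (out-degree 0) is one planar trajectory; an isolated root yields the
#' single-region trajectory `[root]`.
#'
#' @param graph a [build_region_graph()] result.
#' @param root_region the root region label (must be a graph node).
#' @return list of `planar_trajectory` objects: each a list with
#'   `section_id`, `timepoint`, `z_um`, `chain` (character vector),
#'   `subtrajectories` (list of region pairs) and `spots` (pseudotime tibble
#'   restricted to chain regions).
#' @export
extract_planar_trajectories <- function(graph, root_region = "VL") {
  stopifnot(inherits(graph, "region_graph"))
  if (!root_region %in% graph$nodes) {
    abort(paste0("root region '", root_region, "' not in region graph of '",
                 graph$section_id, "'"))
  }
  g <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                     vertices = graph$nodes)
  if (!igraph::is_dag(g)) {
    abort("region graph contains a cycle; this should be unreachable")
  }
  sinks <- names(which(igraph::degree(g, mode = "out") == 0))
  reach <- names(igraph::subcomponent(g, root_region, mode = "out"))
  sinks <- intersect(sinks, reach)
  chains <- if (identical(sinks, root_region)) list(root_region) else {
    unlist(lapply(setdiff(sinks, root_region), function(s) {
      lapply(igraph::all_simple_paths(g, from = root_region, to = s,
                                      mode = "out"),
             function(p) names(p))
    }), recursive = FALSE)
  }
  if (length(chains) == 0L) chains <- list(root_region)
  map(chains, function(chain) {
    structure(list(
      section_id = graph$section_id, timepoint = graph$timepoint,
      z_um = graph$z_um, chain = chain,
      subtrajectories = if (length(chain) > 1L)
        map(seq_len(length(chain) - 1L), function(i) chain[i:(i + 1L)])
      else list(),
      spots = graph$spots |> filter(.data$region %in% chain)),
      class = "planar_trajectory")
  })
}

#' @export
print.planar_trajectory <- function(x, ...) {
  cat(sprintf("<planar_trajectory> %s (%s, z=%g): %s  [%d spots]\n",
              x$section_id, x$timepoint, x$z_um,
              chain_to_string(x$chain), nrow(x$spots)))
  invisible(x)
}
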