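# Diffusion pseudotime for one planar section: PCA of log-normalised counts,
# a k-nearest-neighbour graph with a self-tuning Gaussian kernel, diffusion
# components of the graph's Markov transition operator, and diffusion
# distance from a root-region medoid, min-max rescaled to [0, 1].

#' k-nearest-neighbour spot graph over expression PCA
#'
#' The graph that diffusion pseudotime runs on: spots are connected to their
#' `k_neighbors` nearest neighbours in the top `n_pcs` principal components
#' of log-normalised expression, with edges symmetrised (union).
#'
#' @param section a [section_dataset].
#' @param k_neighbors neighbours per spot.
#' @param n_pcs number of principal components (capped by data rank).
#' @return an undirected `igraph` with vertex names = barcodes, edge weights
#'   = Euclidean PCA distances; attributes `pca` (scores matrix) and
#'   `sigma` (per-spot distance to the k-th neighbour).
#' @export
spot_knn_graph <- function(section, k_neighbors = 15, n_pcs = 30) {
  x <- log_normalize(section$counts)
  keep <- which(apply(x, 2, sd) > 0)
  n <- nrow(x)
  k <- min(k_neighbors, n - 1L)
  if (length(keep) == 0L) {
    # no expression variance at all: empty graph, flagged degenerate
    g <- igraph::make_empty_graph(n, directed = FALSE)
    igraph::V(g)$name <- rownames(x)
    attr(g, "degenerate") <- TRUE
    return(g)
  }
  rank_max <- min(n - 1L, length(keep))
  pca <- prcomp(x[, keep, drop = FALSE], center = TRUE,
                rank. = min(n_pcs, rank_max))
  d <- as.matrix(dist(pca$x))
  nn <- t(apply(d, 1, function(row) order(row)[2:(k + 1L)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::V(g)$name <- rownames(x)
  igraph::E(g)$weight <- d[edges]
  attr(g, "pca") <- pca$x
  attr(g, "sigma") <- vapply(seq_len(n),
                             function(i) d[i, nn[i, k]], numeric(1))
  attr(g, "degenerate") <- max(d) == 0
  g
}

# medoid barcode of the root region in PCA space (tie -> first barcode)
root_medoid <- function(section, graph, root_region) {
  idx <- which(section$spots$region == root_region)
  pca <- attr(graph, "pca")
  if (is.null(pca) || length(idx) == 1L) return(section$spots$barcode[idx[1]])
  d <- as.matrix(dist(pca[idx, , drop = FALSE]))
  section$spots$barcode[idx[which.min(rowSums(d))]]
}

#' Diffusion pseudotime from a root region
#'
#' Computes diffusion components of the Markov transition operator on the
#' spot k-NN graph (self-tuning Gaussian kernel, bandwidth = distance to the
#' k-th neighbour) and takes each spot's pseudotime as its diffusion distance
#' from the root region's medoid spot, rescaled to `[0, 1]`. Spots in graph
#' components unreachable from the root get `NA` and are flagged, never
#' silently zeroed.
#'
#' @param section a [section_dataset].
#' @param root_region region label whose medoid anchors pseudotime 0.
#' @param k_neighbors neighbours for the spot graph.
#' @param n_pcs principal components for the spot graph.
#' @param n_dcs diffusion components used for the diffusion distance.
#' @return tibble with columns `barcode`, `region`, `pseudotime`, `reached`;
#'   attributes `degenerate` (logical: no usable expression structure, all
#'   pseudotimes 0), `root_barcode`, `n_unreached`.
#' @export
compute_pseudotime <- function(section, root_region = "VL",
                               k_neighbors = 15, n_pcs = 30, n_dcs = 10) {
  if (!root_region %in% section$spots$region) {
    abort(paste0("root region '", root_region, "' absent from section '",
                 section$section_id, "'"))
  }
  g <- spot_knn_graph(section, k_neighbors, n_pcs)
  n <- igraph::vcount(g)
  bc <- igraph::V(g)$name
  out <- tibble(barcode = bc, region = section$spots$region,
                pseudotime = 0, reached = TRUE)

  if (isTRUE(attr(g, "degenerate"))) {
    attr(out, "degenerate") <- TRUE
    attr(out, "root_barcode") <- NA_character_
    attr(out, "n_unreached") <- 0L
    return(out)
  }

  root_bc <- root_medoid(section, g, root_region)
  comp <- igraph::components(g)
  root_comp <- comp$membership[root_bc]
  reached <- comp$membership == root_comp
  pca <- attr(g, "pca")
  sigma <- attr(g, "sigma")
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1)

  idx <- which(reached)
  m <- length(idx)
  d2 <- as.matrix(dist(pca[idx, , drop = FALSE]))^2
  adj <- igraph::as_adjacency_matrix(
    igraph::induced_subgraph(g, idx), sparse = FALSE) > 0
  w <- exp(-d2 / outer(sigma[idx], sigma[idx])) * adj
  diag(w) <- 0
  deg <- rowSums(w)
  deg[deg == 0] <- 1
  s <- w / sqrt(outer(deg, deg))           # D^-1/2 W D^-1/2, symmetric
  eig <- eigen(s, symmetric = TRUE)
  n_use <- min(n_dcs, m - 1L)
  lambda <- eig$values[2:(n_use + 1L)]
  lambda <- pmin(lambda, 1 - 1e-10)
  psi <- eig$vectors[, 2:(n_use + 1L), drop = FALSE] / sqrt(deg)
  coords <- sweep(psi, 2, lambda / (1 - lambda), "*")

  root_i <- match(root_bc, bc[idx])
  dpt <- sqrt(rowSums(sweep(coords, 2, coords[root_i, ], "-")^2))
  rng <- range(dpt)
  degenerate <- !is.finite(diff(rng)) || diff(rng) < 1e-12
  pt <- if (degenerate) rep(0, m) else (dpt - rng[1]) / diff(rng)

  out$pseudotime <- NA_real_
  out$pseudotime[idx] <- pt
  out$reached <- reached
  attr(out, "degenerate") <- degenerate
  attr(out, "root_barcode") <- root_bc
  attr(out, "n_unreached") <- sum(!reached)
  out
}
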