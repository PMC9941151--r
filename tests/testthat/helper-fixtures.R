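# Fixtures are built in code: tiny hand-made sections for exact-rule tests,
# and small synthetic configs for statistical ones.

# a minimal valid section: spots on a line, two region bands, Poisson counts
tiny_section <- function(n_spots = 20, n_genes = 10, regions = NULL,
                         section_id = "s1", timepoint = "d3", z_um = 0,
                         seed = 1) {
  set.seed(seed)
  barcodes <- sprintf("bc%02d", seq_len(n_spots))
  genes <- sprintf("g%02d", seq_len(n_genes))
  counts <- matrix(rpois(n_spots * n_genes, 5), nrow = n_spots,
                   dimnames = list(barcodes, genes))
  coords <- tibble::tibble(barcode = barcodes,
                           x_um = (seq_len(n_spots) - 1) * 100, y_um = 0)
  if (is.null(regions)) {
    regions <- rep(c("VL", "A"), c(ceiling(n_spots / 2), floor(n_spots / 2)))
  }
  section_dataset(counts, coords,
                  tibble::tibble(barcode = barcodes, region = regions),
                  section_id = section_id, timepoint = timepoint, z_um = z_um)
}

# 1D band section with a strong smooth expression gradient along x
band_section <- function(n_spots = 60, n_genes = 24, seed = 1) {
  set.seed(seed)
  barcodes <- sprintf("bc%02d", seq_len(n_spots))
  genes <- sprintf("g%02d", seq_len(n_genes))
  pt <- (seq_len(n_spots) - 1) / (n_spots - 1)
  sign <- rep(c(1, -1), length.out = n_genes)
  mu <- exp(1 + outer(pt - 0.5, sign * 2))
  counts <- matrix(rpois(length(mu), mu), nrow = n_spots,
                   dimnames = list(barcodes, genes))
  coords <- tibble::tibble(barcode = barcodes,
                           x_um = (seq_len(n_spots) - 1) * 100, y_um = 0)
  regions <- rep(c("VL", "A"), c(10, n_spots - 10))
  section_dataset(counts, coords,
                  tibble::tibble(barcode = barcodes, region = regions),
                  section_id = "band", timepoint = "d3", z_um = 0)
}

# build a transition_genes object directly from gene/rho vectors
make_tg <- function(genes, rhos, sub = "A>B", tp = "d3", sid = "s1", K = 30) {
  scores <- tibble::tibble(gene = genes, rho = rhos)
  up <- scores[scores$rho > 0, ]
  up <- head(up[order(-up$rho, up$gene), ], K)
  down <- scores[scores$rho < 0, ]
  down <- head(down[order(down$rho, down$gene), ], K)
  trajspace:::new_transition_genes(scores, up, down, K, sub, tp, sid)
}

# build a planar_trajectory directly from a chain
make_planar <- function(chain, sid, tp = "d3", z = 0) {
  structure(list(section_id = sid, timepoint = tp, z_um = z,
                 chain = chain,
                 subtrajectories = chain_subtrajectories(chain),
                 spots = tibble::tibble(barcode = character(),
                                        region = character(),
                                        pseudotime = numeric())),
            class = "planar_trajectory")
}

# build a region_graph directly from an edge table
make_region_graph <- function(nodes, edges, sid = "s1", tp = "d3") {
  structure(list(section_id = sid, timepoint = tp, z_um = 0,
                 nodes = nodes, edges = edges,
                 medians = setNames(rep(NA_real_, length(nodes)), nodes),
                 spots = tibble::tibble(barcode = character(),
                                        region = character(),
                                        pseudotime = numeric())),
            class = "region_graph")
}

# independent brute-force oracle for the 3D union: explicit loops, explicit
# max-|rho| conflict resolution (positive wins exact ties), re-truncation
brute_force_union <- function(sets, K) {
  pool <- list()
  for (s in sets) {
    tab <- rbind(as.data.frame(s$up), as.data.frame(s$down))
    for (i in seq_len(nrow(tab))) pool[[length(pool) + 1L]] <- tab[i, ]
  }
  pool <- do.call(rbind, pool)
  genes <- sort(unique(pool$gene))
  best <- numeric(0)
  for (g in genes) {
    vals <- pool$rho[pool$gene == g]
    mx <- max(abs(vals))
    cand <- vals[abs(vals) == mx]
    best[g] <- if (any(cand > 0)) mx else -mx
  }
  df <- data.frame(gene = names(best), rho = unname(best),
                   stringsAsFactors = FALSE)
  up <- df[df$rho > 0, ]
  up <- head(up[order(-up$rho, up$gene), ], K)
  down <- df[df$rho < 0, ]
  down <- head(down[order(down$rho, down$gene), ], K)
  list(up = up, down = down)
}

# textbook tie-corrected Kruskal-Wallis H, written from the formula
kw_reference_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  groups <- as.factor(groups)
  rsum <- tapply(r, groups, sum)
  nj <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / nj) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# random subtype profile over a small gene universe (0 = absent)
random_profile <- function(universe, assignment, id = "p") {
  present <- assignment != 0
  if (!any(present)) return(NULL)
  subtype_profile(universe[present], assignment[present],
                  trajectory_id = id)
}
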