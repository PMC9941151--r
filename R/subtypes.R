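# Cell-subtype profiles (signed marker sets per trajectory and time point),
# sign-aware similarity across time points, hypergeometric matching against
# a local cell-type marker database, and mutual-pathway-set similarity.

#' Build a cell-subtype profile from a trajectory's 3D transition sets
#'
#' The profile of a trajectory at a time point is the union, over the
#' trajectory's subtrajectories, of the 3D up (+) and down (-) transition
#' genes. A gene appearing with conflicting signs in different
#' subtrajectories keeps the sign of the score with greatest absolute value
#' (same conflict rule as [union_3d()]).
#'
#' @param transition_sets list of `transition_genes` objects (typically the
#'   3D sets of each subtrajectory) sharing one time point.
#' @param trajectory_id identifier for the trajectory (e.g. its chain
#'   string).
#' @param timepoint time point label; defaults to the sets' common one.
#' @return object of class `subtype_profile`: tibble with columns `gene`,
#'   `sign` (+1/-1), `score`; attributes `trajectory_id`, `timepoint`.
#' @export
build_subtype_profile <- function(transition_sets, trajectory_id,
                                  timepoint = NULL) {
  if (length(transition_sets) == 0L) abort("no transition sets supplied")
  stopifnot(all(vapply(transition_sets, inherits, logical(1),
                       "transition_genes")))
  timepoint <- timepoint %||% unique(map_chr(transition_sets, "timepoint"))[1]
  pooled <- purrr::map_dfr(transition_sets,
                           function(s) bind_rows(s$up, s$down))
  if (nrow(pooled) == 0L) abort("transition sets contain no marker genes")
  prof <- pooled |>
    arrange(desc(abs(.data$rho)), desc(.data$rho), .data$gene) |>
    distinct(.data$gene, .keep_all = TRUE) |>
    mutate(sign = ifelse(.data$rho > 0, 1L, -1L), score = .data$rho) |>
    select("gene", "sign", "score") |>
    arrange(.data$gene)
  structure(prof, class = c("subtype_profile", class(prof)),
            trajectory_id = trajectory_id, timepoint = timepoint)
}

#' Construct a subtype profile directly from signed markers
#'
#' @param genes character vector of marker genes.
#' @param signs +1/-1 per gene.
#' @param scores optional signed scores (default = signs).
#' @param trajectory_id,timepoint identifiers.
#' @return a `subtype_profile`; see [build_subtype_profile()].
#' @export
subtype_profile <- function(genes, signs, scores = NULL,
                            trajectory_id = "trajectory",
                            timepoint = "unspecified") {
  stopifnot(length(genes) == length(signs), all(signs %in% c(-1L, 1L)))
  if (anyDuplicated(genes)) abort("one sign per gene: duplicated genes")
  if (length(genes) == 0L) abort("markers must be non-empty")
  prof <- tibble(gene = genes, sign = as.integer(signs),
                 score = scores %||% as.numeric(signs)) |>
    arrange(.data$gene)
  structure(prof, class = c("subtype_profile", class(prof)),
            trajectory_id = trajectory_id, timepoint = timepoint)
}

#' Sign-aware similarity between two subtype profiles
#'
#' The number of genes shared with equal sign divided by the size of the
#' union of the two marker gene sets (a sign-aware Jaccard index):
#' symmetric, in `[0, 1]`, 1 iff the profiles are identical in genes and
#' signs, 0 iff the gene sets are disjoint or every shared gene disagrees
#' in sign.
#'
#' @param profile_a,profile_b `subtype_profile` objects.
#' @return a single number in `[0, 1]`.
#' @export
subtype_similarity <- function(profile_a, profile_b) {
  if (nrow(profile_a) == 0L || nrow(profile_b) == 0L) {
    abort("profiles must be non-empty")
  }
  union_genes <- union(profile_a$gene, profile_b$gene)
  shared <- intersect(profile_a$gene, profile_b$gene)
  agree <- sum(profile_a$sign[match(shared, profile_a$gene)] ==
                 profile_b$sign[match(shared, profile_b$gene)])
  agree / length(union_genes)
}

#' Match a subtype profile to cell types in a marker database
#'
#' Each cell type is scored by hypergeometric enrichment (upper tail) of the
#' profile's genes, sign ignored, in the cell type's marker set against a
#' gene universe. Symbols are matched case-insensitively. Ties in p-value
#' break by larger overlap, then lexicographic cell type.
#'
#' @param profile a `subtype_profile`.
#' @param marker_db named list (cell type -> marker genes), e.g. from
#'   [load_marker_db()].
#' @param top_n number of top-ranked cell types returned (default 5).
#' @param universe gene universe; defaults to the union of all database
#'   marker genes and the profile's genes.
#' @return tibble: `cell_type`, `overlap`, `n_markers`, `p_value`, `rank`,
#'   top `top_n` rows by rank.
#' @export
match_cell_types <- function(profile, marker_db, top_n = 5, universe = NULL) {
  if (length(marker_db) == 0L) abort("empty marker database")
  db <- map(marker_db, toupper)
  prof_genes <- toupper(profile$gene)
  universe <- toupper(universe %||% union(unlist(db, use.names = FALSE),
                                          prof_genes))
  n_univ <- length(unique(universe))
  prof_in <- intersect(unique(prof_genes), universe)
  scored <- purrr::imap_dfr(db, function(genes, ct) {
    m <- length(intersect(unique(genes), universe))
    k <- length(intersect(unique(genes), prof_in))
    tibble(cell_type = ct, overlap = k, n_markers = m,
           p_value = phyper(k - 1, m, n_univ - m, length(prof_in),
                            lower.tail = FALSE))
  })
  scored |>
    arrange(.data$p_value, desc(.data$overlap), .data$cell_type) |>
    mutate(rank = row_number()) |>
    head(top_n)
}

#' Union of matched cell types across time points
#'
#' @param matches list of tibbles from [match_cell_types()] (one per time
#'   point of the same trajectory).
#' @return sorted character vector of the distinct matched cell types.
#' @export
cell_type_union <- function(matches) {
  sort(unique(unlist(map(matches, "cell_type"), use.names = FALSE)))
}

#' Mutual pathway set and overlap-coefficient similarity
#'
#' `P_inter` is the intersection of the pathway set of the identified
#' subtype (`p_a`) and that of its similar cell types (`p_b`); similarity is
#' the overlap coefficient `|P_inter| / min(|P_A|, |P_B|)`, defined as 0
#' when either set is empty.
#'
#' @param p_a,p_b character vectors of pathway IDs.
#' @return object of class `pathway_sets`: list with `p_a`, `p_b`,
#'   `p_inter`, `n_a`, `n_b`, `n_inter`, `similarity`.
#' @export
pathway_set_similarity <- function(p_a, p_b) {
  p_a <- unique(trimws(as.character(p_a)))
  p_b <- unique(trimws(as.character(p_b)))
  p_a <- p_a[nzchar(p_a)]
  p_b <- p_b[nzchar(p_b)]
  p_inter <- intersect(p_a, p_b)
  sim <- if (length(p_a) == 0L || length(p_b) == 0L) 0 else
    length(p_inter) / min(length(p_a), length(p_b))
  structure(list(p_a = p_a, p_b = p_b, p_inter = p_inter,
                 n_a = length(p_a), n_b = length(p_b),
                 n_inter = length(p_inter), similarity = sim),
            class = "pathway_sets")
}

#' @export
print.pathway_sets <- function(x, ...) {
  cat(sprintf("<pathway_sets> |P_A|=%d |P_B|=%d |P_inter|=%d similarity=%.3f\n",
              x$n_a, x$n_b, x$n_inter, x$similarity))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.pathway_sets <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b, n_inter = x$n_inter,
         similarity = x$similarity)
}
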