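# Transition genes: Spearman correlation of each gene's log-normalised
# expression with pseudotime over the spots of one subtrajectory's region
# pair, top-K per direction, and the cross-section union with the signed
# max-absolute-value conflict rule.

new_transition_genes <- function(scores, up, down, K, subtrajectory,
                                 timepoint, section_id) {
  structure(list(scores = scores, up = up, down = down, K = K,
                 subtrajectory = subtrajectory, timepoint = timepoint,
                 section_id = section_id),
            class = "transition_genes")
}

#' @export
print.transition_genes <- function(x, ...) {
  cat(sprintf("<transition_genes> %s @ %s (%s): %d up, %d down (K=%d)\n",
              x$subtrajectory, x$timepoint, x$section_id,
              nrow(x$up), nrow(x$down), x$K))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.transition_genes <- function(x, ...) {
  bind_rows(x$up |> mutate(direction = "up"),
            x$down |> mutate(direction = "down")) |>
    mutate(subtrajectory = x$subtrajectory, timepoint = x$timepoint,
           section_id = x$section_id) |>
    select("subtrajectory", "timepoint", "section_id",
           "gene", "rho", "direction")
}

#' Rank transition genes along one subtrajectory
#'
#' Spearman correlation of each gene's log-normalised expression with
#' pseudotime over the spots of the subtrajectory's two regions. The top `K`
#' positively correlated genes form the up list, the top `K` negative the
#' down list; zero-variance genes are excluded; ties in |rho| break
#' lexicographically by gene ID.
#'
#' @param section a [section_dataset].
#' @param pseudotime output of [compute_pseudotime()] for that section.
#' @param subtrajectory length-2 character vector of region labels.
#' @param K list size per direction (default 30).
#' @param min_spots minimum spots required across the two regions.
#' @return a `transition_genes` object: full signed `scores` (tibble gene,
#'   rho) plus `up` and `down` top-K tibbles.
#' @export
rank_transition_genes <- function(section, pseudotime, subtrajectory,
                                  K = 30, min_spots = 10) {
  if (length(subtrajectory) != 2L) {
    abort("`subtrajectory` must be a pair of region labels")
  }
  spots <- section$spots |>
    left_join(pseudotime[, c("barcode", "pseudotime")], by = "barcode") |>
    filter(.data$region %in% subtrajectory, !is.na(.data$pseudotime))
  if (nrow(spots) < min_spots) {
    abort(sprintf("subtrajectory %s has %d spots (< min_spots = %d)",
                  chain_to_string(subtrajectory), nrow(spots), min_spots))
  }
  x <- log_normalize(section$counts)[spots$barcode, , drop = FALSE]
  v <- apply(x, 2, function(col) length(unique(col)) > 1L)
  if (!any(v)) abort("all genes have zero variance over the subtrajectory spots")
  rho <- suppressWarnings(
    cor(x[, v, drop = FALSE], spots$pseudotime, method = "spearman"))[, 1]
  scores <- tibble(gene = names(rho), rho = unname(rho)) |>
    filter(is.finite(.data$rho)) |>
    arrange(.data$gene)
  up <- scores |> filter(.data$rho > 0) |>
    arrange(desc(.data$rho), .data$gene) |> head(K)
  down <- scores |> filter(.data$rho < 0) |>
    arrange(.data$rho, .data$gene) |> head(K)
  new_transition_genes(scores, up, down, K,
                       subtrajectory = chain_to_string(subtrajectory),
                       timepoint = section$timepoint,
                       section_id = section$section_id)
}

#' Union planar transition-gene sets into a 3D set
#'
#' Pools the per-section top-K up and down lists of the same subtrajectory
#' and time point. A gene seen in several sections keeps the signed score of
#' greatest absolute value (the conflict rule for genes that are up in one
#' section and down in another; an exact |rho| tie keeps the positive
#' score). The merged lists are re-truncated to the top K per direction
#' by |rho|.
#'
#' @param sets list of `transition_genes` objects for the same
#'   subtrajectory and time point.
#' @param K merged list size per direction; defaults to the largest input K.
#' @return a `transition_genes` object with `section_id = "3D"`.
#' @export
union_3d <- function(sets, K = NULL) {
  if (length(sets) == 0L) abort("no transition-gene sets supplied")
  stopifnot(all(vapply(sets, inherits, logical(1), "transition_genes")))
  subs <- unique(map_chr(sets, "subtrajectory"))
  tps <- unique(map_chr(sets, "timepoint"))
  if (length(subs) > 1L) {
    abort(paste0("cannot union mixed subtrajectories: ",
                 paste(subs, collapse = " vs ")))
  }
  if (length(tps) > 1L) {
    abort(paste0("cannot union mixed timepoints: ",
                 paste(tps, collapse = " vs ")))
  }
  K <- K %||% max(map_int(sets, "K"))
  pooled <- purrr::map_dfr(sets, function(s) bind_rows(s$up, s$down))
  merged <- pooled |>
    arrange(desc(abs(.data$rho)), desc(.data$rho), .data$gene) |>
    distinct(.data$gene, .keep_all = TRUE)
  up <- merged |> filter(.data$rho > 0) |>
    arrange(desc(.data$rho), .data$gene) |> head(K)
  down <- merged |> filter(.data$rho < 0) |>
    arrange(.data$rho, .data$gene) |> head(K)
  new_transition_genes(merged |> arrange(.data$gene), up, down, K,
                       subtrajectory = subs, timepoint = tps,
                       section_id = "3D")
}
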