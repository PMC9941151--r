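# Merge planar trajectories from serial sections of the same time point into
# 3D global pseudospace-time trajectories, count supporting sections, filter
# by support, and classify trajectory bundles by their terminal region class.

#' Default region classes for bundle classification
#'
#' Bundle I ends in the hippocampus with no integrator region on the way;
#' bundle II passes a thalamic/hypothalamic integrator before ending in the
#' hippocampus; bundle III ends in the cortex. `transit` regions (root,
#' white-matter tracts) are allowed anywhere without affecting the label.
#'
#' @return named list of character vectors (`hippocampal`, `integrator`,
#'   `cortical`, `transit`), user-editable.
#' @export
bundle_rules <- function() {
  list(hippocampal = c("CA1", "CA3", "DG"),
       integrator = c("TH", "HY", "HYL", "MB"),
       cortical = c("I", "II", "III", "IV", "V", "VIa", "VIb",
                    "RSP", "PIR", "CTXsp", "COA"),
       transit = c("VL", "fxs", "cpd"))
}

#' Classify a trajectory chain into a bundle
#'
#' @param chain character vector of region labels, root first.
#' @param rules region classes as from [bundle_rules()].
#' @return `"I"`, `"II"`, `"III"` or `"unclassified"` (with a warning when
#'   the chain contains a region not in any class).
#' @export
classify_bundle <- function(chain, rules = bundle_rules()) {
  known <- unlist(rules, use.names = FALSE)
  unknown <- setdiff(chain, known)
  if (length(unknown) > 0L) {
    warn(paste0("unknown region(s) in chain: ", paste(unknown, collapse = ", ")))
    return("unclassified")
  }
  terminal <- chain[length(chain)]
  if (terminal %in% rules$hippocampal) {
    if (any(chain %in% rules$integrator)) "II" else "I"
  } else if (terminal %in% rules$cortical) {
    "III"
  } else {
    "unclassified"
  }
}

# prefix-preserving subsequence: same first region, order preserved
chain_mergeable <- function(short, long) {
  length(short) <= length(long) && short[1] == long[1] &&
    is_subsequence(short, long)
}

#' Reconstruct 3D global pseudospace-time trajectories
#'
#' Planar trajectories from different sections of the same time point are
#' merged when their region chains are identical (`merge_mode = "exact"`) or
#' when one is a prefix-preserving subsequence of the other, the merged chain
#' being the longer (`merge_mode = "subsequence"`, default). In subsequence
#' mode the merged (maximal) chains are those not contained in any other
#' observed chain, and each maximal chain is supported by every section whose
#' chain it contains; chains that are not subsequence-related are never
#' force-merged and remain separate. Support is the number of distinct
#' supporting sections; trajectories under `min_support` are dropped.
#'
#' @param planar list of `planar_trajectory` objects (any mix of time
#'   points; merging happens within a time point).
#' @param min_support minimum number of distinct supporting sections.
#' @param merge_mode `"subsequence"` (default) or `"exact"`.
#' @param rules bundle-classification region classes ([bundle_rules()]).
#' @return tibble of class `trajectory3d_set`, sorted by (support desc,
#'   chain lexicographic) within time point: columns `timepoint`,
#'   `chain` (list), `chain_str`, `support`, `sections` (list of tibbles
#'   with section_id, z_um), `bundle`.
#' @export
reconstruct_3d <- function(planar, min_support = 2,
                           merge_mode = c("subsequence", "exact"),
                           rules = bundle_rules()) {
  merge_mode <- match.arg(merge_mode)
  if (length(planar) == 0L) abort("no planar trajectories supplied")
  tab <- purrr::map_dfr(planar, function(p) {
    tibble(timepoint = p$timepoint, section_id = p$section_id,
           z_um = p$z_um, chain_str = chain_to_string(p$chain))
  }) |> distinct()

  out <- tab |> group_by(.data$timepoint) |>
    dplyr::group_modify(function(df, key) {
      uniq <- unique(df$chain_str)
      chains <- map(uniq, string_to_chain)
      if (merge_mode == "exact") {
        keep <- seq_along(uniq)
        supports <- map(seq_along(uniq), function(i) {
          df[df$chain_str == uniq[i], c("section_id", "z_um")] |>
            distinct() |> arrange(.data$section_id)
        })
      } else {
        maximal <- vapply(seq_along(chains), function(i) {
          !any(vapply(seq_along(chains), function(j) {
            i != j && chain_mergeable(chains[[i]], chains[[j]]) &&
              !identical(chains[[i]], chains[[j]])
          }, logical(1)))
        }, logical(1))
        keep <- which(maximal)
        supports <- map(keep, function(i) {
          consistent <- uniq[vapply(chains, chain_mergeable,
                                    logical(1), long = chains[[i]])]
          df[df$chain_str %in% consistent, c("section_id", "z_um")] |>
            distinct() |> arrange(.data$section_id)
        })
      }
      tibble(chain_str = uniq[keep],
             chain = chains[keep],
             sections = supports,
             support = map_int(supports,
                               ~ dplyr::n_distinct(.x$section_id)))
    }) |> ungroup() |>
    filter(.data$support >= min_support) |>
    mutate(bundle = map_chr(.data$chain, classify_bundle, rules = rules)) |>
    arrange(.data$timepoint, desc(.data$support), .data$chain_str) |>
    select("timepoint", "chain", "chain_str", "support", "sections", "bundle")
  class(out) <- c("trajectory3d_set", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.trajectory3d_set <- function(x, ...) {
  as_tibble(x) |>
    mutate(n_regions = lengths(.data$chain)) |>
    select("timepoint", "chain_str", "support", "bundle", "n_regions")
}

#' Subtrajectories (consecutive region pairs) of a chain
#'
#' @param chain character vector of region labels.
#' @return list of length-2 character vectors; empty for single-region chains.
#' @export
chain_subtrajectories <- function(chain) {
  if (length(chain) < 2L) return(list())
  map(seq_len(length(chain) - 1L), function(i) chain[i:(i + 1L)])
}
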