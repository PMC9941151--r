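# End-to-end orchestration: one validated config drives trajectories ->
# transition genes -> subtypes -> communication -> pathways, writing tidy
# TSV tables and a machine-readable JSON run report.

#' Validated pipeline configuration
#'
#' @param manifest path to the section manifest JSON.
#' @param lr_db path to the CellTalkDB-style LR pair TSV.
#' @param out_dir output directory for all tables and the run report.
#' @param marker_db optional path to a cell-type marker TSV.
#' @param pathway_a,pathway_b optional pathway-set files (identified subtype
#'   and similar cell types, respectively).
#' @param root_region trajectory root region.
#' @param k_neighbors,n_pcs spot-graph parameters for pseudotime.
#' @param min_delta,min_adjacent region-graph edge thresholds.
#' @param top_k transition genes per direction.
#' @param min_support,merge_mode 3D reconstruction parameters.
#' @param z_star,n_perm,neighbor_radius communication parameters.
#' @param top_n_celltypes matched cell types per profile.
#' @param gene_universe `"intersection"` or `"union"`.
#' @param seed master seed; all stage seeds derive from it.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(manifest, lr_db, out_dir,
                       marker_db = NULL, pathway_a = NULL, pathway_b = NULL,
                       root_region = "VL", k_neighbors = 15, n_pcs = 30,
                       min_delta = 0.05, min_adjacent = 1, top_k = 30,
                       min_support = 2, merge_mode = "subsequence",
                       z_star = 1.96, n_perm = 200, neighbor_radius = NULL,
                       top_n_celltypes = 5,
                       gene_universe = "intersection", seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("manifest", "lr_db", "marker_db", "pathway_a", "pathway_b")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("config file for `", f, "` not found: ", p))
    }
  }
  structure(cfg, class = "run_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Stages: (1) trajectories - per-section pseudotime, region graphs, planar
#' trajectories, 3D reconstruction and bundle classification; (2) transition
#' genes - per-section Spearman ranking and 3D union per subtrajectory;
#' (3) subtypes - profiles per (trajectory, time point), sign-aware
#' similarities across time points, optional cell-type matching; (4)
#' communication - LR density per (trajectory, time point) and the
#' Kruskal-Wallis comparison; (5) pathways - mutual-pathway similarity when
#' both pathway files are supplied. Writes one TSV per output table plus
#' `report.json`; the run is deterministic given the config and seed.
#'
#' @param config a [run_config()].
#' @return invisibly, the report as a list (also written to
#'   `out_dir/report.json`).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config[setdiff(names(config), "")],
                 package_version = as.character(utils::packageVersion("trajspace")),
                 seed = config$seed, stages = list())
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(config$out_dir, name))
    nrow(x)
  }

  # stage 1: trajectories
  dataset <- stage_try("load", load_multisection(config$manifest,
                                                 config$gene_universe))
  lr_pairs <- stage_try("load", load_lr_database(config$lr_db))
  planar <- list(); pt_rows <- list()
  stage_try("trajectories", {
    for (sec in dataset$sections) {
      pt <- compute_pseudotime(sec, config$root_region,
                               config$k_neighbors, config$n_pcs)
      pt_rows[[sec$section_id]] <- pt |>
        mutate(section_id = sec$section_id, timepoint = sec$timepoint)
      rg <- build_region_graph(sec, pt, config$neighbor_radius,
                               config$min_delta, config$min_adjacent)
      planar <- c(planar, extract_planar_trajectories(rg, config$root_region))
    }
  })
  pseudotime_tbl <- bind_rows(pt_rows) |>
    select("section_id", "timepoint", "barcode", "region",
           "pseudotime", "reached")
  traj3d <- stage_try("trajectories",
                      reconstruct_3d(planar, config$min_support,
                                     config$merge_mode))
  n1 <- tsv(pseudotime_tbl, "pseudotime.tsv")
  n2 <- tsv(tidy(traj3d), "trajectories.tsv")
  report$stages$trajectories <- list(
    status = "completed", n_sections = length(dataset$sections),
    n_planar = length(planar), n_trajectories_3d = nrow(traj3d),
    rows = c(pseudotime = n1, trajectories = n2))

  # stage 2: transition genes (3D union per subtrajectory and time point)
  sets_3d <- list()
  tg_rows <- list()
  stage_try("transition_genes", {
    for (ti in seq_len(nrow(traj3d))) {
      tp <- traj3d$timepoint[ti]
      for (sub in chain_subtrajectories(traj3d$chain[[ti]])) {
        key <- paste(tp, chain_to_string(sub), sep = "|")
        if (!is.null(sets_3d[[key]])) next
        sec_ids <- traj3d$sections[[ti]]$section_id
        per_sec <- list()
        for (sid in sec_ids) {
          sec <- dataset$sections[[sid]]
          pt <- pt_rows[[sid]]
          ts <- tryCatch(
            rank_transition_genes(sec, pt, sub, K = config$top_k),
            error = function(e) NULL)
          if (!is.null(ts)) per_sec[[sid]] <- ts
        }
        if (length(per_sec) == 0L) next
        sets_3d[[key]] <- union_3d(per_sec, K = config$top_k)
        tg_rows[[key]] <- tidy(sets_3d[[key]])
      }
    }
  })
  tg_tbl <- if (length(tg_rows)) bind_rows(tg_rows) else
    tibble(subtrajectory = character(), timepoint = character(),
           section_id = character(), gene = character(),
           rho = numeric(), direction = character())
  n3 <- tsv(tg_tbl, "transition_genes.tsv")
  report$stages$transition_genes <- list(
    status = "completed", n_sets_3d = length(sets_3d),
    rows = c(transition_genes = n3))

  # stage 3: subtype profiles, similarities, cell-type matches
  profiles <- list(); prof_rows <- list(); sim_rows <- list()
  match_rows <- list()
  marker_db <- if (!is.null(config$marker_db))
    stage_try("subtypes", load_marker_db(config$marker_db)) else NULL
  stage_try("subtypes", {
    for (ti in seq_len(nrow(traj3d))) {
      tp <- traj3d$timepoint[ti]
      tid <- traj3d$chain_str[ti]
      keys <- paste(tp, map_chr(chain_subtrajectories(traj3d$chain[[ti]]),
                                chain_to_string), sep = "|")
      sets <- purrr::compact(sets_3d[keys])
      if (length(sets) == 0L) next
      prof <- build_subtype_profile(sets, trajectory_id = tid,
                                    timepoint = tp)
      profiles[[paste(tid, tp, sep = "|")]] <- prof
      prof_rows[[paste(tid, tp, sep = "|")]] <- prof |>
        as_tibble() |> mutate(trajectory_id = tid, timepoint = tp)
      if (!is.null(marker_db)) {
        match_rows[[paste(tid, tp, sep = "|")]] <-
          match_cell_types(prof, marker_db, config$top_n_celltypes) |>
          mutate(trajectory_id = tid, timepoint = tp)
      }
    }
    keys <- names(profiles) %||% character()
    tids <- vapply(strsplit(keys, "|", fixed = TRUE), `[`, "", 1)
    for (tid in unique(tids)) {
      ks <- keys[tids == tid]
      if (length(ks) < 2L) next
      for (i in seq_along(ks)) for (j in seq_along(ks)) {
        if (i >= j) next
        sim_rows[[paste(ks[i], ks[j])]] <- tibble(
          trajectory_id = tid,
          timepoint_a = attr(profiles[[ks[i]]], "timepoint"),
          timepoint_b = attr(profiles[[ks[j]]], "timepoint"),
          similarity = subtype_similarity(profiles[[ks[i]]],
                                          profiles[[ks[j]]]))
      }
    }
  })
  n4 <- tsv(if (length(prof_rows)) bind_rows(prof_rows) else
    tibble(gene = character(), sign = integer(), score = numeric(),
           trajectory_id = character(), timepoint = character()),
    "subtype_profiles.tsv")
  n5 <- tsv(if (length(sim_rows)) bind_rows(sim_rows) else
    tibble(trajectory_id = character(), timepoint_a = character(),
           timepoint_b = character(), similarity = numeric()),
    "subtype_similarity.tsv")
  n6 <- tsv(if (length(match_rows)) bind_rows(match_rows) else
    tibble(cell_type = character(), overlap = integer(),
           n_markers = integer(), p_value = numeric(), rank = integer(),
           trajectory_id = character(), timepoint = character()),
    "cell_type_matches.tsv")
  report$stages$subtypes <- list(
    status = "completed", n_profiles = length(profiles),
    rows = c(profiles = n4, similarities = n5, cell_type_matches = n6))

  # stage 4: communication density + Kruskal-Wallis across time points
  dens_rows <- list(); spot_rows <- list(); test_rows <- list()
  stage_try("communication", {
    for (tid in unique(traj3d$chain_str)) {
      chain <- traj3d$chain[[match(tid, traj3d$chain_str)]]
      cd <- communication_density(
        dataset, chain, lr_pairs, trajectory_id = tid,
        n_perm = config$n_perm, seed = config$seed,
        z_star = config$z_star, neighbor_radius = config$neighbor_radius)
      dens_rows[[tid]] <- cd$density
      spot_rows[[tid]] <- cd$spots |> mutate(trajectory_id = tid)
      if (length(unique(cd$density$timepoint)) >= 2L) {
        test_rows[[tid]] <- as_tibble(compare_densities(cd$density)) |>
          mutate(trajectory_id = tid)
      }
    }
  })
  n7 <- tsv(if (length(dens_rows)) bind_rows(dens_rows) else
    tibble(trajectory_id = character(), timepoint = character(),
           pair_id = character(), n_spots = integer(),
           zt_total = integer(), density = numeric()),
    "communication_density.tsv")
  n8 <- tsv(if (length(spot_rows)) bind_rows(spot_rows) else
    tibble(barcode = character()), "communication_spots.tsv")
  n9 <- tsv(if (length(test_rows)) bind_rows(test_rows) else
    tibble(trajectory_id = character(), n_groups = integer(),
           statistic = numeric(), df = integer(), p_value = numeric()),
    "density_tests.tsv")
  report$stages$communication <- list(
    status = "completed", n_trajectories = length(dens_rows),
    rows = c(density = n7, spots = n8, tests = n9))

  # stage 5: pathway similarity
  if (!is.null(config$pathway_a) && !is.null(config$pathway_b)) {
    ps <- stage_try("pathways", pathway_set_similarity(
      load_pathway_sets(config$pathway_a),
      load_pathway_sets(config$pathway_b)))
    n10 <- tsv(glance(ps), "pathway_similarity.tsv")
    report$stages$pathways <- list(status = "completed",
                                   rows = c(pathway_similarity = n10))
  } else {
    report$stages$pathways <- list(status = "skipped",
                                   reason = "no pathway sets supplied")
  }

  report$n_completed_stages <- sum(vapply(report$stages, function(s)
    identical(s$status, "completed"), logical(1)))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}

#' Write a synthetic dataset to disk (simulate command)
#'
#' Thin wrapper over [write_synthetic_dataset()] for the command-line
#' `simulate` subcommand.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
simulate_command <- function(config, dir) write_synthetic_dataset(config, dir)
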