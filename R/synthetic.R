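# Synthetic multi-section Visium-like data with planted structure: region
# bands ordered along a spatial axis, a pseudotime gradient along the planted
# region chain, signed monotone transition genes per subtrajectory, and
# spatially contiguous ligand-receptor co-expression hotspots whose intensity
# varies by time point. Every planted fact is returned as ground truth.

#' Configuration for the synthetic multi-section generator
#'
#' Defaults emulate a small serial-section study: three 20 x 20-spot sections
#' per time point at 100 um spacing, a four-region band layout crossed by the
#' planted chain VL -> A -> B -> C, 2000 background genes, 10 up- and 10
#' downregulated transition genes per subtrajectory with log-scale slope
#' `effect_size`, negative-binomial counts, and contiguous LR hotspots in
#' region "A" whose intensity is multiplied per time point (sham 1, d3 5,
#' d7 1 - a rise-then-fall contrast across time).
#'
#' @param n_sections_per_timepoint sections per time point (stacked at
#'   `section_interval_um` spacing).
#' @param spots_per_section spots per section, laid on a square grid.
#' @param grid_spacing_um centre-to-centre spot spacing, micrometres.
#' @param region_layout region labels as ordered spatial bands, root first.
#' @param planted_chain the true region chain (subset of `region_layout`).
#' @param n_genes number of background genes (LR genes are appended).
#' @param n_transition_up,n_transition_down planted monotone genes per
#'   subtrajectory and direction.
#' @param effect_size log-scale expression slope along local pseudotime
#'   (> 0; the down direction uses its negation).
#' @param n_gradient_genes genes monotone in true pseudotime across the
#'   whole planted chain (half up, half down): the smooth expression
#'   manifold that makes diffusion pseudotime recoverable, as in real
#'   tissue where expression drifts continuously along a propagation path.
#' @param gradient_effect log-scale slope of the gradient genes.
#' @param n_region_markers marker genes elevated in each region (region
#'   identity, emulating anatomically distinct expression profiles).
#' @param marker_effect log-scale elevation of region markers.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param base_logmean_sd spread of per-gene baseline log-means.
#' @param n_lr_pairs number of ligand-receptor pairs with planted hotspots.
#' @param hotspot_region region hosting the hotspots.
#' @param hotspot_fraction fraction of the region's spots in each hotspot
#'   (contiguous disc), in (0, 1].
#' @param hotspot_intensity baseline expression multiplier inside a hotspot.
#' @param timepoint_effects named numeric: per-time-point scaling of the
#'   hotspot log-intensity (0 = no hotspot, 1 = the full
#'   `hotspot_intensity` boost); the names define which time points are
#'   generated.
#' @param marker_shift named numeric per time point: fraction of each
#'   subtrajectory's transition genes swapped for time-point-private genes,
#'   so subtype marker sets can diverge across time points.
#' @param section_interval_um z spacing between consecutive sections.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sections_per_timepoint = 3,
                             spots_per_section = 400,
                             grid_spacing_um = 100,
                             region_layout = c("VL", "A", "B", "C"),
                             planted_chain = c("VL", "A", "B", "C"),
                             n_genes = 2000,
                             n_transition_up = 10,
                             n_transition_down = 10,
                             effect_size = 1.0,
                             n_gradient_genes = 100,
                             gradient_effect = 1.5,
                             n_region_markers = 15,
                             marker_effect = 1.5,
                             nb_dispersion = 0.3,
                             base_logmean_sd = 0.5,
                             n_lr_pairs = 6,
                             hotspot_region = "A",
                             hotspot_fraction = 0.15,
                             hotspot_intensity = 4,
                             timepoint_effects = c(sham = 0, d3 = 1, d7 = 0),
                             marker_shift = c(sham = 0.7, d3 = 0, d7 = 0.1),
                             section_interval_um = 20,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (!all(planted_chain %in% region_layout)) {
    abort("planted_chain contains a region absent from region_layout")
  }
  if (spots_per_section < length(region_layout)) {
    abort("spots_per_section must be at least the number of layout regions")
  }
  if (hotspot_fraction <= 0 || hotspot_fraction > 1) {
    abort("hotspot_fraction must be in (0, 1]")
  }
  if (effect_size < 0) abort("effect_size must be >= 0")
  if (is.null(names(timepoint_effects)) || any(names(timepoint_effects) == "")) {
    abort("timepoint_effects must be a named vector")
  }
  if (!hotspot_region %in% region_layout && n_lr_pairs > 0) {
    abort("hotspot_region absent from region_layout")
  }
  structure(cfg, class = "synthetic_config")
}

# deterministic per-stream sub-seed, kept well below 2^31
# (double arithmetic: exact for these magnitudes, no integer overflow)
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2000000000)
}

#' Generate a synthetic multi-section dataset with ground truth
#'
#' Spots are laid on a square grid; regions are contiguous vertical bands in
#' `region_layout` order (root at low x). True pseudotime is the normalised
#' arc length of a spot's x position across the planted chain's bands.
#' Transition genes ramp monotonically (log-linear, slope `effect_size`) in
#' local pseudotime over their subtrajectory's two bands and are flat
#' elsewhere; which genes are planted can differ per time point via
#' `marker_shift`. Each LR pair gets one contiguous hotspot disc in
#' `hotspot_region` where ligand and receptor means are multiplied by
#' `exp(log(hotspot_intensity) * timepoint_effects[tp])` (so a time-point
#' effect of 0 plants no hotspot). Counts are negative binomial.
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` (a `multisection_dataset`), `truth` (class
#'   `ground_truth`: per-spot true pseudotime, planted transition genes per
#'   time point and subtrajectory, hotspot memberships, LR pair table) and
#'   `lr_pairs` (tibble as from [load_lr_database()]).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)

  timepoints <- names(config$timepoint_effects)
  n_sub <- length(config$planted_chain) - 1L
  per_sub <- config$n_transition_up + config$n_transition_down

  # gene universe: background genes, then reserved LR genes
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  lr_tbl <- NULL
  if (config$n_lr_pairs > 0) {
    lr_tbl <- tibble(
      ligand = sprintf("LG%02d", seq_len(config$n_lr_pairs)),
      receptor = sprintf("RG%02d", seq_len(config$n_lr_pairs))) |>
      mutate(pair_id = paste0(toupper(.data$ligand), "_",
                              toupper(.data$receptor)))
  }
  all_genes <- c(gene_ids,
                 if (!is.null(lr_tbl)) c(rbind(lr_tbl$ligand, lr_tbl$receptor)))

  set.seed(sub_seed(config$seed, 1L))
  base_logmean <- setNames(rnorm(length(all_genes), 0, config$base_logmean_sd),
                           all_genes)
  # transition genes are planted among well-expressed genes: a ramp in a
  # barely-detected gene is not a usable transition marker
  base_logmean[seq_len(n_sub * per_sub * (1L + length(timepoints)))] <-
    base_logmean[seq_len(n_sub * per_sub * (1L + length(timepoints)))] + 2

  # planted transition genes: a base block per subtrajectory plus a private
  # block per (timepoint, subtrajectory) used for marker_shift swaps
  n_regions_total <- length(config$region_layout)
  blocks_needed <- n_sub * per_sub * (1L + length(timepoints)) +
    config$n_gradient_genes + n_regions_total * config$n_region_markers
  if (blocks_needed > config$n_genes) {
    abort("n_genes too small for the requested planted gene blocks")
  }
  block <- function(i) gene_ids[((i - 1L) * per_sub + 1L):(i * per_sub)]
  n_trans_blocks <- n_sub * (1L + length(timepoints))
  grad_genes <- gene_ids[n_trans_blocks * per_sub +
                           seq_len(config$n_gradient_genes)]
  grad_sign <- rep(c(1L, -1L), length.out = config$n_gradient_genes)
  marker_start <- n_trans_blocks * per_sub + config$n_gradient_genes
  region_markers <- setNames(
    map(seq_len(n_regions_total), function(r) {
      gene_ids[marker_start + (r - 1L) * config$n_region_markers +
                 seq_len(config$n_region_markers)]
    }), config$region_layout)
  base_sets <- map(seq_len(n_sub), function(s) {
    g <- block(s)
    tibble(gene = g,
           sign = rep(c(1L, -1L),
                      c(config$n_transition_up, config$n_transition_down)))
  })
  truth_genes <- purrr::map_dfr(seq_along(timepoints), function(ti) {
    tp <- timepoints[ti]
    shift <- unname(config$marker_shift[tp] %||% 0)
    purrr::map_dfr(seq_len(n_sub), function(s) {
      tab <- base_sets[[s]]
      n_swap <- floor(shift * nrow(tab))
      if (n_swap > 0) {
        priv <- block(n_sub + (ti - 1L) * n_sub + s)
        tab$gene[seq_len(n_swap)] <- priv[seq_len(n_swap)]
      }
      tab |> mutate(
        timepoint = tp,
        subtrajectory = paste(config$planted_chain[s],
                              config$planted_chain[s + 1L], sep = ">"))
    })
  })

  # section geometry (identical across sections): square grid, region bands
  side <- ceiling(sqrt(config$spots_per_section))
  grid <- tidyr::expand_grid(col = seq_len(side), row = seq_len(side)) |>
    head(config$spots_per_section) |>
    mutate(x_um = (.data$col - 1) * config$grid_spacing_um,
           y_um = (.data$row - 1) * config$grid_spacing_um)
  n_regions <- length(config$region_layout)
  band <- pmin(floor((grid$col - 1) / side * n_regions) + 1L, n_regions)
  grid$region <- config$region_layout[band]

  chain_idx <- grid$region %in% config$planted_chain
  x_chain <- grid$x_um[chain_idx]
  true_pt <- rep(NA_real_, nrow(grid))
  true_pt[chain_idx] <- (x_chain - min(x_chain)) /
    max(max(x_chain) - min(x_chain), 1)
  grid$true_pt <- true_pt

  # local pseudotime per subtrajectory (NA outside its two bands)
  local_pt <- map(seq_len(n_sub), function(s) {
    pair <- config$planted_chain[s:(s + 1L)]
    idx <- grid$region %in% pair
    lp <- rep(NA_real_, nrow(grid))
    x <- grid$x_um[idx]
    lp[idx] <- (x - min(x)) / max(max(x) - min(x), 1)
    lp
  })

  # hotspot discs: one deterministic contiguous disc per LR pair
  hotspots <- NULL
  if (config$n_lr_pairs > 0) {
    set.seed(sub_seed(config$seed, 2L))
    reg_idx <- which(grid$region == config$hotspot_region)
    n_hot <- max(1L, round(config$hotspot_fraction * length(reg_idx)))
    hotspots <- map(seq_len(config$n_lr_pairs), function(p) {
      centre <- sample(reg_idx, 1L)
      d2 <- (grid$x_um[reg_idx] - grid$x_um[centre])^2 +
        (grid$y_um[reg_idx] - grid$y_um[centre])^2
      reg_idx[order(d2)][seq_len(n_hot)]
    })
    names(hotspots) <- lr_tbl$pair_id
  }

  dispersion_size <- 1 / config$nb_dispersion
  sections <- list()
  truth_pt <- list()
  truth_hot <- list()
  si <- 0L
  for (ti in seq_along(timepoints)) {
    tp <- timepoints[ti]
    tp_mult <- unname(config$timepoint_effects[ti])
    genes_tp <- truth_genes |> filter(.data$timepoint == tp)
    for (k in seq_len(config$n_sections_per_timepoint)) {
      si <- si + 1L
      section_id <- sprintf("%s_s%d", tp, k)
      barcodes <- sprintf("%s_spot%03d", section_id, seq_len(nrow(grid)))

      log_mu <- matrix(rep(base_logmean[all_genes], each = nrow(grid)),
                       nrow = nrow(grid),
                       dimnames = list(barcodes, all_genes))
      chain_spots <- which(!is.na(grid$true_pt))
      if (length(grad_genes) > 0L) {
        log_mu[chain_spots, grad_genes] <-
          log_mu[chain_spots, grad_genes] +
          outer(grid$true_pt[chain_spots] - 0.5,
                grad_sign * config$gradient_effect)
      }
      if (config$n_region_markers > 0L) {
        for (r in names(region_markers)) {
          ridx <- which(grid$region == r)
          log_mu[ridx, region_markers[[r]]] <-
            log_mu[ridx, region_markers[[r]]] + config$marker_effect
        }
      }
      for (s in seq_len(n_sub)) {
        sub_id <- paste(config$planted_chain[s], config$planted_chain[s + 1L],
                        sep = ">")
        gset <- genes_tp |> filter(.data$subtrajectory == sub_id)
        lp <- local_pt[[s]]
        idx <- which(!is.na(lp))
        for (r in seq_len(nrow(gset))) {
          log_mu[idx, gset$gene[r]] <- log_mu[idx, gset$gene[r]] +
            gset$sign[r] * config$effect_size * (lp[idx] - 0.5)
        }
      }
      if (!is.null(hotspots) && tp_mult > 0) {
        for (p in seq_len(config$n_lr_pairs)) {
          boost <- log(config$hotspot_intensity) * tp_mult
          idx <- hotspots[[p]]
          log_mu[idx, lr_tbl$ligand[p]] <- log_mu[idx, lr_tbl$ligand[p]] +
            boost
          log_mu[idx, lr_tbl$receptor[p]] <- log_mu[idx, lr_tbl$receptor[p]] +
            boost
        }
      }

      set.seed(sub_seed(config$seed, 100L + si))
      counts <- matrix(
        rnbinom(length(log_mu), mu = exp(log_mu), size = dispersion_size),
        nrow = nrow(log_mu), dimnames = dimnames(log_mu))

      coords <- tibble(barcode = barcodes, x_um = grid$x_um, y_um = grid$y_um)
      regions <- tibble(barcode = barcodes, region = grid$region)
      sections[[section_id]] <- section_dataset(
        counts, coords, regions, section_id = section_id, timepoint = tp,
        z_um = (k - 1) * config$section_interval_um,
        timepoint_levels = union(TIMEPOINT_LEVELS, timepoints))
      truth_pt[[section_id]] <- tibble(
        section_id = section_id, barcode = barcodes,
        region = grid$region, true_pseudotime = grid$true_pt)
      if (!is.null(hotspots) && tp_mult > 0) {
        truth_hot[[section_id]] <- purrr::imap_dfr(hotspots, function(idx, pid) {
          tibble(timepoint = tp, section_id = section_id, pair_id = pid,
                 barcode = barcodes[idx])
        })
      }
    }
  }

  truth <- structure(
    list(pseudotime = bind_rows(truth_pt),
         transition_genes = truth_genes |>
           select("timepoint", "subtrajectory", "gene", "sign"),
         hotspots = if (length(truth_hot)) bind_rows(truth_hot) else
           tibble(timepoint = character(), section_id = character(),
                  pair_id = character(), barcode = character()),
         lr_pairs = lr_tbl %||% tibble(ligand = character(),
                                       receptor = character(),
                                       pair_id = character()),
         planted_chain = config$planted_chain,
         config = config),
    class = "ground_truth")

  list(dataset = new_multisection(sections, gene_universe = "intersection"),
       truth = truth, lr_pairs = lr_tbl)
}

#' Summarise planted ground truth as one tidy table
#'
#' @param gt a `ground_truth` object from [generate_dataset()].
#' @return tibble with columns `kind` (`"pseudotime"`, `"transition_gene"`,
#'   `"hotspot"`), `timepoint`, `key` (subtrajectory or LR pair; `NA` for
#'   pseudotime rows, which are per-section), `item` (gene or barcode) and
#'   `sign` (+1/-1 for transition genes, `NA` otherwise).
#' @export
ground_truth_summary <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  bind_rows(
    gt$pseudotime |>
      mutate(kind = "pseudotime", timepoint = NA_character_,
             key = .data$section_id, item = .data$barcode,
             sign = NA_integer_) |>
      select("kind", "timepoint", "key", "item", "sign"),
    gt$transition_genes |>
      mutate(kind = "transition_gene", key = .data$subtrajectory,
             item = .data$gene) |>
      select("kind", "timepoint", "key", "item", "sign"),
    gt$hotspots |>
      mutate(kind = "hotspot", key = .data$pair_id, item = .data$barcode,
             sign = NA_integer_) |>
      select("kind", "timepoint", "key", "item", "sign"))
}

#' Write a synthetic dataset to disk in the formats the loaders read
#'
#' Emits per-section MTX + TSV counts, positions and regions CSVs, a
#' `manifest.json`, a CellTalkDB-style `lr_pairs.tsv` and a
#' `ground_truth.json`, so the full pipeline can be exercised from files.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory, created if needed.
#' @return invisibly, the manifest path.
#' @export
write_synthetic_dataset <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_dataset(config)
  man <- purrr::imap(gen$dataset$sections, function(ds, sid) {
    sdir <- file.path(dir, sid)
    write_section(ds, sdir)
    list(section_id = sid, timepoint = ds$timepoint, z_um = ds$z_um,
         counts_dir = file.path(sid, "counts"),
         positions = file.path(sid, "tissue_positions.csv"),
         regions = file.path(sid, "regions.csv"))
  })
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(unname(man), manifest_path, auto_unbox = TRUE,
                       digits = NA)
  if (nrow(gen$truth$lr_pairs) > 0) {
    readr::write_tsv(
      tibble(ligand_gene_symbol = gen$truth$lr_pairs$ligand,
             receptor_gene_symbol = gen$truth$lr_pairs$receptor),
      file.path(dir, "lr_pairs.tsv"))
  }
  jsonlite::write_json(
    list(planted_chain = gen$truth$planted_chain,
         transition_genes = gen$truth$transition_genes,
         hotspots = gen$truth$hotspots,
         seed = config$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}
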