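# Ligand-receptor communication scoring: per-spot raw interaction intensity
# from neighbour co-expression, a spot-permutation z-score, binary (or
# binned) discretisation, the per-trajectory Density statistic, and the
# Kruskal-Wallis comparison of densities across time points.

#' Spots of a section belonging to a trajectory's regions
#'
#' @param section a [section_dataset].
#' @param chain character vector of region labels.
#' @return character vector of barcodes (errors when empty).
#' @export
select_trajectory_spots <- function(section, chain) {
  bc <- section$spots$barcode[section$spots$region %in% chain]
  if (length(bc) == 0L) {
    abort(paste0("no spots of section '", section$section_id,
                 "' fall in trajectory regions ", chain_to_string(chain)))
  }
  bc
}

# row-normalised neighbour matrix: radius neighbourhood, self excluded;
# neighbourless spots get an all-zero row (neighbour mean 0)
neighbor_matrix <- function(coords, radius) {
  n <- nrow(coords)
  d2 <- outer(coords[, 1], coords[, 1], "-")^2 +
    outer(coords[, 2], coords[, 2], "-")^2
  a <- d2 <= radius^2
  diag(a) <- FALSE
  deg <- rowSums(a)
  a <- a / pmax(deg, 1)
  Matrix::Matrix(a, sparse = TRUE)
}

raw_intensity <- function(l, r, a) {
  0.5 * (l * as.numeric(a %*% r) + r * as.numeric(a %*% l))
}

#' Per-spot raw ligand-receptor interaction intensity
#'
#' For spot i, `raw_i = 0.5 * (L_i * mean(R over neighbours) +
#' R_i * mean(L over neighbours))` on log-normalised expression; spots with
#' no neighbour within the radius use a neighbour mean of 0.
#'
#' @param section a [section_dataset].
#' @param pair length-2 character vector `c(ligand, receptor)` (matched
#'   case-insensitively against the section's genes).
#' @param neighbor_radius neighbourhood radius, micrometres; default 1.5 x
#'   the inferred grid spacing.
#' @return named numeric vector of raw intensities (barcodes as names), or
#'   `NULL` with a warning when either gene is absent.
#' @export
spot_intensity <- function(section, pair, neighbor_radius = NULL) {
  genes_up <- toupper(section$genes)
  il <- match(toupper(pair[1]), genes_up)
  ir <- match(toupper(pair[2]), genes_up)
  if (is.na(il) || is.na(ir)) {
    warn(paste0("LR pair ", pair[1], "_", pair[2],
                ": gene(s) missing from section '", section$section_id,
                "'; pair skipped"))
    return(NULL)
  }
  neighbor_radius <- neighbor_radius %||% (1.5 * grid_spacing(section))
  x <- log_normalize(section$counts)
  a <- neighbor_matrix(as.matrix(section$spots[, c("x_um", "y_um")]),
                       neighbor_radius)
  setNames(raw_intensity(x[, il], x[, ir], a), section$spots$barcode)
}

#' Permutation z-score of ligand-receptor intensity
#'
#' The null distribution is built by permuting the spot labels of the ligand
#' and receptor expression vectors independently `n_perm` times and
#' recomputing the raw intensity; `Zscore_i = (raw_i - mean_null_i) /
#' sd_null_i`. Spots with zero null standard deviation get z = 0 and are
#' flagged. Deterministic given `seed`.
#'
#' @param section a [section_dataset].
#' @param pair `c(ligand, receptor)`.
#' @param n_perm number of permutations (must be >= 100).
#' @param seed integer seed for the permutation stream.
#' @param neighbor_radius as in [spot_intensity()].
#' @return tibble: `barcode`, `raw`, `zscore`, `degenerate` (logical per
#'   spot); `NULL` when the pair's genes are absent.
#' @export
permutation_zscore <- function(section, pair, n_perm = 200, seed = 1,
                               neighbor_radius = NULL) {
  if (n_perm < 100) abort("n_perm must be at least 100")
  genes_up <- toupper(section$genes)
  il <- match(toupper(pair[1]), genes_up)
  ir <- match(toupper(pair[2]), genes_up)
  if (is.na(il) || is.na(ir)) {
    warn(paste0("LR pair ", pair[1], "_", pair[2],
                ": gene(s) missing from section '", section$section_id,
                "'; pair skipped"))
    return(NULL)
  }
  neighbor_radius <- neighbor_radius %||% (1.5 * grid_spacing(section))
  x <- log_normalize(section$counts)
  a <- neighbor_matrix(as.matrix(section$spots[, c("x_um", "y_um")]),
                       neighbor_radius)
  l <- x[, il]; r <- x[, ir]
  raw <- raw_intensity(l, r, a)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed) %% 2000000000L)

  n <- length(l)
  # accumulate deviations from the observed raw: numerically exact zero
  # variance when permutation leaves the intensity unchanged
  s1 <- numeric(n); s2 <- numeric(n)
  for (p in seq_len(n_perm)) {
    d <- raw_intensity(l[sample.int(n)], r[sample.int(n)], a) - raw
    s1 <- s1 + d
    s2 <- s2 + d^2
  }
  mu <- raw + s1 / n_perm
  var_null <- pmax((s2 - s1^2 / n_perm) / (n_perm - 1), 0)
  sd_null <- sqrt(var_null)
  degenerate <- sd_null < 1e-10 * pmax(abs(raw), 1)
  z <- ifelse(degenerate, 0, (raw - mu) / ifelse(degenerate, 1, sd_null))
  tibble(barcode = section$spots$barcode, raw = raw, zscore = z,
         degenerate = degenerate)
}

#' Discretise z-scores and compute the Density statistic
#'
#' Binary mode (default): `ZT_i = 1` if `Zscore_i >= z_star` else 0, so
#' `Density = ZT_Total / N` lies in `[0, 1]`. Binned mode: `ZT_i =
#' trunc(Zscore_i / z_star)`, a signed integer count of threshold multiples.
#' In both, `ZT_Total = sum(ZT_i)` exactly.
#'
#' @param zscores numeric vector of per-spot z-scores (the N spots of one
#'   trajectory/time point, possibly pooled over sections).
#' @param z_star discretisation threshold (default 1.96).
#' @param mode `"binary"` or `"binned"`.
#' @param trajectory_id,timepoint,pair_id identifiers carried into the
#'   result row.
#' @return tibble of class `communication_result` with one row:
#'   `trajectory_id`, `timepoint`, `pair_id`, `n_spots`, `zt_total`,
#'   `density`; attribute `zt` holds the per-spot discrete intensities.
#' @export
discretize_and_density <- function(zscores, z_star = 1.96,
                                   mode = c("binary", "binned"),
                                   trajectory_id = NA_character_,
                                   timepoint = NA_character_,
                                   pair_id = NA_character_) {
  mode <- match.arg(mode)
  if (length(zscores) == 0L) abort("empty zscore vector")
  zt <- if (mode == "binary") as.integer(zscores >= z_star) else
    as.integer(trunc(zscores / z_star))
  out <- tibble(trajectory_id = trajectory_id, timepoint = timepoint,
                pair_id = pair_id, n_spots = length(zt),
                zt_total = sum(zt), density = sum(zt) / length(zt))
  attr(out, "zt") <- zt
  class(out) <- c("communication_result", class(out))
  out
}

#' Communication density of a trajectory across sections and time points
#'
#' For every LR pair and every section supporting the trajectory's time
#' point, computes permutation z-scores over the whole section, keeps the
#' spots of the trajectory's regions, pools them across the time point's
#' sections, and discretises to one Density per (time point, pair).
#'
#' @param dataset a `multisection_dataset`.
#' @param chain trajectory region chain.
#' @param lr_pairs tibble from [load_lr_database()] (columns ligand,
#'   receptor, pair_id).
#' @param trajectory_id identifier carried into the result.
#' @param n_perm,seed,z_star,mode,neighbor_radius see
#'   [permutation_zscore()] and [discretize_and_density()]; each
#'   (section, pair) gets a deterministic sub-seed of `seed`.
#' @return list with `density` (tibble: trajectory_id, timepoint, pair_id,
#'   n_spots, zt_total, density) and `spots` (per-spot tibble with zscore
#'   and ZT for the trajectory's spots).
#' @export
communication_density <- function(dataset, chain, lr_pairs,
                                  trajectory_id = chain_to_string(chain),
                                  n_perm = 200, seed = 1, z_star = 1.96,
                                  mode = "binary", neighbor_radius = NULL) {
  stopifnot(inherits(dataset, "multisection_dataset"))
  per_spot <- list()
  for (si in seq_along(dataset$sections)) {
    sec <- dataset$sections[[si]]
    traj_bc <- tryCatch(select_trajectory_spots(sec, chain),
                        error = function(e) character())
    if (length(traj_bc) == 0L) next
    for (pi in seq_len(nrow(lr_pairs))) {
      z <- permutation_zscore(
        sec, c(lr_pairs$ligand[pi], lr_pairs$receptor[pi]),
        n_perm = n_perm,
        seed = sub_seed(seed, si * 1000L + pi),
        neighbor_radius = neighbor_radius)
      if (is.null(z)) next
      per_spot[[length(per_spot) + 1L]] <- z |>
        filter(.data$barcode %in% traj_bc) |>
        mutate(section_id = sec$section_id, timepoint = sec$timepoint,
               pair_id = lr_pairs$pair_id[pi])
    }
  }
  if (length(per_spot) == 0L) {
    abort(paste0("trajectory ", trajectory_id,
                 ": no scoreable (section, pair) combinations"))
  }
  spots <- bind_rows(per_spot)
  density <- spots |>
    group_by(.data$timepoint, .data$pair_id) |>
    dplyr::group_modify(function(df, key) {
      discretize_and_density(df$zscore, z_star = z_star, mode = mode) |>
        select("n_spots", "zt_total", "density")
    }) |> ungroup() |>
    mutate(trajectory_id = trajectory_id) |>
    select("trajectory_id", "timepoint", "pair_id",
           "n_spots", "zt_total", "density")
  zt <- if (mode == "binary") as.integer(spots$zscore >= z_star) else
    as.integer(trunc(spots$zscore / z_star))
  list(density = density, spots = spots |> mutate(zt = zt))
}

#' Compare communication densities across time points (Kruskal-Wallis)
#'
#' Groups are time points; observations are the per-LR-pair densities of one
#' trajectory. Uses the tie-corrected Kruskal-Wallis H; when every value is
#' identical (H undefined under the tie correction) the documented
#' convention H = 0, p = 1 applies. An exact permutation p-value (group
#' labels permuted) is available for small samples.
#'
#' @param density tibble with columns `timepoint` and `density` (e.g. the
#'   `density` element of [communication_density()]).
#' @param exact if `TRUE`, adds a permutation p-value.
#' @param n_perm permutations for the exact p-value.
#' @param seed seed for the permutation p-value.
#' @return tibble of class `density_comparison`: `n_groups`, `statistic`
#'   (H), `df`, `p_value`, and `p_exact` when requested.
#' @export
compare_densities <- function(density, exact = FALSE, n_perm = 1999,
                              seed = 1) {
  groups <- split(density$density, density$timepoint)
  if (length(groups) < 2L) abort("need at least 2 timepoint groups")
  if (any(lengths(groups) == 0L)) abort("a timepoint group is empty")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    out <- tibble(n_groups = length(groups), statistic = 0,
                  df = length(groups) - 1L, p_value = 1)
  } else {
    kw <- kruskal.test(values, labels)
    out <- tibble(n_groups = length(groups),
                  statistic = unname(kw$statistic),
                  df = unname(kw$parameter), p_value = kw$p.value)
  }
  if (exact) {
    h_stat <- function(lab) {
      if (length(unique(values)) == 1L) return(0)
      unname(kruskal.test(values, lab)$statistic)
    }
    h_obs <- out$statistic
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed) %% 2000000000L)
    exceed <- sum(vapply(seq_len(n_perm), function(i) {
      h_stat(sample(labels)) >= h_obs - 1e-12
    }, logical(1)))
    out$p_exact <- (1 + exceed) / (n_perm + 1)
  }
  class(out) <- c("density_comparison", class(out))
  out
}

#' @exportS3Method generics::glance
glance.density_comparison <- function(x, ...) as_tibble(x)
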