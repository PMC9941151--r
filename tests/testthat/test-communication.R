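lr_section <- function(l_counts, r_counts, x = NULL, region = "A",
                       extra_genes = 0, seed = 1) {
  n <- length(l_counts)
  barcodes <- sprintf("bc%02d", seq_len(n))
  set.seed(seed)
  counts <- cbind(Lg = as.integer(l_counts), Rg = as.integer(r_counts))
  if (extra_genes > 0) {
    counts <- cbind(counts, matrix(rpois(n * extra_genes, 5), nrow = n,
                                   dimnames = list(NULL,
                                                   sprintf("e%02d",
                                                           seq_len(extra_genes)))))
  }
  rownames(counts) <- barcodes
  section_dataset(
    counts,
    tibble::tibble(barcode = barcodes,
                   x_um = x %||% ((seq_len(n) - 1) * 100), y_um = 0),
    tibble::tibble(barcode = barcodes, region = rep_len(region, n)),
    "lr", "d3", 0)
}

test_that("trajectory spot selection counts regions and errors when empty", {
  sec <- tiny_section(n_spots = 20,
                      regions = rep(c("VL", "CA1", "DG", "X"), each = 5))
  expect_length(select_trajectory_spots(sec, c("VL", "CA1", "DG")), 15)
  expect_length(select_trajectory_spots(sec, c("VL", "CA1", "ZZ")), 10)
  expect_error(select_trajectory_spots(sec, c("QQ", "ZZ")), "no spots")
})

test_that("raw intensity has its closed forms", {
  # uniform expression: raw = c^2 for every spot with neighbours
  sec <- lr_section(rep(5, 10), rep(5, 10))
  raw <- spot_intensity(sec, c("Lg", "Rg"), neighbor_radius = 150)
  x <- log_normalize(sec$counts)
  cval <- x[1, "Lg"]
  expect_equal(unname(raw), rep(cval^2, 10))

  # zero ligand at a spot with zero-receptor neighbours scores 0
  l <- c(0, 0, 0, 5, 5, 5); r <- c(0, 0, 0, 5, 5, 5)
  sec2 <- lr_section(l, r)
  raw2 <- spot_intensity(sec2, c("Lg", "Rg"), neighbor_radius = 150)
  expect_equal(unname(raw2[1]), 0)

  # an isolated spot has neighbour mean 0 in both directions: raw 0
  sec3 <- lr_section(c(9, 9), c(9, 9), x = c(0, 10000))
  raw3 <- spot_intensity(sec3, c("Lg", "Rg"), neighbor_radius = 150)
  expect_equal(unname(raw3), c(0, 0))

  # missing gene: warning and NULL
  expect_warning(out <- spot_intensity(sec, c("Lg", "Nope")), "skipped")
  expect_null(out)
})

test_that("permutation z-scores are deterministic and flag degeneracy", {
  sec <- lr_section(rpois(30, 6), rpois(30, 6), extra_genes = 3, seed = 5)
  z1 <- permutation_zscore(sec, c("Lg", "Rg"), n_perm = 100, seed = 7)
  z2 <- permutation_zscore(sec, c("Lg", "Rg"), n_perm = 100, seed = 7)
  expect_identical(z1, z2)
  z3 <- permutation_zscore(sec, c("Lg", "Rg"), n_perm = 100, seed = 8)
  expect_false(identical(z1$zscore, z3$zscore))

  flat <- lr_section(rep(4, 12), rep(4, 12))
  zf <- permutation_zscore(flat, c("Lg", "Rg"), n_perm = 100, seed = 1)
  expect_true(all(zf$zscore == 0))
  expect_true(all(zf$degenerate))
  expect_error(permutation_zscore(sec, c("Lg", "Rg"), n_perm = 50),
               "at least 100")
})

test_that("a planted co-expression hotspot stands out in z", {
  cfg <- synthetic_config(n_sections_per_timepoint = 1, n_genes = 300,
                          spots_per_section = 400,
                          timepoint_effects = c(d3 = 1), seed = 19)
  gen <- generate_dataset(cfg)
  sec <- gen$dataset$sections[[1]]
  pair <- gen$truth$lr_pairs[1, ]
  z <- permutation_zscore(sec, c(pair$ligand, pair$receptor),
                          n_perm = 150, seed = 3)
  hot <- gen$truth$hotspots$barcode[gen$truth$hotspots$pair_id == pair$pair_id]
  expect_gt(mean(z$zscore[z$barcode %in% hot]), 1.96)
})

test_that("density is exact bookkeeping and monotone in the threshold", {
  z <- c(rep(0.5, 10), rep(2.5, 10))
  r <- discretize_and_density(z, z_star = 1.96)
  expect_equal(r$density, 0.5)
  expect_identical(r$zt_total, sum(attr(r, "zt")))
  expect_equal(discretize_and_density(rep(0, 5))$density, 0)
  expect_equal(discretize_and_density(rep(3, 5))$density, 1)
  expect_error(discretize_and_density(numeric()), "empty")

  set.seed(4)
  zs <- rnorm(200)
  grid <- seq(-2, 3, by = 0.25)
  dens <- vapply(grid, function(t) {
    r <- discretize_and_density(zs, z_star = t)
    expect_identical(r$zt_total, sum(attr(r, "zt")))
    expect_equal(r$density * r$n_spots, r$zt_total)
    r$density
  }, numeric(1))
  expect_true(all(diff(dens) <= 0))  # lowering z* never lowers density

  rb <- discretize_and_density(c(-4.2, 0.5, 4.2), z_star = 1.96,
                               mode = "binned")
  expect_equal(attr(rb, "zt"), c(-2L, 0L, 2L))
})

test_that("identical density groups give H = 0 and p = 1", {
  d <- tibble::tibble(timepoint = rep(c("sham", "d3"), each = 5),
                      density = rep(0.2, 10))
  out <- compare_densities(d)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_error(compare_densities(d[d$timepoint == "d3", ]), "at least 2")
})

test_that("H matches the textbook tie-corrected formula", {
  set.seed(11)
  vals <- c(1.2, 3.4, 3.4, 2.2, 5.5, 0.1, 2.2, 4.4, 1.2, 3.3, 2.0, 6.1)
  grp <- rep(c("a", "b", "c"), each = 4)
  d <- tibble::tibble(timepoint = grp, density = vals)
  out <- compare_densities(d)
  expect_equal(out$statistic, kw_reference_h(vals, grp), tolerance = 1e-10)
})

test_that("the exact permutation p agrees with the asymptotic one", {
  set.seed(21)
  d <- tibble::tibble(timepoint = rep(c("a", "b"), each = 12),
                      density = c(rnorm(12), rnorm(12, 1.5)))
  out <- compare_densities(d, exact = TRUE, n_perm = 499, seed = 2)
  expect_lt(out$p_value, 0.05)
  expect_lt(out$p_exact, 0.05)
})

test_that("trajectory densities pool spots across supporting sections", {
  cfg <- synthetic_config(n_sections_per_timepoint = 2,
                          spots_per_section = 100, n_genes = 150,
                          n_transition_up = 3, n_transition_down = 3,
                          n_gradient_genes = 20, n_region_markers = 5,
                          n_lr_pairs = 2, timepoint_effects = c(d3 = 1),
                          seed = 23)
  gen <- generate_dataset(cfg)
  cd <- communication_density(gen$dataset, c("VL", "A"), gen$lr_pairs,
                              n_perm = 100, seed = 3)
  expect_equal(sort(unique(cd$density$pair_id)),
               sort(gen$lr_pairs$pair_id))
  per_sec <- sum(gen$dataset$sections[[1]]$spots$region %in% c("VL", "A"))
  expect_true(all(cd$density$n_spots == 2 * per_sec))
  expect_equal(cd$density$density * cd$density$n_spots,
               cd$density$zt_total)
})
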