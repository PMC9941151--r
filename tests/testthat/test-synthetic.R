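small_cfg <- function(...) {
  defaults <- list(n_sections_per_timepoint = 1, spots_per_section = 400,
                   n_genes = 400, timepoint_effects = c(d3 = 1))
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

test_that("generation is deterministic given the seed", {
  g1 <- generate_dataset(small_cfg(seed = 11))
  g2 <- generate_dataset(small_cfg(seed = 11))
  expect_identical(g1$dataset$sections[[1]]$counts,
                   g2$dataset$sections[[1]]$counts)
  expect_identical(ground_truth_summary(g1$truth),
                   ground_truth_summary(g2$truth))
  g3 <- generate_dataset(small_cfg(seed = 12))
  expect_false(identical(g1$dataset$sections[[1]]$counts,
                         g3$dataset$sections[[1]]$counts))
  expect_identical(dim(g1$dataset$sections[[1]]$counts),
                   dim(g3$dataset$sections[[1]]$counts))
})

test_that("configured sections, spots and timepoints are produced", {
  cfg <- synthetic_config(n_sections_per_timepoint = 3,
                          spots_per_section = 100, n_genes = 400,
                          timepoint_effects = c(d3 = 1))
  gen <- generate_dataset(cfg)
  expect_length(gen$dataset$sections, 3)
  for (s in gen$dataset$sections) {
    expect_equal(nrow(s$counts), 100)
    expect_equal(s$timepoint, "d3")
  }
  expect_equal(gen$dataset$by_timepoint$z_um, c(0, 20, 40))
})

test_that("config validation rejects inconsistent layouts", {
  expect_error(synthetic_config(planted_chain = c("VL", "ZZ")),
               "absent from region_layout")
  expect_error(synthetic_config(spots_per_section = 2), "at least")
  expect_error(synthetic_config(hotspot_fraction = 0), "hotspot_fraction")
})

test_that("with all effects at zero, genes are uncorrelated with pseudotime", {
  cfg <- small_cfg(effect_size = 0, gradient_effect = 0, marker_effect = 0,
                   n_lr_pairs = 0, n_genes = 2000, seed = 3)
  gen <- generate_dataset(cfg)
  sec <- gen$dataset$sections[[1]]
  pt <- gen$truth$pseudotime$true_pseudotime
  x <- log_normalize(sec$counts)
  keep <- apply(x, 2, function(v) length(unique(v)) > 1)
  rho <- suppressWarnings(cor(x[!is.na(pt), keep], pt[!is.na(pt)],
                              method = "spearman"))
  # null Monte-Carlo scale: sd(rho) ~ 1/sqrt(n-1) ~ 0.05 at n = 400
  expect_lt(median(abs(rho)), 0.06)
})

test_that("planted transition genes correlate with the planted sign", {
  gen <- generate_dataset(small_cfg(seed = 5))
  sec <- gen$dataset$sections[[1]]
  x <- log_normalize(sec$counts)
  truth <- gen$truth
  pt_tab <- truth$pseudotime
  ok <- 0L; total <- 0L
  for (sub in unique(truth$transition_genes$subtrajectory)) {
    pair <- strsplit(sub, ">", fixed = TRUE)[[1]]
    idx <- pt_tab$region %in% pair
    tg <- truth$transition_genes[
      truth$transition_genes$subtrajectory == sub, ]
    rho <- suppressWarnings(
      cor(x[idx, tg$gene], pt_tab$true_pseudotime[idx],
          method = "spearman"))[, 1]
    ok <- ok + sum(sign(rho) == tg$sign)
    total <- total + nrow(tg)
  }
  expect_gte(ok / total, 0.95)
})

test_that("hotspot spots co-express ligand and receptor above background", {
  cfg <- synthetic_config(n_sections_per_timepoint = 1, n_genes = 400,
                          timepoint_effects = c(d3 = 1), seed = 8)
  gen <- generate_dataset(cfg)
  sec <- gen$dataset$sections[[1]]
  x <- log_normalize(sec$counts)
  pair <- gen$truth$lr_pairs[1, ]
  hot <- gen$truth$hotspots$barcode[
    gen$truth$hotspots$pair_id == pair$pair_id]
  co <- x[, pair$ligand] * x[, pair$receptor]
  in_hot <- rownames(x) %in% hot
  wt <- wilcox.test(co[in_hot], co[!in_hot], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("ground truth summary is tidy and keyed as planted", {
  cfg <- small_cfg(n_transition_up = 7, n_transition_down = 4, seed = 2)
  gen <- generate_dataset(cfg)
  tab <- ground_truth_summary(gen$truth)
  tg <- tab[tab$kind == "transition_gene" & tab$key == "VL>A", ]
  expect_equal(sum(tg$sign == 1), 7)
  expect_equal(sum(tg$sign == -1), 4)
  expect_equal(nrow(tab[tab$kind == "pseudotime", ]), 400)
  no_hot <- generate_dataset(small_cfg(n_lr_pairs = 0, seed = 2))
  expect_equal(nrow(ground_truth_summary(no_hot$truth)[
    ground_truth_summary(no_hot$truth)$kind == "hotspot", ]), 0)
})

test_that("written dataset reloads into the same counts", {
  cfg <- synthetic_config(n_sections_per_timepoint = 2,
                          spots_per_section = 64, n_genes = 60,
                          n_transition_up = 3, n_transition_down = 3,
                          n_gradient_genes = 10, n_region_markers = 2,
                          n_lr_pairs = 2,
                          timepoint_effects = c(d3 = 1), seed = 4)
  dir <- withr::local_tempdir()
  man <- write_synthetic_dataset(cfg, dir)
  ms <- load_multisection(man)
  gen <- generate_dataset(cfg)
  expect_equal(names(ms$sections), names(gen$dataset$sections))
  expect_equal(ms$sections[[1]]$counts, gen$dataset$sections[[1]]$counts)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_true(file.exists(file.path(dir, "lr_pairs.tsv")))
})
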