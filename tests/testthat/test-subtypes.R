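test_that("profiles union subtrajectory markers with sign resolution", {
  a <- make_tg(sprintf("a%02d", 1:30), seq(0.9, 0.3, length.out = 30),
               sub = "VL>A")
  b <- make_tg(sprintf("b%02d", 1:30), seq(0.9, 0.3, length.out = 30),
               sub = "A>B")
  prof <- build_subtype_profile(list(a, b), "VL>A>B", "d3")
  expect_equal(nrow(prof), 60)
  expect_true(all(prof$sign == 1))

  # conflicting signs across subtrajectories: larger magnitude wins
  c1 <- make_tg("G", 0.4, sub = "VL>A")
  c2 <- make_tg("G", -0.9, sub = "A>B")
  prof2 <- build_subtype_profile(list(c1, c2), "VL>A>B", "d3")
  expect_equal(prof2$sign, -1L)

  # a single subtrajectory is the identity
  prof3 <- build_subtype_profile(list(a), "VL>A", "d3")
  expect_equal(sort(prof3$gene), sort(a$up$gene))
})

test_that("subtype similarity matches hand-enumerated cases", {
  p1 <- subtype_profile(c("G1", "G2"), c(1, 1))
  expect_equal(subtype_similarity(p1, p1), 1.0)
  p2 <- subtype_profile(c("H1", "H2"), c(1, -1))
  expect_equal(subtype_similarity(p1, p2), 0.0)
  # union {G1,G2,G3} = 3 genes, sign-agreeing shared genes = {G1}
  p3 <- subtype_profile(c("G1", "G2", "G3"), c(1, -1, 1))
  expect_equal(subtype_similarity(p1, p3), 1 / 3)
  expect_equal(subtype_similarity(p3, p1), 1 / 3)
})

test_that("similarity axioms hold over all signed 4-gene profiles", {
  universe <- c("g1", "g2", "g3", "g4")
  grid <- expand.grid(rep(list(c(-1L, 0L, 1L)), 4))
  profiles <- list()
  for (i in seq_len(nrow(grid))) {
    p <- random_profile(universe, unlist(grid[i, ]), id = as.character(i))
    if (!is.null(p)) profiles[[length(profiles) + 1L]] <- p
  }
  signed_key <- function(p) paste(p$gene, p$sign, collapse = ";")
  keys <- vapply(profiles, signed_key, "")
  bad_range <- 0L; bad_sym <- 0L; bad_one <- 0L; bad_zero <- 0L
  for (i in seq_along(profiles)) {
    for (j in seq(i, length(profiles))) {
      s <- subtype_similarity(profiles[[i]], profiles[[j]])
      if (s < 0 || s > 1) bad_range <- bad_range + 1L
      if (!identical(s, subtype_similarity(profiles[[j]], profiles[[i]])))
        bad_sym <- bad_sym + 1L
      if ((s == 1) != (keys[i] == keys[j])) bad_one <- bad_one + 1L
      disjoint_signed <- !any(paste(profiles[[i]]$gene, profiles[[i]]$sign)
                              %in% paste(profiles[[j]]$gene,
                                         profiles[[j]]$sign))
      if ((s == 0) != disjoint_signed) bad_zero <- bad_zero + 1L
    }
  }
  expect_equal(bad_range, 0L)
  expect_equal(bad_sym, 0L)
  expect_equal(bad_one, 0L)   # similarity 1 exactly for identical profiles
  expect_equal(bad_zero, 0L)  # similarity 0 exactly for signed-disjoint ones
})

test_that("cell-type matching ranks by enrichment with stable ties", {
  prof <- subtype_profile(c("M1", "M2", "M3"), c(1, 1, -1))
  db <- list(perfect = c("M1", "M2", "M3"),
             partial = c("M1", "X1", "X2", "X3"),
             noise = c("X4", "X5", "X6"))
  out <- match_cell_types(prof, db, top_n = 5)
  expect_equal(out$cell_type[1], "perfect")
  expect_equal(out$overlap[1], 3)

  # identical overlap and set size: lexicographic order decides
  db_tie <- list(zeta = c("M1", "M2"), alpha = c("M1", "M2"),
                 other = c("X1", "X2"))
  out_tie <- match_cell_types(prof, db_tie, top_n = 2)
  expect_equal(out_tie$cell_type, c("alpha", "zeta"))

  # invariant to database order
  out_rev <- match_cell_types(prof, rev(db_tie), top_n = 2)
  expect_equal(out_rev$cell_type, out_tie$cell_type)
  expect_error(match_cell_types(prof, list()), "empty marker database")
})

test_that("top-n default and cross-timepoint union behave", {
  prof <- subtype_profile(c("M1", "M2"), c(1, 1))
  db <- setNames(lapply(1:8, function(i) c("M1", sprintf("X%d", i))),
                 paste0("ct", 1:8))
  out <- match_cell_types(prof, db)
  expect_equal(nrow(out), 5)
  u <- cell_type_union(list(tibble::tibble(cell_type = c("a", "b")),
                            tibble::tibble(cell_type = c("b", "c"))))
  expect_equal(u, c("a", "b", "c"))
})

test_that("pathway similarity is the overlap coefficient", {
  same <- sprintf("GO:%d", 1:9)
  ps <- pathway_set_similarity(same, same)
  expect_equal(ps$similarity, 1.0)
  expect_equal(ps$n_inter, 9)
  ps0 <- pathway_set_similarity(sprintf("GO:%d", 1:5), sprintf("GO:%d", 6:9))
  expect_equal(ps0$similarity, 0.0)
  expect_equal(ps0$n_inter, 0)
  ps5 <- pathway_set_similarity(sprintf("GO:%d", 1:20), sprintf("GO:%d", 16:25))
  expect_equal(ps5$similarity, 5 / 10)
  expect_equal(pathway_set_similarity(character(), same)$similarity, 0)
  expect_equal(glance(ps5)$n_inter, 5)
})

test_that("profiles at close time points are more similar than distant ones", {
  cfg <- synthetic_config(n_sections_per_timepoint = 1,
                          spots_per_section = 400, n_genes = 500, seed = 17)
  gen <- generate_dataset(cfg)
  profs <- list()
  for (tp in c("sham", "d3", "d7")) {
    sec <- gen$dataset$sections[[paste0(tp, "_s1")]]
    pt <- compute_pseudotime(sec)
    sets <- lapply(chain_subtrajectories(gen$truth$planted_chain),
                   function(pair) {
                     union_3d(list(rank_transition_genes(sec, pt, pair)))
                   })
    profs[[tp]] <- build_subtype_profile(sets, "VL>A>B>C", tp)
  }
  sim_d3_d7 <- subtype_similarity(profs$d3, profs$d7)
  sim_sham_d3 <- subtype_similarity(profs$sham, profs$d3)
  expect_gt(sim_d3_d7, sim_sham_d3)
})
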