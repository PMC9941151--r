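test_that("a valid section round-trips through disk exactly", {
  ds <- tiny_section(n_spots = 4, n_genes = 3)
  dir <- withr::local_tempdir()
  paths <- write_section(ds, dir)
  ds2 <- load_section(paths$counts_dir, paths$positions, paths$regions,
                      meta = list(section_id = "s1", timepoint = "d3",
                                  z_um = 0))
  expect_equal(ds2$counts, ds$counts)
  expect_equal(ds2$spots, ds$spots)
  expect_equal(ds2$genes, ds$genes)
  expect_identical(attr(ds2, "n_rejected"), 0L)
})

test_that("validation names the offending cell and catches mismatches", {
  ds <- tiny_section(n_spots = 4, n_genes = 3)
  bad <- ds$counts
  bad[2, 1] <- -1
  expect_error(
    section_dataset(bad, ds$spots[, c("barcode", "x_um", "y_um")],
                    ds$spots[, c("barcode", "region")], "s1", "d3", 0),
    "bc02.*g01|g01.*bc02")
  expect_error(
    section_dataset(ds$counts, ds$spots[-1, c("barcode", "x_um", "y_um")],
                    ds$spots[, c("barcode", "region")], "s1", "d3", 0),
    "barcode mismatch")
  expect_error(
    section_dataset(ds$counts, ds$spots[, c("barcode", "x_um", "y_um")],
                    ds$spots[, c("barcode", "region")], "s1", "d99", 0),
    "unknown timepoint")
})

test_that("positions file missing a counts barcode is a barcode mismatch", {
  ds <- tiny_section(n_spots = 4, n_genes = 3)
  dir <- withr::local_tempdir()
  paths <- write_section(ds, dir)
  pos <- readr::read_csv(paths$positions, show_col_types = FALSE)
  readr::write_csv(pos[-2, ], paths$positions)
  expect_error(
    load_section(paths$counts_dir, paths$positions, paths$regions,
                 meta = list(section_id = "s1", timepoint = "d3", z_um = 0)),
    "barcode mismatch.*bc02")
})

test_that("out-of-tissue spots are dropped but accounted for", {
  ds <- tiny_section(n_spots = 6, n_genes = 3)
  dir <- withr::local_tempdir()
  paths <- write_section(ds, dir)
  pos <- readr::read_csv(paths$positions, show_col_types = FALSE)
  pos$in_tissue[c(1, 4)] <- 0L
  readr::write_csv(pos, paths$positions)
  ds2 <- load_section(paths$counts_dir, paths$positions, paths$regions,
                      meta = list(section_id = "s1", timepoint = "d3",
                                  z_um = 0))
  expect_equal(nrow(ds2$counts) + attr(ds2, "n_rejected"), nrow(ds$counts))
  expect_equal(nrow(ds2$counts), 4)
})

write_manifest_fixture <- function(dir, z_um = c(0, 20, 40),
                                   ids = paste0("s", 1:3),
                                   gene_sets = NULL) {
  entries <- lapply(seq_along(ids), function(i) {
    ds <- tiny_section(n_spots = 6, n_genes = 4, section_id = ids[i],
                       z_um = z_um[i], seed = i)
    if (!is.null(gene_sets)) {
      colnames(ds$counts) <- gene_sets[[i]]
      ds$genes <- gene_sets[[i]]
    }
    write_section(ds, file.path(dir, ids[i]))
    list(section_id = ids[i], timepoint = "d3", z_um = z_um[i],
         counts_dir = file.path(ids[i], "counts"),
         positions = file.path(ids[i], "tissue_positions.csv"),
         regions = file.path(ids[i], "regions.csv"))
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, path, auto_unbox = TRUE)
  path
}

test_that("multisection manifest groups by timepoint in z order", {
  dir <- withr::local_tempdir()
  man <- write_manifest_fixture(dir, z_um = c(40, 0, 20))
  ms <- load_multisection(man)
  expect_equal(ms$by_timepoint$timepoint, rep("d3", 3))
  expect_equal(ms$by_timepoint$z_um, c(0, 20, 40))
  expect_equal(names(ms$sections), c("s2", "s3", "s1"))
})

test_that("duplicate z within a timepoint and empty manifests error", {
  dir <- withr::local_tempdir()
  man <- write_manifest_fixture(dir, z_um = c(0, 0, 20))
  expect_error(load_multisection(man), "duplicate z_um")
  empty <- file.path(dir, "empty.json")
  jsonlite::write_json(list(), empty)
  expect_error(load_multisection(empty), "empty manifest")
})

test_that("gene-universe policy is set algebra, order-independent", {
  dir <- withr::local_tempdir()
  gene_sets <- list(c("A", "B", "C", "X"), c("B", "C", "D", "X"),
                    c("B", "C", "E", "X"))
  man <- write_manifest_fixture(dir, gene_sets = gene_sets)
  ms_int <- load_multisection(man, "intersection")
  expect_setequal(ms_int$genes$d3, c("B", "C", "X"))
  ms_un <- load_multisection(man, "union")
  expect_setequal(ms_un$genes$d3, c("A", "B", "C", "D", "E", "X"))

  # permuting manifest rows leaves the universe unchanged
  entries <- jsonlite::fromJSON(man, simplifyVector = FALSE)
  jsonlite::write_json(rev(entries), man, auto_unbox = TRUE)
  expect_setequal(load_multisection(man, "intersection")$genes$d3,
                  ms_int$genes$d3)
})

test_that("LR database loading deduplicates and skips empty rows", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "lr.tsv")
  readr::write_tsv(tibble::tibble(
    ligand_gene_symbol = c("Apoe", "Apoe", "Tgfb1", "Bad", "Il6"),
    receptor_gene_symbol = c("Lrp1", "Lrp1", "Tgfbr1", "", "Il6ra")), path)
  expect_warning(lr <- load_lr_database(path), "skipped 1")
  expect_equal(nrow(lr), 3)
  expect_equal(lr$pair_id, c("APOE_LRP1", "TGFB1_TGFBR1", "IL6_IL6RA"))
  expect_error(load_lr_database(file.path(dir, "absent.tsv")), "not found")
})

test_that("marker db and pathway lists load", {
  dir <- withr::local_tempdir()
  mdb_path <- file.path(dir, "markers.tsv")
  readr::write_tsv(tibble::tibble(
    cell_type = c("astro", "astro", "microglia"),
    gene = c("Gfap", "Aqp4", "Cx3cr1")), mdb_path)
  db <- load_marker_db(mdb_path)
  expect_named(db, c("astro", "microglia"))
  expect_equal(db$astro, c("Gfap", "Aqp4"))

  txt <- file.path(dir, "pathways.txt")
  writeLines(c("GO:1", "", " GO:2 "), txt)
  expect_equal(load_pathway_sets(txt), c("GO:1", "GO:2"))
  js <- file.path(dir, "pathways.json")
  jsonlite::write_json(list(a = c("GO:1"), b = c("GO:2", "GO:3")), js)
  expect_equal(load_pathway_sets(js), list(a = "GO:1", b = c("GO:2", "GO:3")))
})
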