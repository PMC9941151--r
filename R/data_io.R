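# Readers, writers and validators for the on-disk formats: Matrix Market
# counts with barcode/feature TSVs, Space-Ranger-style tissue positions,
# per-spot region annotations, section manifests, ligand-receptor and
# marker-gene databases, and pathway-set lists.

TIMEPOINT_LEVELS <- c("control", "sham", "d1", "d3", "d7")

#' Construct and validate a section dataset
#'
#' A section dataset bundles one planar section's spot-by-gene counts,
#' spot coordinates (micrometres), per-spot anatomical region labels, the
#' section's position along the cutting axis (`z_um`) and its time point.
#'
#' @param counts spots-by-genes matrix of non-negative integer counts with
#'   barcode rownames and gene colnames.
#' @param coords tibble/data.frame with columns `barcode`, `x_um`, `y_um`.
#' @param regions tibble/data.frame with columns `barcode`, `region`.
#' @param section_id single string identifying the section.
#' @param timepoint single string; one of `timepoint_levels`.
#' @param z_um numeric position of the section plane, micrometres.
#' @param timepoint_levels allowed time point labels (extensible).
#' @return object of class `section_dataset`: a list with elements
#'   `section_id`, `timepoint`, `z_um`, `counts` (dense integer matrix),
#'   `spots` (tibble: barcode, x_um, y_um, region) and `genes`.
#' @export
section_dataset <- function(counts, coords, regions, section_id, timepoint,
                            z_um, timepoint_levels = TIMEPOINT_LEVELS) {
  stopifnot_scalar_string(section_id, "section_id")
  stopifnot_scalar_string(timepoint, "timepoint")
  if (!timepoint %in% timepoint_levels) {
    abort(paste0("unknown timepoint label '", timepoint, "' (expected one of: ",
                 paste(timepoint_levels, collapse = ", "), ")"))
  }
  if (!is.numeric(z_um) || length(z_um) != 1L || !is.finite(z_um)) {
    abort("`z_um` must be a single finite number")
  }
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have barcode rownames and gene colnames")
  }
  if (anyDuplicated(colnames(counts))) abort("gene ids must be unique")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(paste0("invalid count at spot '", rownames(counts)[bad[1, 1]],
                 "', gene '", colnames(counts)[bad[1, 2]], "': ",
                 counts[bad[1, , drop = FALSE]],
                 " (counts must be finite non-negative integers)"))
  }
  coords <- as_tibble(coords)
  regions <- as_tibble(regions)
  bc <- rownames(counts)
  if (!setequal(coords$barcode, bc) || anyDuplicated(coords$barcode)) {
    missing_bc <- setdiff(bc, coords$barcode)
    abort(paste0("barcode mismatch between counts and positions",
                 if (length(missing_bc)) paste0(" (e.g. missing: ",
                                                missing_bc[1], ")")))
  }
  if (!setequal(regions$barcode, bc) || anyDuplicated(regions$barcode)) {
    missing_bc <- setdiff(bc, regions$barcode)
    abort(paste0("barcode mismatch between counts and region annotations",
                 if (length(missing_bc)) paste0(" (e.g. missing: ",
                                                missing_bc[1], ")")))
  }
  coords <- coords[match(bc, coords$barcode), ]
  regions <- regions[match(bc, regions$barcode), ]
  if (any(!is.finite(coords$x_um)) || any(!is.finite(coords$y_um))) {
    abort("spot coordinates must be finite")
  }
  spots <- tibble(barcode = bc, x_um = coords$x_um, y_um = coords$y_um,
                  region = as.character(regions$region))
  structure(
    list(section_id = section_id, timepoint = timepoint, z_um = z_um,
         counts = counts, spots = spots, genes = colnames(counts)),
    class = "section_dataset")
}

#' @export
print.section_dataset <- function(x, ...) {
  cat(sprintf("<section_dataset> %s  timepoint=%s  z=%g um  %d spots x %d genes  regions: %s\n",
              x$section_id, x$timepoint, x$z_um, nrow(x$counts),
              ncol(x$counts), paste(sort(unique(x$spots$region)), collapse = ", ")))
  invisible(x)
}

#' Load one section from Matrix Market counts plus positions and regions
#'
#' @param counts_dir directory containing `matrix.mtx`, `barcodes.tsv` and
#'   `features.tsv` (genes in MTX rows, spots in columns, CellRanger-style).
#' @param positions_path Space-Ranger-style tissue positions CSV with columns
#'   barcode, in_tissue, array_row, array_col, pxl_row, pxl_col. Only
#'   `in_tissue == 1` spots are retained; the retained/rejected split is
#'   recorded in the `n_rejected` attribute.
#' @param regions_path CSV with columns barcode, region.
#' @param meta named list with `section_id`, `timepoint`, `z_um` and
#'   optionally `um_per_px` (pixel-to-micrometre scale, default 1).
#' @return a validated [section_dataset] (attribute `n_rejected` holds the
#'   number of out-of-tissue spots dropped).
#' @export
load_section <- function(counts_dir, positions_path, regions_path, meta) {
  for (p in c(file.path(counts_dir, c("matrix.mtx", "barcodes.tsv", "features.tsv")),
              positions_path, regions_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  m <- Matrix::readMM(file.path(counts_dir, "matrix.mtx"))
  barcodes <- readr::read_tsv(file.path(counts_dir, "barcodes.tsv"),
                              col_names = "barcode", show_col_types = FALSE)$barcode
  features <- readr::read_tsv(file.path(counts_dir, "features.tsv"),
                              col_names = FALSE, show_col_types = FALSE)[[1]]
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    abort("matrix.mtx dimensions do not match barcodes/features files")
  }
  counts <- t(as.matrix(m))
  dimnames(counts) <- list(barcodes, features)

  pos <- readr::read_csv(positions_path, show_col_types = FALSE)
  need <- c("barcode", "in_tissue", "pxl_row", "pxl_col")
  if (!all(need %in% names(pos))) {
    abort(paste0("positions file must have columns: ", paste(need, collapse = ", ")))
  }
  reg <- readr::read_csv(regions_path, show_col_types = FALSE)
  if (!all(c("barcode", "region") %in% names(reg))) {
    abort("regions file must have columns: barcode, region")
  }

  in_tissue <- pos$barcode[pos$in_tissue == 1]
  keep <- intersect(rownames(counts), in_tissue)
  n_rejected <- nrow(counts) - length(keep)
  if (length(keep) == 0L) abort("no in-tissue spots after filtering")
  missing_pos <- setdiff(rownames(counts), pos$barcode)
  if (length(missing_pos) > 0L) {
    abort(paste0("barcode mismatch: positions file missing barcode '",
                 missing_pos[1], "' present in counts"))
  }
  counts <- counts[keep, , drop = FALSE]
  um_per_px <- meta$um_per_px %||% 1
  pos <- pos[match(keep, pos$barcode), ]
  coords <- tibble(barcode = keep,
                   x_um = pos$pxl_col * um_per_px,
                   y_um = pos$pxl_row * um_per_px)
  regions <- reg[reg$barcode %in% keep, c("barcode", "region")]
  ds <- section_dataset(counts, coords, regions,
                        section_id = meta$section_id,
                        timepoint = meta$timepoint, z_um = meta$z_um)
  attr(ds, "n_rejected") <- n_rejected
  ds
}

#' Write a section dataset to disk in the formats [load_section()] reads
#'
#' @param ds a [section_dataset].
#' @param dir output directory (created if absent); counts go to
#'   `counts/matrix.mtx` + TSVs, positions and regions to CSVs.
#' @return invisibly, a named list of the paths written.
#' @export
write_section <- function(ds, dir) {
  cdir <- file.path(dir, "counts")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(t(ds$counts), sparse = TRUE),
                  file.path(cdir, "matrix.mtx"))
  readr::write_tsv(tibble(barcode = rownames(ds$counts)),
                   file.path(cdir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(gene = colnames(ds$counts)),
                   file.path(cdir, "features.tsv"), col_names = FALSE)
  pos <- tibble(barcode = ds$spots$barcode, in_tissue = 1L,
                array_row = 0L, array_col = 0L,
                pxl_row = ds$spots$y_um, pxl_col = ds$spots$x_um)
  readr::write_csv(pos, file.path(dir, "tissue_positions.csv"))
  readr::write_csv(ds$spots[, c("barcode", "region")],
                   file.path(dir, "regions.csv"))
  invisible(list(counts_dir = cdir,
                 positions = file.path(dir, "tissue_positions.csv"),
                 regions = file.path(dir, "regions.csv")))
}

#' Assemble a multi-section dataset from a manifest
#'
#' The manifest is a JSON array of records with fields `section_id`,
#' `timepoint`, `z_um`, `counts_dir`, `positions`, `regions` and optional
#' `um_per_px`. Sections are grouped by time point and ordered by `z_um`
#' within each group; the gene-universe policy is applied within time points
#' and recorded in the result.
#'
#' @param manifest_path path to the manifest JSON.
#' @param gene_universe `"intersection"` (default) or `"union"`: how the
#'   shared gene universe is formed across sections of a time point.
#' @return object of class `multisection_dataset`: list with `sections`
#'   (named list of [section_dataset]), `by_timepoint` (tibble: section_id,
#'   timepoint, z_um), `gene_universe` policy string and `genes` (named list
#'   of gene vectors per timepoint).
#' @export
load_multisection <- function(manifest_path,
                              gene_universe = c("intersection", "union")) {
  gene_universe <- match.arg(gene_universe)
  if (!file.exists(manifest_path)) abort(paste0("file not found: ", manifest_path))
  man <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = TRUE)
  if (is.null(man) || NROW(man) == 0L) abort("empty manifest")
  man <- as_tibble(man)
  if (anyDuplicated(man$section_id)) {
    abort(paste0("duplicate section_id in manifest: ",
                 man$section_id[duplicated(man$section_id)][1]))
  }
  dup_z <- man |> group_by(.data$timepoint, .data$z_um) |>
    summarise(n = n(), .groups = "drop") |> filter(.data$n > 1L)
  if (nrow(dup_z) > 0L) {
    abort(paste0("duplicate z_um ", dup_z$z_um[1], " within timepoint '",
                 dup_z$timepoint[1], "'"))
  }
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  sections <- purrr::pmap(man, function(section_id, timepoint, z_um,
                                        counts_dir, positions, regions, ...) {
    extra <- list(...)
    load_section(resolve(counts_dir), resolve(positions), resolve(regions),
                 meta = list(section_id = section_id, timepoint = timepoint,
                             z_um = z_um, um_per_px = extra$um_per_px %||% 1))
  })
  names(sections) <- man$section_id
  new_multisection(sections, gene_universe)
}

#' Build a multi-section dataset from in-memory sections
#'
#' @param sections list of [section_dataset] objects.
#' @param gene_universe `"intersection"` or `"union"` within time points.
#' @return a `multisection_dataset`; see [load_multisection()].
#' @export
new_multisection <- function(sections,
                             gene_universe = c("intersection", "union")) {
  gene_universe <- match.arg(gene_universe)
  by_tp <- tibble(
    section_id = unname(map_chr(sections, "section_id")),
    timepoint = unname(map_chr(sections, "timepoint")),
    z_um = unname(map_dbl(sections, "z_um"))) |>
    arrange(.data$timepoint, .data$z_um)
  sections <- sections[match(by_tp$section_id, names(sections) %||%
                               map_chr(sections, "section_id"))]
  names(sections) <- by_tp$section_id
  genes <- by_tp |> group_by(.data$timepoint) |>
    summarise(ids = list(.data$section_id), .groups = "drop")
  universe <- setNames(
    map(genes$ids, function(ids) {
      sets <- map(sections[ids], "genes")
      Reduce(if (gene_universe == "intersection") intersect else union, sets)
    }),
    genes$timepoint)
  structure(list(sections = sections, by_timepoint = by_tp,
                 gene_universe = gene_universe, genes = universe),
            class = "multisection_dataset")
}

#' @export
print.multisection_dataset <- function(x, ...) {
  cat(sprintf("<multisection_dataset> %d sections, %d timepoints (%s), gene universe: %s\n",
              length(x$sections), length(unique(x$by_timepoint$timepoint)),
              paste(unique(x$by_timepoint$timepoint), collapse = ", "),
              x$gene_universe))
  invisible(x)
}

#' Load a ligand-receptor pair database (CellTalkDB-style TSV)
#'
#' Expects columns `ligand_gene_symbol` and `receptor_gene_symbol`. Pair
#' identity is case-insensitive (symbols are uppercased for deduplication and
#' downstream matching); the raw case of first occurrence is preserved. Rows
#' with an empty ligand or receptor are skipped with a warning.
#'
#' @param path TSV file path.
#' @return tibble with columns `ligand`, `receptor`, `pair_id` ("L_R",
#'   uppercased), in file order; attribute `n_skipped` counts dropped rows.
#' @export
load_lr_database <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("ligand_gene_symbol", "receptor_gene_symbol")
  if (!all(need %in% names(tab))) {
    abort(paste0("LR database must have columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(tab) == 0L) abort("empty LR database")
  bad <- is.na(tab$ligand_gene_symbol) | tab$ligand_gene_symbol == "" |
    is.na(tab$receptor_gene_symbol) | tab$receptor_gene_symbol == ""
  if (any(bad)) {
    warn(paste0("skipped ", sum(bad), " LR rows with empty ligand or receptor"))
    tab <- tab[!bad, ]
  }
  out <- tibble(ligand = tab$ligand_gene_symbol,
                receptor = tab$receptor_gene_symbol) |>
    mutate(pair_id = paste0(toupper(.data$ligand), "_", toupper(.data$receptor))) |>
    distinct(.data$pair_id, .keep_all = TRUE)
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Load a local cell-type marker database
#'
#' A two-column TSV (`cell_type`, `gene`) mapping each cell type to its
#' marker genes; gene symbols are matched case-insensitively downstream.
#'
#' @param path TSV file path.
#' @return named list of character vectors (cell type -> marker genes).
#' @export
load_marker_db <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("cell_type", "gene") %in% names(tab))) {
    abort("marker database must have columns: cell_type, gene")
  }
  if (nrow(tab) == 0L) abort("empty marker database")
  db <- split(tab$gene, tab$cell_type)
  db <- map(db, unique)
  if (any(lengths(db) == 0L)) abort("marker database has a cell type with no genes")
  db
}

#' Load pathway-set lists
#'
#' Accepts either a plain-text file with one pathway ID per line, or a JSON
#' file whose top level is an array of IDs or a named object of arrays.
#'
#' @param path file path (`.json` parsed as JSON, anything else as lines).
#' @return character vector of pathway IDs (or a named list of them for a
#'   JSON object), whitespace-trimmed, empty entries dropped.
#' @export
load_pathway_sets <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.list(x)) return(map(x, function(v) trimws(as.character(v))))
    return(trimws(as.character(x)))
  }
  lines <- trimws(readLines(path))
  lines[nzchar(lines)]
}
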