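# Shared internal helpers.

#' Library-size normalise and log-transform a counts matrix
#'
#' Counts are scaled per spot to a common library size (default 1e4) and
#' transformed with `log1p()`. This is the expression scale used for
#' pseudotime, transition-gene correlation and ligand-receptor intensity.
#'
#' @param counts spots-by-genes matrix (dense or `Matrix` sparse) of
#'   non-negative integer counts, spots in rows.
#' @param scale_factor target library size per spot.
#' @return dense numeric matrix, same dimnames, log-normalised.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  counts <- as.matrix(counts)
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  log1p(counts / lib * scale_factor)
}

# deterministic chain <-> string encoding used in all output tables
chain_to_string <- function(chain) paste(chain, collapse = ">")
string_to_chain <- function(s) strsplit(s, ">", fixed = TRUE)[[1]]

# is `short` an order-preserving subsequence of `long`?
is_subsequence <- function(short, long) {
  if (length(short) > length(long)) return(FALSE)
  pos <- match(short[1], long)
  j <- 0L
  for (el in short) {
    hits <- which(long == el)
    hits <- hits[hits > j]
    if (length(hits) == 0L) return(FALSE)
    j <- hits[1]
  }
  TRUE
}

# spots within `radius` of each other, across two coordinate sets;
# returns count of cross pairs
count_cross_pairs <- function(xy_a, xy_b, radius) {
  if (nrow(xy_a) == 0L || nrow(xy_b) == 0L) return(0L)
  d2 <- outer(xy_a[, 1], xy_b[, 1], "-")^2 + outer(xy_a[, 2], xy_b[, 2], "-")^2
  sum(d2 <= radius^2)
}

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(paste0("`", what, "` must be a single string"))
  }
}
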