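#' Inter-chromosomal contact matrices
#'
#' An `inter_contacts` object holds raw (or pre-normalised) Hi-C contact
#' values between bins of an odd-parity row grid and an even-parity column
#' grid (or the transpose). All entries must be finite and non-negative.
#'
#' @param counts Numeric matrix, `nrow(row_grid)` by `nrow(col_grid)`.
#' @param row_grid,col_grid `bin_grid` objects for rows and columns.
#' @return An object of class `inter_contacts`.
#' @seealso [load_contacts()], [downsample_contacts()], [contact_probability()]
#' @export
inter_contacts <- function(counts, row_grid, col_grid) {
  counts <- as.matrix(counts)
  stopifnot(inherits(row_grid, "bin_grid"), inherits(col_grid, "bin_grid"))
  if (nrow(counts) != nrow(row_grid) || ncol(counts) != nrow(col_grid))
    stop(sprintf("counts is %dx%d but grids imply %dx%d",
                 nrow(counts), ncol(counts), nrow(row_grid), nrow(col_grid)))
  if (any(!is.finite(counts))) stop("contact values must be finite")
  if (any(counts < 0)) stop("contact values must be non-negative")
  structure(list(counts = counts, row_grid = row_grid, col_grid = col_grid,
                 coverage = sum(counts)),
            class = "inter_contacts")
}

#' Load contact triplets onto a bin-grid pair
#'
#' Reads whitespace-separated contact records into a dense inter-chromosomal
#' matrix. Two layouts are accepted: five columns
#' `chrom_i start_i chrom_j start_j count` (genomic coordinates, as dumped by
#' the standard `.hic`/cooler extractors at a fixed resolution) or three
#' columns `i j count` with 1-based indices into the two grids. Duplicate
#' records for one cell are summed; unreferenced cells are zero.
#'
#' @param x Path to a text file (optionally gzipped), a connection, or a
#'   data frame already holding the columns above.
#' @param row_grid,col_grid Target grids (rows odd parity, columns even, or
#'   the transpose).
#' @return An [inter_contacts()] object.
#' @export
load_contacts <- function(x, row_grid, col_grid) {
  if (is.character(x)) {
    con <- if (grepl("\\.gz$", x)) gzfile(x) else file(x)
    tab <- utils::read.table(con, header = FALSE, stringsAsFactors = FALSE)
  } else if (inherits(x, "connection")) {
    tab <- utils::read.table(x, header = FALSE, stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(x)
  }
  counts <- matrix(0, nrow(row_grid), nrow(col_grid))
  if (nrow(tab) > 0) {
    if (ncol(tab) == 5) {
      i <- grid_index(row_grid, tab[[1]], as.numeric(tab[[2]]))
      j <- grid_index(col_grid, tab[[3]], as.numeric(tab[[4]]))
      v <- as.numeric(tab[[5]])
    } else if (ncol(tab) == 3) {
      i <- as.integer(tab[[1]]); j <- as.integer(tab[[2]])
      i[i < 1 | i > nrow(row_grid)] <- NA
      j[j < 1 | j > nrow(col_grid)] <- NA
      v <- as.numeric(tab[[3]])
    } else {
      stop("expected 3 or 5 columns of triplet data, got ", ncol(tab))
    }
    bad <- which(is.na(i) | is.na(j))
    if (length(bad) > 0)
      stop("triplet line ", bad[1], " references a bin outside the grids: ",
           paste(unlist(tab[bad[1], ]), collapse = " "))
    if (any(v < 0))
      stop("negative count at triplet line ", which(v < 0)[1])
    # duplicates for one cell accumulate
    cell <- (j - 1L) * nrow(row_grid) + i
    agg <- rowsum(v, cell)
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  inter_contacts(counts, row_grid, col_grid)
}

#' Write contacts as triplet text
#'
#' Writes the non-zero cells of a contact matrix in the five-column
#' `chrom_i start_i chrom_j start_j count` layout accepted by
#' [load_contacts()], so matrices round-trip through text.
#'
#' @param m An `inter_contacts` object.
#' @param path Output file path (`.gz` for gzipped output).
#' @export
write_contacts <- function(m, path) {
  stopifnot(inherits(m, "inter_contacts"))
  nz <- which(m$counts != 0, arr.ind = TRUE)
  tab <- data.frame(chrom_i = m$row_grid$chrom[nz[, 1]],
                    start_i = m$row_grid$start[nz[, 1]],
                    chrom_j = m$col_grid$chrom[nz[, 2]],
                    start_j = m$col_grid$start[nz[, 2]],
                    count   = m$counts[nz])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Binomial downsampling of contact counts
#'
#' Simulates a lower-coverage Hi-C experiment by thinning every cell of the
#' contact matrix: each of the `C_ij` read pairs in a cell is kept
#' independently with probability `keep_rate`, i.e. the cell is replaced by a
#' Binomial(`C_ij`, `keep_rate`) draw. This matches the marginal distribution
#' of sampling a fraction of the original read pairs. Non-integer counts are
#' rounded before thinning.
#'
#' @param m An `inter_contacts` object.
#' @param keep_rate Fraction of reads to keep, in `[0, 1]`.
#' @param seed Integer seed (identical seed gives identical output), or NULL
#'   to draw from the current RNG stream.
#' @return A thinned `inter_contacts` object on the same grids.
#' @export
downsample_contacts <- function(m, keep_rate, seed = NULL) {
  stopifnot(inherits(m, "inter_contacts"))
  if (!is.numeric(keep_rate) || length(keep_rate) != 1L ||
      is.na(keep_rate) || keep_rate < 0 || keep_rate > 1)
    stop("'keep_rate' must be a single number in [0, 1]")
  n <- round(m$counts)
  kept <- with_seed(seed, {
    out <- n
    nz <- n > 0
    out[nz] <- stats::rbinom(sum(nz), size = n[nz], prob = keep_rate)
    out
  })
  inter_contacts(kept, m$row_grid, m$col_grid)
}

#' Contact-probability transform
#'
#' Maps raw contact counts to contact probabilities via
#' `P_ij = exp(-1 / C_ij)` for `C_ij > 0` and `P_ij = 0` for `C_ij = 0`
#' (the analytic limit as the count goes to zero; no pseudocount is added,
#' preserving sparsity). The transform is strictly increasing in the count
#' and maps onto `[0, 1)`, compressing extreme Hi-C signals so that
#' reconstruction networks can be optimised with binary cross-entropy.
#'
#' @param m An `inter_contacts` object (non-negative values).
#' @return An object of class `contact_prob` with element `probs` in `[0, 1)`
#'   and the same grids.
#' @examples
#' g1 <- bin_grid(c(chr1 = 2e5)); g2 <- bin_grid(c(chr2 = 2e5))
#' m <- inter_contacts(matrix(c(0, 1, 2, 3), 2), g1, g2)
#' contact_probability(m)$probs[2, 1]  # exp(-1) for a count of 1
#' @export
contact_probability <- function(m) {
  stopifnot(inherits(m, "inter_contacts"))
  p <- matrix(0, nrow(m$counts), ncol(m$counts))
  nz <- m$counts > 0
  p[nz] <- exp(-1 / m$counts[nz])
  structure(list(probs = p, row_grid = m$row_grid, col_grid = m$col_grid),
            class = "contact_prob")
}

#' @method t inter_contacts
#' @export
t.inter_contacts <- function(x) {
  structure(list(counts = t(x$counts), row_grid = x$col_grid,
                 col_grid = x$row_grid, coverage = x$coverage),
            class = "inter_contacts")
}

#' @method t contact_prob
#' @export
t.contact_prob <- function(x) {
  structure(list(probs = t(x$probs), row_grid = x$col_grid,
                 col_grid = x$row_grid),
            class = "contact_prob")
}

#' @export
dim.inter_contacts <- function(x) dim(x$counts)

#' @export
dim.contact_prob <- function(x) dim(x$probs)

#' @export
print.inter_contacts <- function(x, ...) {
  cat(sprintf("inter_contacts: %d x %d bins, %s total contacts\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

# Bins with non-zero marginal count: only these are informative for the
# networks (centromeric/unmappable bins have identically-zero probability
# rows and are annotated NA downstream).
covered_rows <- function(m) rowSums(m$counts) > 0
covered_cols <- function(m) colSums(m$counts) > 0
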