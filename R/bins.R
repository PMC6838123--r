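#' Fixed-width genomic bin grids
#'
#' A bin grid tiles a set of chromosomes with fixed-width, 0-based, half-open
#' bins `[start, start + bin_size)`. Inter-chromosomal contact matrices in
#' this package place odd-numbered autosomes on the rows and even-numbered
#' autosomes on the columns, so a grid is restricted to chromosomes of a
#' single parity. The final bin of each chromosome may be shorter than
#' `bin_size`; it is kept and flagged in the `short` column.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in base
#'   pairs, or a two-column data frame (`chrom`, `size`). Chromosome order is
#'   taken as given and defines row/column order of matrices on the grid.
#' @param bin_size Bin width in base pairs (default 100000, i.e. 100 kb).
#' @param parity `"odd"` or `"even"`; all chromosomes must match. If `NULL`
#'   the parity is inferred from the first chromosome.
#' @return An object of class `bin_grid`: a data frame with columns `chrom`,
#'   `start`, `end`, `short`, plus attributes `bin_size` and `parity`.
#' @examples
#' g <- bin_grid(c(chr1 = 250000, chr3 = 130000), bin_size = 1e5)
#' nrow(g)   # 4 bins: chr1 has 3 (last short), chr3 has 2 (last short)
#' @export
bin_grid <- function(chrom_sizes, bin_size = 1e5, parity = NULL) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- as.numeric(chrom_sizes[[2]])
    names(sizes) <- as.character(chrom_sizes[[1]])
    chrom_sizes <- sizes
  }
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == ""))
    stop("'chrom_sizes' must be named by chromosome")
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  if (bin_size <= 0) stop("'bin_size' must be positive")
  pars <- vapply(names(chrom_sizes), chrom_parity, character(1))
  if (is.null(parity)) parity <- pars[[1]]
  parity <- match.arg(parity, c("odd", "even"))
  if (any(pars != parity))
    stop("all chromosomes on one grid must have parity '", parity, "'; got: ",
         paste(names(chrom_sizes)[pars != parity], collapse = ", "))
  per <- lapply(names(chrom_sizes), function(ch) {
    sz <- chrom_sizes[[ch]]
    starts <- seq(0, sz - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, sz),
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, per)
  g$short <- (g$end - g$start) < bin_size
  rownames(g) <- NULL
  structure(g, bin_size = bin_size, parity = parity,
            class = c("bin_grid", "data.frame"))
}

#' Chromosome parity (odd/even autosome group)
#'
#' @param chrom Chromosome name(s) such as `"chr7"` or `"7"`.
#' @return `"odd"` or `"even"` per element.
#' @export
chrom_parity <- function(chrom) {
  n <- suppressWarnings(as.integer(sub("^chr", "", chrom)))
  if (any(is.na(n)))
    stop("cannot infer parity of chromosome name(s): ",
         paste(chrom[is.na(n)], collapse = ", "))
  ifelse(n %% 2L == 1L, "odd", "even")[seq_along(chrom)]
}

# Row/column position of (chrom, start) pairs on a grid; NA where absent.
# Keys are formatted without scientific notation so integer- and
# double-typed coordinates compare equal.
grid_index <- function(grid, chrom, start) {
  match(sprintf("%s:%.0f", chrom, as.numeric(start)),
        sprintf("%s:%.0f", grid$chrom, as.numeric(grid$start)))
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d bins of %s bp on %d %s chromosome(s)\n",
              nrow(x), format(attr(x, "bin_size"), big.mark = ","),
              length(unique(x$chrom)), attr(x, "parity")))
  invisible(x)
}
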