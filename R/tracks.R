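#' Per-bin subcompartment annotation tracks
#'
#' An annotation track assigns each 100 kb bin a subcompartment label (or NA
#' for uncovered/unmappable bins) and, optionally, the five class
#' probabilities. Coordinates are 0-based half-open.
#'
#' @param bins Data frame with columns `chrom`, `start`, `end` (a `bin_grid`
#'   works), or a list of grids to be concatenated.
#' @param label Vector of labels on the [subcompartments()] levels (NA
#'   allowed), one per bin.
#' @param prob Optional matrix of class probabilities (columns A1..B3); rows
#'   with a label must sum to 1.
#' @param cell_type Optional cell-type tag stored as an attribute.
#' @return A data frame of class `subcomp_track`.
#' @export
subcomp_track <- function(bins, label, prob = NULL, cell_type = NULL) {
  if (is.list(bins) && !is.data.frame(bins))
    bins <- do.call(rbind, lapply(bins, function(g)
      data.frame(chrom = g$chrom, start = g$start, end = g$end)))
  tr <- data.frame(chrom = as.character(bins$chrom),
                   start = bins$start, end = bins$end,
                   label = as_subcompartment(label),
                   stringsAsFactors = FALSE)
  if (!is.null(prob)) {
    prob <- as.matrix(prob)
    stopifnot(nrow(prob) == nrow(tr), ncol(prob) == 5)
    ok <- !is.na(tr$label)
    if (any(ok) && any(abs(rowSums(prob[ok, , drop = FALSE]) - 1) > 1e-6))
      stop("probability rows of labelled bins must sum to 1")
    colnames(prob) <- paste0("p.", subcompartments())
    tr <- cbind(tr, prob)
  }
  rownames(tr) <- NULL
  structure(tr, cell_type = cell_type,
            class = c("subcomp_track", "data.frame"))
}

# Labels of a track at the bins of a grid (matched on chrom + start).
track_labels <- function(track, grid) {
  idx <- grid_index(track, grid$chrom, grid$start)
  lab <- track$label[idx]
  factor(as.character(lab), levels = subcompartments())
}

#' Write an annotation track as BED (and optionally extended TSV)
#'
#' The BED name field carries the subcompartment label and the score field
#' the maximum class probability (when available). Bins with NA labels are
#' omitted from the BED. `tsv` additionally writes every column of the track,
#' including the full five-class probability vector.
#'
#' @param track A [subcomp_track()].
#' @param path Output BED path.
#' @param tsv Optional path for the extended TSV.
#' @export
write_track_bed <- function(track, path, tsv = NULL) {
  keep <- !is.na(track$label)
  gr <- GenomicRanges::GRanges(
    track$chrom[keep],
    IRanges::IRanges(start = track$start[keep] + 1, end = track$end[keep]),
    name = as.character(track$label[keep]))
  pc <- paste0("p.", subcompartments())
  S4Vectors::mcols(gr)$score <- if (all(pc %in% names(track)))
    apply(as.matrix(track[keep, pc]), 1, max) else rep(0, sum(keep))
  rtracklayer::export(gr, path, format = "BED")
  if (!is.null(tsv))
    utils::write.table(as.data.frame(track), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a subcompartment annotation BED
#'
#' Reads a BED file whose name field holds subcompartment labels (such as a
#' reference annotation) into a [subcomp_track()]. When `bins` is given, the
#' labels are placed onto that bin set and unannotated bins become NA.
#'
#' @param path BED file path.
#' @param bins Optional target bins (e.g. the row and column grids as a
#'   list); defaults to the intervals present in the file.
#' @return A `subcomp_track`.
#' @export
read_track_bed <- function(path, bins = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    label = gr$name, stringsAsFactors = FALSE)
  if (is.null(bins))
    return(subcomp_track(tab[, 1:3], tab$label))
  if (is.list(bins) && !is.data.frame(bins))
    bins <- do.call(rbind, lapply(bins, function(g)
      data.frame(chrom = g$chrom, start = g$start, end = g$end)))
  idx <- grid_index(tab, bins$chrom, bins$start)
  subcomp_track(bins, tab$label[idx])
}

#' Read a per-bin signal track (bedGraph/BED4)
#'
#' Imports a bedGraph (or 4-column BED) and averages its values onto a bin
#' set: each bin's value is the width-weighted mean of overlapping records;
#' bins without overlap are NA.
#'
#' @param path bedGraph file path.
#' @param bins Target bins (data frame with `chrom`, `start`, `end`).
#' @return Numeric vector of per-bin values aligned to `bins`.
#' @export
read_signal_bedgraph <- function(path, bins) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tgt <- GenomicRanges::GRanges(
    bins$chrom, IRanges::IRanges(start = bins$start + 1, end = bins$end))
  hits <- GenomicRanges::findOverlaps(tgt, gr)
  ov <- GenomicRanges::pintersect(tgt[S4Vectors::queryHits(hits)],
                                  gr[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(ov)
  v <- gr$score[S4Vectors::subjectHits(hits)]
  num <- rowsum(w * v, S4Vectors::queryHits(hits))
  den <- rowsum(w, S4Vectors::queryHits(hits))
  out <- rep(NA_real_, nrow(bins))
  out[as.integer(rownames(num))] <- num[, 1] / den[, 1]
  out
}

#' Write a per-bin numeric track as bedGraph
#'
#' @param bins Data frame with `chrom`, `start`, `end`.
#' @param value Numeric vector per bin (NA bins are skipped).
#' @param path Output path.
#' @export
write_bedgraph <- function(bins, value, path) {
  keep <- !is.na(value)
  gr <- GenomicRanges::GRanges(
    bins$chrom[keep],
    IRanges::IRanges(start = bins$start[keep] + 1, end = bins$end[keep]),
    score = value[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @export
print.subcomp_track <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("subcomp_track: %d bins (%d labelled)%s\n", n,
              sum(!is.na(x$label)),
              if (!is.null(attr(x, "cell_type")))
                paste0(", cell type ", attr(x, "cell_type")) else ""))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (n > 4) cat("...\n")
  invisible(x)
}
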