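#' Annotation entropy of a label-fraction vector
#'
#' The cross-cell-type conservation of a bin's subcompartment annotation is
#' summarised by the Shannon entropy (natural log) of its label fractions:
#' `S = sum_c -p_c * log(p_c)` with the convention `0 * log 0 = 0`. A
#' unanimous bin has entropy 0; more even annotation splits have higher
#' entropy.
#'
#' @param p Numeric vector of label fractions (must be non-negative and sum
#'   to 1), or a matrix with one fraction vector per row.
#' @return Entropy value(s) in nats.
#' @export
annotation_entropy <- function(p) {
  p <- if (is.matrix(p)) p else matrix(p, nrow = 1)
  if (any(p < 0)) stop("fractions must be non-negative")
  if (any(abs(rowSums(p) - 1) > 1e-8))
    stop("fraction vectors must sum to 1")
  s <- -p * log(p)
  s[p == 0] <- 0
  out <- rowSums(s)
  if (nrow(p) == 1) out[[1]] else out
}

#' Information content of a label fraction
#'
#' `IC = |p * log(p / q)|` with natural log, background `q = 0.2` (uniform
#' over the five subcompartments) and the convention that `p = 0` gives 0.
#' Analogous to position-weight-matrix information content: high values mark
#' bins whose annotation is strongly conserved across cell types.
#'
#' @param p Label fraction(s) in `[0, 1]` (vector or matrix).
#' @param q Background probability, strictly positive (default 0.2).
#' @return Information content, elementwise; ranges over `[0, log(1/q)]`.
#' @export
information_content <- function(p, q = 0.2) {
  if (q <= 0) stop("'q' must be strictly positive")
  if (any(p < 0 | p > 1)) stop("fractions must lie in [0, 1]")
  ic <- abs(p * log(p / q))
  ic[p == 0] <- 0
  ic
}

#' Enumerate annotation count multisets and the conservation-state catalogue
#'
#' With `n_types` cell types annotated into `n_labels` classes, the per-bin
#' count vector takes finitely many values; entropy depends only on the count
#' multiset (the partition of `n_types` into at most `n_labels` parts). This
#' enumerates every multiset, computes its entropy, and assigns conservation
#' states: multisets whose maximum count is not a majority (strictly more
#' than half the cell types; fewer than 5 of 9 in the nine-cell-type case)
#' are merged into the single non-conserved state `"NC"`, and the remaining
#' multisets are numbered `"1", "2", ...` by ascending entropy (state 1 =
#' most conserved). For nine cell types this yields 23 distinct entropy
#' values, of which 11 lack a majority, leaving 12 numbered states plus NC.
#'
#' @param n_types Number of cell types (default 9).
#' @param n_labels Number of annotation classes (default 5).
#' @return Data frame of class `conservation_catalog` with one row per count
#'   multiset: `counts` (decreasing, comma-separated key), `max_count`,
#'   `entropy`, `majority`, and `state`.
#' @export
conservation_state_catalog <- function(n_types = 9, n_labels = 5) {
  if (n_types < 2) stop("need at least 2 cell types")
  parts <- partitions_max_parts(n_types, n_labels)
  entro <- vapply(parts, function(cnt)
    annotation_entropy(c(cnt, rep(0, n_labels - length(cnt))) / n_types),
    numeric(1))
  maxc <- vapply(parts, max, numeric(1))
  cat <- data.frame(
    counts = vapply(parts, paste, character(1), collapse = ","),
    max_count = maxc,
    entropy = entro,
    majority = maxc > n_types / 2,
    stringsAsFactors = FALSE)
  cat <- cat[order(cat$entropy), ]
  cat$state <- ifelse(cat$majority, NA_character_, "NC")
  cat$state[cat$majority] <- as.character(seq_len(sum(cat$majority)))
  rownames(cat) <- NULL
  structure(cat, n_types = n_types, n_labels = n_labels,
            class = c("conservation_catalog", "data.frame"))
}

# All partitions of n into at most k positive parts, each sorted decreasing.
partitions_max_parts <- function(n, k) {
  rec <- function(n, k, maxpart) {
    if (n == 0) return(list(integer(0)))
    if (k == 0) return(list())
    out <- list()
    for (first in seq_len(min(n, maxpart))) {
      for (rest in rec(n - first, k - 1, first))
        out[[length(out) + 1L]] <- c(first, rest)
    }
    out
  }
  rec(n, k, n)
}

#' Cross-cell-type conservation profile
#'
#' Tallies subcompartment annotations across several cell types on a shared
#' bin set and derives, per bin: label counts, fractions, annotation entropy,
#' information content per label, the modal label, and the conservation state
#' from [conservation_state_catalog()]. Bins where any cell type is NA are
#' flagged incomplete and excluded from state assignment (their entropy,
#' computed over the annotated subset, is still reported).
#'
#' @param tracks List of at least two [subcomp_track()] objects on one bin
#'   set (same chrom/start/end in the same order).
#' @param q Background probability for information content (default 0.2).
#' @return Data frame of class `conservation_profile`: bin coordinates,
#'   `n.<label>` counts, `n_total`, `complete`, `p.<label>` fractions,
#'   `entropy`, `mode`, `state`, and `ic.<label>` columns.
#' @export
conservation_profile <- function(tracks, q = 0.2) {
  if (!is.list(tracks) || length(tracks) < 2)
    stop("need a list of >= 2 annotation tracks")
  base <- tracks[[1]]
  for (tr in tracks[-1]) {
    if (nrow(tr) != nrow(base) ||
        !all(tr$chrom == base$chrom & tr$start == base$start))
      stop("all tracks must share one bin grid")
  }
  n_types <- length(tracks)
  labs <- vapply(tracks, function(tr) as.character(tr$label),
                 character(nrow(base)))
  if (!is.matrix(labs)) labs <- matrix(labs, nrow = nrow(base))
  counts <- t(apply(labs, 1, function(a)
    tabulate(factor(a, levels = subcompartments()), nbins = 5)))
  if (ncol(counts) != 5) counts <- t(counts)
  colnames(counts) <- paste0("n.", subcompartments())
  n_total <- rowSums(counts)
  complete <- n_total == n_types
  p <- counts / ifelse(n_total == 0, NA, n_total)
  colnames(p) <- paste0("p.", subcompartments())

  entropy <- rep(NA_real_, nrow(base))
  ok <- n_total > 0
  entropy[ok] <- annotation_entropy(p[ok, , drop = FALSE])

  ic <- information_content(ifelse(is.na(p), 0, p), q)
  ic[is.na(p)] <- NA
  colnames(ic) <- paste0("ic.", subcompartments())

  mode_lab <- rep(NA_character_, nrow(base))
  mode_lab[ok] <- subcompartments()[apply(counts[ok, , drop = FALSE], 1,
                                          which.max)]

  catalog <- conservation_state_catalog(n_types, 5)
  key <- apply(counts, 1, function(cnt)
    paste(sort(cnt[cnt > 0], decreasing = TRUE), collapse = ","))
  state <- catalog$state[match(key, catalog$counts)]
  state[!complete] <- NA_character_

  out <- data.frame(chrom = base$chrom, start = base$start, end = base$end,
                    stringsAsFactors = FALSE)
  out <- cbind(out, counts, n_total = n_total, complete = complete, p,
               entropy = entropy, mode = mode_lab, state = state, ic)
  rownames(out) <- NULL
  structure(out, n_types = n_types, q = q, catalog = catalog,
            class = c("conservation_profile", "data.frame"))
}

#' Write conservation results as genome-browser tracks
#'
#' Writes the conservation state as BED (state in the name field), the
#' annotation entropy as bedGraph, and one information-content bedGraph per
#' subcompartment label, under `prefix`.
#'
#' @param profile A [conservation_profile()].
#' @param prefix Output path prefix (e.g. `"out/conservation"`).
#' @return Invisibly, the vector of files written.
#' @export
write_conservation_tracks <- function(profile, prefix) {
  files <- character(0)
  keep <- !is.na(profile$state)
  bed <- paste0(prefix, "_states.bed")
  gr <- GenomicRanges::GRanges(
    profile$chrom[keep],
    IRanges::IRanges(start = profile$start[keep] + 1, end = profile$end[keep]),
    name = profile$state[keep])
  rtracklayer::export(gr, bed, format = "BED")
  files <- c(files, bed)
  bg <- paste0(prefix, "_entropy.bedGraph")
  write_bedgraph(profile, profile$entropy, bg)
  files <- c(files, bg)
  for (cl in subcompartments()) {
    f <- paste0(prefix, "_ic_", cl, ".bedGraph")
    write_bedgraph(profile, profile[[paste0("ic.", cl)]], f)
    files <- c(files, f)
  }
  invisible(files)
}
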