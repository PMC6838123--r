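#' Planted-subcompartment model for synthetic inter-chromosomal Hi-C
#'
#' Defines a generative block model for inter-chromosomal contact counts with
#' planted subcompartment structure: every bin carries one of the five
#' labels, arranged in contiguous domain-like runs, and the expected contact
#' count between two bins depends only on their label pair through a
#' symmetric positive rate matrix. Counts are Poisson-sampled so the expected
#' total equals `depth`. This emulates the compartmentalised block patterns
#' that inter-chromosomal maps of real genomes show - strong A1-A1 and A2-A2
#' affinity, strong B3-B3 affinity, intermediate B1, weak A-B cross terms -
#' without claiming real contact frequencies.
#'
#' Bins are laid out on pseudo-chromosomes with realistic decreasing sizes:
#' odd parity chr1,3,5,7 (about half the bins, the default training split)
#' plus held-out chr9,11,13,15; even parity chr2,4,6,8,10 plus held-out
#' chr12,14,16,18.
#'
#' @param n_odd,n_even Bins per parity (defaults 400 and 400).
#' @param depth Expected total read-pair count of the dense matrix (default
#'   2e6, i.e. a mean count of 12.5 per cell at the default size).
#' @param proportions Label proportions, summing to 1; the default mix leans
#'   on B3 being the largest class.
#' @param rate_matrix Symmetric positive 5x5 within/between-label contact
#'   propensities (rows/cols in [subcompartments()] order).
#' @param mean_run Mean label run length in bins (runs are `3 + Geometric`,
#'   so domains are at least 300 kb; default mean 7 bins = 700 kb).
#' @param bin_size Bin width in bp (default 1e5).
#' @param seed Integer seed stored in the model; generation is a pure
#'   function of (model, seed).
#' @return An object of class `planted_model`.
#' @export
planted_model <- function(n_odd = 400, n_even = 400, depth = 2e6,
                          proportions = c(A1 = 0.15, A2 = 0.20, B1 = 0.15,
                                          B2 = 0.20, B3 = 0.30),
                          rate_matrix = default_rate_matrix(),
                          mean_run = 7, bin_size = 1e5, seed = 1) {
  if (depth <= 0) stop("'depth' must be positive")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  rate_matrix <- as.matrix(rate_matrix)
  if (!all(dim(rate_matrix) == c(5, 5)))
    stop("rate_matrix must be 5x5")
  if (any(rate_matrix <= 0)) stop("rate_matrix must be positive")
  if (max(abs(rate_matrix - t(rate_matrix))) > 1e-12)
    stop("rate_matrix must be symmetric")
  if (mean_run < 3) stop("'mean_run' must be >= 3 (minimum run length)")
  structure(list(n_odd = n_odd, n_even = n_even, depth = depth,
                 proportions = proportions, rate_matrix = rate_matrix,
                 mean_run = mean_run, bin_size = bin_size, seed = seed),
            class = "planted_model")
}

#' Default planted contact-propensity matrix
#'
#' Diagonal-dominant, symmetric, positive: A1/A2 mutually close, B3 strongly
#' self-associating, B1 intermediate between the A and B blocks, and weak
#' A-B cross terms.
#'
#' @return A 5x5 numeric matrix on the [subcompartments()] labels.
#' @export
default_rate_matrix <- function() {
  m <- matrix(c(
    6.0, 3.5, 1.2, 0.6, 0.5,
    3.5, 5.0, 1.4, 0.8, 0.7,
    1.2, 1.4, 4.0, 1.8, 1.5,
    0.6, 0.8, 1.8, 4.5, 2.2,
    0.5, 0.7, 1.5, 2.2, 5.0), 5, 5,
    dimnames = list(subcompartments(), subcompartments()))
  m
}

# split n bins over pseudo-chromosomes with decreasing sizes so the default
# training chromosomes hold roughly half the bins
synthetic_chrom_sizes <- function(n, parity, bin_size) {
  chroms <- if (parity == "odd") paste0("chr", c(1, 3, 5, 7, 9, 11, 13, 15))
  else paste0("chr", c(2, 4, 6, 8, 10, 12, 14, 16, 18))
  frac <- if (parity == "odd") c(18, 14, 11, 8, 15, 13, 11, 10)
  else c(14, 12, 10, 9, 7, 14, 13, 11, 10)
  counts <- floor(n * frac / sum(frac))
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  sizes <- counts * bin_size
  names(sizes) <- chroms
  sizes[counts > 0]
}

# contiguous label runs, geometric length with minimum 3, per chromosome
plant_labels <- function(grid, proportions, mean_run) {
  p_geo <- 1 / (mean_run - 2)  # mean run = 3 + (1-p)/p ... approx mean_run
  lab <- character(nrow(grid))
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    pos <- 1L
    while (pos <= length(idx)) {
      len <- 3L + stats::rgeom(1, p_geo)
      cl <- sample(subcompartments(), 1, prob = proportions)
      lab[idx[pos:min(pos + len - 1L, length(idx))]] <- cl
      pos <- pos + len
    }
  }
  lab
}

#' Simulate a dense inter-chromosomal matrix with planted truth
#'
#' Draws labels in domain-like runs, then samples
#' `C_ij ~ Poisson(depth * R[label_i, label_j] / Z)` where the normaliser `Z`
#' makes the expected total count equal to `depth`. Consistently permuting
#' the labels and the rate matrix leaves the mean matrix unchanged.
#'
#' @param model A [planted_model()].
#' @return List with `contacts` (dense [inter_contacts()]) and `truth` (a
#'   [subcomp_track()] over all `n_odd + n_even` bins).
#' @export
simulate_hic <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  with_seed(model$seed, {
    row_grid <- bin_grid(synthetic_chrom_sizes(model$n_odd, "odd",
                                               model$bin_size),
                         bin_size = model$bin_size)
    col_grid <- bin_grid(synthetic_chrom_sizes(model$n_even, "even",
                                               model$bin_size),
                         bin_size = model$bin_size)
    lab_odd <- plant_labels(row_grid, model$proportions, model$mean_run)
    lab_even <- plant_labels(col_grid, model$proportions, model$mean_run)
    io <- match(lab_odd, subcompartments())
    ie <- match(lab_even, subcompartments())
    rates <- model$rate_matrix[io, ie, drop = FALSE]
    lambda <- model$depth * rates / sum(rates)
    counts <- matrix(stats::rpois(length(lambda), lambda),
                     nrow(row_grid), nrow(col_grid))
    truth <- subcomp_track(list(row_grid, col_grid), c(lab_odd, lab_even),
                           cell_type = "planted")
    list(contacts = inter_contacts(counts, row_grid, col_grid),
         truth = truth)
  })
}

#' Downsample a simulated dense matrix
#'
#' Thin wrapper over [downsample_contacts()] for assembling sparse fixtures.
#'
#' @param dense An [inter_contacts()].
#' @param keep_rate Fraction of reads kept.
#' @param seed Integer seed.
#' @return A sparse `inter_contacts`.
#' @export
simulate_sparse <- function(dense, keep_rate, seed = NULL)
  downsample_contacts(dense, keep_rate, seed = seed)

#' Simulate a per-bin signal track around planted labels
#'
#' Draws each bin's signal as Gaussian noise around its label's mean,
#' emulating a functional genomic mark (e.g. an active histone modification
#' high in A1/A2 and low in B2/B3).
#'
#' @param truth A [subcomp_track()] with planted labels.
#' @param means Named (or [subcompartments()]-ordered) vector of 5 per-label
#'   signal means.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Numeric vector of per-bin signal aligned to `truth` (NA where the
#'   label is NA).
#' @export
simulate_signal <- function(truth, means, noise_sd = 0.1, seed = NULL) {
  if (length(means) != 5) stop("supply 5 per-label means")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (!is.null(names(means))) means <- means[subcompartments()]
  with_seed(seed, {
    mu <- means[as.integer(truth$label)]
    out <- mu + stats::rnorm(nrow(truth), 0, noise_sd)
    out[is.na(truth$label)] <- NA
    as.numeric(out)
  })
}
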