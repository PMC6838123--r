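#' Confusion matrix between predicted and reference annotations
#'
#' Accuracy is the fraction of 100 kb bins whose predicted annotation matches
#' the reference. Bins that are NA in either track are excluded pairwise.
#'
#' @param pred,ref [subcomp_track()] objects (or factors of labels) on the
#'   same bin set.
#' @return An object of class `subcomp_confusion`: the 5x5 count matrix
#'   (reference in rows, prediction in columns), per-class accuracy
#'   (diagonal over row sum), and overall accuracy (trace over total).
#' @export
confusion_subcomp <- function(pred, ref) {
  p <- if (inherits(pred, "subcomp_track")) pred$label else as_subcompartment(pred)
  r <- if (inherits(ref, "subcomp_track")) ref$label else as_subcompartment(ref)
  if (length(p) != length(r))
    stop("prediction and reference must cover the same bins")
  keep <- !is.na(p) & !is.na(r)
  if (!any(keep)) stop("no overlapping non-NA bins to compare")
  tab <- table(reference = r[keep], predicted = p[keep])
  m <- matrix(as.numeric(tab), 5, 5,
              dimnames = list(reference = subcompartments(),
                              predicted = subcompartments()))
  per_class <- diag(m) / rowSums(m)
  structure(list(matrix = m, per_class = per_class,
                 overall = sum(diag(m)) / sum(m), n = sum(keep)),
            class = "subcomp_confusion")
}

#' @export
print.subcomp_confusion <- function(x, ...) {
  cat(sprintf("subcomp_confusion over %d bins; overall accuracy %.3f\n",
              x$n, x$overall))
  print(round(x$matrix))
  cat("per-class accuracy:",
      paste(sprintf("%s=%.3f", names(x$per_class), x$per_class),
            collapse = " "), "\n")
  invisible(x)
}

#' Area under the precision-recall curve, one-vs-rest per subcompartment
#'
#' For each class, bins of that reference class are the positives and the
#' class's predicted probability is the score. The PR curve is traced over
#' the distinct score thresholds and integrated with step-wise (not linear)
#' interpolation, `sum (R_k - R_{k-1}) * P_k`, which avoids optimistic areas.
#' A class absent from the reference is reported as NA rather than 0.
#'
#' @param prob Matrix of class probabilities (columns in [subcompartments()]
#'   order), or a `subcomp_track` carrying `p.*` columns.
#' @param ref Reference labels (`subcomp_track` or factor).
#' @return Named numeric vector of per-class AUPR in `[0, 1]`.
#' @export
aupr_subcomp <- function(prob, ref) {
  if (inherits(prob, "subcomp_track"))
    prob <- as.matrix(prob[, paste0("p.", subcompartments())])
  prob <- as.matrix(prob)
  r <- if (inherits(ref, "subcomp_track")) ref$label else as_subcompartment(ref)
  keep <- !is.na(r) & stats::complete.cases(prob)
  prob <- prob[keep, , drop = FALSE]; r <- r[keep]
  vapply(seq_along(subcompartments()), function(k) {
    y <- r == subcompartments()[k]
    if (!any(y)) return(NA_real_)
    aupr_step(prob[, k], y)
  }, numeric(1)) -> out
  names(out) <- subcompartments()
  out
}

# Step-interpolated AUPR from scores and binary truth (cumulative-sum form).
aupr_step <- function(score, truth) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- truth[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  # evaluate at the last index of each distinct score (threshold = score >= s)
  last <- which(diff(s) != 0)
  idx <- c(last, length(s))
  prec <- tp[idx] / (tp[idx] + fp[idx])
  rec <- tp[idx] / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Partitions latent vectors into k folds (stratified by label so every fold
#' approximates the class marginal), trains a classifier on the balanced
#' remainder, and reports per-fold per-class accuracy with means and
#' variances. If any class has fewer members than `k`, stratification falls
#' back to plain random folds with a warning.
#'
#' @param latents Matrix of latent vectors.
#' @param labels Subcompartment labels per row (NA rows dropped).
#' @param k Number of folds (default 10).
#' @param hidden,epochs,batch_size,learning_rate,dropout_rate,balance_n
#'   Passed to [balance_training_set()] / [train_classifier()].
#' @param seed Integer seed; identical seeds give identical folds and fits.
#' @return List with `folds` (fold id per kept row), `per_class` (k x 5
#'   accuracy matrix), `overall` (per fold), `mean`, and `variance`.
#' @export
kfold_cv <- function(latents, labels, k = 10, hidden = c(64, 16),
                     epochs = 25, batch_size = 32, learning_rate = 0.001,
                     dropout_rate = 0.25, balance_n = NULL, seed = 1) {
  if (k < 2) stop("'k' must be >= 2")
  latents <- as.matrix(latents)
  labels <- as_subcompartment(labels)
  keep <- !is.na(labels)
  latents <- latents[keep, , drop = FALSE]; labels <- labels[keep]
  with_seed(seed, {
    sizes <- table(labels)
    fold <- integer(length(labels))
    if (any(sizes < k)) {
      warning("class(es) smaller than k; using non-stratified folds")
      fold <- sample(rep_len(seq_len(k), length(labels)))
    } else {
      for (cl in subcompartments()) {
        idx <- which(labels == cl)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
    per_class <- matrix(NA_real_, k, 5,
                        dimnames = list(NULL, subcompartments()))
    overall <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      bset <- balance_training_set(latents[tr, , drop = FALSE], labels[tr],
                                   n = balance_n, seed = NULL)
      clf <- train_classifier(bset, hidden = hidden, epochs = epochs,
                              batch_size = batch_size,
                              learning_rate = learning_rate,
                              dropout_rate = dropout_rate, seed = NULL)
      pred <- predict(clf, latents[!tr, , drop = FALSE], type = "class")
      cm <- confusion_subcomp(pred, labels[!tr])
      per_class[f, ] <- cm$per_class
      overall[f] <- cm$overall
    }
    list(folds = fold, per_class = per_class, overall = overall,
         mean = colMeans(per_class, na.rm = TRUE),
         variance = apply(per_class, 2, stats::var, na.rm = TRUE))
  })
}

#' Signal enrichment fold change per subcompartment
#'
#' Fold change of a functional genomic mark in a subcompartment is the median
#' signal over that subcompartment's bins divided by the median signal over
#' all annotated bins. Bins with NA label or NA signal are excluded, as are
#' short terminal bins (their width differs from the rest of the grid).
#'
#' @param signal Numeric per-bin signal aligned to `track`.
#' @param track A [subcomp_track()].
#' @return Named numeric vector of per-label fold changes (NA for empty
#'   classes).
#' @export
enrichment_fold_change <- function(signal, track) {
  if (length(signal) != nrow(track))
    stop("signal and track must cover the same bins")
  widths <- track$end - track$start
  keep <- !is.na(signal) & !is.na(track$label) & widths == max(widths)
  if (!any(keep)) stop("no annotated bins with signal")
  overall <- stats::median(signal[keep])
  vapply(subcompartments(), function(cl) {
    sel <- keep & track$label == cl
    if (!any(sel)) return(NA_real_)
    stats::median(signal[sel]) / overall
  }, numeric(1))
}

#' Mean signal profile across subcompartment boundaries
#'
#' A boundary is a position where the annotations of two adjacent 100 kb bins
#' on the same chromosome differ; here boundaries switching from
#' `pair[1]` (upstream/left) to `pair[2]` (downstream/right) are profiled.
#' The signal is averaged per 100 kb offset over `[-window, +window)` around
#' each boundary (8 offsets for the default 400 kb window). Boundaries whose
#' window is truncated by a chromosome end, or spans NA labels or NA signal,
#' are excluded.
#'
#' @param signal Numeric per-bin signal aligned to `track`.
#' @param track A [subcomp_track()].
#' @param pair Character vector `c(left_label, right_label)`.
#' @param window Half-window in base pairs; must be a multiple of the bin
#'   size (default 400000).
#' @return Data frame with `offset` (bp of each offset bin's start relative
#'   to the boundary) and `mean_signal`; attribute `n_boundaries`.
#' @export
boundary_profile <- function(signal, track, pair, window = 4e5) {
  stopifnot(length(pair) == 2)
  pair <- as.character(pair)
  bin <- max(track$end - track$start)
  if (window %% bin != 0 || window <= 0)
    stop("'window' must be a positive multiple of the bin size")
  w <- window / bin
  lab <- as.character(track$label)
  n <- nrow(track)
  adj <- which(track$chrom[-n] == track$chrom[-1] &
                 track$start[-1] == track$start[-n] + bin)
  bidx <- adj[!is.na(lab[adj]) & !is.na(lab[adj + 1]) &
                lab[adj] == pair[1] & lab[adj + 1] == pair[2]]
  offsets <- seq(-window, window - bin, by = bin)
  prof <- matrix(NA_real_, 0, 2 * w)
  for (i in bidx) {
    pos <- (i - w + 1):(i + w)
    if (any(pos < 1 | pos > n)) next
    if (any(track$chrom[pos] != track$chrom[i])) next
    if (!all(track$start[pos] == track$start[i] + (pos - i) * bin)) next
    if (anyNA(lab[pos]) || anyNA(signal[pos])) next
    prof <- rbind(prof, signal[pos])
  }
  out <- data.frame(offset = offsets,
                    mean_signal = if (nrow(prof) > 0) colMeans(prof)
                    else rep(NA_real_, 2 * w))
  attr(out, "n_boundaries") <- nrow(prof)
  out
}

#' Accuracy across a coverage titration
#'
#' Re-runs the full pipeline (downsample to each rate, fit, annotate) and
#' reports overall held-out accuracy against a reference annotation per
#' coverage level, emulating a coverage-titration evaluation on data where
#' the truth is known.
#'
#' @param contacts Dense [inter_contacts()].
#' @param reference Reference [subcomp_track()] covering the grids.
#' @param rates Numeric vector of keep rates in (0, 1].
#' @param held_out Evaluate on held-out chromosomes only (default TRUE);
#'   otherwise on all covered bins.
#' @param seed Master seed; rate r uses the same stream so runs reproduce
#'   bitwise.
#' @param ... Passed to [fit_subcompartments()].
#' @return Data frame with one row per rate: `rate`, `accuracy`, `n_bins`.
#' @export
coverage_sweep <- function(contacts, reference, rates, held_out = TRUE,
                           seed = 1, ...) {
  if (any(rates <= 0 | rates > 1)) stop("rates must lie in (0, 1]")
  rows <- lapply(seq_along(rates), function(k) {
    model <- fit_subcompartments(contacts, reference, keep_rate = rates[k],
                                 seed = seed, ...)
    sparse <- with_seed(seed,
                        downsample_contacts(contacts, rates[k], seed = NULL))
    ann <- predict(model, sparse)
    acc <- annotation_accuracy(ann, reference, model,
                               held_out = held_out)
    data.frame(rate = rates[k], accuracy = acc$accuracy, n_bins = acc$n)
  })
  do.call(rbind, rows)
}

# Overall accuracy of an annotation track vs a reference, optionally
# restricted to the model's held-out chromosomes.
annotation_accuracy <- function(ann, reference, model = NULL,
                                held_out = FALSE) {
  ref_lab <- track_labels(reference, ann)
  keep <- rep(TRUE, nrow(ann))
  if (held_out && !is.null(model)) {
    tc <- unlist(model$manifest$train_chroms)
    keep <- !(ann$chrom %in% tc)
  }
  ok <- keep & !is.na(ann$label) & !is.na(ref_lab)
  list(accuracy = mean(as.character(ann$label[ok]) ==
                         as.character(ref_lab[ok])),
       n = sum(ok))
}
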