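#' Fit the subcompartment imputation-and-classification model
#'
#' End-to-end training on a high-coverage inter-chromosomal contact matrix
#' with reference subcompartment labels. The dense matrix is downsampled to
#' `keep_rate` of its read pairs to emulate a moderate-coverage experiment;
#' both matrices are converted to contact probabilities; a denoising
#' autoencoder is trained to reconstruct dense probability rows from sparse
#' ones; the classifier is then trained on the (balanced) latent embeddings
#' of the training bins against the reference labels. Because the
#' inter-chromosomal matrix is not symmetric, two independent model pairs are
#' fitted: one on the rows (odd-numbered chromosomes) and one on the columns
#' of the transposed matrix (even-numbered chromosomes). By default the odd
#' model trains on bins of chr1, chr3, chr5 and chr7 and the even model on
#' chr2, chr4, chr6, chr8 and chr10; the remaining chromosomes are held out.
#'
#' @param contacts Dense [inter_contacts()] (rows odd parity).
#' @param reference A [subcomp_track()] (or data frame with `chrom`, `start`,
#'   `label`) covering at least the training chromosomes of both parities.
#' @param keep_rate Fraction of reads retained when simulating moderate
#'   coverage (default 0.1, i.e. removing 90\% of reads).
#' @param train_chroms List with elements `odd` and `even` naming the
#'   training chromosomes; defaults as above, intersected with the grids.
#' @param epochs,batch_size,learning_rate,loss Autoencoder training
#'   hyperparameters (see [train_autoencoder()]); the classifier uses the
#'   same epochs/batch/learning rate.
#' @param interior Autoencoder interior widths (see [build_autoencoder()]).
#' @param hidden Classifier hidden widths (see [train_classifier()]).
#' @param dropout_rate Dropout fraction for both networks.
#' @param balance_n Samples per class for training-set balancing (default:
#'   largest class count + 1).
#' @param seed Master seed; fixes downsampling, initialisation, shuffling,
#'   dropout and balancing, so identical calls reproduce bitwise.
#' @return An object of class `subcomp_model`: the odd and even
#'   autoencoder/classifier pairs, the grids, and a `manifest` recording
#'   every hyperparameter and seed of the run.
#' @seealso [predict.subcomp_model()], [impute_contacts()]
#' @export
fit_subcompartments <- function(contacts, reference, keep_rate = 0.1,
                                train_chroms = NULL,
                                epochs = 25, batch_size = 32,
                                learning_rate = 0.001, loss = "bce",
                                interior = NULL, hidden = c(64, 16),
                                dropout_rate = 0.25, balance_n = NULL,
                                seed = 1) {
  stopifnot(inherits(contacts, "inter_contacts"))
  if (is.null(train_chroms))
    train_chroms <- list(
      odd = intersect(c("chr1", "chr3", "chr5", "chr7"),
                      unique(contacts$row_grid$chrom)),
      even = intersect(c("chr2", "chr4", "chr6", "chr8", "chr10"),
                       unique(contacts$col_grid$chrom)))
  if (length(train_chroms$odd) == 0 || length(train_chroms$even) == 0)
    stop("no training chromosomes found on the grids; pass 'train_chroms'")
  if (keep_rate == 1)
    warning("keep_rate = 1: the 'sparse' input equals the dense target, ",
            "so the autoencoder sees no downsampling noise")

  ref_odd <- track_labels(reference, contacts$row_grid)
  ref_even <- track_labels(reference, contacts$col_grid)
  chk <- function(lab, grid, chroms, side) {
    sel <- grid$chrom %in% chroms
    if (all(is.na(lab[sel])))
      stop("reference labels do not cover the ", side,
           " training chromosomes")
  }
  chk(ref_odd, contacts$row_grid, train_chroms$odd, "odd")
  chk(ref_even, contacts$col_grid, train_chroms$even, "even")

  fit_side <- function(p_sparse, p_dense, grid, ref, chroms, cover) {
    train <- grid$chrom %in% chroms & cover & !is.na(ref)
    ae <- train_autoencoder(p_sparse[train, , drop = FALSE],
                            p_dense[train, , drop = FALSE],
                            epochs = epochs, batch_size = batch_size,
                            learning_rate = learning_rate, loss = loss,
                            interior = interior,
                            dropout_rate = dropout_rate, seed = NULL)
    lat <- encode(ae, p_sparse[train, , drop = FALSE])
    bset <- balance_training_set(lat, ref[train], n = balance_n, seed = NULL)
    clf <- train_classifier(bset, hidden = hidden, epochs = epochs,
                            batch_size = batch_size,
                            learning_rate = learning_rate,
                            dropout_rate = dropout_rate, seed = NULL)
    list(autoencoder = ae, classifier = clf, train_bins = which(train))
  }

  model <- with_seed(seed, {
    sparse <- downsample_contacts(contacts, keep_rate, seed = NULL)
    p_sp <- contact_probability(sparse)
    p_dn <- contact_probability(contacts)
    odd <- fit_side(p_sp$probs, p_dn$probs, contacts$row_grid, ref_odd,
                    train_chroms$odd, covered_rows(sparse))
    even <- fit_side(t(p_sp$probs), t(p_dn$probs), contacts$col_grid,
                     ref_even, train_chroms$even, covered_cols(sparse))
    list(odd = odd, even = even)
  })

  manifest <- list(
    keep_rate = keep_rate, seed = seed, train_chroms = train_chroms,
    epochs = epochs, batch_size = batch_size,
    learning_rate = learning_rate, loss = loss,
    interior = model$odd$autoencoder$sizes[
      2:(model$odd$autoencoder$latent_index)],
    hidden = hidden, dropout_rate = dropout_rate,
    balance_n = balance_n,
    n_odd = nrow(contacts$row_grid), n_even = nrow(contacts$col_grid),
    package_version = as.character(utils::packageVersion("hicsubcomp")))

  structure(list(odd = model$odd, even = model$even,
                 row_grid = contacts$row_grid, col_grid = contacts$col_grid,
                 manifest = manifest),
            class = "subcomp_model")
}

#' Annotate a cell type from a (sparse) contact matrix
#'
#' Applies a fitted model to a new inter-chromosomal contact matrix: the
#' matrix is converted to contact probabilities, each covered bin's row (odd
#' parity) or column (even parity, via the transpose pathway) is encoded by
#' the matching autoencoder, and the classifier assigns subcompartment
#' probabilities. Bins with zero marginal count are returned as NA. A bin's
#' label comes only from its own parity's model pair.
#'
#' @param object A `subcomp_model`.
#' @param newdata An [inter_contacts()] matrix on grids compatible with the
#'   training dimensions.
#' @param cell_type Optional tag stored on the returned track.
#' @param ... Unused.
#' @return A [subcomp_track()] over all row- and column-grid bins, with
#'   labels, five-class probabilities, and a `parity` column recording which
#'   model produced each call.
#' @export
predict.subcomp_model <- function(object, newdata, cell_type = NULL, ...) {
  stopifnot(inherits(newdata, "inter_contacts"))
  w_odd <- object$odd$autoencoder$sizes[1]
  w_even <- object$even$autoencoder$sizes[1]
  if (ncol(newdata$counts) != w_odd || nrow(newdata$counts) != w_even)
    stop(sprintf(paste0(
      "matrix is %dx%d but the model was trained on %dx%d grids; ",
      "re-bin the contacts onto the training grids (100 kb bins, ",
      "same chromosome set) before annotating"),
      nrow(newdata$counts), ncol(newdata$counts), w_even, w_odd))
  p <- contact_probability(newdata)
  n_r <- nrow(object$row_grid); n_c <- nrow(object$col_grid)

  side <- function(rows, clf, cover, n) {
    prob <- matrix(NA_real_, n, 5)
    lab <- factor(rep(NA_character_, n), levels = subcompartments())
    if (any(cover)) {
      lat <- encode(clf$autoencoder, rows[cover, , drop = FALSE])
      prob[cover, ] <- predict(clf$classifier, lat, type = "prob")
      lab[cover] <- predict(clf$classifier, lat, type = "class")
    }
    list(prob = prob, lab = lab)
  }
  odd <- side(p$probs, object$odd, covered_rows(newdata), n_r)
  even <- side(t(p$probs), object$even, covered_cols(newdata), n_c)

  tr <- subcomp_track(list(object$row_grid, object$col_grid),
                      c(as.character(odd$lab), as.character(even$lab)),
                      rbind(odd$prob, even$prob), cell_type = cell_type)
  tr$parity <- rep(c("odd", "even"), c(n_r, n_c))
  tr
}

#' Impute a dense contact-probability matrix
#'
#' Reconstructs the dense inter-chromosomal contact-probability matrix from a
#' sparse input using the trained autoencoder. `parity = "odd"` (default)
#' assembles the matrix from reconstructed rows; `parity = "even"`
#' reconstructs the transposed matrix through the even model and transposes
#' back. All imputed values lie strictly in (0, 1).
#'
#' @param model A `subcomp_model`.
#' @param sparse An [inter_contacts()] on compatible grids.
#' @param parity Which model pair performs the reconstruction.
#' @return A `contact_prob` object of the same shape as the input.
#' @export
impute_contacts <- function(model, sparse, parity = c("odd", "even")) {
  parity <- match.arg(parity)
  stopifnot(inherits(model, "subcomp_model"), inherits(sparse, "inter_contacts"))
  p <- contact_probability(sparse)
  probs <- if (parity == "odd")
    reconstruct(model$odd$autoencoder, p$probs)
  else
    t(reconstruct(model$even$autoencoder, t(p$probs)))
  structure(list(probs = probs, row_grid = sparse$row_grid,
                 col_grid = sparse$col_grid),
            class = "contact_prob")
}

#' @export
print.subcomp_model <- function(x, ...) {
  m <- x$manifest
  cat("subcomp_model\n")
  cat(sprintf("  grids: %d odd-parity x %d even-parity bins\n",
              m$n_odd, m$n_even))
  cat(sprintf("  trained at keep_rate %.3g, seed %s\n", m$keep_rate, m$seed))
  cat(sprintf("  autoencoder: %s\n",
              paste(x$odd$autoencoder$sizes, collapse = "-")))
  cat(sprintf("  classifier:  %s\n",
              paste(x$odd$classifier$sizes, collapse = "-")))
  cat(sprintf("  training chromosomes: odd %s | even %s\n",
              paste(m$train_chroms$odd, collapse = ","),
              paste(m$train_chroms$even, collapse = ",")))
  invisible(x)
}

#' @method summary subcomp_model
#' @export
summary.subcomp_model <- function(object, ...) {
  print(object)
  cat(sprintf("  odd AE final loss:  %.5f\n",
              object$odd$autoencoder$history[length(object$odd$autoencoder$history)]))
  cat(sprintf("  even AE final loss: %.5f\n",
              object$even$autoencoder$history[length(object$even$autoencoder$history)]))
  cat(sprintf("  odd classifier final loss:  %.5f\n",
              object$odd$classifier$history[length(object$odd$classifier$history)]))
  cat(sprintf("  even classifier final loss: %.5f\n",
              object$even$classifier$history[length(object$even$classifier$history)]))
  invisible(object)
}

#' Choose between coverage-specific model variants
#'
#' Cross-cell-type application trains model variants at different coverage
#' levels (e.g. one at 10\% and one at 5\% of the reference reads) and
#' applies the variant whose training sparsity best matches the target: by
#' default, targets with at least 45 million inter-chromosomal read pairs go
#' to the higher-coverage model, sparser targets to the lower-coverage one.
#'
#' @param high,low `subcomp_model`s trained at the higher / lower keep rate.
#' @param contacts The target [inter_contacts()] matrix.
#' @param boundary Read-pair threshold (default 4.5e7).
#' @return Whichever of `high`/`low` matches the target coverage.
#' @export
select_model_by_coverage <- function(high, low, contacts, boundary = 4.5e7) {
  stopifnot(inherits(contacts, "inter_contacts"))
  if (sum(contacts$counts) >= boundary) high else low
}
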