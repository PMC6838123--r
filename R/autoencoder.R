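#' Build a denoising autoencoder for contact-probability rows
#'
#' Constructs the symmetric nine-layer architecture used for imputing dense
#' inter-chromosomal contact probabilities from sparse ones: layer widths
#' `n_loci, 1024, 512, 256, 128, 256, 512, 1024, n_loci`. Hidden layers are
#' ReLU-activated, the 128-unit latent layer is linear (to maximise the
#' encoding space) and the output layer is sigmoid (to match the `[0,1)`
#' range of contact probabilities). Hidden layers whose default widths are
#' 1024 and 256 - on both the encoder and decoder sides - are followed by
#' 25\% dropout during training.
#'
#' For small matrices the default interior widths are capped at
#' `4 * n_loci` so the architecture keeps its shape at desk scale.
#'
#' @param n_loci Width of the input/output layer (number of columns of the
#'   probability matrix being imputed, i.e. bins of the opposite parity).
#' @param interior Optional integer vector of encoder widths ending in the
#'   latent width, default `c(1024, 512, 256, 128)`. The decoder mirrors all
#'   but the latent entry.
#' @param dropout_rate Dropout fraction applied after the designated hidden
#'   layers during training (default 0.25).
#' @param dropout_widths Hidden widths (on the default schedule) that receive
#'   dropout; default `c(1024, 256)`, i.e. positions 1 and 3 of the encoder
#'   and their decoder mirrors.
#' @param seed Integer seed fixing the weight initialisation, or NULL to use
#'   the current RNG stream.
#' @return An object of class `hic_autoencoder` (untrained).
#' @export
build_autoencoder <- function(n_loci, interior = NULL, dropout_rate = 0.25,
                              dropout_widths = c(1024, 256), seed = NULL) {
  if (n_loci < 1) stop("'n_loci' must be >= 1")
  default_interior <- is.null(interior)
  if (default_interior)
    interior <- pmin(c(1024L, 512L, 256L, 128L), max(4L * n_loci, 2L))
  if (any(interior < 1)) stop("layer sizes must be positive")
  latent <- interior[length(interior)]
  sizes <- c(n_loci, interior, rev(interior[-length(interior)]), n_loci)
  L <- length(sizes) - 1L
  act <- c(rep("relu", length(interior) - 1L), "linear",
           rep("relu", length(interior) - 1L), "sigmoid")
  # dropout follows hidden layers at the 1024/256 positions of the default
  # schedule (encoder positions 1 and 3 and their decoder mirrors)
  drop <- rep(0, L)
  if (dropout_rate > 0 && length(interior) >= 2) {
    enc_hid <- seq_len(length(interior) - 1L)              # encoder hidden
    dec_hid <- length(interior) + enc_hid                  # decoder hidden
    hid_pos <- c(enc_hid, dec_hid)
    sel <- if (default_interior)
      # alternating hidden layers = the 1024- and 256-wide ones (and their
      # capped counterparts), mirrored on the decoder side
      rep(c(TRUE, FALSE), length.out = length(enc_hid))[c(seq_along(enc_hid),
                                                          seq_along(dec_hid))]
    else sizes[hid_pos + 1L] %in% dropout_widths
    if (!any(sel) && !default_interior) sel <- rep(TRUE, length(hid_pos))
    drop[hid_pos[sel]] <- dropout_rate
  }
  net <- with_seed(seed, nn_new(sizes, act, drop))
  structure(list(net = net, sizes = sizes, latent = latent,
                 latent_index = length(interior) + 1L,
                 dropout_rate = dropout_rate, seed = seed,
                 trained = FALSE, history = NULL),
            class = "hic_autoencoder")
}

#' Train a denoising autoencoder on sparse/dense probability row pairs
#'
#' Fits the autoencoder so that rows of a downsampled contact-probability
#' matrix reconstruct the corresponding rows of the dense matrix. The loss is
#' binary cross-entropy between reconstruction and target (a mean-squared
#' error mode is available and performs similarly); optimisation is
#' mini-batch backpropagation with RMSProp (decay 0.9, epsilon 1e-7).
#' Defaults: 25 epochs, batch size 32, learning rate 0.001.
#'
#' @param sparse,dense Matrices of equal shape with values in `[0, 1]`; rows
#'   are genomic bins, columns the opposite-parity bins. `contact_prob`
#'   objects are accepted.
#' @param epochs,batch_size,learning_rate Training hyperparameters.
#' @param loss `"bce"` (default) or `"mse"`.
#' @param ae Optionally a pre-built [build_autoencoder()] object; built from
#'   `ncol(sparse)` otherwise.
#' @param interior,dropout_rate Passed to [build_autoencoder()] when `ae` is
#'   NULL.
#' @param seed Integer seed fixing initialisation, shuffling and dropout.
#' @return A trained `hic_autoencoder` with per-epoch mean loss in
#'   `$history`.
#' @export
train_autoencoder <- function(sparse, dense, epochs = 25, batch_size = 32,
                              learning_rate = 0.001, loss = c("bce", "mse"),
                              ae = NULL, interior = NULL, dropout_rate = 0.25,
                              seed = NULL) {
  loss <- match.arg(loss)
  if (inherits(sparse, "contact_prob")) sparse <- sparse$probs
  if (inherits(dense, "contact_prob")) dense <- dense$probs
  sparse <- as.matrix(sparse); dense <- as.matrix(dense)
  if (!all(dim(sparse) == dim(dense)))
    stop("sparse and dense row sets must have identical shape")
  if (any(sparse < 0 | sparse > 1) || any(dense < 0 | dense > 1))
    stop("probability rows must lie in [0, 1]")
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0)
    stop("training hyperparameters must be positive")
  with_seed(seed, {
    if (is.null(ae))
      ae <- build_autoencoder(ncol(sparse), interior = interior,
                              dropout_rate = dropout_rate, seed = NULL)
    fit <- nn_train(ae$net, sparse, dense, loss = loss, epochs = epochs,
                    batch_size = batch_size, lr = learning_rate)
    ae$net <- fit$net
    ae$history <- fit$history
    ae$trained <- TRUE
    ae$loss <- loss
    ae
  })
}

#' Encode probability rows into latent vectors
#'
#' Runs the encoder half of a trained autoencoder, returning the linear
#' 128-dimensional (by default) latent representation of each row's
#' genome-wide inter-chromosomal contact profile. Inference is
#' deterministic: dropout is disabled.
#'
#' @param ae A `hic_autoencoder`.
#' @param rows Matrix of probability rows (or a `contact_prob` object).
#' @return Matrix with one latent vector per input row.
#' @export
encode <- function(ae, rows) {
  stopifnot(inherits(ae, "hic_autoencoder"))
  if (inherits(rows, "contact_prob")) rows <- rows$probs
  rows <- as.matrix(rows)
  if (ncol(rows) != ae$sizes[1])
    stop("row width ", ncol(rows), " does not match autoencoder input width ",
         ae$sizes[1])
  a <- rows
  # encoder layers run up to (and including) the linear latent layer
  for (i in seq_len(ae$latent_index - 1L)) {
    z <- tcrossprod(a, ae$net$W[[i]]) + rep(ae$net$b[[i]], each = nrow(a))
    a <- nn_activate(z, ae$net$act[i])
  }
  a
}

#' Reconstruct dense probability rows from sparse ones
#'
#' Full forward pass of the autoencoder at inference (no dropout). Outputs
#' are sigmoid-activated and therefore lie strictly in (0, 1).
#'
#' @inheritParams encode
#' @return Matrix of imputed probability rows, same shape as the input.
#' @export
reconstruct <- function(ae, rows) {
  stopifnot(inherits(ae, "hic_autoencoder"))
  if (inherits(rows, "contact_prob")) rows <- rows$probs
  rows <- as.matrix(rows)
  if (ncol(rows) != ae$sizes[1])
    stop("row width ", ncol(rows), " does not match autoencoder input width ",
         ae$sizes[1])
  nn_predict(ae$net, rows)
}

#' @export
print.hic_autoencoder <- function(x, ...) {
  cat("hic_autoencoder:", paste(x$sizes, collapse = "-"),
      if (x$trained) sprintf("(trained, final loss %.4f)",
                             x$history[length(x$history)])
      else "(untrained)", "\n")
  invisible(x)
}

# total parameter count: sum over layers of out*in + out
n_parameters <- function(net) {
  sum(vapply(seq_along(net$W),
             function(i) length(net$W[[i]]) + length(net$b[[i]]), numeric(1)))
}
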