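#' Balance a training set by within-class interpolation
#'
#' Classifier training sets are balanced so every subcompartment is equally
#' represented. For each class, `n` synthetic latent vectors are generated by
#' picking two latent vectors `x` and `y` of that class at random and drawing
#' `r = x + (y - x) * u` with `u ~ Uniform(0, 1)` - a random point on the
#' segment between the pair - until the class holds exactly `n` samples
#' (`5 * n` rows in total).
#'
#' @param latents Numeric matrix of latent vectors (rows = bins).
#' @param labels Subcompartment labels per row (character or factor on the
#'   [subcompartments()] levels); rows with NA labels are dropped first.
#' @param n Samples per class; must exceed the largest class count. Defaults
#'   to `max(2 * largest class count, 500)` so that even small training sets
#'   give the classifier a reasonable number of gradient steps per epoch.
#' @param seed Integer seed, or NULL for the current RNG stream.
#' @return An object of class `balanced_set`: list with `x` (`5n` x d
#'   matrix), `labels` (factor), and `provenance` (generating pair indices
#'   into the original rows plus the interpolation coordinate `u`).
#' @export
balance_training_set <- function(latents, labels, n = NULL, seed = NULL) {
  latents <- as.matrix(latents)
  labels <- as_subcompartment(labels)
  keep <- !is.na(labels)
  latents <- latents[keep, , drop = FALSE]
  labels <- labels[keep]
  sizes <- table(labels)
  if (any(sizes < 2))
    stop("every subcompartment class needs >= 2 members to interpolate; ",
         "short classes: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (is.null(n)) n <- max(2L * max(sizes), 500L)
  if (n <= max(sizes))
    stop("'n' (", n, ") must exceed the largest class count (", max(sizes), ")")
  with_seed(seed, {
    parts <- lapply(subcompartments(), function(cl) {
      idx <- which(labels == cl)
      i1 <- sample(idx, n, replace = TRUE)
      i2 <- sample(idx, n, replace = TRUE)
      u <- stats::runif(n)
      r <- latents[i1, , drop = FALSE] +
        (latents[i2, , drop = FALSE] - latents[i1, , drop = FALSE]) * u
      list(x = r, prov = data.frame(class = cl, i = i1, j = i2, u = u))
    })
    structure(list(
      x = do.call(rbind, lapply(parts, `[[`, "x")),
      labels = as_subcompartment(rep(subcompartments(), each = n)),
      provenance = do.call(rbind, lapply(parts, `[[`, "prov")),
      n = n, seed = seed
    ), class = "balanced_set")
  })
}

#' Train the subcompartment classifier
#'
#' Fits a multilayer perceptron mapping 128-dimensional latent contact
#' embeddings to the five primary subcompartments. The input latents are
#' sigmoid-squashed (limiting inputs to (0,1) and mitigating bias towards
#' large values), hidden layers are ReLU-activated and followed by 25\%
#' dropout during training, and the 5-unit output is softmax so class
#' probabilities sum to one. Optimised with categorical cross-entropy via
#' backpropagation and RMSProp. Default hidden widths are `c(64, 16)`; a
#' 32-unit second hidden layer trains equally well and can be selected with
#' `hidden = c(64, 32)`.
#'
#' @param bset A [balance_training_set()] result, or a list with elements
#'   `x` (latent matrix) and `labels`.
#' @param hidden Integer vector of hidden-layer widths.
#' @param epochs,batch_size,learning_rate Training hyperparameters (defaults
#'   25, 32, 0.001, matching the autoencoder).
#' @param dropout_rate Dropout after each hidden layer (default 0.25).
#' @param seed Integer seed, or NULL for the current RNG stream.
#' @return An object of class `subcomp_classifier` with per-epoch training
#'   loss in `$history`.
#' @export
train_classifier <- function(bset, hidden = c(64, 16), epochs = 25,
                             batch_size = 32, learning_rate = 0.001,
                             dropout_rate = 0.25, seed = NULL) {
  x <- as.matrix(bset$x)
  labels <- as_subcompartment(bset$labels)
  if (anyNA(labels)) stop("training labels must not contain NA")
  y <- diag(5)[as.integer(labels), , drop = FALSE]
  # standardise each latent dimension so the input sigmoid squashing
  # operates in its responsive range whatever the encoder's output scale
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  x <- sweep(sweep(x, 2, center), 2, scale, "/")
  sizes <- c(ncol(x), hidden, 5L)
  L <- length(sizes) - 1L
  act <- c(rep("relu", L - 1L), "softmax")
  drop <- c(rep(dropout_rate, L - 1L), 0)
  with_seed(seed, {
    net <- nn_new(sizes, act, drop, input_activation = "sigmoid")
    fit <- nn_train(net, x, y, loss = "ce", epochs = epochs,
                    batch_size = batch_size, lr = learning_rate)
    structure(list(net = fit$net, sizes = sizes, history = fit$history,
                   hidden = hidden, center = center, scale = scale,
                   seed = seed),
              class = "subcomp_classifier")
  })
}

#' Subcompartment class probabilities and labels
#'
#' Inference on a trained classifier. `type = "prob"` returns the softmax
#' probability matrix (rows sum to 1); `type = "class"` returns the argmax
#' label, with exact ties broken in canonical label order (A1 first).
#'
#' @param object A `subcomp_classifier`.
#' @param newdata Matrix of latent vectors.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of labels, or a numeric matrix of probabilities with one
#'   column per subcompartment.
#' @export
predict.subcomp_classifier <- function(object, newdata,
                                       type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$sizes[1])
    stop("latent width ", ncol(newdata), " does not match classifier input ",
         object$sizes[1])
  if (!is.null(object$center))
    newdata <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  p <- nn_predict(object$net, newdata)
  colnames(p) <- subcompartments()
  if (type == "prob") return(p)
  # which.max returns the first maximum: ties resolve to A1 first
  factor(subcompartments()[apply(p, 1, which.max)],
         levels = subcompartments())
}

#' @export
print.subcomp_classifier <- function(x, ...) {
  cat("subcomp_classifier:", paste(x$sizes, collapse = "-"),
      sprintf("(final training loss %.4f)\n", x$history[length(x$history)]))
  invisible(x)
}
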