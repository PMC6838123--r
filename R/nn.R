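# Minimal feed-forward neural network engine: dense layers, ReLU / linear /
# sigmoid / softmax activations, inverted dropout, backpropagation, and
# RMSProp updates. Written on top of BLAS-backed base matrix ops; samples are
# rows. All stochastic choices (init, shuffling, dropout masks) come from the
# caller's RNG stream so a single set.seed upstream fixes the whole run.

nn_new <- function(sizes, activations, dropout = NULL,
                   input_activation = "identity") {
  L <- length(sizes) - 1L
  stopifnot(length(activations) == L, all(sizes >= 1))
  if (is.null(dropout)) dropout <- rep(0, L)
  stopifnot(length(dropout) == L, all(dropout >= 0 & dropout < 1))
  # seeded uniform fan-in scaling: W_i ~ U(-sqrt(6/n_in), sqrt(6/n_in)),
  # the He-style variance-preserving scale for ReLU stacks
  W <- vector("list", L); b <- vector("list", L)
  for (i in seq_len(L)) {
    s <- sqrt(6) / sqrt(sizes[i])
    W[[i]] <- matrix(stats::runif(sizes[i + 1] * sizes[i], -s, s),
                     sizes[i + 1], sizes[i])
    b[[i]] <- numeric(sizes[i + 1])
  }
  list(sizes = sizes, act = activations, dropout = dropout,
       input_activation = input_activation, W = W, b = b)
}

nn_activate <- function(z, act) {
  switch(act,
         relu    = pmax(z, 0),
         linear  = z,
         sigmoid = 1 / (1 + exp(-z)),
         softmax = {
           e <- exp(z - apply(z, 1, max))
           e / rowSums(e)
         },
         stop("unknown activation: ", act))
}

# derivative of the activation w.r.t. its pre-activation, given post-act A
nn_act_deriv <- function(a, act) {
  switch(act,
         relu    = (a > 0) * 1,
         linear  = 1,
         sigmoid = a * (1 - a),
         stop("no elementwise derivative for activation: ", act))
}

# Forward pass. Returns activations per layer (A[[1]] is the, possibly
# squashed, input) and the dropout masks used (training mode only).
nn_forward <- function(net, x, training = FALSE) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  masks <- vector("list", L)
  A[[1]] <- if (net$input_activation == "sigmoid")
    1 / (1 + exp(-x)) else x
  for (i in seq_len(L)) {
    z <- tcrossprod(A[[i]], net$W[[i]])
    z <- z + rep(net$b[[i]], each = nrow(z))
    a <- nn_activate(z, net$act[i])
    if (training && net$dropout[i] > 0) {
      keep <- 1 - net$dropout[i]
      mask <- matrix((stats::runif(length(a)) < keep) / keep,
                     nrow(a), ncol(a))
      a <- a * mask
      masks[[i]] <- mask
    }
    A[[i + 1L]] <- a
  }
  list(A = A, masks = masks)
}

# Loss and the gradient dL/dz at the output layer. Losses pair with the
# output activation so the combined gradient is (yhat - y) scaled:
#   bce + sigmoid  : mean over all elements
#   ce  + softmax  : mean over samples (sum over classes)
#   mse + sigmoid  : mean over all elements, chain through sigmoid'
nn_loss <- function(yhat, y, loss) {
  eps <- 1e-12
  switch(loss,
         bce = {
           p <- clamp(yhat, eps, 1 - eps)
           -mean(y * log(p) + (1 - y) * log(1 - p))
         },
         ce  = -mean(rowSums(y * log(clamp(yhat, eps, 1)))),
         mse = mean((yhat - y)^2),
         stop("unknown loss: ", loss))
}

nn_output_delta <- function(yhat, y, loss, out_act) {
  m <- nrow(yhat)
  switch(loss,
         bce = {
           stopifnot(out_act == "sigmoid")
           (yhat - y) / (m * ncol(yhat))
         },
         ce = {
           stopifnot(out_act == "softmax")
           (yhat - y) / m
         },
         mse = {
           d <- 2 * (yhat - y) / (m * ncol(yhat))
           if (out_act == "sigmoid") d * yhat * (1 - yhat)
           else if (out_act == "linear") d
           else stop("mse loss supports sigmoid/linear output")
         })
}

# Backward pass from an output delta; returns gradients per layer.
nn_backward <- function(net, fwd, delta) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  for (i in rev(seq_len(L))) {
    gW[[i]] <- crossprod(delta, fwd$A[[i]])
    gb[[i]] <- colSums(delta)
    if (i > 1L) {
      da <- delta %*% net$W[[i]]
      if (!is.null(fwd$masks[[i - 1L]])) da <- da * fwd$masks[[i - 1L]]
      # fwd$A[[i]] is the (post-dropout) activation output of layer i-1
      delta <- da * nn_act_deriv(fwd$A[[i]], net$act[i - 1L])
    }
  }
  list(W = gW, b = gb)
}

# Loss + full analytic gradient in one call (no dropout); used by the
# finite-difference gradient checks in the test suite.
nn_loss_grad <- function(net, x, y, loss) {
  fwd <- nn_forward(net, x, training = FALSE)
  yhat <- fwd$A[[length(fwd$A)]]
  delta <- nn_output_delta(yhat, y, loss, net$act[length(net$act)])
  list(loss = nn_loss(yhat, y, loss), grad = nn_backward(net, fwd, delta))
}

nn_rmsprop_init <- function(net) {
  list(W = lapply(net$W, function(w) w * 0),
       b = lapply(net$b, function(b) b * 0))
}

nn_rmsprop_step <- function(net, grad, state, lr, decay = 0.9, eps = 1e-7) {
  for (i in seq_along(net$W)) {
    state$W[[i]] <- decay * state$W[[i]] + (1 - decay) * grad$W[[i]]^2
    state$b[[i]] <- decay * state$b[[i]] + (1 - decay) * grad$b[[i]]^2
    net$W[[i]] <- net$W[[i]] - lr * grad$W[[i]] / (sqrt(state$W[[i]]) + eps)
    net$b[[i]] <- net$b[[i]] - lr * grad$b[[i]] / (sqrt(state$b[[i]]) + eps)
  }
  list(net = net, state = state)
}

# Mini-batch training loop. Returns the trained net and the mean loss per
# epoch (computed from the training-mode forward passes).
nn_train <- function(net, x, y, loss, epochs, batch_size, lr,
                     decay = 0.9, eps = 1e-7) {
  stopifnot(nrow(x) == nrow(y))
  state <- nn_rmsprop_init(net)
  n <- nrow(x)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (s in seq(1, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]; yb <- y[idx, , drop = FALSE]
      fwd <- nn_forward(net, xb, training = TRUE)
      yhat <- fwd$A[[length(fwd$A)]]
      delta <- nn_output_delta(yhat, yb, loss, net$act[length(net$act)])
      grad <- nn_backward(net, fwd, delta)
      upd <- nn_rmsprop_step(net, grad, state, lr, decay, eps)
      net <- upd$net; state <- upd$state
      tot <- tot + nn_loss(yhat, yb, loss) * length(idx)
    }
    history[ep] <- tot / n
  }
  list(net = net, history = history)
}

nn_predict <- function(net, x) {
  fwd <- nn_forward(net, x, training = FALSE)
  fwd$A[[length(fwd$A)]]
}
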