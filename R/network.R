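#' Rectified linear unit
#'
#' The hidden-layer activation: `max(x, 0)`, applied elementwise.
#'
#' @param x Numeric vector or matrix.
#' @return Same shape as `x`.
#' @export
relu <- function(x) {
  pmax(x, 0)
}

#' Softmax
#'
#' Maps a score vector to a probability distribution,
#' `p_i = exp(y_i) / sum_j exp(y_j)`, computed with max-subtraction for
#' overflow safety. For a matrix, the transform is applied row-wise.
#'
#' @param y Numeric vector of scores, or a matrix with one score vector per
#'   row.
#' @return Probabilities of the same shape; each (row) sums to 1.
#' @examples
#' softmax(c(1, 2, 3))
#' @export
softmax <- function(y) {
  if (is.matrix(y)) {
    z <- exp(y - apply(y, 1, max))
    return(z / rowSums(z))
  }
  z <- exp(y - max(y))
  z / sum(z)
}

#' Cross-entropy loss
#'
#' `H(y, y') = -sum_i y'_i log(y_i)` with natural logarithm, where `y` is
#' the predicted distribution and `y_true` the one-hot truth. Predictions
#' are clipped to `[1e-12, 1]` before the logarithm so a confident wrong
#' prediction yields a large finite loss instead of infinity.
#'
#' @param y Predicted probabilities (vector, or matrix with one distribution
#'   per row).
#' @param y_true One-hot truth of the same shape.
#' @return Scalar loss for vectors; per-row loss vector for matrices.
#' @export
cross_entropy <- function(y, y_true) {
  if (is.matrix(y) != is.matrix(y_true) || !identical(dim(y), dim(y_true)) ||
      (!is.matrix(y) && length(y) != length(y_true)))
    stop("prediction and truth must have identical shape")
  yc <- pmin(pmax(y, 1e-12), 1)
  if (is.matrix(y)) rowSums(-y_true * log(yc)) else sum(-y_true * log(yc))
}

#' L2 regularization penalty
#'
#' `lambda * sum(w^2)` over all weight-matrix entries; biases are excluded.
#'
#' @param x A `gdl_network`, a fitted `gdl_net`, a list of layers, or a
#'   single weight matrix.
#' @param lambda Non-negative regularization weight.
#' @return Scalar penalty.
#' @export
l2_penalty <- function(x, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (inherits(x, "gdl_net")) x <- x$network
  layers <- if (inherits(x, "gdl_network")) x$layers
            else if (is.list(x) && !is.null(x$w)) list(x)
            else if (is.list(x)) x
            else list(list(w = x))
  lambda * sum(vapply(layers, function(l) sum(l$w^2), numeric(1)))
}

#' Initialize a fully connected softmax network
#'
#' Builds the live parameters and their shadow (moving-average) copies for a
#' feed-forward classifier: a stack of fully connected ReLU hidden layers
#' followed by a linear output layer feeding a softmax. Weights draw from a
#' truncated Gaussian (+/- 2 sd), biases start at a small constant; both
#' choices are configurable and seeded. Shadow parameters start equal to
#' the live ones and the training clock (global step) at 0.
#'
#' @param n_inputs Number of input features (collection size).
#' @param hidden Integer vector of hidden-layer widths; the default
#'   pyramid `c(512, 256, 128, 64)` suits ~10000-dimensional inputs.
#'   `integer(0)` gives a single softmax regression layer.
#' @param classes Ordered class names; the output width.
#' @param init_sd Weight init standard deviation.
#' @param init_bias Initial bias value.
#' @param seed Integer seed for the initialization draws.
#' @return Object of class `gdl_network`: list with `layers`, `shadow`
#'   (each a list of `w`/`b`), `step` and `classes`.
#' @export
gdl_network <- function(n_inputs, hidden = c(512L, 256L, 128L, 64L), classes,
                        init_sd = 0.1, init_bias = 0.1, seed = 1L) {
  stopifnot(n_inputs >= 1, length(classes) >= 2)
  hidden <- as.integer(hidden)
  if (any(hidden < 1)) stop("hidden widths must be positive")
  widths <- c(as.integer(n_inputs), hidden, length(classes))
  layers <- with_seed(seed, {
    lapply(seq_len(length(widths) - 1L), function(t) {
      nin <- widths[t]; nout <- widths[t + 1L]
      list(w = matrix(rtruncnorm2(nin * nout, init_sd), nin, nout),
           b = rep(init_bias, nout))
    })
  })
  structure(list(layers = layers, shadow = layers, step = 0L,
                 classes = classes, n_inputs = as.integer(n_inputs),
                 hidden = hidden),
            class = "gdl_network")
}

#' @export
print.gdl_network <- function(x, ...) {
  cat(sprintf("<gdl_network> %d -> %s -> %d classes (step %d)\n",
              x$n_inputs,
              if (length(x$hidden)) paste(x$hidden, collapse = " -> ") else "(linear)",
              length(x$classes), x$step))
  invisible(x)
}

#' Single layer forward pass
#'
#' Computes `f(x %*% w + b)`: each unit outputs the activation of its
#' weighted input sum plus bias.
#'
#' @param x Input vector, or matrix with one sample per row.
#' @param layer A list with weight matrix `w` (inputs x units) and bias
#'   vector `b`.
#' @param activation Activation function (default [relu()]; use `identity`
#'   for the output layer, whose nonlinearity is the softmax stage).
#' @return Activated outputs, matching the shape convention of `x`.
#' @export
layer_forward <- function(x, layer, activation = relu) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(layer$w))
    stop("input width ", ncol(x), " does not match layer input width ",
         nrow(layer$w))
  z <- sweep(x %*% layer$w, 2, layer$b, "+")
  out <- activation(z)
  if (vec) drop(out) else out
}

#' Full network forward pass
#'
#' Composes all fully connected layers (ReLU on hidden layers, identity on
#' the output layer) and the softmax stage. With `use_shadow = TRUE` the
#' exponentially averaged shadow parameters are used — the inference mode —
#' without mutating any state.
#'
#' @param network A [gdl_network()] (or a fitted `gdl_net`).
#' @param x Feature vector or matrix (samples x features).
#' @param use_shadow Evaluate with shadow (moving-average) parameters.
#' @return Probability matrix (samples x classes); rows sum to 1.
#' @export
gdl_forward <- function(network, x, use_shadow = FALSE) {
  if (inherits(network, "gdl_net")) network <- network$network
  stopifnot(inherits(network, "gdl_network"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != network$n_inputs)
    stop("input width ", ncol(x), " does not match network input width ",
         network$n_inputs)
  params <- if (use_shadow) network$shadow else network$layers
  a <- x
  nl <- length(params)
  for (t in seq_len(nl)) {
    act <- if (t < nl) relu else identity
    a <- layer_forward(a, params[[t]], activation = act)
    if (!is.matrix(a)) a <- matrix(a, nrow = nrow(x))
  }
  p <- softmax(a)
  colnames(p) <- network$classes
  rownames(p) <- rownames(x)
  p
}
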