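#' Exponentially decayed learning rate
#'
#' `R = r * d^(g / s)` where `r` is the base learning rate, `d` the decay
#' rate, `g` the global step and `s` the decay step. In staircase mode the
#' exponent is `floor(g / s)`, so the rate decays in discrete jumps once per
#' decay period instead of continuously.
#'
#' @param base_lr Base learning rate `r` (> 0).
#' @param decay_rate Decay rate `d` in (0, 1].
#' @param global_step Non-negative training step `g`.
#' @param decay_steps Decay period `s` (>= 1).
#' @param staircase Use the integer-division form.
#' @return The decayed learning rate.
#' @examples
#' decayed_learning_rate(0.1, 0.96, 200, 200)  # one decay period -> 0.096
#' @export
decayed_learning_rate <- function(base_lr, decay_rate, global_step, decay_steps,
                                  staircase = FALSE) {
  stopifnot(base_lr > 0, decay_rate > 0, decay_rate <= 1,
            decay_steps >= 1, all(global_step >= 0))
  e <- global_step / decay_steps
  if (staircase) e <- floor(e)
  base_lr * decay_rate^e
}

#' Shadow (moving-average) parameter update
#'
#' `S' = d * S + (1 - d) * V`: after every optimizer step each live
#' parameter `V` drags its shadow copy `S` towards itself at rate `1 - d`.
#' Under a constant `V` the shadow converges geometrically,
#' `S_t = V (1 - d^t)` from `S_0 = 0`. The shadow copies are the parameters
#' used at inference time.
#'
#' @param shadow Current shadow value (scalar, vector or matrix).
#' @param value Live parameter value, same shape.
#' @param decay Shadow decay `d` in (0, 1).
#' @return Updated shadow, same shape.
#' @export
ema_update <- function(shadow, value, decay) {
  if (!(decay > 0 && decay < 1)) stop("ema decay must be in (0, 1)")
  decay * shadow + (1 - decay) * value
}

#' Training configuration
#'
#' Collects every optimizer knob. None of these constants is canonical for
#' the method; the defaults are conventional settings for this family of
#' fully connected softmax classifiers and are recorded with every run.
#'
#' @param base_lr Base learning rate `r`.
#' @param decay_rate Exponential decay rate `d` in (0, 1].
#' @param decay_steps Decay period `s` in steps.
#' @param staircase Staircase decay mode.
#' @param l2 L2 regularization weight `lambda`.
#' @param ema_decay Shadow-variable decay in (0, 1).
#' @param batch_size Minibatch size.
#' @param max_steps Number of gradient steps (>= 1).
#' @param seed Integer seed for initialization and batch sampling.
#' @param log_every Trace logging interval in steps.
#' @return Object of class `gdl_config`.
#' @export
gdl_config <- function(base_lr = 0.1, decay_rate = 0.96, decay_steps = 200L,
                       staircase = FALSE, l2 = 1e-4, ema_decay = 0.99,
                       batch_size = 128L, max_steps = 5000L, seed = 1L,
                       log_every = 100L) {
  stopifnot(base_lr > 0, decay_rate > 0, decay_rate <= 1, decay_steps >= 1,
            l2 >= 0, ema_decay > 0, ema_decay < 1, batch_size >= 1,
            log_every >= 1)
  if (max_steps < 1) stop("max_steps must be >= 1")
  structure(list(base_lr = base_lr, decay_rate = decay_rate,
                 decay_steps = as.integer(decay_steps), staircase = staircase,
                 l2 = l2, ema_decay = ema_decay,
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps), seed = as.integer(seed),
                 log_every = as.integer(log_every)),
            class = "gdl_config")
}

#' @export
print.gdl_config <- function(x, ...) {
  cat("<gdl_config>\n")
  for (f in names(x)) cat(sprintf("  %-12s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Back-propagated gradients
#'
#' Exact gradients of the regularized objective — mean cross-entropy over
#' the batch plus the L2 penalty `lambda * sum(w^2)` — with respect to every
#' weight matrix and bias vector, by reverse-mode accumulation through the
#' ReLU stack and the softmax/cross-entropy head (whose combined output
#' gradient is the classic `p - y` residual).
#'
#' @param network A [gdl_network()].
#' @param X Batch feature matrix (samples x features).
#' @param Y Batch one-hot label matrix (samples x classes).
#' @param lambda L2 regularization weight.
#' @return List with per-layer gradients (`w`, `b`) and the batch `loss`
#'   (mean cross-entropy + L2 penalty).
#' @export
backprop_gradients <- function(network, X, Y, lambda = 0) {
  if (inherits(network, "gdl_net")) network <- network$network
  stopifnot(inherits(network, "gdl_network"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1)
  if (nrow(X) == 0) stop("batch must be non-empty")
  if (ncol(X) != network$n_inputs || nrow(X) != nrow(Y))
    stop("batch shapes do not match the network")
  layers <- network$layers
  nl <- length(layers)
  n <- nrow(X)
  # forward, caching activations
  a <- vector("list", nl + 1L)
  z <- vector("list", nl)
  a[[1L]] <- X
  for (t in seq_len(nl)) {
    z[[t]] <- sweep(a[[t]] %*% layers[[t]]$w, 2, layers[[t]]$b, "+")
    a[[t + 1L]] <- if (t < nl) relu(z[[t]]) else z[[t]]
  }
  p <- softmax(a[[nl + 1L]])
  loss <- mean(cross_entropy(p, Y)) + l2_penalty(layers, lambda)
  if (!is.finite(loss))
    stop("non-finite training loss; lower the learning rate or the ",
         "initialization scale")
  # backward
  grads <- vector("list", nl)
  delta <- (p - Y) / n                      # d(mean CE)/d(output scores)
  for (t in rev(seq_len(nl))) {
    grads[[t]] <- list(w = crossprod(a[[t]], delta) + 2 * lambda * layers[[t]]$w,
                       b = colSums(delta))
    if (t > 1L)
      delta <- (delta %*% t(layers[[t]]$w)) * (z[[t - 1L]] > 0)
  }
  list(layers = grads, loss = loss)
}

#' Fit a genome-deep-learning classifier
#'
#' Trains the fully connected softmax network on a binary-encoded dataset by
#' minibatch gradient descent on cross-entropy plus L2, with the
#' exponentially decayed learning rate, and after every step drags the
#' shadow copy of each parameter towards its live value
#' (`S = d*S + (1-d)*V`). Inference ([predict.gdl_net()]) uses the shadow
#' parameters. The run is fully reproducible from `config$seed`.
#'
#' @param data A `gdl_dataset` from [encode_cohort()] or
#'   [assemble_binary_task()].
#' @param split Optional [split_dataset()] result; training uses
#'   `split$train` rows (all rows when `NULL`).
#' @param hidden Hidden-layer widths (see [gdl_network()]).
#' @param config A [gdl_config()].
#' @param init_sd,init_bias Initialization constants (see [gdl_network()]).
#' @return Object of class `gdl_net`: the trained `network` (live + shadow
#'   parameters, global step), `classes`, the collection `sites` fingerprint,
#'   the training `trace` data frame (step, learning rate, batch
#'   cross-entropy, total loss), `config`, `split` and `call`.
#' @examples
#' p <- c(lapply(1:6, function(i) variant_profile(paste0("t", i), "TUMOR",
#'          c("1:100:A:T", "2:50:G:C"))),
#'        lapply(1:6, function(i) variant_profile(paste0("h", i), "HEALTHY",
#'          "3:10:T:A")))
#' col <- build_collection(p[1:6], top_k = 2)
#' ds <- encode_cohort(p, col)
#' fit <- gdl_fit(ds, hidden = c(4L, 3L),
#'                config = gdl_config(max_steps = 50L, batch_size = 4L))
#' predict(fit, ds, type = "class")
#' @export
gdl_fit <- function(data, split = NULL, hidden = c(512L, 256L, 128L, 64L),
                    config = gdl_config(), init_sd = 0.1, init_bias = 0.1) {
  stopifnot(inherits(data, "gdl_dataset"), inherits(config, "gdl_config"))
  rows <- if (is.null(split)) seq_len(nrow(data$X)) else split$train
  X <- data$X[rows, , drop = FALSE]
  Y <- data$Y[rows, , drop = FALSE]
  storage.mode(X) <- "double"
  net <- gdl_network(ncol(X), hidden = hidden, classes = data$classes,
                     init_sd = init_sd, init_bias = init_bias,
                     seed = config$seed)
  n <- nrow(X)
  trace <- list()
  with_seed(config$seed + 1L, {
    for (step in seq_len(config$max_steps)) {
      g <- net$step                       # global step before this update
      lr <- decayed_learning_rate(config$base_lr, config$decay_rate, g,
                                  config$decay_steps, config$staircase)
      idx <- if (n <= config$batch_size) seq_len(n)
             else sample(n, config$batch_size)
      gr <- backprop_gradients(net, X[idx, , drop = FALSE],
                               Y[idx, , drop = FALSE], lambda = config$l2)
      for (t in seq_along(net$layers)) {
        net$layers[[t]]$w <- net$layers[[t]]$w - lr * gr$layers[[t]]$w
        net$layers[[t]]$b <- net$layers[[t]]$b - lr * gr$layers[[t]]$b
        net$shadow[[t]]$w <- ema_update(net$shadow[[t]]$w, net$layers[[t]]$w,
                                        config$ema_decay)
        net$shadow[[t]]$b <- ema_update(net$shadow[[t]]$b, net$layers[[t]]$b,
                                        config$ema_decay)
      }
      net$step <- net$step + 1L
      if (step %% config$log_every == 0 || step == config$max_steps) {
        ce <- gr$loss - l2_penalty(net$layers, config$l2)
        trace[[length(trace) + 1L]] <-
          data.frame(step = g, learning_rate = lr, batch_loss = ce,
                     total_loss = gr$loss)
      }
    }
  })
  structure(list(network = net, classes = data$classes,
                 sites = data$collection$sites,
                 trace = do.call(rbind, trace), config = config,
                 split = split, hidden = as.integer(hidden),
                 call = match.call()),
            class = "gdl_net")
}

#' Predict class probabilities from a fitted classifier
#'
#' Row-wise forward pass using the shadow (moving-average) parameters by
#' default — the inference mode. When `newdata` is a `gdl_dataset` its
#' collection fingerprint must match the one the model was trained on, so a
#' dimension/panel mismatch is caught instead of silently producing garbage.
#'
#' @param object A fitted `gdl_net`.
#' @param newdata A `gdl_dataset` or a binary feature matrix whose columns
#'   follow the training collection's site order.
#' @param type `"prob"` for the probability matrix, `"class"` for argmax
#'   labels (ties broken by lowest class index).
#' @param use_shadow Use shadow parameters (default) or the live ones.
#' @param ... Unused.
#' @return Probability matrix with one row per sample (rows sum to 1), or a
#'   character vector of class labels.
#' @export
predict.gdl_net <- function(object, newdata, type = c("prob", "class"),
                            use_shadow = TRUE, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "gdl_dataset")) {
    if (!identical(newdata$collection$sites, object$sites))
      stop("collection fingerprint mismatch: the dataset was encoded against ",
           "a different mutation collection than the model was trained on")
    X <- newdata$X
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) != object$network$n_inputs)
      stop("newdata has ", ncol(X), " columns; the model expects ",
           object$network$n_inputs)
  }
  storage.mode(X) <- "double"
  p <- gdl_forward(object$network, X, use_shadow = use_shadow)
  if (type == "prob") p
  else object$classes[max.col(p, ties.method = "first")]
}

#' @export
print.gdl_net <- function(x, ...) {
  cat(sprintf("<gdl_net> %d-dimensional input -> %s -> %d classes\n",
              x$network$n_inputs,
              if (length(x$hidden)) paste(x$hidden, collapse = " -> ") else "(linear)",
              length(x$classes)))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained %d step(s); final batch loss %.4f\n",
              x$network$step, utils::tail(x$trace$batch_loss, 1)))
  invisible(x)
}

#' @export
summary.gdl_net <- function(object, ...) {
  npar <- sum(vapply(object$network$layers,
                     function(l) length(l$w) + length(l$b), numeric(1)))
  out <- list(classes = object$classes, hidden = object$hidden,
              n_inputs = object$network$n_inputs, n_parameters = npar,
              steps = object$network$step, config = object$config,
              final = utils::tail(object$trace, 1))
  class(out) <- "summary.gdl_net"
  out
}

#' @export
print.summary.gdl_net <- function(x, ...) {
  cat("Genome deep learning classifier\n")
  cat(sprintf("  input dimensions : %d\n", x$n_inputs))
  cat(sprintf("  hidden layers    : %s\n",
              if (length(x$hidden)) paste(x$hidden, collapse = ", ") else "none"))
  cat(sprintf("  classes          : %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  parameters       : %d\n", x$n_parameters))
  cat(sprintf("  steps trained    : %d\n", x$steps))
  cat(sprintf("  final loss       : %.4f (batch CE %.4f) at lr %.5f\n",
              x$final$total_loss, x$final$batch_loss, x$final$learning_rate))
  invisible(x)
}

#' @export
coef.gdl_net <- function(object, use_shadow = TRUE, ...) {
  params <- if (use_shadow) object$network$shadow else object$network$layers
  names(params) <- paste0("layer", seq_along(params))
  params
}

#' @export
plot.gdl_net <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(tr$step, tr$total_loss, type = "l", xlab = "global step",
                 ylab = "loss", main = "Training loss", ...)
  graphics::lines(tr$step, tr$batch_loss, lty = 2)
  graphics::legend("topright", legend = c("total", "cross-entropy"),
                   lty = c(1, 2), bty = "n")
  graphics::plot(tr$step, tr$learning_rate, type = "l", xlab = "global step",
                 ylab = "learning rate", main = "Decay schedule", ...)
  invisible(x)
}

#' Save or load a fitted classifier
#'
#' The archive holds the live and shadow parameters, global step, class
#' order and the training collection's sites, so predict-time mismatches
#' remain detectable after a round trip.
#'
#' @param object A fitted `gdl_net`.
#' @param path File path (RDS).
#' @return `write_gdl_model()` returns `path` invisibly; `read_gdl_model()`
#'   the restored `gdl_net`.
#' @export
write_gdl_model <- function(object, path) {
  stopifnot(inherits(object, "gdl_net"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_gdl_model
#' @export
read_gdl_model <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "gdl_net")) stop("'", path, "' is not a gdl_net archive")
  object
}
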