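test_that("learning-rate decay follows r * d^(g/s) with staircase floor", {
  expect_equal(decayed_learning_rate(0.1, 0.96, 0, 200), 0.1)
  expect_equal(decayed_learning_rate(0.1, 0.96, 200, 200), 0.096)
  expect_equal(decayed_learning_rate(0.1, 0.96, 300, 200, staircase = TRUE),
               0.096)
  expect_equal(decayed_learning_rate(0.1, 0.96, 300, 200),
               0.1 * 0.96^1.5)
  # strictly decreasing in g (continuous), non-increasing (staircase)
  g <- 0:500
  lr <- decayed_learning_rate(0.1, 0.96, g, 100)
  expect_true(all(diff(lr) < 0))
  lrs <- decayed_learning_rate(0.1, 0.96, g, 100, staircase = TRUE)
  expect_true(all(diff(lrs) <= 0))
})

test_that("shadow update is the exponential moving average of the live value", {
  expect_equal(ema_update(0, 1, 0.99), 0.01)
  expect_equal(ema_update(5, 5, 0.9), 5)            # fixed point
  m <- matrix(1:4, 2); expect_equal(ema_update(m * 0, m, 0.5), m / 2)
  # geometric convergence to a constant live value: S_t = V (1 - d^t)
  for (d in c(0.9, 0.99)) {
    V <- 3; S <- 0
    for (t in 1:50) S <- ema_update(S, V, d)
    expect_equal(S, V * (1 - d^50), tolerance = 1e-12)
  }
  expect_error(ema_update(0, 1, 1), "\\(0, 1\\)")
})

test_that("softmax-head gradient is the p - y residual", {
  # single linear layer, one sample: d(loss)/d(b) equals p - y exactly
  net <- gdl_network(2, hidden = integer(0), classes = c("a", "b", "c"),
                     seed = 4)
  x <- matrix(c(0.3, -1), 1, 2)
  y <- matrix(c(0, 1, 0), 1, 3)
  p <- gdl_forward(net, x)
  gr <- backprop_gradients(net, x, y)
  expect_equal(gr$layers[[1]]$b, drop(p - y), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(gr$layers[[1]]$w, crossprod(x, p - y), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("L2 shifts weight gradients by exactly 2*lambda*w", {
  prob <- random_tiny_problem(21, n_in = 3, hidden = 4, n_classes = 3, n = 5)
  g0 <- backprop_gradients(prob$net, prob$X, prob$Y, lambda = 0)
  g1 <- backprop_gradients(prob$net, prob$X, prob$Y, lambda = 0.05)
  for (t in seq_along(prob$net$layers)) {
    expect_equal(g1$layers[[t]]$w - g0$layers[[t]]$w,
                 2 * 0.05 * prob$net$layers[[t]]$w, tolerance = 1e-12)
    expect_equal(g1$layers[[t]]$b, g0$layers[[t]]$b, tolerance = 1e-12)
  }
})

test_that("backprop matches central finite differences on a tiny net", {
  prob <- random_tiny_problem(1, n_in = 2, hidden = 3, n_classes = 2, n = 4)
  analytic <- backprop_gradients(prob$net, prob$X, prob$Y, lambda = 1e-3)
  numeric <- numeric_gradients(prob$net, prob$X, prob$Y, lambda = 1e-3)
  expect_lt(gradient_rel_error(analytic$layers, numeric), 1e-5)
})

test_that("training is reproducible and actually moves parameters", {
  co <- abc_cohort()
  profiles <- c(co$profiles,
                lapply(1:3, function(i) make_profile(paste0("h", i), "H",
                                                     "9:900:T:A")))
  col <- build_collection(co$profiles, top_k = 3)
  ds <- suppressWarnings(encode_cohort(profiles, col))
  cfg <- gdl_config(max_steps = 5, batch_size = 4, seed = 7, log_every = 1)
  f1 <- gdl_fit(ds, hidden = c(4L), config = cfg)
  f2 <- gdl_fit(ds, hidden = c(4L), config = cfg)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$trace, f2$trace)
  # one step changes parameters
  f3 <- gdl_fit(ds, hidden = c(4L),
                config = gdl_config(max_steps = 1, batch_size = 4, seed = 7))
  init <- gdl_network(3, hidden = c(4L), classes = ds$classes, seed = 7)
  expect_false(identical(coef(f3, use_shadow = FALSE), init$layers))
  expect_error(gdl_config(max_steps = 0), "max_steps")
  # trace learning rates reproduce the decay formula exactly
  expect_equal(f1$trace$learning_rate,
               decayed_learning_rate(cfg$base_lr, cfg$decay_rate,
                                     f1$trace$step, cfg$decay_steps))
})

test_that("full-batch loss is non-increasing at a small constant rate", {
  prob <- random_tiny_problem(33, n_in = 4, hidden = 5, n_classes = 3, n = 8)
  net <- prob$net
  losses <- numeric(50)
  for (i in 1:50) {
    gr <- backprop_gradients(net, prob$X, prob$Y, lambda = 0)
    losses[i] <- gr$loss
    for (t in seq_along(net$layers)) {
      net$layers[[t]]$w <- net$layers[[t]]$w - 0.01 * gr$layers[[t]]$w
      net$layers[[t]]$b <- net$layers[[t]]$b - 0.01 * gr$layers[[t]]$b
    }
  }
  expect_true(all(diff(losses) <= 1e-6))
})

test_that("separable binary synthetic task reaches 100% training accuracy", {
  cfg <- sim_config(classes = "TUM", n_per_class = 30, n_signature = 50,
                    penetrance = 1.0, n_background = 0, bg_rate = 0,
                    signature_overlap = NULL, seed = 13)
  sim <- simulate_cohort(cfg)
  col <- build_collection(sim$profiles[1:30], top_k = 50)
  ds <- suppressWarnings(
    assemble_binary_task(sim$profiles[1:30], sim$profiles[31:60], col))
  fit <- gdl_fit(ds, hidden = c(16L, 8L),
                 config = gdl_config(max_steps = 2000, batch_size = 16,
                                     seed = 5))
  pred <- predict(fit, ds, type = "class")
  truth <- ds$classes[max.col(ds$Y, ties.method = "first")]
  expect_equal(mean(pred == truth), 1)
})

test_that("prediction is side-effect free and checks fingerprints", {
  co <- abc_cohort()
  profiles <- c(co$profiles,
                lapply(1:3, function(i) make_profile(paste0("h", i), "H",
                                                     "9:900:T:A")))
  col <- build_collection(co$profiles, top_k = 2)
  ds <- suppressWarnings(encode_cohort(profiles, col))
  fit <- gdl_fit(ds, hidden = c(3L),
                 config = gdl_config(max_steps = 10, batch_size = 4, seed = 2))
  p1 <- predict(fit, ds)
  expect_identical(p1, predict(fit, ds))
  expect_equal(unname(rowSums(p1)), rep(1, 6), tolerance = 1e-12)
  # duplicated input rows give identical output rows
  X2 <- ds$X[c(1, 1), , drop = FALSE]
  p2 <- predict(fit, X2)
  expect_identical(p2[1, ], p2[2, ])
  # fingerprint mismatch is fatal
  other <- suppressWarnings(encode_cohort(profiles,
    build_collection(profiles, top_k = 3)))
  expect_error(predict(fit, other), "fingerprint")
  expect_error(predict(fit, ds$X[, 1, drop = FALSE]), "columns")
})

test_that("model archive round-trips with fingerprint intact", {
  co <- abc_cohort()
  profiles <- c(co$profiles,
                lapply(1:3, function(i) make_profile(paste0("h", i), "H",
                                                     "9:900:T:A")))
  col <- build_collection(co$profiles, top_k = 2)
  ds <- suppressWarnings(encode_cohort(profiles, col))
  fit <- gdl_fit(ds, hidden = c(3L),
                 config = gdl_config(max_steps = 5, batch_size = 4, seed = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  write_gdl_model(fit, path)
  back <- read_gdl_model(path)
  expect_identical(predict(back, ds), predict(fit, ds))
  expect_identical(back$sites, col$sites)
})
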