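test_that("sigmoid has the right fixed points, symmetry and saturation", {
  expect_equal(sigmoid(0), 0.5)
  x <- c(-3.7, -1, 0.25, 6)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 4))
  expect_lt(abs(sigmoid(50) - 1), 1e-9)
  # stable far into both tails
  expect_equal(sigmoid(c(-500, 500)), c(0, 1), tolerance = 1e-12)
  expect_true(all(is.finite(sigmoid(c(-750, 750)))))
})

test_that("hidden_size follows the sizing rule and validates a", {
  expect_equal(hidden_size(5, 1, 4), 10L)
  expect_equal(hidden_size(5, 4, 1), 10L)
  expect_equal(hidden_size(1, 1, 1), 3L)
  expect_equal(hidden_size(5, 1, 4, rule = "sqrt"), 7L)  # ceil(sqrt(6)) + 4
  expect_error(hidden_size(5, 1, 0), "1-10")
  expect_error(hidden_size(5, 1, 11), "1-10")
})

test_that("forward pass matches hand evaluation and stays in (0,1)", {
  cfg <- network_config(n_input = 2, n_hidden = 3, n_output = 2)
  zero <- decode_genome(rep(0, 2 * 3 + 3 + 4 * 2), cfg)
  fp <- forward(zero, c(0.3, -1.2))
  expect_equal(fp$hidden, rep(0.5, 3))
  expect_equal(fp$output, rep(0.5, 2))

  # 1-1-1 net, unit weights, zero biases, x = 0: hidden f(0)=0.5,
  # output f(0.5)
  cfg1 <- network_config(n_input = 1, n_hidden = 1, n_output = 1)
  w <- decode_genome(c(0, 1, 0, 1), cfg1)
  fp1 <- forward(w, 0)
  expect_equal(fp1$hidden, 0.5)
  expect_equal(fp1$output, 1 / (1 + exp(-0.5)), tolerance = 1e-7)

  expect_error(forward(w, c(1, 2)), "does not match")

  set.seed(3)
  for (i in 1:25) {
    inst <- random_net_instance()
    fp <- forward(inst$weights, runif(3, -5, 5))
    expect_true(all(fp$hidden > 0 & fp$hidden < 1))
    expect_true(all(fp$output > 0 & fp$output < 1))
  }
})

test_that("global_error averages the half squared error per sample", {
  cfg <- network_config(n_input = 2, n_hidden = 2, n_output = 2)
  zero <- decode_genome(rep(0, 3 * 2 + 3 * 2), cfg)
  X1 <- matrix(c(0.1, 0.9), 1, 2)
  # outputs are (0.5, 0.5): b = (1, 0) gives 0.5*(0.25 + 0.25)
  expect_equal(global_error(zero, X1, matrix(c(1, 0), 1, 2)), 0.25)
  # perfect fit
  expect_equal(global_error(zero, X1, matrix(c(0.5, 0.5), 1, 2)), 0)
  # mean over samples
  X2 <- matrix(runif(4), 2, 2)
  B2 <- matrix(c(1, 0.5, 0, 0.5), 2, 2)
  expect_equal(global_error(zero, X2, B2), (0.25 + 0) / 2)
  expect_error(global_error(zero, X1[0, , drop = FALSE],
                            matrix(0, 0, 2)), "empty")
})

test_that("analytic gradients agree with the finite-difference oracle", {
  set.seed(101)
  for (i in 1:5) {
    inst <- random_net_instance()
    g <- bp_gradient(inst$weights, inst$X, inst$B)
    fd <- fd_gradient(inst$weights, inst$X, inst$B)
    denom <- pmax(abs(fd$dV), 1e-8)
    expect_lt(max(abs(g$dV - fd$dV) / denom), 1e-6)
    denom <- pmax(abs(fd$dW), 1e-8)
    expect_lt(max(abs(g$dW - fd$dW) / denom), 1e-6)
  }
})

test_that("a small full-batch step never increases the error", {
  set.seed(202)
  for (i in 1:100) {
    inst <- random_net_instance(m = 2, H = 3, l = 1, n = 4)
    e0 <- global_error(inst$weights, inst$X, inst$B)
    w1 <- backprop_step(inst$weights, inst$X, inst$B, 1e-3, batch = "full")
    expect_lte(global_error(w1, inst$X, inst$B), e0)
  }
})

test_that("zero gradient at a perfect fit leaves weights unchanged", {
  cfg <- network_config(n_input = 2, n_hidden = 2, n_output = 1)
  zero <- decode_genome(rep(0, 3 * 2 + 3), cfg)
  X <- matrix(runif(6), 3, 2)
  b <- rep(0.5, 3)  # zero weights output exactly 0.5
  w1 <- backprop_step(zero, X, b, 0.2, batch = "full")
  expect_equal(w1$V, zero$V)
  expect_equal(w1$W, zero$W)
})

test_that("one online step at the paper's learning rate descends", {
  set.seed(303)
  inst <- random_net_instance(m = 3, H = 4, l = 1, n = 1)
  e0 <- global_error(inst$weights, inst$X, inst$B)
  w1 <- backprop_step(inst$weights, inst$X, inst$B, 0.2, batch = "online")
  expect_lt(global_error(w1, inst$X, inst$B), e0)
})

test_that("min-max normalization maps endpoints and round-trips", {
  X <- matrix(c(2, 6, 10,
                -1, 0, 1), 3, 2)
  nz <- fit_normalizer(X)
  expect_equal(drop(apply_normalizer(nz, c(2, -1))), c(0, 0))
  expect_equal(drop(apply_normalizer(nz, c(10, 1))), c(1, 1))
  expect_equal(drop(apply_normalizer(nz, c(6, 0))), c(0.5, 0.5))
  set.seed(5)
  R <- matrix(runif(20, -1, 10), 10, 2)
  expect_lt(max(abs(invert_normalizer(nz, apply_normalizer(nz, R)) - R)),
            1e-12)
})

test_that("degenerate features are flagged and pinned at 0.5", {
  X <- cbind(a = c(1, 1, 1), b = c(0, 1, 2))
  nz <- fit_normalizer(X)
  expect_equal(unname(nz$degenerate), c(TRUE, FALSE))
  S <- apply_normalizer(nz, X)
  expect_equal(S[, 1], rep(0.5, 3))
  expect_equal(invert_normalizer(nz, S)[, 1], rep(1, 3))
  expect_error(apply_normalizer(list(), X), "not been fitted")
  expect_error(fit_normalizer(X[1, , drop = FALSE]), "at least 2")
})

test_that("training stops at the error goal and is reproducible", {
  toy <- toy_separable_set()
  cfg <- network_config(n_input = 2, n_hidden = 4, max_epochs = 50,
                        error_goal = 10, seed = 9)
  res <- bp_train(cfg, toy$X, toy$b)
  expect_equal(res$epochs_run, 1L)
  expect_true(res$converged)
  expect_length(res$error_history, 1L)

  cfg2 <- network_config(n_input = 2, n_hidden = 4, max_epochs = 40,
                         error_goal = 1e-9, seed = 9)
  r1 <- bp_train(cfg2, toy$X, toy$b)
  r2 <- bp_train(cfg2, toy$X, toy$b)
  expect_identical(r1$error_history, r2$error_history)
  expect_identical(r1$weights, r2$weights)
  expect_equal(r1$epochs_run, 40L)
  expect_false(r1$converged)
  expect_false(r1$ga_initialized)
})

test_that("a representable noiseless toy set trains to the error goal", {
  toy <- toy_separable_set()
  cfg <- network_config(n_input = 2, n_hidden = 4, learning_rate = 0.2,
                        max_epochs = 1000, error_goal = 0.001, seed = 1)
  res <- bp_train(cfg, toy$X, toy$b)
  expect_true(res$converged)
  expect_lt(res$error_history[res$epochs_run], 0.001)
  expect_lte(res$epochs_run, 1000L)
})

test_that("evaluation reports per-sample absolute errors and their mean", {
  toy <- toy_separable_set()
  cfg <- network_config(n_input = 2, n_hidden = 4, max_epochs = 200,
                        seed = 2)
  res <- bp_train(cfg, toy$X, toy$b)
  rep <- evaluate_network(res$weights, NULL, toy$X, toy$b)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(nrow(rep$rows), 4L)
  expect_equal(rep$rows$abs_error, abs(rep$rows$expected - rep$rows$output))
  expect_equal(rep$mean_abs_error, mean(rep$rows$abs_error))
  expect_error(evaluate_network(res$weights, NULL,
                                toy$X[0, , drop = FALSE], numeric(0)),
               "empty")
})
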