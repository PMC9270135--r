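# Three-layer sigmoid perceptron written from first principles: forward pass,
# squared-error global error, backpropagation gradients, min-max
# normalization, hidden-layer sizing, and the training loop.
#
# Weight layout. V is the (m+1) x H input-to-hidden matrix and W the
# (H+1) x l hidden-to-output matrix; row 1 of each is the bias row, fed by a
# constant unit (x_0 = 1, y_0 = 1). Biases are therefore ordinary weights and
# take part in encoding, gradients and GA search like any other entry.

#' Hyperparameters of the three-layer perceptron
#'
#' @param n_input Number of input units m (the five RCM scores by default).
#' @param n_output Number of output units l. The default single sigmoid unit
#'   regresses the continuous treatment-effect target; grades are derived
#'   downstream by thresholding.
#' @param n_hidden Hidden-layer size H. When `NULL`, computed by
#'   [hidden_size()] from `hidden_constant` and `hidden_rule`.
#' @param learning_rate Gradient-descent step in (0, 1); 0.2 by default.
#' @param max_epochs Maximum training epochs (default 1000).
#' @param error_goal Training stops once the global error E falls to or below
#'   this value (default 0.001).
#' @param hidden_constant Additive constant a in 1-10 of the hidden-size rule
#'   (default 4, giving H = 5 + 1 + 4 = 10 for the default architecture).
#' @param hidden_rule `"linear"` for H = m + n + a (default) or `"sqrt"` for
#'   H = ceiling(sqrt(m + n)) + a.
#' @param init_scale Half-width of the uniform weight initialization
#'   \[-init_scale, init_scale\] (default 0.5).
#' @param batch `"online"` (default; one gradient step per sample, in order)
#'   or `"full"` (one accumulated step per epoch). See the methods vignette
#'   for why online updating is the training default.
#' @param seed Integer seed controlling weight initialization in [bp_train()].
#' @return Object of class `network_config`.
#' @export
network_config <- function(n_input = 5L, n_output = 1L, n_hidden = NULL,
                           learning_rate = 0.2, max_epochs = 1000L,
                           error_goal = 0.001, hidden_constant = 4L,
                           hidden_rule = c("linear", "sqrt"),
                           init_scale = 0.5,
                           batch = c("online", "full"), seed = 1L) {
  hidden_rule <- match.arg(hidden_rule)
  batch <- match.arg(batch)
  stopifnot(n_input >= 1, n_output >= 1, max_epochs >= 1, init_scale > 0)
  if (learning_rate <= 0 || learning_rate >= 1) {
    stop("learning_rate must lie in (0, 1)")
  }
  if (error_goal <= 0) stop("error_goal must be positive")
  if (is.null(n_hidden)) {
    n_hidden <- hidden_size(n_input, n_output, hidden_constant, hidden_rule)
  }
  stopifnot(n_hidden >= 1)
  structure(
    list(n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
         n_output = as.integer(n_output), learning_rate = learning_rate,
         max_epochs = as.integer(max_epochs), error_goal = error_goal,
         hidden_constant = as.integer(hidden_constant),
         hidden_rule = hidden_rule, init_scale = init_scale, batch = batch,
         seed = as.integer(seed)),
    class = "network_config")
}

#' Hidden-layer size rule
#'
#' Default rule H = m + n + a with the constant a in 1-10; the `"sqrt"`
#' variant H = ceiling(sqrt(m + n)) + a is the form more commonly attributed
#' to the same sizing heuristic.
#'
#' @param m Input units (>= 1).
#' @param n Output units (>= 1).
#' @param a Integer constant in 1-10.
#' @param rule `"linear"` (default) or `"sqrt"`.
#' @return Integer hidden size.
#' @examples
#' hidden_size(5, 1, 4)  # 10
#' @export
hidden_size <- function(m, n, a, rule = c("linear", "sqrt")) {
  rule <- match.arg(rule)
  stopifnot(m >= 1, n >= 1)
  if (a < 1 || a > 10) stop("hidden-size constant a must lie in 1-10")
  if (rule == "linear") as.integer(m + n + a)
  else as.integer(ceiling(sqrt(m + n)) + a)
}

#' Unipolar sigmoid activation
#'
#' f(x) = 1 / (1 + exp(-x)), computed in a branch-stable form so large
#' negative arguments do not overflow.
#'
#' @param x Numeric vector or matrix.
#' @return Values in (0, 1), same shape as `x`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Random initial weights for a network configuration
#'
#' Entries drawn uniformly from \[-init_scale, init_scale\] using the current
#' RNG state (seed the RNG before calling for reproducibility).
#'
#' @param config A [network_config()].
#' @return Object of class `network_weights`: list with matrices `V`
#'   ((m+1) x H) and `W` ((H+1) x l), bias rows first.
#' @export
init_weights <- function(config) {
  m <- config$n_input; H <- config$n_hidden; l <- config$n_output
  s <- config$init_scale
  new_network_weights(
    V = matrix(stats::runif((m + 1) * H, -s, s), m + 1, H),
    W = matrix(stats::runif((H + 1) * l, -s, s), H + 1, l))
}

new_network_weights <- function(V, W) {
  stopifnot(is.matrix(V), is.matrix(W), ncol(V) + 1L == nrow(W))
  if (!all(is.finite(V)) || !all(is.finite(W))) {
    stop("network weights must be finite")
  }
  structure(list(V = V, W = W), class = "network_weights")
}

# Batch forward pass. X is n x m (rows = samples). Returns hidden and output
# activation matrices.
forward_pass <- function(weights, X) {
  if (ncol(X) + 1L != nrow(weights$V)) {
    stop("input dimension ", ncol(X), " does not match network input size ",
         nrow(weights$V) - 1L)
  }
  Xb <- cbind(1, X)
  Y <- sigmoid(Xb %*% weights$V)
  Yb <- cbind(1, Y)
  O <- sigmoid(Yb %*% weights$W)
  list(hidden = Y, output = O)
}

#' Forward pass for a single input vector
#'
#' Hidden activations y_j = f(sum_i v_ij x_i) and outputs
#' O_k = f(sum_j w_jk y_j), with bias units x_0 = y_0 = 1 and f the
#' [sigmoid()].
#'
#' @param weights A `network_weights` object.
#' @param x Numeric input vector of length m.
#' @return List with `hidden` (length H) and `output` (length l), all values
#'   in (0, 1).
#' @export
forward <- function(weights, x) {
  stopifnot(is.numeric(x))
  fp <- forward_pass(weights, matrix(x, nrow = 1))
  list(hidden = drop(fp$hidden), output = drop(fp$output))
}

as_target_matrix <- function(B, n, l) {
  B <- as.matrix(B)
  if (nrow(B) != n || ncol(B) != l) {
    stop("target dimensions ", nrow(B), "x", ncol(B),
         " do not match ", n, " samples with ", l, " outputs")
  }
  B
}

#' Global network error on a dataset
#'
#' Per-sample squared error 0.5 * sum_k (b_k - O_k)^2, averaged over the
#' samples (the mean keeps E on the same scale regardless of cohort size,
#' matching the 0.001 error goal).
#'
#' @param weights A `network_weights` object.
#' @param X n x m matrix of inputs (rows = samples).
#' @param B n x l matrix (or length-n vector when l = 1) of expected outputs.
#' @return Non-negative scalar E.
#' @export
global_error <- function(weights, X, B) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("dataset is empty")
  B <- as_target_matrix(B, nrow(X), ncol(weights$W))
  O <- forward_pass(weights, X)$output
  mean(0.5 * rowSums((B - O)^2))
}

#' Analytic gradient of the global error
#'
#' Backpropagation by the chain rule with sigmoid derivative
#' f'(net) = f(net)(1 - f(net)), for the mean-over-samples error of
#' [global_error()]. Exposed so the gradients can be checked against finite
#' differences.
#'
#' @inheritParams global_error
#' @return List with matrices `dV` and `dW` matching the weight shapes.
#' @export
bp_gradient <- function(weights, X, B) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("dataset is empty")
  n <- nrow(X)
  B <- as_target_matrix(B, n, ncol(weights$W))
  Xb <- cbind(1, X)
  Y <- sigmoid(Xb %*% weights$V)
  Yb <- cbind(1, Y)
  O <- sigmoid(Yb %*% weights$W)
  # delta at the output layer: dE/dnet_k, with the 1/n of the mean folded in
  delta_out <- -(B - O) * O * (1 - O) / n
  dW <- crossprod(Yb, delta_out)
  delta_hid <- (delta_out %*% t(weights$W[-1, , drop = FALSE])) * Y * (1 - Y)
  dV <- crossprod(Xb, delta_hid)
  list(dV = dV, dW = dW)
}

#' One gradient-descent weight update
#'
#' Full-batch mode takes a single step along the accumulated gradient,
#' Delta w = -mu dE/dw; online mode sweeps the samples in order, stepping on
#' each sample's own error gradient.
#'
#' @inheritParams global_error
#' @param learning_rate Step size mu in (0, 1).
#' @param batch `"full"` or `"online"`.
#' @return Updated `network_weights`.
#' @export
backprop_step <- function(weights, X, B, learning_rate,
                          batch = c("full", "online")) {
  batch <- match.arg(batch)
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("dataset is empty")
  if (learning_rate <= 0 || learning_rate >= 1) {
    stop("learning_rate must lie in (0, 1)")
  }
  B <- as_target_matrix(B, nrow(X), ncol(weights$W))
  if (batch == "full") {
    g <- bp_gradient(weights, X, B)
    return(new_network_weights(weights$V - learning_rate * g$dV,
                               weights$W - learning_rate * g$dW))
  }
  V <- weights$V; W <- weights$W
  Xb <- cbind(1, X)
  # hot loop: plain sigmoid form is safe here (exp overflow saturates to 0/1)
  for (s in seq_len(nrow(X))) {
    xb <- Xb[s, ]
    y <- 1 / (1 + exp(-(xb %*% V)))
    yb <- c(1, y)
    o <- 1 / (1 + exp(-(yb %*% W)))
    d_out <- (o - B[s, ]) * o * (1 - o)
    d_hid <- (d_out %*% t(W[-1L, , drop = FALSE])) * y * (1 - y)
    V <- V - learning_rate * (xb %o% drop(d_hid))
    W <- W - learning_rate * (yb %o% drop(d_out))
  }
  new_network_weights(V, W)
}

#' Train the perceptron by gradient descent
#'
#' Repeats [backprop_step()] until the global error E reaches `error_goal` or
#' `max_epochs` epochs have run. E is recorded after every epoch. With
#' `weights = NULL` the RNG is seeded from `config$seed` and weights are drawn
#' by [init_weights()], so a run is fully reproducible from the config.
#'
#' @param config A [network_config()].
#' @param X n x m matrix of (normalized) training inputs.
#' @param B Training targets in \[0, 1\] (length-n vector or n x l matrix).
#' @param weights Optional starting `network_weights` (e.g. a GA-decoded
#'   genome); overrides random initialization.
#' @return Object of class `train_result`: list with `weights`,
#'   `error_history` (length `epochs_run`), `epochs_run`, `converged`
#'   (E <= error_goal), and `ga_initialized`.
#' @export
bp_train <- function(config, X, B, weights = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("training set is empty")
  B <- as_target_matrix(B, nrow(X), config$n_output)
  if (is.null(weights)) {
    set.seed(config$seed)
    weights <- init_weights(config)
    ga_init <- FALSE
  } else {
    ga_init <- isTRUE(attr(weights, "ga_initialized"))
  }
  history <- numeric(config$max_epochs)
  epochs <- 0L
  converged <- FALSE
  for (ep in seq_len(config$max_epochs)) {
    weights <- backprop_step(weights, X, B, config$learning_rate,
                             batch = config$batch)
    E <- global_error(weights, X, B)
    if (!is.finite(E)) stop("training diverged at epoch ", ep)
    epochs <- ep
    history[ep] <- E
    if (E <= config$error_goal) { converged <- TRUE; break }
  }
  structure(
    list(weights = weights, error_history = history[seq_len(epochs)],
         epochs_run = epochs, converged = converged,
         ga_initialized = ga_init),
    class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %s init, %d epoch(s), final E = %.6g, %s\n",
              if (x$ga_initialized) "GA" else "random", x$epochs_run,
              x$error_history[x$epochs_run],
              if (x$converged) "converged" else "goal not reached"))
  invisible(x)
}

#' Fit a per-feature min-max normalizer
#'
#' Records each feature's minimum and maximum on the training inputs so they
#' can be mapped into \[0, 1\] by X = (I - I_min) / (I_max - I_min). Features
#' that are constant on the training set are flagged degenerate and map to
#' 0.5.
#'
#' @param X Matrix or data.frame of training features (>= 2 rows).
#' @return Object of class `minmax_normalizer`.
#' @export
fit_normalizer <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples to fit a normalizer")
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  structure(list(min = mins, max = maxs, degenerate = maxs == mins),
            class = "minmax_normalizer")
}

#' Apply a fitted min-max normalizer
#'
#' @param normalizer A [fit_normalizer()] result.
#' @param X Matrix (or vector interpreted as one sample) of raw features.
#' @return Scaled matrix; in-range inputs land in \[0, 1\], degenerate
#'   features at 0.5.
#' @export
apply_normalizer <- function(normalizer, X) {
  if (!inherits(normalizer, "minmax_normalizer")) {
    stop("normalizer has not been fitted")
  }
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  rng <- normalizer$max - normalizer$min
  rng[normalizer$degenerate] <- 1  # placeholder; column overwritten below
  S <- sweep(sweep(X, 2, normalizer$min), 2, rng, "/")
  S[, normalizer$degenerate] <- 0.5
  S
}

#' Invert a min-max normalization
#'
#' Maps scaled features back to the original units; the round trip
#' `invert_normalizer(nz, apply_normalizer(nz, X))` reproduces X to machine
#' precision for non-degenerate features (degenerate features return their
#' constant training value).
#'
#' @inheritParams apply_normalizer
#' @param X_scaled Matrix of scaled features.
#' @return Matrix in original units.
#' @export
invert_normalizer <- function(normalizer, X_scaled) {
  if (!inherits(normalizer, "minmax_normalizer")) {
    stop("normalizer has not been fitted")
  }
  X_scaled <- if (is.null(dim(X_scaled))) matrix(X_scaled, nrow = 1)
              else as.matrix(X_scaled)
  rng <- normalizer$max - normalizer$min
  out <- sweep(sweep(X_scaled, 2, rng, "*"), 2, normalizer$min, "+")
  out[, normalizer$degenerate] <-
    matrix(normalizer$min[normalizer$degenerate],
           nrow(out), sum(normalizer$degenerate), byrow = TRUE)
  out
}

#' Evaluate a trained network on a test set
#'
#' Produces one row per test sample — expected output b, model output O, and
#' absolute error |b - O| — plus their mean, mirroring the shape of a
#' validation table.
#'
#' @param weights Trained `network_weights`.
#' @param normalizer The `minmax_normalizer` fitted on the training features,
#'   or `NULL` if inputs are already scaled.
#' @param X Test features (raw units when `normalizer` is given).
#' @param b Expected outputs, length n.
#' @param ids Optional sample identifiers (default 1..n).
#' @return Object of class `evaluation_report`: list with `rows` (data.frame
#'   `id`, `expected`, `output`, `abs_error`) and `mean_abs_error`.
#' @export
evaluate_network <- function(weights, normalizer, X, b, ids = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("test set is empty")
  stopifnot(length(b) == nrow(X))
  if (!is.null(normalizer)) X <- apply_normalizer(normalizer, X)
  O <- drop(forward_pass(weights, X)$output)
  if (is.null(ids)) ids <- seq_len(nrow(X))
  rows <- data.frame(id = ids, expected = as.numeric(b), output = O,
                     abs_error = abs(as.numeric(b) - O))
  structure(list(rows = rows, mean_abs_error = mean(rows$abs_error)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d sample(s), mean |error| = %.4f\n",
              nrow(x$rows), x$mean_abs_error))
  print(utils::head(x$rows, 10), row.names = FALSE)
  if (nrow(x$rows) > 10) cat("...\n")
  invisible(x)
}
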