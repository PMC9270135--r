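# Shared fixtures and independent oracles.

# Central finite-difference gradient of the global error. Deliberately walks
# the error function weight-by-weight, independent of the analytic
# backpropagation path it is used to check.
fd_gradient <- function(weights, X, B, h = 1e-5) {
  num_layer <- function(layer) {
    M <- weights[[layer]]
    G <- M
    for (i in seq_along(M)) {
      wp <- weights; wp[[layer]][i] <- M[i] + h
      wm <- weights; wm[[layer]][i] <- M[i] - h
      G[i] <- (global_error(wp, X, B) - global_error(wm, X, B)) / (2 * h)
    }
    G
  }
  list(dV = num_layer("V"), dW = num_layer("W"))
}

# Random architecture + weights + data for gradient checks.
random_net_instance <- function(m = 3, H = 4, l = 2, n = 5) {
  cfg <- network_config(n_input = m, n_hidden = H, n_output = l)
  w <- init_weights(cfg)
  X <- matrix(runif(n * m), n, m)
  B <- matrix(runif(n * l), n, l)
  list(config = cfg, weights = w, X = X, B = B)
}

# A full MASI assessment data.frame, defaulting to all-zero components.
masi_regions <- function(D = c(0, 0, 0, 0), H = c(0, 0, 0, 0),
                         A = c(0, 0, 0, 0)) {
  data.frame(region = names(masi_region_weights), D = D, H = H, A = A)
}

# Tiny noiseless training set a one-hidden-layer sigmoid net can drive the
# error goal on: four points, two features, smooth monotone targets.
toy_separable_set <- function() {
  X <- matrix(c(0, 0, 1, 1,
                0, 1, 0, 1), 4, 2)
  list(X = X, b = c(0.2, 0.4, 0.6, 0.8))
}
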