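#' Learning configuration
#'
#' Hyperparameters of the joint gradient-descent / SpikeProp training rule.
#'
#' @param eta learning rate in (0, 1). Default 0.03.
#' @param decay multiplicative per-epoch learning-rate factor in (0, 1];
#'   1 keeps the rate fixed. Epoch `e` uses `eta * decay^(e - 1)`.
#' @param denom_floor lower bound on the magnitude of the membrane-potential
#'   slope in SpikeProp delta denominators; shallow threshold crossings make
#'   the raw denominator arbitrarily small, so it is floored (sign preserved)
#'   to keep updates bounded. Default 0.1.
#' @param r_floor floor on the activation inside the `beta / R^2` backward
#'   factor of the reciprocal coding, preventing overflow for near-zero
#'   activations. Default 1e-3.
#' @param max_step elementwise cap on the magnitude of every per-sample
#'   weight increment applied during training. Floored delta denominators
#'   can inflate a single online update by orders of magnitude, which
#'   saturates the sigmoid layer and clamps the whole coding layer to `T` —
#'   an unrecoverable state since the clamp passes no gradient; clipping the
#'   step keeps such excursions bounded while leaving ordinary updates
#'   (orders of magnitude smaller) untouched. Default 0.2.
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(eta = 0.03, decay = 1, denom_floor = 0.1,
                            r_floor = 1e-3, max_step = 0.2) {
  stopifnot(eta > 0, eta < 1, decay > 0, decay <= 1, denom_floor > 0,
            max_step > 0)
  structure(list(eta = eta, decay = decay, denom_floor = denom_floor,
                 r_floor = r_floor, max_step = max_step),
            class = "learning_config")
}

#' Learning rate at a given epoch
#'
#' @param cfg a [learning_config()].
#' @param epoch epoch number (1-based).
#' @return `eta * decay^(epoch - 1)`.
#' @export
effective_eta <- function(cfg, epoch) cfg$eta * cfg$decay^(epoch - 1)

#' Squared-error loss on output firing times
#'
#' `E = 1/2 * sum_j (t_j - t_j^d)^2` between actual and expected output
#' spike times.
#'
#' @param actual a [spike_vector()] or numeric vector of actual firing times.
#' @param expected numeric vector of expected firing times (see
#'   [encode_labels()]).
#' @return Scalar loss.
#' @export
spike_loss <- function(actual, expected) {
  t <- if (inherits(actual, "spike_vector")) actual$times else actual
  stopifnot(length(t) == length(expected))
  0.5 * sum((t - expected)^2)
}

floor_signed <- function(x, fl) {
  s <- ifelse(x < 0, -1, 1)
  ifelse(abs(x) < fl, s * fl, x)
}

#' SpikeProp deltas of the output layer
#'
#' For each output neuron `j`,
#' `delta_j = (t_j^d - t_j) / D_j` with
#' `D_j = sum_q sum_k v[q, j, k] * srm_kernel_deriv(t_j - t_q - d_k)`,
#' the slope of the membrane potential at the firing time. `|D_j|` is floored
#' at `cfg$denom_floor` (sign preserved) to stabilize shallow crossings. A
#' silent neuron carries no genuine crossing: its clamped time `T` may sit
#' on a decaying stretch of the potential, where the raw slope would flip
#' the update away from "raise the weights until it fires", so for unfired
#' neurons the denominator is forced positive (`max(D_j, denom_floor)`). A
#' `floored` attribute records where either guard was active.
#'
#' @param actual [spike_vector()] of actual output firing times.
#' @param expected numeric vector of expected firing times.
#' @param coding_spikes [spike_vector()] feeding the output layer.
#' @param layer the output [srm_layer()].
#' @param cfg a [learning_config()].
#' @return Numeric vector `delta` of length `J` with attribute `floored`.
#' @export
output_delta <- function(actual, expected, coding_spikes, layer,
                         cfg = learning_config()) {
  J <- dim(layer$weights)[2]
  D <- vapply(seq_len(J), function(j)
    membrane_potential_rate(actual$times[j], coding_spikes, layer, j),
    numeric(1))
  Df <- ifelse(actual$fired, floor_signed(D, cfg$denom_floor),
               pmax(D, cfg$denom_floor))
  structure((expected - actual$times) / Df, floored = Df != D)
}

#' Output-layer weight updates
#'
#' `delta_v[q, j, k] = -eta * delta_j * srm_kernel(t_j - t_q - d_k)`: the
#' SpikeProp rule for the weights between the coding layer and the output
#' layer. Synapses whose kernel window has not opened at the firing time
#' (`t_j - t_q - d_k <= 0`) receive no update.
#'
#' @param deltas output of [output_delta()].
#' @param coding_spikes [spike_vector()] feeding the output layer.
#' @param actual [spike_vector()] of output firing times.
#' @param layer the output [srm_layer()].
#' @param cfg a [learning_config()].
#' @param eta learning rate; defaults to `cfg$eta` (pass the decayed rate
#'   during scheduled training).
#' @return Array of weight increments, same shape as `layer$weights`.
#' @export
output_weight_update <- function(deltas, coding_spikes, actual, layer,
                                 cfg = learning_config(), eta = cfg$eta) {
  d <- dim(layer$weights)
  tau <- layer$kernel$tau
  dv <- array(0, dim = d)
  for (j in seq_len(d[2])) {
    s <- outer(actual$times[j] - coding_spikes$times, layer$delays, `-`)
    dv[, j, ] <- -eta * deltas[j] * srm_kernel(s, tau)
  }
  dv
}

#' Loss gradient with respect to a coding-layer spike time
#'
#' `dE/dt_q = sum_j delta_j * sum_k v[q, j, k] *
#' (-srm_kernel_deriv(t_j - t_q - d_k))`: moving a presynaptic spike later
#' shifts every postsynaptic potential, and through it the output firing
#' times.
#'
#' @inheritParams output_weight_update
#' @return Numeric vector `dE/dt_q` over coding-layer positions.
#' @export
hidden_time_gradient <- function(deltas, actual, coding_spikes, layer) {
  d <- dim(layer$weights)
  tau <- layer$kernel$tau
  g <- numeric(d[1])
  for (j in seq_len(d[2])) {
    s <- outer(actual$times[j] - coding_spikes$times, layer$delays, `-`)
    wj <- matrix(layer$weights[, j, ], nrow = d[1])
    g <- g + deltas[j] * rowSums(wj * (-srm_kernel_deriv(s, tau)))
  }
  g
}

#' ANN weight updates of the concatenated network
#'
#' Chains the coding-time gradient through the reciprocal coding
#' (`dt_q/dR_q = -beta/R_q^2`) and the sigmoid
#' (`dR_q/dw_nq = R_q (1 - R_q) x_n`):
#' `delta_w[n, q] = eta * beta * (dE/dt_q) * R_q (1 - R_q) * x_n / R_q^2`.
#' Columns whose coding time was clamped to `T` receive no update (the clamp
#' is flat), and `R_q` is floored at `cfg$r_floor` inside the `beta / R_q^2`
#' factor.
#'
#' @param x input vector with bias appended.
#' @param R activation vector from [ann_forward()].
#' @param time_grads `dE/dt_q` from [hidden_time_gradient()].
#' @param clamped logical clamp mask from [reciprocal_encode()].
#' @param cfg a [learning_config()].
#' @param coding a [coding_config()] (for `beta`).
#' @param eta learning rate; defaults to `cfg$eta`.
#' @return Matrix of weight increments, `length(x)` by `length(R)`.
#' @export
cstnet_ann_update <- function(x, R, time_grads, clamped,
                              cfg = learning_config(),
                              coding = coding_config(), eta = cfg$eta) {
  Rf <- pmax(R, cfg$r_floor)
  colf <- eta * coding$beta * time_grads * R * (1 - R) / Rf^2
  colf[clamped] <- 0
  outer(x, colf)
}

#' Upper-path hidden weight updates of the parallel network
#'
#' The SpikeProp hidden-layer rule for the SRM layer between the encoded
#' input and the upper-path hidden neurons:
#' `delta_b[m, p, k] = eta * (dE/dt_p) * srm_kernel(t_p - s_m - d_k) / D_p`
#' with `D_p` the membrane-potential slope of hidden neuron `p` at its firing
#' time (floored as in [output_delta()]) and `dE/dt_p` obtained from
#' [hidden_time_gradient()] over the hidden positions of the output layer.
#' Hidden neurons that stayed silent receive no update; their count is
#' attached as attribute `n_silent`.
#'
#' @param input_spikes [spike_vector()] of encoded upper-path input times.
#' @param hidden_spikes [spike_vector()] of upper-path hidden firing times.
#' @param deltas output-layer deltas from [output_delta()].
#' @param out_actual [spike_vector()] of output firing times.
#' @param out_layer output [srm_layer()]; its first
#'   `length(hidden_spikes$times)` presynaptic positions are the upper path.
#' @param upper_layer the upper-path [srm_layer()].
#' @param cfg a [learning_config()].
#' @param eta learning rate; defaults to `cfg$eta`.
#' @return Array of weight increments, same shape as `upper_layer$weights`,
#'   with attribute `n_silent`.
#' @export
pstnet_upper_update <- function(input_spikes, hidden_spikes, deltas,
                                out_actual, out_layer, upper_layer,
                                cfg = learning_config(), eta = cfg$eta) {
  P <- length(hidden_spikes$times)
  tau <- upper_layer$kernel$tau
  db <- array(0, dim = dim(upper_layer$weights))
  J <- dim(out_layer$weights)[2]
  # dE/dt_p over the upper-path coding positions (the first P presynaptic
  # slots of the output layer)
  g <- numeric(P)
  for (j in seq_len(J)) {
    s <- outer(out_actual$times[j] - hidden_spikes$times,
               out_layer$delays, `-`)
    wj <- matrix(out_layer$weights[seq_len(P), j, ], nrow = P)
    g <- g + deltas[j] * rowSums(wj * (-srm_kernel_deriv(s, tau)))
  }
  n_silent <- 0L
  for (p in seq_len(P)) {
    if (!hidden_spikes$fired[p]) { n_silent <- n_silent + 1L; next }
    D <- membrane_potential_rate(hidden_spikes$times[p], input_spikes,
                                 upper_layer, p)
    Df <- floor_signed(D, cfg$denom_floor)
    s <- outer(hidden_spikes$times[p] - input_spikes$times,
               upper_layer$delays, `-`)
    db[, p, ] <- eta * g[p] * srm_kernel(s, tau) / Df
  }
  structure(db, n_silent = n_silent)
}

#' Calibrated random initialization of an SRM layer
#'
#' Weights are drawn uniformly on `(0, 2 theta / (K * n_pre * eps_bar))`,
#' where `eps_bar` is the mean kernel value over the simulation window, so
#' that initial peak membrane potentials straddle the threshold and most
#' neurons fire from the first epoch (a silent network produces no firing
#' times to differentiate).
#'
#' @param layer an [srm_layer()].
#' @param sim a [sim_config()].
#' @return The layer with randomized weights (uses the current RNG state).
#' @export
init_srm_layer <- function(layer, sim = sim_config()) {
  d <- dim(layer$weights)
  grid <- seq(0, sim$T, by = sim$dt)
  eps_bar <- mean(srm_kernel(grid, layer$kernel$tau))
  hi <- 2 * sim$theta / (layer$K * d[1] * eps_bar)
  layer$weights <- array(stats::runif(prod(d), 0, hi), dim = d)
  layer
}

#' Glorot-style random initialization of a sigmoid layer
#'
#' Weights uniform on `(-sqrt(6/(n_in + n_out)), +sqrt(6/(n_in + n_out)))`.
#'
#' @param layer a [sigmoid_layer()].
#' @return The layer with randomized weights (uses the current RNG state).
#' @export
init_sigmoid_layer <- function(layer) {
  n_in <- nrow(layer$weights); n_out <- ncol(layer$weights)
  lim <- sqrt(6 / (n_in + n_out))
  layer$weights <- matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
  layer
}
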