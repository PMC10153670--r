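#' Simulation window configuration
#'
#' Settings for the time-discretized simulation of spike-response-model (SRM)
#' layers: the window length `T`, the firing threshold `theta`, the grid step
#' `dt`, and how the threshold-crossing time is reported.
#'
#' A neuron fires when its membrane potential first reaches `theta` within
#' `[0, T]`; a neuron whose potential never reaches the threshold stays
#' silent and its downstream spike time is clamped to `T`. With
#' `refine = "linear"` (the default) the crossing time is refined by linear
#' interpolation inside the grid cell where the potential first reaches the
#' threshold, so firing times vary continuously with the weights; with
#' `refine = "none"` the first grid point at or above the threshold is
#' reported as-is.
#'
#' @param T simulation window length (time units). Default 10.
#' @param theta firing threshold (potential units). Default 1.
#' @param dt time-grid step. Default 0.01.
#' @param refine `"linear"` or `"none"`; see Details.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config()
#' sim_config(dt = 0.001)
#' @export
sim_config <- function(T = 10, theta = 1, dt = 0.01,
                       refine = c("linear", "none")) {
  refine <- match.arg(refine)
  stopifnot(T > 0, theta > 0, dt > 0, dt < T)
  structure(list(T = T, theta = theta, dt = dt, refine = refine),
            class = "sim_config")
}

#' Spike-response kernel configuration
#'
#' @param tau kernel time constant controlling the shape of the postsynaptic
#'   potential. Default 7.
#' @return An object of class `kernel_config`.
#' @export
kernel_config <- function(tau = 7) {
  stopifnot(tau > 0)
  structure(list(tau = tau), class = "kernel_config")
}

#' Spike-response kernel
#'
#' The alpha-shaped kernel `(s/tau) * exp(1 - s/tau)` for `s > 0` and exactly
#' 0 for `s <= 0`. It rises from 0, peaks at value 1 when `s = tau`, and
#' decays back toward 0; it models the postsynaptic potential evoked by one
#' presynaptic spike arriving through one delayed synapse.
#'
#' @param s elapsed time since the (delayed) presynaptic spike; vectorized.
#' @param tau kernel time constant, or a [kernel_config()].
#' @return Kernel values, same length as `s`.
#' @examples
#' srm_kernel(7)            # peak value 1
#' srm_kernel(c(-1, 0, 14)) # zero for s <= 0
#' @export
srm_kernel <- function(s, tau = 7) {
  if (inherits(tau, "kernel_config")) tau <- tau$tau
  ifelse(s > 0, (s / tau) * exp(1 - s / tau), 0)
}

#' Time derivative of the spike-response kernel
#'
#' Analytic derivative `(1/tau) exp(1 - s/tau) - (1/tau) srm_kernel(s)` for
#' `s > 0`, 0 for `s <= 0`. Vanishes at the kernel peak `s = tau`.
#'
#' @inheritParams srm_kernel
#' @return Derivative values, same length as `s`.
#' @export
srm_kernel_deriv <- function(s, tau = 7) {
  if (inherits(tau, "kernel_config")) tau <- tau$tau
  ifelse(s > 0, exp(1 - s / tau) / tau - srm_kernel(s, tau) / tau, 0)
}

#' Spike vector
#'
#' Per-neuron first firing times within the simulation window, with flags for
#' neurons that never reached the threshold (their time is clamped to the
#' window end `T`) and, where relevant, for coding neurons whose analytically
#' computed time was clamped to `T`.
#'
#' @param times numeric vector of firing times in `[0, T]`.
#' @param fired logical vector; `FALSE` for silent neurons.
#' @param clamped logical vector; `TRUE` where a coding rule clamped the time.
#' @param peak optional per-neuron peak membrane potential (diagnostics and
#'   tie-breaking in [first_spike_class()]).
#' @return An object of class `spike_vector`.
#' @export
spike_vector <- function(times, fired = rep(TRUE, length(times)),
                         clamped = rep(FALSE, length(times)), peak = NULL) {
  stopifnot(length(fired) == length(times), length(clamped) == length(times))
  structure(list(times = as.numeric(times), fired = as.logical(fired),
                 clamped = as.logical(clamped), peak = peak),
            class = "spike_vector")
}

#' @export
print.spike_vector <- function(x, ...) {
  cat("spike_vector:", length(x$times), "neurons,",
      sum(x$fired), "fired\n")
  print(round(x$times, 4))
  invisible(x)
}

#' Multi-synapse SRM layer
#'
#' A fully connected spiking layer in which every presynaptic/postsynaptic
#' neuron pair is linked by `K` synapses with distinct conduction delays
#' (default `d_k = k`). The weight tensor is `weights[q, j, k]`.
#'
#' @param n_pre number of presynaptic neurons.
#' @param n_post number of postsynaptic neurons.
#' @param n_synapses synapses per connection (`K`). Default 6.
#' @param delays strictly increasing synaptic delays, length `K`.
#' @param kernel a [kernel_config()].
#' @param weights optional `n_pre x n_post x K` array; zero if omitted.
#' @return An object of class `srm_layer`.
#' @seealso [init_srm_layer()] for the calibrated random initialization used
#'   before training.
#' @export
srm_layer <- function(n_pre, n_post, n_synapses = 6,
                      delays = seq_len(n_synapses),
                      kernel = kernel_config(), weights = NULL) {
  stopifnot(n_pre >= 1, n_post >= 1, n_synapses >= 1,
            length(delays) == n_synapses, all(diff(delays) > 0) || n_synapses == 1)
  if (is.null(weights)) {
    weights <- array(0, dim = c(n_pre, n_post, n_synapses))
  } else {
    weights <- array(as.numeric(weights), dim = c(n_pre, n_post, n_synapses))
  }
  structure(list(weights = weights, delays = as.numeric(delays),
                 K = n_synapses, kernel = kernel),
            class = "srm_layer")
}

#' @export
print.srm_layer <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("srm_layer: %d -> %d neurons, K = %d synapses, tau = %g\n",
              d[1], d[2], x$K, x$kernel$tau))
  invisible(x)
}

check_srm_inputs <- function(inputs, layer) {
  if (length(inputs$times) != dim(layer$weights)[1])
    stop("input spike vector length (", length(inputs$times),
         ") does not match presynaptic count (", dim(layer$weights)[1], ")")
  invisible(TRUE)
}

#' Membrane potential of one postsynaptic SRM neuron
#'
#' Sum of weighted postsynaptic potentials
#' `u_j(t) = sum_q sum_k v[q, j, k] * srm_kernel(t - t_q - d_k)`.
#' Silent presynaptic neurons contribute through their clamped time `T`.
#'
#' @param t evaluation time(s); vectorized.
#' @param inputs a [spike_vector()] of presynaptic firing times.
#' @param layer an [srm_layer()].
#' @param j postsynaptic neuron index (1-based).
#' @return `u_j(t)`, same length as `t`.
#' @export
membrane_potential <- function(t, inputs, layer, j) {
  check_srm_inputs(inputs, layer)
  tau <- layer$kernel$tau
  w <- layer$weights[, j, , drop = FALSE]
  arr <- outer(inputs$times, layer$delays, `+`)  # n_pre x K arrival times
  vapply(t, function(tt) {
    sum(w * array(srm_kernel(tt - arr, tau), dim = dim(w)))
  }, numeric(1))
}

#' Time derivative of the membrane potential
#'
#' `du_j/dt (t) = sum_q sum_k v[q, j, k] * srm_kernel_deriv(t - t_q - d_k)`;
#' the denominator of the SpikeProp firing-time derivative.
#'
#' @inheritParams membrane_potential
#' @return `du_j/dt (t)`, same length as `t`.
#' @export
membrane_potential_rate <- function(t, inputs, layer, j) {
  check_srm_inputs(inputs, layer)
  tau <- layer$kernel$tau
  w <- layer$weights[, j, , drop = FALSE]
  arr <- outer(inputs$times, layer$delays, `+`)
  vapply(t, function(tt) {
    sum(w * array(srm_kernel_deriv(tt - arr, tau), dim = dim(w)))
  }, numeric(1))
}

#' First threshold crossing of an SRM layer
#'
#' Simulates all postsynaptic neurons of `layer` on the uniform grid
#' `t = 0, dt, ..., T` and reports, for each, the first time the membrane
#' potential reaches the threshold (refined within the crossing cell when
#' `sim$refine == "linear"`). Neurons that never cross are reported silent
#' with time `T`. Each neuron fires at most once.
#'
#' @param inputs a [spike_vector()] of presynaptic firing times.
#' @param layer an [srm_layer()].
#' @param sim a [sim_config()].
#' @return A [spike_vector()] with per-neuron peak potentials attached.
#' @examples
#' lay <- srm_layer(1, 1, n_synapses = 1, delays = 1,
#'                  weights = array(2, c(1, 1, 1)))
#' first_crossing(spike_vector(3), lay, sim_config())
#' @export
first_crossing <- function(inputs, layer, sim = sim_config()) {
  check_srm_inputs(inputs, layer)
  d <- dim(layer$weights)
  out <- srm_forward_cpp(inputs$times, as.numeric(layer$weights),
                         d[2], layer$K, layer$delays,
                         layer$kernel$tau, sim$theta, sim$T, sim$dt,
                         sim$refine == "linear")
  spike_vector(out$times, fired = out$fired, peak = out$peak)
}
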