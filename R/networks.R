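#' Concatenated hybrid network (ANN in front, SNN behind)
#'
#' Builds the serial architecture `(N+1):Q:J`: a sigmoid layer extracts
#' spatial features, the non-trainable reciprocal coding layer converts its
#' `Q` activations one-to-one into spike times, and a multi-synapse SRM
#' output layer classifies by the earliest output spike.
#'
#' @param n_features number of input features `N` (bias appended internally).
#' @param n_hidden number of sigmoid units `Q` (equal to the coding width).
#' @param n_classes number of classes `J` (output spiking neurons).
#' @param n_synapses synapses per SRM connection `K`. Default 6.
#' @param tau kernel time constant. Default 7.
#' @param sim a [sim_config()].
#' @param coding a [coding_config()].
#' @param seed optional seed for the weight initialization.
#' @param init randomize weights (default) or leave them zero.
#' @return An object of class `c("cstnet", "stnet_model")`.
#' @examples
#' m <- cstnet(4, 10, 3, seed = 1)
#' m
#' @export
cstnet <- function(n_features, n_hidden, n_classes, n_synapses = 6, tau = 7,
                   sim = sim_config(), coding = coding_config(T = sim$T),
                   seed = NULL, init = TRUE) {
  stopifnot(n_classes >= 2)
  if (!is.null(seed)) set.seed(seed)
  ann <- sigmoid_layer(n_features + 1, n_hidden)
  out <- srm_layer(n_hidden, n_classes, n_synapses, kernel = kernel_config(tau))
  if (init) {
    ann <- init_sigmoid_layer(ann)
    out <- init_srm_layer(out, sim)
  }
  structure(list(ann = ann, out = out, sim = sim, coding = coding,
                 n_features = n_features, n_classes = n_classes,
                 architecture = sprintf("%d:%d:%d", n_features + 1,
                                        n_hidden, n_classes),
                 history = NULL),
            class = c("cstnet", "stnet_model"))
}

#' Parallel hybrid network (SNN path and ANN path spliced in the coding layer)
#'
#' Builds the dual-path architecture: the upper path encodes the raw features
#' into input spikes (Gaussian population coding, or linear time-delay coding
#' for high-dimensional data) and passes them through a hidden SRM layer of
#' `P` spiking neurons; the lower path is the sigmoid layer plus reciprocal
#' coding of [cstnet()]. The two spike-time vectors are concatenated (upper
#' first) in the coding layer and classified by a rear SRM layer. The
#' architecture renders as `(M + (N+1)):(P + Q):J` with `M = N * G`
#' (population) or `M = N` (linear).
#'
#' @param n_features number of raw features `N`.
#' @param n_hidden_snn upper-path hidden spiking neurons `P`.
#' @param n_hidden_ann lower-path sigmoid units `Q`; defaults to `P`
#'   (a balanced hidden layer generalizes best).
#' @param n_classes number of classes `J`.
#' @param encoding `"auto"`, `"population"` or `"linear"` upper-path input
#'   coding; `"auto"` uses population coding while `N * G <= 256` and linear
#'   time-delay coding beyond.
#' @param xrange assumed feature range for the upper-path encoders (features
#'   are expected min-max normalized; see [minmax_normalize()]).
#' @inheritParams cstnet
#' @return An object of class `c("pstnet", "stnet_model")`.
#' @examples
#' m <- pstnet(6, 7, n_classes = 2, encoding = "population",
#'             coding = coding_config(G = 5), seed = 1)
#' m$architecture  # "(30+7):(7+7):2"
#' @export
pstnet <- function(n_features, n_hidden_snn, n_hidden_ann = n_hidden_snn,
                   n_classes = 2, n_synapses = 6, tau = 7,
                   encoding = c("auto", "population", "linear"),
                   sim = sim_config(), coding = coding_config(T = sim$T),
                   xrange = c(0, 1), seed = NULL, init = TRUE) {
  stopifnot(n_classes >= 2)
  encoding <- match.arg(encoding)
  if (encoding == "auto")
    encoding <- if (n_features * coding$G <= 256) "population" else "linear"
  m_upper <- if (encoding == "population") n_features * coding$G else n_features
  if (!is.null(seed)) set.seed(seed)
  upper <- srm_layer(m_upper, n_hidden_snn, n_synapses,
                     kernel = kernel_config(tau))
  ann <- sigmoid_layer(n_features + 1, n_hidden_ann)
  out <- srm_layer(n_hidden_snn + n_hidden_ann, n_classes, n_synapses,
                   kernel = kernel_config(tau))
  if (init) {
    upper <- init_srm_layer(upper, sim)
    ann <- init_sigmoid_layer(ann)
    out <- init_srm_layer(out, sim)
  }
  structure(list(upper = upper, ann = ann, out = out, sim = sim,
                 coding = coding, encoding = encoding, xrange = xrange,
                 n_features = n_features, n_classes = n_classes,
                 architecture = sprintf("(%d+%d):(%d+%d):%d", m_upper,
                                        n_features + 1, n_hidden_snn,
                                        n_hidden_ann, n_classes),
                 history = NULL),
            class = c("pstnet", "stnet_model"))
}

#' @export
print.stnet_model <- function(x, ...) {
  kind <- if (inherits(x, "cstnet")) "concatenated (C)" else "parallel (P)"
  cat(sprintf("STNet, %s variant\n  architecture %s, K = %d, tau = %g, T = %g, theta = %g\n",
              kind, x$architecture, x$out$K, x$out$kernel$tau,
              x$sim$T, x$sim$theta))
  if (inherits(x, "pstnet"))
    cat("  upper-path input coding:", x$encoding, "\n")
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; final MSE %.4f, training accuracy %.1f%%\n",
                nrow(x$history), x$history$mse[nrow(x$history)],
                x$history$accuracy[nrow(x$history)]))
  invisible(x)
}

#' Encode the upper-path input of a parallel network
#'
#' @param model a [pstnet()].
#' @param x raw (normalized) feature vector.
#' @return A [spike_vector()] of upper-path input spike times.
#' @export
encode_upper <- function(model, x) {
  if (model$encoding == "population")
    population_encode(x, model$xrange[1], model$xrange[2], model$coding)
  else
    linear_delay_encode(x, model$xrange[1], model$xrange[2], model$sim$T)
}

#' Forward pass of the concatenated network
#'
#' Sigmoid layer, reciprocal coding, SRM output layer, in sequence. All
#' intermediates are returned for backpropagation and inspection.
#'
#' @param model a [cstnet()].
#' @param x normalized feature vector (without bias; appended internally).
#' @return List with `R` (activations), `coding` (spike_vector) and
#'   `output` (spike_vector).
#' @export
cstnet_forward <- function(model, x) {
  xb <- add_bias(x)
  R <- ann_forward(xb, model$ann)
  cod <- reciprocal_encode(R, model$coding)
  out <- first_crossing(cod, model$out, model$sim)
  list(x = xb, R = R, coding = cod, output = out)
}

#' Forward pass of the parallel network
#'
#' Upper path: encoded input spikes through the hidden SRM layer. Lower
#' path: sigmoid layer plus reciprocal coding. The coding layer concatenates
#' the two (upper first), and the rear SRM layer classifies.
#'
#' @param model a [pstnet()].
#' @param x normalized feature vector.
#' @return List with `upper_in`, `upper` (hidden spikes), `R`, `coding`
#'   (concatenated spike_vector) and `output`.
#' @export
pstnet_forward <- function(model, x) {
  upper_in <- encode_upper(model, x)
  hid <- first_crossing(upper_in, model$upper, model$sim)
  xb <- add_bias(x)
  R <- ann_forward(xb, model$ann)
  cod_low <- reciprocal_encode(R, model$coding)
  cod <- spike_vector(c(hid$times, cod_low$times),
                      fired = c(hid$fired, cod_low$fired),
                      clamped = c(rep(FALSE, length(hid$times)),
                                  cod_low$clamped))
  out <- first_crossing(cod, model$out, model$sim)
  list(x = xb, upper_in = upper_in, upper = hid, R = R,
       coding = cod, output = out)
}

stnet_forward <- function(model, x) {
  if (inherits(model, "cstnet")) cstnet_forward(model, x)
  else pstnet_forward(model, x)
}

#' Class decision from output spikes
#'
#' The predicted class is the output neuron that fires first. An exact tie
#' is broken in favor of the neuron with the larger peak membrane potential;
#' if no output neuron fires at all, the neuron with the largest peak
#' potential over the window wins. Remaining ties go to the lowest index.
#'
#' @param output a [spike_vector()] from the output layer of
#'   [cstnet_forward()] / [pstnet_forward()] (carries peak potentials).
#' @return 0-based class index (matching dataset label coding).
#' @export
first_spike_class <- function(output) {
  peak <- if (is.null(output$peak)) rep(0, length(output$times)) else output$peak
  first_spike_class_cpp(output$times, output$fired, peak) - 1L
}

#' Predict classes for a feature matrix
#'
#' @param object a trained `stnet_model`.
#' @param newdata numeric matrix (samples in rows, normalized features) or a
#'   dataset from [stnet_dataset()].
#' @param ... unused.
#' @return Integer vector of 0-based class predictions.
#' @export
predict.stnet_model <- function(object, newdata, ...) {
  if (inherits(newdata, "stnet_dataset")) newdata <- newdata$x
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  vapply(seq_len(nrow(newdata)), function(i)
    first_spike_class(stnet_forward(object, newdata[i, ])$output),
    integer(1))
}

#' End-to-end loss of a model on one sample
#'
#' Runs the forward pass and evaluates [spike_loss()] against the expected
#' firing-time encoding of the label. This is the quantity the
#' finite-difference oracle (see [fd_loss_gradient()]) perturbs.
#'
#' @param model a `stnet_model`.
#' @param x normalized feature vector.
#' @param expected expected output times, e.g. from [encode_labels()].
#' @return Scalar loss.
#' @export
model_loss <- function(model, x, expected) {
  spike_loss(stnet_forward(model, x)$output, expected)
}
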