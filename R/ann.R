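#' Dense sigmoid layer
#'
#' The conventional (non-spiking) layer of the hybrid networks: a dense
#' weight matrix `w[n, q]` followed by the logistic activation. The input
#' dimension includes the constant bias input appended as the last feature
#' (see [add_bias()]).
#'
#' @param n_in input dimension including the bias position.
#' @param n_out number of sigmoid units.
#' @param weights optional `n_in x n_out` matrix; zero if omitted.
#' @return An object of class `sigmoid_layer`.
#' @export
sigmoid_layer <- function(n_in, n_out, weights = NULL) {
  if (is.null(weights)) weights <- matrix(0, n_in, n_out)
  weights <- matrix(as.numeric(weights), n_in, n_out)
  stopifnot(all(is.finite(weights)))
  structure(list(weights = weights), class = "sigmoid_layer")
}

#' @export
print.sigmoid_layer <- function(x, ...) {
  cat(sprintf("sigmoid_layer: %d -> %d (input includes bias)\n",
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' Forward pass of the sigmoid layer
#'
#' `R_q = sigmoid(sum_n w[n, q] * x[n])`. Every output is strictly inside
#' (0, 1), which the downstream reciprocal coding relies on.
#'
#' @param x numeric input vector with the bias already appended
#'   (length `nrow(layer$weights)`).
#' @param layer a [sigmoid_layer()].
#' @return Activation vector of length `ncol(layer$weights)`.
#' @examples
#' ann_forward(c(0.2, 0.5, 1), sigmoid_layer(3, 4))  # all 0.5
#' @export
ann_forward <- function(x, layer) {
  if (length(x) != nrow(layer$weights))
    stop("input length (", length(x), ") does not match layer input dimension (",
         nrow(layer$weights), "); did you forget add_bias()?")
  z <- drop(crossprod(layer$weights, x))
  1 / (1 + exp(-z))
}

#' Gradient factor of the logistic activation
#'
#' `R * (1 - R)`, the derivative of the sigmoid expressed through its output.
#'
#' @param R activation value(s) in (0, 1).
#' @return `R * (1 - R)`.
#' @export
sigmoid_grad_factor <- function(R) R * (1 - R)
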