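#' Central finite-difference gradient oracle
#'
#' Estimates `dE/d(parameter)` for a single weight coordinate by perturbing
#' the weight by `+h` and `-h` and re-running the full forward simulation on
#' each side: `(E(p + h) - E(p - h)) / (2h)`. Independent of the analytic
#' SpikeProp chain rule, it serves as the ground truth in gradient tests;
#' accuracy improves with a finer simulation grid (pass a model built with
#' `sim_config(dt = 1e-3)` for tight comparisons).
#'
#' @param model a `stnet_model`.
#' @param x normalized feature vector of the sample.
#' @param expected expected output times from [encode_labels()].
#' @param where which weight tensor: `"v"` (output SRM), `"w"` (sigmoid) or
#'   `"b"` (upper-path SRM of the parallel network).
#' @param index integer vector indexing one coordinate of that tensor
#'   (`c(q, j, k)` for arrays, `c(n, q)` for the sigmoid matrix).
#' @param h perturbation half-width. Default 1e-4.
#' @return Scalar central-difference estimate of `dE/d(parameter)`.
#' @export
fd_loss_gradient <- function(model, x, expected, where = c("v", "w", "b"),
                             index, h = 1e-4) {
  where <- match.arg(where)
  stopifnot(h > 0)
  eval_at <- function(delta) {
    m <- model
    if (where == "v") {
      m$out$weights[matrix(index, 1)] <- m$out$weights[matrix(index, 1)] + delta
    } else if (where == "w") {
      m$ann$weights[index[1], index[2]] <- m$ann$weights[index[1], index[2]] + delta
    } else {
      if (!inherits(m, "pstnet")) stop("'b' only exists in the parallel network")
      m$upper$weights[matrix(index, 1)] <- m$upper$weights[matrix(index, 1)] + delta
    }
    model_loss(m, x, expected)
  }
  (eval_at(h) - eval_at(-h)) / (2 * h)
}

#' Analytic loss gradient for one sample, all parameter tensors
#'
#' Computes `-delta_param / eta`, i.e. `dE/d(parameter)`, from the analytic
#' update rules for every coordinate at once, together with diagnostics
#' saying where the comparison against a finite-difference oracle is
#' meaningful (coordinates touched by the denominator floor, coding clamps
#' or silent neurons sit at or beyond discontinuities of the loss surface).
#'
#' @param model a `stnet_model`.
#' @param x normalized feature vector.
#' @param expected expected output times.
#' @param cfg a [learning_config()].
#' @return List of gradient arrays `v`, `w` (and `b` for the parallel
#'   network) plus logical `reliable_*` masks of matching shape.
#' @export
analytic_loss_gradient <- function(model, x, expected,
                                   cfg = learning_config()) {
  fwd <- stnet_forward(model, x)
  d <- output_delta(fwd$output, expected, fwd$coding, model$out, cfg)
  floored <- attr(d, "floored")
  eta <- cfg$eta
  dv <- output_weight_update(d, fwd$coding, fwd$output, model$out, cfg)
  grad_v <- -dv / eta
  # a floored output delta or a silent output neuron makes every coordinate
  # feeding that neuron unreliable
  rel_v <- array(TRUE, dim = dim(grad_v))
  for (j in seq_along(d))
    if (floored[j] || !fwd$output$fired[j]) rel_v[, j, ] <- FALSE
  bad_out <- any(floored | !fwd$output$fired)
  if (inherits(model, "cstnet")) {
    g <- hidden_time_gradient(d, fwd$output, fwd$coding, model$out)
    dw <- cstnet_ann_update(fwd$x, fwd$R, g, fwd$coding$clamped, cfg,
                            model$coding)
    grad_w <- -dw / eta
    rel_w <- matrix(!bad_out, nrow(grad_w), ncol(grad_w))
    rel_w[, fwd$coding$clamped] <- FALSE
    list(v = grad_v, w = grad_w, rel_v = rel_v, rel_w = rel_w, forward = fwd)
  } else {
    P <- dim(model$upper$weights)[2]
    C <- dim(model$out$weights)[1]
    db <- pstnet_upper_update(fwd$upper_in, fwd$upper, d, fwd$output,
                              model$out, model$upper, cfg)
    grad_b <- -db / eta
    rel_b <- array(!bad_out, dim = dim(grad_b))
    for (p in seq_len(P)) if (!fwd$upper$fired[p]) rel_b[, p, ] <- FALSE
    g_all <- hidden_time_gradient(d, fwd$output, fwd$coding, model$out)
    g_low <- g_all[(P + 1):C]
    clamped_low <- fwd$coding$clamped[(P + 1):C]
    dw <- cstnet_ann_update(fwd$x, fwd$R, g_low, clamped_low, cfg,
                            model$coding)
    grad_w <- -dw / eta
    rel_w <- matrix(!bad_out, nrow(grad_w), ncol(grad_w))
    rel_w[, clamped_low] <- FALSE
    list(v = grad_v, w = grad_w, b = grad_b,
         rel_v = rel_v, rel_w = rel_w, rel_b = rel_b, forward = fwd)
  }
}
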