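#' Train a hybrid network by joint gradient descent / SpikeProp
#'
#' Online (per-sample) learning: for every sample the forward pass runs the
#' sigmoid layer, the coding conversions and the SRM simulation in sequence;
#' the backward pass updates the output SRM weights by the SpikeProp rule,
#' the sigmoid weights through the reciprocal coding, and (for the parallel
#' network) the upper-path SRM weights by the hidden-layer SpikeProp rule.
#' Training stops when `epoch >= max_epoch` or the epoch MSE drops to
#' `min_mse` (the MSE is the per-sample average of the summed squared
#' differences between actual and expected output firing times).
#'
#' Presentation order is reshuffled every epoch when `shuffle = TRUE`
#' (seedable; switch off for strict in-order replication). The learning rate
#' of epoch `e` is `eta * decay^(e-1)`.
#'
#' @param model a [cstnet()] or [pstnet()] model.
#' @param dataset an [stnet_dataset()] with normalized features.
#' @param learning a [learning_config()].
#' @param max_epoch epoch cap. Default 100.
#' @param min_mse MSE stopping level. Default 0 (run to `max_epoch`).
#' @param shuffle reshuffle sample order each epoch. Default TRUE.
#' @param seed optional RNG seed for shuffling.
#' @param engine `"cpp"` (fast compiled loop, the default) or `"reference"`
#'   (pure-R composition of the exported gradient functions; identical
#'   updates, used for cross-checking).
#' @param calibrate_init before the first epoch, probe up to 50 samples and
#'   repeatedly scale up (factor 1.5, at most 20 rounds) the incoming
#'   weights of any spiking neuron that stays silent on more than half of
#'   them. SpikeProp learns nothing from a silent neuron — unfired hidden
#'   neurons receive no weight update at all — so the initial network must
#'   spike on typical inputs; random initialization alone cannot guarantee
#'   that when input spikes are spread over the window (population coding).
#'   Default TRUE; ignored for already-trained models re-entering training.
#' @return The trained model; `$history` holds one row per epoch with the
#'   MSE, the online training accuracy, the learning rate used, and
#'   silent-neuron / clamped-coding / floored-denominator diagnostics.
#' @examples
#' ds <- make_synthetic("blobs", n_per_class = 20, n_features = 2,
#'                      n_classes = 2, seed = 1)
#' ds <- minmax_normalize(ds)
#' m <- cstnet(2, 6, 2, seed = 1)
#' m <- train_stnet(m, ds, max_epoch = 5, seed = 1)
#' m$history$mse
#' @export
train_stnet <- function(model, dataset, learning = learning_config(),
                        max_epoch = 100, min_mse = 0, shuffle = TRUE,
                        seed = NULL, engine = c("cpp", "reference"),
                        calibrate_init = is.null(model$history)) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "stnet_model"), inherits(dataset, "stnet_dataset"))
  if (ncol(dataset$x) != model$n_features)
    stop("dataset has ", ncol(dataset$x), " features but the model expects ",
         model$n_features)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dataset$x)
  X <- cbind(dataset$x, 1)  # bias column
  targets <- t(vapply(dataset$y, encode_labels, numeric(model$n_classes),
                      J = model$n_classes, cfg = model$coding))
  S <- NULL
  if (inherits(model, "pstnet")) {
    S <- t(vapply(seq_len(n), function(i)
      encode_upper(model, dataset$x[i, ])$times,
      numeric(dim(model$upper$weights)[1])))
  }
  if (calibrate_init) model <- calibrate_firing(model, dataset, S)
  hist <- vector("list", max_epoch)
  epoch <- 0L
  repeat {
    epoch <- epoch + 1L
    eta_e <- effective_eta(learning, epoch)
    ord <- if (shuffle) sample.int(n) else seq_len(n)
    res <- if (engine == "cpp") {
      run_epoch_cpp(model, X, S, dataset$y, targets, eta_e, learning, ord)
    } else {
      run_epoch_reference(model, X, S, dataset$y, targets, eta_e, learning, ord)
    }
    model <- res$model
    mse <- mean(res$sse)
    if (!is.finite(mse))
      stop("training diverged at epoch ", epoch,
           ": non-finite MSE (first bad sample index ",
           which(!is.finite(res$sse))[1], ")")
    hist[[epoch]] <- data.frame(
      epoch = epoch, mse = mse,
      accuracy = 100 * mean(res$correct), eta = eta_e,
      n_silent_out = res$n_silent_out,
      n_silent_hidden = res$n_silent_hidden,
      n_clamped = res$n_clamped, n_floored = res$n_floored)
    if (epoch >= max_epoch || mse <= min_mse) break
  }
  model$history <- do.call(rbind, hist[seq_len(epoch)])
  model
}

#' Scale spiking layers until their neurons fire on typical inputs
#'
#' The pre-training firing calibration used by [train_stnet()]: on a probe
#' of up to `n_probe` samples, any spiking neuron that stays silent on more
#' than half of them has its incoming weights multiplied by `factor`,
#' repeatedly (at most `max_rounds` times). SpikeProp can only differentiate
#' firing times that exist, so the initial network must spike on typical
#' inputs.
#'
#' @param model a `stnet_model`.
#' @param dataset an [stnet_dataset()] of representative (normalized) inputs.
#' @param S optional precomputed upper-path input spike times (row per
#'   sample); computed from the model's encoder when omitted.
#' @param n_probe probe size. Default 50.
#' @param factor weight scale factor per round. Default 1.5.
#' @param max_rounds maximum scaling rounds. Default 20.
#' @return The model with scaled spiking layers.
#' @export
calibrate_firing <- function(model, dataset, S = NULL, n_probe = 50,
                             factor = 1.5, max_rounds = 20) {
  n <- nrow(dataset$x)
  if (is.null(S) && inherits(model, "pstnet")) {
    S <- t(vapply(seq_len(n), function(i)
      encode_upper(model, dataset$x[i, ])$times,
      numeric(dim(model$upper$weights)[1])))
  }
  probe <- seq_len(min(n, n_probe))
  scale_layer <- function(layer, input_times_list) {
    for (round in seq_len(max_rounds)) {
      silent <- matrix(FALSE, length(input_times_list),
                       dim(layer$weights)[2])
      for (i in seq_along(input_times_list)) {
        fc <- first_crossing(spike_vector(input_times_list[[i]]), layer,
                             model$sim)
        silent[i, ] <- !fc$fired
      }
      mostly_silent <- colMeans(silent) > 0.5
      if (!any(mostly_silent)) break
      layer$weights[, mostly_silent, ] <-
        layer$weights[, mostly_silent, , drop = FALSE] * factor
    }
    layer
  }
  if (inherits(model, "pstnet")) {
    upper_in <- lapply(probe, function(i) S[i, ])
    model$upper <- scale_layer(model$upper, upper_in)
    coding_in <- lapply(probe, function(i) {
      hid <- first_crossing(spike_vector(S[i, ]), model$upper, model$sim)
      R <- ann_forward(add_bias(dataset$x[i, ]), model$ann)
      c(hid$times, reciprocal_encode(R, model$coding)$times)
    })
    model$out <- scale_layer(model$out, coding_in)
  } else {
    coding_in <- lapply(probe, function(i) {
      R <- ann_forward(add_bias(dataset$x[i, ]), model$ann)
      reciprocal_encode(R, model$coding)$times
    })
    model$out <- scale_layer(model$out, coding_in)
  }
  model
}

run_epoch_cpp <- function(model, X, S, y, targets, eta, cfg, ord) {
  if (inherits(model, "cstnet")) {
    r <- cstnet_epoch_cpp(X, as.integer(y), targets, model$ann$weights,
                          as.numeric(model$out$weights), model$out$delays,
                          model$out$kernel$tau, model$coding$beta,
                          model$sim$T, model$sim$theta, model$sim$dt,
                          eta, cfg$denom_floor, cfg$r_floor, cfg$max_step,
                          as.integer(ord - 1L), model$sim$refine == "linear",
                          TRUE)
    model$ann$weights <- r$w
    model$out$weights <- array(r$v, dim = dim(model$out$weights))
    n_sh <- 0L
  } else {
    r <- pstnet_epoch_cpp(S, X, as.integer(y), targets,
                          as.numeric(model$upper$weights), model$ann$weights,
                          as.numeric(model$out$weights),
                          dim(model$upper$weights)[2], model$out$delays,
                          model$out$kernel$tau, model$coding$beta,
                          model$sim$T, model$sim$theta, model$sim$dt,
                          eta, cfg$denom_floor, cfg$r_floor, cfg$max_step,
                          as.integer(ord - 1L), model$sim$refine == "linear",
                          TRUE)
    model$upper$weights <- array(r$b, dim = dim(model$upper$weights))
    model$ann$weights <- r$w
    model$out$weights <- array(r$v, dim = dim(model$out$weights))
    n_sh <- r$n_silent_hidden
  }
  list(model = model, sse = r$sse, correct = r$correct,
       n_silent_out = r$n_silent_out, n_silent_hidden = n_sh,
       n_clamped = r$n_clamped, n_floored = r$n_floored)
}

clip_step <- function(d, mx) pmin(pmax(d, -mx), mx)

# Pure-R reference epoch: composes the exported per-operation gradient
# functions. Same update rules as the compiled loop, used to cross-check it.
run_epoch_reference <- function(model, X, S, y, targets, eta, cfg, ord) {
  n <- nrow(X)
  sse <- numeric(n); correct <- logical(n)
  n_silent_out <- 0L; n_silent_hidden <- 0L
  n_clamped <- 0L; n_floored <- 0L
  for (i in ord) {
    x <- X[i, -ncol(X)]
    fwd <- stnet_forward(model, x)
    cls <- first_spike_class(fwd$output)
    correct[i] <- cls == y[i]
    sse[i] <- sum((fwd$output$times - targets[i, ])^2)
    n_silent_out <- n_silent_out + sum(!fwd$output$fired)
    d <- output_delta(fwd$output, targets[i, ], fwd$coding, model$out, cfg)
    n_floored <- n_floored + sum(attr(d, "floored"))
    dv <- clip_step(output_weight_update(d, fwd$coding, fwd$output,
                                         model$out, cfg, eta = eta),
                    cfg$max_step)
    if (inherits(model, "cstnet")) {
      g <- hidden_time_gradient(d, fwd$output, fwd$coding, model$out)
      dw <- clip_step(cstnet_ann_update(fwd$x, fwd$R, g, fwd$coding$clamped,
                                        cfg, model$coding, eta = eta),
                      cfg$max_step)
      n_clamped <- n_clamped + sum(fwd$coding$clamped)
      model$ann$weights <- model$ann$weights + dw
    } else {
      P <- dim(model$upper$weights)[2]
      db <- pstnet_upper_update(fwd$upper_in, fwd$upper, d, fwd$output,
                                model$out, model$upper, cfg, eta = eta)
      n_silent_hidden <- n_silent_hidden + attr(db, "n_silent")
      g_all <- hidden_time_gradient(d, fwd$output, fwd$coding, model$out)
      g_low <- g_all[(P + 1):length(g_all)]
      clamped_low <- fwd$coding$clamped[(P + 1):length(g_all)]
      dw <- clip_step(cstnet_ann_update(fwd$x, fwd$R, g_low, clamped_low,
                                        cfg, model$coding, eta = eta),
                      cfg$max_step)
      n_clamped <- n_clamped + sum(clamped_low)
      db_clipped <- clip_step(as.vector(db), cfg$max_step)
      model$upper$weights <- model$upper$weights +
        array(db_clipped, dim = dim(model$upper$weights))
      model$ann$weights <- model$ann$weights + dw
    }
    model$out$weights <- model$out$weights + dv  # dv already clipped
  }
  list(model = model, sse = sse, correct = correct,
       n_silent_out = n_silent_out, n_silent_hidden = n_silent_hidden,
       n_clamped = n_clamped, n_floored = n_floored)
}

#' Classification accuracy of a model on a dataset
#'
#' @param model a trained `stnet_model`.
#' @param dataset an [stnet_dataset()].
#' @return Accuracy in percent (0-100).
#' @export
stnet_accuracy <- function(model, dataset) {
  100 * mean(predict(model, dataset$x) == dataset$y)
}
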