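test_that("spike-time loss is half the squared deviation", {
  expect_identical(spike_loss(c(3, 10), c(3, 10)), 0)
  expect_equal(spike_loss(c(4, 10), c(3, 10)), 0.5)
  a <- c(2, 5, 9); e <- c(3, 10, 7)
  p <- c(3, 1, 2)
  expect_equal(spike_loss(a[p], e[p]), spike_loss(a, e))
})

test_that("output deltas vanish at the target and respect the denominator floor", {
  lay <- srm_layer(2, 2, n_synapses = 2,
                   weights = array(c(1, 0.5, 0.2, 0.8, 0.3, 0.9, 0.1, 0.4),
                                   c(2, 2, 2)))
  cod <- spike_vector(c(1, 2))
  actual <- spike_vector(c(5, 6))
  # exact match -> zero delta regardless of the denominator
  d0 <- output_delta(actual, c(5, 6), cod, lay)
  expect_equal(as.numeric(d0), c(0, 0))
  # a shallow-slope neuron uses the floored denominator
  lay_small <- srm_layer(1, 1, n_synapses = 1, delays = 1,
                         weights = array(1e-4, c(1, 1, 1)))
  cod1 <- spike_vector(1)
  act1 <- spike_vector(5)
  d <- output_delta(act1, 3, cod1, lay_small, learning_config())
  expect_true(attr(d, "floored"))
  expect_equal(as.numeric(d), (3 - 5) / 0.1)
})

test_that("output weight updates follow -eta * delta * PSP with causality", {
  lay <- srm_layer(2, 2, n_synapses = 2,
                   weights = array(runif(8), c(2, 2, 2)))
  cod <- spike_vector(c(1, 8))
  actual <- spike_vector(c(5, 6), fired = c(TRUE, TRUE))
  dv0 <- output_weight_update(c(0, 0), cod, actual, lay)
  expect_true(all(dv0 == 0))
  dv <- output_weight_update(c(0.5, -0.2), cod, actual, lay)
  # neuron q=2 spikes at 8; with delays 1,2 its kernel window opens after
  # both output firing times, so its synapses get no update
  expect_true(all(dv[2, , ] == 0))
  # direct formula check on one coordinate
  cfg <- learning_config()
  expect_equal(dv[1, 1, 2], -cfg$eta * 0.5 * srm_kernel(5 - 1 - 2))
})

test_that("analytic gradients match the finite-difference oracle on small nets", {
  # a handful of nets here; the full 20+20 sweep runs in the acceptance suite
  errs <- unlist(lapply(1:5, function(i) {
    c(gradient_check_errors(small_cstnet(100 + i)),
      gradient_check_errors(small_pstnet(200 + i)))
  }))
  expect_gt(length(errs), 20)
  expect_lt(median(errs), 1e-2)
})

test_that("a single small-step update decreases the loss on most random nets", {
  decreased <- vapply(1:20, function(i) {
    case <- if (i %% 2 == 0) small_cstnet(300 + i, dt = 0.01)
            else small_pstnet(400 + i, dt = 0.01)
    m <- case$model
    e0 <- model_loss(m, case$x, case$expected)
    cfg <- learning_config(eta = 0.005)
    an <- analytic_loss_gradient(m, case$x, case$expected, cfg)
    m$out$weights <- m$out$weights - cfg$eta * an$v
    m$ann$weights <- m$ann$weights - cfg$eta * an$w
    if (inherits(m, "pstnet"))
      m$upper$weights <- m$upper$weights - cfg$eta * an$b
    model_loss(m, case$x, case$expected) < e0
  }, logical(1))
  expect_gte(mean(decreased), 0.9)
})

test_that("learning-rate schedule is eta * decay^(epoch-1)", {
  cfg <- learning_config(eta = 0.1, decay = 0.95)
  expect_equal(effective_eta(cfg, 1), 0.1)
  expect_equal(effective_eta(cfg, 4), 0.1 * 0.95^3)
  fixed <- learning_config(eta = 0.03, decay = 1)
  expect_equal(effective_eta(fixed, 50), 0.03)
})

test_that("compiled and reference training engines apply identical updates", {
  ds <- tiny_blobs(5, n_per_class = 8)
  for (build in list(function() cstnet(2, 4, 2, n_synapses = 3, seed = 9),
                     function() pstnet(2, 3, n_classes = 2, n_synapses = 3,
                                       coding = coding_config(G = 4),
                                       seed = 9))) {
    m_cpp <- train_stnet(build(), ds, max_epoch = 2, seed = 31,
                         engine = "cpp")
    m_ref <- train_stnet(build(), ds, max_epoch = 2, seed = 31,
                         engine = "reference")
    expect_equal(m_cpp$out$weights, m_ref$out$weights, tolerance = 1e-8)
    expect_equal(m_cpp$ann$weights, m_ref$ann$weights, tolerance = 1e-8)
    if (inherits(m_cpp, "pstnet"))
      expect_equal(m_cpp$upper$weights, m_ref$upper$weights, tolerance = 1e-8)
    expect_equal(m_cpp$history$mse, m_ref$history$mse, tolerance = 1e-8)
  }
})

test_that("the finite-difference oracle converges as h shrinks", {
  case <- small_cstnet(77)
  idx <- c(1, 1, 1)
  # at large h the O(h^2) truncation error dominates the grid noise, so
  # halving h must shrink the disagreement between successive estimates
  g1 <- fd_loss_gradient(case$model, case$x, case$expected, "v", idx, h = 0.4)
  g2 <- fd_loss_gradient(case$model, case$x, case$expected, "v", idx, h = 0.2)
  g3 <- fd_loss_gradient(case$model, case$x, case$expected, "v", idx, h = 0.1)
  expect_lt(abs(g3 - g2), abs(g2 - g1))
  # and the small-h estimate agrees with the analytic gradient
  ga <- analytic_loss_gradient(case$model, case$x, case$expected)
  gf <- fd_loss_gradient(case$model, case$x, case$expected, "v", idx)
  if (ga$rel_v[1, 1, 1]) expect_lt(rel_err(ga$v[1, 1, 1], gf), 1e-2)
  # a synapse whose kernel window lies beyond the simulation horizon has no
  # effect on the loss
  m <- case$model
  fw <- cstnet_forward(m, case$x)
  dead <- fd_loss_gradient(m, case$x, case$expected, "v",
                           c(which.max(fw$coding$times), 1, m$out$K))
  if (max(fw$coding$times) + m$out$delays[m$out$K] >
        max(fw$output$times)) {
    expect_equal(dead, 0)
  }
})
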