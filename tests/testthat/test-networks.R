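test_that("concatenated forward pass composes its stages", {
  # zero ANN weights: R = 0.5 everywhere, so every coding time is beta/0.5
  m <- cstnet(3, 5, 2, init = FALSE)
  m$out$weights[] <- 0.4
  fw <- cstnet_forward(m, c(0.1, 0.9, 0.3))
  expect_equal(fw$R, rep(0.5, 5))
  expect_equal(fw$coding$times, rep(2, 5))
  # architecture naming follows (N+1):Q:J
  big <- cstnet(60, 40, 2, init = FALSE)
  expect_equal(big$architecture, "61:40:2")
  expect_length(add_bias(runif(60)), nrow(big$ann$weights))
  # determinism
  m2 <- cstnet(3, 5, 2, seed = 4)
  f1 <- cstnet_forward(m2, c(0.2, 0.5, 0.8))
  f2 <- cstnet_forward(m2, c(0.2, 0.5, 0.8))
  expect_identical(f1$output$times, f2$output$times)
})

test_that("parallel forward pass splices the two paths in the coding layer", {
  m <- pstnet(6, 7, n_classes = 2, encoding = "population",
              coding = coding_config(G = 5), seed = 2)
  expect_equal(m$architecture, "(30+7):(7+7):2")
  x <- runif(6)
  fw <- pstnet_forward(m, x)
  expect_length(fw$upper_in$times, 30)
  expect_length(fw$coding$times, 14)
  expect_equal(fw$coding$times[1:7], fw$upper$times)
  # zeroing the upper path reduces the output to a function of the lower path
  m0 <- m
  m0$upper$weights[] <- 0
  m0$out$weights[1:7, , ] <- 0
  fw_a <- pstnet_forward(m0, x)
  m0b <- m0
  m0b$upper$weights[] <- 5  # change upper weights, outputs must not move
  fw_b <- pstnet_forward(m0b, x)
  expect_equal(fw_a$output$times, fw_b$output$times)
  # high-dimensional data falls back to linear time-delay coding
  wide <- pstnet(60, 4, n_classes = 2, seed = 1)
  expect_equal(wide$encoding, "linear")
  expect_length(pstnet_forward(wide, runif(60))$upper_in$times, 60)
})

test_that("first-spike decision uses earliest spike, peak tie-breaks, silent fallback", {
  sv <- spike_vector(c(4.2, 7.1, 9.0), fired = rep(TRUE, 3),
                     peak = c(2, 3, 1))
  expect_equal(first_spike_class(sv), 0L)
  tie <- spike_vector(c(5, 5, 8), fired = rep(TRUE, 3), peak = c(1.2, 3.1, 9))
  expect_equal(first_spike_class(tie), 1L)  # larger peak wins the tie
  silent <- spike_vector(c(10, 10), fired = c(FALSE, FALSE),
                         peak = c(0.4, 0.9))
  expect_equal(first_spike_class(silent), 1L)  # peak fallback
  equal_all <- spike_vector(c(5, 5), fired = c(TRUE, TRUE), peak = c(2, 2))
  expect_equal(first_spike_class(equal_all), 0L)  # lowest index last
})

test_that("prediction is invariant under consistent output permutation", {
  ds <- tiny_blobs(3, n_per_class = 10, n_classes = 3)
  m <- train_stnet(cstnet(2, 5, 3, seed = 6), ds, max_epoch = 10, seed = 6)
  pred <- predict(m, ds)
  perm <- c(3, 1, 2)
  mp <- m
  mp$out$weights <- m$out$weights[, perm, ]
  pred_p <- predict(mp, ds)
  # permuted output neuron j behaves as original neuron perm[j], so the new
  # winner is the position holding the old winner
  expect_equal(pred_p, match(pred + 1L, perm) - 1L)
})

test_that("training stops by epoch cap or MSE level per the loop condition", {
  ds <- tiny_blobs(2, n_per_class = 6)
  m <- cstnet(2, 4, 2, seed = 3)
  trained <- train_stnet(m, ds, max_epoch = 7, min_mse = 0, seed = 1)
  expect_equal(nrow(trained$history), 7)
  # an unreachable MSE level still runs every epoch; an always-satisfied one
  # stops after the first (while epoch < max and MSE > min)
  one <- train_stnet(m, ds, max_epoch = 7, min_mse = Inf, seed = 1)
  expect_equal(nrow(one$history), 1)
})

test_that("a zero-effect learning rate leaves weights and MSE unchanged", {
  ds <- tiny_blobs(4, n_per_class = 6)
  m <- cstnet(2, 4, 2, seed = 8)
  m_cal <- calibrate_firing(m, ds)
  trained <- train_stnet(m_cal, ds, max_epoch = 3, seed = 2,
                         learning = learning_config(eta = 1e-12),
                         calibrate_init = FALSE)
  expect_equal(trained$ann$weights, m_cal$ann$weights, tolerance = 1e-6)
  expect_equal(trained$out$weights, m_cal$out$weights, tolerance = 1e-6)
  expect_lt(diff(range(trained$history$mse)), 1e-6)
})

test_that("training on separable blobs reaches high accuracy for both nets", {
  ds <- minmax_normalize(make_synthetic("blobs", n_per_class = 25,
                                        n_features = 2, n_classes = 2,
                                        seed = 12))
  mc <- train_stnet(cstnet(2, 6, 2, seed = 12), ds, max_epoch = 30, seed = 12)
  expect_gte(stnet_accuracy(mc, ds), 95)
  mp <- train_stnet(pstnet(2, 4, n_classes = 2, seed = 12), ds,
                    max_epoch = 30, seed = 12)
  expect_gte(stnet_accuracy(mp, ds), 95)
  # final training MSE below the first-epoch MSE
  expect_lt(tail(mc$history$mse, 1), mc$history$mse[1])
  expect_lt(tail(mp$history$mse, 1), mp$history$mse[1])
})

test_that("checkpoint serialization round-trips exactly", {
  ds <- tiny_blobs(6, n_per_class = 6)
  m <- train_stnet(pstnet(2, 3, n_classes = 2, seed = 5), ds,
                   max_epoch = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".txt")
  save_stnet(m, path)
  m2 <- load_stnet(path)
  expect_identical(m2$out$weights, m$out$weights)
  expect_identical(m2$upper$weights, m$upper$weights)
  expect_identical(m2$ann$weights, m$ann$weights)
  expect_equal(m2$history, m$history)
  expect_identical(predict(m2, ds), predict(m, ds))
  expect_error(load_stnet(withr::local_tempfile(lines = "list(1)")),
               "checkpoint")
})
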