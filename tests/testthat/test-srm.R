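test_that("spike-response kernel has its closed-form shape", {
  expect_identical(srm_kernel(7, tau = 7), 1)          # peak value
  expect_identical(srm_kernel(0, tau = 7), 0)          # boundary
  expect_identical(srm_kernel(-3, tau = 7), 0)         # causal
  expect_equal(srm_kernel(14, tau = 7), 2 * exp(-1))   # hand evaluation
  # bounded in [0, 1] with argmax at tau, on a dense grid
  s <- seq(-5, 50, by = 0.01)
  v <- srm_kernel(s, tau = 7)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(s[which.max(v)], 7)
  expect_true(all(v[s <= 0] == 0))
})

test_that("kernel derivative matches central differences and vanishes at the peak", {
  expect_identical(srm_kernel_deriv(7, tau = 7), 0)
  expect_identical(srm_kernel_deriv(-1, tau = 7), 0)
  h <- 1e-5
  s <- setdiff(seq(0.05, 30, by = 0.05), 0)  # off the s = 0 kink
  num <- (srm_kernel(s + h, 7) - srm_kernel(s - h, 7)) / (2 * h)
  expect_equal(srm_kernel_deriv(s, 7), num, tolerance = 1e-6)
})

test_that("membrane potential is the weighted kernel sum over synapses", {
  lay <- srm_layer(1, 1, n_synapses = 1, delays = 1,
                   weights = array(2, c(1, 1, 1)))
  # one input spike at 3, delay 1: u(10) = 2 * kernel(6)
  expect_equal(membrane_potential(10, spike_vector(3), lay, 1),
               2 * (6 / 7) * exp(1 / 7))
  # zero weights -> zero potential everywhere
  lay0 <- srm_layer(3, 2, n_synapses = 4)
  sv <- spike_vector(c(1, 2, 3))
  expect_equal(membrane_potential(seq(0, 10, by = 1), sv, lay0, 2),
               rep(0, 11))
  # before any arrival the potential is zero
  expect_identical(membrane_potential(3.9, spike_vector(3), lay, 1), 0)
  # dimension mismatch is a configuration error
  expect_error(membrane_potential(5, spike_vector(c(1, 2)), lay, 1),
               "presynaptic")
})

test_that("membrane potential rate matches numerical differentiation", {
  set.seed(42)
  lay <- srm_layer(3, 2, n_synapses = 4,
                   weights = array(runif(24, -0.5, 1), c(3, 2, 4)))
  sv <- spike_vector(runif(3, 0, 4))
  ts <- seq(0.5, 9.5, by = 0.25)
  h <- 1e-5
  for (j in 1:2) {
    num <- (membrane_potential(ts + h, sv, lay, j) -
              membrane_potential(ts - h, sv, lay, j)) / (2 * h)
    expect_equal(membrane_potential_rate(ts, sv, lay, j), num,
                 tolerance = 1e-6)
  }
  # zero at a connection's kernel peak (single synapse layout)
  lay1 <- srm_layer(1, 1, n_synapses = 1, delays = 1,
                    weights = array(1.3, c(1, 1, 1)))
  expect_equal(membrane_potential_rate(3 + 1 + 7, spike_vector(3), lay1, 1), 0)
})

test_that("first_crossing finds the threshold time found by root-solving", {
  lay <- srm_layer(1, 1, n_synapses = 1, delays = 1,
                   weights = array(2, c(1, 1, 1)))
  fc <- first_crossing(spike_vector(3), lay, sim_config())
  expect_true(fc$fired[1])
  # independent oracle: root of 2 * kernel(t - 4) - 1 on the rising flank
  root <- uniroot(function(t) 2 * srm_kernel(t - 4) - 1, c(4, 7),
                  tol = 1e-12)$root
  expect_equal(fc$times[1], root, tolerance = 1e-3)
  # without interpolation the reported time is the first grid point at/above
  fc_grid <- first_crossing(spike_vector(3), lay,
                            sim_config(refine = "none"))
  expect_equal(fc_grid$times[1], ceiling(root / 0.01) * 0.01,
               tolerance = 1e-9)
  # zero weights -> silent, clamped to T
  lay0 <- srm_layer(2, 2, n_synapses = 3)
  fc0 <- first_crossing(spike_vector(c(1, 2)), lay0, sim_config())
  expect_false(any(fc0$fired))
  expect_equal(fc0$times, c(10, 10))
  # an overwhelming weight fires within the first grid step after arrival
  layb <- srm_layer(1, 1, n_synapses = 1, delays = 1,
                    weights = array(1e5, c(1, 1, 1)))
  fcb <- first_crossing(spike_vector(3), layb, sim_config(refine = "none"))
  expect_equal(fcb$times[1], 4.01, tolerance = 1e-9)
})

test_that("crossing time is monotone non-increasing in any single weight", {
  set.seed(7)
  for (trial in 1:10) {
    w <- array(runif(3 * 2 * 2, 0, 1.2), c(3, 2, 2))
    sv <- spike_vector(runif(3, 0, 3))
    lay <- srm_layer(3, 2, n_synapses = 2, weights = w)
    base <- first_crossing(sv, lay, sim_config())
    idx <- c(sample(3, 1), sample(2, 1), sample(2, 1))
    w2 <- w
    w2[idx[1], idx[2], idx[3]] <- w2[idx[1], idx[2], idx[3]] + runif(1, 0, 1)
    lay2 <- srm_layer(3, 2, n_synapses = 2, weights = w2)
    bumped <- first_crossing(sv, lay2, sim_config())
    j <- idx[2]
    expect_lte(bumped$times[j], base$times[j] + 1e-12)
  }
})

test_that("halving dt never reports a crossing later by more than dt", {
  set.seed(11)
  for (trial in 1:8) {
    lay <- srm_layer(2, 2, n_synapses = 3,
                     weights = array(runif(12, 0, 1), c(2, 2, 3)))
    sv <- spike_vector(runif(2, 0, 4))
    for (dt in c(0.04, 0.02)) {
      coarse <- first_crossing(sv, lay, sim_config(dt = dt))
      fine <- first_crossing(sv, lay, sim_config(dt = dt / 2))
      expect_true(all(fine$times <= coarse$times + dt + 1e-12))
    }
  }
})

test_that("configuration constructors validate their invariants", {
  expect_error(sim_config(T = -1))
  expect_error(sim_config(dt = 20))
  expect_error(kernel_config(tau = 0))
  expect_error(srm_layer(2, 2, n_synapses = 2, delays = c(2, 1)))
  s <- sim_config(T = 10, dt = 0.01)
  expect_equal(length(seq(0, s$T, by = s$dt)), floor(s$T / s$dt) + 1)
})
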