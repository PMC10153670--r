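# Shared helpers: small firing networks and gradient-comparison utilities.

rel_err <- function(a, b) {
  if (abs(a) < 1e-8 && abs(b) < 1e-8) return(0)
  abs(a - b) / max(abs(b), 1e-12)
}

# Small concatenated net (3 features, 4 hidden, 2 classes, 3 synapses) on a
# fine grid, with a random input; calibrated so the output neurons fire.
small_cstnet <- function(seed, dt = 1e-3) {
  set.seed(seed)
  m <- cstnet(3, 4, 2, n_synapses = 3, sim = sim_config(dt = dt),
              seed = seed)
  x <- runif(3)
  m <- calibrate_firing(m, stnet_dataset(matrix(x, 1), 0L))
  list(model = m, x = x, expected = encode_labels(sample(0:1, 1), 2))
}

# Small parallel net (4 features, G = 4 population coding, P = Q = 3,
# 2 classes, 3 synapses), calibrated so hidden and output neurons fire.
small_pstnet <- function(seed, dt = 1e-3) {
  set.seed(seed)
  m <- pstnet(4, 3, 3, n_classes = 2, n_synapses = 3,
              encoding = "population", coding = coding_config(G = 4),
              sim = sim_config(dt = dt), seed = seed)
  xs <- matrix(runif(12), 3, 4)
  m <- calibrate_firing(m, stnet_dataset(xs, c(0L, 1L, 0L)))
  list(model = m, x = xs[1, ], expected = encode_labels(sample(0:1, 1), 2))
}

# Compare analytic gradients against the central finite-difference oracle on
# randomly sampled reliable coordinates; returns the relative errors.
gradient_check_errors <- function(case, n_coords = 4, h = 1e-4) {
  m <- case$model; x <- case$x; expected <- case$expected
  an <- analytic_loss_gradient(m, x, expected)
  errs <- numeric(0)
  sample_idx <- function(dims) vapply(dims, function(d) sample(d, 1), integer(1))
  specs <- list(list("v", dim(m$out$weights), an$v, an$rel_v),
                list("w", dim(m$ann$weights), an$w, an$rel_w))
  if (inherits(m, "pstnet"))
    specs <- c(specs, list(list("b", dim(m$upper$weights), an$b, an$rel_b)))
  for (sp in specs) {
    for (r in seq_len(n_coords)) {
      idx <- sample_idx(sp[[2]])
      reliable <- if (length(idx) == 2) sp[[4]][idx[1], idx[2]]
                  else sp[[4]][idx[1], idx[2], idx[3]]
      if (!reliable) next
      a <- if (length(idx) == 2) sp[[3]][idx[1], idx[2]]
           else sp[[3]][idx[1], idx[2], idx[3]]
      fd <- fd_loss_gradient(m, x, expected, sp[[1]], idx, h = h)
      errs <- c(errs, rel_err(a, fd))
    }
  }
  errs
}

# A tiny normalized blob dataset for quick training tests.
tiny_blobs <- function(seed = 1, n_per_class = 15, n_features = 2,
                       n_classes = 2) {
  minmax_normalize(make_synthetic("blobs", n_per_class = n_per_class,
                                  n_features = n_features,
                                  n_classes = n_classes, seed = seed))
}
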