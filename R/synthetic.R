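#' Generate labeled synthetic classification data
#'
#' Seedable generator for the three fixture families used throughout the
#' test and evaluation paths:
#'
#' * `"blobs"`: `n_classes` isotropic Gaussian clusters in `n_features`
#'   dimensions. Cluster centers are drawn uniformly in `[0, 10]^N` and
#'   redrawn until every pairwise center distance is at least `separation`,
#'   giving moderately separated but not trivial classes at the default
#'   `noise` (the cluster standard deviation).
#' * `"xor"`: the 2-feature 2-class checkerboard; labels follow the XOR of
#'   the two half-plane indicators at 0.5, then Gaussian jitter of sd
#'   `noise` is added to the coordinates.
#' * `"rings"`: concentric annuli around (0.5, 0.5); class `j` has mean
#'   radius proportional to `j + 1`, with radial jitter of sd `noise`.
#'
#' The generator restores the caller's RNG state, so the same `seed` always
#' yields a bit-identical dataset regardless of context.
#'
#' @param kind `"blobs"`, `"xor"` or `"rings"`.
#' @param n_per_class samples per class. Default 50.
#' @param n_features feature count (blobs only; the other kinds are planar).
#' @param n_classes class count (blobs and rings; xor is binary).
#' @param noise see Details; defaults: 1 (blobs), 0.05 (xor), 0.05 (rings).
#' @param separation minimum pairwise distance between blob centers.
#'   Default 4.
#' @param seed RNG seed (required for reproducibility).
#' @return An [stnet_dataset()] with balanced 0-based labels, samples
#'   ordered class-by-class.
#' @examples
#' ds <- make_synthetic("blobs", n_per_class = 10, n_features = 2,
#'                      n_classes = 3, seed = 42)
#' table(ds$y)
#' @export
make_synthetic <- function(kind = c("blobs", "xor", "rings"),
                           n_per_class = 50, n_features = 2, n_classes = 2,
                           noise = NULL, separation = 4, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_per_class >= 1, n_features >= 1, n_classes >= 2)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  ds <- switch(kind,
    blobs = synth_blobs(n_per_class, n_features, n_classes,
                        if (is.null(noise)) 1 else noise, separation),
    xor = synth_xor(n_per_class, if (is.null(noise)) 0.05 else noise),
    rings = synth_rings(n_per_class, n_classes,
                        if (is.null(noise)) 0.05 else noise))
  ds$provenance <- sprintf("synthetic:%s(n_per_class=%d, seed=%d)",
                           kind, n_per_class, seed)
  ds
}

synth_blobs <- function(n_per_class, n_features, n_classes, sd, separation) {
  repeat {
    centers <- matrix(runif(n_classes * n_features, 0, 10),
                      n_classes, n_features)
    if (n_classes < 2 || min(stats::dist(centers)) >= separation) break
  }
  x <- do.call(rbind, lapply(seq_len(n_classes), function(j) {
    matrix(stats::rnorm(n_per_class * n_features, sd = sd),
           n_per_class, n_features) +
      matrix(centers[j, ], n_per_class, n_features, byrow = TRUE)
  }))
  ds <- stnet_dataset(x, rep(seq_len(n_classes) - 1L, each = n_per_class))
  ds$centers <- centers
  ds
}

synth_xor <- function(n_per_class, noise) {
  n <- 2 * n_per_class
  # balanced: fill each class quadrant-pair evenly
  pts <- matrix(runif(4 * n, 0, 1), ncol = 2)
  lab <- as.integer(xor(pts[, 1] > 0.5, pts[, 2] > 0.5))
  keep <- c(which(lab == 0)[seq_len(n_per_class)],
            which(lab == 1)[seq_len(n_per_class)])
  if (anyNA(keep)) stop("internal: not enough points per checkerboard class")
  x <- pts[keep, ] + matrix(stats::rnorm(2 * n, sd = noise), ncol = 2)
  stnet_dataset(x, lab[keep])
}

synth_rings <- function(n_per_class, n_classes, noise) {
  x <- do.call(rbind, lapply(seq_len(n_classes), function(j) {
    r0 <- 0.4 * j / n_classes
    ang <- runif(n_per_class, 0, 2 * pi)
    r <- r0 + stats::rnorm(n_per_class, sd = noise)
    cbind(0.5 + r * cos(ang), 0.5 + r * sin(ang))
  }))
  stnet_dataset(x, rep(seq_len(n_classes) - 1L, each = n_per_class))
}
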