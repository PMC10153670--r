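#' Coding-layer configuration
#'
#' Constants for every conversion between continuous values and spike times.
#' The coding layer holds no trainable parameters; it only translates the
#' spatial signal of the sigmoid layer (and raw features) into the temporal
#' signal the spiking layers consume.
#'
#' @param beta reciprocal-coding constant in `t = beta / R`. Default 1.
#' @param T simulation window (shared with [sim_config()]). Default 10.
#' @param G Gaussian receptive fields per feature for population coding.
#'   Default 6.
#' @param gamma field-width factor: field width is
#'   `(range)/(gamma * (G - 2))`. Default 1.5.
#' @param t_early target firing time of the correct-class output neuron.
#'   Default 3.
#' @param t_late target firing time of wrong-class output neurons. Default `T`.
#' @return An object of class `coding_config`.
#' @export
coding_config <- function(beta = 1, T = 10, G = 6, gamma = 1.5,
                          t_early = 3, t_late = T) {
  stopifnot(beta > 0, T > 0, gamma > 0,
            t_early >= 0, t_early < t_late, t_late <= T)
  structure(list(beta = beta, T = T, G = G, gamma = gamma,
                 t_early = t_early, t_late = t_late),
            class = "coding_config")
}

#' Reciprocal coding of sigmoid activations into spike times
#'
#' `t_q = beta / R_q`: the higher the extracted spatial feature value, the
#' earlier the coding neuron spikes. Times exceeding the window are forcibly
#' set to `T` and flagged `clamped` (the clamp is flat, so no gradient is
#' propagated through clamped entries during learning).
#'
#' @param R activation vector, each entry strictly in (0, 1).
#' @param cfg a [coding_config()].
#' @return A [spike_vector()] with the `clamped` flag set where `beta/R > T`.
#' @examples
#' reciprocal_encode(c(0.5, 0.08), coding_config())  # 2 and clamped 10
#' @export
reciprocal_encode <- function(R, cfg = coding_config()) {
  if (any(R <= 0)) stop("reciprocal coding requires strictly positive activations")
  t <- cfg$beta / R
  clamped <- t > cfg$T
  t[clamped] <- cfg$T
  spike_vector(t, fired = rep(TRUE, length(t)), clamped = clamped)
}

#' Linear time-delay coding of raw features
#'
#' `t = (xmax - x) / (xmax - xmin) * T`: large feature values spike early,
#' small values late. Used for the upper path of the parallel network when a
#' dataset has too many features for population coding. Values outside the
#' stated extrema are clipped; a degenerate feature (`xmax == xmin`) encodes
#' to `T` with a warning.
#'
#' @param x feature vector.
#' @param xmin,xmax per-feature extrema (recycled if scalar).
#' @param T simulation window. Default 10.
#' @return A [spike_vector()] of length `length(x)`.
#' @export
linear_delay_encode <- function(x, xmin, xmax, T = 10) {
  n <- length(x)
  xmin <- rep_len(xmin, n); xmax <- rep_len(xmax, n)
  rng <- xmax - xmin
  if (any(rng < 0)) stop("xmax must be >= xmin")
  t <- rep(T, n)
  ok <- rng > 0
  if (!all(ok)) warning("degenerate feature(s) with xmax == xmin encoded as T")
  xc <- pmin(pmax(x, xmin), xmax)
  t[ok] <- (xmax[ok] - xc[ok]) / rng[ok] * T
  spike_vector(t)
}

#' Centers and width of the Gaussian receptive fields
#'
#' For a feature ranging over `[lo, hi]`, field `g` (of `G >= 3`) is centered
#' at `lo + (2g - 3)/2 * (hi - lo)/(G - 2)` with common width
#' `(hi - lo)/(gamma * (G - 2))`, the classical population-coding layout for
#' temporal-coding spiking networks.
#'
#' @param lo,hi feature extrema.
#' @param G number of fields.
#' @param gamma width factor.
#' @return List with `centers` (length `G`) and `sigma` (scalar).
#' @keywords internal
gaussian_fields <- function(lo, hi, G, gamma = 1.5) {
  if (G < 3) stop("population coding needs G >= 3 Gaussian fields")
  if (hi <= lo) stop("invalid feature extrema for population coding")
  step <- (hi - lo) / (G - 2)
  list(centers = lo + (2 * seq_len(G) - 3) / 2 * step,
       sigma = (hi - lo) / (gamma * (G - 2)))
}

#' Gaussian population coding of raw features
#'
#' Each of the `N` features is represented by `G` spiking input neurons with
#' overlapping Gaussian tuning curves. Field activation
#' `phi = exp(-(x - mu)^2 / (2 sigma^2))` is mapped to a spike time
#' `t = T * (1 - phi)`: a feature value at a field center makes that field
#' fire at time 0, and far-away fields fire near `T`.
#'
#' @param x feature vector of length `N`.
#' @param xmin,xmax per-feature extrema (recycled if scalar).
#' @param cfg a [coding_config()]; uses `G`, `gamma` and `T`.
#' @return A [spike_vector()] of length `N * G`, ordered feature-major
#'   (all fields of feature 1, then feature 2, ...).
#' @export
population_encode <- function(x, xmin, xmax, cfg = coding_config()) {
  n <- length(x)
  xmin <- rep_len(xmin, n); xmax <- rep_len(xmax, n)
  t <- numeric(n * cfg$G)
  for (i in seq_len(n)) {
    gf <- gaussian_fields(xmin[i], xmax[i], cfg$G, cfg$gamma)
    phi <- exp(-(x[i] - gf$centers)^2 / (2 * gf$sigma^2))
    t[(i - 1) * cfg$G + seq_len(cfg$G)] <- pmin(pmax(cfg$T * (1 - phi), 0), cfg$T)
  }
  spike_vector(t)
}

#' Encode a class label as expected output firing times
#'
#' The output neuron of the true class is expected to fire early
#' (`t_early`), all others late (`t_late`); classification by the earliest
#' output spike then decodes the label by `which.min`.
#'
#' @param y 0-based class index.
#' @param J number of classes (output neurons).
#' @param cfg a [coding_config()].
#' @return Numeric vector of length `J` of expected firing times.
#' @examples
#' encode_labels(2, 3)  # c(10, 10, 3)
#' @export
encode_labels <- function(y, J, cfg = coding_config()) {
  if (y < 0 || y >= J) stop("label ", y, " out of range 0..", J - 1)
  t <- rep(cfg$t_late, J)
  t[y + 1] <- cfg$t_early
  t
}

#' Append the constant bias input
#'
#' @param x feature vector (possibly empty).
#' @return `c(x, 1)`.
#' @export
add_bias <- function(x) c(x, 1)
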