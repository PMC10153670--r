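#' Save a model checkpoint as plain text
#'
#' Writes the complete model — every weight tensor, all configuration
#' objects, the architecture string and training history — to a versioned,
#' human-readable text file. Numeric data are serialized in hexadecimal
#' floating point, so a reload reproduces the model bit-for-bit
#' (round-trip exact).
#'
#' Format: a single R expression (readable with [load_stnet()]) of the form
#' `list(format = "stnet-checkpoint", version = 1, model = <model>)`.
#'
#' @param model a `stnet_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
save_stnet <- function(model, path) {
  stopifnot(inherits(model, "stnet_model"))
  payload <- list(format = "stnet-checkpoint", version = 1L, model = model)
  dput(payload, file = path, control = c("all", "hexNumeric"))
  invisible(path)
}

#' Load a model checkpoint written by [save_stnet()]
#'
#' @param path checkpoint file path.
#' @return The restored `stnet_model`, identical to the saved one.
#' @export
load_stnet <- function(path) {
  payload <- dget(path)
  if (!identical(payload$format, "stnet-checkpoint"))
    stop("not an stnet checkpoint: ", path)
  if (payload$version != 1L)
    stop("unsupported checkpoint version ", payload$version)
  payload$model
}
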