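#' Labeled tabular dataset container
#'
#' A plain container for a classification dataset: a numeric feature matrix,
#' 0-based integer class labels, the per-feature extrema used by the spike
#' encoders, and a provenance tag (file path, or generator call plus seed).
#'
#' @param x numeric matrix, samples in rows.
#' @param y integer labels in `0 .. J-1` (or a factor / character vector,
#'   factorized in first-appearance order).
#' @param provenance free-text origin tag.
#' @return An object of class `stnet_dataset` with fields `x`, `y`,
#'   `levels` (original label values), `xmin`, `xmax`, `n_classes`,
#'   `provenance`.
#' @export
stnet_dataset <- function(x, y, provenance = "in-memory") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.numeric(y) || any(y != floor(y))) {
    lev <- unique(as.character(y))
    yy <- match(as.character(y), lev) - 1L
  } else {
    yy <- as.integer(y)
    lev <- as.character(sort(unique(yy)))
    if (min(yy) != 0L || max(yy) != length(unique(yy)) - 1L) {
      lev <- as.character(unique(yy))
      yy <- match(yy, unique(yy)) - 1L
    }
  }
  stopifnot(nrow(x) == length(yy))
  structure(list(x = x, y = yy, levels = lev,
                 xmin = apply(x, 2, min), xmax = apply(x, 2, max),
                 n_classes = length(unique(yy)), provenance = provenance),
            class = "stnet_dataset")
}

#' @export
print.stnet_dataset <- function(x, ...) {
  cat(sprintf("stnet_dataset: %d samples, %d features, %d classes (%s)\n",
              nrow(x$x), ncol(x$x), x$n_classes, x$provenance))
  invisible(x)
}

#' Load a delimited-text classification dataset
#'
#' Reads a UCI-style delimited file: numeric feature columns plus one label
#' column. Labels are factorized to 0-based integers in order of first
#' appearance. Missing feature values (marker `"?"` by UCI convention,
#' configurable) become `NA` for later [impute_mean()].
#'
#' @param path file path.
#' @param delimiter field separator. Default `","`.
#' @param label_col label column position; negative counts from the end
#'   (default -1, the last column).
#' @param header does the file carry a header row? `NA` (default)
#'   auto-detects by attempting a numeric parse of the first row's feature
#'   fields.
#' @param missing missing-value marker. Default `"?"`.
#' @return An [stnet_dataset()].
#' @export
load_tabular <- function(path, delimiter = ",", label_col = -1L,
                         header = NA, missing = "?") {
  raw <- utils::read.table(path, sep = delimiter, header = FALSE,
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           na.strings = missing, colClasses = "character",
                           blank.lines.skip = TRUE)
  if (is.na(header)) {
    first_feats <- raw[1, -resolve_label_col(label_col, ncol(raw)), drop = TRUE]
    header <- anyNA(suppressWarnings(as.numeric(unlist(first_feats))))
  }
  if (header) raw <- raw[-1, , drop = FALSE]
  lc <- resolve_label_col(label_col, ncol(raw))
  y <- raw[[lc]]
  feats <- raw[, -lc, drop = FALSE]
  xm <- matrix(NA_real_, nrow(feats), ncol(feats))
  for (j in seq_len(ncol(feats))) {
    v <- suppressWarnings(as.numeric(feats[[j]]))
    bad <- which(is.na(v) & !is.na(feats[[j]]))
    if (length(bad))
      stop("non-numeric feature value '", feats[[j]][bad[1]],
           "' at data row ", bad[1], ", feature column ", j)
    xm[, j] <- v
  }
  if (anyNA(y)) stop("missing label at data row ", which(is.na(y))[1])
  stnet_dataset(xm, y, provenance = path)
}

resolve_label_col <- function(label_col, ncols) {
  lc <- if (label_col < 0) ncols + label_col + 1L else as.integer(label_col)
  if (lc < 1 || lc > ncols) stop("label column ", label_col, " out of range")
  lc
}

#' Min-max normalize features to [0, 1]
#'
#' Affine per-feature scaling so the observed minimum maps to 0 and the
#' maximum to 1 — the normalization every network in this package expects.
#' Constant features map to 0 with a warning. The pre-scaling extrema are
#' kept in the returned dataset (`$scale_min`, `$scale_max`) so the
#' transform can be inverted.
#'
#' @param ds an [stnet_dataset()].
#' @return The dataset with normalized features and `xmin`/`xmax` of 0/1.
#' @export
minmax_normalize <- function(ds) {
  stopifnot(inherits(ds, "stnet_dataset"))
  lo <- apply(ds$x, 2, min); hi <- apply(ds$x, 2, max)
  rng <- hi - lo
  if (any(rng == 0)) {
    warning("constant feature(s) ", paste(which(rng == 0), collapse = ", "),
            " normalized to 0")
  }
  x <- sweep(ds$x, 2, lo)
  x[, rng > 0] <- sweep(x[, rng > 0, drop = FALSE], 2, rng[rng > 0], `/`)
  x[, rng == 0] <- 0
  ds$scale_min <- lo; ds$scale_max <- hi
  ds$x <- x
  ds$xmin <- apply(x, 2, min); ds$xmax <- apply(x, 2, max)
  ds
}

#' Invert a min-max normalization
#'
#' @param ds a dataset previously passed through [minmax_normalize()].
#' @return The dataset on its original feature scale.
#' @export
minmax_denormalize <- function(ds) {
  if (is.null(ds$scale_min)) stop("dataset carries no normalization to invert")
  rng <- ds$scale_max - ds$scale_min
  ds$x <- sweep(sweep(ds$x, 2, rng, `*`), 2, ds$scale_min, `+`)
  ds$xmin <- apply(ds$x, 2, min); ds$xmax <- apply(ds$x, 2, max)
  ds$scale_min <- NULL; ds$scale_max <- NULL
  ds
}

#' Mean-impute missing feature values
#'
#' Each `NA` entry is replaced by the mean of the observed values of its
#' feature.
#'
#' @param ds an [stnet_dataset()] (possibly with `NA` features).
#' @return The dataset with no missing values.
#' @export
impute_mean <- function(ds) {
  stopifnot(inherits(ds, "stnet_dataset"))
  for (j in seq_len(ncol(ds$x))) {
    miss <- is.na(ds$x[, j])
    if (!any(miss)) next
    if (all(miss)) stop("feature ", j, " has no observed values to impute from")
    ds$x[miss, j] <- mean(ds$x[!miss, j])
  }
  ds$xmin <- apply(ds$x, 2, min); ds$xmax <- apply(ds$x, 2, max)
  ds
}

#' Average satellite spectral bands over their pixel neighborhoods
#'
#' For 36-feature satellite data laid out as 9 neighborhood pixels times 4
#' spectral bands, classification concerns the central pixel only, so each
#' band's nine pixel values are averaged into a single feature, reducing 36
#' features to 4.
#'
#' @param ds an [stnet_dataset()] with exactly 36 features.
#' @param layout `"band"` (default): features ordered band-major
#'   (band 1 pixels 1-9, band 2 pixels 1-9, ...); `"pixel"`: pixel-major
#'   (pixel 1 bands 1-4, pixel 2 bands 1-4, ...).
#' @return The dataset with 4 features (one per band).
#' @export
statlog_band_average <- function(ds, layout = c("band", "pixel")) {
  stopifnot(inherits(ds, "stnet_dataset"))
  layout <- match.arg(layout)
  if (ncol(ds$x) != 36)
    stop("band averaging expects 36 features (9 pixels x 4 bands), got ",
         ncol(ds$x))
  idx <- function(b) if (layout == "band") (b - 1) * 9 + 1:9 else seq(b, 36, by = 4)
  x <- do.call(cbind, lapply(1:4, function(b)
    rowMeans(ds$x[, idx(b), drop = FALSE])))
  ds$x <- x
  ds$xmin <- apply(x, 2, min); ds$xmax <- apply(x, 2, max)
  ds
}

#' Read an IDX-format image/label pair (MNIST layout)
#'
#' Parses the big-endian IDX binary format: magic number `0x00000803` for
#' image files (dimensions: count, rows, cols) and `0x00000801` for label
#' files. Images are flattened row-major to one feature vector per sample
#' and scaled from 0-255 to [0, 1].
#'
#' @param images_path path to the IDX image file.
#' @param labels_path path to the IDX label file.
#' @return An [stnet_dataset()] with `rows * cols` features.
#' @seealso [write_idx_images()] to create fixtures programmatically.
#' @export
read_idx_images <- function(images_path, labels_path) {
  con <- file(images_path, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic != 0x00000803L)
    stop("bad IDX image magic number: ", sprintf("0x%08x", magic))
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  nr <- readBin(con, "integer", 1, size = 4, endian = "big")
  nc <- readBin(con, "integer", 1, size = 4, endian = "big")
  px <- readBin(con, "integer", n * nr * nc, size = 1, signed = FALSE)
  x <- matrix(px / 255, nrow = n, ncol = nr * nc, byrow = TRUE)

  con2 <- file(labels_path, "rb"); on.exit(close(con2), add = TRUE)
  magic2 <- readBin(con2, "integer", 1, size = 4, endian = "big")
  if (magic2 != 0x00000801L)
    stop("bad IDX label magic number: ", sprintf("0x%08x", magic2))
  n2 <- readBin(con2, "integer", 1, size = 4, endian = "big")
  if (n2 != n) stop("image count ", n, " != label count ", n2)
  y <- readBin(con2, "integer", n2, size = 1, signed = FALSE)
  stnet_dataset(x, y, provenance = images_path)
}

#' Write an IDX-format image/label pair
#'
#' The inverse of [read_idx_images()]; mainly useful for building small
#' test fixtures in code.
#'
#' @param x matrix of pixel intensities in [0, 1], one flattened image per
#'   row (`rows * cols` columns).
#' @param y integer labels.
#' @param images_path,labels_path output paths.
#' @param rows,cols image dimensions.
#' @return Invisibly, the two paths.
#' @export
write_idx_images <- function(x, y, images_path, labels_path,
                             rows = 28, cols = 28) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == rows * cols, nrow(x) == length(y))
  con <- file(images_path, "wb")
  writeBin(as.integer(c(0x00000803L, nrow(x), rows, cols)), con,
           size = 4, endian = "big")
  writeBin(as.integer(round(t(x) * 255)), con, size = 1)
  close(con)
  con2 <- file(labels_path, "wb")
  writeBin(as.integer(c(0x00000801L, length(y))), con2,
           size = 4, endian = "big")
  writeBin(as.integer(y), con2, size = 1)
  close(con2)
  invisible(c(images_path, labels_path))
}
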