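test_that("delimited files load with labels factorized in first-appearance order", {
  path <- withr::local_tempfile(lines = c("1.5,2.0,b", "0.5,1.0,a",
                                          "2.5,3.0,b"))
  ds <- load_tabular(path)
  expect_equal(dim(ds$x), c(3, 2))
  expect_equal(ds$y, c(0L, 1L, 0L))
  expect_equal(ds$levels, c("b", "a"))
  # label column anywhere gives the same dataset
  path2 <- withr::local_tempfile(lines = c("b,1.5,2.0", "a,0.5,1.0",
                                           "b,2.5,3.0"))
  ds2 <- load_tabular(path2, label_col = 1)
  expect_equal(ds2$x, ds$x)
  expect_equal(ds2$y, ds$y)
  # non-numeric feature values name the offending row
  bad <- withr::local_tempfile(lines = c("1.0,2.0,a", "oops,1.0,b"))
  expect_error(load_tabular(bad), "row 2")
  # header rows are auto-detected and skipped
  hdr <- withr::local_tempfile(lines = c("f1,f2,label", "1,2,a", "3,4,b"))
  dsh <- load_tabular(hdr)
  expect_equal(nrow(dsh$x), 2)
  # an Iris-shaped file: 150 x 4, 3 classes
  set.seed(1)
  iris_like <- withr::local_tempfile(lines = vapply(1:150, function(i)
    paste(c(round(runif(4), 2), paste0("cls", (i - 1) %/% 50)),
          collapse = ","), character(1)))
  dsi <- load_tabular(iris_like)
  expect_equal(dim(dsi$x), c(150, 4))
  expect_equal(dsi$n_classes, 3)
})

test_that("min-max normalization maps each feature onto [0,1] and inverts", {
  ds <- stnet_dataset(cbind(c(2, 4, 6), c(1, 1, 2)), c(0, 1, 0))
  nrm <- minmax_normalize(ds)
  expect_equal(nrm$x[, 1], c(0, 0.5, 1))
  # already-normalized data is a fixed point
  again <- minmax_normalize(nrm)
  expect_equal(again$x, nrm$x)
  # round trip
  back <- minmax_denormalize(nrm)
  expect_equal(back$x, ds$x, tolerance = 1e-12)
  # constant features warn and map to 0
  const <- stnet_dataset(cbind(c(1, 2, 3), c(5, 5, 5)), c(0, 1, 0))
  expect_warning(nc <- minmax_normalize(const), "constant")
  expect_equal(nc$x[, 2], c(0, 0, 0))
})

test_that("mean imputation fills gaps with the observed feature mean", {
  ds <- stnet_dataset(cbind(c(1, NA, 3), c(4, 5, 6)), c(0, 1, 0))
  imp <- impute_mean(ds)
  expect_equal(imp$x[2, 1], 2)
  expect_equal(mean(imp$x[, 1]), mean(c(1, 3)))
  # no missing values: identity
  expect_equal(impute_mean(imp)$x, imp$x)
  allna <- stnet_dataset(cbind(c(NA, NA), c(1, 2)), c(0, 1))
  expect_error(impute_mean(allna), "feature 1")
})

test_that("band averaging reduces 36 pixel-band features to 4 band means", {
  x <- matrix(0, 2, 36)
  x[1, ] <- 7                      # constant image -> (7,7,7,7)
  x[2, 10:18] <- 1:9               # band 2 (band-major) set to 1..9
  ds <- statlog_band_average(stnet_dataset(x, c(0, 1)))
  expect_equal(ncol(ds$x), 4)
  expect_equal(ds$x[1, ], rep(7, 4))
  expect_equal(ds$x[2, ], c(0, 5, 0, 0))
  # pixel-major layout: band b occupies columns b, b+4, ...
  xp <- matrix(0, 1, 36)
  xp[1, seq(2, 36, by = 4)] <- 1:9
  dsp <- statlog_band_average(stnet_dataset(xp, 0), layout = "pixel")
  expect_equal(dsp$x[1, ], c(0, 5, 0, 0))
  expect_error(statlog_band_average(stnet_dataset(matrix(0, 1, 10), 0)),
               "36 features")
})

test_that("IDX image files round-trip through our writer and reader", {
  x <- rbind(rep(0, 784), runif(784))
  y <- c(7L, 2L)
  img <- withr::local_tempfile(); lab <- withr::local_tempfile()
  write_idx_images(x, y, img, lab)
  ds <- read_idx_images(img, lab)
  expect_equal(dim(ds$x), c(2, 784))
  expect_equal(ds$x[1, ], rep(0, 784))        # all-zero image stays zero
  expect_equal(ds$x[2, ], round(x[2, ] * 255) / 255, tolerance = 1e-12)
  expect_equal(ds$levels[ds$y + 1], c("7", "2"))
  # magic-number mismatch is a format error
  expect_error(read_idx_images(lab, img), "magic")
})

test_that("synthetic generator is deterministic, balanced, and separable at zero noise", {
  a <- make_synthetic("blobs", n_per_class = 20, n_features = 3,
                      n_classes = 3, seed = 5)
  b <- make_synthetic("blobs", n_per_class = 20, n_features = 3,
                      n_classes = 3, seed = 5)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_equal(as.numeric(table(a$y)), rep(20, 3))
  # near-zero noise with separated centers: nearest-center rule is perfect
  ds <- make_synthetic("blobs", n_per_class = 30, n_features = 2,
                       n_classes = 2, noise = 1e-3, seed = 9)
  ctr <- ds$centers
  rule <- apply(ds$x, 1, function(p)
    which.min(colSums((t(ctr) - p)^2)) - 1L)
  expect_equal(rule, ds$y)
  # xor and rings have the declared shapes
  dx <- make_synthetic("xor", n_per_class = 25, seed = 3)
  expect_equal(dim(dx$x), c(50, 2))
  expect_equal(sort(unique(dx$y)), c(0L, 1L))
  dr <- make_synthetic("rings", n_per_class = 15, n_classes = 3, seed = 3)
  expect_equal(dim(dr$x), c(45, 2))
  # the generator does not disturb the caller's RNG stream
  set.seed(123); r1 <- runif(1)
  set.seed(123); invisible(make_synthetic("blobs", seed = 8)); r2 <- runif(1)
  expect_identical(r1, r2)
})
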