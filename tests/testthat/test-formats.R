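test_that("TCK files round-trip streamline structure and coordinates", {
  set.seed(101)
  t <- tractogram(lapply(c(2, 5, 9), function(n) matrix(rnorm(n * 3) * 50, n, 3)),
                  header = list(origin = "unit-test"))
  f <- withr::local_tempfile(fileext = ".tck")
  write_tck(t, f)
  t2 <- read_tck(f)
  expect_identical(vapply(t2$streamlines, nrow, integer(1)), c(2L, 5L, 9L))
  expect_identical(t2$header$count, "3")
  expect_identical(t2$header$origin, "unit-test")
  # stored at single precision: relative error bounded by float32 epsilon
  dev <- max(abs(unlist(t$streamlines) - unlist(t2$streamlines)))
  expect_lt(dev, max(abs(unlist(t$streamlines))) * 2^-22)
})

test_that("TCK round trip holds for many random streamlines", {
  set.seed(202)
  sls <- lapply(sample(2:12, 1000, replace = TRUE),
                function(n) matrix(rnorm(n * 3) * 100, n, 3))
  f <- withr::local_tempfile(fileext = ".tck")
  write_tck(tractogram(sls), f)
  back <- read_tck(f)
  expect_equal(n_streamlines(back), 1000)
  dev <- max(abs(unlist(sls) - unlist(back$streamlines)))
  expect_lt(dev, 100 * 2^-22)
})

test_that("empty tractograms are valid TCK files", {
  f <- withr::local_tempfile(fileext = ".tck")
  write_tck(tractogram(list()), f)
  expect_equal(n_streamlines(read_tck(f)), 0)
})

test_that("header/body mismatches raise truncation errors with byte offsets", {
  f <- withr::local_tempfile(fileext = ".tck")
  write_tck(tractogram(lapply(1:4, function(i) matrix(seq_len(6) + i, 2, 3))), f)
  raw <- readBin(f, "raw", file.size(f))
  # header declares one streamline more than the body holds
  txt <- rawToChar(raw[1:40])
  pos <- regexpr("count: 4", txt, fixed = TRUE)
  stopifnot(pos > 0)
  raw[pos + 7L] <- charToRaw("5")
  f2 <- withr::local_tempfile(fileext = ".tck")
  writeBin(raw, f2)
  expect_error(read_tck(f2), class = "tck_truncation_error")

  # body chopped mid-triplet, sentinel lost
  f3 <- withr::local_tempfile(fileext = ".tck")
  writeBin(raw[seq_len(length(raw) - 20)], f3)
  err <- tryCatch(read_tck(f3), error = function(e) e)
  expect_s3_class(err, "tck_truncation_error")
  expect_match(conditionMessage(err), "byte offset")
})

test_that("malformed TCK headers name the offending key", {
  f <- withr::local_tempfile(fileext = ".tck")
  writeLines(c("mrtrix tracks", "count: 0", "file: . 40", "END"), f, sep = "\n")
  err <- tryCatch(read_tck(f), error = function(e) e)
  expect_s3_class(err, "tck_format_error")
  expect_match(conditionMessage(err), "datatype")

  writeLines(c("not a tractogram"), f)
  expect_error(read_tck(f), class = "tck_format_error")
})

test_that("written TCK files are readable by an independent implementation", {
  py <- Sys.which("python")
  set.seed(33)
  sls <- lapply(c(3, 7), function(n) matrix(rnorm(n * 3) * 20, n, 3))
  f <- withr::local_tempfile(fileext = ".tck")
  write_tck(tractogram(sls), f)
  out <- system2(py, c("-c", shQuote(paste0(
    "import nibabel as nib; t = nib.streamlines.load('", f, "'); ",
    "print(len(t.streamlines)); ",
    "print(' '.join(str(len(s)) for s in t.streamlines)); ",
    "print(float(abs(t.streamlines[1]).max()))"))), stdout = TRUE)
  expect_equal(as.integer(out[1]), 2L)
  expect_equal(as.integer(strsplit(out[2], " ")[[1]]), c(3L, 7L))
  expect_equal(as.numeric(out[3]), max(abs(sls[[2]])), tolerance = 1e-6)
})

test_that("label volumes read/write exactly with their affines", {
  arr <- array(0L, c(10, 10, 10))
  vol <- label_volume(arr)
  expect_equal(vol$voxel_volume, 1.0)

  arr[2:4, 5, 5] <- 1L; arr[8, 8, 8] <- 2L
  vol2 <- label_volume(arr, diag(c(2, 2, 2, 1)))
  expect_equal(vol2$voxel_volume, 8.0)

  # non-axis-aligned affine: a rotation about z plus translation
  th <- 0.3
  aff <- rbind(c(cos(th), -sin(th), 0, -7),
               c(sin(th),  cos(th), 0,  3),
               c(0, 0, 1.5, -2), c(0, 0, 0, 1))
  vol3 <- label_volume(arr, aff)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_label_volume(vol3, f)
  back <- read_label_volume(f)
  expect_identical(back$labels, vol3$labels)
  expect_equal(back$affine, vol3$affine, tolerance = 1e-5)
  expect_equal(back$voxel_volume, 1.5, tolerance = 1e-5)
})

test_that("non-integer labels are rejected", {
  arr <- array(0, c(4, 4, 4)); arr[1, 1, 1] <- 1.5
  expect_error(label_volume(arr), "non-integer")
  arr[1, 1, 1] <- 1 + 1e-9       # within exactness tolerance
  expect_silent(label_volume(arr))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(c(rep(0, 63), 1.5), c(4, 4, 4)))
  RNifti::writeNifti(img, f)
  expect_error(read_label_volume(f), "non-integer")
})

test_that("region tables are validated on read", {
  df <- data.frame(label = 1:4,
                   name = c("Seed", "Left A", "Right A", "Plate"),
                   hemisphere = c("midline", "left", "right", "midline"),
                   compartment = c("none", "nuclear", "nuclear", "none"),
                   role = c("seed", "target", "target", "exclusion"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_region_table(f)
  expect_s3_class(tab, "region_table")
  expect_equal(nrow(tab), 4)
  expect_equal(nrow(bilateral_pairs(tab)), 1)
  expect_equal(bilateral_pairs(tab)$base, "A")

  expect_error(region_table(transform(df, role = c("seed", "seed", "target",
                                                   "exclusion"))),
               "exactly one seed")
  expect_error(region_table(df[-(2:3), ]), "at least one target")
  expect_error(region_table(transform(df, hemisphere = c("midline", "left",
                                                         "sinister", "midline"))),
               "unknown hemisphere")
  expect_error(region_table(transform(df, compartment = c("none", "none",
                                                          "nuclear", "none"))),
               "compartment 'none'")
  # unpaired bilateral target: warn, accept
  expect_warning(tab2 <- region_table(df[-3, ]), "unpaired left")
  expect_equal(sum(tab2$role == "target"), 1)
})

test_that("the packaged density table matches the published values", {
  t1 <- load_table1_fixture()
  expect_equal(nrow(t1), 34)
  rf <- t1[t1$structure == "Right fastigial nucleus", ]
  expect_equal(rf$mean_delta_norm, 17.24)
  expect_equal(rf$sd, 8.41)
  vc <- t1[t1$structure == "Vermis Crus I", ]
  expect_equal(c(vc$mean_delta_norm, vc$sd, vc$cov), c(0, 0, 0))
  # printed means are percentages of a whole: they total 100 up to rounding
  expect_lt(abs(sum(t1$mean_delta_norm) - 100), 0.05)
})
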