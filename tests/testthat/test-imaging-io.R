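test_that("NIfTI round-trip preserves data and spacing", {
  set.seed(5)
  cases <- list(
    float = image_volume(array(rnorm(1000), c(10, 10, 10)), c(1, 1, 1), "T1"),
    aniso = image_volume(array(runif(480), c(8, 6, 10)), c(0.9, 1.1, 2), "T2"),
    mask = image_volume(array(rbinom(512, 1, 0.3), c(8, 8, 8)), c(1, 1, 1), "mask"),
    label = image_volume(array(sample(0:5, 512, TRUE), c(8, 8, 8)), c(1, 1, 1), "label")
  )
  for (nm in names(cases)) {
    v <- cases[[nm]]
    f <- withr::local_tempfile(fileext = ".nii.gz")
    write_volume(v, f)
    r <- read_volume(f, modality = v$modality)
    expect_lt(max(abs(r$data - v$data)), 1e-6, label = nm)
    expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
    if (v$modality %in% c("mask", "label")) {
      expect_identical(r$data, v$data)
    }
  }
})

test_that("read_volume rejects non-3D data", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  arr4 <- array(rnorm(16 * 3), c(2, 2, 4, 3))
  RNifti::writeNifti(RNifti::asNifti(arr4), f)
  expect_error(read_volume(f), "3D")
  expect_error(read_volume("no/such/file.nii"), "unreadable")
})

test_that("image_volume enforces modality invariants", {
  a <- array(0.5, c(3, 3, 3))
  expect_error(image_volume(array(1.4, c(3, 3, 3)), modality = "probability"),
               "\\[0, 1\\]")
  expect_error(image_volume(a, modality = "mask"), "binary")
  expect_error(image_volume(array(-1, c(3, 3, 3)), modality = "label"),
               "non-negative")
  expect_error(image_volume(a, spacing = c(1, 0, 1)), "spacing")
  expect_error(image_volume(matrix(1, 2, 2)), "3D")
})

test_that("assert_coregistered detects grid and spacing mismatches", {
  v1 <- image_volume(array(0, c(8, 8, 8)), c(1, 1, 1))
  v2 <- image_volume(array(1, c(8, 8, 8)), c(1, 1, 1))
  v3 <- image_volume(array(0, c(8, 8, 7)), c(1, 1, 1))
  v4 <- image_volume(array(0, c(8, 8, 8)), c(1, 1, 1.1))
  v5 <- image_volume(array(0, c(8, 8, 8)), c(1, 1, 1 + 5e-4))
  expect_true(assert_coregistered(list(v1, v2)))
  expect_error(assert_coregistered(list(v1, v3)), "shape")
  expect_error(assert_coregistered(list(v1, v4)), "spacing")
  expect_true(assert_coregistered(list(v1, v5)))  # within header tolerance
  expect_error(assert_coregistered(list(v1, v5), tol = 1e-5), "spacing")
})
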