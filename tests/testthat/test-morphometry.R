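test_that("BPF is the parenchyma-to-TIV quotient", {
  dims <- c(10, 10, 10)
  tp <- list(gm = prob_volume(0.47, dims), wm = prob_volume(0.30, dims),
             csf = prob_volume(0.23, dims))
  m <- bpf(tp)
  expect_equal(m$bpf, 0.77)
  expect_equal(m$tiv_mm3, 1000)
  expect_equal(m$parenchymal_mm3, 770)
  # CSF-free maps give BPF 1; all-zero maps error
  expect_equal(bpf(list(gm = prob_volume(0.5, dims), wm = prob_volume(0.5, dims),
                        csf = prob_volume(0, dims)))$bpf, 1)
  expect_error(bpf(list(gm = prob_volume(0, dims), wm = prob_volume(0, dims),
                        csf = prob_volume(0, dims))), "TIV")
})

test_that("BPF is invariant to isotropic spacing rescaling", {
  set.seed(3)
  dims <- c(8, 8, 8)
  g <- array(runif(512, 0, 0.6), dims)
  w <- array(runif(512, 0, 0.3), dims)
  c0 <- pmin(1 - g - w, array(runif(512, 0, 0.4), dims))
  mk <- function(sp) list(gm = image_volume(g, sp, "probability"),
                          wm = image_volume(w, sp, "probability"),
                          csf = image_volume(c0, sp, "probability"))
  expect_equal(bpf(mk(c(1, 1, 1)))$bpf, bpf(mk(c(2.5, 2.5, 2.5)))$bpf,
               tolerance = 1e-12)
  # binarized mode counts voxels at p >= 0.5
  tp <- mk(c(1, 1, 1))
  mb <- bpf(tp, binarize = TRUE)
  expect_equal(mb$gm_mm3, sum(g >= 0.5))
})

test_that("mask volumes scale with spacing and add over disjoint masks", {
  m <- array(0, c(10, 10, 10)); m[1:10, 1, 1] <- 1
  expect_equal(mask_volume(image_volume(m, c(1, 1, 1), "mask")), 10)
  expect_equal(mask_volume(image_volume(m, c(1, 1, 2), "mask")), 20)
  m2 <- array(0, c(10, 10, 10)); m2[1:5, 5, 5] <- 1
  both <- image_volume(m + m2, c(1, 1, 1), "mask")
  expect_equal(mask_volume(both),
               mask_volume(image_volume(m, c(1, 1, 1), "mask")) +
                 mask_volume(image_volume(m2, c(1, 1, 1), "mask")))
  expect_equal(mask_volume(image_volume(array(0, c(4, 4, 4)),
                                        modality = "mask")), 0)
  bad <- image_volume(array(0, c(4, 4, 4)))
  bad$data[1] <- 0.5
  expect_error(mask_volume(bad), "non-binary")
})
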