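test_that("phantom generation is deterministic given the seed", {
  cfg <- phantom_config(grid = c(48, 48, 48), n_tubes = 4, n_ovoids = 1,
                        n_wmh = 1, seed = 3)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$t1$data, b$t1$data)
  expect_identical(a$t2$data, b$t2$data)
  expect_identical(a$truth$labels$data, b$truth$labels$data)
  d <- generate_phantom(phantom_config(grid = c(48, 48, 48), n_tubes = 4,
                                       n_ovoids = 1, n_wmh = 1, seed = 4))
  expect_false(identical(a$t1$data, d$t1$data))
})

test_that("truth table matches the configured object counts and size classes", {
  ph <- generate_phantom(phantom_config(grid = c(64, 64, 64), n_tubes = 7,
                                        n_ovoids = 2, n_wmh = 1, seed = 8))
  tab <- table(ph$truth$objects$class)
  expect_equal(unname(tab[["tube"]]), 7)
  expect_equal(unname(tab[["ovoid"]]), 2)
  expect_equal(unname(tab[["wmh"]]), 1)
  tubes <- ph$truth$objects[ph$truth$objects$class == "tube", ]
  ovoids <- ph$truth$objects[ph$truth$objects$class == "ovoid", ]
  expect_true(all(tubes$diameter_mm < 3))
  expect_true(all(ovoids$diameter_mm > 3))
})

test_that("noiseless tube voxels carry the configured CSF means exactly", {
  cfg <- phantom_config(grid = c(48, 48, 48), noise_sd = c(T1 = 0, T2 = 0),
                        n_tubes = 3, n_ovoids = 1, n_wmh = 0, seed = 2)
  ph <- generate_phantom(cfg)
  lab <- ph$truth$labels$data
  tubes <- ph$truth$objects$id[ph$truth$objects$class == "tube"]
  vox <- lab %in% tubes
  expect_true(all(ph$t1$data[vox] == cfg$t1_means[["CSF"]]))
  expect_true(all(ph$t2$data[vox] == cfg$t2_means[["CSF"]]))
})

test_that("truth volumes conserve mass and objects do not overlap", {
  ph <- small_phantom()
  lab <- ph$truth$labels$data
  obj <- ph$truth$objects
  vv <- voxel_volume(ph$truth$labels)
  # every labelled voxel belongs to exactly one object
  expect_equal(sum(lab > 0), sum(obj$n_voxels))
  counts <- table(lab[lab > 0])
  expect_equal(unname(counts[as.character(obj$id)]),
               obj$n_voxels, ignore_attr = TRUE)
  expect_equal(sum(obj$volume_mm3), sum(lab > 0) * vv)
  # all planted objects live inside the WM compartment
  expect_true(all(ph$tissue$wm$data[lab > 0] == 1))
})

test_that("phantom writing produces a complete, reloadable set", {
  d <- withr::local_tempdir()
  ph <- generate_phantom(phantom_config(grid = c(32, 32, 32), n_tubes = 2,
                                        n_ovoids = 0, n_wmh = 0, seed = 6))
  write_phantom(ph, d)
  expect_true(all(file.exists(file.path(d, c(
    "t1.nii.gz", "t2.nii.gz", "wm_prob.nii.gz", "truth_labels.nii.gz",
    "truth_objects.csv", "config.json")))))
  r <- read_volume(file.path(d, "truth_labels.nii.gz"), "label")
  expect_identical(r$data, ph$truth$labels$data)
})

test_that("synthetic cohort is deterministic with planted analyte structure", {
  a <- generate_cohort(n_cases = 10, n_controls = 10, n_analytes = 30,
                       n_associated = 5, seed = 21)
  b <- generate_cohort(n_cases = 10, n_controls = 10, n_analytes = 30,
                       n_associated = 5, seed = 21)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$analytes, b$analytes)
  expect_equal(nrow(a$subjects), 20)
  expect_equal(sum(a$subjects$status == "CADASIL"), 10)
  expect_false(anyDuplicated(rownames(a$analytes)) > 0)
  expect_true(all(a$analytes > 0))
  expect_equal(sum(a$analyte_info$associated), 5)
  # associated analytes correlate with the ePVS z-score far above the rest
  cors <- abs(cor(log(a$analytes), a$subjects$ePVS_z))
  expect_gt(min(cors[1:5]), max(cors[6:30]))
})

test_that("degenerate cohort specs are rejected", {
  expect_error(cohort_effects(epvs_sdlog = 0), "degenerate")
  expect_error(generate_cohort(n_cases = 1, n_controls = 1))
  expect_error(generate_cohort(n_analytes = 3, n_associated = 5))
})
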