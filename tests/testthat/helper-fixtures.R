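# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

# A reduced phantom for stage-level tests: 64^3, fewer objects, same
# contrast/noise as the default conditions.
small_phantom <- function(seed = 11L) {
  key <- paste0("ph", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_phantom(phantom_config(
      grid = c(64L, 64L, 64L), n_tubes = 6L, tube_length_mm = c(8, 14),
      n_ovoids = 2L, n_wmh = 1L, seed = seed))
  }
  .fixture_cache[[key]]
}

# The full default phantom used by the acceptance suite.
default_phantom <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- generate_phantom(phantom_config())
  }
  .fixture_cache$default
}

# Fraction of planted tubes detected: a tube counts as detected when at
# least half of its truth voxels fall in ePVS-classified clusters.
tube_recall <- function(report, truth) {
  lab <- report$labels$data
  ids <- report$clusters$id[report$clusters$class == "ePVS"]
  emask <- array(lab %in% ids, dim(lab))
  tubes <- truth$objects[truth$objects$class == "tube", ]
  hits <- vapply(tubes$id, function(id)
    mean(emask[truth$labels$data == id]) >= 0.5, TRUE)
  mean(hits)
}

# Number of planted ovoids whose voxels overlap any ePVS-classified cluster.
ovoid_false_positives <- function(report, truth) {
  lab <- report$labels$data
  ids <- report$clusters$id[report$clusters$class == "ePVS"]
  emask <- array(lab %in% ids, dim(lab))
  ov <- truth$objects[truth$objects$class == "ovoid", ]
  sum(vapply(ov$id, function(id)
    any(emask[truth$labels$data == id]), TRUE))
}

# Constant-valued probability volume helper.
prob_volume <- function(value, dims = c(6, 6, 6), spacing = c(1, 1, 1)) {
  image_volume(array(value, dims), spacing, "probability")
}
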