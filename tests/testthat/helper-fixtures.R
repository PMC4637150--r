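# Shared fixtures. Phantoms are generated in code at test time; the small
# 32-voxel phantom scales the default geometry by half and is used wherever
# only plumbing (not segmentation quality) is under test.

small_spec <- function(seed = 11L, ...) {
  g <- default_structure_geometry()
  g <- lapply(g, function(s) {
    s$center <- s$center / 2
    s$semiaxes <- s$semiaxes / 2
    s
  })
  args <- modifyList(
    list(
      grid_shape = c(32, 32, 32),
      structure_geometry = g,
      # degradation scaled with the geometry so the thin half-scale
      # shells keep candidates at the 0.8 threshold
      atlas_fwhm = 1,
      atlas_shift = c(1, 0, 0),
      seed = seed
    ),
    list(...)
  )
  do.call(phantom_spec, args)
}

# memoise the default and small phantoms across tests in one run
.fixture_env <- new.env(parent = emptyenv())

default_phantom <- function() {
  if (is.null(.fixture_env$default)) {
    .fixture_env$default <- generate_phantom(phantom_spec())
  }
  .fixture_env$default
}

small_phantom <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_phantom(small_spec())
  }
  .fixture_env$small
}

# sampling policy with the balanced major-tissue count scaled to the
# phantom's brain volume (the 50,000-voxel count is defined for ~1400 cc
# adult brains; see ?scaled_major_count)
phantom_policy <- function(phantom, method = "knn", seed = 7L, ...) {
  brain_cc <- sum(phantom$brain_mask) * prod(phantom$image$voxel_size) / 1000
  sampling_policy(method, knn_major_count = scaled_major_count(brain_cc),
                  seed = seed, ...)
}

# random probability atlas set on a small grid (white noise rescaled to
# [0, 1] per class) for threshold-monotonicity and disjointness properties
random_atlas_fixture <- function(seed, gs = c(12, 12, 12)) {
  withr::with_seed(seed, {
    maps <- lapply(subseg_classes()$class, function(cl) {
      rescale_unit(array(rnorm(prod(gs)), gs))
    })
    names(maps) <- subseg_classes()$class
    atlas_set(maps, c(1, 1, 1))
  })
}
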