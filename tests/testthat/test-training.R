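# build a candidate mask + image fixture with controlled candidate counts
toy_candidates <- function(counts, gs = c(20, 20, 20), seed = 3L,
                           voxel_size = c(1, 1, 1)) {
  stopifnot(sum(unlist(counts)) <= prod(gs))
  all_classes <- subseg_classes()$class
  masks <- lapply(all_classes, function(cl) array(FALSE, gs))
  names(masks) <- all_classes
  pool <- withr::with_seed(seed, sample(prod(gs)))
  offset <- 0L
  for (cl in names(counts)) {
    take <- pool[offset + seq_len(counts[[cl]])]
    masks[[cl]][take] <- TRUE
    offset <- offset + counts[[cl]]
  }
  cand <- structure(masks, class = "candidate_mask", threshold = 0.8,
                    voxel_size = voxel_size)
  img <- withr::with_seed(seed + 1L, {
    ms_volume(array(rnorm(prod(gs) * 2), c(gs, 2)), voxel_size,
              channels = c("t1", "flair"))
  })
  list(candidates = cand, image = img)
}

test_that("per-class sample sizes follow the 10%/20%/fixed-count rules", {
  fx <- toy_candidates(list(thalamus = 1000, caudate = 37, gm = 4000))
  knn_pol <- sampling_policy("knn", knn_major_count = 500, seed = 1)
  tr <- select_training(fx$candidates, fx$image, knn_pol,
                        required_classes = c("thalamus", "caudate", "gm"))
  n <- table(tr$class)
  expect_identical(as.integer(n[["thalamus"]]), 200L)  # 20% of 1000
  expect_identical(as.integer(n[["caudate"]]), 7L)     # round(0.2 * 37)
  expect_identical(as.integer(n[["gm"]]), 500L)        # fixed major count
  pcda_pol <- sampling_policy("pcda", seed = 1)
  tr2 <- select_training(fx$candidates, fx$image, pcda_pol,
                         required_classes = c("thalamus", "caudate", "gm"))
  n2 <- table(tr2$class)
  expect_identical(as.integer(n2[["thalamus"]]), 100L)  # 10% of 1000
  expect_identical(as.integer(n2[["gm"]]), 400L)        # 10% of 4000
  expect_identical(as.integer(n2[["caudate"]]), 4L)     # round(0.1 * 37)
})

test_that("requests beyond the candidate count clamp with a warning", {
  fx <- toy_candidates(list(wm = 300))
  pol <- sampling_policy("knn", knn_major_count = 500, seed = 2)
  expect_warning(
    tr <- select_training(fx$candidates, fx$image, pol,
                          required_classes = "wm"),
    "clamping"
  )
  expect_identical(nrow(tr), 300L)
})

test_that("a required class without candidates is a fatal error naming it", {
  fx <- toy_candidates(list(wm = 100))
  pol <- sampling_policy("knn", seed = 2)
  expect_error(
    suppressWarnings(select_training(fx$candidates, fx$image, pol,
                                     required_classes = c("wm", "pallidum"))),
    "pallidum"
  )
})

test_that("training selection is deterministic in the seed and uniform without replacement", {
  fx <- toy_candidates(list(thalamus = 400, gm = 1000))
  pol <- sampling_policy("knn", knn_major_count = 200, seed = 9)
  tr1 <- select_training(fx$candidates, fx$image, pol,
                         required_classes = c("thalamus", "gm"))
  tr2 <- select_training(fx$candidates, fx$image, pol,
                         required_classes = c("thalamus", "gm"))
  expect_identical(tr1$voxel, tr2$voxel)
  pol3 <- sampling_policy("knn", knn_major_count = 200, seed = 10)
  tr3 <- select_training(fx$candidates, fx$image, pol3,
                         required_classes = c("thalamus", "gm"))
  expect_false(identical(tr1$voxel, tr3$voxel))
  expect_false(anyDuplicated(tr1$voxel) > 0)
  # every sample is a candidate voxel of its own class
  for (cl in c("thalamus", "gm")) {
    vox <- tr1$voxel[tr1$class == cl]
    expect_true(all(fx$candidates[[cl]][vox]))
  }
})

test_that("spatial features are voxel index times voxel size, intensities uninterpolated", {
  fx <- toy_candidates(list(wm = 50), voxel_size = c(0.94, 0.94, 1.25))
  pol <- sampling_policy("knn", knn_major_count = 50, seed = 4)
  tr <- select_training(fx$candidates, fx$image, pol, required_classes = "wm")
  ijk <- arrayInd(tr$voxel, dim(fx$image))
  expect_equal(tr$x, (ijk[, 1] - 1) * 0.94)
  expect_equal(tr$y, (ijk[, 2] - 1) * 0.94)
  expect_equal(tr$z, (ijk[, 3] - 1) * 1.25)
  expect_equal(tr$t1, fx$image$data[cbind(ijk, 1L)])
  expect_equal(tr$flair, fx$image$data[cbind(ijk, 2L)])
})

test_that("standardization gives exact two-point columns and replays on targets", {
  toy <- tibble::tibble(label = c(1L, 2L), f = c(1, 3), g = c(10, 30))
  std <- standardize_features(toy, targets = data.frame(f = c(1, 3), g = c(30, 10)))
  expect_equal(std$train$f, c(-1, 1))  # population SD convention
  expect_equal(std$train$g, c(-1, 1))
  expect_equal(unname(std$targets[, "f"]), c(-1, 1))
  expect_equal(unname(std$targets[, "g"]), c(1, -1))
  # a target identical to a training voxel standardizes identically
  replay <- standardize_features(toy, targets = toy[, c("f", "g")])
  expect_equal(unname(replay$targets),
               unname(as.matrix(replay$train[, c("f", "g")])))
})

test_that("standardized training columns have mean 0 and unit variance", {
  fx <- toy_candidates(list(wm = 200, gm = 300, thalamus = 150))
  pol <- sampling_policy("knn", knn_major_count = 150, seed = 6)
  tr <- select_training(fx$candidates, fx$image, pol,
                        required_classes = c("wm", "gm", "thalamus"))
  std <- standardize_features(tr)
  for (col in feature_columns(std$train)) {
    v <- std$train[[col]]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(mean((v - mean(v))^2) - 1), 1e-6)
  }
})

test_that("degenerate standardization inputs are rejected informatively", {
  one <- tibble::tibble(label = 1L, f = 2, g = 3)
  expect_error(standardize_features(one), "at least 2")
  flat <- tibble::tibble(label = c(1L, 1L, 2L), f = c(5, 5, 5), g = c(1, 2, 3))
  expect_error(standardize_features(flat), "f")
})

test_that("the training audit CSV round-trips the selected voxels", {
  fx <- toy_candidates(list(wm = 80), voxel_size = c(1, 1, 1))
  pol <- sampling_policy("knn", knn_major_count = 40, seed = 8)
  tr <- select_training(fx$candidates, fx$image, pol, required_classes = "wm")
  path <- withr::local_tempfile(fileext = ".csv")
  export_training_csv(tr, path)
  back <- utils::read.csv(path)
  expect_identical(back$voxel, tr$voxel)
  expect_equal(back$t1, tr$t1)
})

test_that("the balanced major count scales with brain volume", {
  expect_identical(scaled_major_count(1400), 50000L)
  expect_identical(scaled_major_count(700), 25000L)
  expect_gt(scaled_major_count(0.001), 0L)
})
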