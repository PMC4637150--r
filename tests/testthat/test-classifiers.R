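random_instance <- function(seed, n_train = 120, n_targets = 60, d = 5,
                            n_classes = 4) {
  withr::with_seed(seed, list(
    feat = matrix(rnorm(n_train * d), n_train, d),
    lab = sample.int(n_classes, n_train, replace = TRUE),
    targets = matrix(rnorm(n_targets * d), n_targets, d)
  ))
}

test_that("k = 1 returns the label of a coincident training sample", {
  inst <- random_instance(1)
  out <- knn_classify(inst$feat[c(3, 17, 42), ],
                      list(features = inst$feat, labels = inst$lab),
                      knn_config(k = 1))
  expect_identical(out, inst$lab[c(3, 17, 42)])
})

test_that("kNN matches the exhaustive distance-sort oracle on random instances", {
  for (seed in 1:5) {
    inst <- random_instance(seed)
    for (k in c(1, 7, 40)) {
      mine <- knn_classify(inst$targets,
                           list(features = inst$feat, labels = inst$lab),
                           knn_config(k = k))
      oracle <- knn_oracle(inst$feat, inst$lab, inst$targets, k)
      expect_identical(mine, as.integer(oracle))
    }
  }
})

test_that("kNN output is invariant to permutations of the training rows", {
  inst <- random_instance(7)
  base <- knn_classify(inst$targets,
                       list(features = inst$feat, labels = inst$lab),
                       knn_config(k = 7))
  for (pseed in 1:3) {
    perm <- withr::with_seed(pseed, sample(nrow(inst$feat)))
    shuffled <- knn_classify(inst$targets,
                             list(features = inst$feat[perm, ],
                                  labels = inst$lab[perm]),
                             knn_config(k = 7))
    expect_identical(shuffled, base)
  }
})

test_that("a split vote goes to the class of the single nearest neighbour", {
  # k = 4, two classes with two votes each; class 2 owns the nearest sample
  feat <- matrix(c(0.1, 0.5, 0.3, 0.6), ncol = 1)
  lab <- c(2L, 2L, 1L, 1L)
  out <- knn_classify(matrix(0, 1, 1), list(features = feat, labels = lab),
                      knn_config(k = 4))
  expect_identical(out, 2L)
})

test_that("exact-distance ties resolve to the class earlier in the layer order", {
  # two training points equidistant from the target, different classes
  feat <- matrix(c(-1, 1), ncol = 1)
  lab <- c(5L, 4L)
  out <- knn_classify(matrix(0, 1, 1), list(features = feat, labels = lab),
                      knn_config(k = 1))
  expect_identical(out, 4L)  # pallidum (4) precedes putamen (5)
})

test_that("kNN input contracts are enforced", {
  inst <- random_instance(2, n_train = 10)
  expect_error(knn_classify(inst$targets,
                            list(features = inst$feat, labels = inst$lab),
                            knn_config(k = 11)), "exceeds")
  expect_error(knn_classify(inst$targets[, 1:3],
                            list(features = inst$feat, labels = inst$lab),
                            knn_config(k = 2)), "mismatch")
  expect_identical(
    knn_classify(inst$targets[0, , drop = FALSE],
                 list(features = inst$feat, labels = inst$lab),
                 knn_config(k = 2)),
    integer(0)
  )
})

two_cluster_train <- function(seed = 21L, n = 120, gap = 8) {
  withr::with_seed(seed, tibble::tibble(
    label = rep(c(3L, 6L), each = n),
    f1 = c(rnorm(n, -gap / 2), rnorm(n, gap / 2)),
    f2 = rnorm(2 * n),
    f3 = rnorm(2 * n, sd = 0.5)
  ))
}

test_that("PCA projection decorrelates the pooled training features", {
  train <- two_cluster_train()
  model <- pcda_fit(train)
  cv <- cov(model$train_proj)
  expect_true(all(abs(cv[upper.tri(cv)]) < 1e-8))
  expect_identical(model$retained, 3L)  # variance_keep = 1 keeps full rank
})

test_that("separated clusters score higher under their own class density", {
  train <- two_cluster_train()
  model <- pcda_fit(train)
  proj <- model$train_proj
  cls <- match(train$label, model$classes)
  logf <- subseg:::kde_logdens_cpp(t(proj), cls, 2L, model$bandwidths, t(proj))
  own <- logf[cbind(seq_len(nrow(proj)), cls)]
  other <- logf[cbind(seq_len(nrow(proj)), 3L - cls)]
  expect_true(all(own > other))
})

test_that("classes too small for a bandwidth estimate are rejected by name", {
  train <- two_cluster_train()
  train <- train[-(2:120), ]  # leave class 3 (wm) with a single sample
  expect_error(pcda_fit(train), "wm")
})

test_that("PCDA assigns targets at a dense cluster centre to that cluster", {
  train <- two_cluster_train()
  model <- pcda_fit(train)
  targets <- rbind(c(-4, 0, 0), c(4, 0, 0))
  colnames(targets) <- c("f1", "f2", "f3")
  expect_identical(as.integer(pcda_classify(targets, model)), c(3L, 6L))
})

test_that("universal density underflow falls back to the nearest training label", {
  train <- two_cluster_train()
  model <- pcda_fit(train)
  far <- matrix(c(1e4, 0, 0), 1, 3,
                dimnames = list(NULL, c("f1", "f2", "f3")))
  expect_message(out <- pcda_classify(far, model), "underflow")
  expect_identical(as.integer(out), 6L)  # nearest cluster sits at +gap/2
  expect_identical(attr(out, "n_fallback"), 1L)
})

test_that("PCDA feature-dimension mismatches are rejected", {
  model <- pcda_fit(two_cluster_train())
  expect_error(pcda_classify(matrix(0, 2, 2), model), "mismatch")
})

test_that("PCDA tidiers summarise components, counts and retained variance", {
  model <- pcda_fit(two_cluster_train(), variance_keep = 0.9)
  td <- tidy(model)
  expect_identical(nrow(td), 3L)
  expect_equal(td$cumulative_prop[3], 1)
  expect_identical(sum(td$retained), model$retained)
  g <- glance(model)
  expect_identical(g$n_train, 240L)
  expect_identical(g$n_classes, 2L)
  expect_gte(g$variance_retained, 0.9)
  expect_s3_class(autoplot(model), "ggplot")
})

test_that("PCDA approaches the Bayes error on the two-Gaussian toy as n grows", {
  errors <- sapply(c(100, 2000), function(n) {
    train <- withr::with_seed(31L, tibble::tibble(
      label = rep(c(1L, 2L), each = n),
      f = c(rnorm(n, -2), rnorm(n, 2))
    ))
    test <- withr::with_seed(32L, tibble::tibble(
      label = rep(c(1L, 2L), each = 2000),
      f = c(rnorm(2000, -2), rnorm(2000, 2))
    ))
    model <- pcda_fit(train)
    pred <- pcda_classify(matrix(test$f, dimnames = list(NULL, "f")), model)
    mean(pred != test$label)
  })
  bayes <- bayes_error_two_gaussians(2)
  expect_lt(abs(errors[2] - bayes), 0.02)
  expect_lte(abs(errors[2] - bayes), abs(errors[1] - bayes) + 0.005)
})
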