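#' Fit a principal-component discriminant-analysis (PCDA) model
#'
#' Computes a PCA of the pooled standardized training features, projects
#' the training samples onto the retained components, and fits one
#' nonparametric class-conditional density per class: a product-Gaussian
#' kernel density estimate over the retained components with Scott's-rule
#' bandwidth per component per class,
#' \eqn{h_{cj} = \sigma_{cj} \, n_c^{-1/(d+4)}}. Class priors are equal
#' (training sizes are rebalanced by the sampling policy, so empirical
#' priors would import sampling artifacts, not anatomy).
#'
#' @param train Standardized training tibble with `label` and feature
#'   columns (see [standardize_features()]).
#' @param variance_keep Fraction of total variance to retain; components
#'   are kept in order until their cumulative variance share reaches this
#'   value. Default 1.0 keeps every component (the features are
#'   transformed, not truncated).
#' @return An object of class `pcda_model`.
#' @export
pcda_fit <- function(train, variance_keep = 1.0) {
  stopifnot(is.data.frame(train), variance_keep > 0, variance_keep <= 1)
  cols <- feature_columns(train)
  if (length(cols) < 1L) stop("no feature columns found", call. = FALSE)
  feat <- as.matrix(train[, cols])
  labels <- as.integer(train$label)
  classes <- sort(unique(labels))
  n_per_class <- table(factor(labels, levels = classes))
  small <- classes[n_per_class < 2L]
  if (length(small))
    stop("too few training samples for a bandwidth estimate in class(es): ",
         paste(class_name(small), collapse = ", "), call. = FALSE)
  pca <- prcomp(feat, center = TRUE, scale. = FALSE)
  var_share <- pca$sdev^2 / sum(pca$sdev^2)
  retained <- which(cumsum(var_share) >= variance_keep - 1e-12)[1]
  if (is.na(retained)) retained <- length(var_share)
  proj <- pca$x[, seq_len(retained), drop = FALSE]
  # Scott's rule per class and component on the projected samples
  bw <- sapply(classes, function(cl) {
    p <- proj[labels == cl, , drop = FALSE]
    n_c <- nrow(p)
    sds <- apply(p, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance projected component for class '",
           class_name(cl), "'; cannot estimate a bandwidth", call. = FALSE)
    sds * n_c^(-1 / (retained + 4))
  })
  bw <- matrix(bw, nrow = retained)  # d' x K
  structure(
    list(
      rotation = pca$rotation[, seq_len(retained), drop = FALSE],
      center = pca$center,
      sdev = pca$sdev,
      retained = retained,
      variance_keep = variance_keep,
      feature_names = cols,
      classes = classes,
      priors = setNames(rep(1 / length(classes), length(classes)),
                        class_name(classes)),
      bandwidths = bw,
      train_proj = proj,
      train_labels = labels,
      n_per_class = as.integer(n_per_class)
    ),
    class = "pcda_model"
  )
}

#' @export
print.pcda_model <- function(x, ...) {
  cat(sprintf(
    "<pcda_model> %d classes, %d training samples, %d/%d components retained\n",
    length(x$classes), nrow(x$train_proj), x$retained, length(x$sdev)
  ))
  invisible(x)
}

#' Classify target feature vectors with a fitted PCDA model
#'
#' Projects the (standardized) targets onto the model's retained principal
#' components, evaluates every class's kernel density there, and assigns
#' each target by the Bayes decision rule,
#' \eqn{\arg\max_c \pi_c f_c(x)}, computed in log space. Posterior ties go
#' to the class earlier in the layer order. Targets at which every class
#' density underflows to numerical zero fall back to the label of the
#' nearest training sample; their count is reported via a message and the
#' `n_fallback` attribute.
#'
#' @param targets Numeric matrix of standardized target features (same
#'   feature space as the training data).
#' @param model A [pcda_model][pcda_fit()].
#' @return Integer vector of class codes with attribute `n_fallback`.
#' @export
pcda_classify <- function(targets, model) {
  stopifnot(inherits(model, "pcda_model"))
  targets <- as.matrix(targets)
  if (nrow(targets) == 0L) return(integer(0))
  if (ncol(targets) != length(model$center))
    stop("feature dimension mismatch: targets have ", ncol(targets),
         " features, model expects ", length(model$center), call. = FALSE)
  proj <- sweep(targets, 2, model$center) %*% model$rotation
  class_idx <- match(model$train_labels, model$classes)
  logf <- kde_logdens_cpp(t(model$train_proj), class_idx,
                          length(model$classes), model$bandwidths, t(proj))
  logpost <- sweep(logf, 2, log(unname(model$priors)), `+`)
  pick <- max.col(logpost, ties.method = "first")  # earlier class wins ties
  labels <- model$classes[pick]
  # density underflow: every class density is numerically zero
  fallback <- apply(logf, 1, max) < log(.Machine$double.xmin)
  n_fb <- sum(fallback)
  if (n_fb > 0) {
    nn <- knn_vote_cpp(t(model$train_proj), model$train_labels,
                       t(proj[fallback, , drop = FALSE]), 1L)
    labels[fallback] <- nn
    message(n_fb, " voxel(s) with all class densities underflowing; ",
            "fell back to nearest-training-sample labels")
  }
  structure(labels, n_fallback = n_fb)
}

#' Tidy a PCDA model: per-component variance table
#'
#' @param x A [pcda_model][pcda_fit()].
#' @param ... Unused.
#' @return Tibble with `component`, `sdev`, `variance_prop`,
#'   `cumulative_prop`, `retained`.
#' @export
tidy.pcda_model <- function(x, ...) {
  vp <- x$sdev^2 / sum(x$sdev^2)
  tibble::tibble(
    component = seq_along(x$sdev),
    sdev = x$sdev,
    variance_prop = vp,
    cumulative_prop = cumsum(vp),
    retained = seq_along(x$sdev) <= x$retained
  )
}

#' Glance at a PCDA model
#'
#' @param x A [pcda_model][pcda_fit()].
#' @param ... Unused.
#' @return One-row tibble with sample/class/component counts and the
#'   variance retained.
#' @export
glance.pcda_model <- function(x, ...) {
  vp <- x$sdev^2 / sum(x$sdev^2)
  tibble::tibble(
    n_train = nrow(x$train_proj),
    n_classes = length(x$classes),
    n_features = length(x$center),
    n_retained = x$retained,
    variance_retained = sum(vp[seq_len(x$retained)])
  )
}

#' Scree plot for a PCDA model
#'
#' @param object A [pcda_model][pcda_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcda_model <- function(object, ...) {
  td <- tidy.pcda_model(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$component, y = .data$variance_prop,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(breaks = td$component) +
    ggplot2::labs(x = "Principal component", y = "Variance proportion",
                  fill = "Retained") +
    ggplot2::theme_minimal()
}
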