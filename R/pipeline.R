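#' Configuration for a full segmentation run
#'
#' Collects every input and parameter of the atlas-to-label-map pipeline.
#' Spatial inputs can be in-memory objects or NIfTI file paths; files are
#' read lazily by [run_pipeline()]. All inputs must already be
#' coregistered, bias-corrected and skull-stripped on one voxel grid —
#' the pipeline validates geometry but never resamples.
#'
#' @param image [ms_volume()] or named character vector of channel NIfTI
#'   paths.
#' @param atlases [atlas_set()] or named character vector of per-class
#'   atlas NIfTI paths.
#' @param brain_mask Logical array, or a NIfTI path of a 0/1 mask.
#' @param method `"knn"` or `"pcda"`.
#' @param threshold Atlas probability threshold in (0, 1]; default 0.8.
#' @param knn A [knn_config()]; used when `method = "knn"`.
#' @param policy A [sampling_policy()]; defaults to the method's standard
#'   sizes (10% fractions for PCDA; 20% minor fraction and 50,000 balanced
#'   major-tissue voxels for kNN) with `seed`.
#' @param variance_keep PCA variance fraction retained by PCDA; default 1.
#' @param seed Integer seed controlling the training-sample draw.
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes the label map, legend, volume report and audit log there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(image, atlases, brain_mask,
                       method = c("knn", "pcda"),
                       threshold = 0.8,
                       knn = knn_config(),
                       policy = NULL,
                       variance_keep = 1.0,
                       seed = 1L,
                       out_dir = NULL) {
  method <- match.arg(method)
  if (is.null(policy)) policy <- sampling_policy(method, seed = seed)
  stopifnot(inherits(policy, "sampling_policy"), inherits(knn, "knn_config"))
  if (policy$method != method)
    stop("sampling policy is for method '", policy$method,
         "' but the run uses '", method, "'", call. = FALSE)
  structure(
    list(image = image, atlases = atlases, brain_mask = brain_mask,
         method = method, threshold = threshold, knn = knn, policy = policy,
         variance_keep = variance_keep, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Build a run configuration from a YAML file
#'
#' The file mirrors the CLI flags: `channels` (named map class/channel
#' name to path), `atlases` (named map), `mask`, `method`, `threshold`,
#' `k`, `pcda_fraction`, `knn_fraction`, `major_count`, `variance_keep`,
#' `seed`, `out_dir`. Relative paths are resolved against the YAML file's
#' directory.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  channels <- unlist(cfg$channels)
  atlases <- unlist(cfg$atlases)
  method <- cfg$method %||% "knn"
  seed <- as.integer(cfg$seed %||% 1L)
  policy <- sampling_policy(
    method,
    pcda_fraction = cfg$pcda_fraction %||% 0.10,
    knn_minor_fraction = cfg$knn_fraction %||% 0.20,
    knn_major_count = cfg$major_count %||% 50000L,
    seed = seed
  )
  run_config(
    image = setNames(resolve(channels), names(channels)),
    atlases = setNames(resolve(atlases), names(atlases)),
    brain_mask = resolve(cfg$mask),
    method = method,
    threshold = cfg$threshold %||% 0.8,
    knn = knn_config(k = cfg$k %||% 40L),
    policy = policy,
    variance_keep = cfg$variance_keep %||% 1.0,
    seed = seed,
    out_dir = cfg$out_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_inputs <- function(cfg) {
  image <- cfg$image
  if (is.character(image)) image <- read_ms_volume(image)
  atlases <- cfg$atlases
  if (is.character(atlases)) atlases <- read_atlas_set(atlases)
  mask <- cfg$brain_mask
  if (is.character(mask)) {
    m <- read_nifti_array(mask)
    mask <- m$data > 0.5
  }
  check_same_grid(image, atlases, mask, what = "channels, atlases and mask")
  list(image = image, atlases = atlases, brain_mask = mask)
}

#' Run the full atlas-guided segmentation pipeline
#'
#' Executes, in order: atlas layering and thresholding into candidate
#' masks; random training selection per the sampling policy; feature
#' standardization (training statistics applied to all brain voxels); kNN
#' or PCDA classification of every brain-mask voxel; and per-class volume
#' computation. A rerun with the same configuration and seed is
#' bit-identical.
#'
#' @param cfg A [run_config()].
#' @return An object of class `subseg_run`: list with `result` (a
#'   `subseg_result` holding the [label_map()] and provenance), `volumes`
#'   (a [compute_volumes()] report), `training` (per-class sample counts),
#'   and `audit` (config echo, seed, counts, warnings). Written to
#'   `cfg$out_dir` as NIfTI + CSV/JSON when configured.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  inp <- resolve_inputs(cfg)
  warn_log <- character(0)
  candidates <- withCallingHandlers(
    layer_and_threshold(inp$atlases, cfg$threshold, inp$brain_mask),
    warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  train_raw <- withCallingHandlers(
    select_training(candidates, inp$image, cfg$policy),
    warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  tf <- target_features(inp$image, inp$brain_mask)
  std <- standardize_features(train_raw, tf$features)
  labels_vec <- if (cfg$method == "knn") {
    knn_classify(std$targets, std$train, cfg$knn)
  } else {
    model <- pcda_fit(std$train, cfg$variance_keep)
    suppressMessages(pcda_classify(std$targets, model))
  }
  n_fallback <- attr(labels_vec, "n_fallback") %||% 0L
  labs <- array(0L, dim(inp$image))
  labs[tf$voxel] <- as.integer(labels_vec)
  result <- structure(
    list(
      labels = label_map(labs, inp$image$voxel_size),
      method = cfg$method,
      provenance = list(
        method = cfg$method, threshold = cfg$threshold,
        k = cfg$knn$k, variance_keep = cfg$variance_keep,
        seed = cfg$seed, policy = unclass(cfg$policy),
        channels = inp$image$channels,
        standardization = list(center = std$center, scale = std$scale),
        n_fallback = n_fallback
      )
    ),
    class = "subseg_result"
  )
  volumes <- compute_volumes(result)
  training_counts <- dplyr::count(train_raw, .data$class, .data$label,
                                  name = "n_train")
  audit <- list(
    config = result$provenance,
    candidate_counts = tidy.candidate_mask(candidates),
    training_counts = training_counts,
    warnings = warn_log
  )
  run <- structure(
    list(result = result, volumes = volumes, training = training_counts,
         audit = audit),
    class = "subseg_run"
  )
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

#' @export
print.subseg_result <- function(x, ...) {
  cat(sprintf("<subseg_result> method %s, threshold %.2f, seed %d\n",
              x$method, x$provenance$threshold, x$provenance$seed))
  print(x$labels)
  invisible(x)
}

#' @export
print.subseg_run <- function(x, ...) {
  print(x$result)
  cat("Volumes (cc):\n")
  print(x$volumes, n = Inf)
  invisible(x)
}

#' Per-class volume table of a segmentation
#'
#' @param x A `subseg_result` or `subseg_run`.
#' @param ... Unused.
#' @return The [compute_volumes()] tibble.
#' @export
tidy.subseg_result <- function(x, ...) compute_volumes(x)

#' @export
tidy.subseg_run <- function(x, ...) x$volumes

#' One-row summary of a segmentation run
#'
#' @param x A `subseg_run`.
#' @param ... Unused.
#' @return One-row tibble: method, threshold, seed, training size,
#'   labelled voxels, brain volume (cc) and underflow fallback count.
#' @export
glance.subseg_run <- function(x, ...) {
  tibble::tibble(
    method = x$result$method,
    threshold = x$result$provenance$threshold,
    seed = x$result$provenance$seed,
    n_train = sum(x$training$n_train),
    n_voxels = sum(x$volumes$voxels),
    brain_volume_cc = sum(x$volumes$volume_cc),
    n_fallback = x$result$provenance$n_fallback
  )
}

# write label map, legend, reports and audit log to a directory
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_label_map(run$result, file.path(dir, "segmentation.nii.gz"))
  utils::write.csv(as.data.frame(run$volumes),
                   file.path(dir, "volumes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      config = run$audit$config,
      candidate_counts = run$audit$candidate_counts,
      training_counts = run$audit$training_counts,
      warnings = run$audit$warnings,
      volumes = run$volumes
    ),
    file.path(dir, "audit.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(dir)
}
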