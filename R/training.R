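#' Training-sample size policy
#'
#' Encodes how many voxels are drawn per class from the candidate masks.
#' The kNN classifier uses a fixed, balanced count for the three major
#' tissues (training proportional to volume would over-represent GM) and a
#' fraction of each subcortical structure's candidate volume; PCDA is less
#' sensitive to training size and uses one fraction for all seven classes.
#'
#' @param method `"knn"` or `"pcda"`.
#' @param pcda_fraction Fraction of each class's candidate voxels used by
#'   PCDA. Default 0.10.
#' @param knn_minor_fraction Fraction of each subcortical structure's
#'   candidate voxels used by kNN. Default 0.20.
#' @param knn_major_count Fixed voxel count per major tissue (CSF, GM, WM)
#'   for kNN. Default 50000 (50 cc at 1 mm isotropic resolution).
#' @param seed Integer seed for the sampling RNG stream.
#' @return An object of class `sampling_policy`.
#' @export
sampling_policy <- function(method = c("knn", "pcda"),
                            pcda_fraction = 0.10,
                            knn_minor_fraction = 0.20,
                            knn_major_count = 50000L,
                            seed = 1L) {
  method <- match.arg(method)
  stopifnot(pcda_fraction > 0, pcda_fraction <= 1,
            knn_minor_fraction > 0, knn_minor_fraction <= 1,
            knn_major_count >= 1)
  structure(
    list(method = method, pcda_fraction = pcda_fraction,
         knn_minor_fraction = knn_minor_fraction,
         knn_major_count = as.integer(knn_major_count),
         seed = as.integer(seed)),
    class = "sampling_policy"
  )
}

#' Scale the balanced major-tissue training count to a target brain volume
#'
#' The balanced major-tissue training size of 50,000 voxels (50 cc at 1 mm
#' isotropic resolution) was defined for adult intracranial volumes of
#' roughly 1400 cc, i.e. about 3.6% of the brain. Transplanting the
#' absolute count onto a small phantom would saturate the major tissues
#' (every candidate becomes a training sample) and distort the training
#' composition, so for scaled-down targets the count is scaled to preserve
#' that proportion instead.
#'
#' @param brain_volume_cc Brain-mask volume of the target, in cc.
#' @param reference_count Balanced count at full scale; default 50000.
#' @param reference_brain_cc Brain volume the reference count was defined
#'   for; default 1400 cc.
#' @return Integer count (at least 1).
#' @export
#' @examples
#' scaled_major_count(1400)  # full-size brain: 50,000
#' scaled_major_count(88)    # 64 mm phantom: ~3,100
scaled_major_count <- function(brain_volume_cc, reference_count = 50000L,
                               reference_brain_cc = 1400) {
  stopifnot(brain_volume_cc > 0)
  max(1L, as.integer(round(reference_count * brain_volume_cc / reference_brain_cc)))
}

# requested sample size for one class under a policy (before clamping)
requested_size <- function(policy, class, n_candidates) {
  if (policy$method == "pcda") {
    max(1L, as.integer(round(policy$pcda_fraction * n_candidates)))
  } else if (class %in% .major_classes) {
    policy$knn_major_count
  } else {
    max(1L, as.integer(round(policy$knn_minor_fraction * n_candidates)))
  }
}

#' Select training voxels from candidate masks
#'
#' Draws, per class, a uniform random sample without replacement of the
#' policy-determined size from that class's candidate voxels, and extracts
#' raw feature vectors: the three spatial coordinates in mm (0-based voxel
#' index times voxel size, honouring anisotropic voxels) plus the C channel
#' intensities read directly at the voxel (no interpolation). One global
#' RNG stream seeded from the policy makes the draw reproducible; classes
#' are visited in layer order.
#'
#' @param candidates A `candidate_mask` from [layer_and_threshold()].
#' @param image An [ms_volume()] on the same grid.
#' @param policy A [sampling_policy()].
#' @param required_classes Classes that must have at least one candidate;
#'   default all classes present in `candidates`. A required class with no
#'   candidates is a fatal error (lower the threshold or check the atlas).
#' @return A tibble of class `training_set` with columns `class`, `label`
#'   (integer code), `voxel` (linear index), `x`, `y`, `z` (mm) and one
#'   intensity column per channel. Requests exceeding the candidate count
#'   are clamped with a warning.
#' @export
select_training <- function(candidates, image, policy,
                            required_classes = names(candidates)) {
  stopifnot(inherits(candidates, "candidate_mask"),
            inherits(image, "ms_volume"),
            inherits(policy, "sampling_policy"))
  check_same_grid(candidates[[1]], image, what = "candidates and image")
  counts <- vapply(candidates, sum, numeric(1))
  missing <- intersect(required_classes, names(counts)[counts == 0])
  if (length(missing))
    stop("no candidate voxels for required class(es): ",
         paste(missing, collapse = ", "),
         " (threshold too high for these tissues?)", call. = FALSE)
  gs <- dim(image)
  vs <- image$voxel_size
  nchan <- n_channels(image)
  chmat <- matrix(image$data, ncol = nchan)  # voxels x channels
  rows <- withr::with_seed(policy$seed, {
    lapply(names(candidates), function(cl) {
      idx <- which(candidates[[cl]])
      if (length(idx) == 0L) return(NULL)
      size <- requested_size(policy, cl, length(idx))
      if (size > length(idx)) {
        warning("class '", cl, "': requested ", size,
                " training voxels but only ", length(idx),
                " candidates; clamping", call. = FALSE)
        size <- length(idx)
      }
      take <- if (size == length(idx)) idx else sort(sample(idx, size))
      ijk <- arrayInd(take, gs)
      feat <- cbind(
        (ijk[, 1] - 1L) * vs[1],
        (ijk[, 2] - 1L) * vs[2],
        (ijk[, 3] - 1L) * vs[3],
        chmat[take, , drop = FALSE]
      )
      colnames(feat) <- c("x", "y", "z", image$channels)
      tibble::tibble(class = cl, label = class_code(cl), voxel = take,
                     tibble::as_tibble(feat))
    })
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("training_set", class(out)),
            channels = image$channels, voxel_size = vs)
}

#' Feature columns of a training or target table
#'
#' @param x A training-set tibble (or any tibble with `x`, `y`, `z` and
#'   channel intensity columns).
#' @param channels Channel names; taken from the `channels` attribute when
#'   present.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(x, channels = attr(x, "channels")) {
  if (!is.null(channels)) return(c("x", "y", "z", channels))
  numeric_cols <- names(x)[vapply(x, is.numeric, TRUE)]
  setdiff(numeric_cols, c("label", "voxel"))
}

#' Standardize features to zero mean and unit variance
#'
#' Shifts and rescales every feature column (spatial coordinates and
#' channel intensities) to mean 0, variance 1 over the *training* samples,
#' using the population (n-denominator) standard deviation, and applies the
#' same transform to the target voxels. The transform parameters are
#' returned so a run can be audited or replayed.
#'
#' @param train Training tibble from [select_training()] (or any tibble
#'   with the feature columns).
#' @param targets Matrix or tibble of raw target features with the same
#'   columns; optional.
#' @return List with `train` (standardized training tibble), `targets`
#'   (standardized target matrix, or `NULL`), `center` and `scale` (named
#'   numeric vectors).
#' @export
standardize_features <- function(train, targets = NULL) {
  cols <- feature_columns(train)
  tm <- as.matrix(train[, cols])
  if (nrow(tm) < 2L)
    stop("need at least 2 training samples to standardize (SD undefined)",
         call. = FALSE)
  center <- colMeans(tm)
  scale <- sqrt(colMeans(sweep(tm, 2, center)^2))  # population SD
  if (any(scale == 0))
    stop("constant training feature(s): ",
         paste(cols[scale == 0], collapse = ", "), call. = FALSE)
  std <- sweep(sweep(tm, 2, center), 2, scale, `/`)
  out_train <- train
  out_train[, cols] <- tibble::as_tibble(std)
  out_targets <- NULL
  if (!is.null(targets)) {
    gm <- as.matrix(as.data.frame(targets)[, cols, drop = FALSE])
    out_targets <- sweep(sweep(gm, 2, center), 2, scale, `/`)
  }
  list(train = out_train, targets = out_targets,
       center = setNames(center, cols), scale = setNames(scale, cols))
}

# raw feature matrix for every voxel inside a mask, in mm + intensities
target_features <- function(image, brain_mask) {
  gs <- dim(image)
  vs <- image$voxel_size
  idx <- which(brain_mask)
  ijk <- arrayInd(idx, gs)
  chmat <- matrix(image$data, ncol = n_channels(image))
  feat <- cbind(
    (ijk[, 1] - 1L) * vs[1],
    (ijk[, 2] - 1L) * vs[2],
    (ijk[, 3] - 1L) * vs[3],
    chmat[idx, , drop = FALSE]
  )
  colnames(feat) <- c("x", "y", "z", image$channels)
  list(features = feat, voxel = idx)
}

#' Export training voxel coordinates for QC
#'
#' Writes the selected training voxels (class, voxel index, mm coordinates,
#' intensities) as a CSV audit table, e.g. to overlay on the anatomy.
#'
#' @param train A `training_set` tibble.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
export_training_csv <- function(train, path) {
  utils::write.csv(as.data.frame(train), path, row.names = FALSE)
  invisible(path)
}
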