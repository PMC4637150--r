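#' Specification for a synthetic multispectral brain phantom
#'
#' Builds the parameter set for [generate_phantom()]: a piecewise-constant
#' ellipsoidal "brain" (nested CSF / GM / WM shells) carrying four bilateral
#' subcortical structures, imaged in C channels with additive Gaussian noise
#' and an optional smooth multiplicative bias field. Probability atlases are
#' derived from the ground truth by Gaussian smoothing and a rigid
#' translation, emulating atlas registration error.
#'
#' Default class means mimic T1w / T2w / PDw contrast in arbitrary units:
#' CSF dark on T1 and bright on T2, WM brightest on T1, and pallidum means
#' deliberately close to WM on every channel so that intensity alone cannot
#' separate the hardest structure and the spatial features must do real work.
#'
#' @param grid_shape Integer length-3, voxels per axis. Default `c(64, 64, 64)`.
#' @param voxel_size Numeric length-3, mm per axis. Default 1 mm isotropic.
#' @param class_means Numeric matrix, one row per class in
#'   [subseg_classes()] order, one column per channel. Arbitrary units.
#' @param noise_sd Per-channel additive Gaussian SD (same units as
#'   `class_means`). Default 4 for every channel.
#' @param bias_amplitude Fractional amplitude of a smooth multiplicative
#'   bias field (0 disables; bias correction is assumed done upstream).
#' @param atlas_fwhm Full width at half maximum (mm) of the Gaussian used to
#'   smooth the one-hot truth maps into probability atlases. Default 2.
#' @param atlas_shift Length-3 translation (mm) applied to the atlases as a
#'   registration-error surrogate. Default `c(1, 0, 0)`.
#' @param structure_geometry Named list of ellipsoid components; see
#'   [default_structure_geometry()].
#' @param seed Integer RNG seed; the phantom is bit-reproducible for a
#'   fixed spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_size = c(1, 1, 1),
                         class_means = default_class_means(),
                         noise_sd = c(4, 4, 4),
                         bias_amplitude = 0,
                         atlas_fwhm = 2,
                         atlas_shift = c(1, 0, 0),
                         structure_geometry = default_structure_geometry(),
                         seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  class_means <- as.matrix(class_means)
  if (nrow(class_means) != 7L)
    stop("`class_means` needs one row per class (7)", call. = FALSE)
  if (is.null(rownames(class_means))) rownames(class_means) <- .classes
  noise_sd <- as.numeric(noise_sd)
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, ncol(class_means))
  stopifnot(length(noise_sd) == ncol(class_means), all(noise_sd >= 0))
  stopifnot(atlas_fwhm >= 0, length(atlas_shift) == 3L, bias_amplitude >= 0)
  for (cl in .classes) {
    g <- structure_geometry[[cl]]
    if (is.null(g)) stop("structure_geometry missing class '", cl, "'", call. = FALSE)
    if (any(g$semiaxes <= 0))
      stop("semi-axes for '", cl, "' must be positive", call. = FALSE)
  }
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         class_means = class_means, noise_sd = noise_sd,
         bias_amplitude = bias_amplitude, atlas_fwhm = atlas_fwhm,
         atlas_shift = as.numeric(atlas_shift),
         structure_geometry = structure_geometry, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default per-class, per-channel mean intensities
#'
#' Rows follow [subseg_classes()] order; columns are T1w-, T2w- and PDw-like
#' channels. Units are arbitrary (bias-corrected MR signal).
#'
#' @return A 7 x 3 numeric matrix.
#' @export
default_class_means <- function() {
  m <- rbind(
    csf      = c(45, 190, 150),
    gm       = c(105, 95, 110),
    wm       = c(145, 75, 90),
    pallidum = c(132, 62, 86),
    putamen  = c(112, 90, 105),
    thalamus = c(118, 88, 100),
    caudate  = c(108, 92, 108)
  )
  colnames(m) <- c("t1", "t2", "pd")
  m
}

#' Default phantom geometry
#'
#' Ellipsoid components in mm, as offsets from the grid centre. The three
#' major tissues are nested shells (CSF outside GM outside WM); each
#' subcortical structure is a mirrored bilateral ellipsoid pair placed
#' inside the WM core, pairwise disjoint, with sizes scaled down relative
#' to adult anatomy to fit a 64 mm field of view.
#'
#' @return Named list; each element has `center` (mm offset), `semiaxes`
#'   (mm) and `bilateral` (logical: mirror about the mid-sagittal plane).
#' @export
default_structure_geometry <- function() {
  list(
    csf      = list(center = c(0, 0, 0),    semiaxes = c(30, 28, 25), bilateral = FALSE),
    gm       = list(center = c(0, 0, 0),    semiaxes = c(27, 25, 22.5), bilateral = FALSE),
    wm       = list(center = c(0, 0, 0),    semiaxes = c(23, 21, 19), bilateral = FALSE),
    pallidum = list(center = c(7.5, 0.5, -1),  semiaxes = c(5, 6, 5), bilateral = TRUE),
    putamen  = list(center = c(17.5, 2, 0),    semiaxes = c(4.5, 7, 5.5), bilateral = TRUE),
    thalamus = list(center = c(7.5, -12.5, 0), semiaxes = c(6, 7, 6), bilateral = TRUE),
    caudate  = list(center = c(8, 12.5, 2.5),  semiaxes = c(4, 6, 5), bilateral = TRUE)
  )
}

# logical mask of voxels inside an ellipsoid; coords in mm relative to grid centre
ellipsoid_mask <- function(grid_shape, voxel_size, center, semiaxes) {
  ax <- (seq_len(grid_shape[1]) - 1 - (grid_shape[1] - 1) / 2) * voxel_size[1]
  ay <- (seq_len(grid_shape[2]) - 1 - (grid_shape[2] - 1) / 2) * voxel_size[2]
  az <- (seq_len(grid_shape[3]) - 1 - (grid_shape[3] - 1) / 2) * voxel_size[3]
  qx <- ((ax - center[1]) / semiaxes[1])^2
  qy <- ((ay - center[2]) / semiaxes[2])^2
  qz <- ((az - center[3]) / semiaxes[3])^2
  outer(outer(qx, qy, `+`), qz, `+`) <= 1
}

# truth label array from the nested-shell + bilateral-blob geometry
build_truth <- function(spec) {
  gs <- spec$grid_shape; vs <- spec$voxel_size
  geom <- spec$structure_geometry
  labels <- array(0L, gs)
  # nested shells: csf (outer brain), gm, wm override in turn
  for (cl in .major_classes) {
    g <- geom[[cl]]
    labels[ellipsoid_mask(gs, vs, g$center, g$semiaxes)] <- class_code(cl)
  }
  # subcortical structures superimposed in layer order, last wins
  for (cl in .subcortical_classes) {
    g <- geom[[cl]]
    m <- ellipsoid_mask(gs, vs, g$center, g$semiaxes)
    if (isTRUE(g$bilateral)) {
      mirrored <- g$center * c(-1, 1, 1)
      m <- m | ellipsoid_mask(gs, vs, mirrored, g$semiaxes)
    }
    labels[m] <- class_code(cl)
  }
  counts <- tabulate(labels, nbins = 7L)
  if (any(counts == 0L))
    stop("phantom geometry leaves class(es) empty: ",
         paste(.classes[counts == 0L], collapse = ", "), call. = FALSE)
  labels
}

# separable Gaussian smoothing of a 3-D array (zero padding at the edges)
gaussian_smooth3d <- function(arr, fwhm_mm, voxel_size) {
  if (fwhm_mm <= 0) return(arr)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size
  for (d in 1:3) {
    s <- sigma_vox[d]
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r):r / s)^2)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, d)
  }
  arr
}

# 1-D convolution of a 3-D array along axis `d` with an odd symmetric kernel
convolve_axis <- function(arr, kernel, d) {
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(arr))
  n <- dim(arr)[d]
  for (t in seq_along(kernel)) {
    off <- t - 1L - r
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    idx_dst <- which(keep); idx_src <- src[keep]
    if (d == 1L) out[idx_dst, , ] <- out[idx_dst, , ] + kernel[t] * arr[idx_src, , ]
    else if (d == 2L) out[, idx_dst, ] <- out[, idx_dst, ] + kernel[t] * arr[, idx_src, ]
    else out[, , idx_dst] <- out[, , idx_dst] + kernel[t] * arr[, , idx_src]
  }
  out
}

# translate a 3-D array by whole voxels (zero fill)
shift_array <- function(arr, shift_vox) {
  s <- as.integer(round(shift_vox))
  if (all(s == 0L)) return(arr)
  out <- array(0, dim(arr))
  d <- dim(arr)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    dst[[ax]] <- max(1L, 1L + s[ax]):min(d[ax], d[ax] + s[ax])
    src[[ax]] <- dst[[ax]] - s[ax]
    if (length(dst[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# smooth low-order multiplicative bias field in [1 - a, 1 + a]
bias_field <- function(grid_shape, amplitude) {
  if (amplitude == 0) return(array(1, grid_shape))
  gx <- cos(pi * (seq_len(grid_shape[1]) - 1) / (grid_shape[1] - 1))
  gy <- cos(pi * (seq_len(grid_shape[2]) - 1) / (grid_shape[2] - 1))
  gz <- cos(pi * (seq_len(grid_shape[3]) - 1) / (grid_shape[3] - 1))
  1 + amplitude * outer(outer(gx, gy), gz)
}

#' Generate a synthetic multispectral brain phantom
#'
#' Produces a ground-truth label map, a noisy multispectral image whose
#' noiseless intensities equal the per-class means, a brain mask, and one
#' probability atlas per class obtained by smoothing the one-hot truth with
#' a Gaussian of `atlas_fwhm` mm and translating it by `atlas_shift` mm
#' (rounded to whole voxels), clipped to \[0, 1\]. Deterministic for a fixed
#' spec (including its seed).
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `image` ([ms_volume()]),
#'   `truth` ([label_map()]), `atlases` ([atlas_set()]), `brain_mask`
#'   (logical array) and `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32)))
#' ph$image
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- build_truth(spec)
  gs <- spec$grid_shape
  nchan <- ncol(spec$class_means)
  means_by_label <- rbind(0, spec$class_means)  # row 1 = background
  bias <- bias_field(gs, spec$bias_amplitude)
  img <- array(0, c(gs, nchan))
  withr::with_seed(spec$seed, {
    for (ch in seq_len(nchan)) {
      base <- means_by_label[as.vector(truth) + 1L, ch]
      noisy <- base * as.vector(bias) + rnorm(length(base), sd = spec$noise_sd[ch])
      img[, , , ch] <- array(noisy, gs)
    }
  })
  atlases <- lapply(.classes, function(cl) {
    onehot <- array(as.numeric(truth == class_code(cl)), gs)
    sm <- gaussian_smooth3d(onehot, spec$atlas_fwhm, spec$voxel_size)
    sm <- shift_array(sm, spec$atlas_shift / spec$voxel_size)
    # stored at 8-bit precision, like typical published atlas volumes;
    # sub-quantum Gaussian tails therefore carry no support
    round(pmin(pmax(sm, 0), 1) * 255) / 255
  })
  names(atlases) <- .classes
  channels <- colnames(spec$class_means)
  structure(
    list(
      image = ms_volume(img, spec$voxel_size, channels = channels),
      truth = label_map(truth, spec$voxel_size),
      atlases = atlas_set(atlases, spec$voxel_size, layer_order = .classes),
      brain_mask = truth > 0L,
      spec = spec
    ),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>\n")
  print(x$image)
  print(x$truth)
  print(x$atlases)
  invisible(x)
}

#' Write a phantom to a directory as NIfTI-1 files
#'
#' Writes `channel_<name>.nii.gz` per channel, `truth.nii.gz`,
#' `mask.nii.gz`, one `atlas_<class>.nii.gz` per class, and a
#' `legend.json` mapping label codes to class names.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vs <- phantom$image$voxel_size
  for (ch in seq_along(phantom$image$channels)) {
    write_nifti_array(phantom$image$data[, , , ch], vs,
                      file.path(dir, paste0("channel_", phantom$image$channels[ch], ".nii.gz")))
  }
  write_nifti_array(phantom$truth$labels, vs, file.path(dir, "truth.nii.gz"))
  write_nifti_array(phantom$brain_mask * 1L, vs, file.path(dir, "mask.nii.gz"))
  for (cl in names(phantom$atlases$maps)) {
    write_nifti_array(phantom$atlases$maps[[cl]], vs,
                      file.path(dir, paste0("atlas_", cl, ".nii.gz")))
  }
  jsonlite::write_json(
    as.list(setNames(subseg_classes()$code, subseg_classes()$class)),
    file.path(dir, "legend.json"), auto_unbox = TRUE
  )
  invisible(dir)
}
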