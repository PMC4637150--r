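# NIfTI-1 I/O thin wrappers around RNifti. All readers return plain arrays
# plus voxel sizes; geometry agreement across files is checked by the caller.

write_nifti_array <- function(arr, voxel_size, path) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- voxel_size
  RNifti::writeNifti(im, path)
  invisible(path)
}

read_nifti_array <- function(path) {
  im <- RNifti::readNifti(path)
  list(data = as.array(im), voxel_size = RNifti::pixdim(im)[1:3])
}

#' Read coregistered channel volumes into an `ms_volume`
#'
#' @param paths Character vector of NIfTI file paths, one per channel.
#'   Channel names are taken from `names(paths)` or the file basenames.
#' @return An [ms_volume()].
#' @export
read_ms_volume <- function(paths) {
  stopifnot(length(paths) >= 1L)
  vols <- lapply(paths, read_nifti_array)
  dims <- unique(lapply(vols, function(v) dim(v$data)))
  if (length(dims) != 1L)
    stop("channel volumes are not on one grid: ", paste(paths, collapse = ", "),
         call. = FALSE)
  nm <- names(paths)
  if (is.null(nm)) nm <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  data <- array(0, c(dims[[1]], length(vols)))
  for (i in seq_along(vols)) data[, , , i] <- vols[[i]]$data
  ms_volume(data, vols[[1]]$voxel_size, channels = nm)
}

#' Read per-class probability atlases into an `atlas_set`
#'
#' Values are rescaled to \[0, 1\] per class with [rescale_unit()] before
#' assembly, as maps from heterogeneous sources arrive on arbitrary scales.
#'
#' @param paths Named character vector: `class = file`. Names must be class
#'   names from [subseg_classes()].
#' @param layer_order Superimposition order; default is the package's fixed
#'   order (major tissues, then pallidum, putamen, thalamus, caudate).
#' @param rescale Rescale each map to \[0, 1\]? Default `TRUE`.
#' @return An [atlas_set()].
#' @export
read_atlas_set <- function(paths, layer_order = subseg_classes()$class,
                           rescale = TRUE) {
  stopifnot(!is.null(names(paths)))
  vols <- lapply(paths, read_nifti_array)
  maps <- lapply(names(paths), function(cl) {
    m <- vols[[cl]]$data
    if (rescale) rescale_unit(m, class = cl) else m
  })
  names(maps) <- names(paths)
  atlas_set(maps, vols[[1]]$voxel_size,
            layer_order = intersect(layer_order, names(paths)))
}

#' Read a label map and its voxel geometry
#'
#' @param path NIfTI file of integer class codes.
#' @return A [label_map()].
#' @export
read_label_map <- function(path) {
  v <- read_nifti_array(path)
  label_map(array(as.integer(round(v$data)), dim(v$data)), v$voxel_size)
}

#' Write a segmentation label map plus its legend sidecar
#'
#' @param seg A [label_map()] or segmentation result.
#' @param path Output NIfTI path; a `<path>.json` legend (code to class
#'   name) is written alongside.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(seg, path) {
  lm <- if (inherits(seg, "subseg_result")) seg$labels else seg
  stopifnot(inherits(lm, "label_map"))
  write_nifti_array(lm$labels, lm$voxel_size, path)
  jsonlite::write_json(
    as.list(setNames(subseg_classes()$class, subseg_classes()$code)),
    paste0(sub("\\.nii(\\.gz)?$", "", path), "_legend.json"),
    auto_unbox = TRUE
  )
  invisible(path)
}
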