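#' Multispectral volume container
#'
#' Wraps a 4-D numeric array (x, y, z, channel) of coregistered MR channel
#' intensities on one voxel grid. All spatial inputs to a segmentation run
#' (channels, atlases, masks) must share `dim` and `voxel_size`; the package
#' validates geometry but never resamples.
#'
#' @param data Numeric array, either 3-D (single channel) or 4-D with the
#'   channel as the fourth dimension.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @param channels Optional character vector of channel names (e.g.
#'   `c("t1", "t2", "pd")`); defaults to `ch1..chC`.
#' @return An object of class `ms_volume`.
#' @export
ms_volume <- function(data, voxel_size, channels = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (mm)", call. = FALSE)
  nc <- dim(data)[4]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc)
    stop("`channels` must name each of the ", nc, " channels", call. = FALSE)
  structure(
    list(data = data, voxel_size = voxel_size, channels = channels),
    class = "ms_volume"
  )
}

#' @export
print.ms_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ms_volume> %d x %d x %d voxels, %d channel(s) [%s], voxel %s mm\n",
    d[1], d[2], d[3], d[4], paste(x$channels, collapse = ", "),
    paste(signif(x$voxel_size, 4), collapse = " x ")
  ))
  invisible(x)
}

#' @export
dim.ms_volume <- function(x) dim(x$data)[1:3]

n_channels <- function(x) dim(x$data)[4]

#' Integer label map container
#'
#' A 3-D integer array of class codes (see [subseg_classes()]); 0 marks
#' background voxels outside the brain mask.
#'
#' @param labels 3-D integer array of class codes.
#' @param voxel_size Numeric length-3, mm.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, voxel_size) {
  stopifnot(length(dim(labels)) == 3L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (mm)", call. = FALSE)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), c(0L, subseg_classes()$code))
  if (length(bad))
    stop("unknown label codes: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(labels = labels, voxel_size = voxel_size), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  present <- sort(setdiff(unique(as.vector(x$labels)), 0L))
  cat(sprintf(
    "<label_map> %d x %d x %d voxels, voxel %s mm, classes: %s\n",
    d[1], d[2], d[3], paste(signif(x$voxel_size, 4), collapse = " x "),
    paste(class_name(present), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.label_map <- function(x) dim(x$labels)

#' Probability atlas set
#'
#' An ordered collection of per-class probability maps (values in \[0, 1\])
#' on one voxel grid. `layer_order` records the order in which the maps are
#' superimposed when conflicts between overlapping maps are resolved: base
#' tissue classes first, subcortical structures last, so that at a conflict
#' the later (subcortical) layer wins.
#'
#' @param maps Named list of 3-D numeric arrays, one per class; names must
#'   be class names from [subseg_classes()].
#' @param voxel_size Numeric length-3, mm.
#' @param layer_order Character vector giving the superimposition order;
#'   defaults to the names of `maps` in the order supplied.
#' @return An object of class `atlas_set`.
#' @export
atlas_set <- function(maps, voxel_size, layer_order = names(maps)) {
  stopifnot(is.list(maps), !is.null(names(maps)))
  if (anyDuplicated(layer_order) || !setequal(layer_order, names(maps)))
    stop("`layer_order` must list each atlas class exactly once", call. = FALSE)
  unknown <- setdiff(names(maps), .classes)
  if (length(unknown))
    stop("unknown atlas classes: ", paste(unknown, collapse = ", "), call. = FALSE)
  dims <- unique(lapply(maps, dim))
  if (length(dims) != 1L || length(dims[[1]]) != 3L)
    stop("all atlas maps must be 3-D arrays on one grid", call. = FALSE)
  for (cl in names(maps)) {
    rng <- range(maps[[cl]])
    if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
      stop("atlas map for class '", cl, "' has values outside [0, 1]; ",
           "apply rescale_unit() first", call. = FALSE)
  }
  structure(
    list(maps = maps[layer_order], voxel_size = as.numeric(voxel_size),
         layer_order = layer_order),
    class = "atlas_set"
  )
}

#' @export
print.atlas_set <- function(x, ...) {
  d <- dim(x$maps[[1]])
  cat(sprintf(
    "<atlas_set> %d class maps on %d x %d x %d grid, layer order: %s\n",
    length(x$maps), d[1], d[2], d[3], paste(x$layer_order, collapse = " < ")
  ))
  invisible(x)
}

#' @export
dim.atlas_set <- function(x) dim(x$maps[[1]])

# check that a set of spatial objects share grid dims and voxel sizes
check_same_grid <- function(..., what = "inputs") {
  objs <- list(...)
  dims <- lapply(objs, function(o) if (is.array(o)) dim(o)[1:3] else dim(o))
  vox <- lapply(objs, function(o) {
    if (is.array(o)) NULL
    else if (!is.null(o$voxel_size)) o$voxel_size
    else NULL
  })
  if (length(unique(dims)) != 1L)
    stop("grid mismatch across ", what, ": ",
         paste(vapply(dims, function(d) paste(d, collapse = "x"), ""),
               collapse = " vs "), call. = FALSE)
  vox <- vox[!vapply(vox, is.null, TRUE)]
  if (length(vox) > 1L &&
      any(vapply(vox[-1], function(v) any(abs(v - vox[[1]]) > 1e-6), TRUE)))
    stop("voxel size mismatch across ", what, call. = FALSE)
  invisible(TRUE)
}
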