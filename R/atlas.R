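#' Rescale a probability map to the unit interval
#'
#' Affine rescaling so the minimum maps to 0 and the maximum to 1. Applied
#' to every incoming atlas because maps from heterogeneous sources arrive on
#' arbitrary scales (0-255 byte maps, already-unit maps, ...).
#'
#' @param map Numeric array (or vector) with finite values, max > min.
#' @param class Optional class name used in error messages.
#' @return The rescaled map, same shape.
#' @export
#' @examples
#' rescale_unit(c(0, 127, 254))
rescale_unit <- function(map, class = NULL) {
  rng <- range(map)
  if (any(!is.finite(rng)))
    stop("atlas map", if (!is.null(class)) paste0(" for class '", class, "'"),
         " contains non-finite values", call. = FALSE)
  if (rng[2] <= rng[1])
    stop("atlas map", if (!is.null(class)) paste0(" for class '", class, "'"),
         " is constant; cannot rescale to [0, 1]", call. = FALSE)
  (map - rng[1]) / (rng[2] - rng[1])
}

#' Layer and threshold probability atlases into candidate-voxel masks
#'
#' The composite atlas is built in two stages that mirror how it is
#' assembled from heterogeneous sources. The base layer resolves the major
#' tissue maps (CSF, GM, WM), which approximate a partition of the brain:
#' each voxel goes to the major class with the highest probability there.
#' The subcortical maps are then superimposed in layer order; wherever one
#' has any support (`p > 0`) it overwrites the composite, so at overlaps
#' the voxel is assigned to the last superimposed layer. The composite is
#' thresholded at the end: a voxel becomes a training candidate for its
#' assigned class when that class's probability is at least `tau`
#' (inclusive) and the voxel lies inside the brain mask. Because each
#' voxel's assigned class does not depend on `tau`, raising the threshold
#' can only remove candidates, never add them.
#'
#' @param atlases An [atlas_set()].
#' @param tau Probability threshold in (0, 1]; default 0.8.
#' @param brain_mask Logical array on the atlas grid.
#' @return An object of class `candidate_mask`: named list of disjoint
#'   logical arrays (one per class, in layer order) with attributes
#'   `threshold` and `voxel_size`. Classes left without any candidate voxel
#'   trigger a warning naming them; the caller decides whether that is fatal.
#' @export
layer_and_threshold <- function(atlases, tau = 0.8, brain_mask) {
  stopifnot(inherits(atlases, "atlas_set"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1)
    stop("`tau` must be a single number in (0, 1]", call. = FALSE)
  check_same_grid(atlases, brain_mask, what = "atlases and brain mask")
  gs <- dim(atlases)
  majors <- intersect(atlases$layer_order, .major_classes)
  minors <- setdiff(atlases$layer_order, majors)
  assigned <- array(0L, gs)
  prob <- array(0, gs)  # probability of the assigned class at each voxel
  if (length(majors)) {
    stacked <- sapply(atlases$maps[majors], as.vector)
    best <- max.col(stacked, ties.method = "last")  # tie -> later layer
    bestp <- stacked[cbind(seq_len(nrow(stacked)), best)]
    covered <- bestp > 0
    assigned[covered] <- class_code(majors)[best[covered]]
    prob[covered] <- bestp[covered]
  }
  for (cl in minors) {
    covered <- atlases$maps[[cl]] > 0  # any support overwrites the base
    assigned[covered] <- class_code(cl)
    prob[covered] <- atlases$maps[[cl]][covered]
  }
  passes <- prob >= tau & brain_mask
  masks <- lapply(atlases$layer_order,
                  function(cl) passes & assigned == class_code(cl))
  names(masks) <- atlases$layer_order
  empty <- names(masks)[vapply(masks, function(m) !any(m), TRUE)]
  if (length(empty))
    warning("no candidate voxels at threshold ", tau, " for class(es): ",
            paste(empty, collapse = ", "), call. = FALSE)
  structure(masks, class = "candidate_mask", threshold = tau,
            voxel_size = atlases$voxel_size)
}

#' @export
print.candidate_mask <- function(x, ...) {
  counts <- vapply(x, sum, numeric(1))
  cat(sprintf("<candidate_mask> threshold %.2f\n", attr(x, "threshold")))
  print(tibble::tibble(class = names(x), candidates = as.integer(counts)), n = Inf)
  invisible(x)
}

#' Candidate counts as a tibble
#'
#' @param x A `candidate_mask`.
#' @param ... Unused.
#' @return Tibble with `class`, `code`, `candidates`.
#' @export
tidy.candidate_mask <- function(x, ...) {
  tibble::tibble(
    class = names(x),
    code = class_code(names(x)),
    candidates = vapply(x, function(m) as.integer(sum(m)), integer(1))
  )
}
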