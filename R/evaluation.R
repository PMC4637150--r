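#' Per-class voxel counts and volumes
#'
#' Volume is voxel count times voxel volume, reported in cubic centimetres
#' (cc): 50,000 voxels at 1 x 1 x 1 mm resolution correspond to 50 cc. All
#' seven classes are reported (absent classes with zero volume), so the
#' class volumes sum exactly to the labelled (brain-mask) volume.
#'
#' @param seg A segmentation result or [label_map()].
#' @return Tibble of class `volume_report` with `class`, `code`, `voxels`,
#'   `volume_cc`, and a `voxel_size` attribute.
#' @export
#' @examples
#' lm <- label_map(array(3L, c(10, 10, 10)), c(1, 1, 1))
#' compute_volumes(lm)
compute_volumes <- function(seg) {
  lm <- if (inherits(seg, "subseg_result")) seg$labels else seg
  stopifnot(inherits(lm, "label_map"))
  if (is.null(lm$voxel_size) || any(!is.finite(lm$voxel_size)))
    stop("label map has no voxel geometry", call. = FALSE)
  vox_cc <- prod(lm$voxel_size) / 1000  # mm^3 -> cc
  counts <- tabulate(lm$labels, nbins = 7L)
  out <- tibble::tibble(
    class = .classes,
    code = 1:7,
    voxels = as.integer(counts),
    volume_cc = counts * vox_cc
  )
  structure(out, class = c("volume_report", class(out)),
            voxel_size = lm$voxel_size)
}

#' Scan-rescan percent volume difference
#'
#' Symmetric percent difference between two volume estimates of the same
#' structure: \eqn{\Delta\% = |v_1 - v_2| / ((v_1 + v_2)/2) \times 100}.
#' The denominator is the mean of the two volumes, which makes the measure
#' symmetric in its arguments. Vectorized over pairs.
#'
#' @param v1,v2 Volumes (cc), elementwise pairs; each pair must have at
#'   least one positive member.
#' @return Percent differences (numeric), same length as the inputs.
#' @export
#' @examples
#' volume_diff_percent(2.42, 2.26)  # 6.8 to one decimal
volume_diff_percent <- function(v1, v2) {
  stopifnot(length(v1) == length(v2), all(v1 >= 0), all(v2 >= 0))
  if (any(v1 == 0 & v2 == 0))
    stop("percent difference undefined when both volumes are zero",
         call. = FALSE)
  abs(v1 - v2) / ((v1 + v2) / 2) * 100
}

#' Pairwise volume-overlap index between two segmentations
#'
#' Dice coefficient \eqn{2|A \cap B| / (|A| + |B|)} per class (default), or
#' Jaccard \eqn{|A \cap B| / |A \cup B|}. A class absent from both
#' segmentations has no defined overlap and is reported as `NA` rather
#' than 0.
#'
#' @param seg_a,seg_b Segmentation results or [label_map()]s on one grid.
#' @param classes Class names to evaluate; default the four subcortical
#'   structures plus any major tissue present in either map.
#' @param method `"dice"` (default) or `"jaccard"`.
#' @return Tibble with `class`, `code`, `size_a`, `size_b`, `intersection`
#'   and `overlap`.
#' @export
overlap_index <- function(seg_a, seg_b, classes = NULL,
                          method = c("dice", "jaccard")) {
  method <- match.arg(method)
  la <- if (inherits(seg_a, "subseg_result")) seg_a$labels else seg_a
  lb <- if (inherits(seg_b, "subseg_result")) seg_b$labels else seg_b
  stopifnot(inherits(la, "label_map"), inherits(lb, "label_map"))
  check_same_grid(la, lb, what = "segmentations")
  if (is.null(classes)) {
    present <- class_name(sort(intersect(
      union(unique(as.vector(la$labels)), unique(as.vector(lb$labels))),
      1:7
    )))
    classes <- union(intersect(.classes, present), .subcortical_classes)
    classes <- .classes[.classes %in% classes]
  }
  rows <- lapply(classes, function(cl) {
    code <- class_code(cl)
    a <- la$labels == code
    b <- lb$labels == code
    na <- sum(a); nb <- sum(b); ab <- sum(a & b)
    ov <- if (na + nb == 0) NA_real_
          else if (method == "dice") 2 * ab / (na + nb)
          else ab / (na + nb - ab)
    tibble::tibble(class = cl, code = code, size_a = as.integer(na),
                   size_b = as.integer(nb), intersection = as.integer(ab),
                   overlap = ov)
  })
  out <- dplyr::bind_rows(rows)
  if (any(is.na(out$overlap)))
    message("class(es) absent from both segmentations reported as missing: ",
            paste(out$class[is.na(out$overlap)], collapse = ", "))
  attr(out, "method") <- method
  out
}

#' Reference scan-rescan reproducibility table
#'
#' Bundled table of published scan/rescan subcortical volume estimates (cc)
#' for three subjects, for both classifiers and both channel combinations,
#' together with the percent volume differences as printed at one decimal.
#' Used in tests and documentation to exercise [volume_diff_percent()].
#'
#' @return Tibble with `method`, `channels`, `subject`, `structure`,
#'   `scan_cc`, `rescan_cc`, `delta_printed_pct`.
#' @export
reference_reproducibility <- function() {
  path <- system.file("extdata", "scan_rescan_volumes.csv", package = "subseg")
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(out)
}
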