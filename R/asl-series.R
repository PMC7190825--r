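#' Multi-TI ASL control/label image series
#'
#' Container for a single-slice multi-TI pulsed-ASL acquisition: control and
#' label image stacks indexed by inversion time and repetition, with the
#' echo time, voxel geometry and labelling-scheme metadata needed for
#' quantification.
#'
#' @param controls,labels Numeric 4D arrays `[x, y, n_ti, n_rep]` of control
#'   and label images; must be congruent in shape.
#' @param ti_list Inversion times in seconds, strictly increasing, one per
#'   third-dimension slab.
#' @param te Echo time, seconds, > 0.
#' @param voxel_dims Voxel dimensions in mm, length 3 (in-plane x, y and
#'   slice thickness).
#' @param scheme Labelling geometry metadata, a list; by default FAIR with a
#'   19.2 mm slice-selective inversion width.
#' @return An object of class `asl_series`.
#' @export
asl_series <- function(controls, labels, ti_list, te,
                       voxel_dims = c(0.625, 0.625, 2.4),
                       scheme = list(type = "FAIR", labelling_width_mm = 19.2)) {
  if (!is.array(controls) || length(dim(controls)) != 4L) {
    stop("controls must be a 4D array [x, y, n_ti, n_rep]", call. = FALSE)
  }
  if (!identical(dim(controls), dim(labels))) {
    stop("controls and labels must have identical dimensions", call. = FALSE)
  }
  if (dim(controls)[3] != length(ti_list)) {
    stop("third array dimension must match length(ti_list)", call. = FALSE)
  }
  if (length(ti_list) > 1 && any(diff(ti_list) <= 0)) {
    stop("ti_list must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(te) || te <= 0) stop("te must be > 0", call. = FALSE)
  stopifnot(length(voxel_dims) == 3, all(voxel_dims > 0))
  structure(
    list(controls = controls, labels = labels, ti_list = as.numeric(ti_list),
         te = te, repetitions = dim(controls)[4],
         voxel_dims = as.numeric(voxel_dims), scheme = scheme),
    class = "asl_series"
  )
}

#' @export
print.asl_series <- function(x, ...) {
  d <- dim(x$controls)
  cat(sprintf("<asl_series> %dx%d matrix, %d TIs (%s s), %d repetitions, TE %g ms\n",
              d[1], d[2], d[3], paste(x$ti_list, collapse = ", "),
              x$repetitions, x$te * 1000))
  invisible(x)
}

#' Region-of-interest specification
#'
#' A boolean voxel mask together with the voxel volume, the resulting ROI
#' volume, and (optionally) the true anatomical ventricle volume from
#' structural-image segmentation, needed for the partial-volume M0
#' correction.
#'
#' @param mask Logical (or 0/1) matrix marking ROI voxels.
#' @param voxel_dims Voxel dimensions, mm, length 3.
#' @param ventricle_volume Anatomical lateral-ventricle volume in mm^3
#'   (from manual segmentation of a structural scan); `NA` when not needed.
#' @return An object of class `roi_spec` with fields `mask`,
#'   `voxel_volume` (mm^3), `roi_volume` (mm^3) and `ventricle_volume`.
#' @examples
#' m <- matrix(FALSE, 32, 32); m[18:20, 12:13] <- TRUE; m[18:20, 19:20] <- TRUE
#' roi_spec(m) # 12 voxels -> 11.25 mm^3
#' @export
roi_spec <- function(mask, voxel_dims = c(0.625, 0.625, 2.4),
                     ventricle_volume = NA_real_) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  mask <- mask != 0
  if (sum(mask) == 0) stop("ROI mask is empty", call. = FALSE)
  vv <- prod(voxel_dims)
  structure(
    list(mask = mask, voxel_volume = vv, roi_volume = sum(mask) * vv,
         ventricle_volume = ventricle_volume),
    class = "roi_spec"
  )
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> %d voxels, %.4g mm^3 (voxel %.4g mm^3)",
              sum(x$mask), x$roi_volume, x$voxel_volume))
  if (is.finite(x$ventricle_volume)) {
    cat(sprintf(", ventricle %.4g mm^3", x$ventricle_volume))
  }
  cat("\n")
  invisible(x)
}
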