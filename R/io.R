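SIDECAR_VERSION <- "1.0"

#' Write an ASL series to NIfTI volumes with a JSON sidecar
#'
#' Writes the control and label stacks as two 4D NIfTI-1 files
#' (`<prefix>_control.nii`, `<prefix>_label.nii`, dimensions
#' `[x, y, n_ti, n_rep]` with TI varying along the third dimension) plus a
#' JSON sidecar `<prefix>.json` holding the acquisition metadata. Sidecar
#' field names mirror BIDS-ASL where an equivalent exists
#' (`InversionTimes`, `EchoTime`, `Repetitions`, `VoxelDims`,
#' `LabellingScheme`); voxel-index space only, no world-space geometry.
#'
#' @param series An [asl_series()].
#' @param prefix Output path prefix (directory must exist).
#' @return `prefix`, invisibly.
#' @export
write_asl_dataset <- function(series, prefix) {
  stopifnot(inherits(series, "asl_series"))
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir,
                             call. = FALSE)
  RNifti::writeNifti(RNifti::asNifti(series$controls,
                                     pixdim = c(series$voxel_dims, 1)),
                     paste0(prefix, "_control.nii"))
  RNifti::writeNifti(RNifti::asNifti(series$labels,
                                     pixdim = c(series$voxel_dims, 1)),
                     paste0(prefix, "_label.nii"))
  sidecar <- list(
    SidecarVersion = SIDECAR_VERSION,
    InversionTimes = series$ti_list,
    EchoTime = series$te,
    Repetitions = series$repetitions,
    VoxelDims = series$voxel_dims,
    LabellingScheme = series$scheme
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read an ASL series from NIfTI volumes and a JSON sidecar
#'
#' Counterpart of [write_asl_dataset()]. Validates the sidecar fields and
#' the congruence of the control and label stacks; inversion times are
#' re-ordered to be strictly increasing (re-ordering the image slabs
#' accordingly) so shuffled inputs are handled.
#'
#' @param prefix Path prefix used when writing.
#' @return An [asl_series()].
#' @export
read_asl_dataset <- function(prefix) {
  sidecar_path <- paste0(prefix, ".json")
  for (p in c(paste0(prefix, "_control.nii"), paste0(prefix, "_label.nii"),
              sidecar_path)) {
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
  }
  sc <- tryCatch(jsonlite::read_json(sidecar_path, simplifyVector = TRUE),
                 error = function(e) {
                   stop("sidecar is not valid JSON: ", sidecar_path,
                        call. = FALSE)
                 })
  req <- c("InversionTimes", "EchoTime", "Repetitions", "VoxelDims")
  for (fld in req) {
    if (is.null(sc[[fld]])) {
      stop(sprintf("sidecar %s: missing required field '%s'",
                   sidecar_path, fld), call. = FALSE)
    }
  }
  ti <- as.numeric(sc$InversionTimes)
  if (any(!is.finite(ti)) || length(ti) < 1) {
    stop(sprintf("sidecar %s: field 'InversionTimes' is not a numeric vector",
                 sidecar_path), call. = FALSE)
  }
  controls <- unclass(as.array(RNifti::readNifti(paste0(prefix, "_control.nii"))))
  labels <- unclass(as.array(RNifti::readNifti(paste0(prefix, "_label.nii"))))
  attributes(controls) <- list(dim = dim(controls))
  attributes(labels) <- list(dim = dim(labels))
  if (length(dim(controls)) == 3L) {
    # single repetition collapsed by the writer; restore the 4th axis
    dim(controls) <- c(dim(controls), 1L)
    dim(labels) <- c(dim(labels), 1L)
  }
  if (dim(controls)[3] != length(ti)) {
    stop(sprintf("sidecar %s: 'InversionTimes' length %d does not match %d image slabs",
                 sidecar_path, length(ti), dim(controls)[3]), call. = FALSE)
  }
  ord <- order(ti)
  scheme <- if (!is.null(sc$LabellingScheme)) as.list(sc$LabellingScheme) else
    list(type = "FAIR", labelling_width_mm = NA_real_)
  asl_series(controls[, , ord, , drop = FALSE], labels[, , ord, , drop = FALSE],
             ti_list = ti[ord], te = as.numeric(sc$EchoTime),
             voxel_dims = as.numeric(sc$VoxelDims), scheme = scheme)
}

#' Default run configuration
#'
#' All defaults equal the preclinical mouse protocol: six inversion times
#' from 200 to 6500 ms, TE 20/220 ms with 5/20 repetitions for the
#' standard and long-TE readouts, FAIR labelling with a 19.2 mm
#' slice-selective width, blood T1 2.4 s, and unit labelling efficiency.
#'
#' @return A nested list of protocol, relaxation and fitting settings.
#' @export
default_config <- function() {
  rel <- relaxation_set()
  list(
    protocol = list(
      ti_list = c(0.2, 0.75, 1.5, 2.75, 4.0, 6.5),
      te_bbb = 0.020, te_bcsfb = 0.220,
      repetitions_bbb = 5L, repetitions_bcsfb = 20L,
      alpha = 1.0, labelling_width_mm = 19.2, noise_sd = 0.2
    ),
    relaxation = unclass(rel),
    fitting = list(
      pin_tau = NULL, tau_tissue = 3.0, magnitude_ir = FALSE,
      subtraction_order = "control-label", f_max = 0.1,
      exclude_2sd = FALSE
    ),
    seed = 1L
  )
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' Unknown fields are rejected; missing fields fall back to
#' [default_config()] values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- default_config()
  merge_section <- function(base_sec, user_sec, name) {
    if (is.null(user_sec)) return(base_sec)
    unknown <- setdiff(names(user_sec), names(base_sec))
    if (length(unknown) > 0) {
      stop(sprintf("config section '%s': unknown field(s) %s", name,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(base_sec, user_sec)
  }
  top_unknown <- setdiff(names(raw), names(base))
  if (length(top_unknown) > 0) {
    stop("config: unknown top-level field(s) ",
         paste(top_unknown, collapse = ", "), call. = FALSE)
  }
  out <- base
  for (sec in c("protocol", "relaxation", "fitting")) {
    out[[sec]] <- merge_section(base[[sec]], raw[[sec]], sec)
  }
  if (!is.null(raw$seed)) out$seed <- as.integer(raw$seed)
  # re-validate relaxation through the constructor
  out$relaxation <- unclass(do.call(relaxation_set, out$relaxation))
  out
}

#' Serialise a fit result to JSON
#'
#' @param fit An `asl_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "asl_fit"))
  out <- list(
    model = fit$model,
    estimates = fit$estimates,
    stderr = as.list(fit$stderr),
    rss = fit$rss,
    converged = fit$converged,
    n_points = fit$n_points,
    reported = as.list(fit$reported)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
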