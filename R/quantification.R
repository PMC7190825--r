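#' Pairwise control-minus-label subtraction
#'
#' Averages, for each inversion time, the pairwise difference between the
#' control and label images across repetitions, producing one delta-M image
#' per TI. The default sign convention (control minus label) yields a
#' positive difference for delivered labelled water; `order = "label-control"`
#' flips it for datasets with the opposite convention.
#'
#' @param series An [asl_series()].
#' @param order Subtraction order.
#' @return A 3D array `[x, y, n_ti]` of delta-M images.
#' @export
pairwise_subtract <- function(series, order = c("control-label", "label-control")) {
  stopifnot(inherits(series, "asl_series"))
  order <- match.arg(order)
  diff4 <- series$controls - series$labels
  if (order == "label-control") diff4 <- -diff4
  apply(diff4, c(1, 2, 3), mean)
}

#' Sum of image signal within an ROI
#'
#' @param image Numeric matrix congruent with the ROI mask.
#' @param roi An [roi_spec()].
#' @return Scalar sum of voxel values under the mask.
#' @export
roi_sum <- function(image, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  if (!is.matrix(image) || !identical(dim(image), dim(roi$mask))) {
    stop("image and ROI mask dimensions differ", call. = FALSE)
  }
  sum(image[roi$mask])
}

#' Mean image signal within an ROI
#'
#' @inheritParams roi_sum
#' @return Scalar mean of voxel values under the mask.
#' @export
roi_mean <- function(image, roi) {
  roi_sum(image, roi) / sum(roi$mask)
}

#' Per-TI ROI series from a control/label acquisition
#'
#' Convenience extractor: repetition-averaged control signal and pairwise
#' difference signal aggregated within an ROI at every inversion time.
#'
#' @param series An [asl_series()].
#' @param roi An [roi_spec()].
#' @param aggregate `"sum"` (as used for the ventricle ROI) or `"mean"`.
#' @param order Subtraction order, see [pairwise_subtract()].
#' @return A tibble with columns `ti`, `control`, `dm`.
#' @export
roi_series <- function(series, roi, aggregate = c("sum", "mean"),
                       order = "control-label") {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "sum") roi_sum else roi_mean
  dm <- pairwise_subtract(series, order)
  ctrl <- apply(series$controls, c(1, 2, 3), mean)
  n_ti <- length(series$ti_list)
  tibble::tibble(
    ti = series$ti_list,
    control = vapply(seq_len(n_ti), function(i) agg(ctrl[, , i], roi), numeric(1)),
    dm = vapply(seq_len(n_ti), function(i) agg(dm[, , i], roi), numeric(1))
  )
}

#' Ventricle partial-volume correction of the fitted M0
#'
#' Rescales the CSF equilibrium magnetisation fitted from the functional
#' ROI by the ratio of the ROI volume to the anatomical ventricle volume.
#' Without this step the fitted M0 — the normalisation factor for flow
#' quantification — depends strongly on ventricle size through partial
#' volume effects in the low-resolution functional images.
#'
#' @param m0_fit Fitted M0 from the ROI-summed control signal.
#' @param roi An [roi_spec()] carrying a positive `ventricle_volume`.
#' @return Corrected M0: `m0_fit * roi_volume / ventricle_volume`.
#' @examples
#' r <- roi_spec(matrix(TRUE, 3, 4), ventricle_volume = 3.75)
#' m0_correction(100, r)
#' @export
m0_correction <- function(m0_fit, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  if (!is.finite(roi$ventricle_volume) || roi$ventricle_volume <= 0) {
    stop("m0_correction requires a positive ventricle_volume in the ROI spec",
         call. = FALSE)
  }
  m0_fit * roi$roi_volume / roi$ventricle_volume
}

#' Convert a fractional delivery rate to reporting units
#'
#' `f` in s^-1 (ml per ml per second) becomes ml/100 ml/min: `f * 6000`.
#' With a tissue density of 1 g/ml the same factor converts perfusion to
#' ml/100 g/min.
#'
#' @param f Fractional rate, s^-1, >= 0. Vectorised.
#' @return Rate in ml/100 ml/min.
#' @examples
#' flow_to_reporting_units(0.004) # 24
#' @export
flow_to_reporting_units <- function(f) {
  stopifnot(all(f >= 0))
  f * 6000
}

#' Total labelled-water delivery rate to the ventricles
#'
#' Converts the ROI-normalised delivery rate into an absolute volumetric
#' rate: `(f / 100) * roi_volume`, with mm^3 read as microlitres. At the
#' mean adult rate of 24 ml/100 ml/min over the 11.25 mm^3 functional ROI
#' this gives 2.7 ul/min.
#'
#' @param f Delivery rate, ml/100 ml/min.
#' @param roi_volume Functional ROI volume, mm^3.
#' @return Total delivery rate, ul/min.
#' @examples
#' total_delivery_rate(24, 11.25)
#' @export
total_delivery_rate <- function(f, roi_volume) {
  stopifnot(all(f >= 0), all(roi_volume >= 0))
  f / 100 * roi_volume
}

#' Choroid plexus blood flow from total delivery and CP mass
#'
#' Expresses the total labelled-water delivery rate per unit mass of
#' choroid plexus tissue, assuming a single-pass extraction fraction
#' (100% by default): `(total / extraction) / cp_mass * 100`, with
#' ul/(min mg) identical to ml/(min g).
#'
#' @param total Total delivery rate, ul/min.
#' @param cp_mass Choroid plexus mass within the lateral ventricles, mg.
#' @param extraction Extraction fraction in (0, 1].
#' @return CP blood flow, ml/100 g/min.
#' @examples
#' cp_blood_flow(2.7, 0.22) # ~1227
#' @export
cp_blood_flow <- function(total, cp_mass, extraction = 1.0) {
  stopifnot(all(total >= 0))
  if (any(!is.finite(cp_mass)) || any(cp_mass <= 0)) {
    stop("cp_mass must be > 0", call. = FALSE)
  }
  if (any(extraction <= 0) || any(extraction > 1)) {
    stop("extraction must lie in (0, 1]", call. = FALSE)
  }
  (total / extraction) / cp_mass * 100
}

#' Percent change from baseline
#'
#' @param baseline Baseline value(s), non-zero.
#' @param post Post-intervention value(s).
#' @return `100 * (post - baseline) / baseline`.
#' @examples
#' percent_change(251, 218) # -13.1 percent
#' @export
percent_change <- function(baseline, post) {
  if (any(baseline == 0)) stop("baseline must be non-zero", call. = FALSE)
  100 * (post - baseline) / baseline
}

#' Two-group comparison by t-test
#'
#' Compares a quantity between two groups with a two-sample t-test (pooled
#' variance by default, Welch optionally). The one-tailed default tests
#' whether the first group exceeds the second, matching the planned
#' directional comparisons of adult versus aged cohorts.
#'
#' @param data Data frame with a value column and a group column.
#' @param value,group Column names (strings).
#' @param tail `"one"` (first group greater) or `"two"`.
#' @param pooled Pooled-variance t-test (`TRUE`) or Welch (`FALSE`).
#' @return A one-row tibble: `mean_a`, `mean_b`, `diff`, `t`, `df`,
#'   `p_value`, `n_a`, `n_b`, `tail`.
#' @examples
#' d <- data.frame(value = c(20, 21, 19, 13, 14, 12),
#'                 group = rep(c("adult", "aged"), each = 3))
#' cohort_compare(d)
#' @export
cohort_compare <- function(data, value = "value", group = "group",
                           tail = c("one", "two"), pooled = TRUE) {
  tail <- match.arg(tail)
  stopifnot(is.data.frame(data), value %in% names(data), group %in% names(data))
  g <- data[[group]]
  levs <- if (is.factor(g)) levels(g) else unique(g)
  if (length(levs) != 2) stop("exactly two groups required", call. = FALSE)
  a <- data[[value]][g == levs[1]]
  b <- data[[value]][g == levs[2]]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  alt <- if (tail == "one") "greater" else "two.sided"
  tt <- stats::t.test(a, b, alternative = alt, var.equal = pooled)
  tibble::tibble(
    group_a = as.character(levs[1]), group_b = as.character(levs[2]),
    mean_a = mean(a), mean_b = mean(b), diff = mean(a) - mean(b),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, n_a = length(a), n_b = length(b), tail = tail
  )
}

#' Pearson correlation between two quantities
#'
#' @param data Data frame holding both columns.
#' @param x,y Column names (strings).
#' @return A one-row tibble: `r`, `t`, `df`, `p_value` (two-sided), `n`.
#' @examples
#' d <- data.frame(f = c(18, 21, 24, 26), vol = c(3.0, 3.4, 3.9, 4.4))
#' correlate(d, "f", "vol")
#' @export
correlate <- function(data, x = "x", y = "y") {
  stopifnot(is.data.frame(data), x %in% names(data), y %in% names(data))
  xv <- data[[x]]
  yv <- data[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 3) stop("correlate needs n >= 3", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    r = unname(ct$estimate), t = unname(ct$statistic),
    df = unname(ct$parameter), p_value = ct$p.value, n = length(xv)
  )
}

#' Scan-rescan reproducibility error
#'
#' Mean absolute difference between baseline and repeat measurements across
#' subjects.
#'
#' @param data Data frame with columns `baseline` and `rescan`.
#' @return A one-row tibble: `mean_abs_diff`, `n`.
#' @examples
#' scan_rescan_error(data.frame(baseline = c(20, 10), rescan = c(21, 9)))
#' @export
scan_rescan_error <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("baseline", "rescan") %in% names(data)))
  if (nrow(data) < 1) stop("at least one pair required", call. = FALSE)
  tibble::tibble(
    mean_abs_diff = mean(abs(data$rescan - data$baseline)),
    n = nrow(data)
  )
}

#' Quantify one subject from paired standard and long-TE acquisitions
#'
#' Runs the full ROI-level pipeline: pairwise subtraction of both series;
#' inversion-recovery fits of the repetition-averaged control signal to
#' obtain M0 and T1 for the cortical tissue (standard TE series, ROI mean)
#' and for ventricular CSF (long-TE series, ROI sum); ventricle
#' partial-volume correction of the CSF M0; a Buxton general-kinetic-model
#' fit of the cortical delta-M/M0 series for CBF; a BCSFB delivery-model
#' fit of the ventricular delta-M/M0corr series, with the CSF apparent
#' relaxation rate taken from the long-TE inversion-recovery fit; and unit
#' conversions to reporting units, including the total delivery rate and —
#' when a choroid plexus mass is supplied — CP blood flow.
#'
#' @param bbb_series Standard ASL [asl_series()] (short TE, e.g. 20 ms).
#' @param bcsfb_series Long-TE [asl_series()] (e.g. 220 ms) isolating CSF.
#' @param cortex_roi [roi_spec()] for the cortical ROI.
#' @param ventricle_roi [roi_spec()] for the functional ventricle ROI; must
#'   carry the anatomical `ventricle_volume`.
#' @param rel A [relaxation_set()] of fixed constants (blood T1, partition
#'   coefficients).
#' @param alpha Labelling efficiency assumed in quantification.
#' @param cp_mass Choroid plexus mass, mg, or `NA` to skip CP blood flow.
#' @param pin_tau Fix the BCSFB bolus duration (seconds); `NULL` fits it.
#' @param tau_tissue Bolus duration fixed in the cortical Buxton fit, s.
#' @param order Subtraction order, see [pairwise_subtract()].
#' @return A one-row tibble (the subject quantification record):
#'   `f_bcsfb` (ml/100 ml/min), `cbf_cortex` (ml/100 g/min), `t1_csf`,
#'   `t1_tissue` (s), `m0_csf`, `m0_corr`, `delta_csf`, `tau_csf`,
#'   `delta_tissue` (s), `ventricle_volume` (mm^3), `total_delivery`
#'   (ul/min), `cp_blood_flow` (ml/100 g/min or `NA`), and convergence
#'   flags `ok_ir_tissue`, `ok_ir_csf`, `ok_buxton`, `ok_bcsfb`.
#' @export
quantify_subject <- function(bbb_series, bcsfb_series, cortex_roi,
                             ventricle_roi, rel = relaxation_set(),
                             alpha = 1.0, cp_mass = NA_real_,
                             pin_tau = NULL, tau_tissue = 3.0,
                             order = "control-label") {
  stopifnot(inherits(bbb_series, "asl_series"),
            inherits(bcsfb_series, "asl_series"),
            inherits(cortex_roi, "roi_spec"),
            inherits(ventricle_roi, "roi_spec"),
            inherits(rel, "relaxation_set"))
  if (!is.finite(ventricle_roi$ventricle_volume) ||
      ventricle_roi$ventricle_volume <= 0) {
    stop("quantify_subject [m0 correction]: ventricle_roi must carry a ",
         "positive ventricle_volume", call. = FALSE)
  }
  r1a <- 1 / rel$t1_blood

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("quantify_subject [%s]: %s", what, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- cortical (standard TE) branch -----------------------------------
  ctx <- stage("cortex ROI extraction",
               roi_series(bbb_series, cortex_roi, aggregate = "mean",
                          order = order))
  ir_ctx <- stage("cortical inversion-recovery fit",
                  fit_inversion_recovery(
                    data.frame(ti = ctx$ti, signal = ctx$control)))
  m0_ctx <- ir_ctx$estimates$m0
  t1_ctx <- ir_ctx$estimates$t1
  bux <- stage("Buxton fit", fit_buxton(
    data.frame(ti = ctx$ti, dm = ctx$dm / m0_ctx),
    fixed = list(alpha = alpha, lambda_tissue = rel$lambda_tissue,
                 t1_tissue = t1_ctx, r1a = r1a, tau = tau_tissue)))

  # --- ventricular (long TE) branch ------------------------------------
  ven <- stage("ventricle ROI extraction",
               roi_series(bcsfb_series, ventricle_roi, aggregate = "sum",
                          order = order))
  ir_csf <- stage("CSF inversion-recovery fit",
                  fit_inversion_recovery(
                    data.frame(ti = ven$ti, signal = ven$control)))
  m0_csf <- ir_csf$estimates$m0
  t1_csf <- ir_csf$estimates$t1
  m0_corr <- m0_correction(m0_csf, ventricle_roi)
  bcs <- stage("BCSFB fit", fit_bcsfb(
    data.frame(ti = ven$ti, dm = ven$dm / m0_corr),
    fixed = list(alpha = alpha, phi = rel$phi_csf, r1a = r1a,
                 r1app = 1 / t1_csf),
    pin_tau = pin_tau))

  f_rep <- flow_to_reporting_units(bcs$estimates$f)
  total <- total_delivery_rate(f_rep, ventricle_roi$roi_volume)
  cpf <- if (is.finite(cp_mass)) cp_blood_flow(total, cp_mass) else NA_real_

  tibble::tibble(
    f_bcsfb = f_rep,
    cbf_cortex = flow_to_reporting_units(bux$estimates$f),
    t1_csf = t1_csf,
    t1_tissue = t1_ctx,
    m0_csf = m0_csf,
    m0_corr = m0_corr,
    delta_csf = bcs$estimates$delta,
    tau_csf = if (!is.null(bcs$estimates$tau)) bcs$estimates$tau else pin_tau,
    delta_tissue = bux$estimates$delta,
    ventricle_volume = ventricle_roi$ventricle_volume,
    total_delivery = total,
    cp_blood_flow = cpf,
    ok_ir_tissue = ir_ctx$converged,
    ok_ir_csf = ir_csf$converged,
    ok_buxton = bux$converged,
    ok_bcsfb = bcs$converged
  )
}
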