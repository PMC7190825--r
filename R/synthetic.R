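#' Specification of a digital single-slice mouse-brain phantom
#'
#' Describes a 32 x 32 single-slice phantom emulating the preclinical
#' acquisition geometry (20 x 20 mm field of view, 2.4 mm slice): a dorsal
#' cortical band of pure tissue and two caudal ventricle blobs of 3 x 2
#' voxels (the 12-voxel functional ROI) whose CSF partial-volume fractions
#' integrate to the requested anatomical ventricle volume. The delivery
#' rate `f_bcsfb_true` follows the reporting convention of the ROI-volume
#' normalised quantification (ml/100 ml/min over the functional ROI), so
#' the total delivery to the ventricles is `f_bcsfb_true / 100 *
#' roi_volume` ul/min regardless of ventricle size.
#'
#' @param grid Matrix size (square), default 32.
#' @param voxel_dims Voxel dimensions in mm, default `c(0.625, 0.625, 2.4)`.
#' @param f_bcsfb_true True BCSFB-mediated labelled-water delivery rate,
#'   ml/100 ml/min (ROI-volume convention).
#' @param cbf_true True cortical blood flow, ml/100 g/min.
#' @param ventricle_volume Anatomical lateral-ventricle volume, mm^3.
#' @param relaxation A [relaxation_set()].
#' @param delta_csf,tau_csf CSF transit time and bolus duration, seconds.
#' @param delta_tissue,tau_tissue Cortical transit time and bolus duration,
#'   seconds.
#' @param m0 Equilibrium magnetisation per unit compartment fraction,
#'   arbitrary units.
#' @param beta Inversion efficiency of the recovery curves.
#' @param d_csf,d_tissue Apparent diffusion coefficients of CSF and tissue,
#'   mm^2/s, used when the protocol applies diffusion weighting.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = 32L,
                         voxel_dims = c(0.625, 0.625, 2.4),
                         f_bcsfb_true = 24,
                         cbf_true = 283,
                         ventricle_volume = 3.75,
                         relaxation = relaxation_set(),
                         delta_csf = 1.0, tau_csf = 3.0,
                         delta_tissue = 0.3, tau_tissue = 3.0,
                         m0 = 100, beta = 1.0,
                         d_csf = 0.003, d_tissue = 0.0008) {
  stopifnot(grid >= 8, length(voxel_dims) == 3, all(voxel_dims > 0),
            f_bcsfb_true >= 0, cbf_true >= 0, ventricle_volume >= 0,
            inherits(relaxation, "relaxation_set"),
            delta_csf >= 0, tau_csf > 0, delta_tissue >= 0, tau_tissue > 0,
            m0 > 0, beta > 0, beta <= 1, d_csf >= 0, d_tissue >= 0)
  structure(
    list(grid = as.integer(grid), voxel_dims = as.numeric(voxel_dims),
         f_bcsfb_true = f_bcsfb_true, cbf_true = cbf_true,
         ventricle_volume = ventricle_volume, relaxation = relaxation,
         delta_csf = delta_csf, tau_csf = tau_csf,
         delta_tissue = delta_tissue, tau_tissue = tau_tissue,
         m0 = m0, beta = beta, d_csf = d_csf, d_tissue = d_tissue),
    class = "phantom_spec"
  )
}

#' Build a digital phantom from its specification
#'
#' Lays out the compartment partial-volume fraction maps: a dorsal cortical
#' band (tissue fraction 1) and two caudal 3 x 2 ventricle blobs whose CSF
#' fractions are uniform across the 12 functional-ROI voxels and sum to
#' `ventricle_volume / voxel_volume` voxels' worth. The remainder of each
#' ROI voxel is signal-free background, so the long-TE control signal over
#' the ROI is a pure CSF signal. Deterministic for a given spec and seed.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed (kept for interface symmetry with the other
#'   generators; the layout is deterministic).
#' @return An object of class `asl_phantom`: the spec plus fraction maps
#'   (`frac_csf`, `frac_tissue`), the ROI masks (`cortex_roi`,
#'   `ventricle_roi`), and the per-voxel-volume in mm^3.
#' @export
make_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  voxel_volume <- prod(spec$voxel_dims)

  frac_csf <- matrix(0, g, g)
  frac_tissue <- matrix(0, g, g)

  # dorsal cortical band, pure tissue
  ctx_rows <- seq.int(max(3L, round(g * 0.12)), max(6L, round(g * 0.28)))
  ctx_cols <- seq.int(round(g * 0.25), round(g * 0.75))
  frac_tissue[ctx_rows, ctx_cols] <- 1

  # two caudal 3x2 ventricle blobs: the 12-voxel functional ROI
  v_rows <- seq.int(round(g * 0.56), round(g * 0.56) + 2L)
  v_cols_l <- seq.int(round(g * 0.38), round(g * 0.38) + 1L)
  v_cols_r <- seq.int(round(g * 0.59), round(g * 0.59) + 1L)
  ventricle_mask <- matrix(FALSE, g, g)
  ventricle_mask[v_rows, v_cols_l] <- TRUE
  ventricle_mask[v_rows, v_cols_r] <- TRUE
  n_roi <- sum(ventricle_mask)

  csf_voxels_worth <- spec$ventricle_volume / voxel_volume
  if (csf_voxels_worth > n_roi) {
    stop(sprintf("ventricle_volume (%.3g mm^3) exceeds the %d-voxel ROI capacity (%.3g mm^3)",
                 spec$ventricle_volume, n_roi, n_roi * voxel_volume),
         call. = FALSE)
  }
  if (csf_voxels_worth > 0) {
    frac_csf[ventricle_mask] <- csf_voxels_worth / n_roi
  }

  cortex_mask <- matrix(FALSE, g, g)
  cortex_mask[ctx_rows, ctx_cols] <- TRUE

  structure(
    list(spec = spec, frac_csf = frac_csf, frac_tissue = frac_tissue,
         cortex_mask = cortex_mask, ventricle_mask = ventricle_mask,
         voxel_volume = voxel_volume, seed = as.integer(seed)),
    class = "asl_phantom"
  )
}

#' @export
print.asl_phantom <- function(x, ...) {
  cat(sprintf("<asl_phantom> %dx%d, ventricle %.3g mm^3 in %d ROI voxels, f %.3g ml/100ml/min, CBF %.3g ml/100g/min\n",
              x$spec$grid, x$spec$grid, x$spec$ventricle_volume,
              sum(x$ventricle_mask), x$spec$f_bcsfb_true, x$spec$cbf_true))
  invisible(x)
}

#' Scale phantom flows to model an intervention
#'
#' Multiplies the true choroid-plexus delivery rate and the true cortical
#' perfusion by independent factors, modelling interventions that modulate
#' CP blood flow selectively (e.g. vasopressin, which strongly reduces CP
#' flow with little parenchymal change).
#'
#' @param phantom An `asl_phantom` from [make_phantom()].
#' @param cp_factor Multiplier for the BCSFB delivery rate, >= 0.
#' @param cortex_factor Multiplier for cortical perfusion, >= 0.
#' @return The modified phantom.
#' @export
apply_intervention <- function(phantom, cp_factor, cortex_factor = 1.0) {
  stopifnot(inherits(phantom, "asl_phantom"),
            cp_factor >= 0, cortex_factor >= 0)
  phantom$spec$f_bcsfb_true <- phantom$spec$f_bcsfb_true * cp_factor
  phantom$spec$cbf_true <- phantom$spec$cbf_true * cortex_factor
  phantom
}

#' ROI specifications of a phantom
#'
#' @param phantom An `asl_phantom`.
#' @return A list with `cortex` and `ventricle` [roi_spec()]s; the
#'   ventricle spec carries the phantom's anatomical ventricle volume.
#' @export
phantom_rois <- function(phantom) {
  stopifnot(inherits(phantom, "asl_phantom"))
  list(
    cortex = roi_spec(phantom$cortex_mask, phantom$spec$voxel_dims),
    ventricle = roi_spec(phantom$ventricle_mask, phantom$spec$voxel_dims,
                         ventricle_volume = phantom$spec$ventricle_volume)
  )
}

#' Simulate a control/label acquisition of a phantom
#'
#' Forward-simulates a multi-TI FAIR acquisition voxel by voxel: the
#' control image is the sum over compartments of partial-volume fraction
#' times the inversion-recovery signal, attenuated by [t2_attenuation()] at
#' the protocol echo time and by [diffusion_attenuation()] when the
#' protocol applies diffusion weighting; the label image subtracts the
#' compartment difference signals — [buxton_delta_m()] for tissue,
#' [bcsfb_delta_m()] for CSF — under the same attenuations. Independent
#' Gaussian noise of standard deviation `protocol$noise_sd` is added to
#' every voxel of every repetition of both image types.
#'
#' The per-CSF-millilitre exchange rate driving the CSF model is
#' `f_bcsfb_true * roi_volume / ventricle_volume`, i.e. the phantom's
#' ROI-convention rate re-expressed per unit CSF volume, which keeps the
#' total delivery to the ventricles independent of ventricle size.
#'
#' @param phantom An `asl_phantom`.
#' @param protocol An [asl_protocol()] / [bcsfb_protocol()] list.
#' @param seed Integer seed for the noise stream.
#' @return An [asl_series()].
#' @export
simulate_acquisition <- function(phantom, protocol, seed = 1L) {
  stopifnot(inherits(phantom, "asl_phantom"), is.list(protocol))
  sp <- phantom$spec
  rel <- sp$relaxation
  g <- sp$grid
  ti <- protocol$ti_list
  n_ti <- length(ti)
  n_rep <- protocol$repetitions
  r1a <- 1 / rel$t1_blood

  att_tissue <- t2_attenuation(protocol$te, rel$t2_tissue) *
    diffusion_attenuation(protocol$b_value, sp$d_tissue)
  att_csf <- t2_attenuation(protocol$te, rel$t2_csf) *
    diffusion_attenuation(protocol$b_value, sp$d_csf)

  # per-unit-fraction control recovery and difference signals at each TI
  ir_tissue <- ir_signal(ti, m0 = sp$m0, t1 = rel$t1_tissue, beta = sp$beta)
  ir_csf <- ir_signal(ti, m0 = sp$m0, t1 = rel$t1_csf, beta = sp$beta)

  kp_tissue <- kinetic_params(
    f = sp$cbf_true / 6000, delta = sp$delta_tissue, tau = sp$tau_tissue,
    alpha = protocol$alpha, phi = 1, r1app = 1 / rel$t1_csf, r1a = r1a,
    m0 = sp$m0)
  dm_tissue <- if (sp$cbf_true > 0 && protocol$alpha > 0) {
    buxton_delta_m(ti, kp_tissue, rel)
  } else rep(0, n_ti)

  roi_volume <- sum(phantom$ventricle_mask) * phantom$voxel_volume
  f_csf_native <- if (sp$ventricle_volume > 0) {
    (sp$f_bcsfb_true / 6000) * roi_volume / sp$ventricle_volume
  } else 0
  dm_csf <- if (f_csf_native > 0 && protocol$alpha > 0) {
    kp_csf <- kinetic_params(
      f = f_csf_native, delta = sp$delta_csf, tau = sp$tau_csf,
      alpha = protocol$alpha, phi = rel$phi_csf, r1app = 1 / rel$t1_csf,
      r1a = r1a, m0 = sp$m0)
    bcsfb_delta_m(ti, kp_csf)
  } else rep(0, n_ti)

  controls <- array(0, c(g, g, n_ti, n_rep))
  labels <- array(0, c(g, g, n_ti, n_rep))
  for (i in seq_len(n_ti)) {
    ctrl_img <- phantom$frac_tissue * ir_tissue[i] * att_tissue +
      phantom$frac_csf * ir_csf[i] * att_csf
    dm_img <- phantom$frac_tissue * dm_tissue[i] * att_tissue +
      phantom$frac_csf * dm_csf[i] * att_csf
    for (r in seq_len(n_rep)) {
      controls[, , i, r] <- ctrl_img
      labels[, , i, r] <- ctrl_img - dm_img
    }
  }
  if (protocol$noise_sd > 0) {
    set.seed(seed)
    controls <- controls + stats::rnorm(length(controls), 0, protocol$noise_sd)
    labels <- labels + stats::rnorm(length(labels), 0, protocol$noise_sd)
  }

  asl_series(controls, labels, ti_list = ti, te = protocol$te,
             voxel_dims = sp$voxel_dims,
             scheme = list(type = "FAIR",
                           labelling_width_mm = protocol$labelling_width_mm,
                           b_value = protocol$b_value))
}

#' Specification of a simulated cohort
#'
#' Generative description of a group of subjects: sample size, group mean
#' and between-subject standard deviation of the BCSFB delivery rate and
#' of cortical CBF, the ventricle-volume distribution, an optional
#' flow-volume association, and the acquisition noise level. Defaults
#' describe an adult mouse group (f 20 ml/100 ml/min, CBF 251 ml/100
#' g/min, n = 12) with between-subject SDs inferred from group standard
#' errors at n = 12 (SEM 1 -> SD ~3.5 for f, SEM 7 -> SD ~24 for CBF).
#'
#' @param n Number of subjects, >= 2.
#' @param f_mean,f_sd BCSFB delivery rate mean and between-subject SD,
#'   ml/100 ml/min.
#' @param cbf_mean,cbf_sd Cortical CBF mean and SD, ml/100 g/min.
#' @param vol_mean,vol_sd Ventricle-volume distribution, mm^3.
#' @param flow_volume_slope Linear dependence of f on ventricle volume,
#'   (ml/100 ml/min) per mm^3; 0 for no association. The residual SD is
#'   reduced so the marginal SD of f stays `f_sd`.
#' @param rescan_sd Within-subject (scan-rescan) SD of f, ml/100 ml/min.
#' @param noise_sd Per-repetition image noise SD in signal units; the
#'   default puts the ROI-summed peak difference signal at roughly ten
#'   times the averaged noise for the 20-repetition long-TE protocol.
#' @param label Group label carried into the truth table.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 12L, f_mean = 20, f_sd = 3.5,
                        cbf_mean = 251, cbf_sd = 24,
                        vol_mean = 3.75, vol_sd = 0.5,
                        flow_volume_slope = 0, rescan_sd = 0,
                        noise_sd = 0.2, label = "group") {
  stopifnot(n >= 2, f_sd >= 0, cbf_sd >= 0, vol_sd >= 0, rescan_sd >= 0,
            noise_sd >= 0, f_mean >= 0, cbf_mean >= 0, vol_mean > 0)
  structure(
    list(n = as.integer(n), f_mean = f_mean, f_sd = f_sd,
         cbf_mean = cbf_mean, cbf_sd = cbf_sd,
         vol_mean = vol_mean, vol_sd = vol_sd,
         flow_volume_slope = flow_volume_slope, rescan_sd = rescan_sd,
         noise_sd = noise_sd, label = label),
    class = "cohort_spec"
  )
}

#' Simulate a cohort of subjects with known ground truth
#'
#' Draws per-subject true parameters from the cohort distribution
#' (truncated below at physiological floors), builds a phantom per subject,
#' and simulates the paired standard-TE (5 repetitions) and long-TE (20
#' repetitions) acquisitions. Deterministic for a given spec and seed.
#'
#' @param cohort A [cohort_spec()].
#' @param seed Integer seed.
#' @param phantom_base A [phantom_spec()] providing geometry, relaxation
#'   and kinetics shared by all subjects.
#' @param protocol_bbb,protocol_bcsfb Acquisition protocols; the cohort's
#'   `noise_sd` overrides the protocol noise.
#' @return A list with `subjects` (each a list `bbb`, `bcsfb`, `phantom`,
#'   `rois`) and `truth`, a tibble of the generating parameters per
#'   subject (`subject`, `group`, `f_true`, `cbf_true`, `ventricle_volume`).
#' @export
simulate_cohort <- function(cohort, seed = 1L,
                            phantom_base = phantom_spec(),
                            protocol_bbb = asl_protocol(),
                            protocol_bcsfb = bcsfb_protocol()) {
  stopifnot(inherits(cohort, "cohort_spec"))
  set.seed(seed)
  n <- cohort$n

  vol <- pmax(0.5, stats::rnorm(n, cohort$vol_mean, cohort$vol_sd))
  slope <- cohort$flow_volume_slope
  resid_var <- max(0, cohort$f_sd^2 - slope^2 * cohort$vol_sd^2)
  f_true <- pmax(0.5, cohort$f_mean + slope * (vol - cohort$vol_mean) +
                   stats::rnorm(n, 0, sqrt(resid_var)))
  cbf_true <- pmax(10, stats::rnorm(n, cohort$cbf_mean, cohort$cbf_sd))
  sub_seeds <- sample.int(2^30, 2 * n)

  protocol_bbb$noise_sd <- cohort$noise_sd
  protocol_bcsfb$noise_sd <- cohort$noise_sd

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- phantom_base
    sp$f_bcsfb_true <- f_true[i]
    sp$cbf_true <- cbf_true[i]
    sp$ventricle_volume <- vol[i]
    ph <- make_phantom(sp, seed = sub_seeds[2 * i - 1])
    subjects[[i]] <- list(
      bbb = simulate_acquisition(ph, protocol_bbb, seed = sub_seeds[2 * i - 1]),
      bcsfb = simulate_acquisition(ph, protocol_bcsfb, seed = sub_seeds[2 * i]),
      phantom = ph,
      rois = phantom_rois(ph)
    )
  }
  truth <- tibble::tibble(
    subject = seq_len(n), group = cohort$label,
    f_true = f_true, cbf_true = cbf_true, ventricle_volume = vol
  )
  list(subjects = subjects, truth = truth)
}

#' Quantify every subject of a simulated cohort
#'
#' Maps [quantify_subject()] over the output of [simulate_cohort()] and
#' joins the ground-truth table.
#'
#' @param sim Output of [simulate_cohort()].
#' @param ... Passed to [quantify_subject()].
#' @return A tibble: one row per subject, truth columns plus the
#'   quantification record.
#' @export
quantify_cohort <- function(sim, ...) {
  est <- purrr::map_dfr(sim$subjects, function(s) {
    quantify_subject(s$bbb, s$bcsfb, s$rois$cortex, s$rois$ventricle, ...)
  })
  # the quantification echoes the ventricle volume it was given; keep the
  # truth-table column as the single copy
  est$ventricle_volume <- NULL
  dplyr::bind_cols(sim$truth, est)
}
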