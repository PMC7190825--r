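#' Relaxation constants for blood, tissue and CSF
#'
#' Bundles the longitudinal (T1) and transverse (T2) relaxation times and the
#' water partition coefficients used throughout quantification. Defaults are
#' mouse values at 9.4 T: T2 of 38, 30 and 200 ms for parenchyma, blood and
#' ventricular CSF, blood T1 of 2.4 s, and a blood-CSF partition coefficient
#' of 1.
#'
#' @param t1_blood Blood T1 in seconds.
#' @param t1_tissue Cortical tissue T1 in seconds.
#' @param t1_csf Ventricular CSF T1 in seconds.
#' @param t2_tissue,t2_blood,t2_csf Transverse relaxation times in seconds.
#' @param phi_csf Blood-CSF water partition coefficient (dimensionless).
#' @param lambda_tissue Blood-tissue water partition coefficient
#'   (ml blood water per ml tissue water, dimensionless).
#' @return An object of class `relaxation_set` (a validated named list).
#' @examples
#' rel <- relaxation_set()
#' 1 / rel$t1_blood # arterial blood R1a, s^-1
#' @export
relaxation_set <- function(t1_blood = 2.4,
                           t1_tissue = 1.9,
                           t1_csf = 4.0,
                           t2_tissue = 0.038,
                           t2_blood = 0.030,
                           t2_csf = 0.200,
                           phi_csf = 1.0,
                           lambda_tissue = 0.9) {
  x <- list(
    t1_blood = t1_blood, t1_tissue = t1_tissue, t1_csf = t1_csf,
    t2_tissue = t2_tissue, t2_blood = t2_blood, t2_csf = t2_csf,
    phi_csf = phi_csf, lambda_tissue = lambda_tissue
  )
  times <- unlist(x[c("t1_blood", "t1_tissue", "t1_csf",
                      "t2_tissue", "t2_blood", "t2_csf")])
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all relaxation times must be finite and > 0", call. = FALSE)
  }
  for (p in c("phi_csf", "lambda_tissue")) {
    if (!is.finite(x[[p]]) || x[[p]] <= 0 || x[[p]] > 1.2) {
      stop(sprintf("%s must lie in (0, 1.2]", p), call. = FALSE)
    }
  }
  structure(x, class = "relaxation_set")
}

#' Kinetic parameters of the single-compartment delivery models
#'
#' The full parameter set of the labelled-water delivery models: delivery
#' rate `f`, transit time `delta`, bolus duration `tau`, labelling
#' efficiency `alpha`, partition coefficient `phi`, apparent longitudinal
#' relaxation rate of the destination compartment `r1app`, arterial blood
#' relaxation rate `r1a`, and equilibrium magnetisation `m0`. All times are
#' seconds and all rates s^-1; `f` is a fractional rate in s^-1 (multiply by
#' 6000 for ml/100 ml/min).
#'
#' @param f Delivery rate of labelled blood water, s^-1. Must be >= 0.
#' @param delta Transit (arrival) time, seconds, >= 0.
#' @param tau Temporal width of the labelled bolus, seconds, > 0.
#' @param alpha Labelling (inversion) efficiency in \[0, 1\].
#' @param phi Blood-destination water partition coefficient.
#' @param r1app Apparent longitudinal relaxation rate of the destination
#'   compartment, s^-1.
#' @param r1a Longitudinal relaxation rate of arterial blood, s^-1
#'   (1/2.4 s by default).
#' @param m0 Equilibrium magnetisation, arbitrary signal units, > 0.
#' @return An object of class `kinetic_params`.
#' @examples
#' kp <- kinetic_params(f = 24 / 6000, delta = 1, tau = 3, r1app = 1 / 4.0)
#' bcsfb_delta_m(4, kp)
#' @export
kinetic_params <- function(f = 0.004, delta = 1.0, tau = 3.0,
                           alpha = 1.0, phi = 1.0,
                           r1app = 1 / 4.0, r1a = 1 / 2.4, m0 = 1.0) {
  x <- list(f = f, delta = delta, tau = tau, alpha = alpha, phi = phi,
            r1app = r1app, r1a = r1a, m0 = m0)
  if (any(!vapply(x, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1)))) {
    stop("all kinetic parameters must be finite scalars", call. = FALSE)
  }
  if (f < 0) stop("f must be >= 0", call. = FALSE)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (phi <= 0) stop("phi must be > 0", call. = FALSE)
  if (r1app <= 0 || r1a <= 0) stop("r1app and r1a must be > 0", call. = FALSE)
  if (m0 <= 0) stop("m0 must be > 0", call. = FALSE)
  structure(x, class = "kinetic_params")
}

#' @export
print.relaxation_set <- function(x, ...) {
  cat("<relaxation_set>\n")
  cat(sprintf("  T1 (s): blood %.3g, tissue %.3g, CSF %.3g\n",
              x$t1_blood, x$t1_tissue, x$t1_csf))
  cat(sprintf("  T2 (s): blood %.3g, tissue %.3g, CSF %.3g\n",
              x$t2_blood, x$t2_tissue, x$t2_csf))
  cat(sprintf("  partition: phi_csf %.3g, lambda_tissue %.3g\n",
              x$phi_csf, x$lambda_tissue))
  invisible(x)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  f %.4g s^-1 (%.3g ml/100ml/min), delta %.3g s, tau %.3g s\n",
              x$f, x$f * 6000, x$delta, x$tau))
  cat(sprintf("  alpha %.3g, phi %.3g, r1app %.4g, r1a %.4g, m0 %.4g\n",
              x$alpha, x$phi, x$r1app, x$r1a, x$m0))
  invisible(x)
}

#' Default mouse acquisition protocol
#'
#' The single-slice FAIR protocol used for multi-TI acquisitions: six
#' inversion times (200, 750, 1500, 2750, 4000, 6500 ms), 32 x 32 matrix
#' over a 20 x 20 mm field of view with a 2.4 mm slice. The standard
#' (blood-brain barrier) readout uses TE = 20 ms with 5 repetitions; the
#' ultra-long TE readout that isolates CSF uses TE = 220 ms with 20
#' repetitions.
#'
#' @param te Echo time, seconds.
#' @param repetitions Number of control/label pair repetitions.
#' @param ti_list Inversion times, seconds, strictly increasing.
#' @param alpha Labelling efficiency in \[0, 1\].
#' @param noise_sd Additive Gaussian noise standard deviation per repetition,
#'   in signal units (0 = noiseless).
#' @param b_value Diffusion sensitisation, s/mm^2 (0 = none).
#' @param labelling_width_mm Slice-selective inversion width, mm.
#' @return A named list of protocol parameters.
#' @export
asl_protocol <- function(te = 0.020,
                         repetitions = 5L,
                         ti_list = c(0.2, 0.75, 1.5, 2.75, 4.0, 6.5),
                         alpha = 1.0,
                         noise_sd = 0,
                         b_value = 0,
                         labelling_width_mm = 19.2) {
  stopifnot(te > 0, repetitions >= 1, length(ti_list) >= 1,
            all(diff(ti_list) > 0), alpha >= 0, alpha <= 1,
            noise_sd >= 0, b_value >= 0)
  list(te = te, repetitions = as.integer(repetitions), ti_list = ti_list,
       alpha = alpha, noise_sd = noise_sd, b_value = b_value,
       labelling_width_mm = labelling_width_mm)
}

#' @rdname asl_protocol
#' @export
bcsfb_protocol <- function(te = 0.220, repetitions = 20L, ...) {
  asl_protocol(te = te, repetitions = repetitions, ...)
}
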