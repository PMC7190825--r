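#' Transverse (T2) signal attenuation at a given echo time
#'
#' `exp(-te/t2)`: the fraction of the TE = 0 signal surviving at echo time
#' `te` for a compartment with transverse relaxation time `t2`. At the
#' ultra-long echo time of 220 ms the mouse-brain values (T2 = 38, 30 and
#' 200 ms for parenchyma, blood and CSF) leave ~0.3%, ~0.07% and ~33% of the
#' theoretical signal, which is what lets the long-TE acquisition isolate
#' the CSF compartment.
#'
#' @param te Echo time, seconds, >= 0. Vectorised.
#' @param t2 Transverse relaxation time, seconds, > 0.
#' @return Attenuation fraction in (0, 1].
#' @examples
#' t2_attenuation(0.220, 0.200) # ~0.33, CSF survives
#' t2_attenuation(0.220, 0.038) # ~0.003, parenchyma nulled
#' @export
t2_attenuation <- function(te, t2) {
  if (any(!is.finite(t2)) || any(t2 <= 0)) {
    stop("t2 must be finite and > 0", call. = FALSE)
  }
  if (any(te < 0)) stop("te must be >= 0", call. = FALSE)
  exp(-te / t2)
}

#' Inversion-recovery signal model
#'
#' `m0 * (1 - 2 * beta * exp(-ti / t1))`, the standard inversion-recovery
#' curve with an inversion-efficiency factor `beta` (beta = 1 is perfect
#' inversion). Control images of a FAIR acquisition follow this model as a
#' function of TI, which is how M0 and T1 of each compartment are estimated.
#'
#' @param ti Inversion time(s), seconds, >= 0. Vectorised.
#' @param m0 Equilibrium magnetisation, > 0.
#' @param t1 Longitudinal relaxation time, seconds, > 0.
#' @param beta Inversion efficiency in (0, 1].
#' @param magnitude If `TRUE` return the magnitude signal `abs(...)`, as
#'   produced by magnitude image reconstruction.
#' @return Signal at each `ti`.
#' @examples
#' ir_signal(log(2) * 4, m0 = 100, t1 = 4) # null point
#' @export
ir_signal <- function(ti, m0, t1, beta = 1, magnitude = FALSE) {
  stopifnot(all(ti >= 0), m0 > 0, t1 > 0, beta > 0, beta <= 1)
  s <- m0 * (1 - 2 * beta * exp(-ti / t1))
  if (magnitude) abs(s) else s
}

# Shared closed form of the rectangular-bolus delivery models.
# Integral of a bolus arriving on [delta, delta+tau], decaying at r1a in
# transit, then at `r1dest` once delivered:
#   dM(t) = (2 m0 f alpha / phi) exp(-t r1dest)
#           [exp(min(t, delta+tau) dR) - exp(delta dR)] / dR,  dR = r1dest - r1a
# with the analytic limit (min(t,delta+tau) - delta) when |dR| < tol
# (double-precision cancellation dominates below ~1e-6 s^-1).
delta_m_closed <- function(ti, f, delta, tau, alpha, phi, r1dest, r1a, m0,
                           dr_tol = 1e-6) {
  dr <- r1dest - r1a
  upper <- pmin(ti, delta + tau)
  amp <- 2 * m0 * f * alpha / phi
  if (abs(dr) < dr_tol) {
    core <- upper - delta
  } else {
    core <- (exp(upper * dr) - exp(delta * dr)) / dr
  }
  out <- amp * exp(-ti * r1dest) * core
  out[ti <= delta] <- 0
  out
}

#' BCSFB-ASL difference-signal kinetic model
#'
#' Closed-form difference signal (control minus label) for labelled blood
#' water delivered across the blood-CSF barrier into ventricular CSF,
#' following the single-compartment extravascular delivery model: a
#' rectangular arterial bolus of duration `tau` arriving after transit time
#' `delta`, decaying at the blood rate `r1a` in transit and at the apparent
#' CSF rate `r1app` after delivery. The intravascular component is absent
#' because the ultra-long echo time nulls blood signal. Zero before arrival
#' (`ti <= delta`); the degenerate case `r1app == r1a` uses the analytic
#' limit, never a division by zero.
#'
#' @param ti Inversion time(s), seconds, >= 0. Vectorised.
#' @param params A [kinetic_params()] object (`r1app` is the CSF apparent
#'   rate, `phi` the blood-CSF partition coefficient).
#' @return Difference signal (same units as `m0`), >= 0.
#' @examples
#' kp <- kinetic_params(f = 24 / 6000, delta = 1, tau = 3, r1app = 1 / 4.0)
#' bcsfb_delta_m(c(0.2, 0.75, 1.5, 2.75, 4, 6.5), kp)
#' @export
bcsfb_delta_m <- function(ti, params) {
  stopifnot(inherits(params, "kinetic_params"), all(ti >= 0))
  p <- params
  delta_m_closed(ti, p$f, p$delta, p$tau, p$alpha, p$phi,
                 r1dest = p$r1app, r1a = p$r1a, m0 = p$m0)
}

#' Buxton general kinetic model for pulsed ASL
#'
#' The standard pulsed-ASL (FAIR) single-compartment solution for labelled
#' water delivered to tissue: rectangular bolus on `[delta, delta + tau]`
#' decaying at the blood rate in transit, then cleared at the apparent
#' tissue rate `1/T1' = 1/t1_tissue + f/lambda_tissue` which accounts for
#' venous outflow. Continuous in `ti` at both phase boundaries; zero flow
#' gives zero signal.
#'
#' @param ti Inversion time(s), seconds, >= 0. Vectorised.
#' @param params A [kinetic_params()] object; `f` is perfusion in s^-1
#'   (ml blood per ml tissue per second), `phi` is ignored.
#' @param rel A [relaxation_set()] supplying `t1_tissue` and
#'   `lambda_tissue`.
#' @return Difference signal in the units of `m0` (tissue equilibrium
#'   magnetisation).
#' @examples
#' kp <- kinetic_params(f = 251 / 6000, delta = 0.3, tau = 3, m0 = 100)
#' buxton_delta_m(2.75, kp, relaxation_set())
#' @export
buxton_delta_m <- function(ti, params, rel) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(rel, "relaxation_set"), all(ti >= 0))
  p <- params
  r1_app_tissue <- 1 / rel$t1_tissue + p$f / rel$lambda_tissue
  delta_m_closed(ti, p$f, p$delta, p$tau, p$alpha, phi = rel$lambda_tissue,
                 r1dest = r1_app_tissue, r1a = p$r1a, m0 = p$m0)
}

#' Numerical-convolution oracle for the delivery models
#'
#' Evaluates the delivery integral
#' `2 m0 f alpha / phi * int c(s) exp(-(ti - s) * clearance_rate) ds`
#' with `c(s)` a rectangular bolus on `[delta, delta + tau]` decaying at
#' `r1a`, by adaptive quadrature. This is the integral form underlying both
#' [bcsfb_delta_m()] and [buxton_delta_m()]; it exists to verify the closed
#' forms independently and is deliberately not written in terms of them.
#'
#' @param ti Inversion time(s), seconds. Vectorised.
#' @param params A [kinetic_params()] object.
#' @param clearance_rate Longitudinal decay rate of the destination
#'   compartment, s^-1 (for the CSF model this is `r1app`; for the tissue
#'   model `1/t1_tissue + f/lambda_tissue`).
#' @param phi Partition coefficient dividing the amplitude (defaults to
#'   `params$phi`).
#' @return Difference signal, quadrature error below 1e-10.
#' @export
delivery_convolution_oracle <- function(ti, params, clearance_rate,
                                        phi = params$phi) {
  stopifnot(inherits(params, "kinetic_params"), all(ti >= 0))
  p <- params
  vapply(ti, function(t1i) {
    upper <- min(t1i, p$delta + p$tau)
    if (upper <= p$delta || p$f == 0) return(0)
    integrand <- function(s) {
      exp(-s * p$r1a) * exp(-(t1i - s) * clearance_rate)
    }
    q <- stats::integrate(integrand, lower = p$delta, upper = upper,
                          rel.tol = 1e-12, abs.tol = 1e-14)
    2 * p$m0 * p$f * p$alpha / phi * q$value
  }, numeric(1))
}

#' Mono-exponential diffusion attenuation
#'
#' `exp(-b * d)`: signal attenuation of a compartment with (pseudo-)
#' diffusion coefficient `d` under diffusion sensitisation `b`. Fitting this
#' model across b-values yields the apparent diffusion coefficient `D_app`,
#' which is elevated by intravascular (flowing) spins — the intravoxel
#' incoherent motion effect used to check that the long-TE difference
#' signal carries no vascular contamination.
#'
#' @param b Diffusion weighting, s/mm^2, >= 0. Vectorised.
#' @param d Apparent diffusion coefficient, mm^2/s, >= 0.
#' @return Attenuation fraction in (0, 1].
#' @examples
#' diffusion_attenuation(200, 0.003)
#' @export
diffusion_attenuation <- function(b, d) {
  stopifnot(all(b >= 0), all(d >= 0))
  exp(-b * d)
}
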