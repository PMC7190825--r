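# Bounded Levenberg-Marquardt least squares around minpack.lm::nls.lm.
# `resid_fn(par)` returns the residual vector; par, lower, upper are named.
# Returns list(par, stderr, rss, converged, info).
lm_bounded <- function(resid_fn, start, lower, upper, maxiter = 200) {
  res <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  par <- res$par
  rss <- res$deviance
  n <- length(resid_fn(par))
  p <- length(par)
  stderr <- rep(NA_real_, p)
  names(stderr) <- names(par)
  if (n > p) {
    sigma2 <- rss / (n - p)
    # parameters pinned at a box bound have no local covariance; invert the
    # reduced hessian over the interior parameters only
    pv <- unlist(par)
    scale <- pmax(abs(pv), 1e-8)
    free <- (pv - lower) > 1e-8 * scale & (upper - pv) > 1e-8 * scale
    if (any(free)) {
      # nls.lm's hessian approximates 2 J'J, so cov = 2 sigma^2 H^-1
      covm <- tryCatch(2 * sigma2 * solve(res$hessian[free, free, drop = FALSE]),
                       error = function(e) NULL)
      if (!is.null(covm)) {
        dv <- diag(covm)
        stderr[free] <- ifelse(dv >= 0, sqrt(dv), NA_real_)
      }
    }
  }
  list(par = par, stderr = stderr, rss = rss,
       # info 1-3: x/f-convergence; 4: gradient orthogonality (exact fits)
       converged = res$info %in% 1:4 && all(is.finite(unlist(par))),
       info = res$info)
}

check_series <- function(data, cols, n_min, what) {
  if (!is.data.frame(data)) stop(sprintf("%s expects a data frame", what),
                                 call. = FALSE)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing column(s) %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  d <- data[cols]
  if (any(!stats::complete.cases(d))) d <- d[stats::complete.cases(d), ]
  if (nrow(d) < n_min) {
    stop(sprintf("%s needs at least %d points, got %d", what, n_min, nrow(d)),
         call. = FALSE)
  }
  d
}

#' Fit the inversion-recovery model to a multi-TI control series
#'
#' Estimates equilibrium magnetisation `m0`, longitudinal relaxation time
#' `t1` and inversion efficiency `beta` from control-signal recovery across
#' inversion times, by bounded Levenberg-Marquardt least squares on
#' [ir_signal()]. Signed data are assumed by default; `magnitude = TRUE`
#' fits the absolute-value model, restoring polarity by a null-point search
#' over candidate sign flips of the earliest TIs.
#'
#' @param data Data frame with columns `ti` (seconds) and `signal`.
#' @param magnitude Fit the magnitude (absolute-value) variant.
#' @param fix_beta Fix the inversion efficiency at this value instead of
#'   fitting it (e.g. `1` for ideal inversion); `NULL` fits beta.
#' @param t1_bounds Lower/upper bounds on `t1`, seconds.
#' @return An `asl_fit` with estimates `m0`, `t1` and (unless fixed)
#'   `beta`. See [tidy.asl_fit()], [glance.asl_fit()], [autoplot.asl_fit()].
#' @examples
#' tis <- c(0.2, 0.75, 1.5, 2.75, 4, 6.5)
#' d <- data.frame(ti = tis, signal = ir_signal(tis, m0 = 100, t1 = 1.9))
#' tidy(fit_inversion_recovery(d))
#' @export
fit_inversion_recovery <- function(data, magnitude = FALSE, fix_beta = NULL,
                                   t1_bounds = c(0.1, 10)) {
  fit_beta <- is.null(fix_beta)
  n_free <- if (fit_beta) 3L else 2L
  d <- check_series(data, c("ti", "signal"), n_free, "fit_inversion_recovery")
  ti <- d$ti
  sig <- d$signal

  m0_init <- max(abs(sig), 1e-6)
  t1_init <- max(t1_bounds[1], min(t1_bounds[2], stats::median(ti) / log(2)))
  start <- list(m0 = m0_init, t1 = t1_init)
  lower <- c(m0 = 0, t1 = t1_bounds[1])
  upper <- c(m0 = Inf, t1 = t1_bounds[2])
  if (fit_beta) {
    # initialise just inside the upper bound: Levenberg-Marquardt with box
    # constraints cannot move a parameter started exactly on its bound
    start$beta <- 1 - 1e-3
    lower <- c(lower, beta = 0.05)
    upper <- c(upper, beta = 1)
  }

  model_of <- function(par, tt) {
    b <- if (fit_beta) par$beta else fix_beta
    par$m0 * (1 - 2 * b * exp(-tt / par$t1))
  }

  if (magnitude) {
    # restore polarity by null-point search: with TIs in increasing order the
    # signed recovery is negative up to the null crossing, so try every
    # prefix flip of |signal| and keep the best-fitting signed series
    ord <- order(ti)
    ti_s <- ti[ord]
    mag <- abs(sig)[ord]
    best <- NULL
    for (k in 0:length(ti_s)) {
      signs <- rep(1, length(ti_s))
      if (k > 0) signs[seq_len(k)] <- -1
      cand_sig <- signs * mag
      cand <- lm_bounded(function(par) model_of(par, ti_s) - cand_sig,
                         start, lower, upper)
      if (is.null(best) || cand$rss < best$rss) {
        best <- cand
        sig_signed <- cand_sig
      }
    }
    res <- best
    ti <- ti_s
    sig <- sig_signed
  } else {
    res <- lm_bounded(function(par) model_of(par, ti) - sig,
                      start, lower, upper)
  }

  degenerate <- res$par$m0 <= 1e-8 * m0_init
  converged <- res$converged && !degenerate
  if (!converged) {
    warning("inversion-recovery fit did not converge; estimates are unreliable",
            call. = FALSE)
  }
  est <- res$par
  if (!fit_beta) est$beta <- NULL
  pf <- function(tt) model_of(res$par, tt)
  new_asl_fit(est, res$stderr, res$rss, converged, nrow(d),
              model = "inversion_recovery",
              data = data.frame(ti = ti, signal = sig), predict_fn = pf)
}

# Multi-start bounded LM on delta; best RSS wins, ties to smallest delta.
multistart_delta <- function(resid_fn, start, lower, upper,
                             delta_starts = c(0.2, 0.5, 1.0)) {
  best <- NULL
  for (d0 in delta_starts) {
    s <- start
    s$delta <- min(max(d0, lower[["delta"]]), upper[["delta"]])
    cand <- lm_bounded(resid_fn, s, lower, upper)
    if (is.null(best) ||
        cand$rss < best$rss - 1e-12 ||
        (abs(cand$rss - best$rss) <= 1e-12 &&
         cand$par$delta < best$par$delta)) {
      best <- cand
    }
  }
  best
}

#' Fit the BCSFB delivery model to a normalised difference-signal series
#'
#' Estimates the rate of labelled blood-water delivery to ventricular CSF
#' `f` (s^-1), the CSF transit time `delta` (s) and the bolus duration
#' `tau` (s) from the dimensionless difference signal (delta-M divided by
#' the ventricle-corrected M0) as a function of TI, using [bcsfb_delta_m()]
#' with `m0 = 1`. Labelling efficiency, partition coefficient and the two
#' relaxation rates are supplied as fixed constants. Fits use bounded
#' Levenberg-Marquardt with three starts on `delta` (0.2, 0.5, 1.0 s) to
#' avoid the shallow delta/tau trade-off; best residual sum of squares
#' wins, ties broken towards the smallest `delta`.
#'
#' @param data Data frame with columns `ti` (seconds) and `dm`
#'   (delta-M / corrected M0, dimensionless).
#' @param fixed Named list of fixed constants: `alpha`, `phi`, `r1a`,
#'   `r1app` (all required; see [kinetic_params()] for meanings).
#' @param pin_tau Fix the bolus duration at this value (seconds) instead of
#'   fitting it; `NULL` (default) fits `tau` within `[0.1, 10]` s.
#' @param f_max Upper bound on `f`, s^-1.
#' @return An `asl_fit` with estimates `f`, `delta` and (unless pinned)
#'   `tau`; `$reported` carries `f_ml_100ml_min = f * 6000`.
#' @examples
#' kp <- kinetic_params(f = 20 / 6000, delta = 1, tau = 3, r1app = 0.25)
#' tis <- c(0.2, 0.75, 1.5, 2.75, 4, 6.5)
#' d <- data.frame(ti = tis, dm = bcsfb_delta_m(tis, kp))
#' fit_bcsfb(d, fixed = list(alpha = 1, phi = 1, r1a = 1 / 2.4, r1app = 0.25))
#' @export
fit_bcsfb <- function(data, fixed, pin_tau = NULL, f_max = 0.1) {
  d <- check_series(data, c("ti", "dm"), 4L, "fit_bcsfb")
  stopifnot(is.list(fixed))
  req <- c("alpha", "phi", "r1a", "r1app")
  if (!all(req %in% names(fixed))) {
    stop("fixed must supply alpha, phi, r1a and r1app", call. = FALSE)
  }
  fx <- lapply(fixed[req], as.numeric)
  if (any(!is.finite(unlist(fx)))) {
    stop("fixed constants must be finite", call. = FALSE)
  }
  ti <- d$ti
  dm <- d$dm
  fit_tau <- is.null(pin_tau)

  if (all(dm == 0)) {
    est <- list(f = 0, delta = 0)
    if (fit_tau) est$tau <- 1 else est$tau <- NULL
    pf <- function(tt) rep(0, length(tt))
    se <- rep(NA_real_, length(est))
    names(se) <- names(est)
    fit <- new_asl_fit(est, se, 0, TRUE, nrow(d), model = "bcsfb_kinetic",
                       data = data.frame(ti = ti, dm = dm), predict_fn = pf)
    fit$reported <- c(f_ml_100ml_min = 0)
    return(fit)
  }

  model_of <- function(par, tt) {
    tau <- if (fit_tau) par$tau else pin_tau
    delta_m_closed(tt, par$f, par$delta, tau, fx$alpha, fx$phi,
                   r1dest = fx$r1app, r1a = fx$r1a, m0 = 1)
  }
  start <- list(f = max(1e-4, min(f_max / 2, max(dm))), delta = 0.5)
  lower <- c(f = 0, delta = 0)
  upper <- c(f = f_max, delta = max(ti))
  if (fit_tau) {
    start$tau <- 3
    lower <- c(lower, tau = 0.1)
    upper <- c(upper, tau = 10)
  }
  res <- multistart_delta(function(par) model_of(par, ti) - dm,
                          start, lower, upper)
  est <- res$par
  pf <- function(tt) model_of(res$par, tt)
  fit <- new_asl_fit(est, res$stderr, res$rss, res$converged, nrow(d),
                     model = "bcsfb_kinetic",
                     data = data.frame(ti = ti, dm = dm), predict_fn = pf)
  fit$reported <- c(f_ml_100ml_min = flow_to_reporting_units(est$f))
  if (!res$converged) {
    warning("BCSFB kinetic fit did not converge", call. = FALSE)
  }
  fit
}

#' Fit the Buxton general kinetic model to a cortical ASL series
#'
#' Estimates cortical perfusion `f` (s^-1) and arterial transit time
#' `delta` (s) from the normalised difference signal (delta-M / M0) as a
#' function of TI using [buxton_delta_m()] with `m0 = 1`. The bolus
#' duration is fixed (default 3 s) unless `fit_tau = TRUE`. Perfusion is
#' additionally reported as CBF in ml/100 g/min (`f * 6000`, tissue density
#' 1 g/ml).
#'
#' @param data Data frame with columns `ti` (seconds) and `dm`
#'   (delta-M / M0, dimensionless).
#' @param fixed Named list: `alpha`, `lambda_tissue`, `t1_tissue`, `r1a`,
#'   and optionally `tau` (default 3 s).
#' @param fit_tau Also fit the bolus duration.
#' @param f_max Upper bound on `f`, s^-1.
#' @return An `asl_fit` with estimates `f`, `delta` (and `tau` if fitted);
#'   `$reported` carries `cbf_ml_100g_min`.
#' @export
fit_buxton <- function(data, fixed, fit_tau = FALSE, f_max = 0.1) {
  d <- check_series(data, c("ti", "dm"), 3L, "fit_buxton")
  req <- c("alpha", "lambda_tissue", "t1_tissue", "r1a")
  if (!all(req %in% names(fixed))) {
    stop("fixed must supply alpha, lambda_tissue, t1_tissue and r1a",
         call. = FALSE)
  }
  fx <- lapply(fixed[req], as.numeric)
  tau_fixed <- if (!is.null(fixed$tau)) as.numeric(fixed$tau) else 3.0
  ti <- d$ti
  dm <- d$dm

  if (all(dm == 0)) {
    est <- list(f = 0, delta = 0)
    if (fit_tau) est$tau <- 1
    pf <- function(tt) rep(0, length(tt))
    se <- rep(NA_real_, length(est))
    names(se) <- names(est)
    fit <- new_asl_fit(est, se, 0, TRUE, nrow(d), model = "buxton_gkm",
                       data = data.frame(ti = ti, dm = dm), predict_fn = pf)
    fit$reported <- c(cbf_ml_100g_min = 0)
    return(fit)
  }

  model_of <- function(par, tt) {
    tau <- if (fit_tau) par$tau else tau_fixed
    r1t <- 1 / fx$t1_tissue + par$f / fx$lambda_tissue
    delta_m_closed(tt, par$f, par$delta, tau, fx$alpha, fx$lambda_tissue,
                   r1dest = r1t, r1a = fx$r1a, m0 = 1)
  }
  start <- list(f = max(1e-4, min(f_max / 2, max(dm))), delta = 0.3)
  lower <- c(f = 0, delta = 0)
  upper <- c(f = f_max, delta = max(ti))
  if (fit_tau) {
    start$tau <- 3
    lower <- c(lower, tau = 0.1)
    upper <- c(upper, tau = 10)
  }
  res <- multistart_delta(function(par) model_of(par, ti) - dm,
                          start, lower, upper)
  est <- res$par
  pf <- function(tt) model_of(res$par, tt)
  fit <- new_asl_fit(est, res$stderr, res$rss, res$converged, nrow(d),
                     model = "buxton_gkm",
                     data = data.frame(ti = ti, dm = dm), predict_fn = pf)
  fit$reported <- c(cbf_ml_100g_min = flow_to_reporting_units(est$f))
  if (!res$converged) warning("Buxton fit did not converge", call. = FALSE)
  fit
}

#' Fit the mono-exponential diffusion model across b-values
#'
#' Apparent (pseudo-)diffusion coefficient from signals at two or more
#' diffusion weightings. With exactly two b-values the closed form
#' `d_app = log(S(b1)/S(b2)) / (b2 - b1)` is used; with more, a log-linear
#' least-squares fit.
#'
#' @param data Data frame with columns `b` (s/mm^2) and `signal` (> 0).
#' @return An `asl_fit` with estimates `s0` (signal at b = 0) and `d_app`
#'   (mm^2/s).
#' @examples
#' fit_dapp(data.frame(b = c(0, 200), signal = c(1, exp(-0.6))))
#' @export
fit_dapp <- function(data) {
  d <- check_series(data, c("b", "signal"), 2L, "fit_dapp")
  if (length(unique(d$b)) < 2) {
    stop("fit_dapp needs at least 2 distinct b-values", call. = FALSE)
  }
  if (any(d$signal <= 0)) {
    stop("fit_dapp: signals must be positive (log model)", call. = FALSE)
  }
  b <- d$b
  s <- d$signal
  if (nrow(d) == 2) {
    dapp <- log(s[1] / s[2]) / (b[2] - b[1])
    s0 <- s[1] * exp(b[1] * dapp)
    est <- list(s0 = s0, d_app = dapp)
    se <- c(s0 = NA_real_, d_app = NA_real_)
    rss <- 0
  } else {
    lf <- stats::lm(log(s) ~ b)
    co <- stats::coef(lf)
    sm <- suppressWarnings(summary(lf))$coefficients
    s0 <- exp(co[[1]])
    dapp <- -co[[2]]
    est <- list(s0 = s0, d_app = dapp)
    se <- c(s0 = s0 * sm[1, 2], d_app = sm[2, 2])
    rss <- sum((s - s0 * exp(-b * dapp))^2)
  }
  pf <- function(bb) est$s0 * exp(-bb * est$d_app)
  new_asl_fit(est, se, rss, TRUE, nrow(d), model = "mono_exponential",
              data = data.frame(b = b, signal = s), predict_fn = pf)
}
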