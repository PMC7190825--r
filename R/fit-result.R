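new_asl_fit <- function(estimates, stderr, rss, converged, n_points,
                        model, data, predict_fn, reported = NULL) {
  structure(
    list(estimates = estimates, stderr = stderr, rss = rss,
         converged = converged, n_points = n_points, model = model,
         data = data, predict_fn = predict_fn, reported = reported),
    class = "asl_fit"
  )
}

#' @export
print.asl_fit <- function(x, ...) {
  cat(sprintf("<asl_fit: %s>  %s, rss = %.4g, n = %d\n", x$model,
              if (x$converged) "converged" else "NOT converged",
              x$rss, x$n_points))
  est <- x$estimates
  se <- x$stderr[names(est)]
  for (nm in names(est)) {
    cat(sprintf("  %-8s %.6g", nm, est[[nm]]))
    if (is.finite(se[[nm]])) cat(sprintf("  (se %.3g)", se[[nm]]))
    cat("\n")
  }
  if (!is.null(x$reported)) {
    for (nm in names(x$reported)) {
      cat(sprintf("  %-18s %.6g\n", nm, x$reported[[nm]]))
    }
  }
  invisible(x)
}

#' Tidy a model fit into one row per parameter
#'
#' @param x An `asl_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @importFrom generics tidy
#' @export
tidy.asl_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(unlist(x$estimates)),
    std.error = unname(x$stderr[names(x$estimates)])
  )
}

#' One-row fit summary
#'
#' @param x An `asl_fit` object.
#' @param ... Unused.
#' @return A tibble with `model`, `rss`, `sigma`, `converged`, `n_points`,
#'   `df.residual`.
#' @importFrom generics glance
#' @export
glance.asl_fit <- function(x, ...) {
  dfres <- x$n_points - length(x$estimates)
  tibble::tibble(
    model = x$model,
    rss = x$rss,
    sigma = if (dfres > 0) sqrt(x$rss / dfres) else NA_real_,
    converged = x$converged,
    n_points = x$n_points,
    df.residual = dfres
  )
}

#' Fitted values and residuals of a model fit
#'
#' @param object An `asl_fit` object.
#' @param ... Unused.
#' @return A tibble: the fitted data augmented with `.fitted` and `.resid`.
#' @export
augment.asl_fit <- function(object, ...) {
  d <- tibble::as_tibble(object$data)
  fitted <- object$predict_fn(d[[1]])
  d$.fitted <- fitted
  d$.resid <- d[[2]] - fitted
  d
}

#' @importFrom generics augment
#' @export
generics::augment

#' @export
generics::tidy

#' @export
generics::glance

#' Plot data and fitted curve for a model fit
#'
#' @param object An `asl_fit` object.
#' @param n_curve Number of points on the fitted curve.
#' @param ... Unused.
#' @return A ggplot object: observed points plus the fitted model curve.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.asl_fit <- function(object, n_curve = 200, ...) {
  d <- tibble::as_tibble(object$data)
  xnm <- names(d)[1]
  ynm <- names(d)[2]
  grid <- tibble::tibble(x = seq(min(d[[1]]), max(d[[1]]), length.out = n_curve))
  grid$y <- object$predict_fn(grid$x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[xnm]], y = .data[[ynm]])) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "steelblue") +
    ggplot2::labs(title = sprintf("%s fit", object$model),
                  subtitle = sprintf("rss = %.3g%s", object$rss,
                                     if (object$converged) "" else " (not converged)")) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
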