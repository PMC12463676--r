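#' Four-parameter logistic (sigmoidal) dose-response fit
#'
#' Fits the four-parameter logistic model, the standard "Rodbard"
#' sigmoid, on the log-concentration axis by least squares:
#' \deqn{y = bottom + \frac{top - bottom}{1 + (x / EC_{50})^{slope}}}
#' With a positive slope the response falls from `top` at low dose to
#' `bottom` at high dose (the granule-count convention); nuclear-partition
#' readouts that rise with dose fit with a negative slope.
#'
#' The optimizer (Levenberg-Marquardt, [minpack.lm::nlsLM()]) is started
#' from a grid of slope signs/magnitudes and EC50 locations and the best
#' converged start is kept. Fits are flagged unreliable when the dynamic
#' range is negligible (`top ~ bottom`), the EC50 lands outside
#' `[min(conc)/10, max(conc)*10]`, or no start converges; flagged fits are
#' returned with diagnostics, never silently replaced.
#'
#' @param concentrations strictly positive concentrations (>= 5 distinct)
#' @param responses numeric responses, same length
#' @param slope_starts initial slope grid (default `c(-2, -1, 1, 2)`)
#' @return object of class `dose_response_fit` with elements
#'   `coefficients` (`bottom`, `top`, `ec50`, `slope`), `fitted`,
#'   `residuals`, `rss`, `converged`, `flags` (character vector, empty
#'   when the fit is clean), `concentrations`, `responses`
#' @examples
#' conc <- 10^seq(-8, -4, length.out = 12)
#' y <- 0.1 + (3 - 0.1) / (1 + (conc / 2e-6)^1.5)
#' fit <- fit_dose_response(conc, y)
#' coef(fit)["ec50"]
#' @export
fit_dose_response <- function(concentrations, responses,
                              slope_starts = c(-2, -1, 1, 2)) {
  stopifnot(length(concentrations) == length(responses))
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (length(unique(concentrations)) < 5L) {
    stop("need at least 5 distinct concentrations")
  }
  lx <- log(concentrations)
  y <- responses
  yr <- range(y)
  # degenerate case: no usable dynamic range, nothing to fit
  if (diff(yr) <= 1e-6 * max(abs(yr), 1)) {
    m <- mean(y)
    out <- list(coefficients = c(bottom = m, top = m, ec50 = NA_real_,
                                 slope = NA_real_),
                fitted = rep(m, length(y)), residuals = y - m,
                rss = sum((y - m)^2), converged = FALSE,
                flags = "flat_response",
                concentrations = concentrations, responses = responses)
    class(out) <- "dose_response_fit"
    return(out)
  }
  model <- function(p, lx) {
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + exp(p[["slope"]] * (lx - p[["log_ec50"]])))
  }
  best <- NULL
  le_starts <- quantile(lx, c(0.25, 0.5, 0.75), names = FALSE)
  for (sl in slope_starts) {
    for (le in le_starts) {
      start <- list(bottom = yr[1], top = yr[2], log_ec50 = le, slope = sl)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) /
            (1 + exp(slope * (lx - log_ec50))),
          start = start,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12 * max(best$rss, 1)) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  flags <- character()
  if (is.null(best)) {
    co <- c(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
            slope = NA_real_)
    out <- list(coefficients = co, fitted = rep(NA_real_, length(y)),
                residuals = rep(NA_real_, length(y)), rss = NA_real_,
                converged = FALSE, flags = "no_convergence",
                concentrations = concentrations, responses = responses)
    class(out) <- "dose_response_fit"
    return(out)
  }
  p <- coef(best$fit)
  co <- c(bottom = unname(p["bottom"]), top = unname(p["top"]),
          ec50 = exp(unname(p["log_ec50"])), slope = unname(p["slope"]))
  # canonical form: slope > 0, top = low-dose asymptote
  if (co["slope"] < 0) {
    co[c("bottom", "top")] <- co[c("top", "bottom")]
    co["slope"] <- -co["slope"]
  }
  span <- abs(co["top"] - co["bottom"])
  if (span < 0.05 * max(diff(yr), .Machine$double.eps) || diff(yr) == 0) {
    flags <- c(flags, "flat_response")
  }
  lo <- min(concentrations) / 10
  hi <- max(concentrations) * 10
  if (co["ec50"] < lo || co["ec50"] > hi) {
    flags <- c(flags, "ec50_outside_range")
  }
  fitted_y <- model(list(bottom = co[["bottom"]], top = co[["top"]],
                         log_ec50 = log(co[["ec50"]]),
                         slope = co[["slope"]]), lx)
  out <- list(coefficients = co, fitted = fitted_y,
              residuals = y - fitted_y, rss = best$rss, converged = TRUE,
              flags = flags, concentrations = concentrations,
              responses = responses)
  class(out) <- "dose_response_fit"
  out
}

#' @export
coef.dose_response_fit <- function(object, ...) object$coefficients

#' @export
residuals.dose_response_fit <- function(object, ...) object$residuals

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  co <- object$coefficients
  x <- if (is.null(newdata)) object$concentrations
       else if (is.list(newdata)) newdata$concentrations
       else newdata
  co[["bottom"]] + (co[["top"]] - co[["bottom"]]) /
    (1 + (x / co[["ec50"]])^co[["slope"]])
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  if (!x$converged) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  co <- x$coefficients
  cat(sprintf("  EC50: %.4g   slope: %.3g\n", co["ec50"], co["slope"]))
  cat(sprintf("  top (low dose): %.4g   bottom (high dose): %.4g\n",
              co["top"], co["bottom"]))
  cat(sprintf("  RSS: %.4g over %d points\n", x$rss,
              length(x$responses)))
  if (length(x$flags)) {
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  plot(x$concentrations, x$responses, log = "x",
       xlab = "concentration", ylab = "response", ...)
  if (x$converged) {
    xx <- exp(seq(log(min(x$concentrations)), log(max(x$concentrations)),
                  length.out = 200))
    lines(xx, predict(x, xx))
    abline(v = x$coefficients[["ec50"]], lty = 2)
  }
  invisible(x)
}
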