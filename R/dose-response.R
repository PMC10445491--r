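#' Initial velocity from a progress trace
#'
#' Ordinary least-squares slope of RFU versus time over the linear window.
#' Starting from the full trace, points are dropped from the end until the
#' fit reaches r-squared >= `r2_min` or only 4 points remain (the result is
#' then flagged `linear = FALSE`). A perfectly flat trace has velocity 0 and
#' is treated as linear.
#'
#' @param trace A `kinetic_trace` (or any list with `times` and `rfu`).
#' @param r2_min Linearity threshold on r-squared (default 0.98).
#' @return A `rate_measurement`: list with `velocity` (RFU/min), `se`,
#'   `r_squared`, `window` (start, end in min), `linear`.
#' @export
estimate_velocity <- function(trace, r2_min = 0.98) {
  t <- trace$times; y <- trace$rfu
  if (length(t) < 4) stop("at least 4 time points are required")
  n <- length(t)
  repeat {
    fit <- stats::lm(y[1:n] ~ t[1:n])
    r2 <- .slope_r2(t[1:n], y[1:n], fit)
    if (r2 >= r2_min || n == 4) break
    n <- n - 1
  }
  s <- suppressWarnings(summary(fit)$coefficients)
  structure(list(velocity = unname(s[2, 1]), se = unname(s[2, 2]),
                 r_squared = r2, window = c(t[1], t[n]),
                 linear = r2 >= r2_min),
            class = "rate_measurement")
}

# r^2 of a slope fit; a zero-variance response (flat trace) counts as perfect.
.slope_r2 <- function(t, y, fit) {
  tss <- sum((y - mean(y))^2)
  if (tss < .Machine$double.eps * max(1, mean(y)^2)) return(1)
  1 - sum(stats::residuals(fit)^2) / tss
}

#' Fractional inhibition from control and treated velocities
#'
#' `(v_control - v_treated) / v_control`. Negative values (activation) are
#' reported unclipped. Vectorized over `v_treated`.
#'
#' @param v_control Uninhibited velocity, RFU/min (> 0).
#' @param v_treated Velocity under inhibitor, RFU/min.
#' @return Fractional inhibition (dimensionless).
#' @export
percent_inhibition <- function(v_control, v_treated) {
  if (any(v_control <= 0)) stop("control velocity must be > 0")
  (v_control - v_treated) / v_control
}

#' Fit a two-parameter logistic IC50 curve
#'
#' Nonlinear least squares of fractional inhibition on concentration with the
#' model `f = c^h / (c^h + IC50^h)` (bottom fixed at 0, top at 1: the
#' inhibition ratio is already normalized to control). IC50 is fitted on the
#' log scale for stability; the confidence interval comes from the parameter
#' covariance on that scale. Zero-concentration rows are dropped (they are
#' controls, not fit points); replicates at one concentration are averaged
#' before fitting unless `pool = TRUE`.
#'
#' @param concentrations Inhibitor concentrations, uM.
#' @param inhibitions Fractional inhibitions (same length).
#' @param pool Fit all replicate points instead of per-concentration means.
#' @param conf_level Confidence level for the IC50 interval.
#' @return A `dose_response_fit`: list with `ic50`, `hill`, `ic50_ci`
#'   (lower, upper), `r_squared`, `n_points`.
#' @export
fit_ic50 <- function(concentrations, inhibitions, pool = FALSE,
                     conf_level = 0.95) {
  stopifnot(length(concentrations) == length(inhibitions))
  keep <- concentrations > 0
  cc <- concentrations[keep]; ff <- inhibitions[keep]
  if (!pool) {
    means <- tapply(ff, cc, mean)
    cc <- as.numeric(names(means)); ff <- as.numeric(means)
  }
  if (length(unique(cc)) < 4)
    stop("at least 4 distinct positive concentrations are required")
  if (all(ff < 0.3) || all(ff > 0.7))
    stop("dose-response does not bracket 50% inhibition; fit unreliable")
  lc <- log(cc)
  # start: log-IC50 from linear interpolation at f = 0.5, Hill slope 1
  ord <- order(ff)
  l50 <- stats::approx(ff[ord], lc[ord], xout = 0.5, ties = mean)$y
  if (!is.finite(l50)) l50 <- mean(lc)
  fit <- minpack.lm::nls.lm(
    par = c(h = 1, l50 = l50),
    fn = function(p) ff - 1 / (1 + exp(-p[1] * (lc - p[2]))),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- fit$par
  se_l50 <- tryCatch(suppressWarnings(summary(fit)$coefficients["l50", 2]),
                     error = function(e) NA_real_)
  # an exact (zero-residual) fit has no sampling variance to propagate
  if (!is.finite(se_l50)) se_l50 <- 0
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(est[["l50"]] + c(-1, 1) * zq * se_l50)
  res <- fit$fvec
  tss <- sum((ff - mean(ff))^2)
  structure(list(ic50 = exp(est[["l50"]]), hill = est[["h"]],
                 ic50_ci = ci,
                 r_squared = if (tss > 0) 1 - sum(res^2) / tss else 1,
                 n_points = length(ff)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("IC50 = %.4g uM (95%% CI %.4g-%.4g), Hill = %.3f, r2 = %.4f, %d points\n",
              x$ic50, x$ic50_ci[1], x$ic50_ci[2], x$hill, x$r_squared,
              x$n_points))
  invisible(x)
}
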