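#' Substrate-by-inhibitor velocity grid
#'
#' Validates and classes a data.frame of steady-state velocities measured at
#' crossed substrate and inhibitor levels, the input to mode classification.
#' At least 3 substrate levels and 3 inhibitor levels (including 0) are
#' required; all velocities must be positive.
#'
#' @param df A data.frame with columns `substrate`, `inhibitor`, `velocity`
#'   and optionally `se`.
#' @return The data.frame with class `rate_grid`.
#' @export
rate_grid <- function(df) {
  need <- c("substrate", "inhibitor", "velocity")
  if (!all(need %in% names(df)))
    stop("rate grid needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$se)) df$se <- 0
  if (length(unique(df$substrate)) < 3)
    stop("at least 3 substrate levels are required")
  if (length(unique(df$inhibitor)) < 3 || !any(df$inhibitor == 0))
    stop("at least 3 inhibitor levels including 0 are required")
  if (any(df$velocity <= 0)) stop("velocities must be positive")
  class(df) <- c("rate_grid", "data.frame")
  df
}

# Candidate models, ordered fewest-assumptions first; ties in AICc resolve
# in this order (simpler / nested model wins on a near-tie).
.mode_order <- c("none", "competitive", "noncompetitive", "uncompetitive",
                 "mixed")

.n_par <- c(none = 2, competitive = 3, noncompetitive = 3,
            uncompetitive = 3, mixed = 4)

.fit_one_mode <- function(grid, mode, start, weights) {
  s <- grid$substrate; i <- grid$inhibitor; v <- grid$velocity
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                     ptol = 1e-15)
  lower <- switch(mode,
    none  = c(km = 1e-9, vmax = 1e-9),
    mixed = c(km = 1e-9, vmax = 1e-9, ki = 1e-9, alpha = 1e-6),
    c(km = 1e-9, vmax = 1e-9, ki = 1e-9))
  form <- switch(mode,
    none           = v ~ vmax * s / (km + s),
    competitive    = v ~ vmax * s / (km * (1 + i / ki) + s),
    noncompetitive = v ~ vmax * s / ((km + s) * (1 + i / ki)),
    uncompetitive  = v ~ vmax * s / (km + s * (1 + i / ki)),
    mixed = v ~ vmax * s / (km * (1 + i / ki) + s * (1 + i / (alpha * ki))))
  st <- start[names(lower)]
  args <- list(form, start = as.list(st), lower = lower, control = ctrl)
  if (!is.null(weights)) args$weights <- weights
  tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
}

.aicc <- function(rss, n, p) {
  # p fitted parameters + 1 for the error variance
  k <- p + 1
  rss <- max(rss, 1e-300)
  n * log(rss / n) + 2 * k + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
}

#' Classify the inhibition mode and estimate Ki by global fitting
#'
#' Fits the four candidate inhibited Michaelis-Menten rate laws (plus a
#' no-inhibition model) to the full substrate-by-inhibitor grid by weighted
#' nonlinear least squares and selects among them with the small-sample
#' corrected information criterion (AICc). When the best two models are
#' within `delta` AICc units the simpler / nested model wins, with the
#' preference order none > competitive > noncompetitive > uncompetitive >
#' mixed. If the no-inhibition model wins the grid carries no usable
#' inhibition signal: the result is flagged degenerate with Ki = Inf.
#'
#' Fits are unweighted by default: within one grid the velocities span less
#' than an order of magnitude, and weights estimated from the data (observed
#' `1/v^2` or few-replicate SEs) correlate with the residuals, which inflates
#' the apparent improvement of the more flexible candidates and biases the
#' information-criterion comparison toward mixed. `weighting = "relative"`
#' (1/v^2, matching a constant-CV error structure) and `"se"` (empirical
#' 1/se^2) remain available.
#'
#' @param grid A [rate_grid()].
#' @param delta AICc margin below which the simpler model is preferred
#'   (default 2).
#' @param weighting `"none"` (default), `"relative"` (1/v^2), or `"se"`
#'   (1/se^2).
#' @return A `mode_fit`: list with `mode`, `ki`, `ki_se`, `alpha`, `km`,
#'   `vmax`, `apparent` (per-inhibitor apparent Km and Vmax), `scores`
#'   (AICc per candidate), `degenerate`.
#' @export
fit_global_inhibition <- function(grid, delta = 2,
                                  weighting = c("none", "relative", "se")) {
  weighting <- match.arg(weighting)
  grid <- rate_grid(as.data.frame(grid))
  v <- grid$velocity
  w <- switch(weighting,
    relative = 1 / v^2,
    se = if (all(is.finite(grid$se)) && all(grid$se > 0)) 1 / grid$se^2
         else NULL,
    none = NULL)
  # starts from the uninhibited rows (double-reciprocal line) and a crude Ki
  ctrl_rows <- grid[grid$inhibitor == 0, ]
  lb <- stats::lm(I(1 / ctrl_rows$velocity) ~ I(1 / ctrl_rows$substrate))
  vmax0 <- 1 / stats::coef(lb)[[1]]
  km0 <- stats::coef(lb)[[2]] * vmax0
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(v) * 2
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(grid$substrate)
  inh <- grid[grid$inhibitor > 0, ]
  v0_of <- function(s) ctrl_rows$velocity[match(s, ctrl_rows$substrate)]
  drop_frac <- v0_of(inh$substrate) / inh$velocity - 1
  ki0 <- stats::median(inh$inhibitor / pmax(drop_frac, 1e-6))
  if (!is.finite(ki0) || ki0 <= 0) ki0 <- stats::median(inh$inhibitor)
  start <- c(km = km0, vmax = vmax0, ki = ki0, alpha = 1)

  fits <- lapply(.mode_order, function(m) .fit_one_mode(grid, m, start, w))
  names(fits) <- .mode_order
  scores <- vapply(.mode_order, function(m) {
    f <- fits[[m]]
    if (is.null(f)) return(Inf)
    .aicc(sum(stats::residuals(f)^2), nrow(grid), .n_par[[m]])
  }, 0)
  best <- min(scores)
  # first (fewest-assumption) candidate within delta of the minimum
  winner <- .mode_order[which(scores <= best + delta)[1]]
  fit <- fits[[winner]]
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  ki <- if (winner == "none") Inf else cf[["ki"]]
  ki_se <- if (winner != "none" && !is.null(vc) && "ki" %in% rownames(vc))
    sqrt(vc["ki", "ki"]) else NA_real_
  alpha <- if (winner == "mixed") cf[["alpha"]] else NA_real_
  structure(list(mode = winner, ki = ki, ki_se = ki_se, alpha = alpha,
                 km = cf[["km"]], vmax = cf[["vmax"]],
                 apparent = .apparent_constants(winner, cf,
                                                sort(unique(grid$inhibitor))),
                 scores = scores, degenerate = winner == "none"),
            class = "mode_fit")
}

# Apparent Km and Vmax at each inhibitor level implied by the winning law.
.apparent_constants <- function(mode, cf, inhibitors) {
  km <- cf[["km"]]; vmax <- cf[["vmax"]]
  ki <- if (mode == "none") Inf else cf[["ki"]]
  alpha <- if (mode == "mixed") cf[["alpha"]] else 1
  a <- switch(mode,
    none           = data.frame(km_app = km, vmax_app = vmax),
    competitive    = data.frame(km_app = km * (1 + inhibitors / ki),
                                vmax_app = vmax),
    noncompetitive = data.frame(km_app = km,
                                vmax_app = vmax / (1 + inhibitors / ki)),
    uncompetitive  = data.frame(km_app = km / (1 + inhibitors / ki),
                                vmax_app = vmax / (1 + inhibitors / ki)),
    mixed = {
      u <- 1 + inhibitors / (alpha * ki)
      data.frame(km_app = km * (1 + inhibitors / ki) / u, vmax_app = vmax / u)
    })
  cbind(data.frame(inhibitor = if (mode == "none") NA_real_ else inhibitors),
        a)
}

#' @export
print.mode_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("No inhibition signal: mode degenerate, Ki -> Inf\n")
  } else {
    cat(sprintf("Inhibition mode: %s, Ki = %.4g uM (SE %.3g)\n",
                x$mode, x$ki, x$ki_se))
    if (!is.na(x$alpha)) cat(sprintf("  alpha = %.3g\n", x$alpha))
  }
  cat("  AICc scores:\n")
  print(round(x$scores, 2))
  invisible(x)
}

#' Lineweaver-Burk (double-reciprocal) analysis
#'
#' Regresses 1/v on 1/[S] separately at each inhibitor level and reports each
#' line's slope, y-intercept (1/Vmax_app) and x-intercept (-1/Km_app),
#' together with dispersion statistics of the intercepts across levels used
#' as a classification cross-check: competitive families share the
#' y-intercept (Vmax unchanged), non-competitive families share the
#' x-intercept (Km unchanged).
#'
#' Regressions use 1/v^2 weights by default to counteract the variance
#' inflation of the reciprocal transform.
#'
#' @param grid A [rate_grid()].
#' @param weighted Use 1/v^2 weights (default TRUE).
#' @return A `lineweaver_burk` list: `lines` (data.frame per inhibitor level)
#'   and `dispersion` (relative SD of y- and x-intercepts).
#' @export
lineweaver_burk <- function(grid, weighted = TRUE) {
  grid <- as.data.frame(grid)
  if (any(grid$velocity <= 0)) stop("velocities must be positive")
  lines <- do.call(rbind, lapply(split(grid, grid$inhibitor), function(g) {
    x <- 1 / g$substrate; y <- 1 / g$velocity
    w <- if (weighted) g$velocity^2 else NULL
    f <- stats::lm(y ~ x, weights = w)
    b <- stats::coef(f)
    data.frame(inhibitor = g$inhibitor[1], slope = b[[2]],
               y_intercept = b[[1]], x_intercept = -b[[1]] / b[[2]])
  }))
  rownames(lines) <- NULL
  rel_sd <- function(z) if (abs(mean(z)) > 0) stats::sd(z) / abs(mean(z)) else stats::sd(z)
  structure(list(lines = lines,
                 dispersion = c(y_intercept = rel_sd(lines$y_intercept),
                                x_intercept = rel_sd(lines$x_intercept))),
            class = "lineweaver_burk")
}

#' Dixon-plot Ki estimate
#'
#' Fits 1/v against [I] at each substrate level and locates the common
#' intersection of the resulting lines: its abscissa is -Ki for competitive
#' and pure non-competitive inhibitors. Ki is the negated median x-coordinate
#' over all pairwise intersections; their spread is returned as a diagnostic.
#' Near-parallel lines (the pure uncompetitive pattern, which has no Dixon
#' intersection) raise an error pointing to the global fit.
#'
#' @param grid A [rate_grid()] (>= 2 substrate levels, >= 3 inhibitor levels).
#' @param weighted Use 1/v^2 weights (default TRUE).
#' @return A `dixon_fit`: list with `ki`, `intersections` (data.frame of
#'   pairwise x, y), `spread` (SD of intersection abscissae), `lines`.
#' @export
dixon_ki <- function(grid, weighted = TRUE) {
  grid <- as.data.frame(grid)
  if (length(unique(grid$substrate)) < 2)
    stop("at least 2 substrate levels are required")
  if (length(unique(grid$inhibitor)) < 3)
    stop("at least 3 inhibitor levels are required")
  if (any(grid$velocity <= 0)) stop("velocities must be positive")
  lines <- do.call(rbind, lapply(split(grid, grid$substrate), function(g) {
    w <- if (weighted) g$velocity^2 else NULL
    f <- stats::lm(I(1 / velocity) ~ inhibitor, data = g, weights = w)
    b <- stats::coef(f)
    data.frame(substrate = g$substrate[1], intercept = b[[1]], slope = b[[2]])
  }))
  rownames(lines) <- NULL
  pairs <- utils::combn(nrow(lines), 2)
  scale_slope <- max(abs(lines$slope))
  xs <- ys <- numeric(0)
  for (j in seq_len(ncol(pairs))) {
    a <- lines[pairs[1, j], ]; b <- lines[pairs[2, j], ]
    ds <- b$slope - a$slope
    if (abs(ds) < 1e-9 * max(scale_slope, 1e-300)) next
    x <- (a$intercept - b$intercept) / ds
    xs <- c(xs, x); ys <- c(ys, a$intercept + a$slope * x)
  }
  if (length(xs) == 0)
    stop("Dixon lines are parallel (uncompetitive pattern has no ",
         "intersection); use fit_global_inhibition")
  structure(list(ki = -stats::median(xs),
                 intersections = data.frame(x = xs, y = ys),
                 spread = if (length(xs) > 1) stats::sd(xs) else 0,
                 lines = lines),
            class = "dixon_fit")
}

#' Reversibility test from enzyme-dilution lines
#'
#' For each inhibitor level, fits velocity against enzyme concentration by
#' ordinary least squares. A reversible inhibitor yields a family of straight
#' lines through the origin with slope shrinking as `[I]` grows; an
#' irreversible (titrating) inhibitor shifts the lines off the origin. The
#' verdict is `reversible` when every intercept is statistically
#' indistinguishable from zero (|z| < `z_threshold`).
#'
#' @param df Data.frame with columns `enzyme`, `inhibitor`, `velocity`.
#' @param z_threshold Intercept z-score threshold (default 2).
#' @return A `reversibility_result`: list with `lines` (slope, intercept,
#'   intercept_se, z per inhibitor level) and `verdict`.
#' @export
reversibility_test <- function(df, z_threshold = 2) {
  df <- as.data.frame(df)
  need <- c("enzyme", "inhibitor", "velocity")
  if (!all(need %in% names(df)))
    stop("need columns: ", paste(need, collapse = ", "))
  lines <- do.call(rbind, lapply(split(df, df$inhibitor), function(g) {
    if (length(unique(g$enzyme)) < 3)
      stop("at least 3 enzyme levels per inhibitor level are required")
    f <- stats::lm(velocity ~ enzyme, data = g)
    s <- suppressWarnings(summary(f)$coefficients)
    int <- s[1, 1]; se <- s[1, 2]
    # exact-through-origin data has se ~ 0/0; a vanishing intercept counts as 0
    z <- if (se < 1e-10 * max(abs(g$velocity)) &&
             abs(int) < 1e-8 * max(abs(g$velocity))) 0 else int / se
    data.frame(inhibitor = g$inhibitor[1], slope = s[2, 1], intercept = int,
               intercept_se = se, z = z)
  }))
  rownames(lines) <- NULL
  structure(list(lines = lines,
                 verdict = if (all(abs(lines$z) < z_threshold))
                   "reversible" else "irreversible-like"),
            class = "reversibility_result")
}

#' @export
print.reversibility_result <- function(x, ...) {
  cat("Reversibility verdict:", x$verdict, "\n")
  print(x$lines)
  invisible(x)
}
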