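#' Peak intensity of an emission spectrum
#'
#' Maximum intensity over an emission scan and the wavelength where it
#' occurs. A flat spectrum is degenerate: its constant value is returned with
#' the first wavelength and a flag.
#'
#' @param wavelength Scan wavelengths, nm (>= 10 points).
#' @param intensity Intensities, same length.
#' @return A list with `peak`, `wavelength`, `flat`.
#' @export
extract_peak <- function(wavelength, intensity) {
  stopifnot(length(wavelength) == length(intensity))
  if (length(wavelength) == 0) stop("empty spectrum")
  if (length(wavelength) < 10) stop("at least 10 wavelength points required")
  flat <- diff(range(intensity)) <= .Machine$double.eps * max(abs(intensity), 1)
  j <- if (flat) 1L else which.max(intensity)
  list(peak = intensity[j], wavelength = wavelength[j], flat = flat)
}

#' Build a quench titration from spectra
#'
#' Reduces a long-format spectra table (quencher, wavelength, intensity,
#' optionally replicate) to one peak intensity per quencher level (replicates
#' averaged), anchored by F0 at `[Q] = 0`.
#'
#' @param spectra Data.frame with columns `quencher`, `wavelength`,
#'   `intensity` and optionally `replicate`.
#' @return A `quench_titration` data.frame with columns `quencher`, `f`,
#'   plus attribute `f0`.
#' @export
quench_titration <- function(spectra) {
  need <- c("quencher", "wavelength", "intensity")
  if (!all(need %in% names(spectra)))
    stop("need columns: ", paste(need, collapse = ", "))
  if (is.null(spectra$replicate)) spectra$replicate <- 1L
  peaks <- do.call(rbind, lapply(
    split(spectra, spectra[c("replicate", "quencher")], drop = TRUE),
    function(g) data.frame(
      quencher = g$quencher[1], replicate = g$replicate[1],
      f = extract_peak(g$wavelength, g$intensity)$peak)))
  m <- tapply(peaks$f, peaks$quencher, mean)
  out <- data.frame(quencher = as.numeric(names(m)), f = as.numeric(m))
  out <- out[order(out$quencher), ]
  if (!any(out$quencher == 0)) stop("a zero-quencher (F0) level is required")
  attr(out, "f0") <- out$f[out$quencher == 0]
  class(out) <- c("quench_titration", "data.frame")
  out
}

#' Stern-Volmer quenching constant
#'
#' Least-squares slope of `(F0/F - 1)` on `[Q]` through the origin:
#' `F0/F = 1 + KSV [Q]`. Points where F exceeds F0 by more than `tol`
#' (relative) contradict pure quenching and flag the fit.
#'
#' @param titration A [quench_titration()], or a data.frame with columns
#'   `quencher` and `f` plus an `f0` attribute (or a 0-quencher row).
#' @param tol Relative tolerance for F > F0 violations.
#' @return A list with `ksv` (uM^-1), `ksv_per_molar` (L/mol), `r_squared`,
#'   `flagged`.
#' @export
fit_stern_volmer <- function(titration, tol = 1e-6) {
  tt <- .as_titration(titration)
  q <- tt$quencher[tt$quencher > 0]
  f <- tt$f[tt$quencher > 0]
  if (length(q) < 3) stop("at least 3 nonzero quencher levels are required")
  f0 <- attr(tt, "f0")
  flagged <- any(f > f0 * (1 + tol))
  y <- f0 / f - 1
  ksv <- sum(q * y) / sum(q^2)
  fitted <- ksv * q
  tss <- sum(y^2)  # through-origin r^2 about zero
  list(ksv = ksv, ksv_per_molar = ksv * 1e6,
       r_squared = if (tss > 0) 1 - sum((y - fitted)^2) / tss else 1,
       flagged = flagged)
}

#' Double-log binding affinity fit
#'
#' Ordinary least squares of `log10((F0 - F)/F)` on `log10([Q])`: the
#' intercept is `log10 KA` and the slope the number of binding sites n. Free
#' quencher is approximated by total quencher. Points with F >= F0 carry no
#' quenching signal and are excluded with a warning; fewer than 3 usable
#' points is an error.
#'
#' KA's formal unit is uM^-n; `ka_per_molar` applies the 10^6 L/mol
#' conversion as if n = 1, the convention used in published quenching tables
#' (flagged in the `unit_note`).
#'
#' @param titration As in [fit_stern_volmer()].
#' @return A list with `ka` (uM^-n), `ka_per_molar`, `n_sites`, `r_squared`,
#'   `excluded`, `unit_note`.
#' @export
fit_double_log <- function(titration) {
  tt <- .as_titration(titration)
  q <- tt$quencher[tt$quencher > 0]
  f <- tt$f[tt$quencher > 0]
  f0 <- attr(tt, "f0")
  bad <- f >= f0
  if (any(bad))
    warning(sum(bad), " point(s) with F >= F0 excluded from double-log fit")
  q <- q[!bad]; f <- f[!bad]
  if (length(q) < 3) stop("fewer than 3 usable quencher levels")
  fit <- stats::lm(log10((f0 - f) / f) ~ log10(q))
  b <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(ka = 10^b[[1]], ka_per_molar = 10^b[[1]] * 1e6,
       n_sites = b[[2]], r_squared = r2, excluded = sum(bad),
       unit_note = "KA unit is uM^-n; L/mol conversion applies 1e6 as if n = 1")
}

.as_titration <- function(x) {
  if (inherits(x, "quench_titration")) return(x)
  x <- as.data.frame(x)
  if (!all(c("quencher", "f") %in% names(x)))
    stop("need columns quencher and f")
  if (is.null(attr(x, "f0"))) {
    if (!any(x$quencher == 0)) stop("no F0: include a zero-quencher row")
    attr(x, "f0") <- x$f[x$quencher == 0][1]
  }
  x
}

#' Micromolar / molar unit conversions
#'
#' `1 uM^-1 = 1e6 L mol^-1`; the round trip is exact.
#'
#' @param x Value(s) to convert.
#' @return Converted value(s).
#' @export
per_uM_to_per_molar <- function(x) x * 1e6

#' @rdname per_uM_to_per_molar
#' @export
per_molar_to_per_uM <- function(x) x / 1e6
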