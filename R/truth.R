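#' Ground-truth parameter set for a simulated assay
#'
#' Bundles every generating parameter the synthetic-assay module can draw on:
#' Michaelis-Menten constants, an inhibition mode with its Ki (and alpha for
#' mixed inhibition), dose-response parameters (IC50, Hill slope), slow-binding
#' rate constants (k3, k4), and fluorescence-quenching parameters (KSV, KA, n,
#' F0). Only the parameters relevant to the experiment class being generated
#' are validated at simulation time; the rest may stay at their defaults.
#'
#' All concentrations are in micromolar, all times in minutes, intensities in
#' relative fluorescence units (RFU). `enzyme_ref` is the enzyme level (unit/mL)
#' at which `vmax` applies; simulated velocities scale linearly as
#' `enzyme / enzyme_ref`.
#'
#' @param km Michaelis constant, uM.
#' @param vmax Maximal velocity at the reference enzyme level, RFU/min.
#' @param mode Inhibition mode: one of `"competitive"`, `"noncompetitive"`,
#'   `"uncompetitive"`, `"mixed"`, `"none"`.
#' @param ki Inhibition constant, uM (ignored for `mode = "none"`).
#' @param alpha Mixed-mode factor (> 0); the uncompetitive component of a
#'   mixed inhibitor binds with `alpha * ki`.
#' @param ic50 Half-maximal inhibitory concentration, uM.
#' @param hill Hill slope of the dose-response curve.
#' @param k3 Slow-binding forward rate constant, uM^-1 min^-1.
#' @param k4 Slow-binding reverse rate constant, min^-1.
#' @param ksv Stern-Volmer constant, uM^-1.
#' @param ka Binding affinity constant, uM^-n.
#' @param n_sites Number of binding sites (double-log slope).
#' @param f0 Unquenched peak fluorescence intensity, RFU.
#' @param enzyme_ref Reference enzyme level, unit/mL.
#' @return An object of class `assay_truth` (a named list).
#' @examples
#' truth <- assay_truth(mode = "competitive", ki = 0.17)
#' truth$ki
#' @export
assay_truth <- function(km = 100, vmax = 200,
                        mode = c("none", "competitive", "noncompetitive",
                                 "uncompetitive", "mixed"),
                        ki = 1, alpha = 1,
                        ic50 = 1, hill = 1,
                        k3 = 0.141, k4 = 0.0203,
                        ksv = 0.15792, ka = 0.24434, n_sites = 1.2897,
                        f0 = 1000, enzyme_ref = 0.02) {
  mode <- match.arg(mode)
  stopifnot(km > 0, vmax > 0, alpha > 0, enzyme_ref > 0)
  structure(list(km = km, vmax = vmax, mode = mode, ki = ki, alpha = alpha,
                 ic50 = ic50, hill = hill, k3 = k3, k4 = k4,
                 ksv = ksv, ka = ka, n_sites = n_sites, f0 = f0,
                 enzyme_ref = enzyme_ref),
            class = "assay_truth")
}

#' Noise model for simulated replicates
#'
#' Multiplicative Gaussian noise: every generated observation is scaled by
#' `1 + rnorm(1, 0, cv)`. `replicates` independent wells are generated per
#' condition; the `seed` makes the whole draw reproducible (identical seed and
#' truth give bit-identical output).
#'
#' @param cv Coefficient of variation (>= 0); 0.02 mirrors a typical
#'   triplicate plate-reader assay.
#' @param replicates Number of replicate wells per condition (>= 1).
#' @param seed Integer RNG seed, or NULL to leave the RNG state alone.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(cv = 0.02, replicates = 3, seed = NULL) {
  stopifnot(cv >= 0, replicates >= 1)
  structure(list(cv = cv, replicates = as.integer(replicates), seed = seed),
            class = "noise_spec")
}

#' Noiseless single-shot generation
#' @return A `noise_spec` with cv = 0 and one replicate.
#' @rdname noise_spec
#' @export
noise_free <- function() noise_spec(cv = 0, replicates = 1, seed = NULL)

# Seed the session RNG from a noise_spec, restoring nothing: generators are
# documented to consume the global stream when seed is NULL.
.apply_seed <- function(noise) {
  if (!is.null(noise$seed)) set.seed(as.integer(noise$seed))
  invisible(NULL)
}

.noise_factor <- function(n, cv) {
  if (cv == 0) rep(1, n) else 1 + stats::rnorm(n, 0, cv)
}

#' Mode-specific inhibited Michaelis-Menten velocity
#'
#' Textbook steady-state rate laws:
#' \itemize{
#'   \item competitive:    v = Vmax S / (Km (1 + I/Ki) + S)
#'   \item noncompetitive: v = Vmax S / ((Km + S)(1 + I/Ki))
#'   \item uncompetitive:  v = Vmax S / (Km + S (1 + I/Ki))
#'   \item mixed:          v = Vmax S / (Km (1 + I/Ki) + S (1 + I/(alpha Ki)))
#'   \item none:           v = Vmax S / (Km + S)
#' }
#'
#' @param s Substrate concentration(s), uM.
#' @param i Inhibitor concentration(s), uM.
#' @param km,vmax Michaelis-Menten constants.
#' @param mode Inhibition mode label.
#' @param ki Inhibition constant, uM.
#' @param alpha Mixed-mode factor.
#' @return Velocity in RFU/min (same length as the recycled inputs).
#' @export
mm_velocity <- function(s, i = 0, km, vmax, mode = "none", ki = Inf,
                        alpha = 1) {
  if (km <= 0 || vmax <= 0) stop("km and vmax must be strictly positive")
  if (mode != "none" && (!is.finite(ki) || ki <= 0))
    stop("ki must be strictly positive for an inhibited mode")
  switch(mode,
    none           = vmax * s / (km + s),
    competitive    = vmax * s / (km * (1 + i / ki) + s),
    noncompetitive = vmax * s / ((km + s) * (1 + i / ki)),
    uncompetitive  = vmax * s / (km + s * (1 + i / ki)),
    mixed          = vmax * s / (km * (1 + i / ki) + s * (1 + i / (alpha * ki))),
    stop("unknown inhibition mode: ", mode))
}

#' @export
print.assay_truth <- function(x, ...) {
  cat("Assay ground truth (uM, min, RFU)\n")
  cat(sprintf("  Michaelis-Menten: Km = %g, Vmax = %g (at %g unit/mL)\n",
              x$km, x$vmax, x$enzyme_ref))
  cat(sprintf("  Inhibition: mode = %s, Ki = %g, alpha = %g\n",
              x$mode, x$ki, x$alpha))
  cat(sprintf("  Dose-response: IC50 = %g, Hill = %g\n", x$ic50, x$hill))
  cat(sprintf("  Slow binding: k3 = %g uM^-1 min^-1, k4 = %g min^-1\n",
              x$k3, x$k4))
  cat(sprintf("  Quenching: KSV = %g uM^-1, KA = %g uM^-n, n = %g, F0 = %g\n",
              x$ksv, x$ka, x$n_sites, x$f0))
  invisible(x)
}
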