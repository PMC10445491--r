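#' Simulate a single progress-curve trace
#'
#' Generates one well's time course of fluorescence, reading every minute over
#' a 20-min window by default. The initial-rate regime is assumed: RFU grows
#' linearly at the mode-specific inhibited Michaelis-Menten velocity, scaled
#' linearly by enzyme concentration relative to `truth$enzyme_ref`, with no
#' substrate depletion. Multiplicative Gaussian noise is applied per reading.
#'
#' @param truth An [assay_truth()].
#' @param substrate Substrate concentration, uM (> 0).
#' @param inhibitor Inhibitor concentration, uM (>= 0).
#' @param enzyme Enzyme level, unit/mL (> 0).
#' @param noise A [noise_spec()]; `replicates` traces are returned.
#' @param times Read times in minutes (default 0:20).
#' @param baseline Background fluorescence added to every reading.
#' @param preincubation Preincubation time annotation, min. When positive the
#'   trace slope is additionally damped by `exp(-Kobs * preincubation)` with
#'   `Kobs = k4 + k3 * inhibitor` (slow-binding onset).
#' @return A list of `kinetic_trace` objects (length `noise$replicates`), each
#'   a list with `times`, `rfu`, and the annotation fields.
#' @export
simulate_progress_trace <- function(truth, substrate, inhibitor = 0,
                                    enzyme = truth$enzyme_ref,
                                    noise = noise_free(),
                                    times = 0:20, baseline = 0,
                                    preincubation = 0) {
  stopifnot(inherits(truth, "assay_truth"), inherits(noise, "noise_spec"))
  if (substrate <= 0) stop("substrate must be > 0")
  if (enzyme <= 0) stop("enzyme must be > 0")
  if (inhibitor < 0) stop("inhibitor must be >= 0")
  if (is.unsorted(times, strictly = TRUE)) stop("times must strictly increase")
  .apply_seed(noise)
  v <- mm_velocity(substrate, inhibitor, truth$km, truth$vmax, truth$mode,
                   truth$ki, truth$alpha) * enzyme / truth$enzyme_ref
  if (preincubation > 0) {
    if (truth$k3 <= 0 || truth$k4 <= 0)
      stop("k3 and k4 must be strictly positive for preincubation decay")
    v <- v * exp(-(truth$k4 + truth$k3 * inhibitor) * preincubation)
  }
  lapply(seq_len(noise$replicates), function(r) {
    rfu <- baseline + v * times * .noise_factor(length(times), noise$cv)
    kinetic_trace(times, rfu, substrate = substrate, inhibitor = inhibitor,
                  enzyme = enzyme, preincubation = preincubation,
                  replicate = r)
  })
}

#' One well's kinetic trace
#'
#' @param times Read times, min (strictly increasing).
#' @param rfu Fluorescence readings, same length as `times`.
#' @param substrate,inhibitor,enzyme,preincubation Assay annotations
#'   (uM, uM, unit/mL, min; all non-negative).
#' @param replicate Replicate index.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, rfu, substrate = NA_real_,
                          inhibitor = NA_real_, enzyme = NA_real_,
                          preincubation = 0, replicate = 1L) {
  if (length(times) != length(rfu)) stop("times and rfu lengths differ")
  if (is.unsorted(times, strictly = TRUE)) stop("times must strictly increase")
  ann <- c(substrate = substrate, inhibitor = inhibitor, enzyme = enzyme,
           preincubation = preincubation)
  if (any(ann < 0, na.rm = TRUE)) stop("annotations must be non-negative")
  structure(list(times = as.numeric(times), rfu = as.numeric(rfu),
                 substrate = substrate, inhibitor = inhibitor,
                 enzyme = enzyme, preincubation = preincubation,
                 replicate = as.integer(replicate)),
            class = "kinetic_trace")
}

#' Simulate a dose-response experiment
#'
#' Fractional inhibition follows the two-parameter logistic
#' `c^h / (c^h + IC50^h)` with multiplicative noise. A zero-concentration
#' control row must be present (it anchors the control velocity in a real
#' assay); its noiseless inhibition is exactly 0.
#'
#' @param truth An [assay_truth()] supplying `ic50` and `hill`.
#' @param concentrations Inhibitor concentrations, uM; must include 0.
#' @param noise A [noise_spec()].
#' @return A data.frame with columns `concentration`, `replicate`,
#'   `inhibition`. Values are reported unclipped (noise can push them
#'   slightly outside [0, 1]).
#' @export
simulate_dose_response <- function(truth, concentrations,
                                   noise = noise_free()) {
  stopifnot(inherits(truth, "assay_truth"), inherits(noise, "noise_spec"))
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (!any(concentrations == 0)) stop("a zero-concentration control is required")
  if (truth$ic50 <= 0 || truth$hill <= 0) stop("ic50 and hill must be > 0")
  .apply_seed(noise)
  grid <- expand.grid(replicate = seq_len(noise$replicates),
                      concentration = concentrations)
  f <- with(grid, ifelse(concentration == 0, 0,
                         concentration^truth$hill /
                           (concentration^truth$hill + truth$ic50^truth$hill)))
  data.frame(concentration = grid$concentration,
             replicate = grid$replicate,
             inhibition = f * .noise_factor(nrow(grid), noise$cv))
}

#' Simulate a reversibility (enzyme-dilution) experiment
#'
#' For a reversible inhibitor, velocity is proportional to enzyme
#' concentration at every inhibitor level: a family of lines through the
#' origin whose slopes shrink with `[I]` by the mode-specific rate-law factor.
#' Substrate is fixed at Km unless overridden.
#'
#' @param truth An [assay_truth()].
#' @param enzyme_levels Enzyme levels, unit/mL (default the assay's
#'   0.01/0.02/0.04 series).
#' @param inhibitor_levels Inhibitor levels, uM.
#' @param noise A [noise_spec()].
#' @param substrate Fixed substrate level, uM.
#' @return A data.frame with columns `enzyme`, `inhibitor`, `replicate`,
#'   `velocity`.
#' @export
simulate_reversibility <- function(truth,
                                   enzyme_levels = c(0.01, 0.02, 0.04),
                                   inhibitor_levels = c(0, 0.5, 1, 2) * truth$ic50,
                                   noise = noise_free(),
                                   substrate = truth$km) {
  stopifnot(inherits(truth, "assay_truth"), inherits(noise, "noise_spec"))
  if (any(enzyme_levels <= 0)) stop("enzyme levels must be positive")
  .apply_seed(noise)
  grid <- expand.grid(replicate = seq_len(noise$replicates),
                      enzyme = enzyme_levels, inhibitor = inhibitor_levels)
  v <- mm_velocity(substrate, grid$inhibitor, truth$km, truth$vmax,
                   truth$mode, truth$ki, truth$alpha) *
    grid$enzyme / truth$enzyme_ref
  data.frame(enzyme = grid$enzyme, inhibitor = grid$inhibitor,
             replicate = grid$replicate,
             velocity = v * .noise_factor(nrow(grid), noise$cv))
}

#' Simulate a slow-binding preincubation experiment
#'
#' Residual activity after preincubating enzyme with inhibitor decays as
#' `v/v0 = exp(-Kobs t)` with `Kobs = k4 (1 + [I] / (k4/k3)) = k4 + k3 [I]`.
#' There is no steady-state plateau; at t = 0 the noiseless ratio is exactly 1.
#'
#' @param truth An [assay_truth()] supplying `k3` and `k4` (per-minute units).
#' @param inhibitors Inhibitor levels, uM.
#' @param preincubation_times Preincubation times, min; must include 0.
#' @param noise A [noise_spec()].
#' @return A data.frame with columns `inhibitor`, `preincubation`,
#'   `replicate`, `v_over_v0`.
#' @export
simulate_slow_binding <- function(truth, inhibitors = c(0, 0.2, 0.4, 0.8),
                                  preincubation_times = seq(0, 10, by = 2),
                                  noise = noise_free()) {
  stopifnot(inherits(truth, "assay_truth"), inherits(noise, "noise_spec"))
  if (truth$k3 <= 0 || truth$k4 <= 0)
    stop("k3 and k4 must be strictly positive")
  if (!any(preincubation_times == 0))
    stop("preincubation times must include 0")
  .apply_seed(noise)
  grid <- expand.grid(replicate = seq_len(noise$replicates),
                      preincubation = preincubation_times,
                      inhibitor = inhibitors)
  kobs <- truth$k4 + truth$k3 * grid$inhibitor
  ratio <- exp(-kobs * grid$preincubation)
  data.frame(inhibitor = grid$inhibitor,
             preincubation = grid$preincubation,
             replicate = grid$replicate,
             v_over_v0 = ratio * .noise_factor(nrow(grid), noise$cv))
}

#' Simulate fluorescence-quenching emission spectra
#'
#' Each spectrum is a smooth Gaussian emission profile peaking near 340 nm.
#' The peak intensity at quencher level `[Q]` follows one model at a time:
#' Stern-Volmer, `F0/F = 1 + KSV [Q]`, or the double-log binding isotherm
#' inverted to intensity space, `F = F0 / (1 + KA [Q]^n)`. Free quencher is
#' approximated by total quencher (trace enzyme). A single dataset cannot
#' satisfy both models except when n = 1 and KA = KSV.
#'
#' @param truth An [assay_truth()].
#' @param model `"stern_volmer"` or `"double_log"`.
#' @param quencher Quencher levels, uM; must include 0.
#' @param wavelengths Emission scan grid, nm (default 300-400 by 2).
#' @param noise A [noise_spec()].
#' @param peak_nm,peak_sd_nm Peak position and Gaussian width of the
#'   emission profile.
#' @return A data.frame with columns `quencher`, `replicate`, `wavelength`,
#'   `intensity`.
#' @export
simulate_quenching <- function(truth, model = c("stern_volmer", "double_log"),
                               quencher = c(0, 0.2, 0.4, 0.8, 1.6, 3.2),
                               wavelengths = seq(300, 400, by = 2),
                               noise = noise_free(),
                               peak_nm = 340, peak_sd_nm = 22) {
  stopifnot(inherits(truth, "assay_truth"), inherits(noise, "noise_spec"))
  model <- match.arg(model)
  if (any(quencher < 0)) stop("quencher concentrations must be >= 0")
  if (!any(quencher == 0)) stop("quencher levels must include 0")
  if (truth$f0 <= 0) stop("f0 must be positive")
  .apply_seed(noise)
  profile <- exp(-(wavelengths - peak_nm)^2 / (2 * peak_sd_nm^2))
  out <- list()
  for (q in quencher) {
    fpeak <- switch(model,
      stern_volmer = truth$f0 / (1 + truth$ksv * q),
      double_log   = truth$f0 / (1 + truth$ka * q^truth$n_sites))
    for (r in seq_len(noise$replicates)) {
      out[[length(out) + 1L]] <- data.frame(
        quencher = q, replicate = r, wavelength = wavelengths,
        intensity = fpeak * profile * .noise_factor(length(wavelengths),
                                                    noise$cv))
    }
  }
  do.call(rbind, out)
}

#' Simulate a substrate-by-inhibitor rate grid
#'
#' Convenience wrapper for mode-classification studies: simulates replicate
#' progress traces at every substrate x inhibitor combination, estimates each
#' trace's initial velocity, and aggregates replicates to mean and SD. The
#' default design mirrors the fluorometric assay: substrate at 0.5x/1x/2x Km
#' and inhibitor at 0 plus 0.5x/1x/2x IC50.
#'
#' @param truth An [assay_truth()].
#' @param substrates Substrate levels, uM.
#' @param inhibitors Inhibitor levels, uM (must include 0).
#' @param noise A [noise_spec()].
#' @param times Trace read times, min.
#' @return A `rate_grid` data.frame with columns `substrate`, `inhibitor`,
#'   `velocity`, `se`.
#' @export
simulate_rate_grid <- function(truth,
                               substrates = truth$km * c(0.5, 1, 2),
                               inhibitors = c(0, 0.5, 1, 2) * truth$ic50,
                               noise = noise_free(),
                               times = 0:20) {
  stopifnot(inherits(truth, "assay_truth"), inherits(noise, "noise_spec"))
  .apply_seed(noise)
  # draw all traces from the already-seeded stream
  inner <- noise_spec(cv = noise$cv, replicates = noise$replicates, seed = NULL)
  grid <- expand.grid(substrate = substrates, inhibitor = inhibitors)
  rows <- lapply(seq_len(nrow(grid)), function(j) {
    traces <- simulate_progress_trace(truth, grid$substrate[j],
                                      grid$inhibitor[j], noise = inner,
                                      times = times)
    v <- vapply(traces, function(tr) estimate_velocity(tr)$velocity, 0)
    data.frame(substrate = grid$substrate[j], inhibitor = grid$inhibitor[j],
               velocity = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  })
  rate_grid(do.call(rbind, rows))
}
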