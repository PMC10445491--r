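#' Study configuration
#'
#' Defaults mirror the fluorometric neuraminidase assay: Km = 100 uM MUNANA
#' substrate, 1-min reads for 20 min, triplicates at 2% CV.
#'
#' @param km Substrate Michaelis constant, uM.
#' @param read_interval Plate-reader interval, min.
#' @param read_window Total read time, min.
#' @param r2_linearity Linear-window r-squared threshold for velocity
#'   extraction.
#' @param delta_score AICc margin for mode-selection ties.
#' @param z_threshold Reversibility intercept z threshold.
#' @param cv Default noise coefficient of variation.
#' @param replicates Default replicate count.
#' @param seed Default RNG seed (NULL = use current RNG state).
#' @return A `study_config` list.
#' @export
study_config <- function(km = 100, read_interval = 1, read_window = 20,
                         r2_linearity = 0.98, delta_score = 2,
                         z_threshold = 2, cv = 0.02, replicates = 3,
                         seed = NULL) {
  cfg <- list(km = km, read_interval = read_interval,
              read_window = read_window, r2_linearity = r2_linearity,
              delta_score = delta_score, z_threshold = z_threshold,
              cv = cv, replicates = as.integer(replicates), seed = seed)
  .validate_config(cfg)
  structure(cfg, class = "study_config")
}

.validate_config <- function(cfg) {
  if (cfg$km <= 0 || cfg$read_interval <= 0 || cfg$read_window <= 0)
    stop("km, read_interval and read_window must be positive")
  if (cfg$r2_linearity <= 0 || cfg$r2_linearity > 1)
    stop("r2_linearity must lie in (0, 1]")
  if (cfg$delta_score <= 0 || cfg$z_threshold <= 0)
    stop("thresholds must be positive")
  if (cfg$cv < 0 || cfg$replicates < 1)
    stop("cv must be >= 0 and replicates >= 1")
  invisible(cfg)
}

#' Write / read a study configuration (JSON)
#' @param config A [study_config()].
#' @param path File path.
#' @return `read_config` returns a `study_config`; the writer returns the
#'   path invisibly. The round trip is lossless.
#' @export
write_config <- function(config, path) {
  .validate_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(study_config, raw[!vapply(raw, is.null, TRUE)])
}

.kinetics_cols <- c("experiment_id", "compound", "stage", "replicate",
                    "time_min", "rfu", "substrate_uM", "inhibitor_uM",
                    "enzyme_u_per_mL", "preincubation_min")

#' Write / read the long-format kinetics CSV
#'
#' The frozen interchange schema for plate-reader kinetics: one row per
#' reading, columns `experiment_id, compound, stage, replicate, time_min,
#' rfu, substrate_uM, inhibitor_uM, enzyme_u_per_mL, preincubation_min`.
#' `stage` labels the experiment class (`dose`, `mode`, `reversibility`,
#' `slowbind`). The reader validates types and units and reports malformed
#' rows by line number.
#'
#' @param df A kinetics data.frame in the schema above.
#' @param path File path.
#' @return `read_kinetics_csv` returns the validated data.frame (class
#'   `kinetics_data`); the writer returns the path invisibly.
#' @export
write_kinetics_csv <- function(df, path) {
  missing_cols <- setdiff(.kinetics_cols, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(df[.kinetics_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinetics_csv
#' @export
read_kinetics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty kinetics file: ", path)
  missing_cols <- setdiff(.kinetics_cols, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(.kinetics_cols, c("experiment_id", "compound", "stage"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop("non-numeric ", cl, " at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    if (anyNA(v))
      stop("missing ", cl, " at data row(s): ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    df[[cl]] <- v
  }
  for (cl in c("substrate_uM", "inhibitor_uM", "enzyme_u_per_mL",
               "preincubation_min")) {
    bad <- which(df[[cl]] < 0)
    if (length(bad))
      stop("negative ", cl, " at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(df$experiment_id, df$replicate, df$time_min)
  if (anyDuplicated(key))
    stop("duplicated (well, time) at data row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  class(df) <- c("kinetics_data", "data.frame")
  df
}

#' Write / read the quenching spectra CSV
#'
#' Schema: `compound, quencher_uM, replicate, wavelength_nm, intensity`.
#'
#' @param df A spectra data.frame in the schema above.
#' @param path File path.
#' @return `read_quench_csv` returns the validated data.frame; the writer
#'   returns the path invisibly.
#' @export
write_quench_csv <- function(df, path) {
  cols <- c("compound", "quencher_uM", "replicate", "wavelength_nm",
            "intensity")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(df[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quench_csv
#' @export
read_quench_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty quench file: ", path)
  cols <- c("compound", "quencher_uM", "replicate", "wavelength_nm",
            "intensity")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(df$quencher_uM < 0)) stop("negative quencher concentration")
  df
}

#' Write a ground-truth sidecar (JSON)
#'
#' Records the generating parameters of a synthetic study next to its CSVs
#' so recovery tests can compare estimates against truth.
#'
#' @param truths Named list of [assay_truth()] objects.
#' @param path File path.
#' @return `read_truth_sidecar` returns the named list of truths; the
#'   writer returns the path invisibly.
#' @export
write_truth_sidecar <- function(truths, path) {
  jsonlite::write_json(lapply(truths, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_truth_sidecar
#' @export
read_truth_sidecar <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) do.call(assay_truth, as.list(x)))
}

#' Simulate a complete multi-compound study
#'
#' Generates, for each compound truth, every experiment class the pipeline
#' consumes: a dose-response trace set (8 doubling inhibitor concentrations
#' bracketing the compound's IC50 plus a control), a substrate-by-inhibitor
#' mode grid (0.5x/1x/2x Km by 0 + 0.5x/1x/2x IC50), an enzyme-dilution
#' reversibility set (0.01/0.02/0.04 unit/mL), a slow-binding preincubation
#' set ([I] = 0/0.2/0.4/0.8 uM, t = 0-10 min by 2) for compounds with slow
#' onset, and quenching emission scans at [Q] = 0-3.2 uM doublings.
#'
#' @param truths Named list of [assay_truth()] objects (one per compound).
#' @param noise A [noise_spec()]; its seed governs the whole study.
#' @param slow_binding Character vector of compound names that get the
#'   preincubation experiment (default: none).
#' @param quench_model Generating model for the spectra.
#' @return A list with `kinetics` and `quench` data.frames (CSV schemas) and
#'   the `truths`.
#' @export
simulate_study <- function(truths, noise = noise_spec(),
                           slow_binding = character(0),
                           quench_model = "double_log") {
  stopifnot(is.list(truths), length(names(truths)) == length(truths))
  .apply_seed(noise)
  inner <- noise_spec(cv = noise$cv, replicates = noise$replicates,
                      seed = NULL)
  kin <- list(); qch <- list()
  trace_rows <- function(compound, stage, traces, cond_id) {
    do.call(rbind, lapply(traces, function(tr) data.frame(
      experiment_id = paste(compound, stage, cond_id, sep = "/"),
      compound = compound, stage = stage, replicate = tr$replicate,
      time_min = tr$times, rfu = tr$rfu, substrate_uM = tr$substrate,
      inhibitor_uM = tr$inhibitor, enzyme_u_per_mL = tr$enzyme,
      preincubation_min = tr$preincubation)))
  }
  for (cmp in names(truths)) {
    tr <- truths[[cmp]]
    # dose-response traces: doubling dilutions bracketing IC50, plus control
    doses <- c(0, tr$ic50 * 2^(-3:4))
    for (j in seq_along(doses)) {
      tl <- simulate_progress_trace(tr, substrate = tr$km,
                                    inhibitor = doses[j], noise = inner)
      kin[[length(kin) + 1L]] <- trace_rows(cmp, "dose", tl, j)
    }
    # mode grid
    grid <- expand.grid(s = tr$km * c(0.5, 1, 2),
                        i = c(0, 0.5, 1, 2) * tr$ic50)
    for (j in seq_len(nrow(grid))) {
      tl <- simulate_progress_trace(tr, substrate = grid$s[j],
                                    inhibitor = grid$i[j], noise = inner)
      kin[[length(kin) + 1L]] <- trace_rows(cmp, "mode", tl, j)
    }
    # reversibility
    rev_grid <- expand.grid(e = c(0.01, 0.02, 0.04),
                            i = c(0, 0.5, 1, 2) * tr$ic50)
    for (j in seq_len(nrow(rev_grid))) {
      tl <- simulate_progress_trace(tr, substrate = tr$km,
                                    inhibitor = rev_grid$i[j],
                                    enzyme = rev_grid$e[j], noise = inner)
      kin[[length(kin) + 1L]] <- trace_rows(cmp, "reversibility", tl, j)
    }
    # slow-binding preincubation series
    if (cmp %in% slow_binding) {
      sb_grid <- expand.grid(i = c(0, 0.2, 0.4, 0.8),
                             p = seq(0, 10, by = 2))
      for (j in seq_len(nrow(sb_grid))) {
        tl <- simulate_progress_trace(tr, substrate = tr$km,
                                      inhibitor = sb_grid$i[j],
                                      preincubation = sb_grid$p[j],
                                      noise = inner)
        kin[[length(kin) + 1L]] <- trace_rows(cmp, "slowbind", tl, j)
      }
    }
    # quenching spectra
    sp <- simulate_quenching(tr, model = quench_model, noise = inner)
    qch[[length(qch) + 1L]] <- data.frame(
      compound = cmp, quencher_uM = sp$quencher, replicate = sp$replicate,
      wavelength_nm = sp$wavelength, intensity = sp$intensity)
  }
  list(kinetics = do.call(rbind, kin), quench = do.call(rbind, qch),
       truths = truths)
}

# Velocities per condition from trace-level rows of one stage.
.stage_velocities <- function(rows, config) {
  keys <- unique(rows[c("experiment_id", "replicate", "substrate_uM",
                        "inhibitor_uM", "enzyme_u_per_mL",
                        "preincubation_min")])
  keys$velocity <- NA_real_
  for (j in seq_len(nrow(keys))) {
    sel <- rows$experiment_id == keys$experiment_id[j] &
      rows$replicate == keys$replicate[j]
    tr <- rows[sel, ]
    tr <- tr[order(tr$time_min), ]
    keys$velocity[j] <- estimate_velocity(
      list(times = tr$time_min, rfu = tr$rfu),
      r2_min = config$r2_linearity)$velocity
  }
  keys
}

#' Run the full analysis pipeline
#'
#' Turns a kinetics table (and optionally a quenching table) into
#' per-compound results: IC50 fit, inhibition mode with Ki (global fit plus
#' Lineweaver-Burk and Dixon cross-checks), reversibility verdict,
#' slow-binding constants where preincubation data exist, and quenching
#' parameters where spectra exist. Stage errors are collected per compound
#' and the pipeline continues.
#'
#' @param kinetics A `kinetics_data` data.frame (from [read_kinetics_csv()]
#'   or [simulate_study()]), or a path to a kinetics CSV.
#' @param quench Optional spectra data.frame or path to a quench CSV.
#' @param config A [study_config()].
#' @return A `study_report`: list of per-compound result lists
#'   (`ic50`, `mode`, `lineweaver_burk`, `dixon`, `reversibility`,
#'   `slow_binding`, `quenching`, `errors`) plus a `summary` data.frame.
#' @export
run_pipeline <- function(kinetics, quench = NULL, config = study_config()) {
  .validate_config(config)
  if (is.character(kinetics)) kinetics <- read_kinetics_csv(kinetics)
  if (is.character(quench)) quench <- read_quench_csv(quench)
  report <- list()
  for (cmp in unique(kinetics$compound)) {
    res <- list(errors = character(0))
    kc <- kinetics[kinetics$compound == cmp, ]
    try_stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        res$errors <<- c(res$errors, paste0(name, ": ", conditionMessage(e)))
        NULL
      })
    }
    dose_rows <- kc[kc$stage == "dose", ]
    if (nrow(dose_rows)) res$ic50 <- try_stage("ic50", {
      v <- .stage_velocities(dose_rows, config)
      v0 <- mean(v$velocity[v$inhibitor_uM == 0])
      agg <- tapply(v$velocity, v$inhibitor_uM, mean)
      conc <- as.numeric(names(agg))
      fit_ic50(conc, percent_inhibition(v0, as.numeric(agg)))
    })
    mode_rows <- kc[kc$stage == "mode", ]
    if (nrow(mode_rows)) {
      grid <- try_stage("mode", {
        v <- .stage_velocities(mode_rows, config)
        agg <- stats::aggregate(velocity ~ substrate_uM + inhibitor_uM, v,
                                mean)
        sdv <- stats::aggregate(velocity ~ substrate_uM + inhibitor_uM, v,
                                function(z) if (length(z) > 1)
                                  stats::sd(z) / sqrt(length(z)) else 0)
        rate_grid(data.frame(substrate = agg$substrate_uM,
                             inhibitor = agg$inhibitor_uM,
                             velocity = agg$velocity, se = sdv$velocity))
      })
      if (!is.null(grid)) {
        res$mode <- try_stage("mode", fit_global_inhibition(
          grid, delta = config$delta_score))
        res$lineweaver_burk <- try_stage("lineweaver_burk",
                                         lineweaver_burk(grid))
        res$dixon <- try_stage("dixon", dixon_ki(grid))
      }
    }
    rev_rows <- kc[kc$stage == "reversibility", ]
    if (nrow(rev_rows)) res$reversibility <- try_stage("reversibility", {
      v <- .stage_velocities(rev_rows, config)
      reversibility_test(data.frame(enzyme = v$enzyme_u_per_mL,
                                    inhibitor = v$inhibitor_uM,
                                    velocity = v$velocity),
                         z_threshold = config$z_threshold)
    })
    sb_rows <- kc[kc$stage == "slowbind", ]
    if (nrow(sb_rows)) res$slow_binding <- try_stage("slow_binding", {
      v <- .stage_velocities(sb_rows, config)
      kobs <- do.call(rbind, lapply(split(v, v$inhibitor_uM), function(g) {
        prof <- time_dependence_profile(g$preincubation_min, g$velocity)
        k <- fit_kobs(prof$profile$preincubation,
                      prof$profile$residual_activity)
        data.frame(inhibitor = g$inhibitor_uM[1], kobs = k$kobs, se = k$se)
      }))
      fit_rate_constants(kobs$inhibitor, kobs$kobs, kobs$se)
    })
    if (!is.null(quench)) {
      qc <- quench[quench$compound == cmp, ]
      if (nrow(qc)) res$quenching <- try_stage("quenching", {
        tt <- quench_titration(data.frame(quencher = qc$quencher_uM,
                                          replicate = qc$replicate,
                                          wavelength = qc$wavelength_nm,
                                          intensity = qc$intensity))
        list(stern_volmer = fit_stern_volmer(tt),
             double_log = fit_double_log(tt))
      })
    }
    report[[cmp]] <- res
  }
  structure(list(compounds = report,
                 summary = .report_summary(report)),
            class = "study_report")
}

.report_summary <- function(report) {
  do.call(rbind, lapply(names(report), function(cmp) {
    r <- report[[cmp]]
    data.frame(
      compound = cmp,
      ic50_uM = if (!is.null(r$ic50)) r$ic50$ic50 else NA_real_,
      mode = if (!is.null(r$mode)) r$mode$mode else NA_character_,
      ki_uM = if (!is.null(r$mode)) r$mode$ki else NA_real_,
      reversibility = if (!is.null(r$reversibility))
        r$reversibility$verdict else NA_character_,
      k3 = if (!is.null(r$slow_binding)) r$slow_binding$k3 else NA_real_,
      k4 = if (!is.null(r$slow_binding)) r$slow_binding$k4 else NA_real_,
      ki_app_uM = if (!is.null(r$slow_binding))
        r$slow_binding$ki_app else NA_real_,
      ksv_uM = if (!is.null(r$quenching))
        r$quenching$stern_volmer$ksv else NA_real_,
      ka_uM = if (!is.null(r$quenching))
        r$quenching$double_log$ka else NA_real_,
      n_sites = if (!is.null(r$quenching))
        r$quenching$double_log$n_sites else NA_real_,
      n_errors = length(r$errors))
  }))
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (", length(x$compounds), " compound(s))\n", sep = "")
  print(x$summary, digits = 4)
  for (cmp in names(x$compounds)) {
    errs <- x$compounds[[cmp]]$errors
    if (length(errs))
      cat("  ", cmp, " errors: ", paste(errs, collapse = "; "), "\n",
          sep = "")
  }
  invisible(x)
}
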