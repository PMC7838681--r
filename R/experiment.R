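# Ensemble experiment driver: per-stage simulations and the spectral and
# statistical indices (HR, LF, HF, SP, DP, lambda0) with mean +/- SEM.

#' Run a sleep-stage ensemble experiment
#'
#' Runs `n_runs` independent simulations of one stage (seeds `base_seed`,
#' `base_seed + 1`, ...), each with a 1000 s transient followed by a
#' 20-minute analysis stretch, and computes per-run indices:
#' heart rate (60 / mean IBI), mean per-beat systolic and diastolic
#' pressure, LF and HF band powers of the 4-Hz-resampled IBI series, and
#' (optionally) the largest Lyapunov exponent of the 0.05-0.4 Hz
#' band-passed series in 1000 s windows.
#'
#' @param stage `"awake"`, `"rem"` or `"nrem"`.
#' @param n_runs ensemble size (>= 2; default 20).
#' @param base_seed seed of the first run.
#' @param duration,transient,dt simulation settings, see [simulate_cvs()].
#' @param lyapunov logical; compute the Lyapunov exponent per run (the
#'   slowest index).
#' @param lyapunov_unit `"per_second"` or `"per_sample"`; scale on which
#'   `lambda0` is reported in the summary (the estimate object always
#'   carries both). See the methods vignette.
#' @param seeds optional integer vector of length `n_runs` overriding the
#'   consecutive `base_seed` rule (duplicated seeds give duplicated runs
#'   and an SEM of zero).
#' @param ... further arguments passed to [simulate_cvs()].
#'
#' @return An object of class `stage_report`: list with `stage`, `n_runs`,
#'   `per_run` (data frame of per-run indices) and `summary` (data frame
#'   with `index`, `mean`, `sem`).
#' @export
run_stage_experiment <- function(stage, n_runs = 20, base_seed = 1,
                                 duration = 2200, transient = 1000,
                                 dt = 0.001, lyapunov = TRUE,
                                 lyapunov_unit = c("per_sample", "per_second"),
                                 seeds = NULL, ...) {
  stopifnot(n_runs >= 2)
  lyapunov_unit <- match.arg(lyapunov_unit)
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_runs) - 1
  stopifnot(length(seeds) == n_runs)
  runs <- lapply(seq_len(n_runs), function(i) {
    seed <- seeds[i]
    sim <- tryCatch(
      simulate_cvs(stage, duration = duration, transient = transient,
                   dt = dt, seed = seed, ...),
      error = function(e) stop("run ", i, " (seed ", seed, ") failed: ",
                               conditionMessage(e)))
    s <- simulation_summary(sim)
    ser <- resample_ibi(ibi_series(sim))
    sx <- lf_hf(ser)
    lam <- NA_real_
    if (lyapunov) {
      est <- suppressWarnings(
        rosenstein_lyapunov(bandpass_ibi(ser), dim = 13, window_s = 1000))
      lam <- if (lyapunov_unit == "per_sample") est$lambda0_per_sample
             else est$lambda0
    }
    data.frame(run = i, seed = seed, hr_bpm = s$hr_bpm,
               sp_mmHg = s$sp_mmHg, dp_mmHg = s$dp_mmHg,
               lf_ms2 = sx$lf, hf_ms2 = sx$hf, lambda0 = lam)
  })
  per_run <- do.call(rbind, runs)
  idx <- c("hr_bpm", "lf_ms2", "hf_ms2", "sp_mmHg", "dp_mmHg", "lambda0")
  summ <- data.frame(
    index = idx,
    mean = vapply(idx, function(i) mean(per_run[[i]]), numeric(1)),
    sem = vapply(idx, function(i) sd(per_run[[i]]) / sqrt(n_runs), numeric(1)),
    row.names = NULL
  )
  structure(list(stage = stage, n_runs = n_runs, base_seed = base_seed,
                 lyapunov_unit = lyapunov_unit,
                 per_run = per_run, summary = summ),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat("<stage_report>", x$stage, "| n =", x$n_runs, "runs\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s %10.4g +/- %.3g\n", s$index[i], s$mean[i], s$sem[i]))
  }
  invisible(x)
}

#' Reference stage indices of the model
#'
#' The published per-stage model indices (mean +/- SEM): heart rate, LF and
#' HF band powers, systolic and diastolic pressure, and the largest
#' Lyapunov exponent, for the awake state, REM sleep and stage-4 non-REM
#' sleep. Shipped as a plain-text table in `inst/extdata`.
#'
#' @return data frame with columns `stage`, `index`, `mean`, `sem`.
#' @export
reference_table2 <- function() {
  f <- system.file("extdata", "reference_stage_indices.csv",
                   package = "cvsleep", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Compare a stage report against reference indices
#'
#' Tabulates model ensemble means against the reference values with
#' relative deviations, flagging any deviation beyond `tolerance`.
#'
#' @param report a `stage_report`.
#' @param reference a data frame as returned by [reference_table2()].
#' @param tolerance named or scalar relative tolerance(s) for flagging
#'   (default 0.25).
#' @return data frame with `index`, `model`, `reference`, `deviation`
#'   (relative) and `flag`.
#' @export
compare_report <- function(report, reference = reference_table2(),
                           tolerance = 0.25) {
  stopifnot(inherits(report, "stage_report"))
  ref <- reference[reference$stage == report$stage, ]
  if (nrow(ref) == 0) stop("no reference rows for stage ", report$stage)
  s <- report$summary
  s <- s[is.finite(s$mean), ]  # indices not computed (e.g. lyapunov = FALSE)
  missing_idx <- setdiff(s$index, ref$index)
  if (length(missing_idx)) {
    stop("reference is missing indices: ", paste(missing_idx, collapse = ", "))
  }
  m <- merge(s, ref[, c("index", "mean")], by = "index",
             suffixes = c("_model", "_ref"))
  tol <- if (length(tolerance) == 1) rep(tolerance, nrow(m)) else
    tolerance[m$index]
  dev <- (m$mean_model - m$mean_ref) / abs(m$mean_ref)
  data.frame(index = m$index, model = m$mean_model, reference = m$mean_ref,
             deviation = dev, flag = abs(dev) > tol)
}
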