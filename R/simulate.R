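#' Simulate the cardiovascular model
#'
#' Advances the coupled delay-differential system with a fixed-step RK4
#' scheme (1 ms default): integrate-and-fire sinoatrial phase, pulsatile
#' systolic pressure followed by Windkessel diastolic decay, noradrenaline
#' kinetics driven by delayed sympathetic activity, and a phase-gated
#' delayed parasympathetic factor. Heartbeats are located by linear
#' interpolation of the phase-1 crossing inside the step; cycle bookkeeping
#' (pressure capture, cycle length, per-cycle noise redraw, systole entry)
#' switches at the step boundary.
#'
#' Two stochastic inputs drive the variability: a 1/f perturbation of the
#' intrinsic period, redrawn at each beat ([pink_noise()]), and a Gaussian
#' perturbation of the respiratory period, redrawn at each respiratory
#' cycle ([respiratory_jitter()]).
#'
#' @param stage sleep stage preset: `"awake"`, `"rem"` or `"nrem"`.
#' @param duration total simulated time (s). Must exceed `transient` by at
#'   least 60 s.
#' @param dt integration step (s); the default 1 ms resolves the 0.125 s
#'   systole and all delays.
#' @param transient initial stretch (s) flagged as transient and excluded
#'   from the post-transient accessors and summaries (default 1000).
#' @param seed integer seed for both noise streams; `NULL` uses the current
#'   RNG state.
#' @param params model constants, see [cvs_parameters()].
#' @param preset cortical-input preset; defaults to `sleep_preset(stage)`.
#' @param systolic_form systolic pulse kernel, `"peaked"` (default) or
#'   `"literal"`; see [systolic_pressure()].
#' @param sympathetic_form operating-point convention of the sympathetic
#'   sigmoid, `"centered"` (default) or `"printed"`; see
#'   [sympathetic_activity()].
#' @param noise logical; `FALSE` switches both noise sources off.
#' @param denervated logical; `TRUE` clamps both autonomic factors to 1 so
#'   the node fires at its intrinsic period (pressure dynamics still run).
#' @param p_init initial arterial pressure (mmHg).
#' @param keep_traces logical; keep the full state traces (pressure, phase,
#'   noradrenaline concentrations, loop activities, respiration) sampled
#'   every `trace_every` steps.
#' @param trace_every trace decimation factor (steps).
#'
#' @return An object of class `cvs_simulation`: a list with `beat_times`
#'   (s), `ibi` (s, `diff(beat_times)`), per-cycle `sp` and `dp` pressure
#'   extrema (mmHg), optionally `trace` (data frame), and the echoed
#'   `settings`, `params`, `preset`, `stage` and `seed`.
#'
#' @examples
#' \donttest{
#' sim <- simulate_cvs("awake", duration = 1260, transient = 60, seed = 1)
#' sim
#' }
#' @export
simulate_cvs <- function(stage = c("awake", "rem", "nrem"),
                         duration = 2200, dt = 0.001, transient = 1000,
                         seed = NULL,
                         params = cvs_parameters(),
                         preset = sleep_preset(stage),
                         systolic_form = c("peaked", "literal"),
                         sympathetic_form = c("centered", "printed"),
                         noise = TRUE, denervated = FALSE,
                         p_init = 80, keep_traces = FALSE, trace_every = 1L) {
  stage <- match.arg(stage)
  systolic_form <- match.arg(systolic_form)
  sympathetic_form <- match.arg(sympathetic_form)
  stopifnot(duration >= transient + 60, dt > 0, transient >= 0)
  validate_cvs_parameters(params)

  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  n_xi <- ceiling(duration / 0.25) + 64L
  n_zeta <- ceiling(duration / 0.5) + 16L
  if (noise) {
    xi <- pink_noise(n_xi, params$xi_var)
    zeta <- respiratory_jitter(n_zeta, params$zeta_var)
  } else {
    xi <- numeric(n_xi)
    zeta <- numeric(n_zeta)
  }

  res <- cvs_simulate_cpp(unclass(params), unclass(preset), duration, dt,
                          xi, zeta,
                          peaked = systolic_form == "peaked",
                          centered = sympathetic_form == "centered",
                          denervated = denervated,
                          p_init = p_init,
                          record_traces = keep_traces,
                          trace_every = as.integer(trace_every))
  if (nzchar(res$error)) {
    stop("simulation failed at t = ", signif(res$error_time, 6), " s: ",
         res$error)
  }

  out <- list(
    beat_times = res$beat_times,
    ibi = diff(res$beat_times),
    sp = res$sp,
    dp = res$dp,
    trace = if (keep_traces) res$trace else NULL,
    stage = stage,
    seed = seed,
    params = params,
    preset = preset,
    settings = list(duration = duration, dt = dt, transient = transient,
                    systolic_form = systolic_form,
                    sympathetic_form = sympathetic_form,
                    noise = noise, denervated = denervated, p_init = p_init)
  )
  class(out) <- "cvs_simulation"
  out
}

#' @export
print.cvs_simulation <- function(x, ...) {
  tr <- x$settings$transient
  keep <- x$beat_times > tr
  ib <- x$ibi[x$beat_times[-1] > tr]
  cat("<cvs_simulation> stage:", x$stage,
      " duration:", x$settings$duration, "s (transient", tr, "s)\n")
  cat(sprintf("  beats: %d post-transient | HR %.1f bpm | SP %.1f / DP %.1f mmHg\n",
              sum(x$beat_times[-1] > tr),
              60 / mean(ib),
              mean(x$sp[keep]), mean(x$dp[keep])))
  invisible(x)
}

#' Post-transient summary statistics of a simulation
#'
#' Heart rate (60 / mean interbeat interval), mean per-beat systolic and
#' diastolic pressure, and beat count, all restricted to beats after the
#' transient.
#'
#' @param sim a `cvs_simulation`.
#' @return named list with `hr_bpm`, `sp_mmHg`, `dp_mmHg`, `n_beats`.
#' @export
simulation_summary <- function(sim) {
  stopifnot(inherits(sim, "cvs_simulation"))
  tr <- sim$settings$transient
  keep_cycle <- sim$beat_times > tr
  ib <- sim$ibi[sim$beat_times[-1] > tr]
  list(hr_bpm = 60 / mean(ib),
       sp_mmHg = mean(sim$sp[keep_cycle]),
       dp_mmHg = mean(sim$dp[keep_cycle]),
       n_beats = length(ib))
}
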