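#' Default model parameters
#'
#' Returns the full set of stage-independent constants of the cardiovascular
#' model: intrinsic pacemaker period, contractility constants, Windkessel
#' time constant, baroreceptor sensitivities, sigmoid transfer parameters of
#' the two sympathetic loops, noradrenaline kinetics with their conduction
#' delays, the parasympathetic pathway constants, and the noise variances.
#'
#' Units are seconds, mmHg and dimensionless gains; each default is the
#' published operating value for a healthy resting subject. `t_sys` is
#' 0.125 s (the printed parameter table carries an evident copy of the noise
#' variance in that row; the running text states 0.125 s). `t0` is the 1.1 s
#' period of the denervated heart.
#'
#' @param ... named overrides of individual parameters, e.g. `t0 = 1.5`.
#'
#' @return A named list of class `cvs_parameters`.
#'
#' @details Parameter groups:
#' \describe{
#'   \item{pacemaker}{`t0` (s) intrinsic heart period; `xi_var` (s^2)
#'     variance of the 1/f noise perturbing the period.}
#'   \item{contractility}{`s_hat` (mmHg) resting contractility ceiling,
#'     `s0` (mmHg) denervated contractility, `k_sc`, `k_sv` (mmHg)
#'     noradrenaline sensitivities, `k_st` (mmHg/s) cycle-length
#'     sensitivity, `n_c` saturation exponent.}
#'   \item{pressure}{`t_sys` (s) systolic duration, `r0c` (s) unstressed
#'     Windkessel time constant, `k_Rv` vascular noradrenaline gain on
#'     peripheral resistance, `k_pB` respiratory amplitude on pressure.}
#'   \item{respiration}{`t_br` (s) mean respiratory period, `zeta_var`
#'     (s^2) per-cycle period jitter variance.}
#'   \item{baroreceptors}{`p0`, `p0l` (mmHg) thresholds; `k1`, `k1l`
#'     (1/mmHg) and `k2`, `k2l` (s/mmHg) sensitivities for the carotid and
#'     lower-body nodes.}
#'   \item{sympathetic loops}{`a_s`, `b_s`, `y_s` (heart) and `a_sl`,
#'     `b_sl`, `y_sl` (vessel) sigmoid constants; `v_s0`, `v_sl0` resting
#'     afferent tones; `k_sr`, `k_slr` respiratory couplings.}
#'   \item{noradrenaline}{`tau_c`, `tau_v` (s) time constants; `theta_c`,
#'     `theta_v` (s) delays; `k_cS`, `k_vS`, `k_v` transfer coefficients.}
#'   \item{parasympathetic}{`v_p0` resting tone, `k_pb` baroreceptor gain,
#'     `k_pr` respiratory gain, `theta_p` (s) delay, `k_phip`, `v_hat_p`,
#'     `n_p` factor constants.}
#'   \item{sympathetic factor}{`k_phic`, `c_hat_c`, `n_s`.}
#' }
#'
#' @examples
#' p <- cvs_parameters()
#' p$t0
#' cvs_parameters(t0 = 1.5)$t0
#' @export
cvs_parameters <- function(...) {
  p <- list(
    # pacemaker
    t0 = 1.1, xi_var = 0.02,
    # contractility
    s_hat = 40, s0 = -13.8, k_sc = 10, k_sv = 20, k_st = 45, n_c = 2.5,
    # pressure
    t_sys = 0.125, r0c = 2.0, k_Rv = 1.2, k_pB = 4,
    # respiration
    t_br = 3.57, zeta_var = 0.3,
    # baroreceptors
    p0 = 50, p0l = 50, k1 = 0.05, k2 = 0.001, k1l = 0.05, k2l = 0.001,
    # sympathetic loops
    a_s = -1, b_s = 0.44, y_s = -0.25, a_sl = -1, b_sl = 0.44, y_sl = -0.25,
    v_s0 = 4, v_sl0 = 4, k_sr = 0.1, k_slr = 0.1,
    # noradrenaline kinetics
    tau_c = 2, tau_v = 2, theta_c = 1.5, theta_v = 2.5,
    k_cS = 0.04, k_vS = 0.52, k_v = 0.2,
    # parasympathetic pathway
    v_p0 = -0.5, k_pb = 0.44, k_pr = 0.1, theta_p = 0.25,
    k_phip = 3.75, v_hat_p = 2.5, n_p = 2,
    # sympathetic factor
    k_phic = 3.7, c_hat_c = 2, n_s = 2
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  validate_cvs_parameters(p)
  structure(p, class = "cvs_parameters")
}

validate_cvs_parameters <- function(p) {
  stopifnot(
    p$t_sys < p$t0,
    p$tau_c > 0, p$tau_v > 0, p$r0c > 0,
    p$theta_c >= 0, p$theta_v >= 0, p$theta_p >= 0,
    p$n_c > 0, p$n_s > 0, p$n_p > 0,
    p$xi_var >= 0, p$zeta_var >= 0,
    p$t_br > 0, p$t0 > 0
  )
  invisible(p)
}

#' Higher-nervous-centre input presets for the sleep stages
#'
#' The eight cortical-input parameters that shift the autonomic loops
#' between the awake state, REM sleep and stage-4 non-REM sleep. All eight
#' are zero in the awake state; the sleep values reduce sympathetic drive
#' (`c_sb`, `c_slb`, `c_sv`, `c_slv`, `c_phis`) and raise or retune vagal
#' drive (`c_pv`, `c_pk`, `c_phip`).
#'
#' @param stage `"awake"`, `"rem"` or `"nrem"` (stage-4 non-REM).
#'
#' @return A named list of class `cvs_preset` with fields `c_sb`, `c_slb`,
#'   `c_sv`, `c_slv`, `c_pv`, `c_pk`, `c_phis`, `c_phip` and a `stage`
#'   attribute.
#'
#' @examples
#' sleep_preset("awake")   # all zero
#' sleep_preset("nrem")$c_pv
#' @export
sleep_preset <- function(stage = c("awake", "rem", "nrem")) {
  stage <- match.arg(stage)
  v <- switch(stage,
    awake = c(c_sb = 0,      c_slb = 0,      c_sv = 0,    c_slv = 0,
              c_pv = 0,      c_pk = 0,       c_phis = 0,  c_phip = 0),
    rem   = c(c_sb = -0.015, c_slb = -0.015, c_sv = -0.1, c_slv = -0.1,
              c_pv = 0.2,    c_pk = -0.09,   c_phis = -0.2, c_phip = -0.15),
    nrem  = c(c_sb = -0.01,  c_slb = -0.01,  c_sv = -0.5, c_slv = -0.5,
              c_pv = 0.6,    c_pk = -0.19,   c_phis = -0.2, c_phip = 0)
  )
  structure(as.list(v), class = "cvs_preset", stage = stage)
}
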