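# Pure, stateless evaluations of the model equations. These are the
# reference implementations; the compiled integrator mirrors them and is
# checked against their closed forms in the test suite.

#' Respiratory signal
#'
#' The respiratory drive is a unit sinusoid of the respiratory phase. The
#' phase is accumulated cycle by cycle with a jittered period (see
#' [respiratory_jitter()]), so an explicit phase argument is used here
#' rather than clock time.
#'
#' @param resp_phase respiratory phase in radians.
#' @return `sin(resp_phase)`, bounded in \[-1, 1\].
#' @examples
#' respiratory_signal(pi / 2)
#' @export
respiratory_signal <- function(resp_phase) sin(resp_phase)

#' Cardiac contractility
#'
#' Linear contractility `S' = s0 + k_sc*c_c + k_sv*c_v + k_st*l_prev`
#' saturated towards the resting ceiling `s_hat`:
#' `S = S' + (s_hat - S') * S'^n_c / (s_hat^n_c + S'^n_c)`.
#' For non-positive `S'` the saturation term (undefined for fractional
#' `n_c`) is skipped and `S'` is returned; the branch lies far outside the
#' operating regime.
#'
#' @param c_c,c_v cardiac and vascular noradrenaline concentrations
#'   (dimensionless).
#' @param l_prev previous cardiac cycle length (s), must be positive.
#' @param params a [cvs_parameters()] list.
#' @return contractility in mmHg.
#' @examples
#' cardiac_contractility(2, 1, 1, cvs_parameters())  # ~46 mmHg
#' @export
cardiac_contractility <- function(c_c, c_v, l_prev, params = cvs_parameters()) {
  stopifnot(all(l_prev > 0))
  sp <- params$s0 + params$k_sc * c_c + params$k_sv * c_v + params$k_st * l_prev
  ifelse(sp <= 0, sp, {
    sn <- sp^params$n_c
    sp + (params$s_hat - sp) * sn / (params$s_hat^params$n_c + sn)
  })
}

#' Systolic pressure pulse
#'
#' Pressure during the systolic phase of the cycle, launched from the
#' end-diastolic pressure of the previous cycle. With `x = t_elapsed/t_sys`,
#' the default (`form = "peaked"`) pulse kernel is `S * x * exp(1 - x)`,
#' which peaks at exactly `d_prev + S + k_pB * B` at the end of systole. The
#' alternative `form = "literal"` kernel `S * x * exp(x)` overshoots the
#' contractility scale by a factor `e` and is provided for comparison only;
#' see the methods vignette for the rationale.
#'
#' @param t_elapsed time since the start of the current cycle (s), in
#'   `[0, t_sys]`.
#' @param d_prev pressure at the end of the previous cycle (mmHg).
#' @param S current cardiac contractility (mmHg).
#' @param B respiratory signal (dimensionless).
#' @param params a [cvs_parameters()] list.
#' @param form pulse kernel, `"peaked"` (default) or `"literal"`.
#' @return pressure in mmHg.
#' @examples
#' systolic_pressure(0.125, 75, 36, 0, cvs_parameters())  # 111 mmHg
#' @export
systolic_pressure <- function(t_elapsed, d_prev, S, B, params = cvs_parameters(),
                              form = c("peaked", "literal")) {
  form <- match.arg(form)
  if (any(t_elapsed < 0 | t_elapsed > params$t_sys)) {
    stop("t_elapsed must lie in [0, t_sys]")
  }
  x <- t_elapsed / params$t_sys
  kern <- if (form == "peaked") x * exp(1 - x) else x * exp(x)
  d_prev + S * kern + params$k_pB * B
}

#' Windkessel time constant of the peripheral vessels
#'
#' `R(t) C = r0c * (1 + k_Rv * c_v)`: the product of peripheral resistance,
#' modulated by vascular noradrenaline, and aortic compliance.
#'
#' @inheritParams cardiac_contractility
#' @return time constant in seconds.
#' @examples
#' peripheral_resistance_time_constant(0, cvs_parameters())  # 2 s
#' @export
peripheral_resistance_time_constant <- function(c_v, params = cvs_parameters()) {
  rc <- params$r0c * (1 + params$k_Rv * c_v)
  if (any(rc <= 0)) stop("non-positive Windkessel time constant: unphysical parameters")
  rc
}

#' Diastolic pressure derivative (Windkessel decay)
#'
#' `dp/dt = -p / (R(t) C)`, active during diastole.
#'
#' @param p current arterial pressure (mmHg).
#' @inheritParams cardiac_contractility
#' @return derivative in mmHg/s.
#' @export
diastolic_derivative <- function(p, c_v, params = cvs_parameters()) {
  -p / peripheral_resistance_time_constant(c_v, params)
}

#' Baroreceptor activity
#'
#' Afferent activity of a baroreceptor node sensing pressure and its rate
#' of change: `v_b = k1 * (p - p0) + k2 * dp/dt`. Not clipped; negative
#' below threshold.
#'
#' @param p arterial pressure (mmHg).
#' @param dpdt pressure derivative (mmHg/s).
#' @param params a [cvs_parameters()] list.
#' @param node `"carotid"` or `"lower_body"`, selecting the node's own
#'   `(k1, k2, p0)` set.
#' @return dimensionless afferent activity.
#' @examples
#' baroreceptor_activity(110, 0, cvs_parameters())  # 3
#' @export
baroreceptor_activity <- function(p, dpdt, params = cvs_parameters(),
                                  node = c("carotid", "lower_body")) {
  node <- match.arg(node)
  if (node == "carotid") {
    params$k1 * (p - params$p0) + params$k2 * dpdt
  } else {
    params$k1l * (p - params$p0l) + params$k2l * dpdt
  }
}

#' Sympathetic loop activity
#'
#' Sigmoidal transfer of baroreceptor input to sympathetic outflow, with
#' cortical inputs shifting the slope and operating point and a direct
#' respiratory coupling. Two readings of the operating-point shift are
#' supported:
#' \describe{
#'   \item{`"centered"` (default)}{`a * tanh((b + C_b) * (v_b - v_0)) -
#'     C_v ... ` i.e. the resting afferent tone `v_0` recentres the
#'     baroreceptor input before the sigmoid:
#'     `v_s = a * tanh((b + C_b) * (v_b - v_0) - C_v) + y + k_r * B`. This
#'     places the reflex's linear range at physiological pressures and is
#'     the form under which the model reproduces its published stage
#'     indices; see the methods vignette.}
#'   \item{`"printed"`}{`v_s = a * tanh((b + C_b) * v_b - C_v - v_0) + y +
#'     k_r * B`, with the tone subtracted inside the sigmoid argument
#'     unscaled.}
#' }
#' Delays are applied downstream, in the noradrenaline kinetics.
#'
#' @param v_b baroreceptor activity (dimensionless).
#' @param B respiratory signal.
#' @param preset a [sleep_preset()] list.
#' @param params a [cvs_parameters()] list.
#' @param loop `"heart"` or `"vessel"`.
#' @param form sigmoid operating-point convention, see Details.
#' @return dimensionless sympathetic activity.
#' @examples
#' sympathetic_activity(0, 0, sleep_preset("awake"), form = "printed")  # ~0.7493
#' @export
sympathetic_activity <- function(v_b, B, preset = sleep_preset("awake"),
                                 params = cvs_parameters(),
                                 loop = c("heart", "vessel"),
                                 form = c("centered", "printed")) {
  loop <- match.arg(loop)
  form <- match.arg(form)
  if (loop == "heart") {
    a <- params$a_s; b <- params$b_s; y <- params$y_s
    v0 <- params$v_s0; kr <- params$k_sr
    cb <- preset$c_sb; cv <- preset$c_sv
  } else {
    a <- params$a_sl; b <- params$b_sl; y <- params$y_sl
    v0 <- params$v_sl0; kr <- params$k_slr
    cb <- preset$c_slb; cv <- preset$c_slv
  }
  arg <- if (form == "printed") (b + cb) * v_b - cv - v0 else (b + cb) * (v_b - v0) - cv
  a * tanh(arg) + y + kr * B
}

#' Parasympathetic activity
#'
#' Rectified linear combination of baroreceptor input and rectified
#' respiration: `v_p = max(0, c_pv + v_p0 + (c_pk + k_pb) * v_b +
#' k_pr * |B|)`. Always non-negative.
#'
#' @inheritParams sympathetic_activity
#' @return dimensionless parasympathetic activity (>= 0).
#' @examples
#' parasympathetic_activity(3, 0, sleep_preset("awake"))  # 0.82
#' @export
parasympathetic_activity <- function(v_b, B, preset = sleep_preset("awake"),
                                     params = cvs_parameters()) {
  pmax(0, preset$c_pv + params$v_p0 + (preset$c_pk + params$k_pb) * v_b +
         params$k_pr * abs(B))
}

#' Noradrenaline concentration derivative
#'
#' First-order washout driven by delayed sympathetic activity. Cardiac
#' compartment: `dc/dt = -c/tau_c + k_cS * v_s(t - theta_c)`; vascular:
#' `dc/dt = -c/tau_v + k_vS * (v_sl(t - theta_v) + k_v)`. The caller
#' supplies the already-delayed activity.
#'
#' @param c current concentration (dimensionless).
#' @param v_delayed delayed sympathetic activity.
#' @param params a [cvs_parameters()] list.
#' @param compartment `"cardiac"` or `"vascular"`.
#' @return derivative in 1/s.
#' @export
noradrenaline_derivative <- function(c, v_delayed, params = cvs_parameters(),
                                     compartment = c("cardiac", "vascular")) {
  compartment <- match.arg(compartment)
  if (compartment == "cardiac") {
    -c / params$tau_c + params$k_cS * v_delayed
  } else {
    -c / params$tau_v + params$k_vS * (v_delayed + params$k_v)
  }
}

#' Sympathetic factor on the pacemaker
#'
#' `f_s = 1 + (c_phis + k_phic) * (c_c + (c_hat_c - c_c) * c_c^n_s /
#' (c_hat_c^n_s + c_c^n_s))`; equals 1 for `c_c = 0`. For transiently
#' negative `c_c` the saturation term is skipped (linear branch), matching
#' the contractility convention.
#'
#' @inheritParams sympathetic_activity
#' @param c_c cardiac noradrenaline concentration.
#' @return dimensionless factor.
#' @examples
#' sympathetic_factor(0, sleep_preset("awake"))  # 1
#' @export
sympathetic_factor <- function(c_c, preset = sleep_preset("awake"),
                               params = cvs_parameters()) {
  coef <- preset$c_phis + params$k_phic
  sat <- ifelse(c_c <= 0, c_c, {
    cn <- c_c^params$n_s
    c_c + (params$c_hat_c - c_c) * cn / (params$c_hat_c^params$n_s + cn)
  })
  1 + coef * sat
}

#' Parasympathetic factor on the pacemaker
#'
#' `f_p = 1 + (c_phip + k_phip) * g(v_p(t - theta_p)) * F(phi)`, where `g`
#' saturates the delayed vagal activity towards `v_hat_p` and `F` is the
#' phase effectiveness curve: vagal input only acts in the sensitive part
#' of the cycle.
#'
#' @inheritParams sympathetic_activity
#' @param v_p_delayed delayed parasympathetic activity (>= 0).
#' @param phi cardiac cycle phase in `[0, 1]`.
#' @return dimensionless factor.
#' @export
parasympathetic_factor <- function(v_p_delayed, phi, preset = sleep_preset("awake"),
                                   params = cvs_parameters()) {
  stopifnot(all(v_p_delayed >= 0))
  vn <- v_p_delayed^params$n_p
  g <- v_p_delayed + (params$v_hat_p - v_p_delayed) * vn /
    (params$v_hat_p^params$n_p + vn)
  1 + (preset$c_phip + params$k_phip) * g * phase_effectiveness(phi)
}

#' Phase effectiveness curve
#'
#' Phase-dependent sensitivity of the sinoatrial node to vagal input within
#' one cycle: `F(phi) = phi^1.3 * (phi - 0.45) * (1 - phi)^3 / (0.008 +
#' (1 - phi)^3)`. Roots at 0, 0.45 and 1; negative (phase delay) early in
#' the cycle, positive (phase advance) late.
#'
#' @param phi cardiac cycle phase in `[0, 1]`.
#' @return dimensionless effectiveness.
#' @examples
#' phase_effectiveness(c(0, 0.45, 1))  # all zero
#' @export
phase_effectiveness <- function(phi) {
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  om3 <- (1 - phi)^3
  phi^1.3 * (phi - 0.45) * om3 / (0.008 + om3)
}

#' Pacemaker phase derivative
#'
#' `dphi/dt = f_s * f_p / (t0 + xi)`. With noise off and both autonomic
#' factors equal to one the node fires strictly periodically with period
#' `t0`.
#'
#' @param xi current per-cycle period perturbation (s).
#' @param f_s,f_p sympathetic and parasympathetic factors.
#' @param params a [cvs_parameters()] list.
#' @return phase rate in 1/s.
#' @examples
#' phase_derivative(0, 1, 1, cvs_parameters())  # 1/1.1
#' @export
phase_derivative <- function(xi, f_s, f_p, params = cvs_parameters()) {
  period <- params$t0 + xi
  if (any(period <= 0)) stop("non-positive effective period t0 + xi")
  f_s * f_p / period
}
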