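# Independent oracles used across the suite.

# fully chaotic logistic map trajectory
logistic_series <- function(n, x0 = 0.3) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

# Lorenz-63 trajectory by plain RK4 (sigma=10, rho=28, beta=8/3)
lorenz_series <- function(n, dt = 0.01, state = c(1, 1, 20), discard = 2000) {
  f <- function(s) c(10 * (s[2] - s[1]),
                     s[1] * (28 - s[3]) - s[2],
                     s[1] * s[2] - 8 / 3 * s[3])
  rk4 <- function(s, h) {
    k1 <- f(s); k2 <- f(s + h / 2 * k1); k3 <- f(s + h / 2 * k2); k4 <- f(s + h * k3)
    s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out <- numeric(n)
  for (i in seq_len(discard)) state <- rk4(state, dt)
  for (i in seq_len(n)) { state <- rk4(state, dt); out[i] <- state[1] }
  out
}

# tangent-space (Benettin) largest Lyapunov exponent of Lorenz-63:
# integrate the flow and its linearisation, renormalising the perturbation
benettin_lorenz_lambda <- function(n_steps = 60000, dt = 0.01) {
  f <- function(s) c(10 * (s[2] - s[1]),
                     s[1] * (28 - s[3]) - s[2],
                     s[1] * s[2] - 8 / 3 * s[3])
  jac <- function(s) matrix(c(-10, 10, 0,
                              28 - s[3], -1, -s[1],
                              s[2], s[1], -8 / 3), 3, 3, byrow = TRUE)
  rk4 <- function(g, s, h) {
    k1 <- g(s); k2 <- g(s + h / 2 * k1); k3 <- g(s + h / 2 * k2); k4 <- g(s + h * k3)
    s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s <- c(1, 1, 20)
  for (i in 1:2000) s <- rk4(f, s, dt)
  v <- c(1, 0, 0)
  acc <- 0
  for (i in seq_len(n_steps)) {
    s_new <- rk4(f, s, dt)
    # tangent step with the Jacobian frozen at the segment start (adequate at dt = 0.01)
    gv <- function(z) as.numeric(jac(s) %*% z)
    v <- rk4(gv, v, dt)
    s <- s_new
    nv <- sqrt(sum(v^2))
    acc <- acc + log(nv)
    v <- v / nv
  }
  acc / (n_steps * dt)
}

# log-log least-squares slope of the raw periodogram of x
periodogram_slope <- function(x, f_max = 0.1) {
  n <- length(x)
  p <- Mod(fft(x - mean(x))[2:(n %/% 2)])^2
  f <- (1:(n %/% 2 - 1)) / n
  keep <- f <= f_max
  unname(coef(lm(log10(p[keep]) ~ log10(f[keep])))[2])
}

# default model parameters / presets shared by many tests
tab_params <- cvs_parameters()
awake <- sleep_preset("awake")
nrem <- sleep_preset("nrem")
rem <- sleep_preset("rem")
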