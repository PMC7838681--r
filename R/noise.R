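# Stochastic inputs of the model: 1/f ("pink") noise perturbing the
# intrinsic heart period, and per-cycle Gaussian respiratory-period jitter.

#' Pink (1/f) noise sequence
#'
#' Frequency-domain synthesis: a white complex Gaussian spectrum is shaped
#' by `1/sqrt(f)`, inverse-transformed, and the real part rescaled to the
#' requested sample variance. The result is zero-mean with a log-log power
#' spectral density slope of about -1 over the resolved band, and exhibits
#' the long-range positive autocorrelation characteristic of 1/f processes.
#'
#' One value is consumed per cardiac cycle by the simulator, standing in
#' for humoral and other unaccounted slow influences on heart rate.
#'
#' @param n number of samples (>= 1).
#' @param variance target sample variance in s^2 (default 0.02, the model's
#'   operating value).
#' @param seed optional integer; if given, the R RNG is seeded locally and
#'   restored on exit, so the sequence is reproducible without disturbing
#'   the caller's RNG stream.
#' @return numeric vector of length `n`, zero mean, sample variance equal
#'   to `variance`.
#' @examples
#' x <- pink_noise(10000, variance = 0.02, seed = 1)
#' var(x)
#' @export
pink_noise <- function(n, variance = 0.02, seed = NULL) {
  if (length(n) != 1 || n < 1) stop("n must be a positive count")
  if (variance < 0) stop("variance must be non-negative")
  n <- as.integer(n)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  if (variance == 0) return(numeric(n))
  if (n < 8) {
    # too short for spectral shaping; white Gaussian at the target variance
    x <- rnorm(n)
    return(scale_to_variance(x, variance, n))
  }
  nf <- floor(n / 2)
  f <- (1:nf) / n
  spec <- complex(real = rnorm(nf), imaginary = rnorm(nf)) / sqrt(f)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  x <- Re(fft(full, inverse = TRUE)) / n
  scale_to_variance(x, variance, n)
}

scale_to_variance <- function(x, variance, n) {
  x <- x - mean(x)
  v <- sum(x^2) / (n - 1)
  if (v == 0) return(x)
  x * sqrt(variance / v)
}

#' Respiratory period jitter
#'
#' Uncorrelated zero-mean Gaussian draws, one per respiratory cycle,
#' perturbing the instantaneous respiratory period. The simulator requests
#' a new value only at cycle boundaries and realises the cycle by phase
#' accumulation at the perturbed period (clamped to at least 0.5 s).
#'
#' @param n number of draws.
#' @param variance variance in s^2 (default 0.3, the model's operating
#'   value).
#' @param seed optional integer, as in [pink_noise()].
#' @return numeric vector of length `n`.
#' @examples
#' respiratory_jitter(5, seed = 1)
#' @export
respiratory_jitter <- function(n = 1, variance = 0.3, seed = NULL) {
  if (variance < 0) stop("variance must be non-negative")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  if (variance == 0) return(numeric(n))
  rnorm(n, mean = 0, sd = sqrt(variance))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
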