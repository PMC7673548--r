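#' Spectrally synthesized 1/f noise
#'
#' Ongoing, task-independent fluctuations are modeled as 1/f noise: Fourier
#' amplitudes proportional to `1/sqrt(f)` (so power falls as 1/f), uniformly
#' random phases, zero DC. The realization is centered and rescaled to the
#' requested standard deviation; rescaling leaves the spectral shape intact.
#'
#' @param n number of samples (>= 4).
#' @param sd target standard deviation (population convention).
#' @return numeric vector of length `n`.
#' @export
one_over_f_noise <- function(n, sd = 1) {
  n <- as.integer(n)
  stopifnot(n >= 4L, sd >= 0)
  if (sd == 0) return(numeric(n))
  nf <- (n - 1L) %/% 2L
  amp <- 1 / sqrt(seq_len(nf))
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  X <- complex(n)
  X[2:(nf + 1L)] <- spec
  X[n:(n - nf + 1L)] <- Conj(spec)
  if (n %% 2L == 0L) {
    # Nyquist bin must be real; random sign keeps the ensemble phase-random
    X[n %/% 2L + 1L] <- sample(c(-1, 1), 1L) / sqrt(n / 2)
  }
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd / sqrt(mean(x^2))
}

# bounded, positive, mean-1 multiplicative amplitude jitter:
# f(x) + f(-x) = 2 so E[f(X)] = 1 for any symmetric zero-mean X
sigmoid_amp <- function(x) 2 / (1 + exp(-x))
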