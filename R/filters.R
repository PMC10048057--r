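# FIR filtering utilities shared by the preprocessing chain and the
# synthetic generator. All filters are linear-phase windowed-sinc (Hamming)
# designs applied with delay compensation and reflection padding, so the net
# response is zero-phase.

# FFT-based convolution of a signal with a (short) kernel; returns the
# "full" convolution of length n + L - 1.
fftConvolve <- function(x, b) {
  n <- length(x)
  L <- length(b)
  nf <- stats::nextn(n + L - 1L, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nf - n)))
  B <- stats::fft(c(b, numeric(nf - L)))
  Re(stats::fft(X * B, inverse = TRUE))[seq_len(n + L - 1L)] / nf
}

# Zero-phase application of a symmetric odd-length FIR kernel. Symmetric
# linear-phase kernels have a purely real delay-compensated response, so a
# single pass with the group delay removed is exactly zero-phase. The signal
# is reflection-padded by the kernel half-length to absorb edge transients.
firZeroPhase <- function(b, x) {
  L <- length(b)
  if (L %% 2L != 1L) stop("FIR kernel must have odd length")
  d <- (L - 1L) %/% 2L
  n <- length(x)
  pad <- min(d, n - 1L)
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  y <- fftConvolve(xp, b)
  y[(pad + d + 1L):(pad + d + n)]
}

# Hamming windowed-sinc FIR design via signal::fir1. Order is chosen from
# the requested transition width (Hamming: ~3.3 / (transition / fs) taps)
# and forced even so the kernel length is odd.
designFIR <- function(fs, edges, type = c("pass", "stop", "low", "high"),
                      transition = 5) {
  type <- match.arg(type)
  nyq <- fs / 2
  if (any(edges <= 0) || any(edges >= nyq))
    stop("filter edges must lie strictly inside (0, fs/2); fs too low ",
         "for the requested band")
  ord <- ceiling(3.3 * fs / transition)
  ord <- ord + ord %% 2L
  signal::fir1(ord, edges / nyq, type)
}

# Apply a designed FIR zero-phase to every row of a channel x sample matrix.
filterRows <- function(sig, b) {
  t(apply(sig, 1L, function(x) firZeroPhase(b, x)))
}

# 1/f^alpha "colored" background noise, unit standard deviation, generated
# by shaping the spectrum of white Gaussian noise. Uses the current R RNG.
coloredNoise <- function(n, exponent = 1) {
  X <- stats::fft(stats::rnorm(n))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)             # two-sided frequency bin index
  shape <- c(0, f[-1L]^(-exponent / 2))
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Narrowband Gaussian noise synthesized in the frequency domain: complex
# Gaussian coefficients inside [lo, hi] Hz with half-cosine tapered edges
# (taperHz wide), Hermitian-symmetrized and inverse-transformed. Unit SD.
bandNoise <- function(n, fs, lo, hi, taperHz = 0.5) {
  freq <- (seq_len(n) - 1L) * fs / n
  half <- freq <= fs / 2
  w <- numeric(n)
  f <- freq[half]
  w[half] <- ifelse(
    f >= lo & f <= hi, 1,
    ifelse(f > lo - taperHz & f < lo,
           0.5 * (1 + cos(pi * (lo - f) / taperHz)),
           ifelse(f > hi & f < hi + taperHz,
                  0.5 * (1 + cos(pi * (f - hi) / taperHz)), 0)))
  X <- w[seq_len(n)] * (stats::rnorm(n) + 1i * stats::rnorm(n))
  # Hermitian symmetry so the inverse transform is real
  X[1L] <- 0
  if (n %% 2L == 0L) X[n / 2 + 1L] <- Re(X[n / 2 + 1L])
  idx <- 2L:ceiling(n / 2)
  X[n + 2L - idx] <- Conj(X[idx])
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) stop("empty band: no frequency bins between ", lo, " and ", hi,
                   " Hz at this length/rate")
  x / s
}
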