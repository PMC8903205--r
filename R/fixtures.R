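#' Synthetic test signals for the feature extractors
#'
#' Deterministic signal generator used to exercise the acoustic feature
#' extractors: pure tones, equal-amplitude harmonic complexes, tones with
#' cycle-to-cycle period jitter, and white noise.
#'
#' @param kind one of `"sine"`, `"harmonic"`, `"jittered"`, `"noise"`.
#' @param f0 fundamental frequency, Hz (ignored for noise).
#' @param duration_s signal length, s.
#' @param fs sampling rate, Hz.
#' @param n_harmonics number of equal-amplitude harmonics (`"harmonic"`).
#' @param jitter fractional SD of the per-cycle period perturbation
#'   (`"jittered"`).
#' @param amplitude peak amplitude.
#' @param seed RNG seed for the stochastic kinds; the same seed always
#'   reproduces the same signal and the caller's RNG state is untouched.
#' @return numeric signal of `round(duration_s * fs)` samples.
#' @export
make_fixture <- function(kind = c("sine", "harmonic", "jittered", "noise"),
                         f0 = 200, duration_s = 0.4, fs = 44100,
                         n_harmonics = 5, jitter = 0.05, amplitude = 1,
                         seed = 1) {
  kind <- match.arg(kind)
  n <- round(duration_s * fs)
  t <- seq_len(n) / fs
  switch(kind,
    sine = amplitude * sin(2 * pi * f0 * t),
    harmonic = {
      h <- seq_len(n_harmonics)
      amplitude * colSums(sin(2 * pi * outer(h * f0, t))) / n_harmonics
    },
    jittered = {
      # instantaneous frequency redrawn each nominal cycle
      ncyc <- ceiling(duration_s * f0) + 2
      fcyc <- f0 / (1 + jitter * local_rnorm(seed, ncyc))
      per <- 1 / fcyc
      bounds <- cumsum(per)
      cyc <- findInterval(t, c(0, bounds), left.open = TRUE)
      cyc <- pmin(cyc, ncyc)
      phase0 <- c(0, 2 * pi * seq_len(ncyc - 1))
      tstart <- c(0, bounds[-ncyc])
      amplitude * sin(2 * pi * fcyc[cyc] * (t - tstart[cyc]))
    },
    noise = amplitude * (local_runif(seed, n) * 2 - 1)
  )
}

# deterministic normal draws preserving the caller's RNG state
local_rnorm <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n)
}
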