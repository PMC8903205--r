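#' Fundamental frequency by autocorrelation
#'
#' Normalized autocorrelation over the final analysis window with
#' parabolic interpolation around the best peak in the configured search
#' range, gated by a periodicity confidence threshold (the normalized
#' autocorrelation value at the chosen lag).
#'
#' @param x signal.
#' @param fs sampling rate, Hz.
#' @param cfg a [vp_config()] (search range, confidence gate, window).
#' @return fo in Hz, or `NA_real_` when the signal is not confidently
#'   periodic.
#' @export
estimate_f0 <- function(x, fs, cfg = vp_config()) {
  lo <- cfg$f0_range_hz[1]; hi <- cfg$f0_range_hz[2]
  if (length(x) < 4 * fs / lo)
    stop("estimate_f0: signal shorter than 4 periods of ", lo, " Hz")
  x <- analysis_window(x, fs, cfg)
  x <- x - mean(x)
  if (all(x == 0)) return(NA_real_)
  n <- length(x)
  # autocorrelation via FFT
  m <- 2^ceiling(log2(2 * n))
  X <- fft(c(x, numeric(m - n)))
  ac <- Re(fft(X * Conj(X), inverse = TRUE))[1:n] / m
  ac <- ac / ac[1]
  lag_min <- max(2, floor(fs / hi))
  lag_max <- min(n - 2, ceiling(fs / lo))
  if (lag_max <= lag_min) return(NA_real_)
  seg <- ac[(lag_min + 1):(lag_max + 1)]       # ac[k+1] is lag k
  k <- which.max(seg)
  lag <- lag_min + k - 1
  conf <- seg[k]
  if (!is.finite(conf) || conf < cfg$f0_conf_threshold) return(NA_real_)
  # parabolic refinement of the peak lag
  y1 <- ac[lag]; y2 <- ac[lag + 1]; y3 <- ac[lag + 2]
  den <- y1 - 2 * y2 + y3
  delta <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
  delta <- max(-0.5, min(0.5, delta))
  fo <- fs / (lag + delta)
  if (fo < lo || fo > hi) return(NA_real_)
  fo
}

#' Sound pressure level of the radiated signal
#'
#' Radiated intensity at distance R from the mouth from the RMS oral
#' pressure: the power leaving the mouth opening, \eqn{\bar p_o^2 A_m /
#' (\rho c)}, spread over a sphere of radius R with radiation resistance
#' factor R_m, referenced to \eqn{I_0 = 10^{-12}} W/m^2:
#' \deqn{SPL = 10\log_{10}\frac{\bar p_o^2 A_m}{4\pi R^2 R_m \rho c I_0}
#'   + \Delta_{cal}}
#' Evaluated in SI internally; `p` is given in the simulator's CGS unit
#' (dyn/cm^2). Doubling the signal amplitude adds exactly 20 log10(2) dB.
#'
#' @param p oral pressure signal, dyn/cm^2.
#' @param fs sampling rate, Hz (used to select the analysis window).
#' @param cfg a [vp_config()]; uses `spl_R_cm`, `spl_Rm`, `spl_offset_db`
#'   and the mouth area of the airway table.
#' @param A_mouth_cm2 mouth opening area, cm^2 (default: lip section of
#'   the airway table).
#' @return SPL in dB re 1e-12 W/m^2 (`-Inf` for an all-zero signal).
#' @export
spl <- function(p, fs = NULL, cfg = vp_config(),
                A_mouth_cm2 = NULL) {
  if (!length(p)) stop("spl: empty signal")
  if (!is.null(fs)) p <- analysis_window(p, fs, cfg)
  if (is.null(A_mouth_cm2)) {
    sup <- airway_areas(cfg)$sup
    A_mouth_cm2 <- sup[length(sup)]
  }
  prms_Pa <- sqrt(mean((p * 0.1)^2))       # dyn/cm^2 -> Pa
  if (prms_Pa == 0) return(-Inf)
  A_m2 <- A_mouth_cm2 * 1e-4
  R_m <- cfg$spl_R_cm / 100
  rhoc <- (cfg$rho_air * 1e3) * (cfg$c_air / 100)   # SI rayl
  I <- prms_Pa^2 * A_m2 / (rhoc * 4 * pi * R_m^2 * cfg$spl_Rm)
  10 * log10(I / 1e-12) + cfg$spl_offset_db
}

#' Normalized spectral centroid
#'
#' Center of mass of the magnitude spectrum (Hann window over the final
#' analysis window, bins to Nyquist) divided by the fundamental
#' frequency. A pure tone at fo gives 1; equal tones at fo and 2 fo give
#' 1.5; equal harmonics 1..5 give 3.
#'
#' @param x signal.
#' @param fo fundamental frequency, Hz (NA propagates).
#' @param fs sampling rate, Hz.
#' @param cfg a [vp_config()].
#' @return NSC (dimensionless), or NA if `fo` is missing.
#' @export
nsc <- function(x, fo, fs, cfg = vp_config()) {
  if (is.na(fo)) return(NA_real_)
  stopifnot(fo > 0)
  x <- analysis_window(x, fs, cfg)
  x <- x - mean(x)
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)   # Hann
  X <- abs(fft(x * w))
  nb <- floor(n / 2) + 1
  f <- (seq_len(nb) - 1) * fs / n
  mag <- X[seq_len(nb)]
  sc <- sum(f * mag) / sum(mag)
  sc / fo
}

#' Approximate entropy
#'
#' Regularity statistic ApEn(m, r) of a time series: the difference
#' \eqn{\Phi^m(r) - \Phi^{m+1}(r)} of the mean log correlation integrals
#' of the delay-embedded series (Chebyshev distance, self-matches
#' included, delay `tau`). By default `r` is `r_factor` times the sample
#' SD of the signal (the scale-invariant convention);
#' `cfg$apen_r_mode = "variance"` uses `r_factor * var(x)` instead, and
#' an explicit `r` overrides both. Long signals are decimated to
#' `cfg$apen_fs_hz` before embedding when `fs` is supplied.
#'
#' @param x signal.
#' @param m embedding dimension (default 2).
#' @param tau embedding delay in samples (default 1).
#' @param r_factor tolerance scale factor (default 0.2).
#' @param r explicit tolerance (overrides `r_factor`).
#' @param fs sampling rate for decimation; NULL disables decimation.
#' @param cfg a [vp_config()].
#' @return ApEn (dimensionless; 0 for a constant signal).
#' @export
apen <- function(x, m = cfg$apen_m, tau = cfg$apen_tau,
                 r_factor = cfg$apen_r_factor, r = NULL, fs = NULL,
                 cfg = vp_config()) {
  if (!is.null(fs) && fs > cfg$apen_fs_hz) {
    q <- round(fs / cfg$apen_fs_hz)
    if (q > 1) x <- signal::decimate(x, q)
  }
  n <- length(x)
  if (n < 50) stop("apen: need at least 50 samples")
  if (is.null(r)) {
    scale <- if (identical(cfg$apen_r_mode, "variance"))
      stats::var(x) else stats::sd(x)
    r <- r_factor * scale
  }
  if (r <= 0) return(0)   # constant signal: perfectly predictable
  phi <- function(mm) {
    nv <- n - (mm - 1) * tau
    if (nv < 2) return(NA_real_)
    # Chebyshev distances accumulated over embedding coordinates
    d <- matrix(0, nv, nv)
    for (j in seq_len(mm)) {
      idx <- seq_len(nv) + (j - 1) * tau
      d <- pmax(d, abs(outer(x[idx], x[idx], "-")))
    }
    Cm <- rowSums(d <= r) / nv
    mean(log(Cm))
  }
  phi(m) - phi(m + 1)
}

#' Steady-state postural averages
#'
#' Arithmetic means of postural time series over the final steady window
#' (default the last 100 ms).
#'
#' @param data a data frame of time series columns sampled at `fs`
#'   (e.g. `L`, per-layer stresses).
#' @param fs sampling rate, Hz.
#' @param cfg a [vp_config()] (`steady_window_s`).
#' @return one-row tibble of column means over the final window.
#' @export
steady_state_postural <- function(data, fs, cfg = vp_config()) {
  nw <- round(cfg$steady_window_s * fs)
  n <- nrow(data)
  if (n < nw) stop("steady_state_postural: record shorter than the steady window")
  dplyr::summarise(utils::tail(data, nw),
                   dplyr::across(dplyr::everything(), mean))
}

# final analysis window of a signal (whole signal if shorter)
analysis_window <- function(x, fs, cfg) {
  nw <- round(cfg$analysis_window_s * fs)
  if (length(x) > nw) x <- x[(length(x) - nw + 1):length(x)]
  x
}

#' Acoustic feature set of a radiated pressure signal
#'
#' @param p oral pressure signal, dyn/cm^2.
#' @param fs sampling rate, Hz.
#' @param cfg a [vp_config()].
#' @return one-row tibble with `fo_Hz`, `SPL_dB`, `NSC`, `ApEn`.
#' @export
acoustic_features <- function(p, fs, cfg = vp_config()) {
  fo <- estimate_f0(p, fs, cfg)
  tibble::tibble(
    fo_Hz = fo,
    SPL_dB = spl(p, fs, cfg),
    NSC = nsc(p, fo, fs, cfg),
    ApEn = apen(analysis_window(p, fs, cfg), fs = fs, cfg = cfg))
}
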