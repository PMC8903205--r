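# shared fixtures: a cached reduced sweep (expensive, reused by several
# tests) and an independent brute-force ApEn oracle

.shared <- new.env(parent = emptyenv())

# 5x5 (25%-step) feature map under the default configuration
reduced_map <- function() {
  if (is.null(.shared$map25)) .shared$map25 <- run_sweep(25, vp_config())
  .shared$map25
}

# corner grid cells run individually (calibration anchors)
corner_point <- function(aCT, aTA) {
  key <- sprintf("corner_%d_%d", aCT, aTA)
  if (is.null(.shared[[key]])) .shared[[key]] <- run_point(aCT, aTA, vp_config())
  .shared[[key]]
}

# O(N^2) ApEn with explicit loops, independent of the package's
# vectorized implementation (self-matches included, Chebyshev distance)
apen_bruteforce <- function(x, m = 2, r, tau = 1) {
  n <- length(x)
  phi <- function(mm) {
    nv <- n - (mm - 1) * tau
    logC <- numeric(nv)
    for (i in seq_len(nv)) {
      cnt <- 0L
      for (j in seq_len(nv)) {
        dmax <- 0
        for (q in seq_len(mm)) {
          d <- abs(x[i + (q - 1) * tau] - x[j + (q - 1) * tau])
          if (d > dmax) dmax <- d
        }
        if (dmax <= r) cnt <- cnt + 1L
      }
      logC[i] <- log(cnt / nv)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1)
}

# scalar stress-strain law written out independently of passive_stress
eq6_scalar <- function(eps, sigma0, sigma2, B, eps1, eps2) {
  lin <- -(sigma0 / eps1) * (eps - eps1)
  ex <- 0
  if (eps > eps2) ex <- sigma2 * (exp(B * (eps - eps2)) - 1 - B * (eps - eps2))
  lin + ex
}
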