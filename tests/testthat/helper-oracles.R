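# Independent oracles used by the test suite. These deliberately avoid
# the package's own code paths.

# naive per-residue scan for consensus IDR calling
naive_idr_scan <- function(calls, consensus_frac = 0.75, min_run = 10) {
  if (is.null(dim(calls))) calls <- cbind(calls)
  n <- nrow(calls)
  cons <- logical(n)
  for (i in seq_len(n)) {
    cons[i] <- sum(calls[i, ]) / ncol(calls) > consensus_frac
  }
  intervals <- data.frame(start = integer(), end = integer())
  i <- 1L
  while (i <= n) {
    if (cons[i]) {
      j <- i
      while (j < n && cons[j + 1L]) j <- j + 1L
      if (j - i + 1L > min_run) {
        intervals <- rbind(intervals, data.frame(start = i, end = j))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  intervals
}

# spherical-cap volume by quadrature over the solid of revolution:
# the cap occupies y in [r cos(theta), r] of a sphere of radius r
cap_volume_quadrature <- function(a, r) {
  y0 <- r * cos(asin(a / r))
  stats::integrate(function(y) pi * (r^2 - y^2), lower = y0, upper = r,
                   rel.tol = 1e-12)$value
}

# explicit matrix-inverse Mahalanobis distance
mahalanobis_oracle <- function(z, control_z) {
  s_inv <- solve(cov(control_z))
  unname(apply(rbind(z), 1L,
               function(v) sqrt(drop(t(v) %*% s_inv %*% v))))
}

# analytic stability score planted by the melt model: sum over the grid
# of log2 f(T; Tm + dTm) / f(T; Tm), corrected by the abundance score
# (mean of the two lowest temperatures)
analytic_stability <- function(tm, delta_tm, temperatures, slope = 2,
                               plateau = 0.05, delta_abundance = 0) {
  lfc <- log2(melt_fraction(temperatures, tm + delta_tm, slope, plateau) /
                melt_fraction(temperatures, tm, slope, plateau)) +
    delta_abundance
  ab <- mean(lfc[order(temperatures)[1:2]])
  sum(lfc - ab)
}
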