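# Independent oracles used to cross-check the solvers.  These re-derive the
# mass-action algebra from scratch and locate roots by grid scan plus
# bisection, sharing no code with the package's uniroot-based solvers.

# Two-site receptor/titrant equilibrium: scan free titrant on [0, S_total]
# for the titrant-conservation root, then bisect the bracketing interval.
oracle_two_site <- function(E_total, S_total, Kd1, Kd2) {
  species_at <- function(S) {
    den <- 1 + S / Kd1 + S / Kd2 + S * S / (Kd1 * Kd2)
    E <- E_total / den
    c(E = E, S_free = S, SE = E * S / Kd1, ES = E * S / Kd2,
      SES = E * S * S / (Kd1 * Kd2))
  }
  f <- function(S) {
    sp <- species_at(S)
    S + sp[["SE"]] + sp[["ES"]] + 2 * sp[["SES"]] - S_total
  }
  if (S_total == 0) return(species_at(0))
  grid <- seq(0, S_total, length.out = 2049L)
  vals <- vapply(grid, f, numeric(1))
  i <- which(vals[-1] >= 0 & vals[-length(vals)] <= 0)[1]
  lo <- grid[i]; hi <- grid[i + 1L]
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  species_at((lo + hi) / 2)
}

# Competition for one shared site: bisection in free protein.
oracle_competitive <- function(P_total, A_total, B_total, KdA, KdB) {
  f <- function(Pf) {
    Pf + A_total * Pf / (KdA + Pf) + B_total * Pf / (KdB + Pf) - P_total
  }
  lo <- 0; hi <- P_total
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  Pf <- (lo + hi) / 2
  c(bound_probe = A_total * Pf / (KdA + Pf),
    bound_competitor = B_total * Pf / (KdB + Pf), P_free = Pf)
}

# High-resolution trapezoidal sw of a Gaussian-mixture c(s) over a window.
oracle_sw_gaussians <- function(peaks, s_min, s_max, n = 200001L) {
  s <- seq(s_min, s_max, length.out = n)
  cc <- rep(0, n)
  for (i in seq_len(nrow(peaks))) {
    cc <- cc + peaks$area[i] * stats::dnorm(s, peaks$s[i], peaks$width[i])
  }
  h <- s[2] - s[1]
  trap <- function(y) h * (sum(y) - (y[1] + y[n]) / 2)
  trap(s * cc) / trap(cc)
}

# Guinier fit over the analytically correct window for a KNOWN true Rg.
oracle_guinier <- function(q, I, Rg_true, q_rg_max = 1.3) {
  keep <- q <= q_rg_max / Rg_true
  fit <- stats::lm(log(I[keep]) ~ I(q[keep]^2))
  sqrt(-3 * stats::coef(fit)[[2]])
}

rel_err <- function(x, truth) abs(x - truth) / abs(truth)
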