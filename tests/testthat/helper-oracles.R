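# Synthetic single-patient cohort row with controllable parameters.
make_patient <- function(vd = 30, fu = 1, cl_nr = 0, sa_300 = 0.4,
                         sa_100 = 0.6, sa_50 = 0.7, sc = 0.8, id = 1L) {
  tibble::tibble(id = id, body_weight = 70, vd_per_kg = vd / 70, vd = vd,
                 fu = fu, cl_nr = cl_nr, sa_300 = sa_300, sa_100 = sa_100,
                 sa_50 = sa_50, sc = sc)
}

# Independent numerical oracle: re-integrate a cohort_profiles object with
# classic 4th-order Runge-Kutta on dC/dt = r0/Vd - ke C, segment by segment
# so steps never straddle a coefficient discontinuity.
rk4_conc <- function(profiles, dt_max = 0.01) {
  bp <- profiles$breakpoints
  m <- length(profiles$r0)
  conc <- matrix(0, nrow(profiles$conc), m + 1)
  conc[, 1] <- profiles$conc[, 1]
  for (j in seq_len(m)) {
    dtseg <- bp[j + 1] - bp[j]
    nstep <- max(1L, ceiling(dtseg / dt_max))
    h <- dtseg / nstep
    ke <- profiles$ke[, j]
    inp <- profiles$r0[j] / profiles$vd
    f <- function(y) inp - ke * y
    y <- conc[, j]
    for (s in seq_len(nstep)) {
      k1 <- f(y); k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    conc[, j + 1] <- y
  }
  conc
}

# Dense-grid oracle for time above a threshold: sample the profile on a
# 1e-3 h grid, then refine each bracketed crossing by local bisection so the
# oracle's own grid error is ~1e-6 h.
dense_time_above <- function(profile, threshold, window,
                             scale = "free", dt = 1e-3) {
  t <- seq(window[1], window[2], by = dt)
  above <- conc_at(profile, t, scale = scale) > threshold
  hours <- sum(above[-length(above)]) * dt
  flips <- which(above[-1] != above[-length(above)])
  for (i in flips) {
    lo <- t[i]; hi <- t[i + 1]
    for (k in 1:20) {
      mid <- (lo + hi) / 2
      if ((conc_at(profile, mid, scale = scale) > threshold) == above[i])
        lo <- mid else hi <- mid
    }
    cross <- (lo + hi) / 2
    if (above[i]) hours <- hours - (t[i + 1] - cross) # was counted as above
    else hours <- hours + (t[i + 1] - cross)
  }
  hours
}

# Moments of the moment-matched log-normal restricted to [low, high], by
# numerical integration of the density (independent of the sampler).
trunc_lognormal_moments <- function(spec) {
  sigma2 <- log(1 + (spec$sd / spec$mean)^2)
  mu <- log(spec$mean) - sigma2 / 2
  sigma <- sqrt(sigma2)
  lo <- max(spec$low, 0)
  z <- stats::plnorm(spec$high, mu, sigma) - stats::plnorm(lo, mu, sigma)
  mom <- function(p) stats::integrate(
    function(x) x^p * stats::dlnorm(x, mu, sigma), lo, spec$high,
    rel.tol = 1e-10)$value / z
  m1 <- mom(1)
  list(mean = m1, sd = sqrt(mom(2) - m1^2))
}
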