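# Independent oracles used across the suite. None of these call into the
# package's own solvers or the C++ event core.

# Monte-Carlo oracle: one M/M/1/k FCFS queue simulated arrival-by-arrival
# with the Lindley-style departure recursion. Standard errors are batch
# means (successive arrivals are autocorrelated, so binomial s.e. would
# understate the error).
mm1k_mc_oracle <- function(lam, mu, k, d, tau, n_arrivals, seed,
                           lat = 2, nbatch = 50L) {
  set.seed(seed)
  A <- cumsum(stats::rexp(n_arrivals, lam))
  S <- stats::rexp(n_arrivals, mu)
  bsize <- n_arrivals %/% nbatch
  blocked_b <- integer(nbatch); late_b <- integer(nbatch); acc_b <- integer(nbatch)
  q <- numeric(k + 1L); qh <- 1L; qt <- 0L; qn <- 0L
  D_last <- 0
  for (i in seq_len(n_arrivals)) {
    a <- A[i]
    while (qn > 0L && q[qh] <= a) {
      qh <- qh + 1L; if (qh > k + 1L) qh <- 1L
      qn <- qn - 1L
    }
    b <- min((i - 1L) %/% bsize + 1L, nbatch)
    if (qn >= k) blocked_b[b] <- blocked_b[b] + 1L
    else {
      Dn <- max(a, D_last) + S[i]
      D_last <- Dn
      qt <- qt + 1L; if (qt > k + 1L) qt <- 1L
      q[qt] <- Dn; qn <- qn + 1L
      acc_b[b] <- acc_b[b] + 1L
      if (lat * d + (Dn - a) > tau) late_b[b] <- late_b[b] + 1L
    }
  }
  nb <- blocked_b + acc_b
  list(p_loss = sum(blocked_b) / n_arrivals,
       se_loss = stats::sd(blocked_b / nb) / sqrt(nbatch),
       p_delay = sum(late_b) / sum(acc_b),
       se_delay = stats::sd(late_b / pmax(acc_b, 1L)) / sqrt(nbatch),
       p_fail = sum(blocked_b + late_b) / n_arrivals,
       se_fail = stats::sd((blocked_b + late_b) / nb) / sqrt(nbatch))
}

# Damped explicit-Euler fixed-point iteration of the WSLS balance flow,
# started from the uniform distribution; independent of the bisection
# solver's flux inversion.
euler_equilibrium_oracle <- function(system, step = 0.4, max_iter = 4e5,
                                     tol = 1e-11) {
  n <- rep(system$Nu / system$Ng, system$Ng)
  lam <- system$lambda_u
  for (it in seq_len(max_iter)) {
    flux <- lam * n * vapply(seq_along(n), function(i)
      failure_probability(system$goods[[i]], n[i], system)$p_fail, numeric(1L))
    dn <- -flux + (sum(flux) - flux) / (system$Ng - 1)
    n <- n + step * dn / max(lam, 1e-12)
    if (max(abs(dn)) < tol * max(lam, 1e-12) * system$Nu) break
  }
  n
}

# plain bisection, independent of stats::uniroot
bisect_oracle <- function(f, lo, hi, iter = 120L) {
  flo <- f(lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(flo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# convenience: small symmetric system of identical servers
symmetric_system <- function(Ng = 3, rho = 0.75, Nu = 300) {
  goods <- replicate(Ng, queue_server_spec(mu = 100, c = 1, k = 10, d = 0.01),
                     simplify = FALSE)
  system_spec(goods, Nu = Nu, tau = 0.1, rho = rho)
}
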