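#' Queueing-server specification of a common good
#'
#' Describes one server-backed common good as an M/M/c/k loss system: Poisson
#' request arrivals, exponential service at rate `mu` per processor, `c`
#' processors, `k` total places (serving plus waiting), and a deterministic
#' one-way network latency `d` between user and server.
#'
#' @param mu Service capacity of one processor, in requests served per second.
#' @param c Number of processors (positive integer).
#' @param k Buffer size: total number of requests the server can hold,
#'   including those in service. Must satisfy `k >= c`.
#' @param d One-way latency between user and server, in seconds.
#' @return An object of class `"queue_server_spec"`.
#' @examples
#' g1 <- queue_server_spec(mu = 100, c = 1, k = 10, d = 0.010)
#' loss_probability(g1, n = 150, lambda_u = 0.525)
#' @seealso [system_spec()], [failure_probability()]
#' @export
queue_server_spec <- function(mu, c = 1L, k = 10L, d = 0) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single positive number (requests/s)")
  if (length(c) != 1L || c < 1 || c != round(c))
    stop("'c' must be a positive integer")
  if (length(k) != 1L || k < c || k != round(k))
    stop("'k' must be an integer >= c")
  if (!is.numeric(d) || length(d) != 1L || d < 0)
    stop("'d' must be a nonnegative latency in seconds")
  structure(list(mu = mu, c = as.integer(c), k = as.integer(k), d = d),
            class = c("queue_server_spec", "good_spec"))
}

#' Generic common good with an explicit failure curve
#'
#' A common good whose per-attempt failure probability is given directly as a
#' monotone nondecreasing function of the instantaneous load `n`, for commons
#' that are not naturally modelled as queues (grazing land, transport lines,
#' water sources, ...).
#'
#' @param failure_fn Function mapping load `n >= 0` to a failure probability
#'   in \[0, 1\], nondecreasing in `n`. Checked on a grid at construction.
#' @param n_max Upper end of the validation grid (default 1000).
#' @return An object of class `"generic_good_spec"`.
#' @examples
#' g <- generic_good_spec(function(n) n / (n + 100))
#' failure_probability(g, n = 100)$p_fail
#' @export
generic_good_spec <- function(failure_fn, n_max = 1000) {
  if (!is.function(failure_fn)) stop("'failure_fn' must be a function")
  grid <- seq(0, n_max, length.out = 101L)
  v <- vapply(grid, failure_fn, numeric(1L))
  if (any(!is.finite(v)) || any(v < -1e-12) || any(v > 1 + 1e-12))
    stop("'failure_fn' must map [0, n_max] into [0, 1]")
  if (any(diff(v) < -1e-9))
    stop("'failure_fn' must be nondecreasing in the load n")
  structure(list(failure_fn = failure_fn),
            class = c("generic_good_spec", "good_spec"))
}

#' System specification: goods, population and workload
#'
#' Bundles the set of common goods, the user population size, the service
#' timeout and the workload. Exactly one of `rho` (system workload, the ratio
#' of total population request rate to total capacity) or `lambda_u`
#' (per-user request rate, requests/s) is given; the other is derived through
#' `lambda_u = rho * mu / Nu` with `mu = sum(mu_i)`.
#'
#' @param goods List of [queue_server_spec()] / [generic_good_spec()] objects,
#'   length at least 2.
#' @param Nu Population size (number of users).
#' @param tau Service timeout in seconds: a request whose return delay exceeds
#'   `tau` counts as a failure.
#' @param rho System workload `Nu * lambda_u / mu`. Give either this or
#'   `lambda_u`, not both.
#' @param lambda_u Per-user request rate in requests/s.
#' @param latency_mode `"round-trip"` charges the user-server latency twice
#'   (out and back) against `tau`; `"one-way"` charges it once.
#' @return An object of class `"wsls_system"` with derived fields `mu`
#'   (total capacity), `rho`, `lambda_u` and `Ng`.
#' @examples
#' sys <- table1_system(rho = 0.75)
#' sys$lambda_u  # 0.525 requests/s per user
#' @export
system_spec <- function(goods, Nu, tau, rho = NULL, lambda_u = NULL,
                        latency_mode = c("round-trip", "one-way")) {
  latency_mode <- match.arg(latency_mode)
  if (!is.list(goods) || length(goods) < 2L)
    stop("'goods' must be a list of at least 2 good specifications (Ng >= 2)")
  ok <- vapply(goods, inherits, logical(1L), what = "good_spec")
  if (!all(ok)) stop("every element of 'goods' must be a good specification")
  if (length(Nu) != 1L || Nu < 1) stop("'Nu' must be a positive population size")
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a positive timeout in seconds")
  is_queue <- vapply(goods, inherits, logical(1L), what = "queue_server_spec")
  mu_total <- sum(vapply(goods[is_queue], function(g) g$mu, numeric(1L)))
  if (is.null(rho) == is.null(lambda_u))
    stop("give exactly one of 'rho' or 'lambda_u'")
  if (is.null(lambda_u)) {
    if (!all(is_queue))
      stop("'rho' can only be used when all goods are queue servers (total capacity needed); give 'lambda_u'")
    if (rho < 0) stop("'rho' must be nonnegative")
    lambda_u <- rho * mu_total / Nu
  } else {
    if (lambda_u < 0) stop("'lambda_u' must be nonnegative")
    rho <- if (mu_total > 0) Nu * lambda_u / mu_total else NA_real_
  }
  structure(list(goods = goods, Ng = length(goods), Nu = Nu, tau = tau,
                 rho = rho, lambda_u = lambda_u, mu = mu_total,
                 latency_mode = latency_mode),
            class = "wsls_system")
}

#' @export
print.wsls_system <- function(x, ...) {
  cat("WSLS common-good system\n")
  cat(sprintf("  goods: %d, users: %g, timeout tau: %g s (%s latency)\n",
              x$Ng, x$Nu, x$tau, x$latency_mode))
  cat(sprintf("  total capacity mu: %g req/s, workload rho: %.4g, lambda_u: %.4g req/s\n",
              x$mu, x$rho, x$lambda_u))
  for (i in seq_len(x$Ng)) {
    g <- x$goods[[i]]
    if (inherits(g, "queue_server_spec"))
      cat(sprintf("  G%d: M/M/%d/%d, mu = %g req/s, d = %g ms\n",
                  i, g$c, g$k, g$mu, 1000 * g$d))
    else cat(sprintf("  G%d: generic failure curve\n", i))
  }
  invisible(x)
}

# latency multiplier implied by the system's latency accounting
latency_factor <- function(system) if (system$latency_mode == "one-way") 1 else 2

#' Stationary distribution of an M/M/c/k queue
#'
#' Number-in-system distribution of the birth-death chain with arrival rate
#' `lambda`, per-processor service rate `spec$mu`, `spec$c` processors and
#' `spec$k` total places. Computed from log birth/death ratios so that large
#' and small offered loads are equally stable.
#'
#' @param spec A [queue_server_spec()].
#' @param lambda Aggregate Poisson arrival rate at the server (requests/s).
#' @return Numeric vector of length `k + 1`: probabilities of 0..k in system.
#' @export
stationary_distribution <- function(spec, lambda) {
  stopifnot(inherits(spec, "queue_server_spec"), lambda >= 0)
  k <- spec$k
  if (lambda == 0) return(c(1, rep(0, k)))
  # log pi_j / pi_0 = sum_{m=1..j} log(lambda / (min(m, c) mu))
  m <- seq_len(k)
  logratio <- c(0, cumsum(log(lambda) - log(pmin(m, spec$c)) - log(spec$mu)))
  w <- exp(logratio - max(logratio))
  w / sum(w)
}

#' Loss (blocking) probability of a server under load
#'
#' Stationary probability that a request arriving at a server used by `n`
#' users (each emitting Poisson(`lambda_u`) requests) finds the buffer full
#' and is lost. By PASTA this is the stationary probability of `k` in system.
#' `n` may be any nonnegative real: in the mean-field dynamics occupancies
#' are continuous.
#'
#' @inheritParams stationary_distribution
#' @param n Number of users currently on this good (real, `>= 0`).
#' @param lambda_u Per-user request rate (requests/s).
#' @return Blocking probability in \[0, 1\]; 0 when `n * lambda_u == 0`.
#' @examples
#' s <- queue_server_spec(mu = 100, c = 1, k = 10)
#' loss_probability(s, n = 100, lambda_u = 1)  # offered load 1 -> 1/11
#' @export
loss_probability <- function(spec, n, lambda_u) {
  stopifnot(n >= 0, lambda_u >= 0)
  lam <- n * lambda_u
  if (lam == 0) return(0)
  pi <- stationary_distribution(spec, lam)
  pi[spec$k + 1L]
}

# tail P(W + S > t) for an accepted arrival finding j in system:
#   j <  c : sojourn ~ Exp(mu)
#   j >= c : sojourn ~ Erlang(j - c + 1, c mu) + Exp(mu)  (hypoexponential)
# vectorized over j
sojourn_tail <- function(j, mu, c, t) {
  if (t <= 0) return(rep(1, length(j)))
  out <- numeric(length(j))
  nowait <- j < c
  out[nowait] <- exp(-mu * t)
  jw <- j[!nowait]
  if (length(jw)) {
    m <- jw - c + 1          # Erlang stages of the wait
    r <- c * mu              # wait stage rate
    if (c == 1L) {
      # wait and service stages share rate mu: sojourn ~ Erlang(j + 1, mu)
      out[!nowait] <- stats::pgamma(t, shape = m + 1, rate = mu, lower.tail = FALSE)
    } else {
      # P(X + Y > t) = P(X > t) + e^{-mu t} (r/(r-mu))^m P(Erlang(m, r-mu) <= t)
      out[!nowait] <- stats::pgamma(t, shape = m, rate = r, lower.tail = FALSE) +
        exp(-mu * t + m * (log(r) - log(r - mu))) *
          stats::pgamma(t, shape = m, rate = r - mu)
    }
  }
  pmin(out, 1)
}

#' Excessive-delay probability of an accepted request
#'
#' Probability that a request which is *not* blocked returns to its user too
#' late to be useful, i.e. its return delay (network latency per
#' `latency_mode`, plus queueing wait, plus service) exceeds the timeout
#' `tau`. Computed by PASTA as a mixture over the arrival-conditioned
#' non-blocked states: an accepted arrival finding `j` in system has an
#' Erlang sojourn whose tail is evaluated through the regularized incomplete
#' gamma function.
#'
#' @inheritParams loss_probability
#' @param tau Timeout in seconds.
#' @param latency_mode `"round-trip"` (latency charged twice) or `"one-way"`.
#' @return Probability in \[0, 1\] that an accepted request is late.
#' @export
excess_delay_probability <- function(spec, n, lambda_u, tau,
                                     latency_mode = c("round-trip", "one-way")) {
  latency_mode <- match.arg(latency_mode)
  stopifnot(inherits(spec, "queue_server_spec"), n >= 0, lambda_u >= 0, tau > 0)
  lat <- if (latency_mode == "one-way") 1 else 2
  t_eff <- tau - lat * spec$d
  if (!is.finite(tau)) return(0)
  if (t_eff <= 0) return(1)
  lam <- n * lambda_u
  k <- spec$k
  if (lam == 0) {
    # a lone request sees an empty system
    return(sojourn_tail(0L, spec$mu, spec$c, t_eff))
  }
  pi <- stationary_distribution(spec, lam)
  acc <- pi[seq_len(k)]
  acc <- acc / sum(acc)                       # condition on acceptance
  sum(acc * sojourn_tail(0:(k - 1L), spec$mu, spec$c, t_eff))
}

#' Failure probability and quality of a good under load
#'
#' Per-attempt failure probability of a good used by `n` users, composed as
#' `P(F) = P(L) + (1 - P(L)) P(D)`: a request fails if it is lost at a full
#' buffer or if, accepted, it returns after the timeout. For a generic good
#' the failure curve is used directly (`p_loss = p_fail`, `p_delay = 0`).
#'
#' @param spec A [queue_server_spec()] or [generic_good_spec()].
#' @param n Load: number of users on this good (real, `>= 0`).
#' @param system The [system_spec()] supplying `lambda_u`, `tau` and the
#'   latency accounting.
#' @return A list of class `"queue_metrics"` with components `p_loss`,
#'   `p_delay`, `p_fail` and `quality = 1 - p_fail`.
#' @examples
#' sys <- table1_system(rho = 0.75)
#' failure_probability(sys$goods[[1]], n = 150, system = sys)
#' @export
failure_probability <- function(spec, n, system) {
  stopifnot(n >= 0)
  if (inherits(spec, "generic_good_spec")) {
    pf <- spec$failure_fn(n)
    return(structure(list(p_loss = pf, p_delay = 0, p_fail = pf,
                          quality = 1 - pf), class = "queue_metrics"))
  }
  pl <- loss_probability(spec, n, system$lambda_u)
  pd <- excess_delay_probability(spec, n, system$lambda_u, system$tau,
                                 system$latency_mode)
  pf <- pl + (1 - pl) * pd
  structure(list(p_loss = pl, p_delay = pd, p_fail = pf, quality = 1 - pf),
            class = "queue_metrics")
}

#' @export
print.queue_metrics <- function(x, ...) {
  cat(sprintf("P(L) = %.6g, P(D) = %.6g, P(F) = %.6g, quality = %.6g\n",
              x$p_loss, x$p_delay, x$p_fail, x$quality))
  invisible(x)
}

# p_fail for good i of a system at load n (scalar helper used throughout)
good_p_fail <- function(system, i, n) {
  failure_probability(system$goods[[i]], n, system)$p_fail
}

# vector of p_fail across goods at occupancies n
system_p_fail <- function(system, n) {
  vapply(seq_len(system$Ng), function(i) good_p_fail(system, i, n[i]),
         numeric(1L))
}

#' Failure probability of an unloaded good
#'
#' Limit of the failure probability as the load vanishes. For a queue server
#' this is the probability that a single isolated request is late: the
#' latency plus an Exp(`mu`) service exceeding `tau`, i.e.
#' `exp(-mu (tau - lat * d))` (1 if the latency alone exceeds the timeout).
#' Goods whose limiting failure probability exceeds the equalized-quality
#' level are exactly those left unused by the ideal distribution.
#'
#' @inheritParams failure_probability
#' @return Limiting failure probability in \[0, 1\].
#' @examples
#' sys <- table1_system(rho = 0.75)
#' limiting_failure_probability(sys$goods[[1]], sys)  # exp(-8)
#' @export
limiting_failure_probability <- function(spec, system) {
  if (inherits(spec, "generic_good_spec")) return(spec$failure_fn(0))
  lat <- latency_factor(system)
  t_eff <- system$tau - lat * spec$d
  if (t_eff <= 0) return(1)
  exp(-spec$mu * t_eff)
}

#' Reference three-server mobile-network system
#'
#' The benchmark system used throughout the package's experiments: 1000 users
#' and three M/M/1/10 servers with capacities \{100, 200, 400\} requests/s,
#' one-way latencies \{10, 20, 30\} ms and a 100 ms service timeout.
#'
#' @param rho System workload (default 0.75).
#' @param Nu Population size (default 1000).
#' @param scale Proportional scaling factor applied to `Nu` and every `mu_i`
#'   (workload `rho` is preserved); used for fast reduced-scale runs. Note
#'   that scaling capacities changes service times relative to the timeout,
#'   so failure levels at reduced scale differ from full scale.
#' @param ... Passed on to [system_spec()] (e.g. `latency_mode`).
#' @return A `"wsls_system"`.
#' @export
table1_system <- function(rho = 0.75, Nu = 1000, scale = 1, ...) {
  stopifnot(scale > 0)
  mus <- c(100, 200, 400) * scale
  ds <- c(0.010, 0.020, 0.030)
  goods <- lapply(seq_along(mus), function(i)
    queue_server_spec(mu = mus[i], c = 1L, k = 10L, d = ds[i]))
  system_spec(goods, Nu = max(1, round(Nu * scale)), tau = 0.100, rho = rho, ...)
}
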