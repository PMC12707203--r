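#' Configure a WSLS agent simulation
#'
#' Assembles a validated configuration for the seeded discrete-event
#' simulation: every user emits an open-loop Poisson stream of requests to
#' its current server, learns each outcome (loss at a full buffer, or a
#' response later than the timeout) after the return latency, and shifts to
#' another good once its per-stay failure count reaches its tolerance for
#' the current good.
#'
#' @param system A [system_spec()] whose goods are all queue servers.
#' @param duration Simulated seconds (> 0).
#' @param mode `"fixed"`: constant tolerances; `"adaptive"`: each agent keeps
#'   per-good failure-probability estimates and moves one tolerance unit
#'   toward its best-estimated good at every shift.
#' @param tolerance Fixed-mode tolerance: a scalar, a length-`Ng` vector, or
#'   an `Nu x Ng` integer matrix (per-agent). Ignored in adaptive mode.
#' @param T0 Adaptive mode: initial tolerance on every good (default 5); the
#'   per-agent tolerance sum stays at `Ng * T0` forever.
#' @param x0 Adaptive mode: initial per-good failure-probability estimate.
#' @param beta Adaptive learning rate in (0, 1\].
#' @param shift_rule `"uniform"`: destination uniform over the other goods;
#'   `"proportional"`: probability proportional to the agent's tolerance on
#'   the other goods (zero-tolerance goods never chosen).
#' @param schedule Optional workload schedule, data.frame with columns
#'   `length` (seconds) and `rho`; segments must cover `duration`. Omitted:
#'   constant workload from `system`.
#' @param seed RNG seed (integer); identical configurations with identical
#'   seeds give bit-identical output.
#' @param sample_dt Metrics sampling interval in seconds (default 1).
#' @param init Optional initial server assignment, length-`Nu` integer vector
#'   in `1..Ng`; default: uniform at random (from the run's RNG).
#' @return An object of class `"sim_config"`.
#' @seealso [run_simulation()]
#' @export
sim_config <- function(system, duration,
                       mode = c("fixed", "adaptive"),
                       tolerance = 1L, T0 = 5L, x0 = 0, beta = 0.1,
                       shift_rule = c("uniform", "proportional"),
                       schedule = NULL, seed = 1L, sample_dt = 1, init = NULL) {
  mode <- match.arg(mode); shift_rule <- match.arg(shift_rule)
  stopifnot(inherits(system, "wsls_system"))
  if (!all(vapply(system$goods, inherits, logical(1L), "queue_server_spec")))
    stop("the agent simulator requires queue-server goods")
  if (duration <= 0) stop("'duration' must be positive")
  if (beta <= 0 || beta > 1) stop("'beta' must be in (0, 1]")
  if (T0 < 1 || T0 != round(T0)) stop("'T0' must be a positive integer")
  if (sample_dt <= 0) stop("'sample_dt' must be positive")
  if (!is.null(schedule)) {
    schedule <- as.data.frame(schedule)
    if (!all(c("length", "rho") %in% names(schedule)))
      stop("'schedule' needs columns 'length' and 'rho'")
    if (sum(schedule$length) < duration - 1e-9)
      stop("schedule does not cover the duration")
  }
  if (!is.null(init)) {
    init <- as.integer(init)
    if (length(init) != system$Nu || any(init < 1L | init > system$Ng))
      stop("'init' must be a length-Nu vector of good indices in 1..Ng")
  }
  structure(list(system = system, duration = duration, mode = mode,
                 tolerance = tolerance, T0 = as.integer(T0), x0 = x0,
                 beta = beta, shift_rule = shift_rule, schedule = schedule,
                 seed = as.integer(seed), sample_dt = sample_dt, init = init),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("WSLS simulation config: %s tolerance, %s shifting, %g s, seed %d\n",
              x$mode, x$shift_rule, x$duration, x$seed))
  print(x$system)
  invisible(x)
}

#' Run the discrete-event WSLS agent simulation
#'
#' Executes the configuration in event order (strict timestamp ordering,
#' ties broken by insertion sequence) and records, every `sample_dt`
#' seconds: the instantaneous occupancy of each good, the per-good and
#' system-level empirical failure probability over the elapsed window
#' (failures / attempts), and the population-mean tolerance per good.
#' Outcomes of requests emitted before an agent's shift still count in the
#' metrics but never toward the new stay's failure counter.
#'
#' @param config A [sim_config()].
#' @return An object of class `"wsls_sim"`: the `config`, a data.frame `ts`
#'   with columns `t`, `n_1..n_Ng`, `fail_1..fail_Ng`, `fail_sys`,
#'   `meanT_1..meanT_Ng`, raw per-window `attempts`/`failures` matrices, the
#'   final per-agent tolerance matrix and assignment, and overall totals.
#' @examples
#' sys <- table1_system(rho = 0.75, scale = 0.1)
#' sim <- run_simulation(sim_config(sys, duration = 50, tolerance = 1, seed = 7))
#' summary(sim)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sys <- config$system
  Nu <- as.integer(sys$Nu); Ng <- sys$Ng
  mu <- vapply(sys$goods, `[[`, numeric(1L), "mu")
  d <- vapply(sys$goods, `[[`, numeric(1L), "d")
  cc <- vapply(sys$goods, `[[`, integer(1L), "c")
  kk <- vapply(sys$goods, `[[`, integer(1L), "k")

  if (config$mode == "adaptive") {
    tol_init <- matrix(config$T0, Nu, Ng)
  } else {
    tl <- config$tolerance
    if (is.matrix(tl)) {
      if (!all(dim(tl) == c(Nu, Ng))) stop("'tolerance' matrix must be Nu x Ng")
      tol_init <- tl
    } else if (length(tl) == 1L) tol_init <- matrix(tl, Nu, Ng)
    else if (length(tl) == Ng) tol_init <- matrix(tl, Nu, Ng, byrow = TRUE)
    else stop("'tolerance' must be a scalar, length-Ng vector, or Nu x Ng matrix")
    if (any(tol_init < 1)) stop("fixed tolerances must be >= 1")
  }
  storage.mode(tol_init) <- "integer"

  if (is.null(config$schedule)) {
    seg_end <- config$duration
    seg_lambda <- sys$lambda_u
  } else {
    seg_end <- cumsum(config$schedule$length)
    seg_lambda <- config$schedule$rho * sys$mu / sys$Nu
  }
  init <- if (is.null(config$init)) rep(-1L, Nu) else config$init - 1L

  raw <- .des_run(Nu, mu, d, cc, kk, sys$tau, latency_factor(sys),
                  as.numeric(seg_end), as.numeric(seg_lambda),
                  config$duration, config$sample_dt,
                  as.integer(config$mode == "adaptive"),
                  config$beta, config$x0, tol_init,
                  as.integer(config$shift_rule == "proportional"),
                  init, as.numeric(config$seed))

  ts <- data.frame(t = raw$t, raw$occupancy, raw$fail_rate,
                   fail_sys = raw$sys_fail, raw$mean_tol)
  names(ts) <- c("t", paste0("n_", seq_len(Ng)), paste0("fail_", seq_len(Ng)),
                 "fail_sys", paste0("meanT_", seq_len(Ng)))
  structure(list(config = config, ts = ts,
                 attempts = raw$attempts, failures = raw$failures,
                 tol_final = raw$tol_final, assign_final = raw$assign_final + 1L,
                 total_attempts = raw$total_attempts,
                 total_failures = raw$total_failures),
            class = "wsls_sim")
}

#' @export
print.wsls_sim <- function(x, ...) {
  Ng <- x$config$system$Ng
  cat(sprintf("WSLS simulation: %g s, %d samples, %s tolerance, seed %d\n",
              x$config$duration, nrow(x$ts), x$config$mode, x$config$seed))
  cat(sprintf("  total attempts: %.0f, overall failure fraction: %.5f\n",
              x$total_attempts, x$total_failures / max(x$total_attempts, 1)))
  cat("  final occupancy:",
      paste(utils::tail(x$ts[paste0("n_", seq_len(Ng))], 1), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.wsls_sim <- function(object, tail_fraction = 0.1, smooth = 0.01, ...) {
  summarize_steady_state(object, tail_fraction = tail_fraction, smooth = smooth)
}

#' @export
plot.wsls_sim <- function(x, what = c("occupancy", "failure", "tolerance"), ...) {
  what <- match.arg(what)
  Ng <- x$config$system$Ng
  cols <- switch(what,
                 occupancy = paste0("n_", seq_len(Ng)),
                 failure = paste0("fail_", seq_len(Ng)),
                 tolerance = paste0("meanT_", seq_len(Ng)))
  graphics::matplot(x$ts$t, as.matrix(x$ts[cols]), type = "l", lty = 1,
                    xlab = "time (s)", ylab = what, ...)
  graphics::legend("topright", legend = paste0("G", seq_len(Ng)),
                   col = seq_len(Ng), lty = 1, bty = "n")
  invisible(x)
}

#' Exponentially smoothed failure estimate update
#'
#' The adaptive learning step applied when an agent leaves a good after
#' accumulating its tolerance `tol_i` of failures over `R` usage attempts:
#' the per-good failure-probability estimate is exponentially smoothed
#' toward the experienced rate, `x <- (1 - beta) x + beta * tol_i / R`.
#'
#' @param est Current estimate in \[0, 1\].
#' @param tol_i Tolerance (failures accumulated), positive integer.
#' @param R Usage attempts over which they accumulated, `R >= tol_i`.
#' @param beta Learning rate in (0, 1\].
#' @return Updated estimate in \[0, 1\].
#' @examples
#' update_estimate(0, tol_i = 5, R = 50, beta = 0.1)  # 0.01
#' @export
update_estimate <- function(est, tol_i, R, beta) {
  if (beta <= 0 || beta > 1) stop("'beta' must be in (0, 1]")
  if (tol_i < 1) stop("'tol_i' must be >= 1")
  if (R < tol_i) stop("inconsistent attempt count: R < tol_i")
  (1 - beta) * est + beta * tol_i / R
}

#' Tolerance reallocation toward the best-estimated good
#'
#' When an agent shifts away from good `i`, one tolerance unit moves from
#' `i` to the good with the lowest estimated failure probability `l`,
#' provided the estimate there is strictly lower than at `i` and the
#' tolerance at `i` stays at least 1. The sum of the vector is preserved.
#' Ties at the minimum are broken uniformly at random (R's RNG).
#'
#' @param tol Integer tolerance vector.
#' @param est Estimated failure probabilities, same length.
#' @param i Index of the good being left.
#' @return Updated tolerance vector.
#' @examples
#' update_tolerance(c(5, 5, 5), c(0.10, 0.02, 0.05), i = 1)  # c(4, 6, 5)
#' @export
update_tolerance <- function(tol, est, i) {
  if (length(tol) != length(est)) stop("'tol' and 'est' must have equal length")
  minima <- which(est == min(est))
  l <- if (length(minima) == 1L) minima else minima[sample.int(length(minima), 1L)]
  if (est[l] < est[i] && tol[i] > 1) {
    tol[i] <- tol[i] - 1L
    tol[l] <- tol[l] + 1L
  }
  tol
}

#' Choose the destination good of a shift
#'
#' Uniform rule: each of the other `Ng - 1` goods with equal probability.
#' Proportional rule: probability proportional to the agent's tolerance on
#' each other good; zero-tolerance goods are never chosen. Uses R's RNG.
#'
#' @param current Index of the good being left.
#' @param Ng Number of goods (`>= 2`).
#' @param rule `"uniform"` or `"proportional"`.
#' @param tol Tolerance vector (required for the proportional rule).
#' @return Destination index, never equal to `current`.
#' @export
shift_destination <- function(current, Ng, rule = c("uniform", "proportional"),
                              tol = NULL) {
  rule <- match.arg(rule)
  if (Ng < 2) stop("shifting is undefined with fewer than 2 goods")
  others <- setdiff(seq_len(Ng), current)
  if (rule == "uniform") return(others[sample.int(Ng - 1L, 1L)])
  if (is.null(tol)) stop("the proportional rule needs the tolerance vector")
  w <- tol[others]
  if (sum(w) <= 0) stop("proportional shift rule: all other goods have zero tolerance")
  others[sample.int(length(others), 1L, prob = w)]
}

#' Steady-state summary of a simulation time series
#'
#' Applies an exponential low-pass filter
#' `s_t = (1 - smooth) s_{t-1} + smooth x_t` to the system-level failure
#' probability and averages it over the trailing `tail_fraction` of samples
#' (default: the last 10%). Also reports per-good occupancy and failure
#' means and their coefficients of variation over a trailing window.
#'
#' @param x A `"wsls_sim"` object, or a data.frame shaped like its `ts`.
#' @param tail_fraction Fraction of trailing samples averaged, in (0, 1\].
#' @param smooth Smoothing constant of the low-pass filter in (0, 1\];
#'   1 disables smoothing.
#' @param cv_window Trailing window (seconds) for the coefficients of
#'   variation (default 2000, clipped to the series length).
#' @return List of class `"wsls_steady"`: `sys_fail` (smoothed trailing
#'   average), `occupancy` and `fail_rate` per-good trailing means,
#'   `cv_occupancy` and `cv_fail` per-good coefficients of variation, and
#'   the window sizes used.
#' @examples
#' s <- summarize_steady_state(data.frame(t = 1:100, fail_sys = rep(0.3, 100)))
#' s$sys_fail  # 0.3
#' @export
summarize_steady_state <- function(x, tail_fraction = 0.1, smooth = 0.01,
                                   cv_window = 2000) {
  ts <- if (inherits(x, "wsls_sim")) x$ts else as.data.frame(x)
  if (tail_fraction <= 0 || tail_fraction > 1)
    stop("'tail_fraction' must be in (0, 1]")
  if (smooth <= 0 || smooth > 1) stop("'smooth' must be in (0, 1]")
  n <- nrow(ts)
  ntail <- max(1L, floor(n * tail_fraction))
  if (ntail < 1 || n < 1) stop("empty series")
  lp <- function(v) {
    s <- v
    for (j in seq_along(v)[-1]) s[j] <- (1 - smooth) * s[j - 1] + smooth * v[j]
    s
  }
  tail_idx <- seq.int(n - ntail + 1L, n)
  out <- list(sys_fail = mean(lp(ts$fail_sys)[tail_idx]),
              n_tail = ntail, smooth = smooth)
  occ_cols <- grep("^n_", names(ts), value = TRUE)
  fail_cols <- grep("^fail_[0-9]+$", names(ts), value = TRUE)
  if (length(occ_cols)) {
    dt <- if (n > 1) stats::median(diff(ts$t)) else 1
    nwin <- min(n, max(2L, floor(cv_window / dt)))
    win <- seq.int(n - nwin + 1L, n)
    cv <- function(v) stats::sd(v) / mean(v)
    out$occupancy <- colMeans(ts[tail_idx, occ_cols, drop = FALSE])
    out$fail_rate <- colMeans(ts[tail_idx, fail_cols, drop = FALSE])
    out$cv_occupancy <- apply(ts[win, occ_cols, drop = FALSE], 2, cv)
    out$cv_fail <- apply(ts[win, fail_cols, drop = FALSE], 2, cv)
    out$cv_n <- nwin
  }
  class(out) <- "wsls_steady"
  out
}

#' @export
print.wsls_steady <- function(x, ...) {
  cat(sprintf("steady state over last %d samples (smoothing %.3g):\n",
              x$n_tail, x$smooth))
  cat(sprintf("  system failure probability: %.5f\n", x$sys_fail))
  if (!is.null(x$occupancy)) {
    cat("  occupancy:", paste(sprintf("%.2f", x$occupancy), collapse = ", "), "\n")
    cat("  per-good failure:", paste(sprintf("%.5f", x$fail_rate), collapse = ", "), "\n")
  }
  invisible(x)
}
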