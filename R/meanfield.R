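#' Rate of change of the population distribution under WSLS
#'
#' Mean-field dynamics of a large homogeneous population using Win-Stay,
#' Lose-Shift: users on good `i` fail at rate `lambda_u * n_i * P_i(F)(n_i)`
#' and leave, while failures elsewhere redistribute uniformly over the other
#' `Ng - 1` goods,
#' \deqn{\dot n_i = -\lambda_u n_i P_i^{(F)}(n_i)
#'   + \frac{1}{N_g - 1}\sum_{j \ne i} \lambda_u n_j P_j^{(F)}(n_j).}
#' The total population is conserved exactly (inflow equals outflow).
#'
#' @param n Occupancy vector (length `Ng`, nonnegative reals).
#' @param system A [system_spec()].
#' @param lambda_u Per-user request rate; defaults to the system's.
#' @return Vector of occupancy rates of change, summing to zero.
#' @examples
#' sys <- table1_system(rho = 0.75)
#' wsls_rhs(rep(sys$Nu / 3, 3), sys)
#' @export
wsls_rhs <- function(n, system, lambda_u = system$lambda_u) {
  stopifnot(length(n) == system$Ng, all(n >= -1e-9))
  flux <- lambda_u * n * system_p_fail(system, n)   # outflow per good
  -flux + (sum(flux) - flux) / (system$Ng - 1)
}

#' Rate of change for a tolerance-typed population
#'
#' Mean-field dynamics of `Nt` subpopulations whose members of type `k`
#' accept `T_i(k)` failures on good `i` before shifting; a randomly chosen
#' attempt triggers a shift with probability `P_i(F)(n_i) / T_i(k)`, so
#' \deqn{\dot n_{ik} = -\lambda_u n_{ik} \frac{P_i^{(F)}(n_i)}{T_i(k)}
#'  + \frac{1}{N_g - 1}\sum_{j \ne i} \lambda_u n_{jk}
#'    \frac{P_j^{(F)}(n_j)}{T_j(k)},}
#' with the failure probability evaluated at the *total* occupancy
#' `n_i = sum_k n_ik`. With a single type and a constant tolerance `T` this
#' reduces to [wsls_rhs()] divided by `T`: the tolerance only stretches the
#' timescale. A zero tolerance means the type never enters that good; a zero
#' tolerance on an occupied good is an error.
#'
#' @param occ Occupancy matrix, `Nt` rows (types) by `Ng` columns (goods).
#' @param system A [system_spec()].
#' @param tol Tolerance matrix `T_i(k)`, same shape as `occ`, nonnegative.
#' @param lambda_u Per-user request rate; defaults to the system's.
#' @return Matrix of rates, each row summing to zero.
#' @export
typed_rhs <- function(occ, system, tol, lambda_u = system$lambda_u) {
  occ <- rbind(occ); tol <- rbind(tol)
  if (!all(dim(occ) == dim(tol)) || ncol(occ) != system$Ng)
    stop("'occ' and 'tol' must both be Nt x Ng matrices")
  if (any(tol < 0)) stop("tolerances must be nonnegative")
  bad <- which(tol == 0 & occ > 1e-12, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("type %d occupies good %d but has zero tolerance there",
                 bad[1, 1], bad[1, 2]))
  pf <- system_p_fail(system, colSums(occ))
  rate <- sweep(occ, 2, lambda_u * pf, "*") / ifelse(tol == 0, 1, tol)
  rate[tol == 0] <- 0
  -rate + (rowSums(rate) - rate) / (system$Ng - 1)
}

#' Integrate the WSLS population dynamics
#'
#' Integrates the homogeneous ([wsls_rhs()]) or typed ([typed_rhs()])
#' mean-field ODEs with `deSolve`'s adaptive stiff-capable `lsoda`
#' (`rtol = 1e-8`). The workload may vary in time through a piecewise-constant
#' schedule of `(length_seconds, rho)` segments; integration restarts at each
#' breakpoint so the discontinuity is exact. Occupancies are renormalized to
#' `sum(n) = Nu` at every output step to suppress integrator drift.
#'
#' @param system A [system_spec()].
#' @param initial Initial occupancy vector (homogeneous) or `Nt x Ng` matrix
#'   (typed). Must sum to `Nu`.
#' @param times Increasing vector of output times (seconds).
#' @param tol Optional tolerance matrix; if given, the typed dynamics are
#'   integrated.
#' @param schedule Optional workload schedule: data.frame or matrix with
#'   columns `length` (seconds) and `rho`. Segments must cover `max(times)`.
#'   Omitted: the system's own constant workload.
#' @return Object of class `"wsls_trajectory"`: list with `times`, occupancy
#'   array `n` (time x goods, types summed), per-good failure probabilities
#'   `p_fail`, population-mean failure `mean_fail`, and the per-type array
#'   `occ` (time x types x goods) when typed.
#' @examples
#' sys <- table1_system(rho = 0.75)
#' tr <- integrate_trajectory(sys, c(900, 50, 50), times = seq(0, 200, 5))
#' tail(tr$n, 1)
#' @export
integrate_trajectory <- function(system, initial, times, tol = NULL,
                                 schedule = NULL) {
  if (is.unsorted(times, strictly = TRUE)) stop("'times' must be strictly increasing")
  typed <- !is.null(tol) || is.matrix(initial)
  init <- if (typed) rbind(initial) else as.numeric(initial)
  if (typed && is.null(tol)) stop("typed initial state needs a tolerance matrix 'tol'")
  if (abs(sum(init) - system$Nu) > 1e-6 * system$Nu)
    stop("initial occupancies must sum to Nu")
  Ng <- system$Ng
  Nt <- if (typed) nrow(init) else 1L

  seg <- if (is.null(schedule)) {
    data.frame(length = max(times), rho = system$rho)
  } else as.data.frame(schedule)
  if (!all(c("length", "rho") %in% names(seg)))
    stop("'schedule' needs columns 'length' and 'rho'")
  brk <- cumsum(seg$length)
  if (max(times) > brk[length(brk)] + 1e-9)
    stop("schedule does not cover the requested times")
  lam_of <- function(rho) rho * system$mu / system$Nu

  deriv <- function(t, y, parms) {
    if (typed) {
      m <- matrix(y, Nt, Ng)
      list(as.vector(typed_rhs(m, system, tol, lambda_u = parms$lam)))
    } else list(wsls_rhs(y, system, lambda_u = parms$lam))
  }

  out_t <- numeric(0); out_y <- NULL
  t0 <- 0; y0 <- as.vector(init)
  for (s in seq_len(nrow(seg))) {
    t1 <- brk[s]
    tt <- times[times > t0 + 1e-12 & times <= t1 + 1e-12]
    grid <- unique(c(t0, tt, min(t1, max(times))))
    if (length(grid) >= 2) {
      sol <- deSolve::ode(y = y0, times = grid, func = deriv,
                          parms = list(lam = lam_of(seg$rho[s])),
                          method = "lsoda", rtol = 1e-8, atol = 1e-8 * system$Nu)
      if (attr(sol, "istate")[1] < 0)
        stop(sprintf("ODE integration failed near t = %g s", utils::tail(sol[, 1], 1)))
      y0 <- as.numeric(sol[nrow(sol), -1])
      y0 <- y0 * system$Nu / sum(y0)            # renormalize conservation
      keep <- sol[, 1] %in% tt
      if (any(keep)) {
        ym <- sol[keep, -1, drop = FALSE]
        ym <- ym * system$Nu / rowSums(ym)
        out_t <- c(out_t, sol[keep, 1]); out_y <- rbind(out_y, ym)
      }
    }
    t0 <- t1
    if (t0 >= max(times)) break
  }
  if (any(abs(times - 0) < 1e-12)) {           # include t = 0 if requested
    out_t <- c(0, out_t); out_y <- rbind(as.vector(init), out_y)
  }
  n_tot <- if (typed) {
    t(apply(out_y, 1, function(y) colSums(matrix(y, Nt, Ng))))
  } else out_y
  pf <- t(apply(n_tot, 1, function(n) system_p_fail(system, n)))
  colnames(n_tot) <- paste0("n", seq_len(Ng))
  colnames(pf) <- paste0("pfail", seq_len(Ng))
  res <- list(times = out_t, n = n_tot, p_fail = pf,
              mean_fail = rowSums(n_tot * pf) / system$Nu,
              system = system, typed = typed)
  if (typed) {
    res$occ <- array(t(out_y), dim = c(Nt, Ng, length(out_t)))
    res$tol <- tol
  }
  class(res) <- "wsls_trajectory"
  res
}

#' @export
print.wsls_trajectory <- function(x, ...) {
  cat(sprintf("WSLS mean-field trajectory: %d samples over [%g, %g] s, %d goods\n",
              length(x$times), min(x$times), max(x$times), ncol(x$n)))
  cat("final occupancies:", paste(sprintf("%.2f", utils::tail(x$n, 1)), collapse = ", "), "\n")
  cat(sprintf("final mean failure probability: %.5f\n", utils::tail(x$mean_fail, 1)))
  invisible(x)
}

#' @export
plot.wsls_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$n, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "occupancy n_i", ...)
  graphics::legend("topright", legend = paste0("G", seq_len(ncol(x$n))),
                   col = seq_len(ncol(x$n)), lty = 1, bty = "n")
  invisible(x)
}

#' As-data.frame for trajectories (CSV-friendly)
#' @param x A `"wsls_trajectory"`.
#' @param ... Unused.
#' @return data.frame with time, occupancies, failure probabilities, mean.
#' @export
as.data.frame.wsls_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$n, x$p_fail, mean_fail = x$mean_fail,
             check.names = FALSE)
}

# invert g(n) = n * p_fail(n) (strictly increasing where p_fail > 0) on [0, Nu]
invert_flux <- function(system, i, phi, Nu = system$Nu) {
  if (phi <= 0) return(0)
  g <- function(n) n * good_p_fail(system, i, n) - phi
  if (g(Nu) < 0) return(Nu)   # cap: this good cannot carry flux phi within [0, Nu]
  stats::uniroot(g, c(0, Nu), tol = 1e-13 * max(1, Nu))$root
}

#' Equilibrium of the homogeneous WSLS dynamics
#'
#' Solves the balance conditions
#' `n_1 P_1(F)(n_1) = ... = n_Ng P_Ng(F)(n_Ng)` with `sum(n_i) = Nu`:
#' at rest every good sheds users (failure flux) at the same rate `phi`.
#' The solver bisects on the common flux `phi`; each good's occupancy
#' `n_i(phi)` is the monotone inverse of `n -> n P_i(F)(n)`, so the outer
#' problem `sum_i n_i(phi) = Nu` is one-dimensional and monotone.
#' Monotonicity of every failure curve is asserted on a grid first.
#'
#' @param system A [system_spec()].
#' @param check_monotone Assert `p_fail` nondecreasing on a 0..Nu grid
#'   (default TRUE).
#' @return Object of class `"wsls_equilibrium"`: occupancies `n`, per-good
#'   `p_fail`, common flux `phi`, population-mean failure `mean_fail`, and
#'   the residual of the balance conditions.
#' @examples
#' eq <- solve_equilibrium(table1_system(rho = 0.75))
#' eq$n
#' @export
solve_equilibrium <- function(system, check_monotone = TRUE) {
  Nu <- system$Nu; Ng <- system$Ng
  if (check_monotone) assert_monotone_failure(system)
  tot <- function(phi) sum(vapply(seq_len(Ng), function(i)
    invert_flux(system, i, phi), numeric(1L)))
  hi <- max(vapply(seq_len(Ng), function(i)
    Nu * good_p_fail(system, i, Nu), numeric(1L)))
  if (hi <= 0) {  # failure-free system: flat dynamics, any state is at rest
    n <- rep(Nu / Ng, Ng)
    return(new_equilibrium(system, n, phi = 0))
  }
  lo <- 0
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (tot(mid) < Nu) lo <- mid else hi <- mid
  }
  phi <- (lo + hi) / 2
  n <- vapply(seq_len(Ng), function(i) invert_flux(system, i, phi), numeric(1L))
  n <- n * Nu / sum(n)
  eq <- new_equilibrium(system, n, phi)
  if (eq$residual > 1e-8 * max(phi, 1e-300))
    stop("equilibrium solver did not reach the requested residual; is every failure curve monotone?")
  eq
}

new_equilibrium <- function(system, n, phi) {
  pf <- system_p_fail(system, n)
  flux <- n * pf
  structure(list(n = n, p_fail = pf, phi = phi,
                 mean_fail = sum(n * pf) / system$Nu,
                 residual = max(abs(flux - mean(flux))),
                 system = system),
            class = "wsls_equilibrium")
}

#' @export
print.wsls_equilibrium <- function(x, ...) {
  cat("WSLS equilibrium (homogeneous population)\n")
  cat("  n      :", paste(sprintf("%.3f", x$n), collapse = ", "), "\n")
  cat("  P(F)   :", paste(sprintf("%.5f", x$p_fail), collapse = ", "), "\n")
  cat(sprintf("  mean failure probability: %.5f (balance residual %.2e)\n",
              x$mean_fail, x$residual))
  invisible(x)
}

# grid assertion that every good's failure curve is nondecreasing in load
assert_monotone_failure <- function(system, grid_n = 64L) {
  grid <- seq(0, system$Nu, length.out = grid_n)
  for (i in seq_len(system$Ng)) {
    v <- vapply(grid, function(n) good_p_fail(system, i, n), numeric(1L))
    if (any(diff(v) < -1e-9))
      stop(sprintf("failure probability of good %d is not nondecreasing in n", i))
  }
  invisible(TRUE)
}

#' Equilibrium of the tolerance-typed WSLS dynamics
#'
#' Solves the typed balance conditions
#' `n_1k P_1(F)(n_1)/T_1(k) = ... = n_Ngk P_Ng(F)(n_Ng)/T_Ng(k)` for all
#' types `k` with per-type populations `sum_i n_ik = Nu(k)`. At equilibrium
#' the per-type occupancies have the closed form
#' `n_ik = Nu(k) (T_i(k)/P_i(F)(n_i)) / sum_j (T_j(k)/P_j(F)(n_j))`,
#' which depends on the unknown totals `n_i` only; the solver iterates this
#' self-consistency map with damping until the balance residual is below
#' `1e-8` (relative). Types with zero tolerance on a good never occupy it.
#'
#' @param system A [system_spec()].
#' @param sizes Subpopulation sizes `Nu(k)`, summing to `Nu`.
#' @param tol Tolerance matrix `T_i(k)` (`Nt` rows, `Ng` columns),
#'   nonnegative; each row must have at least one positive entry.
#' @return Object of class `"wsls_typed_equilibrium"`: per-type occupancy
#'   matrix `occ`, totals `n`, per-good `p_fail`, mean failure, residual.
#' @examples
#' sys <- table1_system(rho = 0.75)
#' eq <- solve_typed_equilibrium(sys, sizes = 1000, tol = matrix(1, 1, 3))
#' @export
solve_typed_equilibrium <- function(system, sizes, tol) {
  tol <- rbind(tol)
  Nt <- nrow(tol); Ng <- system$Ng; Nu <- system$Nu
  if (ncol(tol) != Ng) stop("'tol' must have Ng columns")
  if (length(sizes) != Nt) stop("'sizes' must have one entry per tolerance row")
  if (abs(sum(sizes) - Nu) > 1e-6 * Nu) stop("subpopulation sizes must sum to Nu")
  if (any(tol < 0)) stop("tolerances must be nonnegative")
  if (any(rowSums(tol > 0) == 0)) stop("every type needs a positive tolerance somewhere")
  assert_monotone_failure(system)

  # Parameterize by the per-type shift flux phi_k = n_ik q_i / T_i(k): given
  # phi, each good's total flux is n_i q_i(n_i) = sum_k phi_k T_i(k), whose
  # monotone inversion yields n_i, hence q_i, hence refreshed
  # phi_k = Nu(k) / sum_i T_i(k)/q_i. The inner inversion keeps the
  # iteration on bounded, physically meaningful states.
  occ_of <- function(phi) {
    flux <- as.vector(phi %*% tol)                 # total flux per good
    n_tot <- vapply(seq_len(Ng), function(i)
      invert_flux(system, i, flux[i]), numeric(1L))
    q <- pmax(system_p_fail(system, n_tot), 1e-300)
    occ <- sweep(tol, 2, q, "/") * phi             # n_ik = phi_k T_ik / q_i
    list(occ = occ, n_tot = n_tot, q = q)
  }
  residual_of <- function(st) {
    res <- 0
    for (kk in seq_len(Nt)) {
      sup <- tol[kk, ] > 0
      flux <- st$occ[kk, sup] * st$q[sup] / tol[kk, sup]
      res <- max(res, max(abs(flux - mean(flux))) / max(mean(flux), 1e-300),
                 abs(sum(st$occ[kk, ]) - sizes[kk]) / sizes[kk])
    }
    res
  }
  q0 <- pmax(system_p_fail(system,
                           solve_equilibrium(system, check_monotone = FALSE)$n),
             1e-300)
  phi <- vapply(seq_len(Nt), function(kk)
    sizes[kk] / sum(tol[kk, ] / q0), numeric(1L))
  alpha <- 0.7
  st <- occ_of(phi)
  for (it in 1:2000) {
    phi_new <- vapply(seq_len(Nt), function(kk)
      sizes[kk] / sum(tol[kk, ] / st$q), numeric(1L))
    phi <- exp((1 - alpha) * log(phi) + alpha * log(phi_new))
    st <- occ_of(phi)
    if (residual_of(st) < 1e-10) break
  }
  occ <- st$occ
  # exact per-type normalization removes the last drop of iteration error
  occ <- occ * (sizes / rowSums(occ))
  n_tot <- colSums(rbind(occ))
  res <- residual_of(list(occ = occ, n_tot = n_tot,
                          q = pmax(system_p_fail(system, n_tot), 1e-300)))
  if (res > 1e-8)
    stop(sprintf("typed equilibrium iteration stalled at relative residual %.2e", res))
  pf <- system_p_fail(system, n_tot)
  structure(list(occ = occ, n = n_tot, p_fail = pf,
                 mean_fail = sum(n_tot * pf) / Nu,
                 residual = res, sizes = sizes, tol = tol, system = system),
            class = "wsls_typed_equilibrium")
}

#' @export
print.wsls_typed_equilibrium <- function(x, ...) {
  cat(sprintf("WSLS typed equilibrium: %d types over %d goods\n",
              nrow(x$occ), ncol(x$occ)))
  cat("  totals n:", paste(sprintf("%.3f", x$n), collapse = ", "), "\n")
  cat("  P(F)    :", paste(sprintf("%.5f", x$p_fail), collapse = ", "), "\n")
  cat(sprintf("  mean failure: %.5f (relative residual %.2e)\n",
              x$mean_fail, x$residual))
  invisible(x)
}
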