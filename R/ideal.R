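#' Equalized-quality ideal distribution
#'
#' Computes the ideal distribution `n*`: the occupancies at which every
#' *used* good has the same failure probability `p*` (equal to the
#' population-average experienced failure), while every unused good would
#' exceed `p*` even at vanishing load. This is the ideal-free-distribution
#' notion for congestible commons, computed by water-filling: bisection on
#' the common level `p*`, with each active good's occupancy obtained by
#' monotone inversion of its failure curve; a good is inactive iff its
#' zero-load failure limit already exceeds the candidate `p*`.
#'
#' @param system A [system_spec()].
#' @return Object of class `"wsls_ideal"`: `n_star` (occupancies, summing to
#'   `Nu`), `active` / `inactive` good index sets, `p_star` (common failure
#'   probability), `n_min = min(n_star)`.
#' @examples
#' id <- ideal_distribution(table1_system(rho = 0.75))
#' id$p_star
#' @export
ideal_distribution <- function(system) {
  Nu <- system$Nu; Ng <- system$Ng
  assert_monotone_failure(system)
  lim0 <- vapply(seq_len(Ng), function(i)
    limiting_failure_probability(system$goods[[i]], system), numeric(1L))
  pmax_i <- vapply(seq_len(Ng), function(i) good_p_fail(system, i, Nu), numeric(1L))
  n_of_p <- function(p) vapply(seq_len(Ng), function(i) {
    if (lim0[i] >= p) return(0)              # unused: too bad even when empty
    if (pmax_i[i] <= p) return(Nu)           # cap within [0, Nu]
    stats::uniroot(function(n) good_p_fail(system, i, n) - p, c(0, Nu),
                   tol = 1e-13 * max(1, Nu))$root
  }, numeric(1L))
  lo <- min(lim0); hi <- max(pmax_i)
  if (sum(n_of_p(hi)) < Nu - 1e-9)
    stop("no feasible common failure level: curves cannot absorb the population")
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    if (sum(n_of_p(mid)) < Nu) lo <- mid else hi <- mid
  }
  p_star <- (lo + hi) / 2
  n_star <- n_of_p(p_star)
  active <- which(n_star > 0)
  if (sum(n_star) > 0) n_star[active] <- n_star[active] * (Nu / sum(n_star))
  structure(list(n_star = n_star, active = active,
                 inactive = setdiff(seq_len(Ng), active),
                 p_star = p_star, n_min = min(n_star),
                 lim0 = lim0, system = system),
            class = "wsls_ideal")
}

#' @export
print.wsls_ideal <- function(x, ...) {
  cat("Equalized-quality ideal distribution\n")
  cat("  n*  :", paste(sprintf("%.3f", x$n_star), collapse = ", "), "\n")
  cat(sprintf("  common failure probability p*: %.6f\n", x$p_star))
  if (length(x$inactive))
    cat("  unused goods:", paste(x$inactive, collapse = ", "), "\n")
  invisible(x)
}

#' Tolerance profiles that realize the ideal distribution
#'
#' A typed population reaches the equalized-quality distribution `n*` iff its
#' tolerance vectors satisfy
#' `sum_k Nu(k) * T_i(k) / sum_j T_j(k) = n_i*`
#' (only the *ratios* within each type's vector matter). The constructive
#' mode returns normalized weight rows; with several types the construction
#' gives every type the same weights `n_i*/Nu`, which always satisfies the
#' condition. In verification mode an arbitrary profile is checked against
#' the condition to `1e-9`.
#'
#' @param ideal A [ideal_distribution()] result.
#' @param sizes Subpopulation sizes `Nu(k)`, summing to `Nu` (default: one
#'   type of size `Nu`).
#' @param profile Optional `Nt x Ng` matrix of tolerance weights to verify
#'   instead of construct (rows are normalized internally).
#' @return `Nt x Ng` matrix of normalized tolerance weights (rows sum to 1);
#'   goods with `n_i* = 0` get weight 0 in every row. Verification mode
#'   returns the normalized profile invisibly or errors.
#' @examples
#' id <- ideal_distribution(table1_system(rho = 0.75))
#' tolerance_profile_for(id)
#' @export
tolerance_profile_for <- function(ideal, sizes = ideal$system$Nu, profile = NULL) {
  Nu <- ideal$system$Nu; Ng <- length(ideal$n_star)
  if (abs(sum(sizes) - Nu) > 1e-6 * Nu) stop("'sizes' must sum to Nu")
  Nt <- length(sizes)
  if (!is.null(profile)) {
    profile <- rbind(profile)
    if (!all(dim(profile) == c(Nt, Ng)))
      stop("'profile' must be an Nt x Ng matrix matching 'sizes'")
    if (any(profile < 0)) stop("tolerance weights must be nonnegative")
    w <- profile / rowSums(profile)
    got <- colSums(w * sizes)
    bad <- which(abs(got - ideal$n_star) > 1e-9 * max(1, Nu))
    if (length(bad))
      stop(sprintf("profile does not realize n*: good %d gives %.9g, needs %.9g",
                   bad[1], got[bad[1]], ideal$n_star[bad[1]]))
    return(invisible(w))
  }
  w <- matrix(rep(ideal$n_star / Nu, each = Nt), Nt, Ng)
  if (any(w < 0)) stop(sprintf("infeasible weight for good %d", which(colSums(w) < 0)[1]))
  w
}

#' Convert tolerance weights to integer tolerance counts
#'
#' Agent-based runs need positive integer tolerances; only the ratios are
#' constrained by the theory, so rows are scaled to a configured total and
#' rounded by largest remainder.
#'
#' @param weights Matrix of normalized tolerance weights (rows sum to 1).
#' @param total Integer row total after scaling (default `5 * Ng`, i.e.
#'   `Ng * T0` with the benchmark initial tolerance `T0 = 5`).
#' @return Integer matrix with the requested row totals; zero weights stay 0.
#' @export
integer_tolerances <- function(weights, total = 5L * ncol(rbind(weights))) {
  w <- rbind(weights)
  out <- matrix(0L, nrow(w), ncol(w))
  for (r in seq_len(nrow(w))) {
    x <- w[r, ] / sum(w[r, ]) * total
    fl <- floor(x)
    rem <- total - sum(fl)
    if (rem > 0) {
      ord <- order(x - fl, decreasing = TRUE)
      fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
    }
    out[r, ] <- as.integer(fl)
  }
  out
}

#' Critical fraction of selective users in a hybrid population
#'
#' In a two-type population (a fraction `gamma` of selective users choosing
#' their own tolerance vector, the rest with a constant, good-blind
#' tolerance), the equalized-quality distribution is attainable iff
#' `gamma >= gamma_c = (Nu - Ng * n_min*) / Nu`: at `gamma_c` the selective
#' users put zero weight on the least-used good(s) and cannot compensate
#' further below. Symmetric systems (`n_min* = Nu/Ng`) give `gamma_c = 0`;
#' a good ideally unused (`n_min* = 0`) forces `gamma_c = 1`.
#'
#' @param ideal A [ideal_distribution()] result.
#' @param system The matching [system_spec()] (defaults to the one stored in
#'   `ideal`).
#' @return The critical fraction, clamped to \[0, 1\].
#' @export
critical_selective_fraction <- function(ideal, system = ideal$system) {
  g <- (system$Nu - system$Ng * ideal$n_min) / system$Nu
  min(max(g, 0), 1)
}

#' Selective-tolerance design for a hybrid population
#'
#' Solves the hybrid attainability condition
#' `(1 - gamma) Nu / Ng + gamma Nu w_i = n_i*` for the selective users'
#' tolerance weights `w_i = T_i(2)/sum_j T_j(2)`:
#' `w_i = (n_i* - (1 - gamma) Nu / Ng) / (gamma Nu)`.
#' At `gamma = gamma_c` this reduces to
#' `w_i = (n_i* - n_min*) / (Nu - Ng n_min*)`, with zero weight on every
#' good attaining the minimum; below `gamma_c` some weight would have to be
#' negative and the call errors, quoting the required critical fraction.
#'
#' @param ideal A [ideal_distribution()] result.
#' @param gamma Fraction of selective users, in `[gamma_c, 1]`.
#' @param system The matching [system_spec()].
#' @param T_nonselective Scalar tolerance of the nonselective type (default 5).
#' @return Object of class `"wsls_hybrid"`: `gamma`, `gamma_c`,
#'   `T_nonselective`, and `tol_selective` (normalized weights).
#' @examples
#' id <- ideal_distribution(table1_system(rho = 0.75))
#' hybrid_tolerances(id, gamma = 0.8)
#' @export
hybrid_tolerances <- function(ideal, gamma, system = ideal$system,
                              T_nonselective = 5) {
  gc <- critical_selective_fraction(ideal, system)
  if (gamma < gc - 1e-12)
    stop(sprintf(paste0("gamma = %.6g is below the critical selective fraction ",
                        "gamma_c = %.6g: the least-used good(s) would necessarily ",
                        "exceed n_min*"), gamma, gc))
  if (gamma > 1) stop("'gamma' must be at most 1")
  Nu <- system$Nu; Ng <- system$Ng
  if (gamma == 0) {
    w <- rep(NA_real_, Ng)  # no selective users; only feasible if symmetric
  } else {
    w <- (ideal$n_star - (1 - gamma) * Nu / Ng) / (gamma * Nu)
    w[abs(w) < 1e-12] <- 0
    if (any(w < 0))
      stop(sprintf("infeasible selective weight for good %d", which(w < 0)[1]))
  }
  structure(list(gamma = gamma, gamma_c = gc,
                 T_nonselective = T_nonselective, tol_selective = w,
                 ideal = ideal),
            class = "wsls_hybrid")
}

#' @export
print.wsls_hybrid <- function(x, ...) {
  cat(sprintf("Hybrid population design: gamma = %.4g (critical gamma_c = %.4g)\n",
              x$gamma, x$gamma_c))
  cat("  selective tolerance weights:",
      paste(sprintf("%.4f", x$tol_selective), collapse = ", "), "\n")
  invisible(x)
}
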