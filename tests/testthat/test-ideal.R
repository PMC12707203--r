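test_that("identical goods split evenly and stay fully active", {
  symm <- symmetric_system()
  id <- ideal_distribution(symm)
  expect_equal(id$n_star, rep(100, 3), tolerance = 1e-8)
  expect_identical(id$active, 1:3)
  expect_identical(length(id$inactive), 0L)
  expect_equal(id$p_star,
               failure_probability(symm$goods[[1]], 100, symm)$p_fail,
               tolerance = 1e-8)
})

test_that("benchmark ideal distribution equalizes failure and orders by capacity", {
  sys <- table1_system(rho = 0.75)
  id <- ideal_distribution(sys)
  expect_true(id$n_star[1] < id$n_star[2] && id$n_star[2] < id$n_star[3])
  expect_equal(sum(id$n_star), sys$Nu, tolerance = 1e-9)
  pf <- vapply(1:3, function(i)
    failure_probability(sys$goods[[i]], id$n_star[i], sys)$p_fail, numeric(1L))
  expect_lt(max(abs(pf - id$p_star)), 1e-8)
})

test_that("ideal level matches an independent dense grid search", {
  sys <- table1_system(rho = 0.75)
  id <- ideal_distribution(sys)
  # oracle: total occupancy absorbed at common level p, by plain bisection
  # of each failure curve (no uniroot, no package solver)
  total_at <- function(p) {
    sum(vapply(1:3, function(i) {
      g <- sys$goods[[i]]
      f <- function(n) failure_probability(g, n, sys)$p_fail - p
      if (f(0) >= 0) return(0)
      if (f(sys$Nu) <= 0) return(sys$Nu)
      bisect_oracle(f, 0, sys$Nu)
    }, numeric(1L)))
  }
  # dense local grid at 1e-6 resolution around a coarse sweep
  coarse <- seq(1e-4, 0.2, by = 1e-3)
  miss <- abs(vapply(coarse, total_at, numeric(1L)) - sys$Nu)
  p0 <- coarse[which.min(miss)]
  fine <- seq(p0 - 1e-3, p0 + 1e-3, by = 1e-6)
  missf <- abs(vapply(fine, total_at, numeric(1L)) - sys$Nu)
  p_oracle <- fine[which.min(missf)]
  expect_lt(abs(id$p_star - p_oracle), 2e-6)
})

test_that("ideal distribution is equivariant under relabeling of goods", {
  sys <- table1_system(rho = 0.75)
  perm <- c(3, 1, 2)
  sysp <- system_spec(sys$goods[perm], Nu = sys$Nu, tau = sys$tau, rho = sys$rho)
  id <- ideal_distribution(sys)
  idp <- ideal_distribution(sysp)
  expect_equal(idp$n_star, id$n_star[perm], tolerance = 1e-7)
  expect_equal(idp$p_star, id$p_star, tolerance = 1e-9)
})

test_that("goods too poor even when empty are left unused, forcing zero weights", {
  # good 2's latency alone nearly exhausts the timeout: limiting failure 0.368
  goods <- list(queue_server_spec(mu = 400, c = 1, k = 10, d = 0.001),
                queue_server_spec(mu = 100, c = 1, k = 10, d = 0.045))
  sys <- system_spec(goods, Nu = 40, tau = 0.1, lambda_u = 0.5)
  id <- ideal_distribution(sys)
  expect_identical(id$inactive, 2L)
  expect_identical(id$n_star[2], 0)
  expect_gt(limiting_failure_probability(goods[[2]], sys), id$p_star)
  w <- tolerance_profile_for(id, sizes = c(25, 15))
  expect_equal(w[, 2], c(0, 0))
  expect_equal(critical_selective_fraction(id), 1)
})

test_that("tolerance profiles realize n* and close the loop through the typed solver", {
  sys <- table1_system(rho = 0.75)
  id <- ideal_distribution(sys)
  # single type: weights proportional to n*
  w1 <- tolerance_profile_for(id)
  expect_equal(as.vector(w1), id$n_star / sys$Nu, tolerance = 1e-12)
  # multi-type construction satisfies the attainability condition
  sizes <- c(600, 400)
  w <- tolerance_profile_for(id, sizes)
  expect_equal(colSums(w * sizes), id$n_star, tolerance = 1e-9)
  # verification mode accepts it and rejects a corrupted profile
  expect_silent(tolerance_profile_for(id, sizes, profile = w))
  bad <- w; bad[1, ] <- c(0.5, 0.3, 0.2)
  expect_error(tolerance_profile_for(id, sizes, profile = bad), "good")
  # closing the loop: typed equilibrium under these tolerances recovers n*
  teq <- solve_typed_equilibrium(sys, sizes = sys$Nu, tol = w1)
  expect_lt(max(abs(teq$n - id$n_star)), 1e-6)
  expect_lt(diff(range(teq$p_fail)), 1e-6)
})

test_that("integer tolerance rounding preserves totals and zeros", {
  w <- rbind(c(0.2, 0.5, 0.3), c(0.0, 0.6, 0.4))
  tt <- integer_tolerances(w, total = 15L)
  expect_identical(rowSums(tt), c(15, 15))
  expect_identical(tt[2, 1], 0L)
  expect_equal(tt[1, ], c(3L, 8L, 4L), ignore_attr = TRUE)
})

test_that("critical selective fraction follows the least-used good", {
  symm <- symmetric_system()
  expect_equal(critical_selective_fraction(ideal_distribution(symm)), 0,
               tolerance = 1e-9)
  sys <- table1_system(rho = 0.75)
  id <- ideal_distribution(sys)
  gc <- critical_selective_fraction(id)
  expect_equal(gc, (sys$Nu - 3 * min(id$n_star)) / sys$Nu, tolerance = 1e-12)
  # oracle: smallest gamma on a grid whose design is feasible brackets gamma_c
  feasible <- function(g) {
    w <- (id$n_star - (1 - g) * sys$Nu / 3) / (g * sys$Nu)
    all(w >= -1e-12)
  }
  grid <- seq(0.01, 1, by = 0.01)
  first <- grid[which(vapply(grid, feasible, logical(1L)))[1]]
  expect_true(first - 0.01 <= gc && gc <= first + 1e-12)
})

test_that("hybrid tolerance designs reproduce n* and respect the critical fraction", {
  sys <- table1_system(rho = 0.75)
  id <- ideal_distribution(sys)
  gc <- critical_selective_fraction(id)
  # all selective: weights proportional to n*
  h1 <- hybrid_tolerances(id, gamma = 1)
  expect_equal(h1$tol_selective, id$n_star / sys$Nu, tolerance = 1e-12)
  # at the critical fraction the argmin good gets zero weight
  hc <- hybrid_tolerances(id, gamma = gc)
  expect_equal(hc$tol_selective[which.min(id$n_star)], 0)
  expect_equal(hc$tol_selective,
               (id$n_star - id$n_min) / (sys$Nu - 3 * id$n_min),
               tolerance = 1e-9)
  # strictly between: plugging back reproduces n* exactly
  g <- (gc + 1) / 2
  h <- hybrid_tolerances(id, gamma = g)
  lhs <- (1 - g) * sys$Nu / 3 + g * sys$Nu * h$tol_selective
  expect_equal(lhs, id$n_star, tolerance = 1e-12)
  # below the critical fraction: infeasible, message quotes gamma_c
  expect_error(hybrid_tolerances(id, gamma = gc - 0.05), "critical")
  # gamma = 0 leaves the uniform nonselective distribution: only feasible
  # when uniform IS ideal
  symm <- symmetric_system()
  h0 <- hybrid_tolerances(ideal_distribution(symm), gamma = 0)
  expect_equal(h0$gamma_c, 0)
})

test_that("the equalized ideal dominates the WSLS equilibrium where congestion bites", {
  for (rho in c(0.25, 0.5, 0.75, 1, 1.25)) {
    sys <- table1_system(rho = rho)
    eq <- solve_equilibrium(sys)
    id <- ideal_distribution(sys)
    # the plain equilibrium spreads failure unevenly; the ideal level sits
    # inside that spread and collapses it
    expect_gt(diff(range(eq$p_fail)), 0)
    expect_gte(id$p_star, min(eq$p_fail) - 1e-12)
    expect_lte(id$p_star, max(eq$p_fail) + 1e-12)
    mean_ideal <- sum(id$n_star * vapply(1:3, function(i)
      failure_probability(sys$goods[[i]], id$n_star[i], sys)$p_fail,
      numeric(1L))) / sys$Nu
    # under real congestion equalizing quality also lowers the mean; at
    # light load equalized quality does not minimize the mean and may sit
    # up to about a percent above it
    if (rho >= 0.75) expect_lte(mean_ideal, eq$mean_fail + 1e-12)
    else expect_lte(mean_ideal, eq$mean_fail * 1.011)
  }
})
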