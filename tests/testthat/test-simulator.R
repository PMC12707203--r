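test_that("identical seeds give bit-identical runs; different seeds differ", {
  sys <- table1_system(rho = 0.75, scale = 0.1)
  cfg <- sim_config(sys, duration = 120, tolerance = 1, seed = 9)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$ts, s2$ts)
  expect_identical(s1$tol_final, s2$tol_final)
  s3 <- run_simulation(sim_config(sys, duration = 120, tolerance = 1, seed = 10))
  expect_false(identical(s1$ts, s3$ts))
})

test_that("occupancy is conserved at every sample", {
  sys <- table1_system(rho = 1.0, scale = 0.1)
  sim <- run_simulation(sim_config(sys, duration = 200, mode = "adaptive", seed = 2))
  occ <- as.matrix(sim$ts[paste0("n_", 1:3)])
  expect_true(all(rowSums(occ) == sys$Nu))
})

test_that("zero workload freezes the population and produces no failures", {
  g <- queue_server_spec(100, d = 0.01)
  sys <- system_spec(list(g, g), Nu = 50, tau = 0.1, lambda_u = 0)
  sim <- run_simulation(sim_config(sys, duration = 60, tolerance = 1, seed = 4))
  expect_identical(sim$total_attempts, 0)
  expect_identical(sim$total_failures, 0)
  expect_true(all(sim$ts$n_1 == sim$ts$n_1[1]))
})

test_that("the simulator refuses degenerate systems", {
  g <- queue_server_spec(100)
  expect_error(system_spec(list(g), Nu = 10, tau = 0.1, rho = 0.5), "at least 2")
  sys <- table1_system(rho = 0.75, scale = 0.05)
  expect_error(sim_config(sys, duration = 0), "positive")
  expect_error(sim_config(sys, duration = 10, beta = 0), "beta")
})

test_that("adaptive agents conserve their tolerance budget within printed bounds", {
  sys <- table1_system(rho = 0.75, scale = 0.2)
  sim <- run_simulation(sim_config(sys, duration = 2000, mode = "adaptive",
                                   T0 = 5, seed = 31))
  expect_true(all(rowSums(sim$tol_final) == 15L))
  expect_true(all(sim$tol_final >= 1L & sim$tol_final <= 13L))
  # population totals visible in the sampled mean tolerance too
  mt <- as.matrix(sim$ts[paste0("meanT_", 1:3)])
  expect_true(all(abs(rowSums(mt) - 15) < 1e-9))
})

test_that("estimate updates follow the printed exponential smoothing", {
  expect_equal(update_estimate(0, tol_i = 5, R = 50, beta = 0.1), 0.01)
  expect_equal(update_estimate(0.1, tol_i = 5, R = 50, beta = 0.1),
               0.9 * 0.1 + 0.1 * 0.1)
  # fixed point: est == T/R is unchanged
  expect_equal(update_estimate(0.25, tol_i = 5, R = 20, beta = 0.3), 0.25)
  # geometric decay toward the experienced rate
  x <- 0.8; target <- 5 / 50
  for (m in 1:7) x <- update_estimate(x, 5, 50, beta = 0.1)
  expect_equal(abs(x - target), 0.9^7 * abs(0.8 - target), tolerance = 1e-12)
  expect_error(update_estimate(0.1, tol_i = 5, R = 3, beta = 0.1), "R < tol")
})

test_that("tolerance reallocation moves one unit toward the best estimate", {
  expect_equal(update_tolerance(c(5, 5, 5), c(0.10, 0.02, 0.05), i = 1),
               c(4, 6, 5))
  # guard: cannot drop below 1
  expect_equal(update_tolerance(c(1, 5, 5), c(0.10, 0.02, 0.05), i = 1),
               c(1, 5, 5))
  # tie with the current good: strict inequality fails, no move
  expect_equal(update_tolerance(c(5, 5, 5), c(0.02, 0.02, 0.05), i = 1),
               c(5, 5, 5))
  # sum always preserved over random cases
  set.seed(8)
  for (r in 1:20) {
    tol <- sample(1:9, 4, replace = TRUE)
    est <- runif(4)
    expect_equal(sum(update_tolerance(tol, est, i = sample(4, 1))), sum(tol))
  }
})

test_that("shift destinations avoid the current good and respect the rule", {
  set.seed(11)
  expect_identical(shift_destination(1, Ng = 2), 2L)
  expect_identical(shift_destination(2, Ng = 2), 1L)
  draws <- replicate(1e5, shift_destination(2, Ng = 3))
  expect_false(any(draws == 2))
  tab <- table(draws)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  # proportional: zero-tolerance goods never chosen
  drawp <- replicate(2000, shift_destination(2, Ng = 3, rule = "proportional",
                                             tol = c(3, 7, 0)))
  expect_false(any(drawp == 3))
  expect_error(shift_destination(2, Ng = 3, rule = "proportional",
                                 tol = c(0, 7, 0)), "zero tolerance")
})

test_that("pinned agents reproduce the analytic single-queue failure rates", {
  # all users pinned to server 1 by an effectively infinite tolerance;
  # server 2 exists only to satisfy Ng >= 2
  goods <- list(queue_server_spec(100, c = 1, k = 10, d = 0.01),
                queue_server_spec(100, c = 1, k = 10, d = 0.01))
  n_users <- 200
  pin <- function(tau) {
    sys <- system_spec(goods, Nu = n_users, tau = tau, lambda_u = 0.5)
    cfg <- sim_config(sys, duration = 400, tolerance = .Machine$integer.max,
                      seed = 17, init = rep(1L, n_users))
    run_simulation(cfg)
  }
  batch_se <- function(fail, att, nb = 40L) {
    grp <- cut(seq_along(fail), nb, labels = FALSE)
    r <- tapply(fail, grp, sum) / tapply(att, grp, sum)
    stats::sd(r) / sqrt(nb)
  }
  spec <- goods[[1]]
  # loss only: huge timeout means every failure is a blocking event
  sim_l <- pin(tau = 1e6)
  pl_hat <- sum(sim_l$failures[, 1]) / sum(sim_l$attempts[, 1])
  pl <- loss_probability(spec, n = n_users, lambda_u = 0.5)
  expect_lt(abs(pl_hat - pl),
            3 * batch_se(sim_l$failures[, 1], sim_l$attempts[, 1]))
  # end-to-end failure at the real timeout
  sim_f <- pin(tau = 0.1)
  pf_hat <- sum(sim_f$failures[, 1]) / sum(sim_f$attempts[, 1])
  sysf <- system_spec(goods, Nu = n_users, tau = 0.1, lambda_u = 0.5)
  pf <- failure_probability(spec, n_users, sysf)$p_fail
  expect_lt(abs(pf_hat - pf),
            3 * batch_se(sim_f$failures[, 1], sim_f$attempts[, 1]))
})

test_that("fixed-tolerance steady states sit on the mean-field equilibrium", {
  sys <- table1_system(rho = 0.75)
  eq <- solve_equilibrium(sys)
  occ <- sapply(1:3, function(s) {
    sim <- run_simulation(sim_config(sys, duration = 1200, tolerance = 1,
                                     seed = 40 + s))
    n <- nrow(sim$ts)
    colMeans(sim$ts[(n %/% 2):n, paste0("n_", 1:3)])
  })
  m <- rowMeans(occ)
  se <- apply(occ, 1, stats::sd) / sqrt(3)
  tol_band <- pmax(3 * se, 0.02 * eq$n)
  expect_true(all(abs(m - eq$n) < tol_band))
})

test_that("adaptive learning equalizes per-good failure beyond the fixed rule", {
  sys <- table1_system(rho = 0.75)
  spread <- function(mode, tolerance = 5) {
    sim <- run_simulation(sim_config(sys, duration = 6000, mode = mode,
                                     tolerance = tolerance, seed = 77))
    st <- summarize_steady_state(sim)
    diff(range(st$fail_rate))
  }
  expect_lt(spread("adaptive"), spread("fixed"))
})

test_that("workload schedules change the effective arrival rate mid-run", {
  sys <- table1_system(rho = 0.75, scale = 0.1)
  sched <- data.frame(length = c(150, 150), rho = c(0.75, 0))
  sim <- run_simulation(sim_config(sys, duration = 300, tolerance = 1,
                                   seed = 5, schedule = sched))
  first <- sim$ts$t <= 150
  expect_gt(sum(sim$attempts[first, ]), 0)
  # after the switch to zero workload only in-flight requests can land
  late <- sim$ts$t > 160
  expect_identical(sum(sim$attempts[late, ]), 0)
})

test_that("steady-state summaries match hand-computed filters and averages", {
  ts <- data.frame(t = 1:100, fail_sys = rep(0.3, 100))
  expect_equal(summarize_steady_state(ts)$sys_fail, 0.3)
  # tail_fraction 1 with no smoothing: the global mean
  v <- runif(50)
  ts2 <- data.frame(t = 1:50, fail_sys = v)
  expect_equal(summarize_steady_state(ts2, tail_fraction = 1, smooth = 1)$sys_fail,
               mean(v))
  # piecewise series, trailing average by direct arithmetic
  ts3 <- data.frame(t = 1:100, fail_sys = c(rep(0.5, 80), rep(0.1, 20)))
  expect_equal(summarize_steady_state(ts3, tail_fraction = 0.2, smooth = 1)$sys_fail,
               0.1)
  # smoothed version cross-checked against an independent filter loop
  sm <- 0.05
  s <- ts3$fail_sys[1]
  acc <- numeric(100); acc[1] <- s
  for (j in 2:100) { s <- (1 - sm) * s + sm * ts3$fail_sys[j]; acc[j] <- s }
  expect_equal(summarize_steady_state(ts3, tail_fraction = 0.1, smooth = sm)$sys_fail,
               mean(acc[91:100]))
  expect_error(summarize_steady_state(ts3, tail_fraction = 0), "tail_fraction")
})
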