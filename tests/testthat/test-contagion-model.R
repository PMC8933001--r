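test_that("parameter validation rejects degenerate settings", {
  expect_error(contagion_params(rho = 0.5, mu = 0.1), "never divide")
  expect_s3_class(contagion_params(rho = 0.5, mu = 0.1,
                                   allow_nondividing = TRUE),
                  "contagion_params")
  expect_error(contagion_params(rho = -1, mu = 0.1), "rho")
  expect_error(contagion_params(rho = 20, mu = -0.1), "mu")
  expect_error(contagion_params(rho = 20, mu = 0.1, dt = 0), "dt")
  expect_error(contagion_params(rho = 20, mu = 0.1, t_max = -5), "t_max")
})

test_that("inhibitor steady state is mu * delta * m", {
  p <- contagion_params(rho = 20, mu = 0.65, delta = 1)
  expect_equal(steady_state_inhibition(p, 2), 1.3)
  expect_equal(steady_state_inhibition(p, 0), 0)
  p2 <- contagion_params(rho = 20, mu = 0.52, delta = 2)
  expect_equal(steady_state_inhibition(p2, 1), 1.04)
  expect_error(steady_state_inhibition(p, 3), "0, 1 or 2")
})

test_that("uninhibited division time matches its closed form", {
  p <- contagion_params(rho = 20, mu = 0.65)
  expect_equal(uninhibited_division_time(p), -20 * log(0.95))
  tiny <- contagion_params(rho = 20, mu = 0, theta = 1e-8)
  expect_lt(uninhibited_division_time(tiny), 1e-6)
  expect_error(uninhibited_division_time(
    contagion_params(rho = 1, mu = 0, theta = 1, allow_nondividing = TRUE)),
    "never divides")
})

test_that("the integrator reproduces the closed-form single-cell time", {
  withr::with_seed(2L, {
    for (i in 1:10) {
      p <- contagion_params(rho = runif(1, 5, 80), mu = 0,
                            r = runif(1, 0.5, 2), theta = runif(1, 0.2, 2),
                            dt = 0.002)
      t_star <- uninhibited_division_time(p)
      sim <- simulate_arm(p, 1L)$division_time[["1"]]
      expect_lt(abs(sim - t_star) / t_star, 1e-3)
    }
  })
})

test_that("mu = 0 decouples the cells: perfect synchrony at t*", {
  p <- contagion_params(rho = 20, mu = 0)
  d <- simulate_arm(p, 6L)$division_time[-1L]
  expect_lt(max(d) - min(d), p$dt)
  expect_equal(unname(d[1L]), uninhibited_division_time(p),
               tolerance = 1e-3)
})

test_that("division times never decrease with rank (wave is never overtaken)", {
  cases <- list(c(20, 0.65), c(40, 0.52), c(40, 0.31), c(10, 1.5),
                c(20, 15), c(5, 0.1), c(80, 0.05))
  for (cs in cases) {
    p <- contagion_params(rho = cs[1L], mu = cs[2L], t_max = 600)
    d <- suppressWarnings(simulate_arm(p, 10L)$division_time)
    d <- d[!is.na(d)]
    expect_true(all(diff(d) >= -1e-12),
                info = sprintf("rho=%g mu=%g", cs[1L], cs[2L]))
  }
})

test_that("stronger inhibition never accelerates any division", {
  base <- simulate_arm(contagion_params(rho = 20, mu = 0.3), 8L)$division_time
  for (mu in c(0.5, 1, 3)) {
    d <- simulate_arm(contagion_params(rho = 20, mu = mu), 8L)$division_time
    expect_true(all(d - base >= -1e-9), info = paste("mu =", mu))
  }
})

test_that("halving the step changes division times by far less than 0.1%", {
  p1 <- contagion_params(rho = 20, mu = 0.65, dt = 0.01)
  p2 <- contagion_params(rho = 20, mu = 0.65, dt = 0.005)
  d1 <- simulate_arm(p1, 8L)$division_time[-1L]
  d2 <- simulate_arm(p2, 8L)$division_time[-1L]
  expect_true(all(abs(d1 - d2) / d2 < 1e-3))
})

test_that("trajectories stay within their analytic bounds", {
  p <- contagion_params(rho = 20, mu = 0.65)
  sim <- simulate_arm(p, 6L, record_trajectories = TRUE, record_every = 5L)
  expect_false(is.null(sim$trajectories))
  A <- sim$trajectories$A; I <- sim$trajectories$I
  expect_true(all(A >= 0 & A <= p$r * p$rho + 1e-9))
  expect_true(all(I >= 0 & I <= 2 * p$mu * p$delta + 1e-9))
})

test_that("strong inhibition gives strictly sequential, near-linear waves", {
  # theta > r*rho*g(2*mu*delta): only the frontier cell can cross threshold
  p <- contagion_params(rho = 20, mu = 15, t_max = 400)
  expect_gt(p$theta, p$r * p$rho / (1 + 2 * p$mu * p$delta))
  d <- simulate_arm(p, 12L)$division_time
  gaps <- diff(d)
  expect_true(all(gaps > 0))
  # successive gaps approach a constant: the wave travels at steady speed
  tail_gaps <- gaps[8:11]
  expect_lt(max(tail_gaps) / min(tail_gaps), 1.05)
  x <- as.numeric(names(d))
  f <- lm(d ~ x)
  r2 <- 1 - sum(residuals(f)^2) / sum((d - mean(d))^2)
  expect_gt(r2, 0.99)
  expect_gt(unname(coef(f)[2L]), 0)
})

test_that("weak inhibition gives convex, flattening curves", {
  p <- contagion_params(rho = 20, mu = 0.2)
  d <- simulate_arm(p, 8L)$division_time
  gaps <- diff(d)
  expect_true(all(diff(gaps) <= 1e-9))  # gaps shrink with rank
  expect_lt(gaps[6L], 0.05 * gaps[1L])  # plateau far from the seed
})

test_that("arms are independent and symmetric within a row", {
  p <- contagion_params(rho = 20, mu = 0.65)
  row <- simulate_row(p, n_ant = 5L, n_post = 8L, spacing_um = 25)
  ant <- simulate_arm(p, 5L)$division_time
  post <- simulate_arm(p, 8L)$division_time
  expect_equal(row$time_min[match(-(1:5), row$rank)], unname(ant[-1L]))
  expect_equal(row$time_min[match(1:8, row$rank)], unname(post[-1L]))
  for (k in 1:5)
    expect_equal(row$time_min[row$rank == -k], row$time_min[row$rank == k])
  expect_equal(row$metric_rank_um, row$rank * 25)
  solo <- simulate_row(p, n_ant = 0L, n_post = 3L)
  expect_equal(solo$rank, 0:3)
})

test_that("compiled integrator agrees exactly with the plain-R reference", {
  cases <- list(list(rho = 20, mu = 0.65, open = FALSE),
                list(rho = 40, mu = 0.31, open = FALSE),
                list(rho = 15, mu = 2, open = TRUE))
  for (cs in cases) {
    p <- contagion_params(rho = cs$rho, mu = cs$mu, dt = 0.02, t_max = 100)
    d_cpp <- simulate_arm(p, 6L,
                          boundary = if (cs$open) "open" else "infinite")
    d_ref <- r_simulate_arm(6L, p$r, p$mu, p$rho, p$delta, p$theta,
                            p$dt, p$t_max, open_end = cs$open)
    expect_equal(unname(d_cpp$division_time[-1L]), d_ref,
                 tolerance = 1e-12)
  }
})

test_that("an open row end seeds an early backward wave", {
  p <- contagion_params(rho = 20, mu = 5, t_max = 400)
  d_open <- simulate_arm(p, 8L, boundary = "open")$division_time[-1L]
  d_inf <- simulate_arm(p, 8L)$division_time[-1L]
  expect_lt(d_open[[8L]], d_open[[7L]])      # end cell divides first
  expect_true(all(diff(d_inf) >= -1e-12))    # infinite row stays ordered
})
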