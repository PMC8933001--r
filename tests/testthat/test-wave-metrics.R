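row_of <- function(times, pos = seq(0, by = 30, length.out = length(times))) {
  tibble::tibble(notum_id = "n1", row_id = "R1", side = "unspecified",
                 position_um = pos, division_time_min = times,
                 genotype = "wt")
}

test_that("SOP0 is the earliest divider, ties broken anteriorly, order-invariant", {
  d <- row_of(c(12, 5, 9))
  expect_equal(identify_sop0(d)$division_time_min, 5)

  tie <- row_of(c(5, 5), pos = c(100, 40))
  expect_equal(identify_sop0(tie)$position_um, 40)

  expect_error(identify_sop0(row_of(7)), ">= 2")

  d2 <- row_of(c(30, 12, 50, 4, 80))
  for (perm in list(5:1, c(3, 1, 5, 2, 4))) {
    expect_equal(identify_sop0(d2[perm, ]), identify_sop0(d2))
  }
})

test_that("ranks are signed ordinal offsets with metric = rank x spacing", {
  d <- row_of(c(20, 0, 10, 30), pos = c(0, 30, 60, 90))
  s <- assign_ranks(d)
  expect_equal(s$rank, -1:2)
  expect_equal(s$metric_rank_um, c(-30, 0, 30, 60))
  expect_equal(s$time_min, c(20, 0, 10, 30))
  expect_equal(attr(s, "spacing_um"), 30)
})

test_that("observed-mean spacing is the mean inter-SOP gap; fixed spacing honoured", {
  d <- row_of(c(0, 5, 9), pos = c(0, 10, 40))
  s <- assign_ranks(d)
  expect_equal(attr(s, "spacing_um"), 20)  # mean of gaps 10 and 30
  expect_equal(s$metric_rank_um, c(0, 20, 40))

  s30 <- assign_ranks(d, spacing = 30)
  expect_equal(attr(s30, "spacing_um"), 30)
  expect_equal(s30$metric_rank_um, c(0, 30, 60))
})

test_that("rank assignment is translation-invariant in position and time", {
  d <- row_of(c(40, 11, 25, 60), pos = c(5, 38, 64, 95))
  shifted <- d
  shifted$position_um <- d$position_um + 1000
  shifted$division_time_min <- d$division_time_min + 77
  expect_equal(tibble::as_tibble(assign_ranks(shifted)),
               tibble::as_tibble(assign_ranks(d)))
})

test_that("duplicate positions make rank assignment fail loudly", {
  d <- row_of(c(0, 5, 9), pos = c(0, 30, 30))
  expect_error(assign_ranks(d), "ambiguous")
})

test_that("aggregation means, SEMs and coverage counts are per rank", {
  s1 <- new_rank_series(0:1, c(0, 10), spacing_um = 30)
  s2 <- new_rank_series(-1:1, c(12, 0, 20), spacing_um = 30)
  agg <- aggregate_series(list(s1, s2))
  expect_equal(agg$mean_time_min[agg$rank == 1], 15)
  expect_equal(agg$sem_time_min[agg$rank == 1], 5)  # SD 7.071 / sqrt(2)
  expect_equal(agg$n_rows[agg$rank == -1], 1L)       # only s2 covers rank -1
  expect_true(is.na(agg$sem_time_min[agg$rank == -1]))

  solo <- aggregate_series(list(s2))
  expect_equal(solo$mean_time_min, s2$time_min)
  expect_true(all(is.na(solo$sem_time_min)))
  expect_error(aggregate_series(list()), "at least one")
})

test_that("regression recovers exact lines and the closed-form 3-point fit", {
  lin <- make_linear_series(0.5, n_ant = 3, n_post = 4, spacing_um = 10)
  post <- fit_wave_regression(lin, "posterior")
  ant <- fit_wave_regression(lin, "anterior")
  expect_equal(post$slope_min_per_um, 0.5, tolerance = 1e-12)
  expect_equal(ant$slope_min_per_um, -0.5, tolerance = 1e-12)
  expect_equal(post$r_squared, 1)
  expect_equal(post$n_points, 5L)  # rank 0 belongs to both arms

  tri <- new_rank_series(0:2, c(0, 12, 18), spacing_um = 30)
  f <- fit_wave_regression(tri, "posterior")
  expect_equal(f$slope_min_per_um, 0.3, tolerance = 1e-12)
  expect_equal(f$intercept_min, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 27 / 28, tolerance = 1e-12)

  flat <- new_rank_series(0:3, c(0, 0, 0, 0), spacing_um = 30)
  expect_equal(fit_wave_regression(flat, "posterior")$slope_min_per_um, 0)

  short <- new_rank_series(0:1, c(0, 4), spacing_um = 30)
  expect_error(fit_wave_regression(short, "anterior"), ">= 2 points")
})

test_that("wave rate is the mean absolute inverse slope", {
  mk <- function(slope) structure(list(side = "posterior",
                                       slope_min_per_um = slope,
                                       intercept_min = 0, r_squared = 1,
                                       n_points = 5L),
                                  class = "wave_regression")
  expect_equal(as.numeric(wave_rate(list(mk(0.25), mk(-0.5)))), 3)
  expect_equal(as.numeric(wave_rate(mk(1))), 1)

  expect_warning(r <- wave_rate(list(mk(0.5), mk(0))), "excluded")
  expect_equal(as.numeric(r), 2)
  expect_equal(attr(r, "n_excluded"), 1L)
})

test_that("wave rate converges to the inverse generating slope as noise vanishes", {
  s_true <- 0.4  # min/um
  for (eps in c(0.5, 0.01)) {
    rates <- withr::with_seed(11L, {
      vapply(1:6, function(i) {
        base <- make_linear_series(s_true)
        noisy <- base$time_min + c(0, rnorm(nrow(base) - 1L, 0, eps))
        noisy[base$rank == 0L] <- 0
        s <- new_rank_series(base$rank, pmax(noisy, 0), spacing_um = 30)
        regs <- list(fit_wave_regression(s, "anterior"),
                     fit_wave_regression(s, "posterior"))
        as.numeric(wave_rate(regs))
      }, numeric(1))
    })
    expect_equal(mean(rates), 1 / s_true,
                 tolerance = if (eps < 0.1) 1e-3 else 0.2)
  }
})
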