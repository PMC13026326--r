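test_that("derivative stencils behave on closed forms", {
  cyc <- 1:20
  # linear curve: constant first derivative, zero second
  ds <- compute_derivatives(5 + 0.3 * cyc)
  expect_equal(ds$d1[2:19], rep(0.3, 18))
  expect_equal(ds$d2[2:19], rep(0, 18), tolerance = 1e-12)
  # pure doubling: central difference d1(c) = 0.75 * 2^c
  ds2 <- compute_derivatives(2^cyc)
  expect_equal(ds2$d1[2:19], 0.75 * 2^(2:19))
  expect_error(compute_derivatives(1:6), "7 cycles")
})

test_that("second differences annihilate affine components exactly", {
  set.seed(101)
  for (i in 1:20) {
    f <- cumsum(abs(rnorm(30)))
    a <- runif(1, -50, 50)
    b <- runif(1, -2, 2)
    d2a <- compute_derivatives(f)$d2
    d2b <- compute_derivatives(f + a + b * (1:30))$d2
    expect_equal(d2b, d2a, tolerance = 1e-9)
  }
})

test_that("TD0 is invariant under linear baseline shifts", {
  set.seed(202)
  for (i in 1:100) {
    tr <- sim_truth(N0 = 10^runif(1, 2, 6), E0 = runif(1, 1.85, 2.0),
                    noise_sd = runif(1, 0, 0.03), seed = i)
    f <- simulate_curve(tr)$fluorescence
    a <- runif(1, 0, 200)
    b <- runif(1, -0.5, 2)
    t1 <- call_td0(f)$td0
    t2 <- call_td0(f + a + b * seq_along(f))$td0
    expect_false(is.na(t1))
    expect_equal(t2, t1, tolerance = 1e-9)
  }
})

test_that("flat and pure-noise curves are no-calls, not errors", {
  res <- call_td0(rep(100, 40))
  expect_true(is.na(res$td0))
  expect_equal(res$flags, "no_amplification")
  set.seed(7)
  res2 <- call_td0(100 + rnorm(40, 0, 1.5))
  expect_true(is.na(res2$td0))
})

test_that("TD0 agrees with the dense continuous oracle on noiseless curves", {
  set.seed(303)
  errs <- vapply(1:100, function(i) {
    tr <- sim_truth(N0 = 10^runif(1, 2, 6), E0 = runif(1, 1.85, 2.0),
                    noise_sd = 0, seed = i)
    call_td0(simulate_curve(tr)$fluorescence)$td0 - oracle_td0(tr)
  }, 0)
  expect_true(all(is.finite(errs)))
  expect_lt(max(abs(errs)), 0.05)
})

test_that("TD0 sits within two cycles of the first-derivative maximum", {
  set.seed(404)
  for (i in 1:25) {
    tr <- sim_truth(N0 = 10^runif(1, 2, 5), E0 = runif(1, 1.85, 2.0),
                    noise_sd = 0.02, seed = i)
    res <- call_td0(simulate_curve(tr)$fluorescence)
    expect_lte(abs(res$td0 - res$d1_max), 2)
  }
})

test_that("exponential phase window follows the stop/backtrack/cap rules", {
  # stop = floor(td0 - 0.5)
  f <- 50 + 2 * 1.9^((1:40) / 1.5)   # monotone increasing
  ep <- find_exponential_phase(f, 25.43)
  expect_equal(ep$stop, 24)
  # strictly increasing from cycle 1: window capped at the 9 nearest stop
  ep2 <- find_exponential_phase(f, 30.5)
  expect_equal(ep2$stop, 30)
  expect_equal(ep2$window, 22:30)
  expect_equal(ep2$start_excluded, 21)
  # early td0 cannot form a window
  ep3 <- find_exponential_phase(f, 4.2)
  expect_equal(ep3$flags, "short_exp_phase")
  expect_length(ep3$window, 0)
  # backtrack stops where the fluorescence stops decreasing backwards
  f2 <- c(10, 9, 8, 7, 6, 7, 8.5, 11, 15, 22, 35, 60, 100, 170, 280, 420,
          560, 660, 700, 710)
  ep4 <- find_exponential_phase(f2, 15.4)
  expect_equal(ep4$stop, 14)
  expect_equal(ep4$start_excluded, 5)   # f decreases backwards until cycle 5
  expect_equal(ep4$window, 6:14)
})

test_that("baseline bisection recovers constructed baselines and efficiencies", {
  cyc <- 1:30
  f <- 100 + 3 * 1.9^(cyc - 12)
  w <- 16:24
  be <- estimate_baseline_efficiency(f, w)
  expect_true(be$converged)
  amplitude <- max(f[w]) - min(f[w])
  expect_lt(abs(be$baseline - 100), 0.01 * amplitude)
  expect_lt(abs(be$E_indiv - 1.9), 0.01)
  # zero baseline: already log-linear
  f0 <- 3 * 1.9^(cyc - 12)
  be0 <- estimate_baseline_efficiency(f0, w)
  expect_lt(abs(be0$E_indiv - 1.9), 0.001)
  expect_lt(be0$baseline, min(f0[w]) * 0.01)
  # window too short
  expect_equal(estimate_baseline_efficiency(f, 16:18)$flags,
               "baseline_unreliable")
})

test_that("noiseless recovery of E and baseline is sub-1e-3", {
  for (seed in 1:25) {
    fx <- fix_exp_window(seed)
    be <- estimate_baseline_efficiency(fx$f, fx$window)
    expect_true(be$converged)
    expect_lt(abs(be$E_indiv - fx$E), 1e-3)
    expect_lt(abs(be$baseline - fx$baseline) /
                (max(fx$f[fx$window]) - fx$baseline), 1e-3)
  }
})

test_that("bisection matches the brute-force baseline grid oracle", {
  for (seed in 26:45) {
    fx <- fix_exp_window(seed)
    be <- estimate_baseline_efficiency(fx$f, fx$window)
    gr <- grid_baseline_oracle(fx$f, fx$window, n_grid = 1e5)
    # bisection reaches at least the grid's slope agreement, and lands on
    # the same baseline within the scan resolution
    expect_lt(abs(be$slope_low - be$slope_high), 1e-5)
    expect_lt(abs(be$baseline - gr$baseline),
              max(2 * gr$resolution, 1e-5 / slope_gap_sensitivity(fx, gr)))
    expect_lt(abs(be$E_indiv - gr$E), 1e-4)
  }
})

test_that("efficiency is monotone in the upper-subsection slope", {
  slopes <- seq(0.22, 0.30, by = 0.02)
  Es <- vapply(slopes, function(s) {
    f <- 50 + 10^(s * (1:30) - 3)
    estimate_baseline_efficiency(f, 18:25)$E_indiv
  }, 0)
  expect_true(all(diff(Es) > 0))
})
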