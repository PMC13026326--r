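test_that("mean efficiency applies the iterative Grubbs test when skewed", {
  # identical replicates: no outlier machinery engaged
  st <- mean_target_efficiency(rep(1.9, 7))
  expect_equal(st$E_mean, 1.9)
  expect_equal(st$E_sd, 0)
  expect_equal(nrow(st$outliers), 0)
  # a single wild value among seven is removed at alpha = 0.05
  # (G = 2.267 > 2.020, the two-sided critical value for n = 7)
  x <- c(1.84, 1.85, 1.85, 1.86, 1.86, 1.85, 2.60)
  st2 <- mean_target_efficiency(x, ids = paste0("W", 1:7))
  expect_equal(st2$outliers$E_indiv, 2.60)
  expect_equal(st2$outliers$id, "W7")
  expect_equal(st2$E_mean, 1.8516667, tolerance = 1e-6)
  expect_equal(st2$n_used, 6)
  # two values: no test possible, plain mean
  st3 <- mean_target_efficiency(c(1.8, 2.0))
  expect_equal(st3$E_mean, 1.9)
  expect_equal(nrow(st3$outliers), 0)
  expect_error(mean_target_efficiency(numeric()), "no finite")
})

test_that("Grubbs removal never reduces a target below three reactions", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    x <- c(rnorm(n - 2, 1.9, 0.01), 2.6, 2.8)  # two extremes
    st <- mean_target_efficiency(x)
    expect_gte(st$n_used, 3)
    expect_lte(nrow(st$outliers), length(x) - 3)
  }
})

test_that("limit copies reproduce the worked primer example and regimes", {
  cn <- qpcr_constants()
  # all primers incorporated: 250 nM, 20 uL -> 3.0e12 copies
  d <- dye_config("d", "hydrolysis_probe", C_p = 1)
  tg <- target_config("t", "toi", 250, 100, "d")
  expect_equal(limit_copies(tg, d, 20, cn)$copies, 3.011e12, tolerance = 1e-6)
  expect_equal(limit_copies(tg, d, 20, cn)$regime, "primer_limited")
  # primer-limited C_p 0.1 at 100 nM == dye-limited C_d 1.5, 400 nM, 60 bp
  dp <- dye_config("p", "hydrolysis_probe", C_p = 0.1)
  tp <- target_config("tp", "toi", 100, 60, "p")
  dd <- dye_config("s", "non_saturating_dye", dye_conc = 400, C_d = 1.5)
  td <- target_config("td", "toi", 100, 60, "s")
  expect_equal(limit_copies(tp, dp, 15, cn)$copies,
               limit_copies(td, dd, 15, cn)$copies)
  expect_equal(limit_copies(td, dd, 15, cn)$regime, "dye_limited")
  # zero volume -> zero copies
  expect_equal(limit_copies(tg, d, 0, cn)$copies, 0)
})

test_that("amplicon mass matches the 330 ng example and is linear", {
  expect_equal(amplicon_mass(250, 100, 20), 330e-9, tolerance = 1e-9)
  expect_equal(amplicon_mass(250, 200, 20), 2 * amplicon_mass(250, 100, 20))
  expect_equal(amplicon_mass(0, 100, 20), 0)
})

test_that("ncopy reproduces the printed sensitivity and worked values", {
  sybr <- fix_sybr()
  tg <- fix_target()
  n185 <- ncopy(28, 1.85, tg, sybr, 20, "single")$ncopy
  n190 <- ncopy(28, 1.90, tg, sybr, 20, "single")$ncopy
  expect_equal(round(n185 / n190, 1), 2.1)
  expect_equal(round(1.85^0.1 - 1, 2), 0.06)
  # td0 = 0: the limit itself, times the strandedness factor
  q0 <- ncopy(0, 1.9, tg, sybr, 20, "single")
  expect_equal(q0$ncopy, q0$limit * 2)
  expect_equal(ncopy(0, 1.9, tg, sybr, 20, "double")$ncopy, q0$limit)
  # hand-evaluated dye-limited closed form
  tg100 <- target_config("t", "toi", 250, 100, "SYBR")
  q <- ncopy(25, 1.9, tg100, sybr, 10, "double")
  expect_equal(q$ncopy, 3881.968, tolerance = 1e-6)
  expect_equal(q$regime, "dye_limited")
  expect_error(ncopy(25, 0.99, tg100, sybr, 10), "> 1")
})

test_that("gDNA mass converts to expected single-copy gene counts", {
  expect_equal(expected_copies_from_gdna(4), 1200)
  expect_equal(expected_copies_from_gdna(20), 6000)
  expect_equal(expected_copies_from_gdna(0), 0)
  expect_equal(expected_copies_from_gdna(c(0.2, 2)), c(60, 600))
})

test_that("ncopy monotonicity and scaling invariants hold", {
  sybr <- fix_sybr()
  tg <- fix_target()
  n <- function(td0, E, vol = 20, amp = 100) {
    t2 <- target_config("t", "toi", 250, amp, "SYBR")
    ncopy(td0, E, t2, sybr, vol, "single")$ncopy
  }
  expect_true(all(diff(sapply(seq(20, 30, 2), n, E = 1.9)) < 0))
  expect_true(all(diff(sapply(seq(1.7, 2.0, 0.05), function(E) n(25, E))) < 0))
  expect_equal(n(25, 1.9, vol = 40), 2 * n(25, 1.9, vol = 20))
  expect_equal(n(25, 1.9, amp = 200), n(25, 1.9, amp = 100) / 2)
  # within a target, ratios reproduce TD0 differences exactly
  expect_equal(n(24, 1.9) / n(26.5, 1.9), 1.9^2.5)
})

test_that("quantify_run recovers simulated plates and honours ntc rules", {
  sim <- fix_sim_plate(n = 7, N0 = 1500, seed = 31)
  q <- quantify_run(sim$run)
  expect_equal(nrow(q$results), 7)
  expect_equal(q$target_stats$target, "FSTL1")
  expect_lt(abs(q$target_stats$E_mean - 1.9), 0.05)
  mean_nc <- mean(q$results$ncopy)
  expect_lt(max(mean_nc / 1500, 1500 / mean_nc), 1.5)
  expect_lt(sd(q$results$ncopy) / mean_nc, 0.15)
})

test_that("a plate of flat curves yields no calls and no target stats", {
  sim <- fix_sim_plate(n = 4, seed = 2)
  run <- sim$run
  run$fluorescence[] <- 100
  q <- quantify_run(run)
  expect_true(all(is.na(q$results$td0)))
  expect_true(all(grepl("no_amplification", q$results$flags)))
  expect_equal(nrow(q$target_stats), 0)
})

test_that("two targets on one plate get independent mean efficiencies", {
  sybr <- fix_sybr()
  tA <- fix_target("genA")
  tB <- target_config("genB", "toi", primer_conc = 250, amplicon_length = 200,
                      dye = "SYBR")
  wells <- rbind(
    data.frame(sample_name = "s1", sample_type = "unkn", target = "genA",
               N0 = 1500)[rep(1, 4), ],
    data.frame(sample_name = "s1", sample_type = "unkn", target = "genB",
               N0 = 300)[rep(1, 4), ])
  wells$E0 <- rep(c(1.95, 1.86), each = 4)
  sim <- simulate_run(wells, list(tA, tB), list(sybr), seed = 17,
                      noise_sd = 0.01)
  q <- quantify_run(sim$run)
  expect_equal(nrow(q$target_stats), 2)
  EA <- q$target_stats$E_mean[q$target_stats$target == "genA"]
  EB <- q$target_stats$E_mean[q$target_stats$target == "genB"]
  expect_gt(EA, EB)
  # each reaction uses its own target's mean efficiency
  expect_equal(unique(q$results$E_mean[q$results$target == "genA"]), EA)
  expect_equal(unique(q$results$E_mean[q$results$target == "genB"]), EB)
})

test_that("ntc reactions never enter the mean efficiency and warn if amplified", {
  sim <- fix_sim_plate(n = 6, seed = 13)
  run <- sim$run
  run$wells$sample_type[5:6] <- "ntc"
  # ntc wells flat: no template
  run$fluorescence[5, ] <- 100 + 0.3 * seq_len(ncol(run$fluorescence))
  run$fluorescence[6, ] <- 100 + 0.3 * seq_len(ncol(run$fluorescence))
  q <- quantify_run(run)
  expect_equal(q$target_stats$n_used, 4)
  # a contaminated ntc (amplifying curve) raises a warning
  run2 <- sim$run
  run2$wells$sample_type[6] <- "ntc"
  expect_warning(quantify_run(run2), "ntc")
})
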