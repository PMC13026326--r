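test_that("replicate summaries compute CV and flag rules", {
  r <- res_df(rep(c("a", "b", "c"), c(3, 3, 1)), "g",
              c(100, 100, 100, 60, 100, 140, 77))
  rs <- replicate_stats(r)
  a <- rs[rs$sample_name == "a", ]
  expect_equal(a$cv, 0)
  expect_false(a$high_cv_flag)
  b <- rs[rs$sample_name == "b", ]
  expect_equal(b$mean_ncopy, 100)
  expect_equal(b$cv, 0.4)
  expect_true(b$high_cv_flag)
  cc <- rs[rs$sample_name == "c", ]
  expect_true(is.na(cc$cv))
  expect_true(cc$single_replicate)
})

test_that("dilution efficiency inverts ideal slopes exactly", {
  conc <- 10^(5:1)
  # 10-fold dilution spaced log2(10) cycles: efficiency 2
  de <- suppressWarnings(dilution_efficiency(35 - log2(10) * log10(conc), conc))
  expect_equal(de$E_dil, 2, tolerance = 1e-9)
  # 1 cycle per 2-fold dilution: also 2
  conc2 <- 2^(8:1)
  de2 <- suppressWarnings(dilution_efficiency(30 - log2(conc2), conc2))
  expect_equal(de2$E_dil, 2, tolerance = 1e-9)
  expect_error(dilution_efficiency(c(20, 21), c(10, 1)), "3 distinct")
})

test_that("dilution efficiency recovers the truth under TD0 noise", {
  # 5 levels x 3 replicates, true E 1.90, Gaussian TD0 noise SD 0.1
  conc <- rep(10^(5:1), each = 3)
  slope <- -1 / log10(1.9)
  hit <- vapply(1:200, function(seed) {
    set.seed(seed)
    td0 <- 10 + slope * log10(conc) + rnorm(length(conc), 0, 0.1)
    abs(dilution_efficiency(td0, conc)$E_dil - 1.9) <= 0.05
  }, TRUE)
  expect_gte(mean(hit), 0.95)
})

test_that("single-standard calibration rescales by expected over measured", {
  r <- rbind(
    res_df("u", "g", c(200, 220)),
    res_df("std1k", "g", rep(500, 6), type = "std", std_conc = 50),
    res_df("std10", "g", rep(6, 6), type = "std", std_conc = 0.5))
  cal <- calibrate_with_standard(r, reaction_volume = 20)
  # the standard with the highest amount (50 copies/uL * 20 uL = 1000) wins
  expect_equal(cal$standard_sample, "std1k")
  expect_equal(cal$factor, 2)
  expect_equal(cal$results$ncopy[1:2], c(400, 440))
  # measured == expected: identity
  r2 <- res_df("s", "g", rep(1000, 6), type = "std", std_conc = 50)
  expect_equal(calibrate_with_standard(r2, 20)$factor, 1)
  # advisory warnings outside the recommended design
  r3 <- res_df("s", "g", rep(100, 2), type = "std", std_conc = 50000)
  expect_warning(expect_warning(calibrate_with_standard(r3, 20),
                                "replicate"), "expected copies")
  # no standards: no-op with notice
  expect_message(out <- calibrate_with_standard(res_df("u", "g", 5), 20),
                 "unscaled")
  expect_true(is.na(out$factor))
})

test_that("inter-run correction recovers a plate-level factor exactly", {
  base <- rbind(
    res_df(paste0("s", 1:4), "g1", c(1000, 1400, 500, 700),
           group = c("A", "A", "B", "B")),
    res_df(paste0("s", 1:4), "g2", c(80, 95, 220, 260),
           group = c("A", "A", "B", "B")))
  p2 <- base
  p2$run_id <- "r2"
  p2$ncopy <- p2$ncopy * 3
  irc <- interrun_correction(rbind(base, p2))
  f <- irc$run_factors
  expect_equal(f$factor[f$run_id == "r1"] / f$factor[f$run_id == "r2"], 3,
               tolerance = 1e-9)
  expect_equal(prod(f$factor), 1, tolerance = 1e-9)   # geometric mean one
  # corrected plates agree
  cr <- irc$results
  expect_equal(cr$ncopy[cr$run_id == "r1"], cr$ncopy[cr$run_id == "r2"],
               tolerance = 1e-9)
  # purely multiplicative: within-run ratios preserved
  r1c <- cr$ncopy[cr$run_id == "r1"]
  expect_equal(r1c / r1c[1], base$ncopy / base$ncopy[1], tolerance = 1e-12)
})

test_that("inter-run correction is idempotent and handles edge topologies", {
  base <- res_df(paste0("s", 1:4), "g", c(100, 150, 90, 120),
                 group = c("A", "A", "B", "B"))
  p2 <- base; p2$run_id <- "r2"; p2$ncopy <- p2$ncopy * 2.5
  once <- interrun_correction(rbind(base, p2))
  twice <- interrun_correction(once$results[names(base)])
  expect_true(all(abs(twice$run_factors$factor - 1) < 1e-9))
  # single run: factors 1, results unchanged
  solo <- interrun_correction(base)
  expect_equal(solo$run_factors$factor, 1)
  expect_equal(solo$results$ncopy, base$ncopy)
  # no shared (group, target) cells: error naming components
  p3 <- res_df("s9", "g9", 50, group = "C"); p3$run_id <- "r3"
  expect_error(interrun_correction(rbind(base, p3)), "not connected|overlap")
})

test_that("unbalanced overlap still recovers the factor", {
  set.seed(5)
  base <- res_df(paste0("s", 1:6), "g", exp(rnorm(6, log(500), 0.1)),
                 group = rep(c("A", "B", "C"), each = 2))
  p2 <- base[1:4, ]                      # plate 2 misses group C entirely
  p2$run_id <- "r2"; p2$ncopy <- p2$ncopy * 4
  irc <- interrun_correction(rbind(base, p2))
  f <- irc$run_factors
  expect_equal(f$factor[1] / f$factor[2], 4, tolerance = 1e-9)
})

test_that("fold difference propagates SEM-based errors", {
  fd <- fold_difference(c(9, 10, 11), c(9, 10, 11))
  expect_equal(fd$fold, 1)
  expect_equal(fold_difference(c(8, 10, 12), c(4, 5, 6))$fold, 2)
  expect_error(fold_difference(c(1, 2), c(0, 0)), "zero")
  # against a bootstrap oracle
  set.seed(99)
  a <- rnorm(12, 100, 15)
  b <- rnorm(10, 52, 8)
  fd2 <- fold_difference(a, b)
  boot <- replicate(4000, mean(sample(a, replace = TRUE)) /
                      mean(sample(b, replace = TRUE)))
  expect_lt(abs(fd2$se - sd(boot)) / sd(boot), 0.10)
})
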