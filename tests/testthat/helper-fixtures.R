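# Shared fixtures: assay configurations and small simulated plates.

fix_sybr <- function() dye_config("SYBR", "non_saturating_dye", dye_conc = 400)
fix_probe <- function() dye_config("FAM", "hydrolysis_probe")

fix_target <- function(name = "FSTL1", role = "toi", amp = 100, dye = "SYBR") {
  target_config(name, role, primer_conc = 250, amplicon_length = amp, dye = dye)
}

# replicate plate of one sample/target
fix_plate_wells <- function(n = 7, N0 = 1500, sample = "s1", target = "FSTL1",
                            type = "unkn") {
  data.frame(sample_name = sample, sample_type = type, target = target,
             N0 = N0)[rep(1, n), ]
}

fix_sim_plate <- function(n = 7, N0 = 1500, seed = 1, noise_sd = 0.02,
                          E0 = 1.9, ...) {
  simulate_run(fix_plate_wells(n, N0), list(fix_target()), list(fix_sybr()),
               reaction_volume = 20, E0 = E0, noise_sd = noise_sd,
               seed = seed, ...)
}

# random single-exponential-plus-baseline window (no saturation), for
# baseline/efficiency oracles
fix_exp_window <- function(seed) {
  set.seed(seed)
  E <- runif(1, 1.7, 2.0)
  b0 <- runif(1, 20, 200)
  amp0 <- runif(1, 0.5, 5)
  w <- sample(5:9, 1)
  start <- sample(10:20, 1)
  cyc <- seq_len(start + w + 2)
  f <- b0 + amp0 * E^(cyc - 10)
  list(f = f, window = seq.int(start + 1, start + w), E = E, baseline = b0)
}

# minimal per-reaction results table for experiment-level operations
res_df <- function(sample, target, ncopy, type = "unkn", run = "r1",
                   group = NULL, std_conc = NA_real_) {
  d <- data.frame(run_id = run, sample_name = sample, sample_type = type,
                  target = target, std_conc = std_conc, ncopy = ncopy,
                  stringsAsFactors = FALSE)
  if (!is.null(group)) d$group <- group
  d
}

# |d(slope_low - slope_high)/db| near a baseline value, by finite difference;
# converts the bisection's slope tolerance into a baseline tolerance
slope_gap_sensitivity <- function(fx, gr) {
  gap <- function(b) {
    fw <- fx$f[fx$window]
    w <- length(fw); half <- ceiling(w / 2)
    y <- log10(fw - b)
    sl <- function(i) {
      x <- fx$window[i] - mean(fx$window[i])
      sum(x * y[i]) / sum(x^2)
    }
    sl(seq_len(half)) - sl(seq.int(w - half + 1, w))
  }
  h <- max(gr$resolution, 1e-7)
  abs(gap(gr$baseline + h) - gap(gr$baseline - h)) / (2 * h)
}

# brute-force baseline scan oracle: minimise |slope_low - slope_high| over an
# even grid of candidate baselines
grid_baseline_oracle <- function(f, window, n_grid = 1e5) {
  fw <- f[window]
  w <- length(window)
  half <- ceiling(w / 2)
  i_low <- seq_len(half)
  i_high <- seq.int(w - half + 1, w)
  xs_l <- window[i_low] - mean(window[i_low])
  xs_h <- window[i_high] - mean(window[i_high])
  bs <- seq(0, min(fw) * (1 - 1e-9), length.out = n_grid)
  best <- c(Inf, NA, NA)
  chunk <- 2e4
  for (off in seq(1, n_grid, by = chunk)) {
    bb <- bs[off:min(off + chunk - 1, n_grid)]
    Y <- log10(outer(rep(1, length(bb)), fw) - bb)   # rows: candidates
    sl <- (Y[, i_low, drop = FALSE] %*% xs_l) / sum(xs_l^2)
    sh <- (Y[, i_high, drop = FALSE] %*% xs_h) / sum(xs_h^2)
    d <- abs(sl - sh)
    k <- which.min(d)
    if (d[k] < best[1]) best <- c(d[k], bb[k], 10^sh[k])
  }
  list(delta = best[1], baseline = best[2], E = best[3],
       resolution = bs[2] - bs[1])
}
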