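#' Ground truth of a simulated amplification curve
#'
#' The simulator implements limiting-component kinetics: copies grow by a
#' factor `E0` per cycle while the limiting reagent lasts, and the
#' per-cycle gain collapses as the copy number approaches the ceiling
#' `limit`. The continuous trajectory solves
#' `dN/dt = N * log(1 + (E0 - 1) * (1 - (N/limit)^k))`,
#' whose exact small-N limit is the textbook exponential `N(t) = N0 * E0^t`.
#' The sharpness exponent `k` controls how abruptly the exponential phase
#' ends; `k = 1` is plain linear resource depletion, and the default
#' `k = 2.5` reproduces the fast transition of real reactions (with very
#' gradual saturation the third-derivative zero drifts more than two
#' cycles below the first-derivative maximum and the TD0 call is
#' ill-posed by construction).
#'
#' Fluorescence is read once per cycle:
#' `F(c) = baseline_a + baseline_b * c + scale * N(c) * (1 + eps_c)` with
#' `eps_c ~ Normal(0, noise_sd)`.
#'
#' @param N0 Starting copies.
#' @param E0 Base PCR efficiency (1 < E0 <= 2).
#' @param limit Copy ceiling of the limiting component.
#' @param baseline_a Constant baseline fluorescence.
#' @param baseline_b Linear baseline drift per cycle.
#' @param scale Fluorescence units per copy.
#' @param noise_sd Relative (multiplicative) Gaussian noise SD.
#' @param seed Integer seed; the same truth always yields the same curve.
#' @param n_cycles Number of cycles.
#' @param sat_sharpness Saturation sharpness exponent `k`.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(N0, E0 = 1.9, limit = 7.2e10, baseline_a = 50,
                      baseline_b = 0.1, scale = 5e-8, noise_sd = 0.02,
                      seed = 1L, n_cycles = 45L, sat_sharpness = 2.5) {
  stopifnot(N0 >= 0, E0 > 1, E0 <= 2, limit > N0, scale > 0,
            noise_sd >= 0, n_cycles >= 10, sat_sharpness > 0)
  structure(list(N0 = N0, E0 = E0, limit = limit, baseline_a = baseline_a,
                 baseline_b = baseline_b, scale = scale, noise_sd = noise_sd,
                 seed = as.integer(seed), n_cycles = as.integer(n_cycles),
                 sat_sharpness = sat_sharpness),
            class = "sim_truth")
}

# Continuous limiting-kinetics trajectory N(t) at the requested times.
# Solved with lsoda at tight tolerance so integer samples and the dense
# oracle grid come from one and the same trajectory.
sim_trajectory <- function(truth, times) {
  if (truth$N0 == 0) return(rep(0, length(times)))
  deriv <- function(t, y, p) {
    frac <- max(0, 1 - (y[1] / p$L)^p$k)
    list(y[1] * log(1 + (p$E0 - 1) * frac))
  }
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(y = c(N = truth$N0), times = tt, func = deriv,
                        parms = list(L = truth$limit, E0 = truth$E0,
                                     k = truth$sat_sharpness),
                        rtol = 1e-10, atol = truth$N0 * 1e-10)
  pmin(stats::approx(sol[, 1], sol[, 2], xout = times)$y, truth$limit)
}

#' Simulate one amplification curve
#'
#' @param truth A [sim_truth()].
#' @return List with `fluorescence` (numeric, cycles `1..n_cycles`),
#'   `copies` (noise-free copy numbers per cycle) and `truth`.
#' @examples
#' tr <- sim_truth(N0 = 1500, E0 = 1.9, noise_sd = 0)
#' curve <- simulate_curve(tr)
#' @export
simulate_curve <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  cyc <- seq_len(truth$n_cycles)
  N <- sim_trajectory(truth, cyc)
  eps <- if (truth$noise_sd > 0) {
    with_preserved_rng(truth$seed, stats::rnorm(truth$n_cycles, 0, truth$noise_sd))
  } else {
    rep(0, truth$n_cycles)
  }
  f <- truth$baseline_a + truth$baseline_b * cyc + truth$scale * N * (1 + eps)
  list(fluorescence = f, copies = N, truth = truth)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_preserved_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Independent dense-grid TD0 oracle for a simulated truth
#'
#' Evaluates the noise-free continuous trajectory on a dense grid (default
#' step 0.001 cycles) and applies the TD0 estimand with continuous
#' argument: unit-lag central differences for the first and second
#' derivative, the three-cycle moving geometric mean on the second
#' derivative, and the half-cycle-centred unit difference of the smoothed
#' series as the third derivative. The returned value is the third-derivative
#' zero crossing nearest the first-derivative maximum. [call_td0()] sees
#' only the integer-cycle samples of the same trajectory, so the two
#' implementations are independent routes to the same quantity.
#'
#' @param truth A [sim_truth()].
#' @param dt Grid step in cycles.
#' @return Fractional cycle, or `NA` when no crossing exists.
#' @export
oracle_td0 <- function(truth, dt = 0.001) {
  stopifnot(inherits(truth, "sim_truth"))
  # coarse pass locates the crossing, dense pass refines it
  coarse <- oracle_td0_grid(truth, seq(0, truth$n_cycles, by = 0.02))
  if (!is.finite(coarse)) return(NA_real_)
  lo <- max(0, coarse - 7)
  hi <- min(truth$n_cycles, coarse + 7)
  oracle_td0_grid(truth, seq(lo, hi, by = dt))
}

oracle_td0_grid <- function(truth, tg) {
  dt <- tg[2] - tg[1]
  N <- sim_trajectory(truth, tg)
  f <- truth$baseline_a + truth$baseline_b * tg + truth$scale * N
  m <- round(1 / dt)                 # samples per cycle
  if (length(f) < 5 * m + 2) return(NA_real_)
  len <- length(f)
  # unit-lag stencils with continuous argument t = tg[i], defined where
  # f(t-1) and f(t+1) exist
  i <- (m + 1):(len - m)
  d1 <- (f[i + m] - f[i - m]) / 2
  d2 <- f[i + m] - 2 * f[i] + f[i - m]
  t12 <- tg[i]
  # 3-cycle geometric-mean smoothing: s(t) from d2(t-1), d2(t), d2(t+1)
  j <- (m + 1):(length(d2) - m)
  a <- d2[j - m]; b <- d2[j]; c2 <- d2[j + m]
  s <- ifelse(a > 0 & b > 0 & c2 > 0, (a * b * c2)^(1 / 3), (a + b + c2) / 3)
  ts <- t12[j]
  # third derivative: half-cycle difference of the smoothed series
  h <- round(m / 2)
  kk <- (h + 1):(length(s) - h)
  d3 <- s[kk + h] - s[kk - h]
  t3 <- ts[kk]
  tmax <- t12[which.max(d1)]
  idx <- which(d3[-length(d3)] > 0 & d3[-1] <= 0)
  if (!length(idx)) return(NA_real_)
  t0 <- t3[idx] + dt * d3[idx] / (d3[idx] - d3[idx + 1])
  near <- abs(t0 - tmax) <= 2.5
  if (any(near)) t0 <- t0[near]
  t0[which.min(abs(t0 - tmax))]
}

# Copy fraction consumed at the oracle TD0, as a function of efficiency and
# saturation sharpness only (scale invariant). Used to place the kinetic
# ceiling of simulated plates so that copies-at-TD0 equal the analyzer's
# limiting-component count. Memoised.
.phi_cache <- new.env(parent = emptyenv())

sdm_copy_fraction <- function(E0, sat_sharpness = 2.5) {
  key <- sprintf("%.6f_%.4f", E0, sat_sharpness)
  if (!is.null(.phi_cache[[key]])) return(.phi_cache[[key]])
  n <- ceiling(log(1e10) / log(E0)) + 8
  tr <- sim_truth(N0 = 1e-10 * 1, E0 = E0, limit = 1, baseline_a = 0,
                  baseline_b = 0, scale = 1, noise_sd = 0, n_cycles = n,
                  sat_sharpness = sat_sharpness)
  td0 <- oracle_td0(tr)
  if (!is.finite(td0)) stop("no oracle TD0 for the canonical trajectory")
  phi <- sim_trajectory(tr, td0)
  .phi_cache[[key]] <- phi
  phi
}

#' Simulate an annotated plate with known ground truth
#'
#' Builds a [qpcr_run()] whose wells follow the limiting-component
#' kinetics. The kinetic copy ceiling of each well is placed so that the
#' copy number present at the (oracle) TD0 equals the limiting-component
#' count the analyzer assumes from the dye/primer configuration — the
#' simulated analogue of the empirical calibration behind the `C_p`/`C_d`
#' constants — which makes absolute Ncopy recovery well-posed.
#'
#' @param wells Data frame with one row per well: `sample_name`,
#'   `sample_type`, `target`, `N0` (true starting copies), and optionally
#'   `E0`, `noise_sd`, `std_conc`.
#' @param targets List of [target_config()] objects.
#' @param dyes List of [dye_config()] objects.
#' @param reaction_volume Reaction volume in uL.
#' @param run_id Run identifier.
#' @param E0 Default PCR efficiency for wells without their own.
#' @param noise_sd Default relative noise SD.
#' @param seed Integer seed (each well derives its own sub-seed).
#' @param n_cycles Number of cycles.
#' @param run_factor Multiplicative fluorescence-scale factor of the whole
#'   plate (models plate-to-plate optical differences; it cancels in TD0
#'   and efficiency but is what inter-run correction must recover when it
#'   is applied to copies rather than optics — see `copy_factor`).
#' @param copy_factor Multiplies every well's true `N0` (a systematic
#'   plate-level copy bias, the quantity inter-run correction estimates).
#' @param plateau_fluorescence Approximate plateau height in fluorescence
#'   units, sets the per-copy scale.
#' @param sat_sharpness Saturation exponent, see [sim_truth()].
#' @param constants [qpcr_constants()].
#' @return List with `run` (a [qpcr_run()], double-stranded input) and
#'   `truth` (data frame of per-well ground truth).
#' @export
simulate_run <- function(wells, targets, dyes, reaction_volume = 20,
                         run_id = "sim_run", E0 = 1.9, noise_sd = 0.02,
                         seed = 1L, n_cycles = 45L, run_factor = 1,
                         copy_factor = 1, plateau_fluorescence = 3000,
                         sat_sharpness = 2.5,
                         constants = qpcr_constants()) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_name", "sample_type", "target", "N0") %in%
                  names(wells)),
            run_factor > 0, copy_factor > 0)
  targets <- as_named_config_list(targets, "target_config")
  dyes <- as_named_config_list(dyes, "dye_config")
  if (is.null(wells$E0)) wells$E0 <- E0
  if (is.null(wells$noise_sd)) wells$noise_sd <- noise_sd
  if (is.null(wells$std_conc)) wells$std_conc <- NA_real_
  if (is.null(wells$well_id)) {
    wells$well_id <- sprintf("W%02d", seq_len(nrow(wells)))
  }
  n <- nrow(wells)
  fl <- matrix(NA_real_, n, n_cycles)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    tg <- targets[[wells$target[i]]]
    if (is.null(tg)) stop("well references unknown target: ", wells$target[i])
    dye <- dyes[[tg$dye]]
    lim_analyzer <- limit_copies(tg, dye, reaction_volume, constants)$copies
    phi <- sdm_copy_fraction(wells$E0[i], sat_sharpness)
    lim_kin <- lim_analyzer / phi
    scale <- plateau_fluorescence / lim_kin * run_factor
    N0_true <- wells$N0[i] * copy_factor
    tr <- sim_truth(N0 = N0_true, E0 = wells$E0[i], limit = lim_kin,
                    scale = scale, noise_sd = wells$noise_sd[i],
                    seed = as.integer((as.numeric(seed) * 1009 + i) %% 2147483647),
                    n_cycles = n_cycles, sat_sharpness = sat_sharpness)
    fl[i, ] <- simulate_curve(tr)$fluorescence
    truth_rows[[i]] <- data.frame(
      well_id = wells$well_id[i], sample_name = wells$sample_name[i],
      target = wells$target[i], N0 = N0_true, E0 = wells$E0[i],
      limit_kinetic = lim_kin, limit_analyzer = lim_analyzer,
      noise_sd = wells$noise_sd[i], stringsAsFactors = FALSE
    )
  }
  run <- qpcr_run(run_id = run_id, fluorescence = fl,
                  wells = wells[c("well_id", "sample_name", "sample_type",
                                  "target", "std_conc")],
                  targets = targets, dyes = dyes,
                  reaction_volume = reaction_volume,
                  input_strandedness = "double")
  list(run = run, truth = do.call(rbind, truth_rows))
}
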