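#' Discrete derivative series of an amplification curve
#'
#' Computes the first and second derivative of the raw fluorescence by
#' central differences on the 1-based cycle axis, smooths the second
#' derivative with a three-cycle moving geometric mean, and takes the first
#' difference of the smoothed series as the third derivative. Constant
#' baseline fluorescence cancels in the first derivative and any linear
#' baseline cancels exactly in the second difference, which is what makes
#' the downstream TD0 call independent of machine baseline handling.
#'
#' The geometric mean is undefined for non-positive values; wherever the
#' three second-derivative values are not all positive the smoother falls
#' back to the arithmetic mean of the same three values.
#'
#' @param fluorescence Numeric vector of raw readings, cycles `1..n`,
#'   `n >= 7`.
#' @return A list of class `derivative_series` with elements `d1`, `d2`,
#'   `d2_smoothed` (aligned with cycles; `NA` where the stencil does not
#'   fit) and `d3` with its half-cycle positions `d3_pos` (`d3[i]` is the
#'   difference of the smoothed second derivative across `d3_pos[i]`).
#' @examples
#' ds <- compute_derivatives(5 + 0.3 * (1:20))
#' range(ds$d1, na.rm = TRUE)  # 0.3 everywhere
#' @export
compute_derivatives <- function(fluorescence) {
  f <- as.numeric(fluorescence)
  n <- length(f)
  if (n < 7) stop("need >= 7 cycles to compute the derivative series")
  if (anyNA(f)) stop("fluorescence contains NA")
  d1 <- d2 <- d2s <- rep(NA_real_, n)
  core <- 2:(n - 1)
  d1[core] <- (f[core + 1] - f[core - 1]) / 2
  d2[core] <- f[core + 1] - 2 * f[core] + f[core - 1]
  for (c in 3:(n - 2)) {
    v <- d2[(c - 1):(c + 1)]
    d2s[c] <- if (all(v > 0)) prod(v)^(1 / 3) else mean(v)
  }
  cs <- 3:(n - 3)
  structure(list(d1 = d1, d2 = d2, d2_smoothed = d2s,
                 d3 = d2s[cs + 1] - d2s[cs], d3_pos = cs + 0.5),
            class = "derivative_series")
}

#' Call TD0, the third-derivative zero of an amplification curve
#'
#' TD0 is the fractional cycle at which the third derivative of the
#' amplification curve crosses zero from positive to negative, i.e. the
#' maximum of the three-cycle-smoothed second derivative marking the end
#' of the exponential phase. Only a crossing within two cycles of the
#' first-derivative maximum is accepted (the first-derivative maximum is
#' located to sub-cycle precision by a parabola through its three
#' surrounding values). The call is threshold-free and invariant to
#' constant and linear baseline components.
#'
#' The zero crossing is located to sub-cycle precision by resampling: a
#' provisional straight baseline is fitted to the ground-phase cycles by
#' least squares (a linear fit is exactly equivariant under linear
#' baseline shifts, so the invariance survives), the corrected curve
#' around the second-derivative peak is interpolated with a cubic spline
#' in log space — where an amplification curve is nearly straight — and
#' the derivative/smoothing stencils are evaluated densely on the
#' interpolant. When the resampling path is unavailable (e.g. non-positive
#' corrected readings) the crossing is interpolated linearly between the
#' two bracketing third-derivative values instead.
#'
#' A curve whose total fluorescence rise does not clearly exceed the ground
#' noise (rise less than ten times the robust cycle-to-cycle scatter of the
#' first five cycles) is reported as a no-call with flag
#' `no_amplification`; a no-call is a result, not an error.
#'
#' @param fluorescence Raw fluorescence vector (cycles `1..n`).
#' @return List with `td0` (fractional cycle or `NA`), `d1_max` (sub-cycle
#'   position of the first-derivative maximum), and `flags` (character
#'   vector).
#' @export
call_td0 <- function(fluorescence) {
  f <- as.numeric(fluorescence)
  no_call <- function(flag) list(td0 = NA_real_, d1_max = NA_real_,
                                 flags = flag)
  if (length(f) < 10) return(no_call("no_amplification"))
  if (!amplification_gate(f)) return(no_call("no_amplification"))
  ds <- compute_derivatives(f)
  cstar <- which.max(ds$d1)
  tstar <- d1_max_interp(ds$d1, cstar)
  cpk <- which.max(ds$d2_smoothed)
  td0 <- td0_resampled(f, cpk, tstar)
  if (!is.finite(td0)) td0 <- td0_chord(ds, cpk, tstar)
  if (!is.finite(td0)) return(no_call("no_amplification"))
  list(td0 = td0, d1_max = tstar, flags = character())
}

seq_spaced <- function(from, to, by) {
  if (from > to) return(numeric(0))
  seq(from, to, by = by)
}

# Sub-cycle first-derivative maximum: vertex of the parabola through the
# integer maximum and its neighbours (falls back to the integer cycle).
d1_max_interp <- function(d1, cstar) {
  if (cstar < 2 || cstar > length(d1) - 1) return(cstar)
  y <- d1[(cstar - 1):(cstar + 1)]
  if (anyNA(y)) return(cstar)
  den <- y[1] - 2 * y[2] + y[3]
  if (den >= 0) return(cstar)
  cstar + 0.5 * (y[1] - y[3]) / den
}

# Linear (chord) interpolation of the third-derivative zero bracketing the
# smoothed-second-derivative maximum.
td0_chord <- function(ds, cpk, tstar) {
  p <- ds$d3_pos
  d3 <- ds$d3
  iL <- match(cpk - 0.5, p)
  iR <- match(cpk + 0.5, p)
  if (is.na(iL) || is.na(iR)) return(NA_real_)
  if (!(d3[iL] > 0 && d3[iR] <= 0)) return(NA_real_)
  td <- p[iL] + d3[iL] / (d3[iL] - d3[iR])
  if (abs(td - tstar) > 2) return(NA_real_)
  td
}

# Dense evaluation of the TD0 functional on a regression-spline model of
# the baseline-corrected curve in log space. Spline knots sit on every
# cycle across the bend around the smoothed-second-derivative peak (where
# the curve carries real curvature) and on every second cycle in the
# log-linear flanks, so reading noise in the flanks is averaged instead of
# interpolated. The fit is ordinary least squares on a fixed basis: exactly
# equivariant under linear baseline shifts and free of data-driven tuning.
td0_resampled <- function(f, cpk, tstar, dt = 0.002) {
  n <- length(f)
  cyc <- seq_len(n)
  gw <- 1:max(4, cpk - 8)
  co <- stats::coef(stats::lm(f[gw] ~ gw))
  if (!all(is.finite(co))) return(NA_real_)
  fc <- f - (co[[1]] + co[[2]] * cyc)
  W <- (max(1, cpk - 6)):(min(n, cpk + 6))
  W <- W[fc[W] > 0]
  if (!length(W) || !(cpk %in% W)) return(NA_real_)
  br <- which(diff(W) > 1)
  starts <- c(1, br + 1)
  ends <- c(br, length(W))
  blk <- which(starts <= match(cpk, W) & ends >= match(cpk, W))
  W <- W[starts[blk]:ends[blk]]
  if (length(W) < 6) return(NA_real_)
  kn <- sort(unique(c(seq(cpk - 2, cpk + 3, by = 1),
                      seq_spaced(min(W) + 2, cpk - 3, 2),
                      seq_spaced(cpk + 4, max(W) - 2, 2))))
  kn <- kn[kn > min(W) & kn < max(W)]
  X <- splines::bs(W, knots = kn, degree = 3, Boundary.knots = range(W))
  fit <- stats::lm(log(fc[W]) ~ X)
  cf <- stats::coef(fit)
  if (anyNA(cf)) return(NA_real_)
  tg <- seq(min(W), max(W), by = dt)
  Xg <- splines::bs(tg, knots = kn, degree = 3, Boundary.knots = range(W))
  fd <- exp(drop(cbind(1, Xg) %*% cf))
  m <- round(1 / dt)
  if (length(fd) < 5 * m + 2) return(NA_real_)
  i <- (m + 1):(length(fd) - m)
  d2 <- fd[i + m] - 2 * fd[i] + fd[i - m]
  t2 <- tg[i]
  j <- (m + 1):(length(d2) - m)
  a <- d2[j - m]; b <- d2[j]; c2 <- d2[j + m]
  s <- ifelse(a > 0 & b > 0 & c2 > 0, (a * b * c2)^(1 / 3), (a + b + c2) / 3)
  ts <- t2[j]
  h <- round(m / 2)
  kk <- (h + 1):(length(s) - h)
  d3 <- s[kk + h] - s[kk - h]
  t3 <- ts[kk]
  idx <- which(d3[-length(d3)] > 0 & d3[-1] <= 0)
  if (!length(idx)) return(NA_real_)
  t0 <- t3[idx] + dt * d3[idx] / (d3[idx] - d3[idx + 1])
  t0 <- t0[abs(t0 - tstar) <= 2]
  if (!length(t0)) return(NA_real_)
  # among admissible crossings, the one at the global smoothed-d2 maximum
  smax_t <- ts[which.max(s)]
  t0[which.min(abs(t0 - smax_t))]
}

# Amplification gate: total rise must exceed 10x the robust SD of the
# cycle-to-cycle differences over the first five cycles (ground noise).
amplification_gate <- function(f) {
  rise <- max(f) - min(f)
  noise <- stats::mad(diff(f[1:min(5, length(f))]))
  if (noise == 0) rise > 0 else rise > 10 * noise
}

#' Locate the exponential phase below TD0
#'
#' The exponential phase ends just below TD0: the stop cycle is
#' `floor(td0 - 0.5)`. From the stop cycle the start is found by walking
#' backwards for as long as the fluorescence keeps (strictly) decreasing in
#' that direction; the start cycle itself is excluded from the window
#' because it may still carry residual baseline. The window is the cycle
#' range `(start, stop]`, needs at least 4 cycles and is truncated to the 9
#' cycles nearest the stop cycle.
#'
#' @param fluorescence Raw fluorescence vector.
#' @param td0 Fractional TD0 cycle from [call_td0()].
#' @return List with `start_excluded`, `stop`, `window` (integer cycles) and
#'   `flags` (`short_exp_phase` when no valid window exists).
#' @export
find_exponential_phase <- function(fluorescence, td0) {
  f <- as.numeric(fluorescence)
  short <- function() list(start_excluded = NA_integer_, stop = NA_integer_,
                           window = integer(), flags = "short_exp_phase")
  if (!is.finite(td0)) return(short())
  stop_cycle <- floor(td0 - 0.5)
  if (stop_cycle > length(f)) stop_cycle <- length(f)
  if (stop_cycle < 5) return(short())
  s <- stop_cycle
  while (s > 1 && f[s - 1] < f[s]) s <- s - 1
  # window = (s, stop]; cap at the 9 cycles nearest the stop cycle
  if (stop_cycle - s > 9) s <- stop_cycle - 9
  window <- seq.int(s + 1, stop_cycle)
  if (length(window) < 4) return(short())
  list(start_excluded = s, stop = stop_cycle, window = window,
       flags = character())
}

#' Baseline and individual PCR efficiency by iterative bisection
#'
#' The true baseline lies between zero and the lowest fluorescence of the
#' exponential-phase window. After subtracting a candidate baseline the
#' log10 fluorescence of the window must be a straight line; this is tested
#' by splitting the window into a lower and an upper subsection and
#' comparing their least-squares slopes. A lower slope in the lower
#' subsection means the baseline was underestimated (raise it), the
#' opposite means overestimated (lower it). Bisection iterates until the
#' two slopes agree to within 1e-5; the individual PCR efficiency is ten to
#' the power of the upper-subsection slope at convergence.
#'
#' With an even window of `w` cycles each subsection holds `w/2` points;
#' with an odd window the middle point is shared so both fits keep at least
#' two points at the minimal window of four.
#'
#' @param fluorescence Raw fluorescence vector.
#' @param window Integer cycles of the exponential phase
#'   ([find_exponential_phase()]).
#' @param tol Convergence tolerance on the slope difference.
#' @param max_iter Bisection iteration cap.
#' @return List with `baseline`, `E_indiv` (or `NA`), `slope_low`,
#'   `slope_high`, `iterations`, `converged` and `flags`
#'   (`baseline_unreliable` on failure).
#' @export
estimate_baseline_efficiency <- function(fluorescence, window,
                                         tol = 1e-5, max_iter = 200) {
  f <- as.numeric(fluorescence)
  fail <- function() list(baseline = NA_real_, E_indiv = NA_real_,
                          slope_low = NA_real_, slope_high = NA_real_,
                          iterations = 0L, converged = FALSE,
                          flags = "baseline_unreliable")
  window <- as.integer(window)
  if (length(window) < 4 || any(window < 1) || any(window > length(f))) {
    return(fail())
  }
  fw <- f[window]
  if (any(fw <= 0) || any(diff(fw) <= 0)) return(fail())
  lo <- 0
  hi <- min(fw)
  w <- length(window)
  half <- ceiling(w / 2)
  i_low <- seq_len(half)
  i_high <- seq.int(w - half + 1, w)
  slopes <- function(b) {
    y <- log10(fw - b)
    c(ls_slope(window[i_low], y[i_low]), ls_slope(window[i_high], y[i_high]))
  }
  b <- (lo + hi) / 2
  it <- 0L
  repeat {
    it <- it + 1L
    s <- slopes(b)
    if (!all(is.finite(s))) return(fail())
    if (abs(s[1] - s[2]) < tol) {
      return(list(baseline = b, E_indiv = 10^s[2], slope_low = s[1],
                  slope_high = s[2], iterations = it, converged = TRUE,
                  flags = character()))
    }
    if (it >= max_iter) return(fail())
    if (s[1] < s[2]) lo <- b else hi <- b   # slope_low < slope_high: baseline underestimated
    b <- (lo + hi) / 2
  }
}

ls_slope <- function(x, y) {
  x <- x - mean(x)
  sum(x * y) / sum(x * x)
}

#' Analyze a single amplification curve
#'
#' Runs the per-curve pipeline: TD0 call, exponential-phase search and
#' baseline/efficiency bisection.
#'
#' @param fluorescence Raw fluorescence vector (cycles `1..n`).
#' @param excluded Logical pre-flag (e.g. melting-curve artifact); excluded
#'   curves are not analyzed.
#' @return A list of class `curve_result` with `td0`, `baseline`,
#'   `E_indiv`, `exp_phase` (window description) and `flags`.
#' @export
analyze_curve <- function(fluorescence, excluded = FALSE) {
  if (isTRUE(excluded)) {
    return(structure(list(td0 = NA_real_, baseline = NA_real_,
                          E_indiv = NA_real_, exp_phase = NULL,
                          flags = "excluded_by_annotation"),
                     class = "curve_result"))
  }
  td <- call_td0(fluorescence)
  flags <- td$flags
  ep <- find_exponential_phase(fluorescence, td$td0)
  flags <- union(flags, ep$flags)
  if (length(ep$window) >= 4) {
    be <- estimate_baseline_efficiency(fluorescence, ep$window)
    flags <- union(flags, be$flags)
    baseline <- be$baseline
    E_indiv <- be$E_indiv
  } else {
    baseline <- NA_real_
    E_indiv <- NA_real_
  }
  structure(list(td0 = td$td0, baseline = baseline, E_indiv = E_indiv,
                 exp_phase = ep, flags = flags),
            class = "curve_result")
}
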