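#' Mean PCR efficiency of a target with iterative outlier removal
#'
#' The individual efficiency of a single reaction is noisy; the mean over
#' all reactions of the same target in a run is the efficiency used for
#' quantification. When the distribution of individual efficiencies is
#' skewed (|mean - median| > 0.25 SD) a two-sided Grubbs test at level
#' `alpha` is applied iteratively: the most extreme value is removed while
#' the test rejects, the trigger still fires and more than three values
#' remain.
#'
#' @param E_values Numeric vector of individual PCR efficiencies.
#' @param alpha Significance level of the Grubbs test.
#' @param ids Optional identifiers parallel to `E_values` (e.g. well ids)
#'   used to report outliers.
#' @return A list of class `target_run_stats`: `E_mean`, `E_sd`, `n_used`,
#'   and `outliers` (data frame of removed values).
#' @examples
#' mean_target_efficiency(c(1.84, 1.85, 1.85, 1.86, 1.86, 1.85, 2.60))
#' @export
mean_target_efficiency <- function(E_values, alpha = 0.05, ids = NULL) {
  x <- as.numeric(E_values)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  keep <- is.finite(x)
  x <- x[keep]; ids <- ids[keep]
  if (!length(x)) stop("no finite efficiency values")
  out_val <- numeric()
  out_id <- character()
  while (length(x) > 3 && is_skewed(x)) {
    g <- grubbs_statistic(x)
    if (g$G <= grubbs_critical(length(x), alpha)) break
    out_val <- c(out_val, x[g$idx])
    out_id <- c(out_id, ids[g$idx])
    x <- x[-g$idx]; ids <- ids[-g$idx]
  }
  structure(list(E_mean = mean(x),
                 E_sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                 n_used = length(x),
                 outliers = data.frame(id = out_id, E_indiv = out_val,
                                       stringsAsFactors = FALSE)),
            class = "target_run_stats")
}

is_skewed <- function(x) {
  s <- stats::sd(x)
  s > 0 && abs(mean(x) - stats::median(x)) > 0.25 * s
}

grubbs_statistic <- function(x) {
  d <- abs(x - mean(x))
  idx <- which.max(d)
  list(G = d[idx] / stats::sd(x), idx = idx)
}

# Two-sided Grubbs critical value at level alpha for sample size n.
grubbs_critical <- function(n, alpha) {
  t <- stats::qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Copy number of the limiting component
#'
#' Number of amplicon copies present when the limiting component of the
#' reaction is exhausted, i.e. the copy ceiling entering the Ncopy
#' conversion. For non-saturating dyes the dye itself is limiting and the
#' ceiling scales inversely with amplicon length (the dye stains base
#' pairs); for saturating dyes and hydrolysis probes the primers are
#' limiting.
#'
#' @param target A [target_config()].
#' @param dye A [dye_config()].
#' @param vol Reaction volume in uL.
#' @param constants [qpcr_constants()].
#' @return List with `copies` and `regime` (`"dye_limited"` or
#'   `"primer_limited"`).
#' @examples
#' # all primers incorporated: 250 nM in 20 uL -> 3.0e12 copies
#' sybr <- dye_config("SYBR", "hydrolysis_probe", C_p = 1)
#' tgt <- target_config("t", "toi", 250, 100, "SYBR")
#' limit_copies(tgt, sybr, 20)$copies
#' @export
limit_copies <- function(target, dye, vol, constants = qpcr_constants()) {
  stopifnot(inherits(target, "target_config"), inherits(dye, "dye_config"),
            vol >= 0)
  if (dye$chemistry == "non_saturating_dye") {
    if (target$amplicon_length <= 0) {
      stop("dye-limited regime needs amplicon_length > 0")
    }
    copies <- dye$C_d * dye$dye_conc * constants$N_A * vol /
      (target$amplicon_length * constants$unit_factor)
    regime <- "dye_limited"
  } else {
    copies <- dye$C_p * target$primer_conc * constants$N_A * vol /
      constants$unit_factor
    regime <- "primer_limited"
  }
  list(copies = copies, regime = regime)
}

#' Mass of amplicon produced if all primers are incorporated
#'
#' @param prim Primer concentration in nM.
#' @param amp Amplicon length in bp.
#' @param vol Reaction volume in uL.
#' @param constants [qpcr_constants()].
#' @return Mass in grams.
#' @examples
#' amplicon_mass(250, 100, 20) * 1e9  # 330 ng
#' @export
amplicon_mass <- function(prim, amp, vol, constants = qpcr_constants()) {
  stopifnot(prim >= 0, amp >= 0, vol >= 0)
  prim * amp * vol * constants$bp_mass / constants$unit_factor
}

#' Convert TD0 and mean PCR efficiency into starting copies (Ncopy)
#'
#' The limiting-component ceiling divided by `E^TD0` undoes the exponential
#' amplification and yields the number of target copies at the start of the
#' reaction. Single-stranded input (cDNA, synthetic oligos) yields half the
#' double-stranded product per input molecule in the first cycle, so Ncopy
#' is doubled for single-stranded input.
#'
#' @param td0 Fractional TD0 cycle (>= 0).
#' @param E Mean PCR efficiency of the target (> 1).
#' @param target A [target_config()].
#' @param dye A [dye_config()].
#' @param vol Reaction volume in uL.
#' @param strandedness `"single"` or `"double"` input DNA.
#' @param constants [qpcr_constants()].
#' @return A list of class `quant_result`: `ncopy`, `regime`,
#'   `strandedness_factor`, `limit`, `E_used`, `td0`.
#' @examples
#' sybr <- dye_config("SYBR", "non_saturating_dye", dye_conc = 400)
#' tgt <- target_config("t", "toi", 250, 100, "SYBR")
#' ncopy(td0 = 25, E = 1.9, tgt, sybr, vol = 10, strandedness = "double")
#' @export
ncopy <- function(td0, E, target, dye, vol,
                  strandedness = c("single", "double"),
                  constants = qpcr_constants()) {
  strandedness <- match.arg(strandedness)
  if (!is.finite(E) || E <= 1) stop("PCR efficiency must be > 1")
  stopifnot(is.finite(td0), td0 >= 0)
  lim <- limit_copies(target, dye, vol, constants)
  sf <- if (strandedness == "single") 2 else 1
  structure(list(ncopy = lim$copies / E^td0 * sf, regime = lim$regime,
                 strandedness_factor = sf, limit = lim$copies,
                 E_used = E, td0 = td0),
            class = "quant_result")
}

#' Quantify every reaction of a run
#'
#' The per-run pipeline: each curve is analyzed (TD0, exponential phase,
#' baseline, individual efficiency), individual efficiencies are averaged
#' per target with iterative Grubbs outlier removal, and each reaction's
#' Ncopy is computed from its own TD0 and its target's mean efficiency.
#' No-template controls are analyzed but never contribute to the mean
#' efficiency or downstream statistics; an ntc with a called TD0 raises a
#' contamination warning.
#'
#' @param run A [qpcr_run()].
#' @param constants [qpcr_constants()].
#' @param alpha Significance level for the efficiency outlier test.
#' @return A list of class `run_quant` with `results` (data frame, one row
#'   per reaction) and `target_stats` (data frame, one row per target).
#' @export
quantify_run <- function(run, constants = qpcr_constants(), alpha = 0.05) {
  stopifnot(inherits(run, "qpcr_run"))
  w <- run$wells
  n <- nrow(w)
  curves <- lapply(seq_len(n), function(i) {
    analyze_curve(run$fluorescence[i, ], excluded = w$excluded[i])
  })
  res <- data.frame(
    run_id = run$run_id,
    well_id = w$well_id,
    sample_name = w$sample_name,
    sample_type = w$sample_type,
    target = w$target,
    std_conc = w$std_conc,
    td0 = vapply(curves, `[[`, 0, "td0"),
    baseline = vapply(curves, `[[`, 0, "baseline"),
    E_indiv = vapply(curves, `[[`, 0, "E_indiv"),
    E_mean = NA_real_,
    ncopy = NA_real_,
    regime = NA_character_,
    flags = vapply(curves, function(cr) paste(cr$flags, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  stats_rows <- list()
  for (tg in names(run$targets)) {
    sel <- which(res$target == tg)
    usable <- sel[res$sample_type[sel] != "ntc" & is.finite(res$E_indiv[sel])]
    if (!length(usable)) {
      res$flags[sel] <- flag_add(res$flags[sel], "no_target_efficiency")
      next
    }
    st <- mean_target_efficiency(res$E_indiv[usable], alpha = alpha,
                                 ids = res$well_id[usable])
    stats_rows[[tg]] <- data.frame(
      target = tg, E_mean = st$E_mean, E_sd = st$E_sd, n_used = st$n_used,
      n_outliers = nrow(st$outliers),
      outlier_wells = paste(st$outliers$id, collapse = ";"),
      stringsAsFactors = FALSE
    )
    res$E_mean[sel] <- st$E_mean
    dye <- run$dyes[[run$targets[[tg]]$dye]]
    ok <- sel[is.finite(res$td0[sel])]
    for (i in ok) {
      if (st$E_mean <= 1) {
        res$flags[i] <- flag_add(res$flags[i], "non_amplifying_efficiency")
        next
      }
      q <- ncopy(res$td0[i], st$E_mean, run$targets[[tg]], dye,
                 run$reaction_volume, run$input_strandedness, constants)
      res$ncopy[i] <- q$ncopy
      res$regime[i] <- q$regime
    }
  }
  ntc_amp <- res$sample_type == "ntc" & is.finite(res$td0)
  if (any(ntc_amp)) {
    res$flags[ntc_amp] <- flag_add(res$flags[ntc_amp], "ntc_amplification")
    warning("amplification called in ntc reaction(s): ",
            paste(res$well_id[ntc_amp], collapse = ", "))
  }
  target_stats <- if (length(stats_rows)) {
    do.call(rbind, c(stats_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(target = character(), E_mean = numeric(), E_sd = numeric(),
               n_used = integer(), n_outliers = integer(),
               outlier_wells = character(), stringsAsFactors = FALSE)
  }
  structure(list(results = res, target_stats = target_stats),
            class = "run_quant")
}

flag_add <- function(flags, new) {
  ifelse(nzchar(flags), paste(flags, new, sep = ";"), new)
}

#' @export
print.run_quant <- function(x, ...) {
  cat(sprintf("run_quant: %d reactions, %d target(s) with efficiency\n",
              nrow(x$results), nrow(x$target_stats)))
  print(x$target_stats, ...)
  invisible(x)
}
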