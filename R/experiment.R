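#' Technical-replicate summaries with CV quality flag
#'
#' Reactions sharing sample and target name are technical replicates.
#' Their mean, SD and coefficient of variation quantify pipetting and
#' measurement repeatability; a CV above 0.3 adds more technical variation
#' than a qPCR experiment should carry and is flagged.
#'
#' @param results Data frame with columns `sample_name`, `target`, `ncopy`
#'   (e.g. the `results` of [quantify_run()]); rows with non-finite
#'   `ncopy` are ignored, ntc reactions are excluded.
#' @param cv_warn CV flag threshold.
#' @return Data frame with one row per (sample, target) group: `mean_ncopy`,
#'   `sd_ncopy`, `cv`, `n`, `high_cv_flag`, `single_replicate`.
#' @export
replicate_stats <- function(results, cv_warn = qpcr_constants()$cv_warn) {
  stopifnot(all(c("sample_name", "target", "ncopy") %in% names(results)))
  r <- results[is.finite(results$ncopy), , drop = FALSE]
  if (!is.null(r$sample_type)) r <- r[r$sample_type != "ntc", , drop = FALSE]
  if (!nrow(r)) {
    return(data.frame(sample_name = character(), target = character(),
                      mean_ncopy = numeric(), sd_ncopy = numeric(),
                      cv = numeric(), n = integer(), high_cv_flag = logical(),
                      single_replicate = logical(), stringsAsFactors = FALSE))
  }
  key <- interaction(r$sample_name, r$target, drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(r, key), function(g) {
    m <- mean(g$ncopy)
    s <- if (nrow(g) > 1) stats::sd(g$ncopy) else NA_real_
    cv <- if (nrow(g) > 1) s / m else NA_real_
    data.frame(sample_name = g$sample_name[1], target = g$target[1],
               mean_ncopy = m, sd_ncopy = s, cv = cv, n = nrow(g),
               high_cv_flag = isTRUE(cv > cv_warn),
               single_replicate = nrow(g) == 1, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' PCR efficiency from a dilution (calibration) series
#'
#' A straight line is fitted to TD0 against log10 input concentration;
#' the slope of an ideal series is `-1/log10(E)` cycles per decade, so
#' `E = 10^(-1/slope)`. The SD of the efficiency follows from the slope's
#' standard error by the delta method. This estimate is independent of the
#' per-curve (amplification-curve) efficiency and the agreement of the two
#' is a useful assay diagnostic.
#'
#' @param td0 TD0 values of the dilution reactions.
#' @param conc Input concentrations (copies/uL), same length.
#' @return A list of class `dilution_efficiency`: `E_dil`, `E_dil_sd`,
#'   `slope`, `slope_se`, `intercept`, `r2`, `n_points`, `n_levels`.
#' @examples
#' td0 <- 35 - log2(10) * log10(c(1e2, 1e3, 1e4, 1e5))
#' dilution_efficiency(td0, c(1e2, 1e3, 1e4, 1e5))$E_dil  # 2
#' @export
dilution_efficiency <- function(td0, conc) {
  ok <- is.finite(td0) & is.finite(conc) & conc > 0
  td0 <- td0[ok]; conc <- conc[ok]
  if (length(unique(conc)) < 3) {
    stop("dilution efficiency needs >= 3 distinct concentrations")
  }
  fit <- stats::lm(td0 ~ log10(conc))
  sm <- summary(fit)
  slope <- stats::coef(fit)[[2]]
  se <- sm$coefficients[2, 2]
  if (!is.finite(slope) || slope >= 0) {
    stop("dilution series slope must be negative (higher input, lower TD0)")
  }
  E <- 10^(-1 / slope)
  # delta method: dE/dslope = E * ln(10) / slope^2
  E_sd <- E * log(10) / slope^2 * se
  structure(list(E_dil = E, E_dil_sd = E_sd, slope = slope, slope_se = se,
                 intercept = stats::coef(fit)[[1]], r2 = sm$r.squared,
                 n_points = length(td0), n_levels = length(unique(conc))),
            class = "dilution_efficiency")
}

#' Scale Ncopy values with a single standard of known copies
#'
#' When a standard of known copy number was run, all Ncopy values are
#' multiplied by expected/measured of the standard with the highest amount.
#' The advisory conditions for a reliable single-standard calibration are
#' at least 6 technical replicates of that standard and an expected copy
#' number between 1000 and 5000; violations warn but do not stop.
#'
#' @param results Data frame of reaction results with `sample_name`,
#'   `sample_type`, `std_conc`, `ncopy`.
#' @param reaction_volume Reaction volume in uL (expected copies per
#'   reaction = `std_conc * reaction_volume`).
#' @return List with `results` (Ncopy rescaled in column `ncopy`, original
#'   kept as `ncopy_uncalibrated`), `factor`, `standard_sample`,
#'   `expected`, `measured`. Without std reactions the input is returned
#'   unchanged with `factor = NA` and a message.
#' @export
calibrate_with_standard <- function(results, reaction_volume) {
  stopifnot(all(c("sample_name", "sample_type", "std_conc", "ncopy") %in%
                  names(results)), reaction_volume > 0)
  std <- results[results$sample_type == "std" & is.finite(results$ncopy) &
                   is.finite(results$std_conc), , drop = FALSE]
  if (!nrow(std)) {
    message("no usable standard reactions; Ncopy left unscaled")
    return(list(results = results, factor = NA_real_,
                standard_sample = NA_character_, expected = NA_real_,
                measured = NA_real_))
  }
  per_sample <- do.call(rbind, lapply(split(std, std$sample_name), function(g) {
    data.frame(sample_name = g$sample_name[1],
               expected = g$std_conc[1] * reaction_volume,
               measured = mean(g$ncopy), n = nrow(g),
               stringsAsFactors = FALSE)
  }))
  top <- per_sample[which.max(per_sample$expected), ]
  if (top$n < 6) {
    warning(sprintf("standard '%s' has only %d replicate(s); >= 6 advised",
                    top$sample_name, top$n))
  }
  if (top$expected < 1000 || top$expected > 5000) {
    warning(sprintf(
      "standard '%s' holds %.3g expected copies; 1000-5000 advised",
      top$sample_name, top$expected))
  }
  fac <- top$expected / top$measured
  out <- results
  out$ncopy_uncalibrated <- out$ncopy
  out$ncopy <- out$ncopy * fac
  list(results = out, factor = fac, standard_sample = top$sample_name,
       expected = top$expected, measured = top$measured)
}

#' Inter-run correction from overlapping reactions
#'
#' Ncopy values of one run share small multiplicative biases (plate, seal,
#' optics, baseline handling). When an experiment spans several runs the
#' per-run bias is estimated from all reactions that overlap between runs
#' — replicate reactions of the same experimental group amplifying the
#' same target — by fitting the additive two-way model
#' `log10(Ncopy) = mu(group:target) + rho(run)` by least squares over the
#' overlapping cells. Each run's correction factor is `10^-rho`, rescaled
#' so the factors' geometric mean is one; every Ncopy of a run is
#' multiplied by its factor. Pooling many reactions per factor averages
#' out the technical error of individual wells and the approach tolerates
#' unbalanced designs.
#'
#' @param results Data frame with `run_id`, `group`, `target`, `ncopy`.
#' @return List with `results` (corrected `ncopy`, original kept as
#'   `ncopy_uncorrected`) and `run_factors` (data frame `run_id`,
#'   `factor`).
#' @export
interrun_correction <- function(results) {
  stopifnot(all(c("run_id", "group", "target", "ncopy") %in% names(results)))
  runs <- unique(results$run_id)
  if (length(runs) < 2) {
    rf <- data.frame(run_id = runs, factor = rep(1, length(runs)),
                     stringsAsFactors = FALSE)
    out <- results
    out$ncopy_uncorrected <- out$ncopy
    return(list(results = out, run_factors = rf))
  }
  r <- results[is.finite(results$ncopy) & results$ncopy > 0, , drop = FALSE]
  cell <- paste(r$group, r$target, sep = "\r")
  cell_runs <- tapply(r$run_id, cell, function(x) unique(x))
  overlap_cells <- names(cell_runs)[lengths(cell_runs) >= 2]
  if (!length(overlap_cells)) {
    stop("no (group, target) cell overlaps between runs; cannot correct")
  }
  comp <- run_components(runs, cell_runs[overlap_cells])
  if (length(unique(comp)) > 1) {
    grp <- split(names(comp), comp)
    stop("runs are not connected by overlapping cells; components: ",
         paste(vapply(grp, paste, "", collapse = "+"), collapse = " | "))
  }
  ov <- r[cell %in% overlap_cells, , drop = FALSE]
  ov$cell <- factor(paste(ov$group, ov$target, sep = "\r"))
  ov$run <- factor(ov$run_id, levels = runs)
  fit <- if (nlevels(ov$cell) > 1) {
    stats::lm(log10(ncopy) ~ cell + run, data = ov)
  } else {
    stats::lm(log10(ncopy) ~ run, data = ov)
  }
  rho <- rep(0, length(runs))
  names(rho) <- runs
  cf <- stats::coef(fit)
  for (rn in runs[-1]) {
    nm <- paste0("run", rn)
    if (nm %in% names(cf) && is.finite(cf[[nm]])) rho[rn] <- cf[[nm]]
  }
  rho <- rho - mean(rho)            # geometric mean of factors = 1
  factors <- 10^(-rho)
  out <- results
  out$ncopy_uncorrected <- out$ncopy
  out$ncopy <- out$ncopy * factors[as.character(out$run_id)]
  list(results = out,
       run_factors = data.frame(run_id = runs, factor = unname(factors[runs]),
                                stringsAsFactors = FALSE))
}

# Connected components of runs linked by shared overlap cells.
run_components <- function(runs, cell_runs) {
  comp <- stats::setNames(seq_along(runs), runs)
  for (cr in cell_runs) {
    tgt <- min(comp[cr])
    comp[comp %in% comp[cr]] <- tgt
  }
  comp
}

#' Fold difference between two groups with propagated error
#'
#' @param a,b Numeric vectors of (normalized) Ncopy values of the two
#'   groups; the fold is `mean(a)/mean(b)`.
#' @return List with `fold` and `se` (from the groups' SEMs by first-order
#'   error propagation).
#' @examples
#' fold_difference(c(9, 10, 11), c(4.5, 5, 5.5))$fold  # 2
#' @export
fold_difference <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ma <- mean(a); mb <- mean(b)
  if (mb == 0) stop("reference group mean is zero")
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  fold <- ma / mb
  se <- abs(fold) * sqrt((sem(a) / ma)^2 + (sem(b) / mb)^2)
  list(fold = fold, se = se, mean_a = ma, mean_b = mb,
       n_a = length(a), n_b = length(b))
}
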