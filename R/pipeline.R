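#' Run the full experiment-level analysis pipeline
#'
#' Orchestrates the experiment stages in their canonical order:
#' per-run quantification, optional single-standard calibration, optional
#' inter-run correction, optional geNorm reference validation, optional
#' reference normalization, technical-replicate quality control and
#' between-group statistics. Every multiplicative correction factor is
#' reported so each step's impact stays auditable.
#'
#' @param exp A [qpcr_experiment()] (runs plus sample annotations).
#' @param group_key Annotation key used for grouping (inter-run overlap
#'   cells and group statistics). Required for inter-run correction and
#'   group tests.
#' @param calibrate Apply [calibrate_with_standard()] when std reactions
#'   exist.
#' @param interrun Apply [interrun_correction()] when several runs exist.
#' @param run_genorm Run [genorm()] on the reference-gene candidates and
#'   use its recommended set for normalization.
#' @param normalize Normalize targets of interest to the reference set.
#' @param ref_genes Reference set for normalization; defaults to all
#'   targets annotated with role `"ref"` (or the geNorm recommendation).
#' @param test Statistical family for group tests, see [group_tests()].
#' @param alpha Significance level.
#' @param constants [qpcr_constants()].
#' @return A list of class `experiment_analysis` with `results` (combined
#'   reaction table), `target_stats`, `replicate_summary`, `calibration`,
#'   `run_factors`, `genorm`, `normalization`, `group_stats`.
#' @export
analyze_experiment <- function(exp, group_key = NULL, calibrate = TRUE,
                               interrun = TRUE, run_genorm = FALSE,
                               normalize = TRUE, ref_genes = NULL,
                               test = "t", alpha = 0.05,
                               constants = qpcr_constants()) {
  stopifnot(inherits(exp, "qpcr_experiment"))
  quants <- lapply(exp$runs, quantify_run, constants = constants,
                   alpha = alpha)
  results <- do.call(rbind, c(lapply(quants, `[[`, "results"),
                              list(make.row.names = FALSE)))
  target_stats <- do.call(rbind, c(lapply(names(quants), function(r) {
    ts <- quants[[r]]$target_stats
    if (nrow(ts)) cbind(run_id = r, ts, stringsAsFactors = FALSE) else NULL
  }), list(make.row.names = FALSE)))
  # group labels per sample
  if (!is.null(group_key)) {
    gmap <- sample_groups(exp, group_key)
    missing <- setdiff(unique(results$sample_name[results$sample_type == "unkn"]),
                       names(gmap))
    if (length(missing) && (interrun && length(exp$runs) > 1)) {
      stop("samples lack the '", group_key, "' annotation: ",
           paste(missing, collapse = ", "))
    }
    results$group <- unname(gmap[results$sample_name])
  } else {
    results$group <- results$sample_name
  }
  vol <- exp$runs[[1]]$reaction_volume
  calibration <- NULL
  if (calibrate && any(results$sample_type == "std" & is.finite(results$ncopy))) {
    calibration <- calibrate_with_standard(results, vol)
    results <- calibration$results
    calibration$results <- NULL
  }
  run_factors <- NULL
  if (interrun && length(exp$runs) > 1) {
    irc <- interrun_correction(results)
    results <- irc$results
    run_factors <- irc$run_factors
  }
  all_targets <- unlist(lapply(exp$runs, function(r) {
    vapply(r$targets, `[[`, "", "name")
  }))
  roles <- unlist(lapply(exp$runs, function(r) {
    vapply(r$targets, `[[`, "", "role")
  }))
  ref_candidates <- unique(all_targets[roles == "ref"])
  gn <- NULL
  if (run_genorm && length(ref_candidates) >= 3) {
    mat <- ref_expression_matrix(results, ref_candidates)
    gn <- genorm(mat, cutoff = constants$genorm_cutoff)
    if (is.null(ref_genes)) ref_genes <- gn$recommended_set
  }
  if (is.null(ref_genes)) ref_genes <- ref_candidates
  normalization <- NULL
  if (normalize) {
    if (!length(ref_genes)) stop("normalization requested but no reference genes configured")
    normalization <- normalize_to_references(results, ref_genes)
    results <- normalization$results
    normalization$results <- NULL
  }
  rs <- replicate_stats(results, cv_warn = constants$cv_warn)
  group_stats <- NULL
  if (!is.null(group_key)) {
    value_col <- if (normalize) "ncopy_norm" else "ncopy"
    tois <- setdiff(unique(results$target), ref_genes)
    group_stats <- lapply(stats::setNames(tois, tois), function(tg) {
      sel <- results$target == tg & results$sample_type == "unkn" &
        is.finite(results[[value_col]]) & !is.na(results$group)
      if (!any(sel)) return(NULL)
      # one value per biological sample: mean over technical replicates
      agg <- tapply(results[[value_col]][sel], results$sample_name[sel], mean)
      gr <- unname(sample_groups(exp, group_key)[names(agg)])
      if (length(unique(gr[!is.na(gr)])) < 2) return(NULL)
      tryCatch(group_tests(as.numeric(agg), gr, test = test, alpha = alpha),
               error = function(e) NULL)
    })
    group_stats <- Filter(Negate(is.null), group_stats)
  }
  structure(list(results = results, target_stats = target_stats,
                 replicate_summary = rs, calibration = calibration,
                 run_factors = run_factors, genorm = gn,
                 normalization = normalization, group_stats = group_stats,
                 ref_genes = ref_genes),
            class = "experiment_analysis")
}

# gene x sample matrix of mean Ncopy for the reference candidates
ref_expression_matrix <- function(results, genes) {
  r <- results[results$target %in% genes & is.finite(results$ncopy) &
                 results$ncopy > 0 & results$sample_type != "ntc", ,
               drop = FALSE]
  samples <- sort(unique(r$sample_name))
  mat <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  for (g in genes) {
    for (s in samples) {
      v <- r$ncopy[r$target == g & r$sample_name == s]
      if (length(v)) mat[g, s] <- mean(v)
    }
  }
  keep <- colSums(!is.finite(mat)) == 0
  mat[, keep, drop = FALSE]
}
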