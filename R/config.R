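#' Describe a fluorescence reporter (dye or probe)
#'
#' The reporter chemistry decides which limiting component ends the
#' exponential phase: a non-saturating DNA-binding dye (e.g. SYBR Green I)
#' is itself consumed and limits amplification (dye-limited regime), while
#' saturating dyes (e.g. EvaGreen) and hydrolysis probes leave the primers
#' as the limiting component (primer-limited regime).
#'
#' @param name Dye name (used as the key reactions refer to).
#' @param chemistry One of `"non_saturating_dye"`, `"saturating_dye"`,
#'   `"hydrolysis_probe"`.
#' @param dye_conc Dye concentration in nM; only used for non-saturating
#'   dyes. Default 400 nM (typical SYBR Green I content of commercial
#'   master mixes).
#' @param C_d Empirical dye constant relating dye molecules to stainable
#'   base pairs at TD0; 1.5 for SYBR Green I.
#' @param C_p Empirical fraction of primers consumed at TD0. Defaults to
#'   0.04 for saturating dyes and 0.1 for hydrolysis probes; irrelevant for
#'   non-saturating dyes.
#' @return A list of class `dye_config`.
#' @examples
#' dye_config("SYBR", "non_saturating_dye")
#' dye_config("FAM-probe", "hydrolysis_probe")
#' @export
dye_config <- function(name,
                       chemistry = c("non_saturating_dye", "saturating_dye",
                                     "hydrolysis_probe"),
                       dye_conc = 400, C_d = 1.5, C_p = NULL) {
  chemistry <- match.arg(chemistry)
  if (is.null(C_p)) {
    C_p <- switch(chemistry,
                  saturating_dye = 0.04,
                  hydrolysis_probe = 0.1,
                  non_saturating_dye = NA_real_)
  }
  stopifnot(is.character(name), nzchar(name), C_d > 0)
  if (chemistry == "non_saturating_dye") {
    stopifnot(dye_conc > 0)
  } else {
    stopifnot(C_p > 0, C_p <= 1)
  }
  structure(list(name = name, chemistry = chemistry, dye_conc = dye_conc,
                 C_d = C_d, C_p = C_p),
            class = "dye_config")
}

#' Describe an amplification target (assay)
#'
#' @param name Target name; reactions with the same sample and target name
#'   are treated as technical replicates (case sensitive).
#' @param role `"toi"` (target of interest) or `"ref"` (reference gene).
#' @param primer_conc Primer concentration in nM (each primer).
#' @param amplicon_length Amplicon length in bp.
#' @param dye Name of the [dye_config()] monitoring this target.
#' @param expected_tm Optional expected amplicon melting temperature
#'   (annotation only; melting-curve checks are performed upstream).
#' @return A list of class `target_config`.
#' @examples
#' target_config("FSTL1_109", "toi", primer_conc = 250,
#'               amplicon_length = 109, dye = "SYBR")
#' @export
target_config <- function(name, role = c("toi", "ref"), primer_conc,
                          amplicon_length, dye, expected_tm = NA_real_) {
  role <- match.arg(role)
  stopifnot(is.character(name), nzchar(name),
            primer_conc > 0, amplicon_length >= 1,
            is.character(dye), nzchar(dye))
  structure(list(name = name, role = role, primer_conc = primer_conc,
                 amplicon_length = amplicon_length, dye = dye,
                 expected_tm = expected_tm),
            class = "target_config")
}

#' Assemble an annotated qPCR run
#'
#' A run couples a plate of raw fluorescence readings with its per-well
#' annotations and the assay metadata needed for quantification. The
#' fluorescence must be raw machine output: the TD0 and efficiency
#' algorithms rely on the unmodified baseline (machine baseline subtraction
#' is not reversible and breaks the efficiency fit).
#'
#' @param run_id Run identifier.
#' @param fluorescence Numeric matrix, one row per well, one column per
#'   cycle (cycles 1..n); at least 10 cycles.
#' @param wells Data frame with one row per well: columns `well_id`,
#'   `sample_name`, `sample_type` (`"unkn"`, `"std"`, `"pos"`, `"ntc"`),
#'   `target`, and optionally `std_conc` (copies/uL, required for `"std"`),
#'   `excluded` (logical pre-flag, e.g. melting-curve artifact) and
#'   `exclusion_note`.
#' @param targets List of [target_config()] objects.
#' @param dyes List of [dye_config()] objects.
#' @param reaction_volume Reaction volume in uL.
#' @param input_strandedness `"single"` (default; cDNA or synthetic
#'   amplicons) or `"double"` (genomic DNA). Single-stranded input doubles
#'   the reported Ncopy.
#' @return A list of class `qpcr_run`.
#' @export
qpcr_run <- function(run_id, fluorescence, wells, targets, dyes,
                     reaction_volume, input_strandedness = c("single", "double")) {
  input_strandedness <- match.arg(input_strandedness)
  fluorescence <- as.matrix(fluorescence)
  stopifnot(is.numeric(fluorescence), ncol(fluorescence) >= 10,
            reaction_volume > 0, nrow(wells) == nrow(fluorescence))
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  rownames(wells) <- NULL
  need <- c("well_id", "sample_name", "sample_type", "target")
  miss <- setdiff(need, names(wells))
  if (length(miss)) {
    stop("wells table lacks mandatory column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(wells$std_conc)) wells$std_conc <- NA_real_
  if (is.null(wells$excluded)) wells$excluded <- FALSE
  if (is.null(wells$exclusion_note)) wells$exclusion_note <- ""
  bad_type <- setdiff(unique(wells$sample_type), c("unkn", "std", "pos", "ntc"))
  if (length(bad_type)) {
    stop("unknown sample_type value(s): ", paste(bad_type, collapse = ", "))
  }
  is_std <- wells$sample_type == "std"
  if (any(is_std & !(is.finite(wells$std_conc) & wells$std_conc > 0))) {
    stop("sample_type 'std' requires std_conc > 0 (copies/uL)")
  }
  targets <- as_named_config_list(targets, "target_config")
  dyes <- as_named_config_list(dyes, "dye_config")
  unknown_target <- setdiff(unique(wells$target), names(targets))
  if (length(unknown_target)) {
    stop("wells reference target(s) without a target_config: ",
         paste(unknown_target, collapse = ", "))
  }
  unknown_dye <- setdiff(vapply(targets, `[[`, "", "dye"), names(dyes))
  if (length(unknown_dye)) {
    stop("targets reference dye(s) without a dye_config: ",
         paste(unknown_dye, collapse = ", "))
  }
  rownames(fluorescence) <- wells$well_id
  colnames(fluorescence) <- as.character(seq_len(ncol(fluorescence)))
  structure(list(run_id = run_id, reaction_volume = reaction_volume,
                 input_strandedness = input_strandedness,
                 fluorescence = fluorescence, wells = wells,
                 targets = targets, dyes = dyes),
            class = "qpcr_run")
}

as_named_config_list <- function(x, cls) {
  if (inherits(x, cls)) x <- list(x)
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, cls)))
  names(x) <- vapply(x, `[[`, "", "name")
  if (anyDuplicated(names(x))) stop("duplicated ", cls, " names")
  x
}

#' @export
print.qpcr_run <- function(x, ...) {
  cat(sprintf("qpcr_run '%s': %d wells x %d cycles, %d target(s), %.3g uL, %s-stranded input\n",
              x$run_id, nrow(x$fluorescence), ncol(x$fluorescence),
              length(x$targets), x$reaction_volume, x$input_strandedness))
  invisible(x)
}

#' Bundle runs into an experiment
#'
#' @param runs List of [qpcr_run()] objects (or a single run).
#' @param sample_annotations Optional annotation table, see
#'   [attach_sample_annotations()].
#' @return A list of class `qpcr_experiment`.
#' @export
qpcr_experiment <- function(runs, sample_annotations = NULL) {
  if (inherits(runs, "qpcr_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "qpcr_run")))
  names(runs) <- vapply(runs, `[[`, "", "run_id")
  if (anyDuplicated(names(runs))) stop("duplicated run_id")
  exp <- structure(list(runs = runs,
                        sample_annotations = empty_annotation_table()),
                   class = "qpcr_experiment")
  if (!is.null(sample_annotations)) {
    exp <- attach_sample_annotations(exp, sample_annotations)
  }
  exp
}

empty_annotation_table <- function() {
  data.frame(sample_name = character(), key = character(),
             value = character(), stringsAsFactors = FALSE)
}

#' Attach key-value group annotations to samples
#'
#' Sample-level annotations (treatment, genotype, time point, ...) drive
#' grouping in the experiment-level statistics. Annotations are key-value
#' pairs per sample; re-annotating an existing key overwrites its value
#' (last one wins). Annotations for samples that occur in no run are kept,
#' with a warning, so tables can be prepared before all plates are run.
#'
#' @param exp A [qpcr_experiment()].
#' @param table Data frame with columns `sample_name`, `key`, `value`.
#' @return The experiment with merged annotations.
#' @export
attach_sample_annotations <- function(exp, table) {
  stopifnot(inherits(exp, "qpcr_experiment"))
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (nrow(table) == 0) return(exp)
  need <- c("sample_name", "key", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  }
  table <- table[need]
  table[] <- lapply(table, as.character)
  known <- unique(unlist(lapply(exp$runs, function(r) r$wells$sample_name)))
  unknown <- setdiff(unique(table$sample_name), known)
  if (length(unknown)) {
    warning("annotations for sample(s) not present in any run: ",
            paste(unknown, collapse = ", "))
  }
  merged <- rbind(exp$sample_annotations, table)
  # later rows override earlier ones for the same (sample, key)
  keep <- !duplicated(merged[c("sample_name", "key")], fromLast = TRUE)
  exp$sample_annotations <- merged[keep, , drop = FALSE]
  rownames(exp$sample_annotations) <- NULL
  exp
}

#' Look up a group label per sample for one annotation key
#'
#' @param exp A [qpcr_experiment()].
#' @param key Annotation key.
#' @return Named character vector, sample name -> group label.
#' @export
sample_groups <- function(exp, key) {
  stopifnot(inherits(exp, "qpcr_experiment"))
  ann <- exp$sample_annotations
  ann <- ann[ann$key == key, , drop = FALSE]
  stats::setNames(ann$value, ann$sample_name)
}
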