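#' Read an RDES-style plate table
#'
#' The RDES-style layout expected here has one row per well. Leading
#' columns carry annotations: `well`, `sample`, `sample_type`, `target`,
#' `dye`, and optionally `std_conc`, `excluded`, `exclusion_note`. Every
#' column whose name is an integer is a cycle and holds the raw
#' fluorescence reading of that cycle. The delimiter is auto-detected
#' among comma, semicolon and tab. Assay metadata (reaction volume,
#' strandedness, dye/target configuration) travels in a JSON sidecar, see
#' [write_rdes_table()].
#'
#' Reactions sharing sample name and target name are technical replicates;
#' all names are case sensitive.
#'
#' @param path Path to the delimited table.
#' @param meta Path to the JSON metadata sidecar (default: `path` +
#'   `".json"`).
#' @return A [qpcr_run()].
#' @export
read_rdes_table <- function(path, meta = paste0(path, ".json")) {
  if (!file.exists(path)) stop("RDES table not found: ", path)
  if (!file.exists(meta)) stop("run metadata sidecar not found: ", meta)
  sep <- detect_delimiter(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  mandatory <- c("well", "sample", "sample_type", "target", "dye")
  miss <- setdiff(mandatory, names(tab))
  if (length(miss)) {
    stop("RDES table lacks mandatory column(s): ", paste(miss, collapse = ", "))
  }
  cyc_cols <- names(tab)[grepl("^[0-9]+$", names(tab))]
  if (length(cyc_cols) < 10) {
    stop("RDES table needs >= 10 integer-named cycle columns, found ",
         length(cyc_cols))
  }
  cyc_cols <- cyc_cols[order(as.integer(cyc_cols))]
  if (!identical(as.integer(cyc_cols), seq_along(cyc_cols))) {
    stop("cycle columns must be consecutive integers starting at 1")
  }
  fl <- matrix(NA_real_, nrow(tab), length(cyc_cols))
  for (j in seq_along(cyc_cols)) {
    v <- suppressWarnings(as.numeric(tab[[cyc_cols[j]]]))
    bad <- which(is.na(v) & !(tab[[cyc_cols[j]]] %in% c("NA", "")))
    if (length(bad)) {
      stop(sprintf("non-numeric fluorescence in well '%s', cycle %s: '%s'",
                   tab$well[bad[1]], cyc_cols[j], tab[[cyc_cols[j]]][bad[1]]))
    }
    fl[, j] <- v
  }
  md <- jsonlite::read_json(meta, simplifyVector = FALSE)
  dyes <- lapply(md$dyes, function(d) {
    dye_config(d$name, d$chemistry,
               dye_conc = null_default(d$dye_conc, 400),
               C_d = null_default(d$C_d, 1.5),
               C_p = null_default(d$C_p, NULL))
  })
  targets <- lapply(md$targets, function(t) {
    target_config(t$name, t$role, primer_conc = t$primer_conc,
                  amplicon_length = t$amplicon_length, dye = t$dye,
                  expected_tm = null_default(t$expected_tm, NA_real_))
  })
  wells <- data.frame(
    well_id = tab$well,
    sample_name = tab$sample,
    sample_type = tab$sample_type,
    target = tab$target,
    std_conc = if (!is.null(tab$std_conc)) {
      suppressWarnings(as.numeric(tab$std_conc))
    } else NA_real_,
    excluded = if (!is.null(tab$excluded)) {
      tolower(tab$excluded) %in% c("true", "1", "yes")
    } else FALSE,
    exclusion_note = if (!is.null(tab$exclusion_note)) {
      tab$exclusion_note
    } else "",
    stringsAsFactors = FALSE
  )
  qpcr_run(run_id = md$run_id, fluorescence = fl, wells = wells,
           targets = targets, dyes = dyes,
           reaction_volume = md$reaction_volume,
           input_strandedness = null_default(md$input_strandedness, "single"))
}

null_default <- function(x, default) if (is.null(x)) default else x

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c(",", ";", "\t"), function(s) {
    lengths(regmatches(header, gregexpr(s, header, fixed = TRUE)))
  }, integer(1))
  c(",", ";", "\t")[which.max(counts)]
}

#' Write a run as an RDES-style table plus JSON metadata sidecar
#'
#' Inverse of [read_rdes_table()]: `read_rdes_table(write_rdes_table(run))`
#' reproduces the run on all retained fields.
#'
#' @param run A [qpcr_run()].
#' @param path Output path for the delimited table (written with commas).
#' @param meta Output path for the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_rdes_table <- function(run, path, meta = paste0(path, ".json")) {
  stopifnot(inherits(run, "qpcr_run"))
  w <- run$wells
  tab <- data.frame(well = w$well_id, sample = w$sample_name,
                    sample_type = w$sample_type, target = w$target,
                    dye = vapply(w$target, function(t) run$targets[[t]]$dye, ""),
                    std_conc = w$std_conc, excluded = w$excluded,
                    exclusion_note = w$exclusion_note,
                    stringsAsFactors = FALSE, check.names = FALSE)
  fl <- as.data.frame(run$fluorescence, check.names = FALSE)
  utils::write.table(cbind(tab, fl), path, sep = ",", row.names = FALSE,
                     quote = TRUE)
  md <- list(
    run_id = run$run_id,
    reaction_volume = run$reaction_volume,
    input_strandedness = run$input_strandedness,
    dyes = lapply(unname(run$dyes), function(d) d[!vapply(d, is.na.scalar, TRUE)]),
    targets = lapply(unname(run$targets), function(t) t[!vapply(t, is.na.scalar, TRUE)])
  )
  jsonlite::write_json(md, meta, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

is.na.scalar <- function(x) length(x) == 1 && is.na(x)

#' Write per-reaction quantification results as a delimited table
#'
#' One row per reaction with well, sample, target, TD0, individual and mean
#' PCR efficiency, Ncopy and flags. Numbers are written with 10 significant
#' digits so a read-back reproduces the values to formatting precision.
#'
#' @param results Data frame of per-reaction results (the `results` element
#'   of [quantify_run()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.10g", x))
  })
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = TRUE,
                     na = "")
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path Path to the table.
#' @return Data frame with numeric columns restored.
#' @export
read_results_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in names(tab)) {
    if (nm %in% c("well_id", "sample_name", "sample_type", "target",
                  "flags", "regime", "run_id", "group")) next
    v <- suppressWarnings(as.numeric(tab[[nm]]))
    if (!all(is.na(v) & nzchar(tab[[nm]]) & !is.na(tab[[nm]]))) {
      if (all(is.na(tab[[nm]]) | tab[[nm]] == "" |
              !is.na(suppressWarnings(as.numeric(tab[[nm]]))))) {
        tab[[nm]] <- v
      }
    }
  }
  tab
}
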