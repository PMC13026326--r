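#' geNorm reference-gene stability analysis
#'
#' Ranks candidate reference genes by expression stability and determines
#' how many of the most stable genes are needed for a reliable
#' normalization factor. The stability measure M of a gene is the mean,
#' over all other candidates, of the standard deviation across samples of
#' the pairwise log2 expression ratio: a gene whose ratio to every other
#' gene is constant across samples has M = 0. The least stable gene
#' (highest M) is removed and M recomputed until two genes remain, which
#' yields the stability ranking. The pairwise variation
#' `V(n/n+1) = SD_samples(log2(NF_n / NF_{n+1}))`, with `NF_n` the
#' geometric mean of the n most stable genes, decides the set size: the
#' smallest n (>= 2) with `V(n/n+1)` below the cutoff is recommended.
#' Taking simply the two top-ranked genes without the V criterion can
#' under-power the normalization.
#'
#' @param mat Numeric matrix of Ncopy values, genes in rows, samples in
#'   columns; all values must be positive, >= 3 genes, and >= 8 samples are
#'   advised (fewer warns).
#' @param cutoff Pairwise-variation cutoff (default 0.15).
#' @return A list of class `genorm_result`: `m_values` (M of all genes at
#'   the first iteration), `ranking` (most stable first), `v_ratios`
#'   (named vector, `"2/3"` etc.), `recommended_set`, `cutoff_met`.
#' @examples
#' m <- rbind(g1 = c(100, 200, 50, 80), g2 = c(210, 400, 95, 165),
#'            g3 = c(55, 110, 30, 41))
#' genorm(m)$ranking
#' @export
genorm <- function(mat, cutoff = qpcr_constants()$genorm_cutoff) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("gene", seq_len(nrow(mat)))
  if (nrow(mat) < 3) stop("geNorm needs >= 3 candidate reference genes")
  if (any(!is.finite(mat)) || any(mat <= 0)) {
    stop("geNorm needs positive, finite expression values throughout")
  }
  if (ncol(mat) < 8) {
    warning("fewer than 8 samples; geNorm stability estimates will be weak")
  }
  lmat <- log2(mat)
  m_of <- function(l) {
    vapply(seq_len(nrow(l)), function(j) {
      others <- setdiff(seq_len(nrow(l)), j)
      mean(vapply(others, function(k2) stats::sd(l[j, ] - l[k2, ]), 0))
    }, 0)
  }
  m_first <- stats::setNames(m_of(lmat), rownames(lmat))
  cur <- lmat
  dropped <- character()
  while (nrow(cur) > 2) {
    m <- m_of(cur)
    worst <- which.max(m)
    dropped <- c(rownames(cur)[worst], dropped)
    cur <- cur[-worst, , drop = FALSE]
  }
  last_m <- m_of(cur)
  ranking <- c(rownames(cur)[order(last_m)], dropped)
  # pairwise variation V(n/n+1) along the ranking
  g <- length(ranking)
  nf <- function(n) colMeans(lmat[ranking[seq_len(n)], , drop = FALSE])
  v <- vapply(2:(g - 1), function(n) stats::sd(nf(n) - nf(n + 1)), 0)
  names(v) <- paste(2:(g - 1), 3:g, sep = "/")
  below <- which(v < cutoff)
  if (length(below)) {
    n_rec <- (2:(g - 1))[below[1]]
    cutoff_met <- TRUE
  } else {
    n_rec <- g
    cutoff_met <- FALSE
    warning("no reference set reaches V < ", cutoff,
            "; consider other candidate genes")
  }
  structure(list(m_values = m_first, ranking = ranking, v_ratios = v,
                 recommended_set = ranking[seq_len(max(2, n_rec))],
                 cutoff_met = cutoff_met, cutoff = cutoff),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm ranking (most stable first):",
      paste(x$ranking, collapse = ", "), "\n")
  cat("V(n/n+1):", paste(sprintf("%s=%.3f", names(x$v_ratios), x$v_ratios),
                         collapse = "  "), "\n")
  cat("recommended set:", paste(x$recommended_set, collapse = ", "),
      if (!x$cutoff_met) "(cutoff not met)" else "", "\n")
  invisible(x)
}

#' Normalize targets of interest to a reference-gene set
#'
#' Divides each target-of-interest Ncopy by the geometric mean of the
#' reference-gene Ncopy of the same sample, then multiplies by the overall
#' geometric mean of all reference Ncopy values in the experiment, so the
#' normalized values stay on the absolute copy scale. Samples missing one
#' of the reference genes are flagged and left unnormalized.
#'
#' @param results Data frame with `sample_name`, `target`, `ncopy`.
#' @param ref_set Character vector of reference-gene (target) names.
#' @return List with `results` (column `ncopy_norm` added; reference rows
#'   keep their scaled values too), `sample_factors` (per-sample reference
#'   geometric means), `grand_geomean`, and `skipped_samples`.
#' @export
normalize_to_references <- function(results, ref_set) {
  stopifnot(all(c("sample_name", "target", "ncopy") %in% names(results)),
            length(ref_set) >= 1)
  missing_ref <- setdiff(ref_set, unique(results$target))
  if (length(missing_ref)) {
    stop("reference gene(s) absent from results: ",
         paste(missing_ref, collapse = ", "))
  }
  refs <- results[results$target %in% ref_set & is.finite(results$ncopy) &
                    results$ncopy > 0, , drop = FALSE]
  grand <- exp(mean(log(refs$ncopy)))
  samples <- unique(results$sample_name)
  sf <- stats::setNames(rep(NA_real_, length(samples)), samples)
  for (s in samples) {
    rs <- refs[refs$sample_name == s, , drop = FALSE]
    if (!all(ref_set %in% unique(rs$target))) next
    # per-sample reference level: geometric mean over per-gene means
    gene_means <- vapply(split(log(rs$ncopy), rs$target), mean, 0)
    sf[s] <- exp(mean(gene_means))
  }
  skipped <- names(sf)[!is.finite(sf)]
  if (length(skipped)) {
    warning("sample(s) missing reference measurements, not normalized: ",
            paste(skipped, collapse = ", "))
  }
  out <- results
  out$ncopy_norm <- out$ncopy / sf[out$sample_name] * grand
  list(results = out, sample_factors = sf, grand_geomean = grand,
       skipped_samples = skipped)
}

#' Between-group comparison of normalized Ncopy values
#'
#' One-way comparison of expression between annotated groups: Welch t-test
#' or Mann-Whitney for two groups, one-way ANOVA or Kruskal-Wallis for
#' more. When the omnibus test of three or more groups rejects at `alpha`,
#' pairwise post-hoc comparisons are run inside the omnibus framework
#' (Tukey HSD after ANOVA, Dunn's test with Holm adjustment after
#' Kruskal-Wallis) rather than as independent two-sample tests, avoiding
#' type-I error accumulation. Groups with fewer than two values are
#' excluded with a warning.
#'
#' @param values Numeric vector of (normalized) Ncopy values.
#' @param groups Group label per value.
#' @param test `"t"`/`"anova"` for the parametric family,
#'   `"mannwhitney"`/`"kruskal"` for the non-parametric one (the two-group
#'   and k-group names are interchangeable; the group count picks the
#'   actual procedure).
#' @param alpha Significance level gating the post-hoc step.
#' @return A list of class `group_comparison`: `test`, `statistic`,
#'   `p_value`, `groups`, `posthoc` (data frame or `NULL`).
#' @export
group_tests <- function(values, groups,
                        test = c("t", "anova", "mannwhitney", "kruskal"),
                        alpha = 0.05) {
  test <- match.arg(test)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  cnt <- table(groups)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    warning("group(s) with < 2 values excluded: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  gl <- sort(unique(groups))
  if (length(gl) < 2) stop("need >= 2 groups with >= 2 values each")
  parametric <- test %in% c("t", "anova")
  posthoc <- NULL
  if (length(gl) == 2) {
    a <- values[groups == gl[1]]; b <- values[groups == gl[2]]
    ht <- if (parametric) stats::t.test(a, b) else stats::wilcox.test(a, b)
    used <- if (parametric) "welch_t" else "mannwhitney"
  } else if (parametric) {
    fit <- stats::aov(values ~ factor(groups))
    sm <- summary(fit)[[1]]
    ht <- list(statistic = c(F = sm[1, "F value"]),
               p.value = sm[1, "Pr(>F)"])
    used <- "anova"
    if (ht$p.value < alpha) {
      tk <- stats::TukeyHSD(fit)[[1]]
      posthoc <- data.frame(comparison = rownames(tk),
                            diff = tk[, "diff"], p_adj = tk[, "p adj"],
                            stringsAsFactors = FALSE, row.names = NULL)
    }
  } else {
    ht <- stats::kruskal.test(values, factor(groups))
    used <- "kruskal"
    if (ht$p.value < alpha) posthoc <- dunn_posthoc(values, groups)
  }
  structure(list(test = used, statistic = unname(ht$statistic),
                 p_value = ht$p.value, groups = gl, alpha = alpha,
                 posthoc = posthoc),
            class = "group_comparison")
}

# Dunn's rank-based pairwise comparisons after Kruskal-Wallis, with
# tie-corrected variance and Holm family-wise adjustment.
dunn_posthoc <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  gl <- sort(unique(groups))
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  comb <- utils::combn(gl, 2)
  z <- apply(comb, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[p[1]] + 1 / n[p[2]]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(comparison = paste(comb[1, ], comb[2, ], sep = "-"),
             z = as.numeric(z), p_adj = stats::p.adjust(p_raw, "holm"),
             stringsAsFactors = FALSE)
}

#' Box-and-whisker plot of normalized Ncopy per group
#'
#' Minimal static plot: boxes per group with the individual values
#' overlaid as dots.
#'
#' @param values Numeric vector of (normalized) Ncopy values.
#' @param groups Group label per value.
#' @param ylab Axis label.
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, the boxplot statistics.
#' @export
plot_group_ncopy <- function(values, groups, ylab = "normalized Ncopy", ...) {
  g <- factor(groups)
  bp <- graphics::boxplot(values ~ g, ylab = ylab, outline = FALSE, ...)
  graphics::points(jitter(as.integer(g), amount = 0.1), values, pch = 19,
                   col = grDevices::adjustcolor("steelblue", 0.7))
  invisible(bp)
}
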