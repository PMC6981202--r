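#' Benjamini-Hochberg adjustment with missing-value passthrough
#'
#' Step-up FDR adjustment applied to the non-missing entries only; missing
#' entries are returned as missing and do not count toward the number of
#' tests.  Input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA` allowed.
#' @return Vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- p
  idx <- !is.na(p)
  out[idx] <- p.adjust(p[idx], method = "BH")
  out
}

## Shared tail computations for both designs.  Degenerate zero sample
## variance is floored (flagged) so constant fixtures yield finite
## statistics while the effect size survives into pooling.
finalize_effects <- function(gene, study_id, logfc, var, n, df,
                             var_floor) {
  degenerate <- !is.na(var) & var < var_floor
  var[degenerate] <- var_floor
  df[!is.na(df) & df < 1] <- NA_real_
  t <- logfc / sqrt(var)
  p <- 2 * pt(-abs(t), df)
  ci_half <- qt(0.975, df) * sqrt(var)
  ok <- !is.na(p)
  data.frame(
    gene = gene, study_id = study_id,
    logfc = logfc, var = var, n = n, t = t, df = df, p = p,
    fdr = bh_adjust(p),
    ci_low = logfc - ci_half, ci_high = logfc + ci_half,
    degenerate = degenerate,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Paired within-study differential expression
#'
#' For each gene, the per-subject post-minus-pre difference `d` gives the
#' log2 fold-change `mean(d)` with sampling variance `sd(d)^2 / n`, a
#' paired t statistic on `n - 1` degrees of freedom, two-sided p-value,
#' 95% confidence interval, and BH-adjusted FDR across the study's genes.
#' Genes with fewer than two complete pairs are emitted with missing
#' statistics (one aggregate warning).
#'
#' @param study An [expression_study()] with `design = "PAIRED"`.
#' @param var_floor Floor applied to zero sample variances before the t and
#'   CI computation; such records are flagged in column `degenerate`.
#' @param moderate If `TRUE`, apply empirical-Bayes moderation of the gene
#'   variances (method-of-moments shrinkage on log variances toward their
#'   grand mean) before computing t, p and CI.  Default `FALSE`: plain
#'   per-gene statistics are the reference path.
#' @return `data.frame` of per-gene effects (columns `gene`, `study_id`,
#'   `logfc`, `var`, `n`, `t`, `df`, `p`, `fdr`, `ci_low`, `ci_high`,
#'   `degenerate`).
#' @export
paired_de <- function(study, var_floor = 1e-8, moderate = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  if (study$design != "PAIRED") stop("paired_de requires a PAIRED design")
  sm <- study$samples
  subjects <- unique(sm$subject_id)
  pre_idx <- match(paste0(subjects, ".PRE"),
                   paste0(sm$subject_id, ".", sm$condition))
  post_idx <- match(paste0(subjects, ".POST"),
                    paste0(sm$subject_id, ".", sm$condition))
  d <- study$values[, post_idx, drop = FALSE] -
    study$values[, pre_idx, drop = FALSE]

  n <- rowSums(!is.na(d))
  logfc <- rowMeans(d, na.rm = TRUE)
  ss <- rowSums((d - logfc)^2, na.rm = TRUE)
  s2 <- ss / (n - 1)
  if (moderate) s2 <- moderate_variances(s2, n - 1)
  v <- s2 / n

  few <- n < 2
  if (any(few)) {
    warning(sum(few), " gene(s) with fewer than 2 complete pairs; ",
            "statistics set to NA")
    logfc[few] <- NA_real_
    v[few] <- NA_real_
  }
  finalize_effects(rownames(study$values), study$study_id,
                   logfc, v, n, n - 1, var_floor)
}

#' Unpaired (Welch) within-study differential expression
#'
#' Welch two-sample statistics per gene: `logfc = mean(POST) - mean(PRE)`,
#' sampling variance `s2_post/n_post + s2_pre/n_pre`, Welch-Satterthwaite
#' degrees of freedom, two-sided p, 95% CI and BH FDR as in [paired_de()].
#'
#' @inheritParams paired_de
#' @export
unpaired_de <- function(study, var_floor = 1e-8, moderate = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  if (study$design != "UNPAIRED") stop("unpaired_de requires UNPAIRED design")
  pre <- study$values[, study$samples$condition == "PRE", drop = FALSE]
  post <- study$values[, study$samples$condition == "POST", drop = FALSE]

  n1 <- rowSums(!is.na(pre)); n2 <- rowSums(!is.na(post))
  m1 <- rowMeans(pre, na.rm = TRUE); m2 <- rowMeans(post, na.rm = TRUE)
  s1 <- rowSums((pre - m1)^2, na.rm = TRUE) / (n1 - 1)
  s2 <- rowSums((post - m2)^2, na.rm = TRUE) / (n2 - 1)
  if (moderate) {
    s1 <- moderate_variances(s1, n1 - 1)
    s2 <- moderate_variances(s2, n2 - 1)
  }
  logfc <- m2 - m1
  a1 <- s1 / n1; a2 <- s2 / n2
  v <- a1 + a2
  df <- (a1 + a2)^2 / (a1^2 / (n1 - 1) + a2^2 / (n2 - 1))
  df[!is.finite(df)] <- NA_real_
  zero_var <- !is.na(v) & v <= 0
  df[zero_var] <- pmin(n1, n2)[zero_var] - 1  # Welch df undefined at s = 0

  few <- n1 < 2 | n2 < 2
  if (any(few)) {
    warning(sum(few), " gene(s) with a condition below 2 samples; ",
            "statistics set to NA")
    logfc[few] <- NA_real_
    v[few] <- NA_real_
  }
  out <- finalize_effects(rownames(study$values), study$study_id,
                          logfc, v, pmin(n1, n2), df, var_floor)
  out$n_pre <- n1
  out$n_post <- n2
  out
}

## Method-of-moments empirical-Bayes shrinkage of log sample variances
## toward their grand mean.  The sampling variance of log(s2) on df degrees
## of freedom is trigamma(df/2); the between-gene component is the excess
## of the observed spread over that.
moderate_variances <- function(s2, df) {
  usable <- is.finite(s2) & s2 > 0 & df >= 1
  if (sum(usable) < 2) return(s2)
  z <- log(s2[usable])
  samp <- trigamma(df[usable] / 2)
  between <- max(0, var(z) - mean(samp))
  w <- samp / (samp + between)
  z_shr <- w * mean(z) + (1 - w) * z
  s2[usable] <- exp(z_shr)
  s2
}

#' Bundle per-study effects with their annotations
#'
#' @param records `data.frame` of per-gene effects as produced by
#'   [paired_de()]/[unpaired_de()] (possibly row-bound across studies).
#' @param studies Annotation `data.frame` (see [study_annotation()]).
#' @return An object of class `effect_table`.
#' @export
effect_table <- function(records, studies) {
  validate_annotations(studies)
  stopifnot(is.data.frame(records),
            all(c("gene", "study_id", "logfc", "var") %in% names(records)))
  orphan <- setdiff(unique(records$study_id), studies$study_id)
  if (length(orphan))
    stop("records reference unannotated study_id(s): ",
         paste(orphan, collapse = ", "))
  if (anyDuplicated(records[c("gene", "study_id")]))
    stop("more than one record per (gene, study)")
  structure(list(records = records, studies = studies),
            class = "effect_table")
}

#' @export
print.effect_table <- function(x, ...) {
  cat(sprintf("<effect_table> %d records, %d genes, %d studies\n",
              nrow(x$records), length(unique(x$records$gene)),
              nrow(x$studies)))
  invisible(x)
}

#' Write / read an effect table as TSV
#'
#' Tab-delimited serialization with `"NA"` for missing values; the study
#' annotations travel in a sibling file `<path>.studies.tsv`.
#'
#' @param x An [effect_table()].
#' @param path Output path for the records TSV.
#' @export
write_effect_table <- function(x, path) {
  stopifnot(inherits(x, "effect_table"))
  write.table(x$records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$studies, paste0(path, ".studies.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effect_table
#' @export
read_effect_table <- function(path) {
  records <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  studies <- read.delim(paste0(path, ".studies.tsv"),
                        stringsAsFactors = FALSE, na.strings = "NA")
  effect_table(records, studies)
}
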