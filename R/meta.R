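#' DerSimonian-Laird between-study variance
#'
#' Non-iterative moment estimator of the between-study variance tau^2, used
#' as the fallback when the REML optimizer fails.  With fixed-effect
#' weights `w = 1/v`, `mu_F = sum(w y)/sum(w)`,
#' `Q = sum(w (y - mu_F)^2)` and `C = sum(w) - sum(w^2)/sum(w)`, the
#' estimate is `max(0, (Q - (k - 1))/C)`.
#'
#' @param y Study effects (log2 fold-changes).
#' @param v Their sampling variances (all > 0).
#' @return Nonnegative tau^2 estimate.
#' @export
dl_tau2 <- function(y, v) {
  check_meta_input(y, v)
  w <- 1 / v
  mu_f <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu_f)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (length(y) - 1)) / cc)
}

#' Cochran heterogeneity statistics
#'
#' `Q` is the fixed-effect weighted sum of squared deviations;
#' `I2 = max(0, (Q - (k - 1))/Q) * 100` expresses the percentage of total
#' variability attributable to between-study heterogeneity (0 when
#' `Q = 0`).
#'
#' @inheritParams dl_tau2
#' @return List with elements `Q` and `I2`.
#' @export
heterogeneity_stats <- function(y, v) {
  check_meta_input(y, v)
  w <- 1 / v
  mu_f <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu_f)^2)
  i2 <- if (q <= 0) 0 else max(0, (q - (length(y) - 1)) / q) * 100
  list(Q = q, I2 = i2)
}

check_meta_input <- function(y, v) {
  if (length(y) < 2) stop("at least 2 studies required")
  if (length(y) != length(v)) stop("y and v lengths differ")
  if (any(!is.finite(y)) || any(!is.finite(v))) stop("non-finite input")
  if (any(v <= 0)) stop("sampling variances must be > 0")
  invisible(TRUE)
}

## Restricted (profile) log-likelihood of tau2 for the random-effects
## model y_i ~ N(mu, v_i + tau2).
reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

#' REML random-effects fit for one gene
#'
#' Estimates the between-study variance tau^2 by bounded scalar
#' maximization of the restricted log-likelihood
#' `l_R(tau2) = -1/2 [ sum log(v_i + tau2) + log sum w_i +
#' sum w_i (y_i - mu(tau2))^2 ]` with `w_i = 1/(v_i + tau2)` and
#' `mu(tau2)` the inverse-variance weighted mean, over
#' `tau2 in [0, tau2_max]` (default `10 * var(y)`).  The boundary value 0
#' is compared explicitly so the zero-heterogeneity limit is exact.  If
#' the optimizer returns a non-finite value the DerSimonian-Laird
#' estimate is substituted and flagged.
#'
#' @inheritParams dl_tau2
#' @param tau2_max Upper search bound; default `10 * var(y)`.
#' @param tol Absolute convergence tolerance of the scalar optimizer.
#' @return List with `mu`, `se`, `tau2`, `loglik`, `estimator`
#'   (`"REML"` or `"DL"`) and `converged`.
#' @export
reml_fit <- function(y, v, tau2_max = NULL, tol = 1e-10) {
  check_meta_input(y, v)
  if (is.null(tau2_max)) tau2_max <- 10 * var(y)
  tau2 <- 0
  estimator <- "REML"
  converged <- TRUE
  if (tau2_max > 0) {
    opt <- tryCatch(
      optimize(reml_loglik, c(0, tau2_max), y = y, v = v,
               maximum = TRUE, tol = tol),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$objective)) {
      tau2 <- dl_tau2(y, v)
      estimator <- "DL"
      converged <- FALSE
    } else {
      cand <- c(0, opt$maximum, tau2_max)
      ll <- vapply(cand, reml_loglik, 0, y = y, v = v)
      tau2 <- cand[which.max(ll)]
    }
  }
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  list(mu = mu, se = sqrt(1 / sum(w)), tau2 = tau2,
       loglik = reml_loglik(tau2, y, v),
       estimator = estimator, converged = converged)
}

## One gene's pooled row (no FDR; that is protocol-wide).
meta_one <- function(y, v, knha = FALSE) {
  fit <- reml_fit(y, v)
  k <- length(y)
  se <- fit$se
  if (knha) {
    w <- 1 / (v + fit$tau2)
    se <- sqrt(sum(w * (y - fit$mu)^2) / ((k - 1) * sum(w)) / sum(w))
    crit <- qt(0.975, k - 1)
    z <- fit$mu / se
    p <- 2 * pt(-abs(z), k - 1)
  } else {
    crit <- qnorm(0.975)
    z <- fit$mu / se
    p <- 2 * pnorm(-abs(z))
  }
  het <- heterogeneity_stats(y, v)
  data.frame(
    k = k, mu = fit$mu, se_mu = se,
    ci_low = fit$mu - crit * se, ci_high = fit$mu + crit * se,
    z = z, p = p, fdr = NA_real_,
    tau2 = fit$tau2, Q = het$Q, I2 = het$I2,
    estimator = fit$estimator,
    status = if (fit$converged) "OK" else "NONCONVERGED_FALLBACK",
    stringsAsFactors = FALSE
  )
}

empty_meta_row <- function(status) {
  data.frame(
    k = NA_integer_, mu = NA_real_, se_mu = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, z = NA_real_, p = NA_real_,
    fdr = NA_real_, tau2 = NA_real_, Q = NA_real_, I2 = NA_real_,
    estimator = NA_character_, status = status, stringsAsFactors = FALSE
  )
}

#' Pool all genes of one protocol under the random-effects model
#'
#' For every gene with at least `min_k` contributing studies (non-missing
#' effect and variance) among the studies matching `protocol` and
#' `filters`, fits the REML random-effects model, forms the Wald statistic
#' `z = mu/se`, two-sided p-value and 95% CI, and adjusts p-values by
#' Benjamini-Hochberg across the protocol's successfully pooled genes.
#' Genes observed in fewer than `min_k` studies are reported with status
#' `TOO_FEW_STUDIES` and missing estimates, mirroring the convention of
#' refusing to report pooled scores from too few studies.
#'
#' @param effects An [effect_table()].
#' @param protocol Protocol to pool (one of the seven recognized labels).
#' @param filters Optional [subgroup_filter()] restricting the contributing
#'   studies.
#' @param min_k Minimum number of studies per gene (default 3).
#' @param knha Use the Knapp-Hartung small-sample adjustment (t reference
#'   distribution and robust SE) instead of Wald inference.  Default
#'   `FALSE`.
#' @param var_floor Floor for nonpositive reported sampling variances.
#' @return `data.frame` with one row per gene: `gene`, `protocol`, `k`,
#'   `mu`, `se_mu`, `ci_low`, `ci_high`, `z`, `p`, `fdr`, `tau2`, `Q`,
#'   `I2`, `estimator`, `status`.
#' @export
meta_all_genes <- function(effects, protocol, filters = NULL, min_k = 3,
                           knha = FALSE, var_floor = 1e-8) {
  stopifnot(inherits(effects, "effect_table"))
  protocol <- match.arg(protocol, PROTOCOLS)
  studies <- effects$studies[effects$studies$protocol == protocol, ,
                             drop = FALSE]
  if (!is.null(filters)) studies <- subset_studies(studies, filters)
  if (nrow(studies) == 0)
    stop("no studies match protocol ", protocol,
         if (!is.null(filters)) " under the supplied subgroup filter")

  rec <- effects$records[effects$records$study_id %in% studies$study_id, ,
                         drop = FALSE]
  rec <- rec[!is.na(rec$logfc) & !is.na(rec$var), , drop = FALSE]
  if (any(rec$var <= 0, na.rm = TRUE))
    rec$var[rec$var <= 0] <- var_floor

  genes <- sort(unique(effects$records$gene))
  by_gene <- split(rec[c("logfc", "var")], factor(rec$gene, levels = genes))
  rows <- lapply(genes, function(g) {
    d <- by_gene[[g]]
    if (is.null(d) || nrow(d) < min_k) return(empty_meta_row("TOO_FEW_STUDIES"))
    meta_one(d$logfc, d$var, knha = knha)
  })
  out <- do.call(rbind, rows)
  out <- cbind(gene = genes, protocol = protocol, out,
               stringsAsFactors = FALSE)
  ok <- out$status != "TOO_FEW_STUDIES"
  out$fdr[ok] <- bh_adjust(out$p[ok])
  rownames(out) <- NULL
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Forest data for one gene
#'
#' One row per contributing study (effect, CI, FDR and annotation fields;
#' studies in which the gene was not measured are flagged missing) plus the
#' pooled meta-analysis row for the identical filter set.  The meta row is
#' taken from [meta_all_genes()] so that its FDR is the protocol-wide
#' adjusted value.
#'
#' @inheritParams meta_all_genes
#' @param gene Gene identifier.
#' @return List with `gene`, `protocol`, `study_rows` (`data.frame`),
#'   `meta` (one-row `data.frame`) and `filters`.
#' @export
forest_data <- function(gene, protocol, effects, filters = NULL, min_k = 3,
                        knha = FALSE) {
  stopifnot(inherits(effects, "effect_table"))
  if (!gene %in% effects$records$gene) stop("unknown gene: ", gene)
  protocol <- match.arg(protocol, PROTOCOLS)
  studies <- effects$studies[effects$studies$protocol == protocol, ,
                             drop = FALSE]
  if (!is.null(filters)) studies <- subset_studies(studies, filters)
  if (nrow(studies) == 0)
    stop("no studies match protocol ", protocol,
         " under the supplied subgroup filter")

  rec <- effects$records
  idx <- match(paste(gene, studies$study_id),
               paste(rec$gene, rec$study_id))
  study_rows <- data.frame(
    study_id = studies$study_id,
    logfc = rec$logfc[idx], ci_low = rec$ci_low[idx],
    ci_high = rec$ci_high[idx], fdr = rec$fdr[idx],
    n = rec$n[idx],
    missing = is.na(idx) | is.na(rec$logfc[idx]),
    health_status = studies$health_status,
    muscle = studies$muscle,
    biopsy_timing = studies$biopsy_timing,
    stringsAsFactors = FALSE
  )
  meta_tab <- meta_all_genes(effects, protocol, filters = filters,
                             min_k = min_k, knha = knha)
  list(gene = gene, protocol = protocol, study_rows = study_rows,
       meta = meta_tab[meta_tab$gene == gene, , drop = FALSE],
       filters = filters)
}

#' Convert a log2 effect to fold-change and percent change
#'
#' @param mu Pooled log2 fold-change(s).
#' @return `data.frame` with `fold = 2^mu` and
#'   `percent_change = (2^mu - 1) * 100`, the convention used when
#'   reporting, e.g., a 2.3-fold increase or a 25% decrease.
#' @export
logfc_to_fold <- function(mu) {
  stopifnot(all(is.finite(mu)))
  data.frame(fold = 2^mu, percent_change = (2^mu - 1) * 100)
}

#' Write a meta-analysis result table as TSV
#'
#' @param x A `meta_result` table from [meta_all_genes()].
#' @param path Output path.
#' @export
write_meta_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
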