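#' Assemble the genes x studies fold-change matrix
#'
#' Cell `(g, s)` holds the log2 fold-change of gene `g` in study `s`, or
#' `NA` when the gene was not measured on that study's platform.  Genes are
#' the union across studies, in sorted order.
#'
#' @param effects An [effect_table()].
#' @param studies Optional character vector of study ids (default: all
#'   annotated studies, in annotation order).
#' @return Numeric matrix with gene row names and study column names; the
#'   filter provenance is kept in attribute `provenance`.
#' @export
assemble_fc_matrix <- function(effects, studies = NULL) {
  stopifnot(inherits(effects, "effect_table"))
  if (is.null(studies)) studies <- effects$studies$study_id
  if (length(studies) < 2) stop("at least 2 studies required")
  rec <- effects$records[effects$records$study_id %in% studies, ,
                         drop = FALSE]
  if (nrow(rec) == 0) stop("no effect records for the requested studies")
  genes <- sort(unique(rec$gene))
  m <- matrix(NA_real_, length(genes), length(studies),
              dimnames = list(genes, studies))
  m[cbind(match(rec$gene, genes), match(rec$study_id, studies))] <- rec$logfc
  attr(m, "provenance") <- list(studies = studies)
  m
}

#' Missingness filter and nearest-neighbour fold-change imputation
#'
#' Genes missing in more than `max_missing_fraction` of the studies are
#' excluded; each remaining missing cell `(g, s)` is replaced by the mean
#' of column `s` over the `k_neighbors` complete-profile genes nearest to
#' `g` in Euclidean distance computed over the columns observed in `g`
#' (so imputation never feeds on imputed values).  Observed cells are
#' never modified.
#'
#' @param m Fold-change matrix from [assemble_fc_matrix()].
#' @param max_missing_fraction Exclusion threshold on the per-gene missing
#'   fraction (default 0.10: genes with more than 10% missing values are
#'   excluded).
#' @param k_neighbors Number of neighbours to average (default 10, the
#'   conventional default for nearest-neighbour-averaging expression
#'   imputation); if fewer complete genes exist, all are used.
#' @return Complete matrix; provenance records the settings.
#' @export
filter_and_impute <- function(m, max_missing_fraction = 0.10,
                              k_neighbors = 10) {
  stopifnot(is.matrix(m), max_missing_fraction >= 0,
            max_missing_fraction <= 1, k_neighbors >= 1)
  frac <- rowMeans(is.na(m))
  keep <- frac <= max_missing_fraction
  out <- m[keep, , drop = FALSE]
  todo <- which(rowSums(is.na(out)) > 0)
  if (length(todo)) {
    complete <- which(rowSums(is.na(out)) == 0)
    if (length(complete) == 0)
      stop("no complete-profile genes available as imputation neighbours")
    cm <- out[complete, , drop = FALSE]
    k <- min(k_neighbors, nrow(cm))
    for (g in todo) {
      obs <- which(!is.na(out[g, ]))
      d <- sqrt(rowSums((cm[, obs, drop = FALSE] -
                           rep(out[g, obs], each = nrow(cm)))^2))
      nn <- order(d)[seq_len(k)]
      mis <- which(is.na(out[g, ]))
      out[g, mis] <- colMeans(cm[nn, mis, drop = FALSE])
    }
  }
  attr(out, "provenance") <- c(
    attr(m, "provenance"),
    list(max_missing_fraction = max_missing_fraction,
         k_neighbors = k_neighbors,
         genes_dropped = sum(!keep),
         cells_imputed = sum(is.na(m[keep, , drop = FALSE])))
  )
  out
}

#' Study-by-study Pearson correlation of fold-changes
#'
#' @param m Complete fold-change matrix (genes x studies, >= 3 genes).
#' @return Symmetric studies x studies matrix of Pearson r with unit
#'   diagonal; correlations involving a zero-variance study are set
#'   missing with a warning.
#' @export
correlation_matrix <- function(m) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("matrix must be complete; run filter_and_impute first")
  if (nrow(m) < 3) stop("at least 3 genes required")
  sds <- apply(m, 2L, sd)
  r <- suppressWarnings(cor(m))
  if (any(sds == 0)) {
    warning("zero-variance study column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; correlations set to NA")
    r[sds == 0, ] <- NA_real_
    r[, sds == 0] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Principal component analysis of studies in fold-change space
#'
#' Studies are the observations and genes the variables; each gene is
#' centered across studies and left unscaled (fold-changes already share a
#' log2 scale).  Component signs are fixed by making the largest-magnitude
#' gene loading positive.
#'
#' @param m Complete fold-change matrix (genes x studies).
#' @return List with `scores` (studies x components),
#'   `variance_explained` (percent, sums to 100) and `loadings`.
#' @export
pca_studies <- function(m) {
  stopifnot(is.matrix(m))
  if (ncol(m) < 2) stop("at least 2 studies required")
  if (anyNA(m)) stop("matrix must be complete; run filter_and_impute first")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, variance_explained = ve, loadings = pc$rotation)
}

#' Write a fold-change (or correlation) matrix as TSV
#'
#' Gene/study rows, study columns, `"NA"` for missing.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param row_label Name for the row-identifier column.
#' @export
write_matrix_tsv <- function(m, path, row_label = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- row_label
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, row_label = "gene") {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = "NA")
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}
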