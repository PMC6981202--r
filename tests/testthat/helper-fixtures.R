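# In-code fixtures shared across test files.

# Paired study from a list of per-gene (pre, post) value pairs.
make_paired_study <- function(pre, post, study_id = "S",
                              genes = NULL) {
  pre <- as.matrix(pre)
  post <- as.matrix(post)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(pre)))
  subj <- sprintf("P%d", seq_len(ncol(pre)))
  vals <- cbind(pre, post)
  dimnames(vals) <- list(genes,
                         c(paste0(subj, ":PRE"), paste0(subj, ":POST")))
  expression_study(
    study_id, vals,
    data.frame(subject_id = rep(subj, 2),
               condition = rep(c("PRE", "POST"), each = ncol(pre)),
               stringsAsFactors = FALSE),
    "PAIRED"
  )
}

make_unpaired_study <- function(pre, post, study_id = "S", genes = NULL) {
  pre <- as.matrix(pre)
  post <- as.matrix(post)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(pre)))
  vals <- cbind(pre, post)
  n1 <- ncol(pre); n2 <- ncol(post)
  dimnames(vals) <- list(genes, sprintf("X%d:%s", seq_len(n1 + n2),
                                        rep(c("PRE", "POST"), c(n1, n2))))
  expression_study(
    study_id, vals,
    data.frame(subject_id = sprintf("X%d", seq_len(n1 + n2)),
               condition = rep(c("PRE", "POST"), c(n1, n2)),
               stringsAsFactors = FALSE),
    "UNPAIRED"
  )
}

# Effect table from an explicit genes x studies logfc matrix and a shared
# variance (NA cells are simply absent records).
make_effect_table <- function(logfc, var = 0.05, protocol = "ACUTE_AEROBIC",
                              health_status = NULL) {
  studies <- colnames(logfc)
  if (is.null(studies)) {
    studies <- sprintf("ST%d", seq_len(ncol(logfc)))
    colnames(logfc) <- studies
  }
  if (is.null(rownames(logfc)))
    rownames(logfc) <- sprintf("g%d", seq_len(nrow(logfc)))
  if (length(protocol) == 1) protocol <- rep(protocol, length(studies))
  if (is.null(health_status)) health_status <- rep("HLY", length(studies))
  recs <- do.call(rbind, lapply(seq_along(studies), function(j) {
    keep <- !is.na(logfc[, j])
    if (!any(keep)) return(NULL)
    y <- logfc[keep, j]
    data.frame(gene = rownames(logfc)[keep], study_id = studies[j],
               logfc = y, var = var, n = 8L, t = y / sqrt(var), df = 7L,
               p = 0.5, fdr = 0.5, ci_low = y - 1, ci_high = y + 1,
               degenerate = FALSE, stringsAsFactors = FALSE)
  }))
  ann <- do.call(rbind, lapply(seq_along(studies), function(j)
    study_annotation(studies[j], protocol[j],
                     health_status = health_status[j], n_subjects = 8L)))
  effect_table(recs, ann)
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
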