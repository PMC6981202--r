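#' Construct an expression study container
#'
#' A light container for one study's gene-by-sample log2 expression matrix
#' together with the subject/condition layout.  Paired designs require every
#' subject to appear exactly once under `PRE` and once under `POST`.
#'
#' @param study_id Study identifier.
#' @param values Numeric matrix, genes in rows, samples in columns.  Row
#'   names are gene (or probe) identifiers; missing values are allowed.
#' @param samples `data.frame` with columns `subject_id` and `condition`
#'   (`"PRE"`/`"POST"`), one row per column of `values`.
#' @param design `"PAIRED"` or `"UNPAIRED"`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(study_id, values, samples,
                             design = c("PAIRED", "UNPAIRED")) {
  design <- match.arg(design)
  values <- as.matrix(values)
  stopifnot(
    is.character(study_id), length(study_id) == 1L,
    is.data.frame(samples),
    all(c("subject_id", "condition") %in% names(samples)),
    nrow(samples) == ncol(values),
    !is.null(rownames(values))
  )
  if (!all(samples$condition %in% CONDITIONS))
    stop("sample conditions must be PRE or POST")
  if (design == "PAIRED") {
    tab <- table(samples$subject_id, samples$condition)
    if (!all(tab == 1L) || ncol(tab) != 2L)
      stop("PAIRED design requires each subject exactly once per condition; ",
           "offending subject(s): ",
           paste(rownames(tab)[rowSums(tab == 1L) != 2L], collapse = ", "))
  }
  structure(
    list(study_id = study_id, genes = rownames(values),
         samples = samples, values = values, design = design),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s: %d genes x %d samples (%s)\n",
              x$study_id, nrow(x$values), ncol(x$values), x$design))
  invisible(x)
}

#' Read a gene-by-sample expression table
#'
#' Parses a UTF-8 tab-delimited table whose first column holds gene (or
#' probe) identifiers and whose remaining column headers encode the sample
#' layout as `subject<sep>condition` (e.g. `"S1:PRE"`).  `"NA"` marks
#' missing values.  Duplicate gene rows are preserved so that probe-level
#' tables can be collapsed later with [collapse_to_genes()].
#'
#' @param path Path to the TSV file.
#' @param layout List describing the layout: `design` (`"PAIRED"` or
#'   `"UNPAIRED"`), `sep` (separator inside sample labels, default `":"`),
#'   and optionally `study_id` (defaults to the file name without extension).
#' @return An [expression_study()].
#' @export
read_expression_table <- function(path, layout = list(design = "PAIRED")) {
  sep <- if (is.null(layout$sep)) ":" else layout$sep
  design <- match.arg(layout$design, c("PAIRED", "UNPAIRED"))
  study_id <- if (is.null(layout$study_id))
    tools::file_path_sans_ext(basename(path)) else layout$study_id

  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged table: line %d has %d fields, expected %d",
                 which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))

  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA", colClasses = "character")
  if (ncol(raw) < 2L) stop("malformed header: need gene column plus samples")
  labels <- names(raw)[-1]
  parts <- strsplit(labels, sep, fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed header: sample label(s) not of the form subject", sep,
         "condition: ", paste(labels[lengths(parts) != 2L], collapse = ", "))
  samples <- data.frame(
    subject_id = vapply(parts, `[[`, "", 1L),
    condition = vapply(parts, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )

  num <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(raw[[1]], labels))
  bad <- which(is.na(num) & !is.na(as.matrix(raw[-1])), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at line %d (gene %s, sample %s)",
                 bad[1, 1] + 1L, raw[[1]][bad[1, 1]], labels[bad[1, 2]]))

  expression_study(study_id, num, samples, design)
}

#' Quantile-normalize an expression study
#'
#' Forces every sample column onto a common distribution: after
#' normalization the sorted values of each column equal the row-wise means
#' of the column-sorted matrix.  Tied values within a column receive the
#' mean of the reference values at their tied ranks.  Computation is
#' delegated to [limma::normalizeQuantiles()] with `ties = TRUE`, which
#' implements exactly this rule.
#'
#' @param study An [expression_study()] with no missing values.
#' @return The study with normalized `values`.
#' @export
quantile_normalize <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (anyNA(study$values))
    stop("matrix contains missing values; impute or remove them before ",
         "quantile normalization")
  norm <- limma::normalizeQuantiles(study$values, ties = TRUE)
  dimnames(norm) <- dimnames(study$values)
  study$values <- norm
  study
}

#' Median-of-ratios log normalization for count data
#'
#' Converts a nonnegative count matrix to a per-sample log2 abundance
#' matrix.  The size factor of sample `j` is the median, over genes with a
#' positive geometric mean across samples, of `count[g, j] / geomean(g)`;
#' the output is `log2(count/s + pseudocount)`.
#'
#' @param counts Nonnegative count matrix, genes x samples, with row names.
#' @param pseudocount Positive value added inside the log (default 0.5).
#' @param study_id,samples,design Passed to [expression_study()]; `samples`
#'   defaults to parsing the column names as `subject:condition`.
#' @return An [expression_study()]; size factors are attached as attribute
#'   `size_factors` of `values`.
#' @export
median_ratio_log_normalize <- function(counts, pseudocount = 0.5,
                                       study_id = "counts",
                                       samples = NULL,
                                       design = "PAIRED") {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0, na.rm = FALSE), pseudocount > 0)
  if (any(colSums(counts) == 0)) stop("all-zero sample column")
  loggeo <- rowMeans(log(counts))          # -Inf where any count is zero
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no gene has nonzero counts in every sample; cannot compute ",
         "median-of-ratios size factors")
  s <- apply(counts, 2L, function(cnt)
    exp(median(log(cnt[use]) - loggeo[use])))
  norm <- log2(sweep(counts, 2L, s, "/") + pseudocount)
  attr(norm, "size_factors") <- s
  if (is.null(samples)) {
    parts <- strsplit(colnames(counts), ":", fixed = TRUE)
    samples <- data.frame(
      subject_id = vapply(parts, `[[`, "", 1L),
      condition = vapply(parts, `[[`, "", 2L),
      stringsAsFactors = FALSE
    )
  }
  expression_study(study_id, norm, samples, design)
}

#' Collapse probe-level rows to one row per gene
#'
#' Probes mapping to the same gene are summarized by the per-sample median;
#' probes absent from the map are dropped (a message reports how many).
#'
#' @param study An [expression_study()] whose rows are probes.
#' @param probe_map `data.frame` with columns `probe` and `gene`.
#' @return An [expression_study()] with one row per gene.
#' @export
collapse_to_genes <- function(study, probe_map) {
  stopifnot(inherits(study, "expression_study"),
            all(c("probe", "gene") %in% names(probe_map)))
  idx <- match(rownames(study$values), probe_map$probe)
  dropped <- sum(is.na(idx))
  if (dropped == nrow(study$values))
    stop("no probe of the study appears in the probe map")
  if (dropped > 0)
    message(dropped, " probe(s) absent from the probe map were dropped")
  keep <- !is.na(idx)
  vals <- study$values[keep, , drop = FALSE]
  gene <- probe_map$gene[idx[keep]]
  groups <- split(seq_len(nrow(vals)), gene)
  collapsed <- t(vapply(
    groups,
    function(i) apply(vals[i, , drop = FALSE], 2L, median),
    numeric(ncol(vals))
  ))
  colnames(collapsed) <- colnames(vals)
  study$values <- collapsed
  study$genes <- rownames(collapsed)
  study
}

#' Read a GMT gene-set file
#'
#' Standard tab format: set name, description, then member genes.
#'
#' @param path Path to the GMT file.
#' @return List with elements `sets` (named list of character vectors) and
#'   `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("malformed GMT: every line needs name, description and >= 1 gene")
  nm <- vapply(fields, `[[`, "", 1L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (any(lengths(sets) == 0L)) stop("empty gene set in GMT")
  list(sets = setNames(sets, nm),
       descriptions = setNames(vapply(fields, `[[`, "", 2L), nm))
}

#' Read a complex-to-gene map
#'
#' Two-column TSV (`complex_id`, `gene_id`) listing, for every protein or
#' protein complex, the genes coding for it.
#'
#' @param path Path to the TSV file.
#' @return Named list of character vectors, one per complex.
#' @export
read_complex_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  if (!all(c("complex_id", "gene_id") %in% names(tab)))
    stop("complex map needs columns complex_id and gene_id")
  cmap <- lapply(split(tab$gene_id, tab$complex_id), unique)
  if (any(lengths(cmap) == 0L)) stop("complex with no genes")
  cmap
}
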