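#' Extract the significant gene set of a protocol
#'
#' Genes with a successfully pooled estimate (`status == "OK"`), FDR below
#' the threshold, and pooled effect sign matching `direction`.
#'
#' @param results A `meta_result` table from [meta_all_genes()] (one
#'   protocol).
#' @param fdr_threshold Significance threshold in `(0, 1]` (e.g. 0.01 for
#'   "FDR < 1%" sets, 0.001 for responsive-gene counts).
#' @param direction `"ANY"`, `"UP"` (`mu > 0`) or `"DOWN"` (`mu < 0`).
#' @return Sorted character vector of gene identifiers (possibly empty).
#' @export
significant_set <- function(results, fdr_threshold = 0.01,
                            direction = c("ANY", "UP", "DOWN")) {
  direction <- match.arg(direction)
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1)
  ok <- results$status == "OK" & !is.na(results$fdr) &
    results$fdr < fdr_threshold
  ok <- ok & switch(direction,
                    ANY = TRUE,
                    UP = results$mu > 0,
                    DOWN = results$mu < 0)
  sort(results$gene[ok & !is.na(ok)])
}

#' Venn region counts for 2-5 gene sets
#'
#' Counts every non-empty membership region (named by the member sets
#' joined with `"&"`); the region counts sum to the size of the union.
#'
#' @param sets Named list of 2 to 5 character vectors.
#' @return Named integer vector over all `2^m - 1` regions.
#' @export
venn_counts <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  m <- length(sets)
  if (m < 2) stop("at least 2 sets required")
  if (m > 5) stop("more than 5 sets not supported")
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, ncol = m)
  sig <- apply(membership, 1L, function(b)
    paste(names(sets)[b], collapse = "&"))
  counts <- integer(2^m - 1)
  labels <- character(2^m - 1)
  i <- 0L
  for (size in seq_len(m)) {
    for (combo in utils::combn(names(sets), size, simplify = FALSE)) {
      i <- i + 1L
      labels[i] <- paste(combo, collapse = "&")
      counts[i] <- sum(sig == labels[i])
    }
  }
  setNames(counts, labels)
}

#' Top up- and downregulated genes of a protocol
#'
#' The `n` largest and `n` smallest pooled log2 fold-changes among
#' successfully pooled genes.  Ties are broken by smaller FDR, then by
#' lexicographic gene identifier, so the ranking is fully deterministic.
#'
#' @param results A `meta_result` table.
#' @param n Number of genes per direction (default 5).
#' @return List with character vectors `up` and `down` (in rank order).
#' @export
top_n_genes <- function(results, n = 5) {
  ok <- results[results$status == "OK" & !is.na(results$mu), , drop = FALSE]
  if (nrow(ok) == 0) stop("no successfully pooled genes")
  up <- ok[order(-ok$mu, ok$fdr, ok$gene), , drop = FALSE]
  down <- ok[order(ok$mu, ok$fdr, ok$gene), , drop = FALSE]
  list(up = head(up$gene, n), down = head(down$gene, n))
}

#' Genes responsive in healthy but not metabolically impaired individuals
#'
#' Flags genes with FDR below `fdr_lo` in the healthy meta-analysis and
#' FDR above `fdr_hi` in the metabolically impaired one — the published
#' rule "FDR < 0.01 in healthy and FDR > 0.9 in metabolically impaired".
#'
#' @param healthy,impaired `meta_result`-style tables for the same
#'   protocol; only `gene` and `fdr` are required.
#' @param fdr_lo Healthy significance bound (default 0.01).
#' @param fdr_hi Impaired non-response bound (default 0.9).
#' @return Sorted character vector of flagged genes.
#' @export
healthy_specific <- function(healthy, impaired, fdr_lo = 0.01,
                             fdr_hi = 0.9) {
  merged <- merge(healthy[c("gene", "fdr")], impaired[c("gene", "fdr")],
                  by = "gene", suffixes = c("_hly", "_mti"))
  hit <- !is.na(merged$fdr_hly) & !is.na(merged$fdr_mti) &
    merged$fdr_hly < fdr_lo & merged$fdr_mti > fdr_hi
  sort(merged$gene[hit])
}

#' Concordant genes across up- and down-responding perturbations
#'
#' Intersection of all `up_sets` with all `down_sets`: genes, for example,
#' increased by every acute exercise modality and decreased by inactivity.
#' Significance thresholds are applied by the caller when building the
#' input sets (see [significant_set()]).
#'
#' @param up_sets,down_sets Non-empty lists of character vectors.
#' @return Sorted character vector (empty if any input set is empty).
#' @export
concordance_overlap <- function(up_sets, down_sets) {
  stopifnot(length(up_sets) >= 1, length(down_sets) >= 1)
  sort(Reduce(intersect, c(up_sets, down_sets)))
}

#' Hypergeometric over-representation analysis
#'
#' For each annotated set (intersected with the universe), computes the
#' upper-tail hypergeometric probability of observing at least the actual
#' overlap with the query, and adjusts across sets by Benjamini-Hochberg.
#' Sets with no gene in the universe are dropped.
#'
#' @param query Character vector of query genes (must lie in `universe`);
#'   conventionally the genes passing an FDR threshold.
#' @param universe Character vector of measured background genes
#'   (conventionally all genes with a pooled estimate in the protocol).
#' @param collection A gene-set collection as returned by [read_gmt()], or
#'   a plain named list of character vectors.
#' @return `data.frame` with columns `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `fdr`.
#' @export
ora_hypergeometric <- function(query, universe, collection) {
  sets <- if (is.list(collection) && !is.null(collection$sets))
    collection$sets else collection
  stopifnot(is.list(sets), !is.null(names(sets)))
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe))
    stop("query genes outside the universe: ",
         paste(head(setdiff(query, universe), 5), collapse = ", "))
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    if (length(s) == 0) return(NULL)
    ov <- length(intersect(query, s))
    p <- phyper(ov - 1, length(s), n_u - length(s), n_q,
                lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = length(s),
               query_size = n_q, universe_size = n_u, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_name = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  out$fdr <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Complex-level projection of pooled fold-changes
#'
#' For each protein/complex, the arithmetic mean of the pooled log2
#' fold-changes of its coding genes with a successful estimate in each
#' protocol; missing where no member gene was pooled.
#'
#' @param results_by_protocol Named list of `meta_result` tables (names are
#'   used as column labels).
#' @param cmap Complex map as returned by [read_complex_map()] (named list
#'   of gene vectors).
#' @return Numeric matrix, complexes x protocols.
#' @export
complex_projection <- function(results_by_protocol, cmap) {
  stopifnot(is.list(results_by_protocol), is.list(cmap), length(cmap) >= 1)
  out <- matrix(NA_real_, length(cmap), length(results_by_protocol),
                dimnames = list(names(cmap), names(results_by_protocol)))
  for (j in seq_along(results_by_protocol)) {
    res <- results_by_protocol[[j]]
    ok <- res[res$status == "OK" & !is.na(res$mu), c("gene", "mu")]
    for (i in seq_along(cmap)) {
      mu <- ok$mu[ok$gene %in% cmap[[i]]]
      if (length(mu)) out[i, j] <- mean(mu)
    }
  }
  out
}
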