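#' Published pooled-response tables bundled with the package
#'
#' Two small tables of printed meta-analysis output ship with the package
#' as worked-example inputs:
#' `"exercise"` — pooled log2 fold-change and FDR of 45 top responsive
#' genes across the five pooled protocols in healthy individuals;
#' `"training_mti"` — pooled log2 fold-change and FDR of 10 genes in
#' aerobic/resistance training for healthy versus metabolically impaired
#' groups, the input of the healthy-specific rule (see
#' [healthy_specific()]).
#'
#' @param which `"exercise"` or `"training_mti"`.
#' @return A `data.frame` in long format (`gene`, `protocol` or `group`,
#'   `logfc`, `fdr`).
#' @export
published_response_table <- function(which = c("exercise", "training_mti")) {
  which <- match.arg(which)
  path <- system.file(
    "extdata",
    paste0("published_", if (which == "exercise") "exercise_response"
           else "training_mti", ".tsv"),
    package = "exermeta", mustWork = TRUE
  )
  read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Recast a published long table as a minimal meta-result table
#'
#' Selects one protocol/group from a [published_response_table()] and
#' returns a table with the columns the set operations need (`gene`,
#' `mu`, `fdr`, `status = "OK"`).
#'
#' @param tab Long table from [published_response_table()].
#' @param level Value of the `protocol`/`group` column to keep.
#' @return A minimal `meta_result`-style `data.frame`.
#' @export
published_meta_table <- function(tab, level) {
  key <- if ("protocol" %in% names(tab)) "protocol" else "group"
  sub <- tab[tab[[key]] == level, , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows for level ", level)
  data.frame(gene = sub$gene, mu = sub$logfc, fdr = sub$fdr,
             status = "OK", stringsAsFactors = FALSE)
}
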