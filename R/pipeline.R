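#' Construct a subgroup filter
#'
#' Declarative selection of contributing studies: by protocol, health
#' status, sex composition, age, muscle, biopsy timing, or explicit
#' study include/exclude lists.  An explicit exclusion always wins over
#' any inclusion; an empty filter keeps all studies.
#'
#' @param include_protocols,health_status,muscle,biopsy_timing Character
#'   vectors of allowed values (NULL = no constraint).
#' @param sex_range,age_range Length-2 numeric ranges on
#'   `sex_fraction_female` and `age_mean`.
#' @param include_studies,exclude_studies Explicit study-id lists.
#' @return Object of class `subgroup_filter`.
#' @export
subgroup_filter <- function(include_protocols = NULL, health_status = NULL,
                            sex_range = NULL, age_range = NULL,
                            muscle = NULL, biopsy_timing = NULL,
                            include_studies = NULL, exclude_studies = NULL) {
  if (!is.null(sex_range)) stopifnot(length(sex_range) == 2)
  if (!is.null(age_range)) stopifnot(length(age_range) == 2)
  structure(
    list(include_protocols = include_protocols,
         health_status = health_status,
         sex_range = sex_range, age_range = age_range,
         muscle = muscle, biopsy_timing = biopsy_timing,
         include_studies = include_studies,
         exclude_studies = exclude_studies),
    class = "subgroup_filter"
  )
}

#' Apply a subgroup filter to study annotations
#'
#' Deterministic, order-preserving selection; explicit exclusions are
#' applied last so they override any matching inclusion.
#'
#' @param annotations Annotation `data.frame`.
#' @param filter A [subgroup_filter()] (or NULL for no filtering).
#' @return The filtered annotation `data.frame`.
#' @export
subset_studies <- function(annotations, filter = NULL) {
  if (is.null(filter)) return(annotations)
  stopifnot(inherits(filter, "subgroup_filter"))
  keep <- rep(TRUE, nrow(annotations))
  constrain <- function(keep, column, allowed) {
    if (is.null(allowed)) return(keep)
    keep & annotations[[column]] %in% allowed
  }
  keep <- constrain(keep, "protocol", filter$include_protocols)
  keep <- constrain(keep, "health_status", filter$health_status)
  keep <- constrain(keep, "muscle", filter$muscle)
  keep <- constrain(keep, "biopsy_timing", filter$biopsy_timing)
  if (!is.null(filter$sex_range))
    keep <- keep & !is.na(annotations$sex_fraction_female) &
      annotations$sex_fraction_female >= filter$sex_range[1] &
      annotations$sex_fraction_female <= filter$sex_range[2]
  if (!is.null(filter$age_range))
    keep <- keep & !is.na(annotations$age_mean) &
      annotations$age_mean >= filter$age_range[1] &
      annotations$age_mean <= filter$age_range[2]
  if (!is.null(filter$include_studies))
    keep <- keep & annotations$study_id %in% filter$include_studies
  if (!is.null(filter$exclude_studies))
    keep <- keep & !annotations$study_id %in% filter$exclude_studies
  annotations[keep, , drop = FALSE]
}

#' Interrogate one gene across protocols
#'
#' Per-protocol forest output (per-study effects, CIs, FDRs, annotations,
#' and the pooled meta row) for a single gene under a common subgroup
#' filter — the query semantics of a per-gene meta-analysis browser.
#' Protocols whose filtered study count cannot support pooling return a
#' meta row with status `TOO_FEW_STUDIES` (reported `NA`).
#'
#' @param gene Gene identifier; unknown genes raise an error listing
#'   near-matches.
#' @param protocols Character vector of protocols to query.
#' @param effects An [effect_table()].
#' @param filter Optional [subgroup_filter()].
#' @param min_k Minimum studies per pooled estimate.
#' @return Named list of forest records (see [forest_data()]); protocols
#'   with no matching studies yield an entry with `meta` status
#'   `TOO_FEW_STUDIES` and no study rows.
#' @export
query_gene <- function(gene, protocols, effects, filter = NULL, min_k = 3) {
  stopifnot(inherits(effects, "effect_table"))
  known <- unique(effects$records$gene)
  if (!gene %in% known) {
    near <- agrep(gene, known, max.distance = 0.2, value = TRUE)
    stop("unknown gene '", gene, "'",
         if (length(near)) paste0("; did you mean: ",
                                  paste(head(near, 5), collapse = ", ")))
  }
  out <- lapply(protocols, function(pr) {
    tryCatch(
      forest_data(gene, pr, effects, filters = filter, min_k = min_k),
      error = function(e) list(
        gene = gene, protocol = pr,
        study_rows = NULL,
        meta = cbind(gene = gene, protocol = pr,
                     empty_meta_row("TOO_FEW_STUDIES")),
        filters = filter
      )
    )
  })
  setNames(out, protocols)
}

#' Run the full synthetic or file-driven pipeline
#'
#' Orchestrates ingest -> within-study differential expression -> per-
#' protocol random-effects meta-analysis -> cross-study concordance, and
#' writes a TSV/JSON result bundle with provenance.  The configuration is
#' a list (or path to a YAML file) with entries:
#' \describe{
#'   \item{simulate}{arguments for [simulation_config()]; when present the
#'     pipeline runs on simulated paired expression studies.}
#'   \item{effects}{alternatively, path of an effect-table TSV written by
#'     [write_effect_table()].}
#'   \item{expression}{alternatively, list of expression-table paths with
#'     a shared `layout`, plus `annotations` (path).}
#'   \item{protocols}{protocols to meta-analyze (default: those present).}
#'   \item{min_k, fdr_threshold}{pooling and significance settings.}
#'   \item{crossstudy}{`max_missing_fraction`, `k_neighbors`.}
#' }
#' Protocols with no matching studies are skipped with a logged warning.
#'
#' @param config List or YAML path.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the simulation seed.
#' @return Invisibly, a list with the effect table, per-protocol meta
#'   tables, cross-study results, truth (if simulated) and output paths.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(seed)) sim_args$seed <- seed
    if (!is.null(sim_args$studies))
      sim_args$studies <- as.data.frame(sim_args$studies,
                                        stringsAsFactors = FALSE)
    cfg <- do.call(simulation_config, sim_args)
    say("simulating %d genes x %d studies (seed %d)",
        cfg$n_genes, nrow(cfg$studies), cfg$seed)
    sim <- simulate_expression_studies(cfg)
    truth <- sim$truth
    say("within-study differential expression (paired)")
    records <- do.call(rbind, lapply(sim$studies, paired_de))
    effects <- effect_table(records, sim$annotations)
  } else if (!is.null(config$effects)) {
    say("reading effect table %s", config$effects)
    effects <- read_effect_table(config$effects)
  } else if (!is.null(config$expression)) {
    ann <- read_study_annotations(config$expression$annotations)
    layout <- config$expression$layout
    studies <- lapply(config$expression$tables, read_expression_table,
                      layout = layout)
    say("within-study differential expression on %d studies",
        length(studies))
    records <- do.call(rbind, lapply(studies, function(s)
      if (s$design == "PAIRED") paired_de(s) else unpaired_de(s)))
    effects <- effect_table(records, ann)
  } else {
    stop("config must provide one of: simulate, effects, expression")
  }
  write_effect_table(effects, file.path(out_dir, "effects.tsv"))

  min_k <- if (is.null(config$min_k)) 3 else config$min_k
  protocols <- config$protocols
  if (is.null(protocols))
    protocols <- intersect(PROTOCOLS, unique(effects$studies$protocol))
  meta_tables <- list()
  for (pr in protocols) {
    if (!any(effects$studies$protocol == pr)) {
      say("protocol %s: no studies, skipped", pr)
      warning("protocol ", pr, " has no studies; skipped")
      next
    }
    say("meta-analysis: %s", pr)
    mt <- meta_all_genes(effects, pr, min_k = min_k)
    meta_tables[[pr]] <- mt
    write_meta_table(mt, file.path(out_dir, paste0("meta_", pr, ".tsv")))
  }

  cs <- NULL
  if (nrow(effects$studies) >= 2) {
    csc <- config$crossstudy
    mmf <- if (is.null(csc$max_missing_fraction)) 0.10
           else csc$max_missing_fraction
    knn <- if (is.null(csc$k_neighbors)) 10 else csc$k_neighbors
    say("cross-study analysis (missingness <= %.2f, k = %d)", mmf, knn)
    fc <- assemble_fc_matrix(effects)
    fci <- filter_and_impute(fc, mmf, knn)
    if (nrow(fci) >= 3) {
      cs <- list(fc = fci,
                 correlation = correlation_matrix(fci),
                 pca = pca_studies(fci))
      write_matrix_tsv(fci, file.path(out_dir, "fc_matrix.tsv"))
      write_matrix_tsv(cs$correlation,
                       file.path(out_dir, "correlation.tsv"),
                       row_label = "study_id")
      write_matrix_tsv(cs$pca$scores, file.path(out_dir, "pca_scores.tsv"),
                       row_label = "study_id")
    } else {
      say("cross-study analysis skipped: fewer than 3 complete genes")
    }
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("exermeta")),
    config = config, seed = seed, min_k = min_k,
    protocols = protocols, timestamp = format(Sys.time())
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", force = TRUE)
  writeLines(log_lines, log_path)
  invisible(list(effects = effects, meta = meta_tables, crossstudy = cs,
                 truth = truth, out_dir = out_dir))
}
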