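#' Construct a study annotation record
#'
#' One row of phenotype/protocol metadata for a single study group.  These
#' records drive subgroup filtering (health status, sex, age, muscle, biopsy
#' timing) of the meta-analysis, mirroring how multi-study exercise
#' transcriptome collections annotate their cohorts.
#'
#' @param study_id Unique study identifier (e.g. a repository accession).
#' @param protocol One of `ACUTE_AEROBIC`, `ACUTE_RESISTANCE`, `INACTIVITY`,
#'   `TRAINING_AEROBIC`, `TRAINING_RESISTANCE`, `TRAINING_HIIT`,
#'   `TRAINING_COMBINED`.
#' @param muscle Sampled muscle group.
#' @param sex_fraction_female Proportion of female subjects in `[0, 1]`.
#' @param age_mean,age_sd Age in years.
#' @param bmi_mean,bmi_sd Body mass index in kg/m^2.
#' @param health_status `"HLY"` (healthy) or `"MTI"` (metabolically impaired:
#'   overweight/obese, type 2 diabetic or metabolically dysregulated).
#' @param biopsy_timing `"IMM"` (< 30 min post exercise), `"REC"` (after a
#'   recovery period) or `"UNKNOWN"`.
#' @param platform_kind `"ARRAY"` or `"RNASEQ"`.
#' @param n_subjects Number of subjects (>= 1).
#' @return A one-row `data.frame` with the fields above.
#' @export
study_annotation <- function(study_id, protocol,
                             muscle = "VASTUS_LATERALIS",
                             sex_fraction_female = 0,
                             age_mean = NA_real_, age_sd = NA_real_,
                             bmi_mean = NA_real_, bmi_sd = NA_real_,
                             health_status = "HLY",
                             biopsy_timing = "UNKNOWN",
                             platform_kind = "ARRAY",
                             n_subjects = 1L) {
  protocol <- match.arg(protocol, PROTOCOLS)
  muscle <- match.arg(muscle, MUSCLES)
  health_status <- match.arg(health_status, HEALTH_STATUS)
  biopsy_timing <- match.arg(biopsy_timing, BIOPSY_TIMING)
  platform_kind <- match.arg(platform_kind, PLATFORM_KIND)
  stopifnot(
    is.character(study_id), length(study_id) == 1L, nzchar(study_id),
    sex_fraction_female >= 0, sex_fraction_female <= 1,
    n_subjects >= 1
  )
  data.frame(
    study_id = study_id, protocol = protocol, muscle = muscle,
    sex_fraction_female = sex_fraction_female,
    age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    health_status = health_status, biopsy_timing = biopsy_timing,
    platform_kind = platform_kind, n_subjects = as.integer(n_subjects),
    stringsAsFactors = FALSE
  )
}

#' Validate a table of study annotations
#'
#' @param annotations A `data.frame` whose rows are [study_annotation()]
#'   records.
#' @return The validated `data.frame`, invisibly unchanged.
#' @export
validate_annotations <- function(annotations) {
  stopifnot(is.data.frame(annotations))
  required <- c("study_id", "protocol", "health_status", "n_subjects")
  missing <- setdiff(required, names(annotations))
  if (length(missing))
    stop("annotation table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(annotations$study_id))
    stop("duplicated study_id in annotation table")
  bad <- setdiff(annotations$protocol, PROTOCOLS)
  if (length(bad))
    stop("unknown protocol(s): ", paste(bad, collapse = ", "))
  if ("sex_fraction_female" %in% names(annotations)) {
    sf <- annotations$sex_fraction_female
    if (any(!is.na(sf) & (sf < 0 | sf > 1)))
      stop("sex_fraction_female outside [0, 1]")
  }
  if (any(annotations$n_subjects < 1)) stop("n_subjects must be >= 1")
  invisible(annotations)
}

#' Read study annotations from TSV or JSON
#'
#' @param path Path to a tab-delimited table (one row per study, `NA` for
#'   missing) or a JSON array of records.
#' @return A validated annotation `data.frame`.
#' @export
read_study_annotations <- function(path) {
  ext <- tolower(tools::file_ext(path))
  ann <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  }
  validate_annotations(ann)
  ann
}
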