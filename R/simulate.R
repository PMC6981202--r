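#' Default simulated study collection
#'
#' Per-protocol study counts emulating a curated multi-study exercise /
#' inactivity collection: 12 acute aerobic, 8 acute resistance, 7
#' inactivity, 11 aerobic training and 13 resistance training healthy
#' study groups, plus 8 aerobic and 3 resistance training groups of
#' metabolically impaired individuals.
#'
#' @param n_subjects Subjects per study.
#' @param noise_sd Residual log2 SD per subject difference.
#' @param gene_coverage Fraction of genes measured on each study's
#'   platform.
#' @return `data.frame` with columns `protocol`, `health_status`,
#'   `n_subjects`, `noise_sd`, `gene_coverage`.
#' @export
default_study_grid <- function(n_subjects = 12, noise_sd = 1.0,
                               gene_coverage = 0.9) {
  counts <- c(ACUTE_AEROBIC = 12, ACUTE_RESISTANCE = 8, INACTIVITY = 7,
              TRAINING_AEROBIC = 11, TRAINING_RESISTANCE = 13)
  mti <- c(TRAINING_AEROBIC = 8, TRAINING_RESISTANCE = 3)
  grid <- rbind(
    data.frame(protocol = rep(names(counts), counts),
               health_status = "HLY", stringsAsFactors = FALSE),
    data.frame(protocol = rep(names(mti), mti),
               health_status = "MTI", stringsAsFactors = FALSE)
  )
  grid$n_subjects <- n_subjects
  grid$noise_sd <- noise_sd
  grid$gene_coverage <- gene_coverage
  grid
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a sparse set of
#' truly responsive genes with log2 effects of mean magnitude
#' `effect_mean` and random sign, between-study heterogeneity `tau^2`,
#' per-study sampling noise, platform-dependent gene coverage, and
#' attenuated true effects in metabolically impaired (MTI) study groups.
#'
#' @param n_genes Number of genes.
#' @param studies Study grid as from [default_study_grid()]: one row per
#'   study with `protocol`, `health_status`, `n_subjects`, `noise_sd`,
#'   `gene_coverage`.
#' @param pi_responsive Proportion of truly responsive genes.
#' @param effect_mean,effect_sd Mean and SD (log2 units) of the magnitude
#'   of true pooled effects; each responsive gene's sign is a fair coin.
#' @param tau Between-study SD (log2 units); `tau^2` is the heterogeneity
#'   variance of responsive genes (non-responsive genes are exactly null).
#' @param mti_attenuation Multiplier in `[0, 1]` applied to true effects
#'   in MTI-labelled studies.
#' @param seed Root seed; per-study substreams are derived from it so that
#'   adding a study never perturbs earlier studies' draws.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              studies = default_study_grid(),
                              pi_responsive = 0.05,
                              effect_mean = 1.0, effect_sd = 0.3,
                              tau = sqrt(0.05),
                              mti_attenuation = 0.25,
                              seed = 20200124) {
  stopifnot(
    n_genes >= 1,
    is.data.frame(studies), nrow(studies) >= 1,
    all(c("protocol", "health_status", "n_subjects", "noise_sd",
          "gene_coverage") %in% names(studies)),
    all(studies$protocol %in% PROTOCOLS),
    all(studies$health_status %in% HEALTH_STATUS),
    all(studies$n_subjects >= 2),
    all(studies$noise_sd >= 0),
    all(studies$gene_coverage >= 0 & studies$gene_coverage <= 1),
    pi_responsive >= 0, pi_responsive <= 1,
    effect_sd >= 0, tau >= 0,
    mti_attenuation >= 0, mti_attenuation <= 1,
    is.numeric(seed), length(seed) == 1
  )
  structure(
    list(n_genes = as.integer(n_genes), studies = studies,
         pi_responsive = pi_responsive, effect_mean = effect_mean,
         effect_sd = effect_sd, tau = tau,
         mti_attenuation = mti_attenuation, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

## Substream seed for study i: independent of how many studies follow.
study_seed <- function(root, i) as.integer((root + 104729 * i) %% 2147483647)

gene_ids <- function(n) sprintf("G%05d", seq_len(n))

sim_truth <- function(config) {
  set.seed(config$seed)
  g <- config$n_genes
  responsive <- runif(g) < config$pi_responsive
  sign <- sample(c(-1, 1), g, replace = TRUE)
  mu <- ifelse(responsive,
               sign * rnorm(g, config$effect_mean, config$effect_sd), 0)
  tau2 <- ifelse(responsive, config$tau^2, 0)
  list(genes = gene_ids(g), responsive = responsive, mu = mu, tau2 = tau2)
}

sim_annotations <- function(studies) {
  ids <- sprintf("SIM_%s_%s_%02d", studies$protocol, studies$health_status,
                 stats::ave(seq_len(nrow(studies)),
                            paste(studies$protocol, studies$health_status),
                            FUN = seq_along))
  do.call(rbind, lapply(seq_len(nrow(studies)), function(i)
    study_annotation(
      study_id = ids[i], protocol = studies$protocol[i],
      health_status = studies$health_status[i],
      sex_fraction_female = 0.25, age_mean = 40, age_sd = 12,
      bmi_mean = if (studies$health_status[i] == "HLY") 24 else 33,
      bmi_sd = 2, biopsy_timing = "REC",
      n_subjects = studies$n_subjects[i]
    )))
}

## Per-study realized effects theta_gi and coverage mask, drawn from the
## study's substream.  Returns draws for ALL genes; callers apply the mask.
sim_study_draws <- function(config, truth, i, what = c("effect", "expr")) {
  what <- match.arg(what)
  st <- config$studies[i, ]
  set.seed(study_seed(config$seed, i))
  g <- config$n_genes
  a <- if (st$health_status == "MTI") config$mti_attenuation else 1
  theta <- rnorm(g, truth$mu * a, sqrt(truth$tau2))
  covered <- runif(g) < st$gene_coverage
  list(theta = theta, covered = covered, st = st)
}

#' Simulate per-study effect tables directly
#'
#' Effect-level generator feeding the pooling engine without the
#' expression stage.  For each responsive gene the true pooled effect is
#' `mu_g` (random sign, magnitude `N(effect_mean, effect_sd^2)`); study
#' `i`'s realized effect is `theta_gi ~ N(mu_g * a_i, tau^2)` with
#' `a_i = mti_attenuation` for MTI studies; the observed effect is
#' `y_gi ~ N(theta_gi, v_gi)` with sampling variance
#' `v_gi = noise_sd^2 / n_subjects`.  Each (gene, study) cell is dropped
#' with probability `1 - gene_coverage`.  Identical seeds give identical
#' output.
#'
#' @param config A [simulation_config()].
#' @return List with `effects` (an [effect_table()]) and `truth` (list
#'   with per-gene `responsive`, `mu`, `tau2` and the genes x studies
#'   matrix `theta` of realized effects).
#' @export
simulate_effect_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- sim_truth(config)
  ann <- sim_annotations(config$studies)
  g <- config$n_genes
  theta_all <- matrix(NA_real_, g, nrow(ann),
                      dimnames = list(truth$genes, ann$study_id))
  recs <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    dr <- sim_study_draws(config, truth, i)
    theta_all[, i] <- dr$theta
    n <- dr$st$n_subjects
    v <- dr$st$noise_sd^2 / n
    if (v <= 0) v <- 1e-8
    y <- rnorm(g, dr$theta, sqrt(dr$st$noise_sd^2 / n))
    keep <- which(dr$covered)
    t_stat <- y / sqrt(v)
    p <- 2 * pt(-abs(t_stat), n - 1)
    ci_half <- qt(0.975, n - 1) * sqrt(v)
    recs[[i]] <- data.frame(
      gene = truth$genes[keep], study_id = ann$study_id[i],
      logfc = y[keep], var = v, n = n, t = t_stat[keep], df = n - 1,
      p = p[keep], fdr = bh_adjust(p[keep]),
      ci_low = (y - ci_half)[keep], ci_high = (y + ci_half)[keep],
      degenerate = FALSE, stringsAsFactors = FALSE
    )
  }
  truth$theta <- theta_all
  list(effects = effect_table(do.call(rbind, recs), ann), truth = truth)
}

#' Simulate paired pre/post expression studies
#'
#' Full-pipeline generator: for each study, a genes x subjects `PRE`
#' matrix with per-gene, per-subject baselines `N(7, 1)` and a `POST`
#' matrix `PRE + theta_gi + N(0, noise_sd^2)`, with pairing metadata.
#' Genes not covered by the study's platform are absent from its matrix.
#'
#' @param config A [simulation_config()].
#' @return List with `studies` (list of [expression_study()]),
#'   `annotations` and `truth` as in [simulate_effect_table()].
#' @export
simulate_expression_studies <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- sim_truth(config)
  ann <- sim_annotations(config$studies)
  g <- config$n_genes
  theta_all <- matrix(NA_real_, g, nrow(ann),
                      dimnames = list(truth$genes, ann$study_id))
  out <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    dr <- sim_study_draws(config, truth, i, what = "expr")
    theta_all[, i] <- dr$theta
    n <- dr$st$n_subjects
    keep <- which(dr$covered)
    pre <- matrix(rnorm(g * n, 7, 1), g, n)
    post <- pre + dr$theta +
      matrix(rnorm(g * n, 0, dr$st$noise_sd), g, n)
    vals <- cbind(pre[keep, , drop = FALSE], post[keep, , drop = FALSE])
    subj <- sprintf("S%02d", seq_len(n))
    colnames(vals) <- c(paste0(subj, ":PRE"), paste0(subj, ":POST"))
    rownames(vals) <- truth$genes[keep]
    samples <- data.frame(
      subject_id = rep(subj, 2),
      condition = rep(c("PRE", "POST"), each = n),
      stringsAsFactors = FALSE
    )
    out[[i]] <- expression_study(ann$study_id[i], vals, samples, "PAIRED")
  }
  truth$theta <- theta_all
  list(studies = out, annotations = ann, truth = truth)
}

#' Score meta-analysis results against simulation truth
#'
#' @param results A `meta_result` table from [meta_all_genes()].
#' @param truth Truth list from a generator run.
#' @param fdr_threshold Discovery threshold on the meta FDR (default
#'   0.05).
#' @return List of metrics: `sensitivity` (responsive genes called),
#'   `fdp` (false discovery proportion among calls), `bias_mu` (mean of
#'   `mu_hat - mu_true` over responsive genes with an estimate),
#'   `ci_coverage` (fraction of estimated genes whose 95% CI covers the
#'   true `mu_g`), plus the counts behind them.
#' @export
evaluate_truth <- function(results, truth, fdr_threshold = 0.05) {
  if (!all(results$gene %in% truth$genes))
    stop("results contain genes absent from the simulation truth")
  idx <- match(results$gene, truth$genes)
  responsive <- truth$responsive[idx]
  mu_true <- truth$mu[idx]
  ok <- results$status == "OK"
  called <- ok & !is.na(results$fdr) & results$fdr < fdr_threshold
  n_called <- sum(called)
  est <- ok & responsive
  list(
    sensitivity = if (any(responsive)) mean(called[responsive]) else NA_real_,
    fdp = if (n_called > 0) sum(called & !responsive) / n_called else 0,
    bias_mu = if (any(est)) mean(results$mu[est] - mu_true[est]) else NA_real_,
    ci_coverage = mean(results$ci_low[ok] <= mu_true[ok] &
                         mu_true[ok] <= results$ci_high[ok]),
    n_called = n_called,
    n_responsive = sum(responsive),
    n_ok = sum(ok)
  )
}
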