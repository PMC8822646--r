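#' Configuration for the synthetic kinome study generator
#'
#' Describes a multi-region targeted RNA-seq study: a gene panel, a patient
#' roster with per-sample Ashcroft scores, lognormal baseline expression,
#' severity-linked induced/suppressed gene effects, within-patient
#' dispersion (inflated for IPF), and negative-binomial count noise.
#' Defaults reproduce the study layout: 21 samples from 9 patients (13 IPF
#' over 5 patients with 6,3,2,1,1 samples; 8 control over 4 patients, 2
#' each) on a 612-gene panel with 46 inhibitor-flagged kinases.
#'
#' @param n_genes panel size.
#' @param n_kinase,n_cancer_related genes per category; the remainder is
#'   categorised `"other"`.
#' @param n_inhibitor inhibitor-flagged kinases.
#' @param ipf_samples_per_patient,control_samples_per_patient roster.
#' @param ipf_ashcroft list of per-sample Ashcroft scores, one vector per
#'   IPF patient (controls carry no score).
#' @param n_induced,n_suppressed planted severity-effect genes.
#' @param effect_log2 log2 effect size in the severe (Ashcroft >= 6)
#'   stratum; induced genes get `+effect_log2`, suppressed `-effect_log2`.
#' @param baseline_meanlog,baseline_sdlog lognormal baseline RPKM
#'   parameters (natural-log scale).
#' @param patient_sd_log2 per-(gene, patient) biological noise SD, log2.
#' @param segment_sd_log2 per-(gene, sample) segment noise SD, log2.
#' @param ipf_heterogeneity multiplier on segment noise for IPF samples;
#'   > 1 makes IPF tissue more internally diverse than control.
#' @param nb_dispersion negative-binomial dispersion (0 gives Poisson).
#' @param length_range_bp transcript lengths drawn log-uniformly here.
#' @param mapped_total_range per-sample mapped-library totals drawn
#'   uniformly here.
#' @param severity_mode `"binary"` (default, Ashcroft >= 6 vs < 6) or
#'   `"linear"` (effect scales with Ashcroft/8).
#' @param seed integer seed; fully determines the simulated dataset.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 612L, n_kinase = 517L,
                              n_cancer_related = 46L, n_inhibitor = 46L,
                              ipf_samples_per_patient = c(6L, 3L, 2L, 1L, 1L),
                              control_samples_per_patient = rep(2L, 4L),
                              ipf_ashcroft = list(c(7L, 6L, 6L, 5L, 4L, 3L),
                                                  c(7L, 6L, 5L),
                                                  c(7L, 5L),
                                                  4L, 3L),
                              n_induced = 30L, n_suppressed = 10L,
                              effect_log2 = 2,
                              baseline_meanlog = log(10),
                              baseline_sdlog = 1.2,
                              patient_sd_log2 = 0.25,
                              segment_sd_log2 = 0.25,
                              ipf_heterogeneity = 3,
                              nb_dispersion = 0.05,
                              length_range_bp = c(500L, 10000L),
                              mapped_total_range = c(2e6, 4e6),
                              severity_mode = c("binary", "linear"),
                              seed = 104729L) {
  severity_mode <- match.arg(severity_mode)
  cfg <- list(n_genes = as.integer(n_genes), n_kinase = as.integer(n_kinase),
              n_cancer_related = as.integer(n_cancer_related),
              n_inhibitor = as.integer(n_inhibitor),
              ipf_samples_per_patient = as.integer(ipf_samples_per_patient),
              control_samples_per_patient =
                as.integer(control_samples_per_patient),
              ipf_ashcroft = lapply(ipf_ashcroft, as.integer),
              n_induced = as.integer(n_induced),
              n_suppressed = as.integer(n_suppressed),
              effect_log2 = effect_log2,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              patient_sd_log2 = patient_sd_log2,
              segment_sd_log2 = segment_sd_log2,
              ipf_heterogeneity = ipf_heterogeneity,
              nb_dispersion = nb_dispersion,
              length_range_bp = as.numeric(length_range_bp),
              mapped_total_range = as.numeric(mapped_total_range),
              severity_mode = severity_mode, seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_kinase + n_cancer_related > n_genes)
      stop("category counts exceed panel size")
    if (n_inhibitor > n_kinase)
      stop("more inhibitor flags than kinase genes")
    if (n_induced + n_suppressed > n_genes)
      stop("more effect genes than panel genes")
    if (length(ipf_ashcroft) != length(ipf_samples_per_patient) ||
        !all(lengths(ipf_ashcroft) == ipf_samples_per_patient))
      stop("Ashcroft score list inconsistent with the IPF roster")
    if (any(unlist(ipf_ashcroft) < 0L | unlist(ipf_ashcroft) > 8L))
      stop("Ashcroft scores must lie in 0-8")
    if (any(c(baseline_sdlog, patient_sd_log2, segment_sd_log2,
              nb_dispersion) < 0))
      stop("noise parameters must be non-negative")
    if (ipf_heterogeneity <= 0) stop("heterogeneity multiplier must be > 0")
    if (any(length_range_bp < 1) ||
        length_range_bp[2L] < length_range_bp[1L])
      stop("invalid transcript length range")
    if (any(mapped_total_range <= 0) ||
        mapped_total_range[2L] < mapped_total_range[1L])
      stop("invalid mapped total range")
  })
  invisible(cfg)
}

#' The default synthetic study configuration
#'
#' The 21-sample, 9-patient, 612-gene layout of the study design with the
#' generator's documented default effect and noise values and a fixed seed.
#'
#' @param ... overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
default_study_config <- function(...) simulation_config(...)

# run an expression under a locally seeded RNG, restoring global state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate a synthetic kinome study dataset
#'
#' Draws counts with mean structure
#' \deqn{\mu_{gs} = baseline_g \cdot 2^{effect_g \cdot severity_s
#'   + \epsilon_{gp} + \epsilon_{gs}}}
#' where \eqn{\epsilon_{gp}} is per-(gene, patient) noise and
#' \eqn{\epsilon_{gs}} per-(gene, sample) segment noise whose SD is
#' inflated for IPF samples by the heterogeneity multiplier. Counts are
#' negative-binomial with mean
#' \eqn{\mu_{gs} \times length_g \times total_s / 10^9}, so RPKM
#' normalization recovers \eqn{\mu_{gs}} in expectation.
#'
#' @param config a `simulation_config`.
#' @param seed optional override of `config$seed`.
#' @return List with `counts` (`count_matrix`), `sheet` (`sample_sheet`),
#'   `panel` (`gene_panel`) and `truth` (list: `effects` data frame
#'   gene_id/effect_class/log2_effect, `strata` data frame
#'   sample_id/stratum, `baseline_rpkm`).
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  with_local_seed(seed, {
    ng <- config$n_genes
    gene_id <- sprintf("G%04d", seq_len(ng))
    category <- rep("other", ng)
    category[seq_len(config$n_kinase)] <- "kinase"
    if (config$n_cancer_related > 0L)
      category[config$n_kinase + seq_len(config$n_cancer_related)] <-
        "cancer_related"
    inhibitor <- rep(FALSE, ng)
    inhibitor[sample(which(category == "kinase"), config$n_inhibitor)] <- TRUE
    lengths_bp <- as.integer(round(exp(stats::runif(
      ng, log(config$length_range_bp[1L]), log(config$length_range_bp[2L])))))
    panel <- gene_panel(gene_id, lengths_bp, category, inhibitor)

    # roster
    n_ipf_p <- length(config$ipf_samples_per_patient)
    n_ctl_p <- length(config$control_samples_per_patient)
    patients <- c(sprintf("IPF%d", seq_len(n_ipf_p)),
                  sprintf("CTL%d", seq_len(n_ctl_p)))
    per_patient <- c(config$ipf_samples_per_patient,
                     config$control_samples_per_patient)
    patient_of <- rep(patients, per_patient)
    group_of <- rep(c("IPF", "control"), c(sum(config$ipf_samples_per_patient),
                                           sum(config$control_samples_per_patient)))
    seg_idx <- unlist(lapply(per_patient, seq_len))
    sample_id <- paste0(patient_of, "_S", seg_idx)
    ashcroft <- c(unlist(config$ipf_ashcroft),
                  rep(NA_integer_, sum(config$control_samples_per_patient)))
    sheet <- sample_sheet(sample_id, patient_of, group_of, ashcroft,
                          paste0("segment_", seg_idx))

    # planted effects
    eff_idx <- sample(ng, config$n_induced + config$n_suppressed)
    induced <- eff_idx[seq_len(config$n_induced)]
    suppressed <- setdiff(eff_idx, induced)
    effect <- numeric(ng)
    effect[induced] <- config$effect_log2
    effect[suppressed] <- -config$effect_log2
    severity <- if (config$severity_mode == "binary")
      as.numeric(!is.na(ashcroft) & ashcroft >= 6L) else
      ifelse(is.na(ashcroft), 0, ashcroft / 8)

    baseline <- stats::rlnorm(ng, config$baseline_meanlog,
                              config$baseline_sdlog)
    ns <- length(sample_id)
    pat_noise <- matrix(stats::rnorm(ng * length(patients), 0,
                                     config$patient_sd_log2),
                        ng, dimnames = list(NULL, patients))
    seg_sd <- config$segment_sd_log2 *
      ifelse(group_of == "IPF", config$ipf_heterogeneity, 1)
    seg_noise <- matrix(stats::rnorm(ng * ns, 0, rep(seg_sd, each = ng)), ng)
    log2_mu <- log2(baseline) + outer(effect, severity) +
      pat_noise[, patient_of] + seg_noise
    mu_rpkm <- 2^log2_mu

    totals <- round(stats::runif(ns, config$mapped_total_range[1L],
                                 config$mapped_total_range[2L]))
    mean_counts <- sweep(mu_rpkm * lengths_bp / 1e9, 2L, totals, `*`)
    counts <- if (config$nb_dispersion > 0)
      matrix(stats::rnbinom(ng * ns, mu = mean_counts,
                            size = 1 / config$nb_dispersion), ng) else
      matrix(stats::rpois(ng * ns, mean_counts), ng)
    dimnames(counts) <- list(gene_id, sample_id)

    truth <- list(
      effects = data.frame(
        gene_id = gene_id,
        effect_class = ifelse(effect > 0, "induced",
                              ifelse(effect < 0, "suppressed", "none")),
        log2_effect = effect, stringsAsFactors = FALSE),
      strata = data.frame(
        sample_id = sample_id,
        stratum = ifelse(!is.na(ashcroft) & ashcroft >= 6L, "severe",
                         "non_severe"), stringsAsFactors = FALSE),
      baseline_rpkm = stats::setNames(baseline, gene_id),
      seed = seed)

    list(counts = count_matrix(counts,
                               stats::setNames(totals, sample_id)),
         sheet = sheet, panel = panel, truth = truth)
  })
}
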