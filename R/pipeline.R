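#' Build and validate a full-study run configuration
#'
#' Inputs come either from tabular files (`counts_path`, `sheet_path`,
#' `panel_path`, optional `totals_path`) or from the synthetic generator
#' (`simulate`, a [simulation_config()]). Every analysis option is
#' validated here, before any computation starts; the resolved
#' configuration is echoed verbatim into the output directory by
#' [run_full_study()].
#'
#' @param out_dir output directory (created if absent).
#' @param counts_path,sheet_path,panel_path,totals_path input files.
#' @param simulate a `simulation_config` used when no paths are given.
#' @param delim input/output field delimiter.
#' @param seed integer seed for any stochastic step.
#' @param sd_type,sd_scope SD conventions shared by adjustment and
#'   diversity.
#' @param pseudocount log2 pseudocount.
#' @param distance,linkage,cut_k clustering options.
#' @param cluster_log2 cluster on log2(RPKM + pseudocount) (default) rather
#'   than raw RPKM.
#' @param diversity_summary patient-level aggregation.
#' @param eps,test_mode differential-ranking options.
#' @param top_k per-case ranking depth.
#' @param training_patient voting training patient; default picks the
#'   patient with most samples having both Ashcroft strata.
#' @param voting_threshold,voting_scale gene-selection options.
#' @param verbose log progress messages.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, counts_path = NULL, sheet_path = NULL,
                       panel_path = NULL, totals_path = NULL,
                       simulate = NULL, delim = "\t", seed = 1L,
                       sd_type = "population", sd_scope = "per_gene",
                       pseudocount = 1, distance = "uncentered",
                       linkage = "average", cut_k = 2L, cluster_log2 = TRUE,
                       diversity_summary = "median", eps = 0.1,
                       test_mode = "welch", top_k = 10L,
                       training_patient = NULL, voting_threshold = 1,
                       voting_scale = "log2", verbose = TRUE) {
  match.arg(sd_type, c("population", "sample"))
  match.arg(sd_scope, c("per_gene", "pooled"))
  match.arg(distance, c("uncentered", "pearson", "euclidean"))
  match.arg(linkage, c("average", "single", "complete"))
  match.arg(diversity_summary, c("median", "mean"))
  match.arg(test_mode, c("welch", "student", "paired"))
  match.arg(voting_scale, c("log2", "rpkm"))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (eps < 0) stop("eps must be non-negative")
  if (cut_k < 2L) stop("cut_k must be at least 2")
  paths <- c(counts_path, sheet_path, panel_path, totals_path)
  if (is.null(simulate)) {
    if (is.null(counts_path) || is.null(sheet_path) || is.null(panel_path))
      stop("either input paths or a simulation config must be supplied")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  } else {
    stopifnot(inherits(simulate, "simulation_config"))
  }
  cfg <- list(out_dir = out_dir, counts_path = counts_path,
              sheet_path = sheet_path, panel_path = panel_path,
              totals_path = totals_path, simulate = simulate, delim = delim,
              seed = as.integer(seed), sd_type = sd_type,
              sd_scope = sd_scope, pseudocount = pseudocount,
              distance = distance, linkage = linkage,
              cut_k = as.integer(cut_k), cluster_log2 = isTRUE(cluster_log2),
              diversity_summary = diversity_summary, eps = eps,
              test_mode = test_mode, top_k = as.integer(top_k),
              training_patient = training_patient,
              voting_threshold = voting_threshold,
              voting_scale = voting_scale, verbose = verbose)
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, verbose, expr) {
  if (verbose) message("[fibrokinome] stage: ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

# patient usable for voting: most samples, both Ashcroft strata >= 2
pick_training_patient <- function(sheet) {
  ipf <- sheet[sheet$group == "IPF", , drop = FALSE]
  ok <- vapply(split(ipf, ipf$patient_id), function(d)
    sum(d$ashcroft_score >= 6) >= 2L && sum(d$ashcroft_score < 6) >= 2L,
    logical(1L))
  if (!any(ok)) return(NULL)
  sizes <- table(ipf$patient_id)[names(ok)[ok]]
  names(sizes)[which.max(sizes)]
}

#' Run the full kinome study analysis
#'
#' Sequences every stage of the analysis in the order of the study's
#' results: RPKM normalization, matrix adjustment and sample clustering,
#' stratified DEG counts, per-patient expression diversity, integrated and
#' per-case fold-change rankings, the targetable-kinase subpanel filter,
#' and the weighted-voting severity classifier fitted on one patient and
#' scored on the held-out multi-sample IPF patients. All artifacts are
#' written to `config$out_dir` as delimited tables (plus a Newick
#' dendrogram and a YAML manifest); the run is deterministic given the
#' configuration and seed.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with every in-memory result and the artifact
#'   paths.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- config$verbose
  p <- function(f) file.path(config$out_dir, f)

  data <- stage("load", v, {
    if (!is.null(config$simulate))
      simulate_dataset(config$simulate, seed = config$seed)
    else list(
      counts = read_count_matrix(config$counts_path, config$delim,
                                 config$totals_path),
      sheet = read_sample_sheet(config$sheet_path, config$delim),
      panel = read_gene_panel(config$panel_path, config$delim),
      truth = NULL)
  })

  expr <- stage("normalize", v, compute_rpkm(data$counts, data$panel))

  clus <- stage("cluster", v, {
    cexpr <- if (config$cluster_log2)
      log2_transform(expr, config$pseudocount) else expr
    adj <- adjust_matrix(cexpr, config$sd_type, config$sd_scope)
    dendro <- cluster_samples(adj, config$distance, config$linkage,
                              k = config$cut_k)
    write_result_table(data.frame(gene_id = rownames(adj$values),
                                  adj$values, check.names = FALSE),
                       p("adjusted_matrix.tsv"), config$delim)
    write_newick(dendro, p("dendrogram.newick"))
    write_merge_table(dendro, p("dendrogram_merges.tsv"))
    write_result_table(data.frame(sample_id = names(dendro$labels_k),
                                  cluster = unname(dendro$labels_k)),
                       p("cluster_labels.tsv"), config$delim)
    list(adjusted = adj, dendrogram = dendro)
  })

  degs <- stage("deg_counts", v, {
    grid <- expand.grid(stratum = c("moderate", "severe"),
                        direction = c("up", "down", "both"),
                        stringsAsFactors = FALSE)
    grid$n_genes <- mapply(function(st, di)
      count_degs(expr, data$sheet, st, di, eps = config$eps),
      grid$stratum, grid$direction)
    write_result_table(grid, p("deg_counts.tsv"), config$delim)
    grid
  })

  div <- stage("diversity", v, {
    rep <- compute_diversity(expr, data$sheet, config$sd_type,
                             config$sd_scope, config$diversity_summary)
    cmp <- test_group_diversity(rep, data$sheet, config$diversity_summary)
    write_result_table(rep$long, p("diversity_long.tsv"), config$delim)
    write_result_table(rep$patient_summary, p("diversity_patients.tsv"),
                       config$delim)
    write_result_table(
      data.frame(statistic_used = cmp$statistic_used,
                 direction = cmp$direction, estimate = cmp$estimate,
                 W = cmp$statistic, p_value = cmp$p_value),
      p("diversity_test.tsv"), config$delim)
    list(report = rep, comparison = cmp)
  })

  ranking <- stage("rank", v, {
    integrated <- rank_upregulated(expr, data$sheet, "IPF", "control",
                                   eps = config$eps,
                                   test_mode = config$test_mode)
    write_result_table(as.data.frame(integrated),
                       p("ranking_integrated.tsv"), config$delim,
                       sort_by = "log2_ratio")
    per_case <- list()
    for (pt in unique(data$sheet$patient_id[data$sheet$group == "IPF"])) {
      tab <- rank_upregulated(expr, data$sheet, pt, "control",
                              eps = config$eps,
                              test_mode = config$test_mode,
                              top_k = config$top_k)
      write_result_table(as.data.frame(tab),
                         p(sprintf("ranking_case_%s.tsv", pt)),
                         config$delim, sort_by = "log2_ratio")
      per_case[[pt]] <- tab
    }
    list(integrated = integrated, per_case = per_case)
  })

  subpanel <- stage("subpanel", v, {
    sub <- filter_inhibitor_subpanel(expr, data$panel)
    excl <- attr(sub, "excluded")
    if (nrow(excl))
      write_result_table(excl, p("subpanel_exclusions.tsv"), config$delim)
    profiles <- list()
    for (pt in unique(data$sheet$patient_id[data$sheet$group == "IPF"])) {
      prof <- rank_upregulated(sub, data$sheet, pt, "control",
                               eps = config$eps,
                               test_mode = config$test_mode)
      write_result_table(as.data.frame(prof),
                         p(sprintf("subpanel_profile_%s.tsv", pt)),
                         config$delim, sort_by = "log2_ratio")
      profiles[[pt]] <- prof
    }
    list(expr = sub, excluded = excl, profiles = profiles)
  })

  voting <- stage("vote", v, {
    tp <- config$training_patient
    if (is.null(tp)) tp <- pick_training_patient(data$sheet)
    if (is.null(tp)) {
      if (v) message("[fibrokinome] no patient with both strata duplicated",
                     "; skipping weighted voting")
      NULL
    } else {
      model <- fit_model(expr, data$sheet, tp, config$voting_threshold,
                         config$voting_scale)
      held <- data$sheet[data$sheet$group == "IPF" &
                           data$sheet$patient_id != tp, , drop = FALSE]
      multi <- names(which(table(held$patient_id) >= 2L))
      test_ids <- held$sample_id[held$patient_id %in% multi]
      scores <- if (length(test_ids))
        score_samples(model, expr, test_ids) else NULL
      write_voting_model(model, p("voting_model.tsv"))
      if (!is.null(scores)) {
        truth <- data$sheet$ashcroft_score[match(scores$sample_id,
                                                 data$sheet$sample_id)]
        out <- cbind(scores, true_stratum = ifelse(truth >= 6, "severe",
                                                   "non_severe"))
        write_result_table(out, p("voting_scores.tsv"), config$delim)
      }
      ev <- if (!is.null(scores)) evaluate_model(scores, data$sheet) else NULL
      list(model = model, scores = scores, evaluation = ev,
           training_patient = tp)
    }
  })

  manifest <- stage("manifest", v, {
    echo <- config
    echo$simulate <- if (is.null(config$simulate)) NULL else
      unclass(config$simulate)
    m <- list(package = "fibrokinome",
              version = as.character(utils::packageVersion("fibrokinome")),
              seed = config$seed, config = unclass(echo))
    yaml::write_yaml(m, p("manifest.yaml"))
    m$config_hash <- unname(tools::md5sum(p("manifest.yaml")))
    yaml::write_yaml(m, p("manifest.yaml"))
    m
  })

  invisible(list(data = data, expression = expr, clustering = clus,
                 deg_counts = degs, diversity = div, ranking = ranking,
                 subpanel = subpanel, voting = voting, manifest = manifest,
                 out_dir = config$out_dir))
}
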