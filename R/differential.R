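# resolve a selector into sample ids: a group name, patient ids, or
# explicit sample ids
resolve_samples <- function(selector, sheet, expr = NULL) {
  ids <- NULL
  if (length(selector) == 1L &&
      tolower(selector) %in% c("ipf", "control")) {
    ids <- sheet$sample_id[sheet$group == normalize_group(selector)]
  } else if (all(selector %in% sheet$patient_id)) {
    ids <- sheet$sample_id[sheet$patient_id %in% selector]
  } else if (all(selector %in% sheet$sample_id)) {
    ids <- selector
  } else {
    stop("selector matches no group, patient or sample ids: ",
         paste(utils::head(selector, 5L), collapse = ", "))
  }
  if (!is.null(expr)) ids <- intersect(ids, colnames(expr$values))
  ids
}

#' Per-gene two-sample t tests
#'
#' @param expr an `expression_matrix`.
#' @param group_a,group_b disjoint sample-id vectors, each of size >= 2.
#' @param mode `"welch"` (default), `"student"` (pooled variance), or
#'   `"paired"`. Paired mode requires equal sizes and an explicit pairing:
#'   `pairing[i]` in `group_b` is matched to `group_a[i]`.
#' @param pairing for `mode = "paired"`, the reordering of `group_b`.
#' @return Data frame gene_id, statistic, p_value.
#' @export
two_sample_test <- function(expr, group_a, group_b,
                            mode = c("welch", "student", "paired"),
                            pairing = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  mode <- match.arg(mode)
  if (length(intersect(group_a, group_b)))
    stop("sample groups overlap")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least two samples")
  if (mode == "paired") {
    if (is.null(pairing))
      stop("paired mode requires an explicit pairing map; groups of ",
           length(group_a), " and ", length(group_b),
           " samples are never silently truncated")
    if (length(pairing) != length(group_a) ||
        !setequal(pairing, group_b))
      stop("pairing must reorder group_b to match group_a")
    group_b <- pairing
  }
  a <- expr$values[, group_a, drop = FALSE]
  b <- expr$values[, group_b, drop = FALSE]
  res <- t(vapply(seq_len(nrow(a)), function(i) {
    tt <- tryCatch(switch(mode,
      welch = stats::t.test(a[i, ], b[i, ]),
      student = stats::t.test(a[i, ], b[i, ], var.equal = TRUE),
      paired = stats::t.test(a[i, ], b[i, ], paired = TRUE)),
      error = function(e) list(statistic = NA_real_, p.value = NA_real_))
    c(unname(tt$statistic), tt$p.value)
  }, numeric(2L)))
  data.frame(gene_id = rownames(a), statistic = res[, 1L],
             p_value = res[, 2L], stringsAsFactors = FALSE)
}

#' Rank genes by fold change between a case selection and a reference group
#'
#' For each gene, the log2 ratio of group-mean RPKM (case over reference),
#' with a small pseudocount keeping ratios finite when a mean is zero:
#' \code{log2((mean_case + eps) / (mean_ref + eps))}. The table is sorted by
#' descending log2 ratio; `passes_twofold` marks genes upregulated by
#' strictly more than twofold (log2 ratio > 1).
#'
#' @param expr an `expression_matrix` of RPKM values.
#' @param sheet a `sample_sheet`.
#' @param case_selector group name (`"IPF"`), patient ids, or sample ids.
#' @param reference_selector same, default `"control"`.
#' @param eps ratio pseudocount in RPKM units (default 0.1). With `eps = 0`
#'   genes whose reference mean is zero are reported with `log2_ratio = NA`
#'   (unranked, sorted last) rather than infinite.
#' @param test_mode t-test flavour for the significance column; `NULL`
#'   skips testing.
#' @param top_k optionally return only the k top-ranked genes.
#' @return A `ranking_table` data frame: gene_id, mean_case, mean_reference,
#'   log2_ratio, statistic, p_value, passes_twofold.
#' @export
rank_upregulated <- function(expr, sheet, case_selector,
                             reference_selector = "control", eps = 0.1,
                             test_mode = "welch", top_k = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  case_ids <- resolve_samples(case_selector, sheet, expr)
  ref_ids <- resolve_samples(reference_selector, sheet, expr)
  if (!length(case_ids) || !length(ref_ids))
    stop("empty case or reference selection")
  if (length(intersect(case_ids, ref_ids)))
    stop("case and reference selections overlap")
  mc <- rowMeans(expr$values[, case_ids, drop = FALSE])
  mr <- rowMeans(expr$values[, ref_ids, drop = FALSE])
  if (eps < 0) stop("eps must be non-negative")
  lr <- if (eps > 0) log2((mc + eps) / (mr + eps)) else
    ifelse(mr == 0 | mc == 0, NA_real_, log2(mc / mr))
  tab <- data.frame(gene_id = rownames(expr$values), mean_case = mc,
                    mean_reference = mr, log2_ratio = lr,
                    statistic = NA_real_, p_value = NA_real_,
                    passes_twofold = !is.na(lr) & lr > 1,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(test_mode) && length(case_ids) >= 2L &&
      length(ref_ids) >= 2L) {
    tt <- two_sample_test(expr, case_ids, ref_ids, mode = test_mode)
    tab$statistic <- tt$statistic[match(tab$gene_id, tt$gene_id)]
    tab$p_value <- tt$p_value[match(tab$gene_id, tt$gene_id)]
  }
  tab <- tab[order(-xtfrm(tab$log2_ratio), tab$gene_id, na.last = TRUE), ,
             drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(top_k)) tab <- utils::head(tab, top_k)
  class(tab) <- c("ranking_table", "data.frame")
  tab
}

#' Count genes differentially expressed beyond twofold in an Ashcroft stratum
#'
#' Compares the IPF samples of one severity stratum against all control
#' samples and counts genes with |log2 ratio| > 1, optionally restricted to
#' one direction.
#'
#' @param expr an `expression_matrix` of RPKM values.
#' @param sheet a `sample_sheet`.
#' @param stratum `"severe"` (Ashcroft >= 6) or `"moderate"` (< 6).
#' @param direction `"both"`, `"up"` or `"down"`.
#' @param eps ratio pseudocount, as in [rank_upregulated()].
#' @return Integer count of differentially expressed genes.
#' @export
count_degs <- function(expr, sheet, stratum = c("severe", "moderate"),
                       direction = c("both", "up", "down"), eps = 0.1) {
  stratum <- match.arg(stratum)
  direction <- match.arg(direction)
  ipf <- sheet[sheet$group == "IPF", , drop = FALSE]
  sel <- if (stratum == "severe") ipf$ashcroft_score >= 6 else
    ipf$ashcroft_score < 6
  ids <- ipf$sample_id[sel]
  ids <- intersect(ids, colnames(expr$values))
  if (!length(ids)) stop("no IPF samples in stratum '", stratum, "'")
  tab <- rank_upregulated(expr, sheet, ids, "control", eps = eps,
                          test_mode = NULL)
  lr <- tab$log2_ratio[!is.na(tab$log2_ratio)]
  switch(direction,
         both = sum(abs(lr) > 1),
         up = sum(lr > 1),
         down = sum(lr < -1))
}
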