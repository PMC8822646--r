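# expression scale used for gene selection and voting; the +-1 selection
# threshold means "twofold" only on the log2 scale, which is the default
voting_scale <- function(expr, scale = c("log2", "rpkm"), pseudocount = 1) {
  scale <- match.arg(scale)
  if (scale == "log2" && !expr$log_transformed)
    expr <- log2_transform(expr, pseudocount)
  expr
}

#' Signal-to-noise statistic of one gene between two classes
#'
#' \deqn{S_x = (\mu_{pos} - \mu_{neg}) / (\sigma_{pos} + \sigma_{neg})}
#' the per-gene weight of the weighted-voting classifier. Positive class is
#' the severe stratum (Ashcroft >= 6).
#'
#' @param values_pos,values_neg per-sample expression of the gene in each
#'   class; at least two values per class.
#' @param sd_type `"population"` (default) or `"sample"` SD.
#' @return The signal-to-noise ratio, a single number.
#' @export
signal_to_noise <- function(values_pos, values_neg,
                            sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(values_pos) < 2L || length(values_neg) < 2L)
    stop("each class needs at least two values")
  sdfun <- if (sd_type == "population") sd_pop else stats::sd
  s <- sdfun(values_pos) + sdfun(values_neg)
  if (s <= 0) stop("degenerate gene: both class SDs are zero")
  (mean(values_pos) - mean(values_neg)) / s
}

# training-stratum sample ids of one patient, split at Ashcroft 6
training_strata <- function(sheet, training_patient) {
  tr <- sheet[sheet$patient_id == training_patient, , drop = FALSE]
  if (!nrow(tr)) stop("unknown training patient: ", training_patient)
  if (any(is.na(tr$ashcroft_score)))
    stop("training patient has samples without Ashcroft score")
  pos <- tr$sample_id[tr$ashcroft_score >= 6]
  neg <- tr$sample_id[tr$ashcroft_score < 6]
  if (length(pos) < 2L || length(neg) < 2L)
    stop("training patient needs >= 2 samples in each Ashcroft stratum ",
         "(has ", length(pos), " severe, ", length(neg), " non-severe)")
  list(pos = pos, neg = neg)
}

#' Select induced and suppressed genes from one patient's strata
#'
#' Genes whose class-mean difference (severe minus non-severe stratum of
#' the training patient) exceeds `+threshold` are "induced"; below
#' `-threshold`, "suppressed"; all others are unselected.
#'
#' @param expr an `expression_matrix`.
#' @param sheet a `sample_sheet`.
#' @param training_patient patient id with >= 2 samples in each stratum.
#' @param threshold mean-difference cut, default 1 (twofold on the default
#'   log2 scale).
#' @param scale `"log2"` (default) or `"rpkm"` expression scale.
#' @return List with character vectors `induced` and `suppressed`.
#' @export
select_genes <- function(expr, sheet, training_patient, threshold = 1,
                         scale = c("log2", "rpkm")) {
  stopifnot(inherits(expr, "expression_matrix"))
  expr <- voting_scale(expr, scale)
  st <- training_strata(sheet, training_patient)
  mu_pos <- rowMeans(expr$values[, st$pos, drop = FALSE])
  mu_neg <- rowMeans(expr$values[, st$neg, drop = FALSE])
  diff <- mu_pos - mu_neg
  list(induced = names(diff)[diff > threshold],
       suppressed = names(diff)[diff < -threshold])
}

#' Fit the signal-to-noise weighted-voting model
#'
#' Selects induced/suppressed genes on the training patient's Ashcroft
#' strata, then stores for each selected gene the weight
#' \eqn{S_x = (\mu_{\ge 6} - \mu_{<6})/(\sigma_{\ge 6} + \sigma_{<6})} and
#' the decision boundary \eqn{b_x = (\mu_{\ge 6} + \mu_{<6})/2}, both
#' computed on the training patient's samples only.
#'
#' @inheritParams select_genes
#' @param sd_type SD convention for \eqn{S_x}.
#' @return A `weighted_voting_model`: data frame gene_id, class_label, s, b
#'   with training metadata attributes.
#' @export
fit_model <- function(expr, sheet, training_patient, threshold = 1,
                      scale = c("log2", "rpkm"),
                      sd_type = c("population", "sample")) {
  stopifnot(inherits(expr, "expression_matrix"))
  scale <- match.arg(scale)
  sd_type <- match.arg(sd_type)
  sexpr <- voting_scale(expr, scale)
  st <- training_strata(sheet, training_patient)
  sel <- select_genes(expr, sheet, training_patient, threshold, scale)
  genes <- c(sel$induced, sel$suppressed)
  if (!length(genes)) stop("no genes cross the selection threshold")
  pos <- sexpr$values[genes, st$pos, drop = FALSE]
  neg <- sexpr$values[genes, st$neg, drop = FALSE]
  s <- vapply(seq_along(genes), function(i)
    signal_to_noise(pos[i, ], neg[i, ], sd_type), numeric(1L))
  b <- (rowMeans(pos) + rowMeans(neg)) / 2
  model <- data.frame(
    gene_id = genes,
    class_label = rep(c("induced", "suppressed"),
                      c(length(sel$induced), length(sel$suppressed))),
    s = s, b = unname(b), stringsAsFactors = FALSE, row.names = NULL)
  structure(model,
            class = c("weighted_voting_model", "data.frame"),
            training_patient = training_patient,
            training_samples = st, threshold = threshold,
            scale = scale, sd_type = sd_type)
}

#' Score samples with a fitted weighted-voting model
#'
#' Each model gene casts a vote \eqn{V_x = S_x (g_x - b_x)} from the
#' sample's expression \eqn{g_x}; the summed vote's sign predicts the
#' class: severe (Ashcroft >= 6) when positive, non-severe otherwise. An
#' exactly zero total is called non-severe and flagged as a tie.
#'
#' @param model a `weighted_voting_model`.
#' @param expr an `expression_matrix` containing every model gene.
#' @param sample_ids samples to score, default all columns of `expr`.
#' @return A `voting_scores` data frame: sample_id, total_score, predicted
#'   (`"severe"`/`"non_severe"`), tie; per-gene votes attached as attribute
#'   `"votes"` (genes x samples).
#' @export
score_samples <- function(model, expr, sample_ids = NULL) {
  stopifnot(inherits(model, "weighted_voting_model"),
            inherits(expr, "expression_matrix"))
  expr <- voting_scale(expr, attr(model, "scale"))
  if (is.null(sample_ids)) sample_ids <- colnames(expr$values)
  miss <- setdiff(sample_ids, colnames(expr$values))
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  missg <- setdiff(model$gene_id, rownames(expr$values))
  if (length(missg))
    stop("model genes absent from expression matrix: ",
         paste(missg, collapse = ", "))
  g <- expr$values[model$gene_id, sample_ids, drop = FALSE]
  votes <- model$s * sweep(g, 1L, model$b)
  total <- colSums(votes)
  if (any(total == 0)) warning("tie (total score 0) for sample(s): ",
                               paste(sample_ids[total == 0], collapse = ", "))
  out <- data.frame(sample_id = sample_ids, total_score = unname(total),
                    predicted = ifelse(total > 0, "severe", "non_severe"),
                    tie = total == 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("voting_scores", "data.frame")
  attr(out, "votes") <- votes
  out
}

#' Confusion table and accuracy of voting predictions
#'
#' Compares predicted classes against the true Ashcroft stratum (severe iff
#' score >= 6) from the sample sheet.
#'
#' @param scores a `voting_scores` data frame.
#' @param sheet a `sample_sheet` with Ashcroft scores for every scored
#'   sample.
#' @return List with `confusion` (2x2 table truth x prediction) and
#'   `accuracy`.
#' @export
evaluate_model <- function(scores, sheet) {
  stopifnot(inherits(scores, "voting_scores"))
  idx <- match(scores$sample_id, sheet$sample_id)
  if (any(is.na(idx)))
    stop("scored samples missing from sheet: ",
         paste(scores$sample_id[is.na(idx)], collapse = ", "))
  sc <- sheet$ashcroft_score[idx]
  if (any(is.na(sc)))
    stop("unknown Ashcroft stratum for sample(s): ",
         paste(scores$sample_id[is.na(sc)], collapse = ", "))
  truth <- factor(ifelse(sc >= 6, "severe", "non_severe"),
                  levels = c("non_severe", "severe"))
  pred <- factor(scores$predicted, levels = c("non_severe", "severe"))
  confusion <- table(truth = truth, predicted = pred)
  list(confusion = confusion,
       accuracy = mean(as.character(truth) == as.character(pred)))
}

#' Write a voting model as a plain tabular file
#'
#' @param model a `weighted_voting_model`.
#' @param path output TSV path.
#' @export
write_voting_model <- function(model, path) {
  stopifnot(inherits(model, "weighted_voting_model"))
  write_result_table(as.data.frame(model), path)
}

#' Read a voting model written by [write_voting_model()]
#'
#' @param path model TSV path.
#' @param scale,sd_type metadata to attach (not stored in the table body).
#' @return A `weighted_voting_model`.
#' @export
read_voting_model <- function(path, scale = "log2",
                              sd_type = "population") {
  df <- read_delim_checked(path, "\t")
  need <- c("gene_id", "class_label", "s", "b")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("model file missing columns: ", paste(miss, collapse = ", "))
  structure(df[, need], class = c("weighted_voting_model", "data.frame"),
            scale = scale, sd_type = sd_type)
}
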