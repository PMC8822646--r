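#' Construct an expression matrix
#'
#' @param values non-negative numeric matrix (genes x samples) with dimnames.
#' @param log_transformed whether values are on the log2 scale.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, log_transformed = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression values must carry gene rownames and sample colnames")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (!log_transformed && any(values < 0))
    stop("RPKM values must be non-negative")
  structure(list(values = values, log_transformed = log_transformed),
            class = "expression_matrix")
}

#' RPKM normalization of panel read counts
#'
#' Reads per kilobase of transcript per million mapped reads:
#' \deqn{RPKM_{gs} = counts_{gs} \times 10^9 / (L_g \times N_s)}
#' with \eqn{L_g} the transcript length in bp and \eqn{N_s} the sample's
#' total mapped-read count (library-wide, not the panel column sum).
#'
#' @param counts a `count_matrix`.
#' @param panel a `gene_panel` supplying transcript lengths; every gene in
#'   `counts` must be present.
#' @return An `expression_matrix` of RPKM values.
#' @export
compute_rpkm <- function(counts, panel) {
  stopifnot(inherits(counts, "count_matrix"), inherits(panel, "gene_panel"))
  genes <- rownames(counts$counts)
  miss <- setdiff(genes, panel$gene_id)
  if (length(miss))
    stop("genes absent from panel: ", paste(utils::head(miss, 5L),
                                            collapse = ", "))
  if (any(counts$mapped_total <= 0)) stop("zero mapped total")
  len <- panel$transcript_length_bp[match(genes, panel$gene_id)]
  rpkm <- counts$counts * 1e9 /
    outer(as.numeric(len), as.numeric(counts$mapped_total))
  dimnames(rpkm) <- dimnames(counts$counts)
  expression_matrix(rpkm, log_transformed = FALSE)
}

#' Restrict to the clinically-targetable kinase subpanel
#'
#' Keeps the inhibitor-flagged genes of the panel, then drops flagged genes
#' whose per-gene summary RPKM falls below the overall median RPKM of the
#' full matrix (all gene x sample entries pooled). The summary across
#' samples is the median by default; the mean is selectable since neither
#' convention is canonical.
#'
#' @param expr an `expression_matrix`, not log-transformed.
#' @param panel a `gene_panel`.
#' @param summary per-gene summary across samples, `"median"` or `"mean"`.
#' @return The surviving subpanel `expression_matrix`; the exclusion report
#'   (data frame gene/reason) is attached as attribute `"excluded"`.
#' @export
filter_inhibitor_subpanel <- function(expr, panel,
                                      summary = c("median", "mean")) {
  stopifnot(inherits(expr, "expression_matrix"))
  summary <- match.arg(summary)
  if (expr$log_transformed)
    stop("subpanel filtering operates on raw RPKM, not log values")
  flagged <- panel$gene_id[panel$inhibitor_available]
  flagged <- flagged[flagged %in% rownames(expr$values)]
  if (!length(flagged))
    stop("no inhibitor-flagged genes present in the expression matrix")
  # the threshold is defined against the full panel matrix; a previously
  # filtered subpanel carries it along, making the filter idempotent
  overall_median <- attr(expr, "overall_median")
  if (is.null(overall_median)) overall_median <- stats::median(expr$values)
  fun <- if (summary == "median") stats::median else mean
  per_gene <- apply(expr$values[flagged, , drop = FALSE], 1L, fun)
  keep <- flagged[per_gene >= overall_median]
  drop <- flagged[per_gene < overall_median]
  if (!length(keep)) stop("no subpanel genes survive the median filter")
  out <- expression_matrix(expr$values[keep, , drop = FALSE])
  attr(out, "excluded") <- data.frame(
    gene_id = drop,
    reason = if (length(drop))
      sprintf("%s RPKM %.4g below overall median %.4g", summary,
              per_gene[drop], overall_median) else character(0),
    stringsAsFactors = FALSE
  )
  attr(out, "overall_median") <- overall_median
  out
}

#' Log2-transform an expression matrix
#'
#' @param expr an `expression_matrix`, not already log-transformed.
#' @param pseudocount positive offset added before taking log2.
#' @return An `expression_matrix` with `log_transformed = TRUE`.
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$log_transformed) stop("matrix is already log-transformed")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive")
  expression_matrix(log2(expr$values + pseudocount), log_transformed = TRUE)
}
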