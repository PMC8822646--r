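# reserved row label carrying per-sample mapped-library totals in count files
TOTALS_ROW <- "mapped_total"

#' Construct a gene panel annotation table
#'
#' The panel describes the genes captured by the targeted kinome assay:
#' gene symbol, transcript length (the RPKM length denominator), a category,
#' and a flag marking kinases with a clinically available inhibitor.
#'
#' @param gene_id character vector of unique gene symbols.
#' @param transcript_length_bp positive integer transcript lengths in bp.
#' @param category one of `"kinase"`, `"cancer_related"`, `"other"` per gene.
#' @param inhibitor_available logical flag per gene.
#' @return A `gene_panel` data frame.
#' @export
gene_panel <- function(gene_id, transcript_length_bp, category,
                       inhibitor_available) {
  df <- data.frame(
    gene_id = as.character(gene_id),
    transcript_length_bp = as.integer(transcript_length_bp),
    category = as.character(category),
    inhibitor_available = as.logical(inhibitor_available),
    stringsAsFactors = FALSE
  )
  validate_gene_panel(df)
  class(df) <- c("gene_panel", "data.frame")
  df
}

validate_gene_panel <- function(df) {
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    stop("duplicate gene ids in panel: ", paste(dup, collapse = ", "))
  if (any(is.na(df$transcript_length_bp)) || any(df$transcript_length_bp < 1))
    stop("transcript_length_bp must be a positive integer for every gene")
  bad <- setdiff(unique(df$category), c("kinase", "cancer_related", "other"))
  if (length(bad))
    stop("unknown panel category: ", paste(bad, collapse = ", "))
  if (any(is.na(df$inhibitor_available)))
    stop("inhibitor_available may not be missing")
  invisible(df)
}

#' Read a gene panel table from a delimited file
#'
#' @param path file with columns `gene_id`, `transcript_length_bp`,
#'   `category`, `inhibitor_available`.
#' @param delim field delimiter, tab by default.
#' @return A `gene_panel` data frame.
#' @export
read_gene_panel <- function(path, delim = "\t") {
  df <- read_delim_checked(path, delim)
  need <- c("gene_id", "transcript_length_bp", "category",
            "inhibitor_available")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene panel file missing columns: ", paste(miss, collapse = ", "))
  gene_panel(df$gene_id, df$transcript_length_bp, df$category,
             as_flag(df$inhibitor_available))
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Construct a sample sheet
#'
#' Per-sample annotations: patient of origin, IPF/control group, Ashcroft
#' fibrosis score (0-8; may be missing only for control samples) and a free
#' anatomical segment label.
#'
#' @param sample_id unique sample identifiers.
#' @param patient_id patient identifiers; each patient belongs to one group.
#' @param group `"IPF"` or `"control"` (case-insensitive on input).
#' @param ashcroft_score integer 0-8, `NA` allowed for controls only.
#' @param segment_label free-text anatomical label.
#' @return A `sample_sheet` data frame.
#' @export
sample_sheet <- function(sample_id, patient_id, group, ashcroft_score,
                         segment_label = "") {
  grp <- normalize_group(group)
  df <- data.frame(
    sample_id = as.character(sample_id),
    patient_id = as.character(patient_id),
    group = grp,
    ashcroft_score = suppressWarnings(as.integer(ashcroft_score)),
    segment_label = as.character(segment_label),
    stringsAsFactors = FALSE
  )
  validate_sample_sheet(df)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

normalize_group <- function(group) {
  g <- tolower(trimws(as.character(group)))
  out <- ifelse(g == "ipf", "IPF", ifelse(g == "control", "control", NA))
  if (any(is.na(out)))
    stop("unknown group label: ",
         paste(unique(group[is.na(out)]), collapse = ", "),
         " (expected IPF or control)")
  out
}

validate_sample_sheet <- function(df) {
  if (nrow(df) == 0L) stop("no samples in sample sheet")
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  ipf_na <- df$sample_id[df$group == "IPF" & is.na(df$ashcroft_score)]
  if (length(ipf_na))
    stop("IPF samples with missing Ashcroft score: ",
         paste(ipf_na, collapse = ", "))
  sc <- df$ashcroft_score[!is.na(df$ashcroft_score)]
  if (any(sc < 0 | sc > 8))
    stop("Ashcroft scores must lie in 0-8")
  gp <- unique(df[, c("patient_id", "group")])
  bad <- gp$patient_id[duplicated(gp$patient_id)]
  if (length(bad))
    stop("patient assigned to both groups: ", paste(bad, collapse = ", "))
  invisible(df)
}

#' Read a sample sheet from a delimited file
#'
#' @inheritParams read_gene_panel
#' @return A `sample_sheet` data frame.
#' @export
read_sample_sheet <- function(path, delim = "\t") {
  df <- read_delim_checked(path, delim)
  need <- c("sample_id", "patient_id", "group", "ashcroft_score",
            "segment_label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("no samples in sample sheet")
  sample_sheet(df$sample_id, df$patient_id, df$group, df$ashcroft_score,
               df$segment_label)
}

#' Construct a count matrix with mapped-library totals
#'
#' Raw integer read counts (genes x samples) plus each sample's total
#' mapped-read count. The totals are carried explicitly because a targeted
#' panel captures only a subset of the library, so the per-million
#' denominator of RPKM cannot be recovered from panel column sums.
#'
#' @param counts non-negative integer matrix with gene rownames and sample
#'   colnames.
#' @param mapped_total named positive numeric vector, one entry per sample.
#' @return A `count_matrix` object (list with `counts` and `mapped_total`).
#' @export
count_matrix <- function(counts, mapped_total) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  dupg <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dupg)) stop("duplicate gene ids: ", paste(dupg, collapse = ", "))
  dups <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dups))
    stop("duplicate sample ids: ", paste(dups, collapse = ", "))
  check_counts_integral(counts)
  if (is.null(names(mapped_total)))
    names(mapped_total) <- colnames(counts)
  miss <- setdiff(colnames(counts), names(mapped_total))
  if (length(miss))
    stop("missing mapped totals for samples: ", paste(miss, collapse = ", "))
  mapped_total <- mapped_total[colnames(counts)]
  if (any(is.na(mapped_total)) || any(mapped_total <= 0))
    stop("mapped totals must be positive for every sample")
  over <- colnames(counts)[colSums(counts) > mapped_total]
  if (length(over))
    stop("panel counts exceed mapped total for samples: ",
         paste(over, collapse = ", "))
  structure(list(counts = counts, mapped_total = mapped_total),
            class = "count_matrix")
}

check_counts_integral <- function(counts) {
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    cells <- apply(bad[seq_len(min(5L, nrow(bad))), , drop = FALSE], 1L,
                   function(ij) sprintf("(%s, %s)", rownames(counts)[ij[1]],
                                        colnames(counts)[ij[2]]))
    stop("counts must be non-negative integers; offending cells: ",
         paste(cells, collapse = ", "))
  }
  invisible(counts)
}

#' Read a count matrix from a delimited file
#'
#' First column gene ids, header row sample ids. Mapped-library totals are
#' supplied either as a reserved row named `mapped_total` inside the file or
#' through `totals_path`, a two-column sidecar (`sample_id`, `mapped_total`).
#' Totals are never silently substituted by panel column sums.
#'
#' @param path count file.
#' @param delim field delimiter.
#' @param totals_path optional sidecar file with mapped totals.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(path, delim = "\t", totals_path = NULL) {
  df <- read_delim_checked(path, delim)
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  colnames(mat) <- names(df)[-1L]  # keep duplicates visible to validation
  rownames(mat) <- ids
  if (!is.null(totals_path)) {
    tt <- read_delim_checked(totals_path, delim)
    if (!all(c("sample_id", "mapped_total") %in% names(tt)))
      stop("totals sidecar needs columns sample_id and mapped_total")
    totals <- stats::setNames(as.numeric(tt$mapped_total),
                              as.character(tt$sample_id))
  } else if (TOTALS_ROW %in% ids) {
    totals <- mat[TOTALS_ROW, ]
    mat <- mat[ids != TOTALS_ROW, , drop = FALSE]
  } else {
    stop("mapped totals not found: supply a '", TOTALS_ROW,
         "' row or a totals sidecar file")
  }
  storage.mode(mat) <- "double"
  count_matrix(mat, totals)
}

read_delim_checked <- function(path, delim) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a result table with deterministic order and fixed precision
#'
#' @param table non-empty data frame.
#' @param path output path.
#' @param delim field delimiter.
#' @param sort_by optional column name to sort on (descending for numeric
#'   columns, ascending otherwise); by default rows are written as given.
#' @param digits significant digits for floating-point columns.
#' @export
write_result_table <- function(table, path, delim = "\t", sort_by = NULL,
                               digits = 6L) {
  table <- as.data.frame(table)
  if (nrow(table) == 0L) stop("refusing to write an empty result table")
  if (!is.null(sort_by)) {
    if (!sort_by %in% names(table)) stop("unknown sort column: ", sort_by)
    key <- table[[sort_by]]
    ord <- if (is.numeric(key)) order(-key, table[[1L]]) else order(key)
    table <- table[ord, , drop = FALSE]
  }
  num <- vapply(table, is.double, logical(1L))
  table[num] <- lapply(table[num], signif, digits = digits)
  ok <- tryCatch({
    utils::write.table(table, path, sep = delim, quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("could not write table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Write a count matrix (with its totals row) to a delimited file
#'
#' @param cm a `count_matrix`.
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_count_matrix <- function(cm, path, delim = "\t") {
  stopifnot(inherits(cm, "count_matrix"))
  mat <- rbind(cm$counts, matrix(cm$mapped_total, nrow = 1L,
                                 dimnames = list(TOTALS_ROW, NULL)))
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}
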