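# population (divide-by-n) standard deviation; the convention of the
# clustering software the analysis follows
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Median-centre and SD-scale an expression matrix for clustering
#'
#' Two-step adjustment: (1) subtract each sample's median from its column;
#' (2) divide each gene row by that gene's standard deviation computed
#' across all samples of the centred matrix. Genes whose centred row has
#' zero variance are dropped with a warning rather than producing
#' infinities.
#'
#' @param expr an `expression_matrix`.
#' @param sd_type `"population"` (divide by n, default) or `"sample"` (n-1).
#' @param sd_scope `"per_gene"` (default) scales each row by its own SD;
#'   `"pooled"` divides the whole centred matrix by its single pooled SD.
#' @return An `adjusted_matrix`: list with `values`, `centering_record`
#'   (per-sample median subtracted), `scaling_record` (per-gene divisor),
#'   `dropped_genes`.
#' @export
adjust_matrix <- function(expr, sd_type = c("population", "sample"),
                          sd_scope = c("per_gene", "pooled")) {
  stopifnot(inherits(expr, "expression_matrix"))
  sd_type <- match.arg(sd_type)
  sd_scope <- match.arg(sd_scope)
  x <- expr$values
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("adjustment requires at least 2 genes and 2 samples")
  med <- apply(x, 2L, stats::median)
  centred <- sweep(x, 2L, med)
  sdfun <- if (sd_type == "population") sd_pop else stats::sd
  if (sd_scope == "per_gene") {
    divisor <- apply(centred, 1L, sdfun)
  } else {
    divisor <- rep(sdfun(as.vector(centred)), nrow(centred))
    names(divisor) <- rownames(centred)
  }
  zero <- divisor <= 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance gene(s): ",
            paste(utils::head(rownames(centred)[zero], 5L), collapse = ", "))
    centred <- centred[!zero, , drop = FALSE]
    divisor <- divisor[!zero]
  }
  if (nrow(centred) == 0L) stop("no genes left after dropping zero variance")
  structure(list(values = centred / divisor,
                 centering_record = med,
                 scaling_record = divisor,
                 dropped_genes = rownames(x)[zero],
                 sd_type = sd_type, sd_scope = sd_scope),
            class = "adjusted_matrix")
}

# pairwise distances between sample columns
sample_distances <- function(values, distance) {
  n <- ncol(values)
  d <- matrix(0, n, n, dimnames = list(colnames(values), colnames(values)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- values[, i]; b <- values[, j]
    dij <- switch(distance,
      uncentered = 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
      pearson = 1 - stats::cor(a, b),
      euclidean = sqrt(sum((a - b)^2))
    )
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Agglomerative hierarchical clustering of samples
#'
#' Clusters the sample columns of an adjusted matrix. Defaults follow the
#' common settings of classic gene-expression clustering software:
#' uncentered Pearson correlation distance with average linkage. Merging is
#' deterministic: on equal merge distances the pair containing the
#' lexicographically smallest leaf-id pair merges first.
#'
#' @param adj an `adjusted_matrix` (or `expression_matrix`).
#' @param distance `"uncentered"`, `"pearson"` or `"euclidean"`.
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @param k optional number of flat clusters to cut; labels attached as
#'   `$labels_k`.
#' @return A `sample_dendrogram`: list with an [stats::hclust]-compatible
#'   tree (`$hclust`), `distance`, `linkage`, and flat labels when `k` is
#'   given.
#' @export
cluster_samples <- function(adj, distance = c("uncentered", "pearson",
                                              "euclidean"),
                            linkage = c("average", "single", "complete"),
                            k = NULL) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  values <- if (inherits(adj, "adjusted_matrix") ||
                inherits(adj, "expression_matrix")) adj$values else
    as.matrix(adj)
  n <- ncol(values)
  if (n < 2L) stop("clustering requires at least 2 samples")
  d <- sample_distances(values, distance)
  hc <- agglomerate(d, linkage)
  out <- structure(list(hclust = hc, distance = distance, linkage = linkage),
                   class = "sample_dendrogram")
  if (!is.null(k)) out$labels_k <- stats::cutree(hc, k = k)
  out
}

# deterministic agglomeration over a distance matrix; cluster-cluster
# distances are recomputed from the original matrix each step, so average
# linkage is the plain mean over all original leaf pairs (UPGMA)
agglomerate <- function(d, linkage) {
  labels <- rownames(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))        # leaf indices per active cluster
  node_id <- -seq_len(n)                # hclust convention
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  linkfun <- switch(linkage, average = mean, single = min, complete = max)
  for (step in seq_len(n - 1L)) {
    m <- length(members)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dij <- linkfun(d[members[[i]], members[[j]]])
      key <- sort(labels[c(members[[i]], members[[j]])])
      better <- dij < best_d - 1e-12 ||
        (abs(dij - best_d) <= 1e-12 && !is.null(best_key) &&
           lex_less(key, best_key))
      if (is.null(best) || better) {
        best <- c(i, j); best_d <- dij; best_key <- key
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(node_id[i], node_id[j]))
    height[step] <- best_d
    members[[i]] <- c(members[[i]], members[[j]])
    node_id[i] <- step
    members[[j]] <- NULL
    node_id <- node_id[-j]
  }
  hc <- list(merge = merge, height = height,
             order = hclust_order(merge, n), labels = labels,
             method = linkage, call = match.call(),
             dist.method = "custom")
  class(hc) <- "hclust"
  hc
}

lex_less <- function(a, b) {
  for (k in seq_len(min(length(a), length(b)))) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  length(a) < length(b)
}

hclust_order <- function(merge, n) {
  leaves <- function(node) {
    if (node < 0L) return(-node)
    c(leaves(merge[node, 1L]), leaves(merge[node, 2L]))
  }
  leaves(n - 1L)
}

#' Chance-adjusted agreement between two flat partitions
#'
#' Adjusted Rand index: 1 iff the labelings are identical up to renaming,
#' approximately 0 in expectation for unrelated labelings (slightly
#' negative values can occur by chance).
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return Numeric agreement score.
#' @export
compare_partitions <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings differ in length")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Export a dendrogram in Newick format
#'
#' Merge heights become branch lengths via [ape::as.phylo].
#'
#' @param dendro a `sample_dendrogram`.
#' @param path output file.
#' @export
write_newick <- function(dendro, path) {
  stopifnot(inherits(dendro, "sample_dendrogram"))
  ape::write.tree(ape::as.phylo(dendro$hclust), file = path)
  invisible(path)
}

#' Export a dendrogram as a merge table
#'
#' One row per merge: the two child node ids (negative = leaf index) and the
#' merge height.
#'
#' @param dendro a `sample_dendrogram`.
#' @param path output file.
#' @export
write_merge_table <- function(dendro, path) {
  stopifnot(inherits(dendro, "sample_dendrogram"))
  hc <- dendro$hclust
  df <- data.frame(child_a = hc$merge[, 1L], child_b = hc$merge[, 2L],
                   height = hc$height)
  write_result_table(df, path)
}
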