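# Independent brute-force oracles: plain nested loops, no shared code with
# the implementation paths they check.

pop_sd <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / length(x))

oracle_rpkm <- function(counts, lengths_bp, totals) {
  out <- counts * NA_real_
  for (g in seq_len(nrow(counts))) for (s in seq_len(ncol(counts)))
    out[g, s] <- counts[g, s] * 1e9 / (lengths_bp[g] * totals[s])
  out
}

oracle_adjust <- function(x) {
  cen <- x
  for (s in seq_len(ncol(x))) cen[, s] <- x[, s] - stats::median(x[, s])
  keep <- rep(TRUE, nrow(cen))
  out <- cen
  for (g in seq_len(nrow(cen))) {
    sdg <- pop_sd(cen[g, ])
    if (sdg <= 0) keep[g] <- FALSE else out[g, ] <- cen[g, ] / sdg
  }
  out[keep, , drop = FALSE]
}

oracle_diversity <- function(x, patient_of) {
  pts <- unique(patient_of)
  pts <- pts[vapply(pts, function(p) sum(patient_of == p) >= 2L, logical(1))]
  rows <- list()
  for (p in pts) for (g in rownames(x)) {
    v <- x[g, patient_of == p]
    sdg <- pop_sd(x[g, ])
    if (sdg > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p, gene_id = g,
        scaled_range = (max(v) - min(v)) / sdg,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

oracle_log2_ratio <- function(x, case_cols, ref_cols, eps) {
  out <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    mc <- sum(x[g, case_cols]) / length(case_cols)
    mr <- sum(x[g, ref_cols]) / length(ref_cols)
    out[g] <- log2((mc + eps) / (mr + eps))
  }
  stats::setNames(out, rownames(x))
}

# S_x, b_x on training columns and summed votes on test columns
oracle_voting <- function(x, pos_cols, neg_cols, test_cols) {
  genes <- rownames(x)
  s <- b <- stats::setNames(numeric(length(genes)), genes)
  for (g in genes) {
    mp <- mean(x[g, pos_cols]); mn <- mean(x[g, neg_cols])
    s[g] <- (mp - mn) / (pop_sd(x[g, pos_cols]) + pop_sd(x[g, neg_cols]))
    b[g] <- (mp + mn) / 2
  }
  totals <- stats::setNames(numeric(length(test_cols)), test_cols)
  for (tc in test_cols) {
    tot <- 0
    for (g in genes) tot <- tot + s[g] * (x[g, tc] - b[g])
    totals[tc] <- tot
  }
  list(s = s, b = b, totals = totals)
}

# agglomeration oracle: partitions held as explicit index sets, cluster
# distances recomputed as explicit double loops over original leaf pairs
oracle_merge_heights <- function(d, linkage = "average") {
  clusters <- lapply(seq_len(nrow(d)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf
    bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        vals <- c()
        for (a in clusters[[i]]) for (b in clusters[[j]])
          vals <- c(vals, d[a, b])
        dd <- switch(linkage, average = mean(vals), single = min(vals),
                     complete = max(vals))
        if (dd < best) { best <- dd; bi <- i; bj <- j }
      }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# --- small fixtures ------------------------------------------------------

toy_panel <- function(genes, lengths = rep(1000L, length(genes)),
                      inhibitor = rep(FALSE, length(genes))) {
  gene_panel(genes, lengths, rep("kinase", length(genes)), inhibitor)
}

toy_expr <- function(values, log = FALSE) {
  expression_matrix(values, log_transformed = log)
}

# sheet matching the study layout used across tests
study_sheet <- function() {
  sample_sheet(
    sample_id = c(paste0("IPF1_S", 1:6), paste0("IPF2_S", 1:3),
                  paste0("IPF3_S", 1:2), "IPF4_S1", "IPF5_S1",
                  paste0("CTL", rep(1:4, each = 2), "_S", rep(1:2, 4))),
    patient_id = c(rep("IPF1", 6), rep("IPF2", 3), rep("IPF3", 2),
                   "IPF4", "IPF5", rep(paste0("CTL", 1:4), each = 2)),
    group = c(rep("IPF", 13), rep("control", 8)),
    ashcroft_score = c(7, 6, 6, 5, 4, 3, 7, 6, 5, 7, 5, 4, 3,
                       rep(NA, 8)),
    segment_label = "seg")
}

# generator settings used by the recovery-style tests (see vignette):
# deep totals + tight dispersion so count noise does not masquerade as
# biological noise
low_noise_config <- function(...) {
  simulation_config(segment_sd_log2 = 0.2, ipf_heterogeneity = 1,
                    nb_dispersion = 0.01,
                    mapped_total_range = c(1e7, 1e7), ...)
}

# strong severity signature: the planted stratum dominates the variance
strong_effect_config <- function(...) {
  simulation_config(effect_log2 = 3, n_induced = 60L, n_suppressed = 30L,
                    patient_sd_log2 = 0.05, segment_sd_log2 = 0.2,
                    ipf_heterogeneity = 1, nb_dispersion = 0.01, ...)
}

sim_rpkm <- function(cfg, seed) {
  d <- simulate_dataset(cfg, seed = seed)
  d$expr <- compute_rpkm(d$counts, d$panel)
  d
}
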