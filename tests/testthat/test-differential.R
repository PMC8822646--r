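# expression fixture: deterministic group means, named samples
two_group_expr <- function(vals_case, vals_ref, genes = NULL) {
  m <- cbind(vals_case, vals_ref)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  dimnames(m) <- list(genes, c(paste0("case", seq_len(ncol(vals_case))),
                               paste0("ref", seq_len(ncol(vals_ref)))))
  toy_expr(m)
}

two_group_sheet <- function(n_case, n_ref, ashcroft = 7) {
  sample_sheet(c(paste0("case", 1:n_case), paste0("ref", 1:n_ref)),
               c(paste0("casep", 1:n_case), paste0("refp", 1:n_ref)),
               rep(c("IPF", "control"), c(n_case, n_ref)),
               c(rep(ashcroft, n_case), rep(NA, n_ref)), "seg")
}

test_that("log2 ratios follow the closed form and twofold rule", {
  e <- two_group_expr(matrix(c(8, 5), 2, 2), matrix(c(2, 5), 2, 2))
  sheet <- two_group_sheet(2, 2)
  tab <- rank_upregulated(e, sheet, "IPF", "control", eps = 0,
                          test_mode = NULL)
  expect_equal(tab$log2_ratio[tab$gene_id == "g1"], 2)
  expect_true(tab$passes_twofold[tab$gene_id == "g1"])
  expect_equal(tab$log2_ratio[tab$gene_id == "g2"], 0)
  expect_false(tab$passes_twofold[tab$gene_id == "g2"])
})

test_that("ranking equals a brute-force recomputation on a random instance", {
  set.seed(21)
  e <- two_group_expr(matrix(rlnorm(50 * 3, 2), 50), matrix(rlnorm(50 * 3, 2), 50))
  sheet <- two_group_sheet(3, 3)
  tab <- rank_upregulated(e, sheet, "IPF", "control", eps = 0.1,
                          test_mode = NULL)
  want <- oracle_log2_ratio(e$values, paste0("case", 1:3),
                            paste0("ref", 1:3), eps = 0.1)
  expect_equal(stats::setNames(tab$log2_ratio, tab$gene_id),
               want[tab$gene_id])
  expect_false(is.unsorted(rev(tab$log2_ratio)))  # descending
  top10 <- rank_upregulated(e, sheet, "IPF", "control", eps = 0.1,
                            test_mode = NULL, top_k = 10)
  expect_identical(top10$gene_id,
                   names(sort(want, decreasing = TRUE))[1:10])
})

test_that("ranking is group-order invariant and antisymmetric at eps 0", {
  set.seed(22)
  e <- two_group_expr(matrix(rlnorm(30 * 4, 1), 30),
                      matrix(rlnorm(30 * 2, 1), 30))
  sheet <- two_group_sheet(4, 2)
  t1 <- rank_upregulated(e, sheet, "IPF", "control", test_mode = NULL)
  perm <- e
  perm$values <- perm$values[, c(3, 1, 4, 2, 6, 5)]
  t2 <- rank_upregulated(perm, sheet, "IPF", "control", test_mode = NULL)
  expect_equal(t1$log2_ratio, t2$log2_ratio)

  fwd <- rank_upregulated(e, sheet, "IPF", "control", eps = 0,
                          test_mode = NULL)
  rev_ <- rank_upregulated(e, sheet, "control", "IPF", eps = 0,
                           test_mode = NULL)
  expect_equal(stats::setNames(fwd$log2_ratio, fwd$gene_id)[sort(fwd$gene_id)],
               -stats::setNames(rev_$log2_ratio, rev_$gene_id)[sort(fwd$gene_id)])

  expect_error(rank_upregulated(e, sheet, "IPF", "IPF"), "overlap")
  expect_error(rank_upregulated(e, sheet, character(0), "control"), "empty")
})

test_that("DEG counts recover a planted severe-only signature", {
  genes <- sprintf("g%02d", 1:40)
  base <- matrix(10, 40, 8, dimnames = list(genes, NULL))
  colnames(base) <- c(paste0("sev", 1:2), paste0("mod", 1:2),
                      paste0("ref", 1:4))
  base[1:12, 1:2] <- 30  # 12 genes at 3-fold in the severe stratum only
  sheet <- sample_sheet(colnames(base),
                        c("P1", "P1", "P2", "P2", paste0("C", 1:4)),
                        rep(c("IPF", "control"), c(4, 4)),
                        c(7, 7, 4, 4, rep(NA, 4)), "seg")
  e <- toy_expr(base)
  expect_identical(count_degs(e, sheet, "severe", "both"), 12L)
  expect_identical(count_degs(e, sheet, "severe", "up"), 12L)
  expect_identical(count_degs(e, sheet, "moderate", "both"), 0L)
  # up + down partitions both
  expect_identical(count_degs(e, sheet, "severe", "up") +
                     count_degs(e, sheet, "severe", "down"),
                   count_degs(e, sheet, "severe", "both"))
  # cross-module consistency with the ranking table
  tab <- rank_upregulated(e, sheet, c("sev1", "sev2"), "control",
                          test_mode = NULL)
  expect_identical(sum(abs(tab$log2_ratio) > 1, na.rm = TRUE),
                   as.integer(count_degs(e, sheet, "severe", "both")))
})

test_that("t tests match the textbook formula and behave under the null", {
  # identical groups: t = 0, p = 1
  x <- rbind(g1 = c(1, 2, 3, 1, 2, 3))
  colnames(x) <- paste0("s", 1:6)
  e <- toy_expr(x)
  tt <- two_sample_test(e, paste0("s", 1:3), paste0("s", 4:6),
                        mode = "student")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)

  # hand-computed 3-vs-3 pooled-variance t
  a <- c(4.1, 5.0, 6.3); b <- c(2.0, 2.8, 3.1)
  m2 <- rbind(g1 = c(a, b), g2 = c(b, a))
  colnames(m2) <- paste0("s", 1:6)
  e2 <- toy_expr(m2)
  tt2 <- two_sample_test(e2, paste0("s", 1:3), paste0("s", 4:6),
                         mode = "student")
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(tt2$statistic[1], t_manual, tolerance = 1e-10)
  expect_equal(tt2$p_value[1],
               2 * stats::pt(-abs(t_manual), df = 4), tolerance = 1e-10)

  # paired mode never silently truncates
  expect_error(two_sample_test(e2, paste0("s", 1:3), paste0("s", 4:5),
                               mode = "paired"), "pairing")

  # null p values are uniform
  set.seed(23)
  m <- matrix(rnorm(1000 * 10), 1000,
              dimnames = list(paste0("g", 1:1000), paste0("s", 1:10)))
  en <- toy_expr(m, log = TRUE)
  pn <- two_sample_test(en, paste0("s", 1:5), paste0("s", 6:10))$p_value
  ks <- suppressWarnings(stats::ks.test(pn, "punif")$statistic)
  expect_lt(ks, 0.05)
})
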