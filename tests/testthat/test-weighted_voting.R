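# expression fixtures on the log scale so values pass through unchanged
log_expr <- function(m) toy_expr(m, log = TRUE)

# training sheet: one patient, 3 severe + 3 moderate samples
train_sheet <- function(extra_ids = character(0), extra_pat = character(0),
                        extra_ash = integer(0)) {
  sample_sheet(c(paste0("sev", 1:3), paste0("mod", 1:3), extra_ids),
               c(rep("P1", 6), extra_pat),
               "IPF",
               c(7, 7, 6, 5, 4, 3, extra_ash), "seg")
}

test_that("signal-to-noise follows its closed form", {
  expect_equal(signal_to_noise(c(1.5, 2.5), c(-0.5, 0.5)), 2)
  expect_equal(signal_to_noise(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(signal_to_noise(c(1, 1), c(2, 2)), "degenerate")
  expect_error(signal_to_noise(1, c(2, 3)), "two values")

  set.seed(31)
  for (r in 1:20) {
    p <- rnorm(3); n <- rnorm(3)
    expect_equal(signal_to_noise(p, n),
                 (mean(p) - mean(n)) / (pop_sd(p) + pop_sd(n)),
                 tolerance = 1e-12)
  }
})

test_that("gene selection splits on the +-1 mean-difference threshold", {
  m <- rbind(up = c(rep(1.2, 3), rep(0, 3)),
             dn = c(rep(-1.2, 3), rep(0, 3)),
             flat = c(rep(0.5, 3), rep(0, 3)))
  colnames(m) <- c(paste0("sev", 1:3), paste0("mod", 1:3))
  # within-class spread that sums to zero, so class means stay exact
  m <- sweep(m, 2L, rep(c(-0.05, 0.05, 0), 2), `+`)
  sel <- select_genes(log_expr(m), train_sheet(), "P1", threshold = 1)
  expect_identical(sel$induced, "up")
  expect_identical(sel$suppressed, "dn")

  sel_inf <- select_genes(log_expr(m), train_sheet(), "P1",
                          threshold = Inf)
  expect_identical(length(sel_inf$induced), 0L)
  expect_identical(length(sel_inf$suppressed), 0L)
  expect_error(fit_model(log_expr(m), train_sheet(), "P1",
                         threshold = Inf), "threshold")
})

test_that("fitted weights and boundaries match the formula oracle", {
  # mu_pos = 4 (values 5,3,4 have pop SD sqrt(2/3); use 5,3 for SD 1)
  m <- rbind(g1 = c(5, 3, 4, 1, -1, 0))
  colnames(m) <- c(paste0("sev", 1:3), paste0("mod", 1:3))
  fit <- fit_model(log_expr(m), train_sheet(), "P1")
  # mu_pos 4, mu_neg 0; pop SDs sqrt(2/3) each
  expect_equal(fit$s, 4 / (2 * sqrt(2 / 3)))
  expect_equal(fit$b, 2)
  expect_identical(fit$class_label, "induced")

  set.seed(32)
  m2 <- matrix(rnorm(8 * 6, 0, 2), 8, 6,
               dimnames = list(paste0("g", 1:8),
                               c(paste0("sev", 1:3), paste0("mod", 1:3))))
  fit2 <- fit_model(log_expr(m2), train_sheet(), "P1", threshold = 0.2)
  want <- oracle_voting(m2, paste0("sev", 1:3), paste0("mod", 1:3),
                        character(0))
  expect_equal(stats::setNames(fit2$s, fit2$gene_id),
               want$s[fit2$gene_id], tolerance = 1e-12)
  expect_equal(stats::setNames(fit2$b, fit2$gene_id),
               want$b[fit2$gene_id], tolerance = 1e-12)
  # refitting is deterministic
  expect_identical(fit2, fit_model(log_expr(m2), train_sheet(), "P1",
                                   threshold = 0.2))
  # a stratum with < 2 samples is refused
  bad_sheet <- sample_sheet(colnames(m2), "P1", "IPF",
                            c(7, 5, 5, 5, 4, 3), "seg")
  expect_error(fit_model(log_expr(m2), bad_sheet, "P1"), "2 samples")
})

test_that("votes accumulate as S_x (g_x - b_x) and classify by sign", {
  m <- rbind(g1 = c(2, 0, 1, 0, -2, -1, 3, 1))
  colnames(m) <- c(paste0("sev", 1:3), paste0("mod", 1:3), "t1", "t2")
  sheet <- train_sheet(c("t1", "t2"), c("P2", "P2"), c(7L, 5L))
  fit <- fit_model(log_expr(m), sheet, "P1")
  expect_equal(fit$s, 2 / (2 * pop_sd(c(2, 0, 1))))
  expect_equal(fit$b, 0)
  sc <- score_samples(fit, log_expr(m), c("t1", "t2"))
  expect_equal(sc$total_score, fit$s * (c(3, 1) - fit$b))
  expect_identical(sc$predicted, c("severe", "severe"))

  # one-gene model S=2, b=1 scoring g=3 gives V=4
  model <- structure(data.frame(gene_id = "g1", class_label = "induced",
                                s = 2, b = 1),
                     class = c("weighted_voting_model", "data.frame"),
                     scale = "log2")
  e <- log_expr(matrix(3, 1, 1, dimnames = list("g1", "x")))
  sc1 <- score_samples(model, e, "x")
  expect_equal(sc1$total_score, 4)
  expect_identical(sc1$predicted, "severe")

  # g = b for every gene: total 0, tie resolved to non-severe with warning
  e0 <- log_expr(matrix(1, 1, 1, dimnames = list("g1", "x")))
  expect_warning(sc0 <- score_samples(model, e0, "x"), "tie")
  expect_identical(sc0$predicted, "non_severe")
  expect_true(sc0$tie)

  # missing model gene is an error, never imputed
  e2 <- log_expr(matrix(3, 1, 1, dimnames = list("other", "x")))
  expect_error(score_samples(model, e2, "x"), "g1")
})

test_that("training-label swap negates weights and scores", {
  set.seed(33)
  m <- matrix(rnorm(6 * 8, 0, 2), 6, 8,
              dimnames = list(paste0("g", 1:6),
                              c(paste0("sev", 1:3), paste0("mod", 1:3),
                                "t1", "t2")))
  sheet <- train_sheet(c("t1", "t2"), c("P2", "P2"), c(7L, 4L))
  swapped <- sheet
  swapped$ashcroft_score[1:6] <- c(5, 4, 3, 7, 7, 6)  # invert strata
  f1 <- fit_model(log_expr(m), sheet, "P1", threshold = 0.2)
  f2 <- fit_model(log_expr(m), swapped, "P1", threshold = 0.2)
  common <- intersect(f1$gene_id, f2$gene_id)
  expect_setequal(f1$gene_id, f2$gene_id)
  expect_equal(stats::setNames(f1$s, f1$gene_id)[common],
               -stats::setNames(f2$s, f2$gene_id)[common])
  s1 <- score_samples(f1, log_expr(m), c("t1", "t2"))
  s2 <- score_samples(f2, log_expr(m), c("t1", "t2"))
  expect_equal(s1$total_score, -s2$total_score)
})

test_that("votes are affine-equivariant and gene-order invariant", {
  set.seed(34)
  m <- matrix(rnorm(5 * 8, 0, 2), 5, 8,
              dimnames = list(paste0("g", 1:5),
                              c(paste0("sev", 1:3), paste0("mod", 1:3),
                                "t1", "t2")))
  sheet <- train_sheet(c("t1", "t2"), c("P2", "P2"), c(7L, 4L))
  f1 <- fit_model(log_expr(m), sheet, "P1", threshold = 0.1)
  # adding c to one gene everywhere shifts its boundary, not its votes
  m2 <- m; m2["g2", ] <- m2["g2", ] + 3.7
  f2 <- fit_model(log_expr(m2), sheet, "P1", threshold = 0.1)
  expect_setequal(f1$gene_id, f2$gene_id)
  expect_equal(f2$b[f2$gene_id == "g2"], f1$b[f1$gene_id == "g2"] + 3.7)
  expect_equal(score_samples(f2, log_expr(m2), c("t1", "t2"))$total_score,
               score_samples(f1, log_expr(m), c("t1", "t2"))$total_score)
  # gene order within the model does not matter
  f_perm <- f1[rev(seq_len(nrow(f1))), ]
  attr(f_perm, "scale") <- "log2"
  class(f_perm) <- c("weighted_voting_model", "data.frame")
  expect_equal(score_samples(f_perm, log_expr(m), "t1")$total_score,
               score_samples(f1, log_expr(m), "t1")$total_score)
  # summed votes equal the naive loop oracle
  want <- oracle_voting(m[f1$gene_id, , drop = FALSE], paste0("sev", 1:3),
                        paste0("mod", 1:3), c("t1", "t2"))
  expect_equal(score_samples(f1, log_expr(m), c("t1", "t2"))$total_score,
               unname(want$totals), tolerance = 1e-12)
})

test_that("evaluation reports confusion counts and a calibrated null", {
  sheet <- train_sheet(c("t1", "t2"), c("P2", "P2"), c(7L, 4L))
  sc <- structure(data.frame(sample_id = c("t1", "t2"),
                             total_score = c(5, -5),
                             predicted = c("severe", "non_severe"),
                             tie = FALSE),
                  class = c("voting_scores", "data.frame"))
  ev <- evaluate_model(sc, sheet)
  expect_equal(ev$accuracy, 1)
  sc$predicted <- rev(sc$predicted)
  expect_equal(evaluate_model(sc, sheet)$accuracy, 0)

  # random predictions vs random labels: accuracy centred on 0.5
  set.seed(35)
  acc <- replicate(500, {
    pred <- sample(c("severe", "non_severe"), 100, TRUE)
    truth <- sample(c(7, 4), 100, TRUE)
    mean(pred == ifelse(truth >= 6, "severe", "non_severe"))
  })
  se <- sd(acc) / sqrt(length(acc))
  expect_lt(abs(mean(acc) - 0.5), 3 * se + 1e-3)
})

test_that("voting models round trip through their tabular file", {
  set.seed(36)
  m <- matrix(rnorm(6 * 6, 0, 2), 6, 6,
              dimnames = list(paste0("g", 1:6),
                              c(paste0("sev", 1:3), paste0("mod", 1:3))))
  fit <- fit_model(log_expr(m), train_sheet(), "P1", threshold = 0.2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_voting_model(fit, f)
  back <- read_voting_model(f)
  expect_identical(back$gene_id, fit$gene_id)
  expect_equal(back$s, fit$s, tolerance = 1e-5)
  expect_equal(back$b, fit$b, tolerance = 1e-5)
})
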