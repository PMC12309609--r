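# one bundle shared across the blocks (built once for speed)
w <- small_world(seed = 17, n = 45)
bundle <- build_bundle(w$panel, w$bm)

test_that("bundle prediction is consistent with training-time scores", {
  expect_length(bundle$models, 2 + nrow(w$bm$values))   # 11 on the 9-KIR panel
  rep1 <- predict_binding(bundle, w$panel$sequence[1])
  # training allele scored through betas equals its reference score
  for (id in names(bundle$models)) {
    ref <- bundle$reference_scores[[id]]
    s <- rep1$score[rep1$model_id == id]
    expect_true(any(abs(ref - s) < 1e-8))
  }
  expect_equal(attr(rep1, "n_ignored_positions"), 0)
  # all-unknown sequence scores at the intercept, every position ignored
  blank <- strrep("*", bundle$panel_length)
  rep2 <- predict_binding(bundle, blank)
  expect_equal(rep2$score,
               sapply(bundle$models, function(m) m$intercept),
               ignore_attr = TRUE)
  expect_equal(attr(rep2, "n_ignored_positions"), bundle$panel_length)
  expect_error(predict_binding(bundle, "RAK"), "length")
})

test_that("percentiles follow the midpoint-tie convention and are duplicate-stable", {
  id <- "overall_binder"
  ref <- bundle$reference_scores[[id]]
  top <- w$panel$sequence[which.max(sapply(w$panel$sequence, function(s)
    predict_binding(bundle, s)$score[1]))]
  p_top <- predict_binding(bundle, top)$percentile[1]
  n <- length(ref)
  expect_equal(p_top, 100 * (n - 0.5) / n, tolerance = 1e-8)
  # percentile monotone in score across the panel
  reps <- t(sapply(w$panel$sequence[1:10], function(s) {
    r <- predict_binding(bundle, s); c(r$score[1], r$percentile[1])
  }))
  expect_identical(order(reps[, 1]), order(reps[, 2]))
  # appending duplicate reference alleles leaves percentiles unchanged
  b2 <- bundle
  b2$reference_scores <- lapply(b2$reference_scores, function(r) rep(r, 2))
  expect_equal(predict_binding(b2, w$panel$sequence[3])$percentile,
               predict_binding(bundle, w$panel$sequence[3])$percentile)
})

test_that("genotype averaging is the mean of per-allotype scores", {
  seq1 <- w$panel$sequence[2]
  kirs <- grep("KIR", names(bundle$models), value = TRUE)[1:2]
  r <- predict_binding(bundle, seq1)
  s1 <- r$score[r$model_id == kirs[1]]
  s2 <- r$score[r$model_id == kirs[2]]
  expect_equal(predict_genotype(bundle, seq1, kirs), (s1 + s2) / 2)
  expect_equal(predict_genotype(bundle, seq1, rev(kirs)),
               predict_genotype(bundle, seq1, kirs))
  expect_equal(predict_genotype(bundle, seq1, kirs[1]), s1)  # homozygote
  expect_error(predict_genotype(bundle, seq1, "KIR3DL1*999"), "unknown")
})

test_that("mutation deltas are linear, antisymmetric, and beta-determined", {
  seq1 <- w$panel$sequence[1]
  # position with all-zero betas: delta is zero
  pc_pos <- unique(bundle$feature_labels$position)
  quiet <- setdiff(seq_len(bundle$panel_length), pc_pos)[1]
  from <- substr(seq1, quiet, quiet)
  expect_equal(unname(mutation_delta(bundle, seq1, quiet, from, "A")),
               rep(0, length(bundle$models)))
  # antisymmetry and beta identity at a polymorphic position
  p <- pc_pos[1]
  res_here <- bundle$feature_labels$residue[bundle$feature_labels$position == p]
  fr <- substr(seq1, p, p); to <- setdiff(res_here, fr)[1]
  mut <- seq1; substr(mut, p, p) <- to
  d1 <- mutation_delta(bundle, seq1, p, fr, to)
  d2 <- mutation_delta(bundle, mut, p, to, fr)
  expect_equal(d1, -d2)
  beta_of <- function(m, lab) if (lab %in% names(m$betas)) m$betas[[lab]] else 0
  expected <- sapply(bundle$models, function(m)
    beta_of(m, paste0(to, p)) - beta_of(m, paste0(fr, p)))
  expect_equal(unname(d1), unname(expected))
  expect_error(mutation_delta(bundle, seq1, p, to = fr, from = "*"), "carries")
})

test_that("reciprocity analysis matches Fig-7B conventions", {
  # purely linear model: inverse = -direct, all points on the diagonal
  d <- c(0.4, -1.2, 2.2, 0.1)
  r <- reciprocity_analysis(d, -d)
  expect_equal(r$table$y, r$table$x)
  expect_equal(r$correlation, 1)
  set.seed(33)
  rn <- reciprocity_analysis(rnorm(50), rnorm(50))
  expect_lt(abs(rn$correlation), 0.35)
  expect_equal(reciprocity_analysis(d, d)$correlation,
               -reciprocity_analysis(d, -d)$correlation)
  expect_error(reciprocity_analysis(1:2, 1:2), "three")
})

test_that("degranulation correlation is a tie-aware Spearman on normalized logs", {
  # inhibitory receptor: degranulation decreasing in binding -> rho = -1
  pred <- c(1, 3, 5, 7)
  deg <- c(0.9, 0.5, 0.3, 0.1)
  expect_equal(degranulation_correlation(pred, deg, baseline = rep(2, 4))$spearman, -1)
  # brute-force midrank formula oracle with ties
  set.seed(12)
  p2 <- sample(1:5, 15, replace = TRUE)
  d2 <- sample(1:4, 15, replace = TRUE) / 10
  got <- degranulation_correlation(p2, d2, baseline = rep(1.7, 15))$spearman
  rx <- rank(p2); ry <- rank(log(d2 / 1.7))
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got, oracle, tolerance = 1e-12)
  # baseline rescaling cannot change ranks
  expect_equal(degranulation_correlation(p2, d2, baseline = rep(8.1, 15))$spearman,
               got)
  # per-group output
  g <- rep(c("KIR3DL1*005", "KIR3DL1*015"), c(7, 8))
  out <- degranulation_correlation(p2, d2, rep(1, 15), group = g)
  expect_identical(out$group, sort(unique(g)))
  expect_error(degranulation_correlation(rep(1, 4), 1:4, rep(1, 4)), "constant")
})

test_that("beta-matrix export and import reproduce every model's scores", {
  p <- tempfile(fileext = ".csv")
  export_betas(bundle, p)
  back <- import_betas(p)
  for (s in w$panel$sequence[1:8]) {
    r1 <- predict_binding(bundle, s)
    r2 <- predict_binding(back, s)
    expect_equal(r2$score, r1$score, tolerance = 1e-10)
    expect_equal(r2$percentile, r1$percentile, tolerance = 1e-10)
  }
})
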