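test_that("fold assignment is balanced, deterministic, and stratifiable", {
  for (n in 5:25) {
    f <- make_folds(paste0("a", 1:n), k = 5, seed = 1)
    sz <- table(factor(f$fold_of_allele, levels = 1:5))
    expect_lte(diff(range(sz)), 1)
  }
  expect_identical(make_folds(letters, seed = 42)$fold_of_allele,
                   make_folds(letters, seed = 42)$fold_of_allele)
  expect_false(identical(make_folds(letters, seed = 1)$fold_of_allele,
                         make_folds(letters, seed = 2)$fold_of_allele))
  # stratification keeps both classes in every fold when possible
  strata <- rep(c("x", "y"), each = 10)
  f <- make_folds(paste0("a", 1:20), k = 5, seed = 3, strata = strata)
  per_fold <- table(f$fold_of_allele, strata)
  expect_true(all(per_fold > 0))
  expect_error(make_folds(letters, k = 1), "at least 2")
})

test_that("AUC equals brute-force pair counting and is rank-invariant", {
  expect_equal(auc(c(1, 2, 3, 4), c(-1, -1, 1, 1)), 1)
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == -1]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(14)
  for (i in 1:10) {
    s <- sample(1:8, 50, replace = TRUE)     # heavy ties
    y <- sample(c(1, -1), 50, replace = TRUE, prob = c(.4, .6))
    if (length(unique(y)) < 2) next
    expect_equal(auc(s, y), brute(s, y), tolerance = 1e-12)
    expect_equal(auc(exp(s / 2), y), auc(s, y))   # monotone transform
  }
  # label-free scores average to one half
  nulls <- replicate(100, {
    s <- rnorm(100); y <- sample(rep(c(1, -1), 50))
    auc(s, y)
  })
  expect_lt(abs(mean(nulls) - 0.5), 0.02)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("cross-validation is leakage-free and perfect on noiseless data", {
  # noiseless, fully linked motif: a genuinely separable world
  panel <- generate_panel(45, seed = 4, flip_prob = 0)
  pm <- planted_model(panel, sigma = 0, seed = 4)
  gen <- generate_binding(panel, pm, seed = 4)
  bm <- aggregate_replicates(gen$runs)
  t <- run_cv_experiment(panel, bm, mask = "helices", seed = 4)
  expect_true(all(t$auc_test[!is.na(t$auc_test)] == 1))
  expect_true(all(t$auc_train == 1))
  # structural leakage guard: folds partition the allele set
  sch <- attr(t, "scheme")
  expect_setequal(names(sch$fold_of_allele),
                  intersect(panel$name, colnames(bm$values)))
  # per-fold projection route also runs and is perfect here
  t2 <- run_cv_experiment(panel, bm, mask = "helices", seed = 4,
                          per_fold_projection = TRUE)
  expect_true(all(t2$auc_test[!is.na(t2$auc_test)] == 1))
  # per-allotype task layout
  t3 <- run_cv_experiment(panel, bm, task = "per_allotype", seed = 4)
  expect_setequal(unique(t3$task), paste0("kir:", rownames(bm$values)))
})

test_that("configuration comparison reproduces a hand-computed two-way ANOVA", {
  # balanced 2 x 2 x 5 toy table
  set.seed(2)
  grid <- expand.grid(mask = c("bw4", "helices"), loci = c("A/B", "A/B/C"),
                      fold = 1:5)
  grid$auc_test <- 0.7 + 0.1 * (grid$mask == "helices") +
    0.02 * (grid$loci == "A/B/C") + rnorm(20, 0, 0.01)
  grid$task <- "overall_binder"
  class(grid) <- c("auc_table", class(grid))
  rep_ <- compare_configurations(grid)
  # hand-computed balanced two-way decomposition
  y <- grid$auc_test
  a <- factor(grid$mask); b <- factor(grid$loci)
  ss <- function(x) sum(x^2)
  gm <- mean(y)
  ssa <- 10 * ss(tapply(y, a, mean) - gm)
  ssb <- 10 * ss(tapply(y, b, mean) - gm)
  cellm <- tapply(y, interaction(a, b), mean)
  ssab <- 5 * ss(cellm - rep(tapply(y, a, mean), 2) -
                   tapply(y, b, mean)[rep(1:2, each = 2)] + gm)
  sse <- ss(y - cellm[interaction(a, b)])
  f_a <- (ssa / 1) / (sse / 16)
  expect_equal(rep_$two_way$F[rep_$two_way$term == "mask"], f_a,
               tolerance = 1e-8)
  expect_lt(rep_$two_way$p[rep_$two_way$term == "mask"], 0.05)
  # identical AUCs: nothing significant
  grid2 <- grid; grid2$auc_test <- 0.8
  rep2 <- compare_configurations(grid2)
  expect_false(any(rep2$two_way$p < 0.05, na.rm = TRUE))
})
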