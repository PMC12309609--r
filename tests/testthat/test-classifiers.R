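sep_data <- function(n = 40, seed = 1, gap = 4) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n), n / 2, 2) + gap,
             matrix(rnorm(n), n / 2, 2) - gap)
  list(X = X, y = rep(c(1, -1), each = n / 2))
}

test_that("SVM separates separable clouds and is label-symmetric", {
  d <- sep_data()
  m <- fit_svm(d$X, d$y)
  expect_equal(auc(score(m, d$X), d$y), 1)
  m2 <- fit_svm(d$X, -d$y)
  expect_equal(score(m2, d$X), -score(m, d$X), tolerance = 1e-6)
  expect_error(fit_svm(d$X, rep(1, nrow(d$X))), "both classes")
})

test_that("SVM objective agrees with the dual-QP reference solver", {
  set.seed(21)
  for (r in 1:4) {
    X <- matrix(rnorm(30), 10, 3)
    y <- sample(rep(c(1, -1), 5))
    f <- fit_svm(X, y)
    o <- svm_dual_reference(X, y)
    expect_lt(abs(f$objective - o$objective), 1e-6)
    # convexity: warm-started refit from a random point agrees
    p <- mlvo_problem(X, y_bin = y, mu = 0)
    f2 <- fit_mlvo(p, theta0 = rnorm(4))
    expect_lt(abs(f2$objective - f$objective), 1e-6)
  }
})

test_that("balanced weighting lifts minority recall on imbalanced data", {
  recalls <- sapply(1:5, function(s) {
    set.seed(s)
    n1 <- 90; n2 <- 10
    X <- rbind(matrix(rnorm(2 * n1), n1), matrix(rnorm(2 * n2) + 1.2, n2))
    y <- c(rep(-1, n1), rep(1, n2))
    rec <- function(cw) {
      m <- fit_svm(X, y, class_weight = cw)
      mean(score(m, X[y == 1, ]) > 0)
    }
    c(bal = rec("balanced"), unbal = rec("none"))
  })
  expect_gte(mean(recalls["bal", ] - recalls["unbal", ]), 0)
})

test_that("MLVO reduces to the SVM and couples both label types usefully", {
  d <- sep_data(seed = 3)
  msvm <- fit_svm(d$X, d$y)
  mred <- fit_mlvo(mlvo_problem(d$X, y_bin = d$y, mu = 0))
  expect_lt(abs(msvm$objective - mred$objective), 1e-8)
  expect_equal(mred$w, msvm$w, tolerance = 1e-6)
  # with consistent labels, joint training is no worse than binary-only
  wins <- sapply(1:10, function(s) {
    set.seed(100 + s)
    w_true <- c(1, -0.5, 0.25)
    gen <- function(n) {
      X <- matrix(rnorm(3 * n), n)
      sc <- X %*% w_true
      list(X = X, y = ifelse(sc > 0, 1, -1), c = as.numeric(sc) + rnorm(n, 0, .1))
    }
    tr <- gen(40); te <- gen(200)
    a_joint <- auc(score(fit_mlvo(mlvo_problem(tr$X, tr$y, tr$c)), te$X), te$y)
    a_bin <- auc(score(fit_svm(tr$X, tr$y), te$X), te$y)
    a_joint - a_bin
  })
  expect_gte(mean(wins), 0)
  expect_error(mlvo_problem(matrix(0, 2, 2), y_bin = c(1, NA),
                            y_cont = c(NA, NA)), "at least one label")
  expect_error(mlvo_problem(matrix(0, 2, 2), y_bin = c(1, -1), mu = -1),
               "non-negative")
})

test_that("continuous-only MLVO recovers a planted weight vector", {
  errs <- sapply(1:3, function(s) {
    set.seed(s)
    X <- matrix(rnorm(1000), 200, 5)
    ws <- rnorm(5)
    yc <- as.numeric(X %*% ws) + 0.5 + rnorm(200, 0, 0.01)
    m <- fit_mlvo(mlvo_problem(X, y_cont = yc, lambda = 1e-8, mu = 1))
    sqrt(sum((m$w - ws)^2) / sum(ws^2))
  })
  expect_lt(max(errs), 0.05)
})

test_that("back-projection reproduces scores through per-feature betas", {
  enc <- one_hot_encode(generate_panel(40, seed = 6))
  proj <- fit_pca(enc, K = 7)
  Z <- project(proj, enc)
  y <- ifelse(seq_len(40) %% 2 == 0, 1, -1)
  m <- back_project(fit_svm(Z, y), proj)
  direct <- enc$matrix %*% m$betas + m$intercept
  expect_equal(as.numeric(direct), score(m, Z), tolerance = 1e-8)
  # identity projection: betas equal w exactly
  idp <- fit_identity(enc)
  mid <- back_project(fit_svm(enc$matrix, y), idp)
  expect_equal(unname(mid$betas), mid$w)
  expect_equal(mid$intercept, mid$b)
  # zero weights give zero betas
  mzero <- m; mzero$w <- rep(0, 7)
  expect_equal(unname(back_project(mzero, proj)$betas), rep(0, ncol(enc$matrix)))
  # refusals: polynomial kernel and MCA
  mp <- fit_svm(Z, y, kernel = "polynomial")
  expect_error(back_project(mp, proj), "polynomial")
  expect_error(back_project(fit_svm(project(fit_mca(enc, 7), enc), y),
                            fit_mca(enc, 7)), "MCA")
})

test_that("position contributions aggregate and normalize as specified", {
  b <- c(I80 = 0.7, T80 = -0.3, R83 = 0, G83 = 0)
  pc <- position_contributions(b)
  expect_equal(unname(pc[c("80", "83")]), c(1, 0))
  b2 <- c(A1 = 2, B2 = -4, C3 = 6)
  expect_equal(unname(position_contributions(b2)), c(0, 0.5, 1))
  expect_equal(position_contributions(b2 * 3), position_contributions(b2))
})
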