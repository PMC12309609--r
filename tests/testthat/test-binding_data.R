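mk_runs <- function(...) {
  lapply(list(...), function(v) {
    m <- matrix(v, nrow = 1, dimnames = list("KIR3DL1*001", c("h1", "h2")))
    m
  })
}

test_that("replicate aggregation averages then max-normalizes per KIR", {
  runs <- mk_runs(c(0.2, 0.6), c(0.4, 0.8), c(0.6, 1.0))
  agg <- aggregate_replicates(runs)
  # cell means 0.4 and 0.8; row max 0.8 -> 0.5 and 1.0
  expect_equal(unname(agg$values[1, ]), c(0.5, 1.0))
  # run-order permutation invariance
  expect_equal(aggregate_replicates(rev(runs))$values, agg$values)
  # single run: values / row max
  one <- aggregate_replicates(mk_runs(c(0.2, 0.5)))
  expect_equal(unname(one$values[1, ]), c(0.4, 1.0))
  # normalize-first order and global max variants stay in [0, 1]
  nf <- aggregate_replicates(runs, order = "normalize_first")
  expect_equal(max(nf$values), 1)
  gl <- aggregate_replicates(runs, max_by = "global")
  expect_equal(max(gl$values), 1)
  expect_error(aggregate_replicates(mk_runs(c(0, 0))), "no positive")
  bad <- mk_runs(c(0.2, 0.6), c(0.4, 0.8))
  colnames(bad[[2]]) <- c("h1", "h3")
  expect_error(aggregate_replicates(bad), "mismatched")
})

test_that("log transform replaces zeros by 1% of the minimal positive value", {
  v <- matrix(c(0, 0.05, 1, 0.5), 2, 2,
              dimnames = list(c("k1", "k2"), c("h1", "h2")))
  lg <- log_transform(binding_matrix(v))
  expect_equal(lg$values[1, 1], log(0.01 * 0.05))
  expect_equal(lg$values[1, 2], 0)          # log(1) = 0
  expect_true(all(is.finite(lg$values)))
  # no zeros: exact elementwise log
  v2 <- matrix(c(0.2, 0.4, 0.8, 1), 2, 2)
  expect_equal(log_transform(binding_matrix(v2))$values,
               log(binding_matrix(v2)$values))
  # strict monotonicity on positives, replaced zeros strictly below
  expect_true(lg$values[1, 1] < min(log(v[v > 0])))
  # per-row replacement option
  lr <- log_transform(binding_matrix(v), per_row = TRUE)
  expect_equal(lr$values[1, 1], log(0.01 * 1))
  expect_error(log_transform(binding_matrix(matrix(0, 1, 2))), "positive")
})

test_that("per-KIR min-max maps each row onto [0, 100] preserving order", {
  v <- matrix(c(-5, -1, 3, 0, 10, 40), 2, 3, byrow = TRUE,
              dimnames = list(c("k1", "k2"), c("h1", "h2", "h3")))
  nm <- minmax_per_kir(binding_matrix(v, stage = "log"))
  expect_equal(unname(nm$values[1, ]), c(0, 50, 100))
  expect_equal(unname(nm$values[2, ]), c(0, 25, 100))
  # idempotence: re-applying the affine map changes nothing
  expect_equal(minmax_per_kir(nm)$values, nm$values)
  # order preservation
  expect_identical(order(nm$values[2, ]), order(v[2, ]))
  expect_error(minmax_per_kir(binding_matrix(matrix(c(1, 1, 2, 3), 2, 2,
                                                    byrow = TRUE),
                                             stage = "log")),
               "constant")
})

test_that("binding matrix io round-trips", {
  w <- small_world()
  p <- tempfile(fileext = ".tsv")
  write_binding_matrix(w$bm, p)
  back <- read_binding_matrix(p)
  expect_equal(back$values, w$bm$values, tolerance = 1e-12)
  # long-format replicate reader reproduces the run matrices
  long <- do.call(rbind, lapply(seq_along(w$gen$runs), function(r) {
    m <- w$gen$runs[[r]]
    data.frame(kir = rep(rownames(m), ncol(m)),
               hla = rep(colnames(m), each = nrow(m)),
               run = r, value = as.numeric(m))
  }))
  lf <- tempfile(fileext = ".tsv")
  utils::write.table(long, lf, sep = "\t", quote = FALSE, row.names = FALSE)
  runs2 <- read_binding_runs(lf)
  expect_equal(runs2[[1]], w$gen$runs[[1]], tolerance = 1e-12)
})
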