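#' Allele-level cross-validation folds
#'
#' Random near-equal partition of HLA alleles into k folds, fixed by a
#' seed. The same scheme is reused for every KIR task so that each allele
#' is always entirely in training or entirely in test across all tasks.
#' Optional stratification keeps class proportions similar per fold, which
#' avoids single-class folds on small panels.
#'
#' @param alleles character vector of allele names.
#' @param k number of folds (default 5, i.e. 80/20 train/test splits).
#' @param seed integer RNG seed.
#' @param strata optional categorical labels (same length) to stratify on.
#' @return An object of class `cv_scheme`: list with `fold_of_allele`
#'   (named integer 1..k), `k`, `seed`.
#' @export
make_folds <- function(alleles, k = 5L, seed = 1L, strata = NULL) {
  if (k < 2L) stopf("k must be at least 2")
  n <- length(alleles)
  if (n < k) stopf("need at least k alleles")
  if (anyDuplicated(alleles)) stopf("duplicated allele names")
  fold <- integer(n); names(fold) <- alleles
  with_seed(seed, {
    if (is.null(strata)) {
      fold[] <- rep_len(seq_len(k), n)[sample.int(n)]
    } else {
      strata <- factor(strata)
      nxt <- 0L  # rotating fold counter across strata keeps sizes within 1
      for (lv in levels(strata)) {
        idx <- which(strata == lv)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- (nxt + seq_along(idx) - 1L) %% k + 1L
        nxt <- (nxt + length(idx)) %% k
      }
    }
  })
  structure(list(fold_of_allele = fold, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties counted one half
#' (midranks; the Mann-Whitney statistic scaled to `[0, 1]`).
#'
#' @param scores continuous decision values.
#' @param labels positive/negative labels (`+1`/`-1`, logical, or
#'   two-level factor).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- to_pm1(labels)
  n1 <- sum(y == 1); n0 <- sum(y == -1)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# derive task labels (binary and continuous) from clustering of the
# binding matrix; shared by run_cv_experiment and build_bundle
derive_task_labels <- function(norm, labels, task) {
  hla <- colnames(norm$values)
  if (task == "overall_binder") {
    list(y_bin = stats::setNames(ifelse(labels$binder[hla], 1, -1), hla),
         y_cont = stats::setNames(colMeans(norm$values)[hla], hla))
  } else if (task == "high_vs_low") {
    keep <- hla[labels$binder[hla]]
    list(y_bin = stats::setNames(ifelse(labels$high_vs_low[keep], 1, -1), keep),
         y_cont = stats::setNames(colMeans(norm$values)[keep], keep))
  } else {  # per-allotype task: "kir:<name>"
    kir <- sub("^kir:", "", task)
    if (!kir %in% rownames(norm$values)) stopf("unknown KIR allotype %s", kir)
    list(y_bin = stats::setNames(ifelse(labels$binder[hla], 1, -1), hla),
         y_cont = stats::setNames(norm$values[kir, hla], hla))
  }
}

# fit one task on a train/test split of projected coordinates
fit_task <- function(Ztr, Zte, ytr, yte, ctr, method, C = 0.01, mu = 1) {
  model <- if (method == "mlvo")
    fit_mlvo(mlvo_problem(Ztr, y_bin = ytr, y_cont = ctr, C = C, mu = mu))
  else fit_svm(Ztr, ytr, C = C)
  list(model = model,
       auc_train = auc(score(model, Ztr), ytr),
       auc_test = if (length(unique(yte)) == 2L) auc(score(model, Zte), yte)
                  else NA_real_)
}

#' Run an allele-level cross-validated experiment
#'
#' Composes the pipeline for one configuration: one-hot encode the panel
#' over a region mask and locus subset, project to K dimensions, derive
#' labels from the three-cluster cut of the normalized binding matrix, and
#' train/evaluate the classifier fold by fold. Per the study protocol the
#' projection is fit once on all one-hot vectors (set
#' `per_fold_projection = TRUE` for a strictly leakage-free refit per
#' fold). A structural leakage guard asserts that no test allele enters
#' any training matrix.
#'
#' @param panel an [allele_panel()] of HLA allotypes.
#' @param binding a raw [binding_matrix()] (replicate-aggregated).
#' @param mask region mask name (default `"helices"`).
#' @param loci loci to include (default `c("A", "B", "C")`).
#' @param method `"mlvo"` (default) or `"svm"`.
#' @param task `"overall_binder"` (default), `"high_vs_low"`, or
#'   `"kir:<allotype>"`; `task = "per_allotype"` expands to every KIR row.
#' @param dimred `"pca"` (default), `"mca"`, or `"identity"`.
#' @param K projection dimension (default 7).
#' @param k,seed fold count and RNG seed for [make_folds()].
#' @param repeats number of repeated cross-validations (default 1).
#' @param per_fold_projection refit the projection on training folds only.
#' @param C,mu classifier hyperparameters.
#' @return An object of class `auc_table`: data frame with columns `mask`,
#'   `loci`, `method`, `task`, `repeat_`, `fold`, `auc_train`, `auc_test`;
#'   attribute `scheme` holds the fold assignment.
#' @export
run_cv_experiment <- function(panel, binding, mask = "helices",
                              loci = c("A", "B", "C"), method = "mlvo",
                              task = "overall_binder", dimred = "pca",
                              K = 7L, k = 5L, seed = 1L, repeats = 1L,
                              per_fold_projection = FALSE,
                              C = 0.01, mu = 1) {
  stopifnot(inherits(panel, "allele_panel"), inherits(binding, "binding_matrix"))
  norm <- minmax_per_kir(log_transform(binding))
  labels <- label_three_groups(hierarchical_cluster(norm, "hla"), norm)
  sub <- panel[panel$locus %in% loci & panel$name %in% colnames(norm$values), ]
  sub <- allele_panel(sub$name, sub$sequence, sub$locus)
  enc <- one_hot_encode(sub, build_region_mask(mask, panel_length(sub)))
  tasks <- if (identical(task, "per_allotype"))
    paste0("kir:", rownames(norm$values)) else task
  fit_proj <- switch(dimred, pca = fit_pca, mca = fit_mca,
                     identity = function(X, K) fit_identity(X))
  rows <- list(); scheme <- NULL
  for (rep_i in seq_len(repeats)) {
    for (tk in tasks) {
      lab <- derive_task_labels(norm, labels, tk)
      alle <- intersect(names(lab$y_bin), sub$name)
      X <- enc$matrix[alle, , drop = FALSE]
      ybin <- lab$y_bin[alle]
      ycont <- lab$y_cont[alle]
      strat <- factor(ybin)
      sch <- make_folds(alle, k = k, seed = seed + 1000L * (rep_i - 1L),
                        strata = strat)
      if (is.null(scheme)) scheme <- sch
      proj_all <- if (!per_fold_projection) fit_proj(X, K) else NULL
      for (f in seq_len(k)) {
        te <- alle[sch$fold_of_allele == f]
        tr <- setdiff(alle, te)
        stopifnot(length(intersect(tr, te)) == 0L)  # leakage guard
        if (length(unique(ybin[match(tr, alle)])) < 2L) {
          warning(sprintf("fold %d lacks both classes in training; skipped", f))
          next
        }
        proj <- proj_all %||% fit_proj(X[tr, , drop = FALSE], K)
        Ztr <- project(proj, X[tr, , drop = FALSE])
        Zte <- project(proj, X[te, , drop = FALSE])
        r <- fit_task(Ztr, Zte, ybin[match(tr, alle)], ybin[match(te, alle)],
                      ycont[match(tr, alle)], method, C = C, mu = mu)
        rows[[length(rows) + 1L]] <- data.frame(
          mask = mask, loci = paste(loci, collapse = "/"), method = method,
          task = tk, repeat_ = rep_i, fold = f,
          auc_train = r$auc_train, auc_test = r$auc_test,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "scheme") <- scheme
  class(out) <- c("auc_table", "data.frame")
  out
}

#' Aggregate an AUC table
#' @param t an `auc_table`.
#' @return data frame of mean and SD test AUC per configuration and task.
#' @export
summarize_auc <- function(t) {
  agg <- stats::aggregate(auc_test ~ mask + loci + method + task, data = t,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  cbind(agg[, 1:4], mean = agg$auc_test[, "mean"], sd = agg$auc_test[, "sd"])
}

#' Compare model configurations by ANOVA
#'
#' Two-way ANOVA of the test AUCs with region mask and locus set as
#' factors (the study's repeated-measures comparison of input types), a
#' one-way ANOVA across tasks/allotypes where several are present, and
#' Tukey HSD post-hocs.
#'
#' @param t an `auc_table` combining at least two levels per factor
#'   (rows from several [run_cv_experiment()] calls).
#' @return list with `two_way` (data frame of factor F/p), `tukey`, and
#'   `one_way_task` (or `NULL`).
#' @export
compare_configurations <- function(t) {
  t <- as.data.frame(t)
  t <- t[!is.na(t$auc_test), ]
  two_way <- NULL; tukey <- NULL
  if (length(unique(t$mask)) >= 2L && length(unique(t$loci)) >= 2L) {
    cells <- table(t$mask, t$loci)
    if (any(cells == 0)) stopf("unbalanced design: empty mask x loci cells")
    fit <- stats::aov(auc_test ~ mask * loci, data = t)
    s <- summary(fit)[[1]]
    two_way <- data.frame(term = trimws(rownames(s)), F = s[, "F value"],
                          p = s[, "Pr(>F)"], row.names = NULL)
    tukey <- lapply(stats::TukeyHSD(fit), function(m)
      data.frame(pair = rownames(m), diff = m[, "diff"], p_adj = m[, "p adj"],
                 row.names = NULL))
  } else if (length(unique(t$mask)) >= 2L) {
    fit <- stats::aov(auc_test ~ mask, data = t)
    s <- summary(fit)[[1]]
    two_way <- data.frame(term = trimws(rownames(s)), F = s[, "F value"],
                          p = s[, "Pr(>F)"], row.names = NULL)
    tukey <- lapply(stats::TukeyHSD(fit), function(m)
      data.frame(pair = rownames(m), diff = m[, "diff"], p_adj = m[, "p adj"],
                 row.names = NULL))
  }
  one_way <- NULL
  if (length(unique(t$task)) >= 2L) {
    fit1 <- stats::aov(auc_test ~ task, data = t)
    s1 <- summary(fit1)[[1]]
    one_way <- data.frame(term = trimws(rownames(s1)), F = s1[, "F value"],
                          p = s1[, "Pr(>F)"], row.names = NULL)
  }
  list(two_way = two_way, tukey = tukey, one_way_task = one_way)
}
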