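#' Train the deployable multi-model bundle
#'
#' Fits the full model set of the prediction tool on one panel and binding
#' matrix: an `overall_binder` model (binder vs non-binder over all
#' allotypes), a `high_vs_low` model (restricted to binders), and one
#' model per KIR allotype row of the binding matrix (for the nine-tetramer
#' study panel this yields the published eleven models). Binary labels
#' come from the three-cluster cut of the normalized matrix; MLVO models
#' additionally use the normalized log binding (the mean over KIR
#' allotypes, or the allotype's own column) as the continuous label. All
#' models are linear, trained in the projected space and back-projected to
#' per-feature betas, so prediction on new sequences needs only the beta
#' matrix.
#'
#' @param panel an [allele_panel()] of HLA allotypes (training references).
#' @param binding a raw [binding_matrix()].
#' @param mask region mask name (default `"helices"`, the study's
#'   best-performing minimal model).
#' @param loci loci included (default `c("A", "B", "C")`).
#' @param method `"mlvo"` (default) or `"svm"`.
#' @param dimred `"pca"` (default) or `"identity"` (MCA is refused:
#'   no exact beta back-projection exists).
#' @param K projection dimension (default 7).
#' @param C,mu classifier hyperparameters.
#' @return An object of class `model_bundle`: list with `models` (named
#'   list of back-projected `linear_model`s), `reference_scores` (per-model
#'   sorted training-panel scores for percentiles), `feature_labels`,
#'   `panel_length`, `metadata`.
#' @export
build_bundle <- function(panel, binding, mask = "helices",
                         loci = c("A", "B", "C"), method = "mlvo",
                         dimred = c("pca", "identity"), K = 7L,
                         C = 0.01, mu = 1) {
  dimred <- match.arg(dimred)
  stopifnot(inherits(panel, "allele_panel"), inherits(binding, "binding_matrix"))
  norm <- minmax_per_kir(log_transform(binding))
  labels <- label_three_groups(hierarchical_cluster(norm, "hla"), norm)
  sub <- panel[panel$locus %in% loci & panel$name %in% colnames(norm$values), ]
  sub <- allele_panel(sub$name, sub$sequence, sub$locus)
  enc <- one_hot_encode(sub, build_region_mask(mask, panel_length(sub)))
  proj <- if (dimred == "pca") fit_pca(enc, K) else fit_identity(enc)
  Z <- project(proj, enc)
  ids <- c("overall_binder", "high_vs_low",
           paste0("kir:", rownames(norm$values)))
  models <- list(); refs <- list()
  for (id in ids) {
    lab <- derive_task_labels(norm, labels, id)
    alle <- intersect(names(lab$y_bin), sub$name)
    ybin <- lab$y_bin[alle]; ycont <- lab$y_cont[alle]
    Zi <- Z[alle, , drop = FALSE]
    m <- if (method == "mlvo")
      fit_mlvo(mlvo_problem(Zi, y_bin = ybin, y_cont = ycont, C = C, mu = mu))
    else fit_svm(Zi, ybin, C = C)
    m <- back_project(m, proj)
    m$model_id <- sub("^kir:", "", id)
    m$metadata <- list(mask = mask, loci = loci, method = method,
                       dimred = dimred, K = proj$K, C = C, mu = mu,
                       task = id, n_train = length(alle),
                       binary_labels = "global 3-cluster cut")
    models[[m$model_id]] <- m
    # reference scores go through the same beta route as predict_binding so
    # tie detection in the percentile is bitwise-consistent
    refs[[m$model_id]] <- sort(as.numeric(enc$matrix %*% m$betas + m$intercept))
  }
  structure(list(models = models, reference_scores = refs,
                 feature_labels = enc$feature_labels,
                 panel_length = panel_length(sub),
                 metadata = list(mask = mask, loci = loci, method = method,
                                 dimred = dimred, K = proj$K,
                                 n_alleles = nrow(sub),
                                 kir_allotypes = rownames(norm$values))),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model_bundle: %d models (%s, mask '%s', K = %d), %d features\n",
              length(x$models), x$metadata$method, x$metadata$mask,
              x$metadata$K, nrow(x$feature_labels)))
  invisible(x)
}

# score one aligned sequence through a back-projected model's betas;
# unknown ('*') and never-seen residues contribute 0
beta_score <- function(model, residues, feature_labels) {
  known <- residues != "*"
  lab <- paste0(residues, seq_along(residues))
  hit <- match(lab[known], names(model$betas))
  sum(model$betas[hit[!is.na(hit)]]) + model$intercept
}

#' Predict binding of an arbitrary allotype sequence
#'
#' Scores an aligned amino-acid sequence against every model in the
#' bundle: the score is the sum of the betas of its known
#' (position, residue) features plus the intercept. Unknown (`*`) residues
#' are ignored (contributing zero) and counted; residues never seen in
#' training at a position also contribute zero. Each score is accompanied
#' by its percentile against the bundle's reference panel (fraction of
#' reference scores strictly below, ties at half weight).
#'
#' @param bundle a [build_bundle()] result.
#' @param seq an aligned amino-acid string, or a single-row
#'   [allele_panel()] subset.
#' @return An object of class `prediction_report`: data frame with
#'   `model_id`, `score`, `percentile`; attribute `n_ignored_positions`.
#' @export
predict_binding <- function(bundle, seq) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (inherits(seq, "allele_panel")) {
    if (nrow(seq) != 1L) stopf("predict one sequence at a time")
    seq <- seq$sequence
  }
  seq <- gsub("[-.]", "*", toupper(seq))
  if (nchar(seq) != bundle$panel_length)
    stopf("sequence length %d does not match the model coordinate system (%d)",
          nchar(seq), bundle$panel_length)
  residues <- strsplit(seq, "")[[1]]
  out <- data.frame(model_id = names(bundle$models), score = NA_real_,
                    percentile = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    m <- bundle$models[[out$model_id[i]]]
    s <- beta_score(m, residues, bundle$feature_labels)
    ref <- bundle$reference_scores[[out$model_id[i]]]
    out$score[i] <- s
    out$percentile[i] <- 100 * (sum(ref < s) + 0.5 * sum(ref == s)) / length(ref)
  }
  attr(out, "n_ignored_positions") <- sum(residues == "*")
  class(out) <- c("prediction_report", "data.frame")
  out
}

#' Average predicted binding over a KIR3DL1 genotype
#'
#' Individuals may express one or two KIR3DL1 allotypes; the expected
#' binding is the arithmetic mean of the per-allotype model scores.
#'
#' @param bundle a [build_bundle()] result.
#' @param seq aligned HLA sequence (as in [predict_binding()]).
#' @param kir_alleles character vector of expressed KIR3DL1 allotype ids
#'   (names of per-allotype models in the bundle).
#' @return averaged numeric score.
#' @export
predict_genotype <- function(bundle, seq, kir_alleles) {
  bad <- setdiff(kir_alleles, names(bundle$models))
  if (length(bad)) stopf("unknown KIR3DL1 allotype id: %s", bad[1])
  rep <- predict_binding(bundle, seq)
  mean(rep$score[match(kir_alleles, rep$model_id)])
}

#' Score change of a point mutation
#'
#' For a linear model the score change of mutating `from -> to` at one
#' position equals `beta(to) - beta(from)` there, independent of the
#' sequence background, so direct and inverse mutations have exactly
#' opposite effects.
#'
#' @param bundle a [build_bundle()] result.
#' @param seq aligned wild-type sequence carrying `from` at `position`.
#' @param position 1-based position.
#' @param from,to one-letter residues.
#' @return named numeric vector: per-model score change.
#' @export
mutation_delta <- function(bundle, seq, position, from, to) {
  if (inherits(seq, "allele_panel")) seq <- seq$sequence[1]
  seq <- toupper(seq)
  if (substr(seq, position, position) != from)
    stopf("sequence carries %s at position %d, not %s",
          substr(seq, position, position), position, from)
  mut <- seq
  substr(mut, position, position) <- to
  wt_rep <- predict_binding(bundle, seq)
  mu_rep <- predict_binding(bundle, mut)
  stats::setNames(mu_rep$score - wt_rep$score, wt_rep$model_id)
}

#' Reciprocal-mutation scatter and correlation
#'
#' Pairs a direct mutation's effect (log degranulation ratio or predicted
#' score change) with minus the effect of the reciprocal mutation on the
#' other allele background. Under a purely additive (linear) model all
#' points fall on the identity diagonal; the correlation quantifies how
#' close reality comes.
#'
#' @param direct numeric vector of direct-mutation effects.
#' @param inverse numeric vector of reciprocal-mutation effects (same
#'   order).
#' @return list with `table` (data frame `x`, `y` where `y = -inverse`)
#'   and `correlation` (Pearson).
#' @export
reciprocity_analysis <- function(direct, inverse) {
  if (length(direct) != length(inverse)) stopf("pair vectors differ in length")
  if (length(direct) < 3L) stopf("need at least three mutation pairs")
  tab <- data.frame(x = direct, y = -inverse)
  list(table = tab, correlation = stats::cor(tab$x, tab$y))
}

#' Spearman correlation of predicted binding with NK degranulation
#'
#' Degranulation responses are first normalized to the HLA-deficient
#' parental-line response of their assay (the maximal degranulation),
#' log-scaled, and rank-correlated with the predicted binding score within
#' each KIR3DL1 context group.
#'
#' @param predicted numeric predicted scores per target.
#' @param degranulation observed degranulation per target.
#' @param baseline parental-line (maximal) response per target's assay;
#'   must be positive.
#' @param group optional KIR3DL1-context labels; one coefficient per group.
#' @return data frame with `group`, `n`, `spearman`.
#' @export
degranulation_correlation <- function(predicted, degranulation, baseline,
                                      group = NULL) {
  if (any(baseline <= 0)) stopf("baselines must be positive")
  norm <- log(degranulation / baseline)
  group <- factor(group %||% rep("all", length(predicted)))
  out <- lapply(levels(group), function(g) {
    i <- group == g
    if (stats::sd(predicted[i]) == 0 || stats::sd(norm[i]) == 0)
      stopf("constant vector in group %s: Spearman undefined", g)
    data.frame(group = g, n = sum(i),
               spearman = stats::cor(predicted[i], norm[i],
                                     method = "spearman"))
  })
  do.call(rbind, out)
}

#' Export the bundle's beta matrix as CSV
#'
#' Rows are (position, residue) features plus a final intercept row;
#' columns are the model ids. A JSON sidecar (`<path>.meta.json`) stores
#' model metadata, reference scores and the alignment length, so
#' [import_betas()] reconstructs a fully working bundle.
#'
#' @param bundle a [build_bundle()] result.
#' @param path CSV output path.
#' @export
export_betas <- function(bundle, path) {
  fl <- bundle$feature_labels
  mat <- sapply(bundle$models, function(m) m$betas[fl$label])
  mat <- rbind(mat, sapply(bundle$models, function(m) m$intercept))
  # full double precision so the round-trip is bit-exact
  mat_chr <- apply(mat, 2, function(x) sprintf("%.17g", x))
  d <- data.frame(position = c(fl$position, 0L),
                  residue = c(fl$residue, "(Intercept)"),
                  mat_chr, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(d) <- c("position", "residue", names(bundle$models))
  utils::write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(panel_length = bundle$panel_length,
         metadata = bundle$metadata,
         model_ids = names(bundle$models),
         model_metadata = lapply(bundle$models, function(m) m$metadata),
         # serialized as strings to preserve full double precision
         reference_scores = lapply(bundle$reference_scores,
                                   function(r) sprintf("%.17g", r))),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a beta matrix exported by [export_betas()]
#' @param path CSV path (with its `.meta.json` sidecar alongside).
#' @return a `model_bundle` usable with [predict_binding()].
#' @export
import_betas <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  ic <- d$residue == "(Intercept)"
  fl <- data.frame(position = d$position[!ic], residue = d$residue[!ic],
                   stringsAsFactors = FALSE)
  fl$label <- paste0(fl$residue, fl$position)
  ids <- setdiff(names(d), c("position", "residue"))
  models <- lapply(ids, function(id) {
    structure(list(w = NULL, b = NULL, method = "imported", kernel = "linear",
                   betas = stats::setNames(d[[id]][!ic], fl$label),
                   intercept = d[[id]][ic], model_id = id,
                   metadata = meta$model_metadata[[id]]),
              class = "linear_model")
  })
  names(models) <- ids
  refs <- lapply(ids, function(id) as.numeric(meta$reference_scores[[id]]))
  names(refs) <- ids
  structure(list(models = models, reference_scores = refs,
                 feature_labels = fl,
                 panel_length = as.integer(meta$panel_length),
                 metadata = meta$metadata),
            class = "model_bundle")
}
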