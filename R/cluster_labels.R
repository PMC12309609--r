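#' Average-linkage hierarchical clustering of a binding matrix
#'
#' Clusters one axis of the binding matrix with average-link (UPGMA)
#' agglomeration on Euclidean distances. Each HLA allotype is represented
#' by its vector of normalized binding values over the KIR allotypes (for
#' 9 tetramers, a nine-dimensional vector); clustering the KIR axis uses
#' the transposed representation.
#'
#' @param m a [binding_matrix()], normally at stage `"normalized"`.
#' @param axis `"hla"` (default) or `"kir"`.
#' @return An object of class `cluster_result`: list with `axis`, `hclust`
#'   (the merge tree), and `leaf_order` (dendrogram leaf ordering).
#' @export
hierarchical_cluster <- function(m, axis = c("hla", "kir")) {
  axis <- match.arg(axis)
  stopifnot(inherits(m, "binding_matrix"))
  X <- if (axis == "hla") t(m$values) else m$values
  if (nrow(X) < 2L) stopf("need at least two items on the %s axis", axis)
  if (anyNA(X)) stopf("missing values in binding vectors; aggregate/complete first")
  h <- stats::hclust(stats::dist(X, method = "euclidean"), method = "average")
  structure(list(axis = axis, hclust = h, leaf_order = h$labels[h$order]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result (%s axis): %d leaves, average linkage\n",
              x$axis, length(x$leaf_order)))
  invisible(x)
}

#' Cut a cluster tree into k groups
#' @param cluster a [hierarchical_cluster()] result.
#' @param k number of clusters.
#' @return named integer vector of cluster memberships.
#' @export
cut_clusters <- function(cluster, k) {
  stopifnot(inherits(cluster, "cluster_result"))
  stats::cutree(cluster$hclust, k = k)
}

#' Dendrogram as a Newick string
#' @param cluster a [hierarchical_cluster()] result.
#' @return a Newick-format character string.
#' @export
cluster_newick <- function(cluster) {
  h <- cluster$hclust
  rec <- function(i) {
    if (i < 0) h$labels[-i]
    else sprintf("(%s,%s):%g", rec(h$merge[i, 1]), rec(h$merge[i, 2]),
                 h$height[i])
  }
  paste0("(", rec(h$merge[nrow(h$merge), 1]), ",",
         rec(h$merge[nrow(h$merge), 2]), ");")
}

#' Derive high / low / non-binder classes from the 3-cluster cut
#'
#' Cuts the HLA-axis tree into its top three clusters and names them by
#' mean binding in descending order: `high`, `low`, `non`. The derived
#' binary tasks are binder (high or low) versus non-binder over all
#' allotypes, and high versus low over the binders only.
#'
#' @param cluster a [hierarchical_cluster()] result on the HLA axis.
#' @param m the [binding_matrix()] that was clustered.
#' @return An object of class `binding_class_labels`: list with `class`
#'   (named factor `high`/`low`/`non` per HLA), `binder` (named logical),
#'   and `high_vs_low` (named logical, `NA` on non-binders).
#' @export
label_three_groups <- function(cluster, m) {
  stopifnot(inherits(cluster, "cluster_result"), inherits(m, "binding_matrix"))
  if (cluster$axis != "hla") stopf("three-group labels are defined on the HLA axis")
  n <- length(cluster$leaf_order)
  if (n < 3L) stopf("need at least three HLA allotypes")
  vec <- t(m$values)
  if (nrow(unique(vec)) < 3L)
    stopf("fewer than three distinct binding vectors: cannot form three groups")
  memb <- cut_clusters(cluster, 3L)
  mean_bind <- tapply(rowMeans(vec[names(memb), , drop = FALSE]), memb, mean)
  ord <- order(mean_bind, decreasing = TRUE)       # descending binding strength
  lab <- c("high", "low", "non")[match(memb, ord)]
  cls <- factor(stats::setNames(lab, names(memb)),
                levels = c("high", "low", "non"))
  binder <- stats::setNames(cls != "non", names(cls))
  hvl <- stats::setNames(ifelse(binder, cls == "high", NA), names(cls))
  structure(list(class = cls, binder = binder, high_vs_low = hvl),
            class = "binding_class_labels")
}

#' @export
print.binding_class_labels <- function(x, ...) {
  cat("binding_class_labels:", paste(sprintf("%s=%d", names(table(x$class)),
      table(x$class)), collapse = " "), "\n")
  invisible(x)
}

#' Group-difference statistics for binding scores
#'
#' For per-HLA scores grouped by a categorical label (e.g. the 80/83 motif
#' combinations): two-sided Mann-Whitney rank-sum tests of each group
#' against a reference group (exact for small samples, normal approximation
#' with tie correction otherwise — the default behaviour of
#' [stats::wilcox.test()]), a one-way ANOVA over all groups, and all-pairs
#' Tukey HSD adjusted p-values. Per-group stars are not multiplicity
#' corrected; the Tukey family provides the corrected comparisons.
#'
#' @param values numeric scores per item.
#' @param groups categorical labels, same length.
#' @param reference reference group for the rank-sum comparisons (default:
#'   the group with the lowest mean score).
#' @return list with `rank_sum` (data frame group/p/stars), `anova`
#'   (F, p), `tukey` (data frame of all pairs), `reference`.
#' @export
group_difference_tests <- function(values, groups, reference = NULL) {
  groups <- factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  cnt <- table(groups)
  if (length(cnt) < 2L) stopf("need at least two groups")
  if (any(cnt < 2L))
    stopf("group %s has fewer than two members", names(cnt)[cnt < 2][1])
  if (is.null(reference))
    reference <- names(which.min(tapply(values, groups, mean)))
  if (!reference %in% levels(groups)) stopf("unknown reference group %s", reference)
  others <- setdiff(levels(groups), reference)
  rs <- data.frame(group = others, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(others))
    rs$p[i] <- suppressWarnings(stats::wilcox.test(
      values[groups == others[i]], values[groups == reference],
      alternative = "two.sided"))$p.value
  rs$stars <- as.character(p_stars(rs$p))
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      stars = as.character(p_stars(tk[, "p adj"])),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(rank_sum = rs,
       anova = list(F = an[1, "F value"], p = an[1, "Pr(>F)"]),
       tukey = tukey, reference = reference)
}
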