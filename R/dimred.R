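#' Principal component analysis of a one-hot panel
#'
#' Mean-centered PCA via singular value decomposition; indicator columns
#' are commensurate so no unit-variance scaling is applied. Component signs
#' follow a deterministic convention (the largest-magnitude loading of each
#' component is positive) so saved models reload bit-identically. The
#' default output dimension is K = 7, chosen from the drop in variance
#' contribution beyond the seventh eigenvector of the study panel.
#'
#' @param X numeric matrix or an [one_hot_encode()] result.
#' @param K number of components to keep (default 7); clipped to the rank
#'   of the centered matrix with a warning.
#' @return An object of class `projection_model` with fields `method`,
#'   `K`, `center`, `components` (features x K, orthonormal), `explained`
#'   (variance shares of the kept components), `feature_labels`.
#' @export
fit_pca <- function(X, K = 7L) {
  fl <- NULL
  if (inherits(X, "encoded_panel")) { fl <- X$feature_labels; X <- X$matrix }
  X <- as.matrix(X)
  if (nrow(X) < 2L) stopf("need at least two rows")
  if (K < 1L) stopf("K must be at least 1")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc)
  tol <- max(dim(X)) * max(sv$d, 0) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r == 0L) stopf("matrix has rank zero after centering")
  if (K > r) {
    warning(sprintf("K = %d exceeds rank %d; clipping", K, r))
    K <- r
  }
  eig <- sv$d^2 / (nrow(X) - 1)
  comp <- sv$v[, seq_len(K), drop = FALSE]
  comp <- fix_signs(comp)
  rownames(comp) <- colnames(X)
  structure(list(method = "pca", K = K, center = center, components = comp,
                 explained = eig[seq_len(K)] / sum(eig),
                 feature_labels = fl),
            class = "projection_model")
}

# deterministic sign convention: largest-|loading| entry positive
fix_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

#' Multiple correspondence analysis of a one-hot panel
#'
#' Correspondence analysis of the indicator matrix: row and column masses
#' weight the standardized residuals, whose SVD yields the principal axes.
#' Projection uses row profiles (each row divided by its total indicator
#' count), centered at the column masses and scaled by the inverse square
#' root of the column masses.
#'
#' @param X binary indicator matrix or [one_hot_encode()] result.
#' @param K number of axes to keep (default 7).
#' @return a `projection_model` with `method = "mca"`; `explained` holds
#'   principal-inertia shares (summing to at most 1 over all axes).
#' @export
fit_mca <- function(X, K = 7L) {
  fl <- NULL
  if (inherits(X, "encoded_panel")) { fl <- X$feature_labels; X <- X$matrix }
  X <- as.matrix(X)
  if (any(colSums(X) == 0)) stopf("empty categories (all-zero columns) in indicator matrix")
  if (any(rowSums(X) == 0)) stopf("rows with no known categories")
  P <- X / sum(X)
  r <- rowSums(P); cm <- colSums(P)
  S <- sweep(sweep(P - outer(r, cm), 1, sqrt(r), "/"), 2, sqrt(cm), "/")
  sv <- svd(S)
  tol <- max(dim(X)) * max(sv$d, 0) * .Machine$double.eps
  rk <- sum(sv$d > tol)
  if (rk == 0L) stopf("indicator matrix carries no inertia")
  if (K > rk) {
    warning(sprintf("K = %d exceeds rank %d; clipping", K, rk))
    K <- rk
  }
  comp <- sweep(sv$v[, seq_len(K), drop = FALSE], 1, sqrt(cm), "/")
  comp <- fix_signs(comp)
  rownames(comp) <- colnames(X)
  structure(list(method = "mca", K = K, center = cm, components = comp,
                 explained = (sv$d^2 / sum(sv$d^2))[seq_len(K)],
                 feature_labels = fl),
            class = "projection_model")
}

#' Identity projection
#'
#' A pass-through projection used when the regression runs directly on the
#' one-hot vectors (the Bw4-only configuration, whose feature space is
#' already small).
#'
#' @param X indicator matrix or [one_hot_encode()] result.
#' @return a `projection_model` with `method = "identity"`.
#' @export
fit_identity <- function(X) {
  fl <- NULL
  if (inherits(X, "encoded_panel")) { fl <- X$feature_labels; X <- X$matrix }
  X <- as.matrix(X)
  comp <- diag(ncol(X))
  rownames(comp) <- colnames(X)
  structure(list(method = "identity", K = ncol(X),
                 center = stats::setNames(rep(0, ncol(X)), colnames(X)),
                 components = comp, explained = rep(NA_real_, ncol(X)),
                 feature_labels = fl),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("projection_model (%s): %d features -> K = %d\n",
              x$method, nrow(x$components), x$K))
  invisible(x)
}

#' Project data through a fitted projection model
#'
#' @param model a [fit_pca()], [fit_mca()] or [fit_identity()] result.
#' @param X matrix (or [one_hot_encode()] result) with the same feature
#'   columns the model was fit on.
#' @return n x K coordinate matrix.
#' @export
project <- function(model, X) {
  stopifnot(inherits(model, "projection_model"))
  if (inherits(X, "encoded_panel")) {
    if (!is.null(model$feature_labels) &&
        !identical(X$feature_labels$label, rownames(model$components)))
      stopf("feature labels of the data do not match the projection model")
    X <- X$matrix
  }
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$components))
    stopf("feature dimension mismatch: data has %d, model expects %d",
          ncol(X), nrow(model$components))
  if (model$method == "mca") {
    tot <- rowSums(X)
    if (any(tot == 0)) stopf("rows with no known categories cannot be projected by MCA")
    X <- X / tot
  }
  sweep(X, 2, model$center) %*% model$components
}

#' Serialize a projection model to JSON
#' @param model a `projection_model`.
#' @param path output file.
#' @export
write_projection_json <- function(model, path) {
  jsonlite::write_json(
    list(method = model$method, K = model$K,
         center = as.numeric(model$center),
         components = apply(model$components, 2, as.numeric, simplify = FALSE),
         explained = as.numeric(model$explained),
         feature_labels = rownames(model$components)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a projection model from JSON
#' @param path file written by [write_projection_json()].
#' @return a `projection_model`.
#' @export
read_projection_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- j$components
  comp <- if (is.list(comp)) do.call(cbind, lapply(comp, as.numeric))
          else t(as.matrix(comp))        # simplified to a K x features array
  rownames(comp) <- j$feature_labels
  structure(list(method = j$method, K = as.integer(j$K),
                 center = stats::setNames(as.numeric(j$center), j$feature_labels),
                 components = comp, explained = as.numeric(j$explained),
                 feature_labels = NULL),
            class = "projection_model")
}
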