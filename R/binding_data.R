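#' Binding matrices
#'
#' A `binding_matrix` wraps a KIR allotype x HLA allotype matrix of bead
#' binding values together with its processing `stage`:
#' `"raw"` (replicate-averaged, per-KIR max-normalized, values in `[0, 1]`),
#' `"log"` (natural log after zero replacement, finite), or
#' `"normalized"` (per-KIR affine map of the log values to `[0, 100]`).
#' Untested pairs are carried as `NA` and never imputed.
#'
#' @param values numeric matrix with KIR allotypes as rows (rownames) and
#'   HLA allotypes as columns (colnames).
#' @param stage one of `"raw"`, `"log"`, `"normalized"`.
#' @param n_replicates replicate count per cell (scalar or matrix), metadata.
#' @return an object of class `binding_matrix`.
#' @export
binding_matrix <- function(values, stage = "raw", n_replicates = 1L) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("KIR3DL1*", sprintf("%03d", seq_len(nrow(values))))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("HLA", seq_len(ncol(values)))
  stage <- match.arg(stage, c("raw", "log", "normalized"))
  if (stage == "raw" && any(values < -1e-12 | values > 1 + 1e-9, na.rm = TRUE))
    stopf("raw binding values must lie in [0, 1]")
  structure(list(values = values, stage = stage, n_replicates = n_replicates),
            class = "binding_matrix")
}

#' @export
print.binding_matrix <- function(x, ...) {
  cat(sprintf("binding_matrix (%s): %d KIR x %d HLA allotypes, %d missing cells\n",
              x$stage, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Aggregate replicate binding runs
#'
#' Cellwise mean across replicate runs, then normalization against the
#' maximal response. The default normalizes each KIR row by its own maximum
#' (each tetramer's own maximal response); `max_by = "global"` divides the
#' whole matrix by one maximum. `order = "normalize_first"` max-normalizes
#' each run before averaging (the alternative reading of
#' averaged-and-normalized).
#'
#' @param runs list of congruent kir x hla matrices (replicate runs).
#' @param max_by `"kir"` (default) or `"global"`.
#' @param order `"average_first"` (default) or `"normalize_first"`.
#' @return a [binding_matrix()] at stage `"raw"`.
#' @export
aggregate_replicates <- function(runs, max_by = c("kir", "global"),
                                 order = c("average_first", "normalize_first")) {
  max_by <- match.arg(max_by); order <- match.arg(order)
  if (!is.list(runs)) runs <- list(runs)
  if (length(runs) < 1L) stopf("need at least one run")
  dims <- unique(lapply(runs, dim))
  if (length(dims) != 1L) stopf("runs have mismatched dimensions")
  nm <- dimnames(runs[[1]])
  for (r in runs)
    if (!identical(dimnames(r), nm)) stopf("runs have mismatched axes")
  norm_rows <- function(m) {
    mx <- apply(m, 1, max, na.rm = TRUE)
    if (any(!is.finite(mx) | mx <= 0))
      stopf("cannot normalize: KIR row %s has no positive value",
            rownames(m)[which(!is.finite(mx) | mx <= 0)[1]])
    sweep(m, 1, mx, "/")
  }
  norm_global <- function(m) {
    mx <- max(m, na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0) stopf("cannot normalize an all-zero matrix")
    m / mx
  }
  norm <- if (max_by == "kir") norm_rows else norm_global
  if (order == "normalize_first") runs <- lapply(runs, norm)
  avg <- Reduce(`+`, lapply(runs, function(m) ifelse(is.na(m), 0, m))) /
         Reduce(`+`, lapply(runs, function(m) as.numeric(!is.na(m))))
  avg[!is.finite(avg)] <- NA_real_
  dimnames(avg) <- nm
  binding_matrix(norm(avg), stage = "raw", n_replicates = length(runs))
}

#' Log-transform a binding matrix with zero replacement
#'
#' Zeros are replaced by `min_frac` (default 1%) of the minimal positive
#' value before taking the natural log, so all entries are finite. The
#' minimum is global by default (`per_row = TRUE` uses each KIR row's own
#' minimal positive value).
#'
#' @param m a [binding_matrix()] at stage `"raw"`.
#' @param min_frac fraction of the minimal positive value used to replace
#'   zeros.
#' @param per_row compute the replacement minimum per KIR row.
#' @return a [binding_matrix()] at stage `"log"`.
#' @export
log_transform <- function(m, min_frac = 0.01, per_row = FALSE) {
  stopifnot(inherits(m, "binding_matrix"))
  if (m$stage != "raw") stopf("log_transform expects a raw binding matrix")
  v <- m$values
  if (any(v < 0, na.rm = TRUE)) stopf("binding values must be non-negative")
  repl <- function(x) {
    pos <- x[!is.na(x) & x > 0]
    if (length(pos) == 0L) stopf("all-zero matrix/row: no positive minimum exists")
    x[!is.na(x) & x == 0] <- min_frac * min(pos)
    x
  }
  v <- if (per_row) t(apply(v, 1, repl)) else repl(v)
  dimnames(v) <- dimnames(m$values)
  out <- binding_matrix(log(v), stage = "log", n_replicates = m$n_replicates)
  out$values[is.na(m$values)] <- NA_real_
  out
}

#' Per-KIR min-max normalization to \[0, 100\]
#'
#' Maps each KIR row of a log binding matrix affinely onto `[0, 100]`, so
#' every row attains both endpoints. This is the representation used for
#' HLA clustering (each HLA is its vector of normalized affinities over the
#' KIR allotypes).
#'
#' @param m a [binding_matrix()] at stage `"log"` (stage `"raw"` accepted).
#' @return a [binding_matrix()] at stage `"normalized"`.
#' @export
minmax_per_kir <- function(m) {
  stopifnot(inherits(m, "binding_matrix"))
  v <- m$values
  rng <- t(apply(v, 1, range, na.rm = TRUE))
  if (any(rng[, 2] - rng[, 1] <= 0))
    stopf("constant KIR row %s cannot be min-max normalized",
          rownames(v)[which(rng[, 2] - rng[, 1] <= 0)[1]])
  out <- 100 * (v - rng[, 1]) / (rng[, 2] - rng[, 1])
  binding_matrix(out, stage = "normalized", n_replicates = m$n_replicates)
}
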