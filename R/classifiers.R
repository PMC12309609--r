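#' @section The SVM / MLVO objective:
#' Both classifiers minimize one convex objective over a linear score
#' `f(x) = w . x + b`:
#'
#'   P(w, b) = lambda ||w||^2
#'           + sum_i c_i * max(0, 1 - y_i f(x_i))        (binary labels)
#'           + mu * sum_j (f(x_j) - t_j)^2               (continuous labels)
#'
#' With `mu = 0` this is the soft-margin SVM (libsvm parameterization:
#' `lambda = 1/2`, per-sample costs `c_i` built from the box constraint C;
#' "balanced" weighting sets `c_i = C * n / (2 * n_class(y_i))` so the
#' per-class penalty is inversely proportional to class size). The MLVO
#' objective couples partially observed binary and continuous labels
#' through the shared score, which enforces the assumed monotone link
#' between class and affinity.
#' @name svm-mlvo-objective
#' @keywords internal
NULL

# Huberized (smoothed) hinge: equals the hinge outside a gamma-window
# around the kink; objective gap to the true hinge is at most gamma/2 per
# active sample, so the continuation down to gamma = 1e-6 solves the exact
# problem to well below the 1e-6 comparison tolerance.
huber_hinge <- function(z, gamma) {
  out <- numeric(length(z))
  lo <- z <= 1 - gamma
  mid <- !lo & z < 1
  out[lo] <- 1 - z[lo] - gamma / 2
  out[mid] <- (1 - z[mid])^2 / (2 * gamma)
  out
}
huber_hinge_grad <- function(z, gamma) {
  g <- numeric(length(z))
  lo <- z <= 1 - gamma
  mid <- !lo & z < 1
  g[lo] <- -1
  g[mid] <- -(1 - z[mid]) / gamma
  g
}

# Solve min_{w,b} lambda||w||^2 + sum c_i hinge(y_i f_i) + mu sum (f_j-t_j)^2
# by BFGS on a smoothing continuation. Xb/yb may be NULL (no binary part),
# Xc/tc may be NULL (no continuous part).
solve_score_objective <- function(Xb, yb, cost, Xc, tc, mu, lambda,
                                  theta0 = NULL, tol = 1e-12) {
  d <- if (!is.null(Xb)) ncol(Xb) else ncol(Xc)
  theta <- theta0 %||% rep(0, d + 1)
  obj <- function(theta, gamma) {
    w <- theta[seq_len(d)]; b <- theta[d + 1]
    v <- lambda * sum(w^2)
    if (!is.null(Xb)) v <- v + sum(cost * huber_hinge(yb * (Xb %*% w + b), gamma))
    if (!is.null(Xc) && mu > 0) v <- v + mu * sum((Xc %*% w + b - tc)^2)
    v
  }
  grad <- function(theta, gamma) {
    w <- theta[seq_len(d)]; b <- theta[d + 1]
    gw <- 2 * lambda * w; gb <- 0
    if (!is.null(Xb)) {
      z <- as.numeric(Xb %*% w + b)
      g <- cost * huber_hinge_grad(yb * z, gamma) * yb
      gw <- gw + as.numeric(crossprod(Xb, g)); gb <- gb + sum(g)
    }
    if (!is.null(Xc) && mu > 0) {
      r <- as.numeric(Xc %*% w + b - tc)
      gw <- gw + 2 * mu * as.numeric(crossprod(Xc, r)); gb <- gb + 2 * mu * sum(r)
    }
    c(gw, gb)
  }
  gammas <- if (is.null(Xb)) 1e-6 else c(1e-1, 1e-3, 1e-6)
  for (g in gammas) {
    fit <- stats::optim(theta, obj, grad, gamma = g, method = "BFGS",
                        control = list(maxit = 1000, reltol = tol))
    theta <- fit$par
  }
  w <- theta[seq_len(d)]; b <- theta[d + 1]
  # exact (non-smoothed) objective at the solution
  val <- lambda * sum(w^2)
  if (!is.null(Xb)) val <- val + sum(cost * pmax(0, 1 - yb * (Xb %*% w + b)))
  if (!is.null(Xc) && mu > 0) val <- val + mu * sum((Xc %*% w + b - tc)^2)
  list(w = w, b = b, objective = as.numeric(val))
}

# per-sample costs from the box constraint
svm_costs <- function(y, C, class_weight) {
  n <- length(y)
  if (identical(class_weight, "balanced")) {
    cnt <- table(factor(y, levels = c(-1, 1)))
    C * n / (2 * as.numeric(cnt[as.character(y)]))
  } else rep(C, n)
}

# explicit feature map of the inhomogeneous polynomial kernel (1 + x.y)^d
poly_features <- function(X, degree) {
  X <- as.matrix(X)
  expand <- function(A, B) {                 # all products of columns
    out <- matrix(0, nrow(A), ncol(A) * ncol(B))
    k <- 0L
    for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
      k <- k + 1L; out[, k] <- A[, i] * B[, j]
    }
    out
  }
  base <- cbind(1, X)                        # (1, x); tensor powers give (1+x.y)^d
  out <- base
  if (degree > 1) for (k in 2:degree) out <- expand(out, base)
  out
}

#' Fit a soft-margin SVM in the projected space
#'
#' Linear (default) or polynomial-kernel support vector classifier with a
#' small box constraint (`C = 0.01`, the study default) and balanced class
#' weighting (per-class penalty inversely proportional to class size).
#' Decision scores are continuous. The polynomial kernel is trained through
#' its explicit feature map and is intended for comparison runs only: it
#' admits no exact per-feature back-projection.
#'
#' @param X n x K numeric matrix of projected coordinates.
#' @param y labels in `{-1, +1}` (logicals/factors with two levels accepted).
#' @param C box constraint (default 0.01).
#' @param kernel `"linear"` or `"polynomial"`.
#' @param degree polynomial degree (default 2), ignored for linear.
#' @param class_weight `"balanced"` (default) or `"none"`.
#' @return An object of class `linear_model`: list with `w`, `b`,
#'   `objective`, `method`, `kernel`, and training metadata.
#' @export
fit_svm <- function(X, y, C = 0.01, kernel = c("linear", "polynomial"),
                    degree = 2L, class_weight = "balanced") {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- to_pm1(y)
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  cost <- svm_costs(y, C, class_weight)
  Xt <- if (kernel == "polynomial") poly_features(X, degree) else X
  sol <- solve_score_objective(Xt, y, cost, NULL, NULL, 0, lambda = 0.5)
  structure(list(w = sol$w, b = sol$b, objective = sol$objective,
                 method = "svm", kernel = kernel,
                 degree = if (kernel == "polynomial") degree else NULL,
                 C = C, class_weight = class_weight, lambda = 0.5, mu = 0,
                 K = ncol(X), model_id = NULL, metadata = list()),
            class = "linear_model")
}

to_pm1 <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1, -1))
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stopf("binary labels must have two levels")
    return(ifelse(y == levels(y)[2], 1, -1))
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stopf("numeric labels must be -1/+1")
  y
}

#' Assemble an MLVO problem
#'
#' Joint binary/continuous training data for [fit_mlvo()]. Every sample
#' must carry at least one label type; `NA` marks an absent label.
#' Continuous labels live on the (normalized) log-binding scale.
#'
#' @param X n x K coordinates.
#' @param y_bin binary labels in `{-1, +1}` with `NA` for unlabelled
#'   samples (or `NULL` for none).
#' @param y_cont continuous labels with `NA` for unlabelled samples (or
#'   `NULL`).
#' @param C box constraint used to build the hinge costs (default 0.01).
#' @param lambda ridge weight on `w` (default 1/2, the libsvm scale).
#' @param mu weight of the continuous squared-error loss (default 1).
#' @param class_weight `"balanced"` or `"none"`.
#' @return an object of class `mlvo_problem`.
#' @export
mlvo_problem <- function(X, y_bin = NULL, y_cont = NULL, C = 0.01,
                         lambda = 0.5, mu = 1, class_weight = "balanced") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (mu < 0) stopf("mu must be non-negative")
  if (is.null(y_bin)) y_bin <- rep(NA_real_, n)
  else { tmp <- rep(NA_real_, n); ok <- !is.na(y_bin); tmp[ok] <- to_pm1(y_bin[ok]); y_bin <- tmp }
  if (is.null(y_cont)) y_cont <- rep(NA_real_, n)
  y_cont <- as.numeric(y_cont)
  if (length(y_bin) != n || length(y_cont) != n)
    stopf("label lengths must match nrow(X)")
  if (any(is.na(y_bin) & is.na(y_cont)))
    stopf("every sample needs at least one label")
  if (all(is.na(y_bin)) && all(is.na(y_cont))) stopf("no labels at all")
  structure(list(X = X, y_bin = y_bin, y_cont = y_cont, C = C,
                 lambda = lambda, mu = mu, class_weight = class_weight),
            class = "mlvo_problem")
}

#' Fit a multi-label vector optimization (MLVO) model
#'
#' Minimizes `lambda ||w||^2 + sum_i c_i hinge(y_i (w.x_i + b)) +`
#' `mu sum_j (w.x_j + b - t_j)^2` over the samples carrying binary and/or
#' continuous labels. The single shared score ties the binary class to the
#' continuous affinity (the assumed monotone link). With `mu = 0` (or no
#' continuous labels) the fit reduces to [fit_svm()].
#'
#' @param problem an [mlvo_problem()].
#' @param theta0 optional warm start `c(w, b)`.
#' @return a `linear_model` with `method = "mlvo"`.
#' @export
fit_mlvo <- function(problem, theta0 = NULL) {
  stopifnot(inherits(problem, "mlvo_problem"))
  bi <- !is.na(problem$y_bin); ci <- !is.na(problem$y_cont)
  Xb <- if (any(bi)) problem$X[bi, , drop = FALSE] else NULL
  yb <- problem$y_bin[bi]
  cost <- if (any(bi)) svm_costs(yb, problem$C, problem$class_weight) else NULL
  Xc <- if (any(ci) && problem$mu > 0) problem$X[ci, , drop = FALSE] else NULL
  tc <- problem$y_cont[ci]
  if (is.null(Xb) && is.null(Xc))
    stopf("no usable labels (mu = 0 with only continuous labels)")
  sol <- solve_score_objective(Xb, yb, cost, Xc, tc, problem$mu,
                               problem$lambda, theta0 = theta0)
  structure(list(w = sol$w, b = sol$b, objective = sol$objective,
                 method = "mlvo", kernel = "linear", C = problem$C,
                 class_weight = problem$class_weight,
                 lambda = problem$lambda, mu = problem$mu,
                 K = ncol(problem$X), model_id = NULL, metadata = list()),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("linear_model (%s, %s kernel): K = %d, objective = %.6g\n",
              x$method, x$kernel, x$K, x$objective))
  invisible(x)
}

#' Decision scores of a fitted model
#'
#' `w . x + b` per row; monotone in predicted binding.
#'
#' @param model a `linear_model`.
#' @param X matrix in the space the model was trained in (projected
#'   coordinates; raw coordinates for polynomial kernels are expanded
#'   automatically).
#' @return numeric vector of scores.
#' @export
score <- function(model, X) {
  stopifnot(inherits(model, "linear_model"))
  X <- as.matrix(X)
  if (identical(model$kernel, "polynomial")) X <- poly_features(X, model$degree)
  if (ncol(X) != length(model$w))
    stopf("dimension mismatch: data has %d columns, model expects %d",
          ncol(X), length(model$w))
  as.numeric(X %*% model$w + model$b)
}

#' Back-project model weights to per-feature betas
#'
#' Maps the K-dimensional weight vector back through a linear projection to
#' one beta per (position, residue) feature, with the projection's
#' centering absorbed into the intercept, so that
#' `score = X_onehot . betas + intercept` holds exactly. Refused for
#' polynomial kernels (no linear preimage) and for MCA (the row-profile
#' normalization makes the projection nonlinear in the indicators).
#'
#' @param model a linear `linear_model`.
#' @param projection the `projection_model` the training coordinates came
#'   from ([fit_pca()] or [fit_identity()]).
#' @return the `linear_model` augmented with `betas` (named per-feature
#'   vector) and `intercept`.
#' @export
back_project <- function(model, projection) {
  stopifnot(inherits(model, "linear_model"),
            inherits(projection, "projection_model"))
  if (identical(model$kernel, "polynomial"))
    stopf("polynomial kernels admit no exact linear back-projection")
  if (projection$method == "mca")
    stopf("MCA projections are not linear in the indicators; back-projection refused")
  if (length(model$w) != ncol(projection$components))
    stopf("model dimension does not match projection K")
  betas <- as.numeric(projection$components %*% model$w)
  names(betas) <- rownames(projection$components)
  model$betas <- betas
  model$intercept <- model$b - sum(projection$center * betas)
  model
}

#' Per-position contribution of a beta vector
#'
#' Sums `|beta|` over the residues of each position, then min-max
#' normalizes across positions so the most influential position scores 1
#' and the least scores 0.
#'
#' @param betas named numeric vector of per-feature betas (names
#'   `R80`-style) or a back-projected `linear_model`.
#' @param feature_labels optional data frame with `position` per beta
#'   (defaults to parsing the names).
#' @return named numeric vector of per-position contributions in `[0, 1]`.
#' @export
position_contributions <- function(betas, feature_labels = NULL) {
  if (inherits(betas, "linear_model")) {
    if (is.null(betas$betas)) stopf("model has no betas; run back_project() first")
    betas <- betas$betas
  }
  pos <- if (!is.null(feature_labels)) feature_labels$position
         else as.integer(sub("^[A-Z*]+", "", names(betas)))
  if (anyNA(pos)) stopf("cannot determine positions of the beta features")
  s <- c(tapply(abs(betas), pos, sum))   # plain named numeric
  if (length(s) == 1L) return(stats::setNames(1, names(s)))
  rng <- range(s)
  if (rng[2] == rng[1]) return(stats::setNames(rep(0, length(s)), names(s)))
  (s - rng[1]) / (rng[2] - rng[1])
}

#' Reference dual solver for the linear SVM (oracle)
#'
#' Solves the SVM dual box-constrained quadratic program
#' `max sum(alpha) - 1/(4 lambda) || sum alpha_i y_i x_i ||^2` subject to
#' `0 <= alpha_i <= c_i`, `sum alpha_i y_i = 0` by accelerated projected
#' gradient (FISTA), recovering `w` from the dual variables and the
#' intercept by exact minimization of the piecewise-linear primal in `b`.
#' This is an independent route to the same optimum used to validate
#' [fit_svm()]; it is exact but slow and not meant for production fits.
#'
#' @param X,y,C,class_weight as in [fit_svm()].
#' @param max_iter,tol iteration controls.
#' @return list with `w`, `b`, `objective` (primal objective value).
#' @export
svm_dual_reference <- function(X, y, C = 0.01, class_weight = "balanced",
                               max_iter = 200000L, tol = 1e-14) {
  X <- as.matrix(X); y <- to_pm1(y)
  n <- nrow(X); lambda <- 0.5
  cc <- svm_costs(y, C, class_weight)
  Q <- (y %o% y) * (X %*% t(X)) / (2 * lambda)
  # projection onto {0 <= a <= c, sum a*y = 0} via bisection on the shift
  proj <- function(a) {
    f <- function(th) sum(y * pmin(pmax(a - th * y, 0), cc))
    lo <- -(max(cc) + max(abs(a)) + 1); hi <- -lo
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    pmin(pmax(a - (lo + hi) / 2 * y, 0), cc)
  }
  Lip <- max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  a <- proj(rep(0, n)); z <- a; t0 <- 1
  for (it in seq_len(max_iter)) {
    g <- Q %*% z - 1
    a_new <- proj(as.numeric(z - g / Lip))
    t1 <- (1 + sqrt(1 + 4 * t0^2)) / 2
    z <- a_new + ((t0 - 1) / t1) * (a_new - a)
    if (max(abs(a_new - a)) < tol && it > 10) { a <- a_new; break }
    a <- a_new; t0 <- t1
  }
  w <- as.numeric(crossprod(X, a * y)) / (2 * lambda)
  # exact line search in b: weighted hinge in b is piecewise linear
  f0 <- as.numeric(X %*% w)
  bp <- sort(unique((1 - y * f0) / y))
  primal_b <- function(b) sum(cc * pmax(0, 1 - y * (f0 + b)))
  cand <- unique(c(bp, (bp[-1] + bp[-length(bp)]) / 2))
  b <- cand[which.min(vapply(cand, primal_b, numeric(1)))]
  list(w = w, b = b,
       objective = lambda * sum(w^2) + primal_b(b))
}
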