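# SIMCA-equivalent chemometrics core: PCA, NIPALS PLS2, multiclass OPLS-DA
# with VIP scores, stratified 7-fold Q2 cross-validation, label-permutation
# testing and CV-ANOVA.

#' Principal component analysis
#'
#' Thin wrapper around [stats::prcomp()] (column-centered, unscaled)
#' returning scores, loadings and explained-variance fractions.
#'
#' @param x Numeric matrix, samples x features.
#' @param k Number of components, at most `rank(x)`.
#' @return List with `scores` (n x k), `loadings` (p x k), `explained`
#'   (length-k fractions, non-increasing).
#' @export
pca <- function(x, k = 2L) {
  x <- as.matrix(x)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  pos <- pc$sdev^2 > max(pc$sdev^2) * 1e-12
  rk <- sum(pos)
  if (k > rk) stop("k = ", k, " exceeds the matrix rank (", rk, ")")
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       center = pc$center)
}

#' NIPALS PLS2 regression
#'
#' Fits a partial least-squares model of `y` (one or more columns) on `x`
#' by the NIPALS algorithm.  Both blocks are column-centered internally.
#' With `a = rank(x)` the fitted values coincide with the ordinary
#' least-squares fit.
#'
#' @param x Predictor matrix.
#' @param y Response matrix or vector.
#' @param a Number of latent components.
#' @param tol NIPALS inner-loop convergence tolerance.
#' @return List with score matrix `scores` (T), weights `weights` (W),
#'   x-loadings `loadings` (P), y-loadings `yloadings` (Q), rotated weights
#'   `wstar` (W(P'W)^-1), regression coefficients `coef` (for centered
#'   blocks), centers, fitted values and per-component explained y sums of
#'   squares `ssq_y`.
#' @export
pls_nipals <- function(x, y, a, tol = 1e-10) {
  x <- as.matrix(x); y <- as.matrix(y)
  storage.mode(x) <- "double"; storage.mode(y) <- "double"
  stopifnot(nrow(x) == nrow(y), a >= 1L)
  x_mean <- colMeans(x); y_mean <- colMeans(y)
  e <- sweep(x, 2L, x_mean); f <- sweep(y, 2L, y_mean)
  if (all(abs(e) < 1e-300)) stop("x has zero variance")
  n <- nrow(e); p <- ncol(e); m <- ncol(y)
  W <- matrix(0, p, a); P <- matrix(0, p, a); Q <- matrix(0, m, a)
  TT <- matrix(0, n, a); ssq <- numeric(a)
  for (comp in seq_len(a)) {
    u <- f[, which.max(colSums(f^2))]
    if (sum(f^2) < 1e-24) stop("response exhausted before component ", comp,
                               ": more components than useful rank")
    repeat {
      w <- crossprod(e, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) stop("more components than rank of x")
      w <- w / nw
      t_ <- e %*% w
      tt <- sum(t_^2)
      if (tt < 1e-14) stop("more components than rank of x")
      q <- crossprod(f, t_) / tt
      if (m == 1L) break
      u_new <- f %*% q / sum(q^2)
      if (sum((u_new - u)^2) / max(sum(u_new^2), 1e-300) < tol^2) {
        u <- u_new; break
      }
      u <- u_new
    }
    p_ <- crossprod(e, t_) / tt
    e <- e - t_ %*% t(p_)
    f <- f - t_ %*% t(q)
    W[, comp] <- w; P[, comp] <- p_; Q[, comp] <- q; TT[, comp] <- t_
    ssq[comp] <- tt * sum(q^2)
  }
  wstar <- W %*% solve(crossprod(P, W))
  coef <- wstar %*% t(Q)
  fitted <- sweep(TT %*% t(Q), 2L, y_mean, `+`)
  rownames(W) <- rownames(P) <- rownames(wstar) <- colnames(x)
  list(scores = TT, weights = W, loadings = P, yloadings = Q,
       wstar = wstar, coef = coef, x_mean = x_mean, y_mean = y_mean,
       fitted = fitted, ssq_y = ssq, residual_y = f)
}

# Orthonormal basis (Gram-Schmidt) of the columns of m, dropping
# numerically null directions.
.orthonormal_basis <- function(m) {
  keep <- NULL
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (!is.null(keep)) v <- v - keep %*% crossprod(keep, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-10) keep <- cbind(keep, v / nv)
  }
  keep
}

#' Fit an OPLS(-DA) model
#'
#' Orthogonal partial least-squares discriminant analysis: class-uncorrelated
#' (orthogonal) variation is stripped from `x` by orthogonal signal
#' correction before a NIPALS PLS2 fit of the remaining predictive
#' variation on the one-hot class matrix.  With `a_orth = 0` the model
#' reduces exactly to [pls_nipals()].
#'
#' @param x Numeric matrix (already scaled as desired, e.g. unit variance).
#' @param labels Class labels; every class needs >= 2 samples.
#' @param a_pred Number of predictive components (default: classes - 1).
#' @param a_orth Number of orthogonal components (default 1).
#' @return An `opls` object: predictive scores `scores`, orthogonal scores
#'   `scores_orth`, weights/loadings for both blocks, `r2y`, per-feature
#'   `vip` (mean VIP^2 = 1), class levels and centering parameters.
#' @examples
#' x <- matrix(rnorm(60), 20); y <- rep(c("a", "b"), each = 10)
#' m <- opls_fit(x, y, a_pred = 1, a_orth = 1)
#' @export
opls_fit <- function(x, labels, a_pred = NULL, a_orth = 1L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("need >= 2 classes")
  if (any(tab < 2L)) {
    stop("degenerate class with a single sample: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  a_pred <- as.integer(a_pred %||% (length(tab) - 1L))
  if (a_pred < 1L) stop("`a_pred` must be >= 1")
  if (a_orth < 0L) stop("`a_orth` must be >= 0")
  y <- one_hot(labels)
  x_mean <- colMeans(x)
  e <- sweep(x, 2L, x_mean)
  yc <- sweep(y, 2L, colMeans(y))
  w_orth <- p_orth <- NULL
  t_orth <- matrix(0, nrow(x), 0L)
  for (j in seq_len(a_orth)) {
    basis <- .orthonormal_basis(crossprod(e, yc))
    comp <- pls_nipals(e, yc, a = 1L)
    p_ <- comp$loadings[, 1L]
    wo <- if (is.null(basis)) p_ else p_ - basis %*% crossprod(basis, p_)
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break  # no y-uncorrelated variation left
    wo <- wo / nwo
    to <- e %*% wo
    po <- crossprod(e, to) / sum(to^2)
    e <- e - to %*% t(po)
    w_orth <- cbind(w_orth, wo); p_orth <- cbind(p_orth, po)
    t_orth <- cbind(t_orth, to)
  }
  fit <- pls_nipals(e, y, a = a_pred)
  ss_y <- sum(yc^2)
  r2y <- 1 - sum(fit$residual_y^2) / ss_y
  w <- fit$weights
  ssq <- fit$ssq_y
  vip <- sqrt(ncol(x) * as.vector(w^2 %*% ssq) / sum(ssq))
  names(vip) <- colnames(x)
  structure(list(scores = fit$scores, scores_orth = t_orth,
                 weights = fit$weights, loadings = fit$loadings,
                 yloadings = fit$yloadings, wstar = fit$wstar,
                 coef = fit$coef, weights_orth = w_orth,
                 loadings_orth = p_orth, x_mean = x_mean,
                 y_mean = fit$y_mean, r2y = r2y, vip = vip,
                 a_pred = a_pred, a_orth = ncol(t_orth),
                 classes = colnames(y), labels = labels, q2 = NULL),
            class = "opls")
}

#' @export
print.opls <- function(x, ...) {
  cat(sprintf("OPLS-DA model: %d classes, A_pred = %d, A_orth = %d\n",
              length(x$classes), x$a_pred, x$a_orth))
  cat(sprintf("  R2Y = %.3f", x$r2y))
  if (!is.null(x$q2)) cat(sprintf(", Q2 = %.3f", x$q2))
  cat("\n")
  invisible(x)
}

# Remove fitted orthogonal variation from new (uncentered) data, then
# return the centered predictive block.
.opls_filter <- function(object, newx) {
  e <- sweep(as.matrix(newx), 2L, object$x_mean)
  if (object$a_orth > 0L) {
    for (j in seq_len(object$a_orth)) {
      to <- e %*% object$weights_orth[, j]
      e <- e - to %*% t(object$loadings_orth[, j])
    }
  }
  e
}

#' Predict from an OPLS model
#'
#' @param object An `opls` object.
#' @param newx New data matrix on the scale the model was fitted on.
#' @param type `"response"` for the predicted class-indicator matrix,
#'   `"class"` for hard class labels, `"scores"` for predictive scores.
#' @param ... Unused.
#' @export
predict.opls <- function(object, newx, type = c("response", "class", "scores"),
                         ...) {
  type <- match.arg(type)
  e <- .opls_filter(object, newx)
  if (type == "scores") return(e %*% object$wstar)
  yhat <- sweep(e %*% object$coef, 2L, object$y_mean, `+`)
  colnames(yhat) <- object$classes
  if (type == "class") return(object$classes[max.col(yhat, "first")])
  yhat
}

#' Variable importance in projection
#'
#' VIP over the predictive components:
#' `VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)` where `SS_a` is the
#' class-matrix sum of squares explained by component `a`.  The mean of the
#' squared VIPs equals 1 for every model.
#'
#' @param object A fitted `opls` object.
#' @param ... Unused.
#' @return Non-negative per-feature vector.
#' @export
vip <- function(object, ...) UseMethod("vip")

#' @export
vip.opls <- function(object, ...) object$vip

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin across folds.
.stratified_folds <- function(labels, folds, seed) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' Seven-fold (by default) stratified cross-validation: each fold's class
#' matrix is predicted from a model refitted without it, and
#' `Q2 = 1 - PRESS / SS_Y` with `SS_Y` the mean-corrected class-matrix sum
#' of squares.
#'
#' @inheritParams opls_fit
#' @param folds Number of folds (>= 2); every training part must contain
#'   all classes.
#' @param seed Seed for the stratified fold assignment.
#' @return A `q2_cv` object: `q2`, `press`, `ss_y`, the cross-validated
#'   residual matrix `residuals`, fold ids and the total component count.
#' @export
q2_crossval <- function(x, labels, a_pred = NULL, a_orth = 1L, folds = 7L,
                        seed = 1L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (folds < 2L) stop("`folds` must be >= 2")
  y <- one_hot(labels)
  a_pred <- as.integer(a_pred %||% (ncol(y) - 1L))
  fold <- .stratified_folds(labels, folds, seed)
  resid <- matrix(NA_real_, nrow(x), ncol(y), dimnames = list(NULL, colnames(y)))
  for (k in sort(unique(fold))) {
    tr <- fold != k
    if (length(unique(labels[tr])) < ncol(y) || min(table(labels[tr])) < 2L) {
      stop("a class is (nearly) absent from a training fold; use fewer folds")
    }
    m <- opls_fit(x[tr, , drop = FALSE], labels[tr], a_pred = a_pred,
                  a_orth = a_orth)
    yhat <- predict(m, x[!tr, , drop = FALSE], type = "response")
    resid[!tr, ] <- y[!tr, colnames(yhat), drop = FALSE] - yhat
  }
  press <- sum(resid^2)
  ss_y <- sum(sweep(y, 2L, colMeans(y))^2)
  structure(list(q2 = 1 - press / ss_y, press = press, ss_y = ss_y,
                 residuals = resid, folds = fold,
                 a_total = a_pred + a_orth, n = nrow(x)),
            class = "q2_cv")
}

#' CV-ANOVA significance test
#'
#' F-test comparing the cross-validated predictive residuals against the
#' total class-matrix variation around its mean (Eriksson-style CV-ANOVA):
#' `F = ((SS_Y - PRESS) / A) / (PRESS / (N - A - 1))` with `A` the total
#' number of fitted components.  Models whose cross-validated predictions
#' are no better than the mean give p near 1.
#'
#' @param cv A `q2_cv` object from [q2_crossval()].
#' @return p-value in `[0, 1]`.
#' @export
cv_anova <- function(cv) {
  stopifnot(inherits(cv, "q2_cv"))
  if (cv$ss_y <= 0) stop("zero total class-matrix variance")
  a <- cv$a_total
  df2 <- cv$n - a - 1L
  if (df2 < 1L) stop("too few samples for CV-ANOVA degrees of freedom")
  f <- max(0, (cv$ss_y - cv$press) / a) / (cv$press / df2)
  pf(f, a, df2, lower.tail = FALSE)
}

#' Label-permutation test for an OPLS-DA model
#'
#' Refits the model `n_perm` times with randomly permuted class labels,
#' recording for each permutation the correlation between the permuted and
#' original class matrices together with the permuted R2Y and Q2.  A model
#' that is not overfitted shows the original Q2 well above the permuted
#' distribution.
#'
#' @inheritParams q2_crossval
#' @param n_perm Number of permutations (200 in the classical display).
#' @return An `opls_permutation` object with `original` (R2Y, Q2) and a
#'   data frame `permuted` (`cor`, `r2y`, `q2`).
#' @export
permutation_test <- function(x, labels, n_perm = 200L, seed = 1L,
                             a_pred = NULL, a_orth = 1L, folds = 7L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (n_perm < 0L) stop("`n_perm` must be >= 0")
  fit <- opls_fit(x, labels, a_pred = a_pred, a_orth = a_orth)
  q2 <- q2_crossval(x, labels, a_pred = fit$a_pred, a_orth = a_orth,
                    folds = folds, seed = seed)$q2
  y0 <- one_hot(labels)
  perm <- with_seed(seed, {
    rows <- lapply(seq_len(n_perm), function(i) {
      pl <- sample(labels)
      yp <- one_hot(pl, levels_ = colnames(y0))
      pf_ <- opls_fit(x, pl, a_pred = fit$a_pred, a_orth = a_orth)
      pq2 <- tryCatch(
        q2_crossval(x, pl, a_pred = fit$a_pred, a_orth = a_orth,
                    folds = folds, seed = seed + i)$q2,
        error = function(e) NA_real_)
      c(cor = cor(as.vector(yp), as.vector(y0)), r2y = pf_$r2y, q2 = pq2)
    })
    as.data.frame(do.call(rbind, rows))
  })
  structure(list(original = c(r2y = fit$r2y, q2 = q2),
                 permuted = perm, n_perm = as.integer(n_perm)),
            class = "opls_permutation")
}

#' @export
print.opls_permutation <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations)\n", x$n_perm))
  cat(sprintf("  original R2Y = %.3f, Q2 = %.3f\n",
              x$original["r2y"], x$original["q2"]))
  if (x$n_perm > 0L) {
    cat(sprintf("  permuted Q2 below original: %.0f%%\n",
                100 * mean(x$permuted$q2 < x$original["q2"], na.rm = TRUE)))
  }
  invisible(x)
}
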