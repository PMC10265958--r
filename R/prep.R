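# Preprocessing: total-area normalization, Z-score standardization and
# supervised 2-D reduction (PLS-DR).  The pipeline order is fixed:
# normalize -> split -> zscore_fit on train -> plsdr_fit on train; held-out
# rows are only ever transformed with training-set parameters.

#' Total-area normalization
#'
#' Rescales every row of a peak table so its feature sum equals the cohort
#' median total area.  Idempotent; applied (if at all) before any
#' train/validation split.
#'
#' @param table A peak table.
#' @return The normalized peak table.
#' @export
normalize_total_area <- function(table) {
  m <- peak_matrix(table)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    stop("non-positive total area for sample(s): ",
         paste(table$sample_id[totals <= 0], collapse = ", "))
  }
  target <- median(totals)
  m <- m * (target / totals)
  table[, peak_features(table)] <- m
  table
}

#' Fit / apply Z-score standardization
#'
#' `zscore_fit` computes per-feature training means and population
#' (1/n) standard deviations; `zscore_apply` standardizes any matrix with
#' those frozen parameters, so validation and external rows never leak into
#' the statistics.
#'
#' @param x Numeric training matrix (samples x features), >= 2 rows.
#' @param drop_constant Drop zero-variance features instead of erroring?
#' @return `zscore_fit`: a `zscore_params` object (means, SDs, retained
#'   feature names, any dropped features).  `zscore_apply`: the standardized
#'   matrix restricted to retained features.
#' @export
zscore_fit <- function(x, drop_constant = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 rows to fit a scaler")
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  const <- sdev <= .Machine$double.eps * 10
  dropped <- character(0)
  if (any(const)) {
    if (!drop_constant) {
      stop("constant training column(s): ",
           paste(colnames(x)[const] %||% which(const), collapse = ", "),
           " (set drop_constant = TRUE to remove)")
    }
    dropped <- colnames(x)[const] %||% as.character(which(const))
    mu <- mu[!const]
    sdev <- sdev[!const]
  }
  structure(list(mean = mu, sd = sdev,
                 features = names(mu) %||% seq_along(mu),
                 dropped = dropped),
            class = "zscore_params")
}

#' @rdname zscore_fit
#' @param params A `zscore_params` object.
#' @export
zscore_apply <- function(params, x) {
  stopifnot(inherits(params, "zscore_params"))
  x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    missing <- setdiff(params$features, colnames(x))
    if (length(missing)) {
      stop("missing feature(s): ", paste(missing, collapse = ", "))
    }
    x <- x[, params$features, drop = FALSE]
  }
  sweep(sweep(x, 2L, params$mean), 2L, params$sd, `/`)
}

# One-hot (dummy) class encoding with fixed level order.
one_hot <- function(labels, levels_ = NULL) {
  f <- factor(labels, levels = levels_ %||% unique(as.character(labels)))
  if (anyNA(f)) stop("labels outside the declared class levels")
  y <- model.matrix(~ f - 1)
  colnames(y) <- levels(f)
  attr(y, "assign") <- NULL
  attr(y, "contrasts") <- NULL
  y
}

#' Supervised 2-D reduction (PLS-DR)
#'
#' `plsdr_fit` fits a two-component NIPALS PLS2 model of the standardized
#' feature matrix against the one-hot class encoding and keeps the x-side
#' projection; `plsdr_apply` maps any matrix into the two latent
#' coordinates.  The two training score vectors are mutually orthogonal.
#'
#' @param x Standardized training matrix (>= 2 columns).
#' @param labels Class labels (>= 2 classes present).
#' @return `plsdr_fit`: a `plsdr_params` object; `plsdr_apply`: an n x 2
#'   coordinate matrix.
#' @export
plsdr_fit <- function(x, labels) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need >= 2 feature columns for PLS-DR")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("need >= 2 classes to fit PLS-DR")
  y <- one_hot(labels)
  # Degenerate (numerically rank-1) feature blocks arise in the noise-free
  # limit; fall back to a single latent variable with a zero second axis.
  fit <- tryCatch(pls_nipals(x, y, a = 2L), error = function(e) NULL)
  if (is.null(fit)) {
    fit <- pls_nipals(x, y, a = 1L)
    fit$wstar <- cbind(fit$wstar, 0)
    fit$scores <- cbind(fit$scores, 0)
  }
  structure(list(x_mean = fit$x_mean, wstar = fit$wstar[, 1:2, drop = FALSE],
                 classes = colnames(y), scores = fit$scores),
            class = "plsdr_params")
}

#' @rdname plsdr_fit
#' @param params A `plsdr_params` object.
#' @export
plsdr_apply <- function(params, x) {
  stopifnot(inherits(params, "plsdr_params"))
  x <- as.matrix(x)
  out <- sweep(x, 2L, params$x_mean) %*% params$wstar
  colnames(out) <- c("LV1", "LV2")
  out
}
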