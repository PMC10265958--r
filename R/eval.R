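# Metrics and validation workflows: confusion-matrix reports, macro
# one-vs-rest AUC, decision-region export, internal/external validation and
# tandem-vs-flat model comparison.

#' Evaluate predictions against truth
#'
#' @param predictions Predicted leaf labels, or the route data frame from
#'   [predict.wound_tandem()] (its `leaf` column is used and the routes are
#'   kept in the report).
#' @param truth True leaf labels, same length.
#' @param levels Class level order for the confusion matrix (defaults to
#'   the sorted union of both label sets).
#' @return An `eval_report`: `n`, `n_correct`, `accuracy`, `confusion`
#'   (true x predicted), per-class `recall`, and `routes` when available.
#' @export
evaluate <- function(predictions, truth, levels = NULL) {
  routes <- NULL
  if (is.data.frame(predictions)) {
    routes <- predictions
    predictions <- predictions$leaf
  }
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  if (length(predictions) != length(truth)) {
    stop("`predictions` and `truth` must have equal length")
  }
  levels <- levels %||% sort(unique(c(truth, predictions)))
  if (!all(truth %in% levels) || !all(predictions %in% levels)) {
    stop("labels outside the declared class levels")
  }
  tf <- factor(truth, levels = levels)
  pf_ <- factor(predictions, levels = levels)
  confusion <- table(truth = tf, predicted = pf_)
  n <- length(truth)
  n_correct <- sum(diag(confusion))
  recall <- diag(confusion) / pmax(rowSums(confusion), 1L)
  structure(list(n = n, n_correct = n_correct, accuracy = n_correct / n,
                 confusion = confusion, recall = recall, routes = routes),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Accuracy: %d / %d = %.1f%%\n", x$n_correct, x$n,
              100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

# Rank-based (Mann-Whitney, midrank ties) one-vs-rest AUC for one class.
.auc_binary <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged one-vs-rest ROC AUC
#'
#' Computes a rank-based (trapezoidal, midrank-tied) AUC for each class's
#' score column against the one-vs-rest truth, then averages over classes.
#' Classes absent from `truth` are excluded with a warning.
#'
#' @param class_scores Numeric matrix n x K, columns named by class.
#' @param truth True class labels.
#' @return Macro AUC in `[0, 1]`.
#' @export
roc_auc_macro <- function(class_scores, truth) {
  class_scores <- as.matrix(class_scores)
  truth <- as.character(truth)
  if (is.null(colnames(class_scores))) {
    stop("`class_scores` columns must be named by class")
  }
  missing_scores <- setdiff(unique(truth), colnames(class_scores))
  if (length(missing_scores)) {
    stop("no score column for class(es): ",
         paste(missing_scores, collapse = ", "))
  }
  present <- colnames(class_scores) %in% truth
  if (!all(present)) {
    warning("class(es) absent from truth excluded: ",
            paste(colnames(class_scores)[!present], collapse = ", "))
  }
  aucs <- vapply(colnames(class_scores)[present], function(cl) {
    .auc_binary(class_scores[, cl], truth == cl)
  }, numeric(1))
  mean(aucs)
}

#' Decision-region grid of a node classifier
#'
#' Evaluates a node's classifier over a regular grid of the 2-D reduced
#' space, for hyperplane-style plots or CSV export.
#'
#' @param node A `tandem_node`.
#' @param bbox Numeric `c(x_min, x_max, y_min, y_max)`; defaults to the
#'   node's training-score range padded by 10%.
#' @param grid_n Grid resolution per axis.
#' @return Data frame with `grid_n^2` rows: `LV1`, `LV2`, `label`.
#' @export
decision_regions <- function(node, bbox = NULL, grid_n = 100L) {
  stopifnot(inherits(node, "tandem_node"))
  if (!is.null(node$passthrough)) stop("passthrough node has no classifier")
  if (is.null(bbox)) {
    r1 <- range(node$train_coords[, 1L]); r2 <- range(node$train_coords[, 2L])
    pad1 <- 0.1 * diff(r1); pad2 <- 0.1 * diff(r2)
    bbox <- c(r1[1] - pad1, r1[2] + pad1, r2[1] - pad2, r2[2] + pad2)
  }
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) {
    stop("degenerate bounding box")
  }
  gx <- seq(bbox[1], bbox[2], length.out = grid_n)
  gy <- seq(bbox[3], bbox[4], length.out = grid_n)
  grid <- expand.grid(LV1 = gx, LV2 = gy, KEEP.OUT.ATTRS = FALSE)
  lab <- as.character(predict(node$classifier, as.matrix(grid)))
  cbind(grid, label = lab, stringsAsFactors = FALSE)
}

#' Internal validation of a tandem model
#'
#' Routes every contused study sample (training and validation alike)
#' through the full tandem pipeline and scores the predicted leaf windows
#' against the windows containing each sample's true time label.
#'
#' @param tandem A `wound_tandem` model.
#' @param study_table A peak table with the contused study rows.
#' @return An `eval_report` (with per-sample routes).
#' @export
run_internal_validation <- function(tandem, study_table) {
  study <- study_table[study_table$role == "study" &
                         study_table$label != tandem$control_label, ,
                       drop = FALSE]
  if (nrow(study) == 0L) stop("no contused study rows to validate on")
  routes <- predict(tandem, study)
  truth <- leaf_of(tandem$scheme, study$label)
  evaluate(routes, truth, levels = scheme_leaves(tandem$scheme))
}

#' External validation of a tandem model
#'
#' @param tandem A `wound_tandem` model.
#' @param external_table Peak table of held-out samples (`role =
#'   "external"`).
#' @param key Answer key (`sample_id`, `label`) as returned by
#'   [generate_external()].
#' @return An `eval_report`.
#' @export
run_external_validation <- function(tandem, external_table, key) {
  ext <- external_table[external_table$role == "external", , drop = FALSE]
  if (nrow(ext) == 0L) stop("empty external sample set")
  truth_label <- key$label[match(ext$sample_id, key$sample_id)]
  if (anyNA(truth_label)) stop("answer key misses sample(s)")
  routes <- predict(tandem, ext)
  truth <- leaf_of(tandem$scheme, truth_label)
  evaluate(routes, truth, levels = scheme_leaves(tandem$scheme))
}

#' Compare the tandem model with flat single-level baselines
#'
#' For each seed, fits the tandem model and the four flat baselines on the
#' identical stratified split and scores both by internal validation over
#' all contused study samples.  The differential screen is deterministic,
#' so panels are assembled once and shared.
#'
#' @param study_table A peak table with study rows.
#' @param scheme A [group_scheme()].
#' @param specs Candidate learner specs.
#' @param seeds Integer vector of seeds.
#' @param ... Passed to [tandem_fit()] (thresholds etc.).
#' @return A `model_comparison`: long data frame `results` (seed, model,
#'   accuracy), aggregate `medians`, and `scatter` counts per (model,
#'   actual, predicted) cell.
#' @export
compare_models <- function(study_table, scheme = group_scheme(),
                           specs = learner_specs(), seeds = 1:10, ...) {
  panels <- assemble_panels(study_table[study_table$role == "study", ,
                                        drop = FALSE], scheme)
  res <- list(); scat <- list()
  truth_all <- NULL
  for (s in seeds) {
    tm <- tandem_fit(study_table, scheme, specs, seed = s, panels = panels,
                     ...)
    fl <- flat_baseline(study_table, scheme, specs, seed = s,
                        panels = panels)
    study <- study_table[study_table$role == "study" &
                           study_table$label != "control", , drop = FALSE]
    truth <- leaf_of(scheme, study$label)
    rep_t <- run_internal_validation(tm, study_table)
    res[[length(res) + 1L]] <- data.frame(seed = s, model = "tandem",
                                          accuracy = rep_t$accuracy)
    scat[[length(scat) + 1L]] <- cbind(model = "tandem", seed = s,
                                       as.data.frame(rep_t$confusion))
    for (nm in names(fl$models)) {
      pred <- node_predict(fl$models[[nm]], study)
      rep_f <- evaluate(pred, truth, levels = scheme_leaves(scheme))
      res[[length(res) + 1L]] <- data.frame(seed = s, model = nm,
                                            accuracy = rep_f$accuracy)
      scat[[length(scat) + 1L]] <- cbind(model = nm, seed = s,
                                         as.data.frame(rep_f$confusion))
    }
  }
  results <- do.call(rbind, res)
  scatter <- do.call(rbind, scat)
  names(scatter)[names(scatter) == "Freq"] <- "count"
  medians <- tapply(results$accuracy, results$model, median)
  structure(list(results = results, medians = medians, scatter = scatter,
                 seeds = seeds),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Internal-validation accuracy over", length(x$seeds), "seeds (median):\n")
  ord <- c("LR", "SVM", "RF", "MLP", "tandem")
  m <- x$medians[intersect(ord, names(x$medians))]
  print(round(m, 3))
  invisible(x)
}
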