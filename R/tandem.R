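# Two-level tandem classifier: a first-level node assigns a coarse
# post-injury phase, then a group-specific second-level node assigns the
# final wound-age window.  Every node owns its feature panel, scaler,
# PLS-DR reducer and selected classifier.

#' Wound-age grouping scheme
#'
#' Defines the coarse phases and the leaf wound-age windows.  The default
#' mirrors the contusion study: Group I (4-12 h), Group II (16-32 h),
#' Group III (36-48 h), subdivided into seven windows
#' 4, 8, 12, 16-20, 24-32, 36-40 and 44-48 h.
#'
#' @param coarse Named list: coarse group -> character vector of hour labels.
#' @param leaves Named list of named lists: coarse group -> (leaf label ->
#'   hour labels).  Leaves must partition their group's labels.
#' @return A `group_scheme` object.
#' @examples
#' sch <- group_scheme()
#' scheme_leaves(sch)
#' @export
group_scheme <- function(coarse = NULL, leaves = NULL) {
  if (is.null(coarse)) {
    coarse <- list(I = c("4", "8", "12"),
                   II = c("16", "20", "24", "28", "32"),
                   III = c("36", "40", "44", "48"))
  }
  if (is.null(leaves)) {
    leaves <- list(
      I = list(`4` = "4", `8` = "8", `12` = "12"),
      II = list(`16-20` = c("16", "20"), `24-32` = c("24", "28", "32")),
      III = list(`36-40` = c("36", "40"), `44-48` = c("44", "48")))
  }
  stopifnot(is.list(coarse), is.list(leaves),
            identical(sort(names(coarse)), sort(names(leaves))))
  all_labels <- unlist(coarse, use.names = FALSE)
  if (anyDuplicated(all_labels)) stop("coarse groups must not overlap")
  for (g in names(coarse)) {
    labs <- sort(unlist(leaves[[g]], use.names = FALSE))
    if (!identical(labs, sort(coarse[[g]]))) {
      stop("leaves of group ", g, " must partition its labels")
    }
  }
  structure(list(coarse = coarse, leaves = leaves), class = "group_scheme")
}

#' @rdname group_scheme
#' @param scheme A `group_scheme`.
#' @return `scheme_leaves`: leaf labels in scheme order.
#' @export
scheme_leaves <- function(scheme) {
  unlist(lapply(scheme$leaves, names), use.names = FALSE)
}

#' @rdname group_scheme
#' @param labels Hour labels to map.
#' @return `coarse_of` / `leaf_of`: the coarse group / leaf of each label.
#' @export
coarse_of <- function(scheme, labels) {
  map <- unlist(lapply(names(scheme$coarse), function(g) {
    setNames(rep(g, length(scheme$coarse[[g]])), scheme$coarse[[g]])
  }))
  out <- map[as.character(labels)]
  if (anyNA(out)) stop("label(s) outside the scheme: ",
                       paste(unique(labels[is.na(out)]), collapse = ", "))
  unname(out)
}

#' @rdname group_scheme
#' @export
leaf_of <- function(scheme, labels) {
  map <- unlist(lapply(scheme$leaves, function(lv) {
    unlist(lapply(names(lv), function(leaf) {
      setNames(rep(leaf, length(lv[[leaf]])), lv[[leaf]])
    }))
  }), use.names = TRUE)
  names(map) <- sub("^[^.]*\\.", "", names(map))
  out <- map[as.character(labels)]
  if (anyNA(out)) stop("label(s) outside the scheme: ",
                       paste(unique(labels[is.na(out)]), collapse = ", "))
  unname(out)
}

#' @export
print.group_scheme <- function(x, ...) {
  cat("Wound-age grouping scheme:", length(x$coarse), "coarse groups,",
      length(scheme_leaves(x)), "leaf windows\n")
  for (g in names(x$coarse)) {
    cat(sprintf("  %s (%s h): leaves %s\n", g,
                paste(range(as.numeric(x$coarse[[g]])), collapse = "-"),
                paste(names(x$leaves[[g]]), collapse = ", ")))
  }
  invisible(x)
}

#' Candidate learner specifications
#'
#' The four candidate classifiers trained at every node, with the study's
#' hyperparameters: logistic regression (L-BFGS-style quasi-Newton fit),
#' SVM with `C = 1.5` (radial kernel by default), random forest with 128
#' trees, and an MLP with hidden layers (32, 32), Adam optimizer, adaptive
#' learning rate and at most 3000 iterations.
#'
#' @param svm_kernel Kernel for the SVM candidate (`"radial"` or
#'   `"linear"`).
#' @return Named list of learner specs, in the order LR, SVM, RF, MLP.
#' @export
learner_specs <- function(svm_kernel = "radial") {
  list(LR = list(kind = "LR", maxit = 1000L),
       SVM = list(kind = "SVM", cost = 1.5, kernel = svm_kernel),
       RF = list(kind = "RF", ntree = 128L),
       MLP = list(kind = "MLP", hidden = c(32L, 32L), max_iter = 3000L))
}

#' Stratified train/validation split
#'
#' Randomly splits a peak table into training and validation rows,
#' stratified by class label; per class, `round(frac * n)` samples (at
#' least 1, at most n - 1) go to training.
#'
#' @param table A peak table.
#' @param frac Training fraction, in (0, 1).
#' @param seed Split seed.
#' @param by Optional vector of class labels aligned with `table` rows
#'   (defaults to `table$label`).
#' @return List with logical `train` indicator plus `train`/`validation`
#'   sample-id vectors.
#' @export
split_train_val <- function(table, frac = 0.7, seed = 1L, by = NULL) {
  if (frac <= 0 || frac >= 1) stop("`frac` must lie strictly in (0, 1)")
  cls <- as.character(by %||% table$label)
  tab <- table(cls)
  if (any(tab < 2L)) {
    stop("class(es) with a single sample cannot be split: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  train <- logical(length(cls))
  with_seed(seed, {
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      n_tr <- min(max(round(frac * length(idx)), 1L), length(idx) - 1L)
      train[sample(idx, n_tr)] <- TRUE
    }
  })
  list(train = train,
       train_ids = table$sample_id[train],
       validation_ids = table$sample_id[!train])
}

# -- candidate learners ------------------------------------------------------

fit_learner <- function(spec, x, y, seed) {
  x <- as.matrix(x)
  colnames(x) <- c("LV1", "LV2")
  y <- factor(y)
  fit <- switch(spec$kind,
    LR = {
      df <- data.frame(y = y, x)
      with_seed(seed, nnet::multinom(y ~ LV1 + LV2, data = df,
                                     maxit = spec$maxit %||% 1000L,
                                     trace = FALSE))
    },
    SVM = with_seed(seed, suppressWarnings(
      # degenerate 2nd latent axis (noise-free limit) triggers a harmless
      # constant-column scaling warning
      e1071::svm(x, y, kernel = spec$kernel %||% "radial",
                 cost = spec$cost %||% 1.5, probability = TRUE))),
    RF = with_seed(seed, randomForest::randomForest(
      x, y, ntree = spec$ntree %||% 128L)),
    MLP = mlp_fit(x, y, hidden = spec$hidden %||% c(32L, 32L),
                  max_iter = spec$max_iter %||% 3000L, seed = seed),
    stop("unknown learner kind: ", spec$kind))
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 classes = levels(y), seed = seed),
            class = "wound_learner")
}

#' @export
predict.wound_learner <- function(object, newx, type = c("class", "prob"),
                                  ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  colnames(newx) <- c("LV1", "LV2")
  cls <- object$classes
  if (type == "class") {
    out <- switch(object$kind,
      LR = as.character(predict(object$fit,
                                newdata = as.data.frame(newx))),
      SVM = as.character(predict(object$fit, newx)),
      RF = as.character(predict(object$fit, newx)),
      MLP = as.character(predict(object$fit, newx, type = "class")))
    return(factor(out, levels = cls))
  }
  prob <- switch(object$kind,
    LR = {
      pr <- predict(object$fit, newdata = as.data.frame(newx),
                    type = "probs")
      if (is.null(dim(pr))) {
        if (length(cls) == 2L) pr <- cbind(1 - pr, pr) else pr <- rbind(pr)
      }
      colnames(pr) <- cls
      pr
    },
    SVM = {
      pr <- attr(predict(object$fit, newx, probability = TRUE),
                 "probabilities")
      pr[, cls, drop = FALSE]
    },
    RF = predict(object$fit, newx, type = "prob")[, cls, drop = FALSE],
    MLP = predict(object$fit, newx, type = "prob")[, cls, drop = FALSE])
  prob
}

#' Train a tandem node
#'
#' Fits the node's scaler (on training rows only), its 2-D PLS-DR reducer,
#' and all candidate learners on the reduced training data, then selects
#' the candidate with the highest validation accuracy.  Ties resolve in
#' favour of the later entry in the order LR < SVM < RF < MLP, preferring
#' the deeper model.  Candidates that fail to train are excluded with a
#' warning.
#'
#' @param train,val Peak-table rows for training and validation.
#' @param class_labels Function or named map from hour label to node class;
#'   or a character vector aligned with `rbind(train, val)` rows.
#' @param panel Feature names the node may use.
#' @param specs Candidate learner specs ([learner_specs()]).
#' @param seed Node seed.
#' @return A `tandem_node` object.
#' @export
train_node <- function(train, val, class_labels, panel,
                       specs = learner_specs(), seed = 1L) {
  cls_of <- function(tab) {
    if (is.function(class_labels)) {
      vapply(tab$label, class_labels, character(1))
    } else {
      unname(class_labels[as.character(tab$label)])
    }
  }
  y_tr <- cls_of(train)
  if (length(unique(y_tr)) < 2L) {
    stop("node training data contains a single class")
  }
  m_tr <- peak_matrix(train, log = TRUE)[, panel, drop = FALSE]
  scaler <- zscore_fit(m_tr, drop_constant = TRUE)
  z_tr <- zscore_apply(scaler, m_tr)
  reducer <- plsdr_fit(z_tr, y_tr)
  c_tr <- plsdr_apply(reducer, z_tr)
  has_val <- !is.null(val) && nrow(val) > 0L
  if (has_val) {
    y_va <- cls_of(val)
    m_va <- peak_matrix(val, log = TRUE)[, panel, drop = FALSE]
    c_va <- plsdr_apply(reducer, zscore_apply(scaler, m_va))
  }
  fits <- list(); acc <- setNames(rep(NA_real_, length(specs)), names(specs))
  for (nm in names(specs)) {
    fit <- tryCatch(fit_learner(specs[[nm]], c_tr, y_tr, seed = seed),
                    error = function(e) {
                      warning("candidate ", nm, " failed: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(fit)) next
    fits[[nm]] <- fit
    acc[nm] <- if (has_val) {
      mean(as.character(predict(fit, c_va)) == y_va)
    } else {
      mean(as.character(predict(fit, c_tr)) == y_tr)
    }
  }
  if (!length(fits)) stop("all candidate learners failed")
  ok <- names(fits)
  best <- ok[max(which(acc[ok] == max(acc[ok], na.rm = TRUE)))]
  structure(list(panel = panel, scaler = scaler, reducer = reducer,
                 classifier = fits[[best]], chosen = best,
                 classes = fits[[best]]$classes,
                 val_accuracy = acc, seed = seed,
                 train_coords = c_tr, train_classes = y_tr),
            class = "tandem_node")
}

# Map peak-table rows through a node's scaler + reducer.
node_reduce <- function(node, table) {
  feats <- peak_features(table)
  missing <- setdiff(node$panel, feats)
  if (length(missing)) {
    stop("sample table lacks panel feature(s): ",
         paste(missing, collapse = ", "))
  }
  m <- peak_matrix(table, log = TRUE)[, node$panel, drop = FALSE]
  plsdr_apply(node$reducer, zscore_apply(node$scaler, m))
}

node_predict <- function(node, table) {
  if (!is.null(node$passthrough)) {
    return(rep(node$passthrough, nrow(table)))
  }
  as.character(predict(node$classifier, node_reduce(node, table)))
}

#' @export
print.tandem_node <- function(x, ...) {
  if (!is.null(x$passthrough)) {
    cat("Passthrough node ->", x$passthrough, "\n")
    return(invisible(x))
  }
  cat(sprintf("Tandem node: %d features -> 2-D, classes {%s}\n",
              length(x$panel), paste(x$classes, collapse = ", ")))
  cat("  chosen:", x$chosen, " validation accuracy:",
      paste(sprintf("%s=%.3f", names(x$val_accuracy), x$val_accuracy),
            collapse = " "), "\n")
  invisible(x)
}

#' Fit the two-level tandem wound-age model
#'
#' The central model fit.  Control samples are used only for the
#' differential screen; classifier training uses the contused study rows,
#' split 70/30 (stratified by leaf window).  The first-level node is
#' trained on the coarse phases over the union panel; each second-level
#' node is trained only on its coarse group's rows with its own panel,
#' scaler and reducer.  At every node, LR, SVM, RF and MLP candidates are
#' trained and the best validation accuracy wins.
#'
#' @param table A peak table with study rows (control + contusion groups).
#' @param scheme A [group_scheme()].
#' @param specs Candidate learner specs ([learner_specs()]).
#' @param seed Master seed; the split and every node seed derive from it.
#' @param split_frac Training fraction of the 70/30 split.
#' @param vip_thr,q_thr Screening thresholds for [assemble_panels()].
#' @param normalize Apply [normalize_total_area()] first?
#' @param panels Optional precomputed [assemble_panels()] result (the
#'   screen is deterministic, so it can be shared across seeds).
#' @param control_label Label of the control group.
#' @return A `wound_tandem` object with `level1`, `level2`, `panels`,
#'   `scheme` and the recorded split.
#' @examples
#' \donttest{
#' cfg <- synthetic_config(n_background = 50, seed = 1)
#' tab <- generate_study(cfg)
#' fit <- tandem_fit(tab, seed = 1)
#' fit
#' }
#' @export
tandem_fit <- function(table, scheme = group_scheme(),
                       specs = learner_specs(), seed = 1L,
                       split_frac = 0.7, vip_thr = 1, q_thr = 0.05,
                       normalize = FALSE, panels = NULL,
                       control_label = "control") {
  stopifnot(inherits(scheme, "group_scheme"))
  if (normalize) table <- normalize_total_area(table)
  study <- table[table$role == "study", , drop = FALSE]
  if (is.null(panels)) {
    panels <- assemble_panels(study, scheme, control_label = control_label,
                              vip_thr = vip_thr, q_thr = q_thr)
  }
  contused <- study[study$label != control_label, , drop = FALSE]
  leaves <- leaf_of(scheme, contused$label)
  split <- split_train_val(contused, frac = split_frac, seed = seed,
                           by = leaves)
  tr <- contused[split$train, , drop = FALSE]
  va <- contused[!split$train, , drop = FALSE]
  coarse_map <- function(lab) coarse_of(scheme, lab)
  level1 <- if (length(scheme$coarse) == 1L) {
    # degenerate scheme: the tandem is just its single level-2 node
    structure(list(passthrough = names(scheme$coarse)),
              class = "tandem_node")
  } else {
    train_node(tr, va, coarse_map, panels$union, specs = specs, seed = seed)
  }
  level2 <- list()
  for (g in names(scheme$coarse)) {
    in_g_tr <- coarse_of(scheme, tr$label) == g
    in_g_va <- coarse_of(scheme, va$label) == g
    lv <- scheme$leaves[[g]]
    if (length(lv) < 2L) {
      level2[[g]] <- structure(list(passthrough = names(lv)),
                               class = "tandem_node")
      next
    }
    leaf_map <- function(lab) leaf_of(scheme, lab)
    level2[[g]] <- train_node(tr[in_g_tr, , drop = FALSE],
                              va[in_g_va, , drop = FALSE],
                              leaf_map, panels$groups[[g]], specs = specs,
                              seed = seed + match(g, names(scheme$coarse)))
  }
  structure(list(scheme = scheme, panels = panels, level1 = level1,
                 level2 = level2, specs = specs, seed = as.integer(seed),
                 split = split[c("train_ids", "validation_ids")],
                 normalize = normalize, control_label = control_label),
            class = "wound_tandem")
}

#' Predict wound-age windows with a tandem model
#'
#' Routes every sample through the first-level node to a coarse phase,
#' then through that phase's second-level node to a leaf window.  Each
#' node standardizes and reduces the sample with its own fitted
#' parameters, so the predicted leaf always lies inside the predicted
#' coarse group.
#'
#' @param object A `wound_tandem` model.
#' @param newdata A peak table whose features cover all node panels.
#' @param ... Unused.
#' @return Data frame `sample_id`, `coarse`, `leaf` (the route record),
#'   one row per sample, in input order.
#' @export
predict.wound_tandem <- function(object, newdata, ...) {
  if (nrow(newdata) == 0L) {
    return(data.frame(sample_id = character(0), coarse = character(0),
                      leaf = character(0), stringsAsFactors = FALSE))
  }
  if (object$normalize) newdata <- normalize_total_area(newdata)
  coarse <- node_predict(object$level1, newdata)
  leaf <- character(nrow(newdata))
  for (g in unique(coarse)) {
    idx <- coarse == g
    leaf[idx] <- node_predict(object$level2[[g]],
                              newdata[idx, , drop = FALSE])
  }
  data.frame(sample_id = newdata$sample_id, coarse = coarse, leaf = leaf,
             stringsAsFactors = FALSE)
}

#' @export
print.wound_tandem <- function(x, ...) {
  cat("Two-level tandem wound-age model\n")
  cat(sprintf("  union panel: %d features; leaves: %s\n",
              length(x$panels$union),
              paste(scheme_leaves(x$scheme), collapse = ", ")))
  if (!is.null(x$level1$passthrough)) {
    cat(sprintf("  level 1: passthrough -> %s\n", x$level1$passthrough))
  } else {
    cat(sprintf("  level 1 [%s]: %s\n", x$level1$chosen,
                paste(sprintf("%s=%.3f", names(x$level1$val_accuracy),
                              x$level1$val_accuracy), collapse = " ")))
  }
  for (g in names(x$level2)) {
    n2 <- x$level2[[g]]
    if (!is.null(n2$passthrough)) {
      cat(sprintf("  level 2 %s: passthrough -> %s\n", g, n2$passthrough))
    } else {
      cat(sprintf("  level 2 %s [%s]: %s\n", g, n2$chosen,
                  paste(sprintf("%s=%.3f", names(n2$val_accuracy),
                                n2$val_accuracy), collapse = " ")))
    }
  }
  invisible(x)
}

#' @export
summary.wound_tandem <- function(object, ...) {
  acc <- if (is.null(object$level1$passthrough)) {
    rbind(level1 = object$level1$val_accuracy)
  } else {
    NULL
  }
  for (g in names(object$level2)) {
    n2 <- object$level2[[g]]
    if (is.null(n2$passthrough)) {
      acc <- rbind(acc, n2$val_accuracy)
      rownames(acc)[nrow(acc)] <- paste0("level2_", g)
    }
  }
  out <- list(accuracies = acc,
              chosen = c(level1 = object$level1$chosen %||% "passthrough",
                         vapply(object$level2, function(n)
                           n$chosen %||% "passthrough", character(1))),
              panel_counts = object$panels$counts)
  class(out) <- "summary.wound_tandem"
  out
}

#' @export
print.summary.wound_tandem <- function(x, ...) {
  cat("Per-node candidate validation accuracies:\n")
  print(round(x$accuracies, 3))
  cat("Chosen learners:\n")
  print(x$chosen)
  cat("Panel sizes:\n")
  print(x$panel_counts)
  invisible(x)
}

#' Plot a tandem node's decision regions
#'
#' Base-graphics rendering of the 2-D classification regions of the
#' first-level node (or any node), with the training scores overlaid.
#'
#' @param x A `wound_tandem` model.
#' @param node Which node: `"level1"` or a coarse group name.
#' @param grid_n Grid resolution.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.wound_tandem <- function(x, node = "level1", grid_n = 120L, ...) {
  nd <- if (identical(node, "level1")) x$level1 else x$level2[[node]]
  if (is.null(nd) || !is.null(nd$passthrough)) {
    stop("node '", node, "' has no decision surface")
  }
  grid <- decision_regions(nd, grid_n = grid_n)
  cls <- sort(unique(grid$label))
  cols <- grDevices::hcl.colors(max(3L, length(cls)), "Set 2")[seq_along(cls)]
  graphics::plot(grid$LV1, grid$LV2, col = cols[match(grid$label, cls)],
                 pch = 15, cex = 0.5, xlab = "LV1", ylab = "LV2", ...)
  graphics::points(nd$train_coords, pch = 21,
                   bg = cols[match(nd$train_classes, cls)])
  graphics::legend("topright", legend = cls, fill = cols, bty = "n")
  invisible(x)
}

#' Flat single-level baseline models
#'
#' Trains the four candidate learners as one-stage classifiers over all
#' leaf windows, on the same union panel and the same stratified split as
#' the tandem model, for comparison.
#'
#' @inheritParams tandem_fit
#' @return A `flat_models` object: shared scaler/reducer, one fitted
#'   learner per spec with its validation accuracy, and the split record.
#' @export
flat_baseline <- function(table, scheme = group_scheme(),
                          specs = learner_specs(), seed = 1L,
                          split_frac = 0.7, panels = NULL,
                          control_label = "control", ...) {
  study <- table[table$role == "study", , drop = FALSE]
  if (is.null(panels)) {
    panels <- assemble_panels(study, scheme, control_label = control_label,
                              ...)
  }
  contused <- study[study$label != control_label, , drop = FALSE]
  leaves <- leaf_of(scheme, contused$label)
  split <- split_train_val(contused, frac = split_frac, seed = seed,
                           by = leaves)
  leaf_map <- function(lab) leaf_of(scheme, lab)
  models <- list()
  for (nm in names(specs)) {
    models[[nm]] <- train_node(contused[split$train, , drop = FALSE],
                               contused[!split$train, , drop = FALSE],
                               leaf_map, panels$union,
                               specs = specs[nm], seed = seed)
  }
  structure(list(models = models, panels = panels, scheme = scheme,
                 seed = as.integer(seed),
                 split = split[c("train_ids", "validation_ids")],
                 val_accuracy = vapply(models, function(m)
                   unname(m$val_accuracy[m$chosen]), numeric(1))),
            class = "flat_models")
}

#' @export
print.flat_models <- function(x, ...) {
  cat("Flat one-stage baselines over",
      length(scheme_leaves(x$scheme)), "leaf windows\n")
  print(round(x$val_accuracy, 3))
  invisible(x)
}
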