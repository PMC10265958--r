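# Text-only model-bundle serialization: a YAML manifest (scheme, specs,
# seeds, chosen learners, panels) plus per-node CSV parameter files
# (scaler, reducer, reduced training data).  Classifiers are refitted
# deterministically from the stored 2-D training data and node seed on
# load, so a round-tripped bundle predicts identically.

.node_dirname <- function(name) gsub("[^A-Za-z0-9_-]", "_", name)

.save_node <- function(node, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(node$passthrough)) {
    yaml::write_yaml(list(passthrough = node$passthrough),
                     file.path(dir, "node.yaml"))
    return(invisible(dir))
  }
  yaml::write_yaml(list(panel = node$panel, chosen = node$chosen,
                        spec = node$classifier$spec, seed = node$seed,
                        classes = node$classes,
                        val_accuracy = as.list(node$val_accuracy),
                        scaler_dropped = node$scaler$dropped),
                   file.path(dir, "node.yaml"))
  write.csv(data.frame(feature = node$scaler$features,
                       mean = unname(node$scaler$mean),
                       sd = unname(node$scaler$sd)),
            file.path(dir, "scaler.csv"), row.names = FALSE)
  write.csv(data.frame(feature = names(node$reducer$x_mean),
                       x_mean = unname(node$reducer$x_mean),
                       w1 = node$reducer$wstar[, 1L],
                       w2 = node$reducer$wstar[, 2L]),
            file.path(dir, "reducer.csv"), row.names = FALSE)
  write.csv(data.frame(LV1 = node$train_coords[, 1L],
                       LV2 = node$train_coords[, 2L],
                       class = node$train_classes),
            file.path(dir, "train.csv"), row.names = FALSE)
  invisible(dir)
}

.load_node <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "node.yaml"))
  if (!is.null(meta$passthrough)) {
    return(structure(list(passthrough = meta$passthrough),
                     class = "tandem_node"))
  }
  sc <- read.csv(file.path(dir, "scaler.csv"), stringsAsFactors = FALSE)
  scaler <- structure(list(mean = setNames(sc$mean, sc$feature),
                           sd = setNames(sc$sd, sc$feature),
                           features = sc$feature,
                           dropped = unlist(meta$scaler_dropped) %||%
                             character(0)),
                      class = "zscore_params")
  rd <- read.csv(file.path(dir, "reducer.csv"), stringsAsFactors = FALSE)
  reducer <- structure(list(x_mean = setNames(rd$x_mean, rd$feature),
                            wstar = cbind(rd$w1, rd$w2),
                            classes = unlist(meta$classes)),
                       class = "plsdr_params")
  rownames(reducer$wstar) <- rd$feature
  tr <- read.csv(file.path(dir, "train.csv"), stringsAsFactors = FALSE)
  coords <- as.matrix(tr[, c("LV1", "LV2")])
  y <- factor(tr$class, levels = unlist(meta$classes))
  classifier <- fit_learner(meta$spec, coords, y, seed = meta$seed)
  structure(list(panel = unlist(meta$panel), scaler = scaler,
                 reducer = reducer, classifier = classifier,
                 chosen = meta$chosen, classes = unlist(meta$classes),
                 val_accuracy = unlist(meta$val_accuracy),
                 seed = meta$seed, train_coords = coords,
                 train_classes = as.character(tr$class)),
            class = "tandem_node")
}

#' Save / load a tandem model bundle
#'
#' `save_tandem` writes a directory bundle: `manifest.yaml` (scheme,
#' learner specs, master seed, chosen learners) plus one subdirectory per
#' node holding its scaler, reducer and reduced training data as CSV.
#' `load_tandem` reconstructs the model; classifiers are refitted from the
#' stored node data under the stored seeds, so predictions are identical
#' to the original model's.
#'
#' @param tandem A `wound_tandem` model.
#' @param dir Bundle directory.
#' @return `save_tandem`: `dir`, invisibly.  `load_tandem`: a
#'   `wound_tandem` model.
#' @export
save_tandem <- function(tandem, dir) {
  stopifnot(inherits(tandem, "wound_tandem"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    scheme = list(coarse = tandem$scheme$coarse,
                  leaves = tandem$scheme$leaves),
    specs = tandem$specs,
    seed = tandem$seed,
    normalize = tandem$normalize,
    control_label = tandem$control_label,
    split = tandem$split,
    panels = tandem$panels[c("union", "groups")],
    level2_nodes = names(tandem$level2))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  .save_node(tandem$level1, file.path(dir, "level1"))
  for (g in names(tandem$level2)) {
    .save_node(tandem$level2[[g]],
               file.path(dir, paste0("level2_", .node_dirname(g))))
  }
  invisible(dir)
}

#' @rdname save_tandem
#' @export
load_tandem <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  scheme <- group_scheme(
    coarse = lapply(manifest$scheme$coarse, as.character),
    leaves = lapply(manifest$scheme$leaves,
                    function(lv) lapply(lv, as.character)))
  level1 <- .load_node(file.path(dir, "level1"))
  level2 <- list()
  for (g in manifest$level2_nodes) {
    level2[[g]] <- .load_node(file.path(dir,
                                        paste0("level2_", .node_dirname(g))))
  }
  panels <- list(union = unlist(manifest$panels$union),
                 groups = lapply(manifest$panels$groups, unlist))
  panels$counts <- c(union = length(panels$union),
                     vapply(panels$groups, length, 1L))
  structure(list(scheme = scheme, panels = panels, level1 = level1,
                 level2 = level2, specs = manifest$specs,
                 seed = manifest$seed,
                 split = lapply(manifest$split, unlist),
                 normalize = isTRUE(manifest$normalize),
                 control_label = manifest$control_label),
            class = "wound_tandem")
}
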