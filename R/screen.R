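# Differential-feature screening: two-class OPLS-DA VIP combined with a
# Welch t-test and Benjamini-Hochberg FDR control (select when VIP > 1 and
# q < 0.05), per-level panel assembly for the tandem classifier, and
# metabolite clustering for heatmap ordering.

#' Feature-wise Welch t-test p-values
#'
#' Two-sided Welch (unequal-variance) t-test on log-transformed peak areas,
#' one test per feature, between two label groups of study samples.
#'
#' @param table A peak table.
#' @param labels_a,labels_b Character vectors of labels defining the two
#'   groups (each must cover >= 2 study rows).
#' @return Named per-feature p-value vector.
#' @export
univariate_p <- function(table, labels_a, labels_b) {
  study <- table[table$role == "study", , drop = FALSE]
  m <- peak_matrix(study, log = TRUE)
  ia <- study$label %in% as.character(labels_a)
  ib <- study$label %in% as.character(labels_b)
  if (sum(ia) < 2L || sum(ib) < 2L) {
    stop("each group needs >= 2 study samples")
  }
  welch_p(m[ia, , drop = FALSE], m[ib, , drop = FALSE])
}

# Vectorised two-sided Welch t-test over matching columns.
welch_p <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2L, var); v2 <- apply(b, 2L, var)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t_ <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(-abs(t_), df)
  # degenerate zero-variance columns: identical groups -> p = 1
  zero <- se2 <= 0 | !is.finite(t_)
  p[zero] <- ifelse(abs(m1 - m2)[zero] > 0, 0, 1)
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()], with input validation.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Screen differential features against control
#'
#' One comparison: the pooled case groups against the control group.  VIP
#' scores come from a two-class OPLS-DA (one predictive + one orthogonal
#' component) on unit-variance log areas; p-values from the feature-wise
#' Welch test; q-values from Benjamini-Hochberg across all features of the
#' comparison.  A feature is selected when `vip > vip_thr` and `q < q_thr`.
#' Only study rows ever enter the computation.
#'
#' @param table A peak table.
#' @param case_labels Labels of the case groups (e.g. the hours of one
#'   coarse phase).
#' @param control_label Label of the control group.
#' @param vip_thr,q_thr Selection thresholds.
#' @return A `screen_table` data frame: `feature,vip,p,q,selected,direction`.
#' @export
screen_features <- function(table, case_labels, control_label = "control",
                            vip_thr = 1, q_thr = 0.05) {
  study <- table[table$role == "study", , drop = FALSE]
  keep <- study$label %in% c(as.character(case_labels),
                             as.character(control_label))
  sub <- study[keep, , drop = FALSE]
  if (!any(sub$label == control_label)) stop("no control rows present")
  cls <- ifelse(sub$label == control_label, "control", "case")
  m <- peak_matrix(sub, log = TRUE)
  sc <- zscore_fit(m, drop_constant = TRUE)
  z <- zscore_apply(sc, m)
  fit <- opls_fit(z, cls, a_pred = 1L, a_orth = 1L)
  vips <- setNames(numeric(ncol(m)), colnames(m))
  vips[names(fit$vip)] <- fit$vip
  p <- welch_p(m[cls == "case", , drop = FALSE],
               m[cls == "control", , drop = FALSE])
  q <- bh_adjust(p)
  direction <- sign(colMeans(m[cls == "case", , drop = FALSE]) -
                      colMeans(m[cls == "control", , drop = FALSE]))
  out <- data.frame(feature = colnames(m), vip = unname(vips),
                    p = unname(p), q = unname(q),
                    selected = unname(vips > vip_thr & q < q_thr),
                    direction = unname(direction),
                    stringsAsFactors = FALSE)
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Export a screen table as CSV
#'
#' @param screen A `screen_table`.
#' @param path Output CSV path.
#' @export
write_screen_table <- function(screen, path) {
  write.csv(as.data.frame(screen), path, row.names = FALSE)
  invisible(path)
}

#' Assemble per-level feature panels for the tandem classifier
#'
#' For every coarse group of the scheme, screens the group's study samples
#' against control; the level-1 panel is the union of the per-group
#' selections, and each level-2 node panel is its group's screen restricted
#' to that union (so every node panel is contained in the union).
#'
#' @param study_table A peak table with study rows.
#' @param scheme A [group_scheme()].
#' @param control_label Control group label.
#' @param vip_thr,q_thr Selection thresholds passed to [screen_features()].
#' @return List with `union` (level-1 panel), `groups` (named list of node
#'   panels), and `counts`.
#' @export
assemble_panels <- function(study_table, scheme, control_label = "control",
                            vip_thr = 1, q_thr = 0.05) {
  stopifnot(inherits(scheme, "group_scheme"))
  screens <- lapply(scheme$coarse, function(labs) {
    s <- screen_features(study_table, labs, control_label,
                         vip_thr = vip_thr, q_thr = q_thr)
    s$feature[s$selected]
  })
  feats <- peak_features(study_table)
  union_panel <- feats[feats %in% unique(unlist(screens))]
  if (length(union_panel) == 0L) {
    stop("empty level-1 panel: no feature passes both thresholds; ",
         "consider a larger effect size")
  }
  groups <- lapply(screens, function(sel) union_panel[union_panel %in% sel])
  empty <- names(groups)[vapply(groups, length, 1L) == 0L]
  if (length(empty)) {
    stop("empty panel for group(s) ", paste(empty, collapse = ", "),
         "; consider a larger effect size")
  }
  list(union = union_panel, groups = groups,
       counts = c(union = length(union_panel),
                  vapply(groups, length, 1L)))
}

#' Hierarchical clustering of metabolite temporal profiles
#'
#' Ward-linkage agglomerative clustering (Euclidean distance on row
#' z-scored group means), as used to order metabolites in temporal
#' heatmaps.  Deterministic; ties resolve by input index order.
#'
#' @param group_mean_matrix Metabolites x groups matrix of mean (log)
#'   abundances.
#' @return List with `order` (leaf order), `merge`, `height` and the
#'   underlying [stats::hclust] object.
#' @export
hcluster_metabolites <- function(group_mean_matrix) {
  m <- as.matrix(group_mean_matrix)
  if (nrow(m) < 2L) stop("need >= 2 metabolites to cluster")
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans(sweep(m, 1L, mu)^2))
  sdev[sdev == 0] <- 1
  z <- sweep(sweep(m, 1L, mu), 1L, sdev, `/`)
  hc <- hclust(dist(z), method = "ward.D2")
  list(order = hc$order, merge = hc$merge, height = hc$height, hclust = hc)
}
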