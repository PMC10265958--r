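# Synthetic peak-table generator emulating the contusion study design:
# a control group plus 12 contusion time points (4..48 h, n = 9), pooled QC
# injections, and a small external test set.  Peak areas are log-normal;
# panel metabolites follow phase-structured temporal trajectories while
# background features are label-independent.

# Archetype log-scale phase profiles (rows: early-peak, mid-peak, late-rise,
# monotone-fall; columns: phases 4-12 h, 16-32 h, 36-48 h).  Adjacent-phase
# gaps are all 1.1 log units so between-phase separation dominates the
# within-phase substructure by exactly `phase_gap`.
.arch_profiles <- rbind(
  c(2.2, 1.1, 0.0),
  c(1.1, 2.2, 1.1),
  c(0.0, 1.1, 2.2),
  c(-0.8, -1.9, -3.0)
)
.arch_gap <- 1.1
.arch_dir <- c(1, -1, 1, -1)

#' Synthetic study configuration
#'
#' Bundles the design parameters of the synthetic contusion study.  Defaults
#' mirror the emulated design: 12 contusion time points (4 to 48 h in 4-h
#' steps) plus a control group, nine replicates per group (117 study
#' samples), 500 uninformative background features next to the 43-metabolite
#' panel, and 12 pooled-QC injections.
#'
#' @param timepoints Ordered numeric vector of contusion hours.
#' @param n_per_group Replicates per group (control and each time point).
#' @param n_background Number of label-independent background features.
#' @param effect_scale Dimensionless multiplier on the log-scale group-mean
#'   offsets; 0 gives a global null.
#' @param within_sd Log-scale within-group noise SD.
#' @param phase_gap Ratio (> 1) by which between-phase mean differences
#'   exceed within-phase differences.
#' @param qc_count Pooled-QC replicates appended by [add_qc()].
#' @param seed Integer RNG seed; all generator randomness flows from it.
#' @return A `synthetic_config` list.
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' @export
synthetic_config <- function(timepoints = seq(4, 48, by = 4),
                             n_per_group = 9L,
                             n_background = 500L,
                             effect_scale = 1,
                             within_sd = 0.25,
                             phase_gap = 3,
                             qc_count = 12L,
                             seed = 1L) {
  stopifnot(length(timepoints) >= 1L, !is.unsorted(timepoints),
            all(timepoints > 0))
  if (n_per_group < 1L) stop("`n_per_group` must be >= 1")
  if (effect_scale < 0) stop("`effect_scale` must be >= 0")
  if (within_sd <= 0) stop("`within_sd` must be > 0")
  if (phase_gap <= 1) stop("`phase_gap` must be > 1")
  if (n_background < 0L) stop("`n_background` must be >= 0")
  if (qc_count < 0L) stop("`qc_count` must be >= 0")
  structure(list(timepoints = as.numeric(timepoints),
                 n_per_group = as.integer(n_per_group),
                 n_background = as.integer(n_background),
                 effect_scale = effect_scale,
                 within_sd = within_sd,
                 phase_gap = phase_gap,
                 qc_count = as.integer(qc_count),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic contusion study design\n")
  cat("  time points :", paste(x$timepoints, collapse = ", "), "h\n")
  cat("  replicates  :", x$n_per_group, "per group (",
      (length(x$timepoints) + 1L) * x$n_per_group, "study samples )\n")
  cat("  features    : 43 panel +", x$n_background, "background\n")
  cat(sprintf("  effect_scale %.3g, within_sd %.3g, phase_gap %.3g, seed %d\n",
              x$effect_scale, x$within_sd, x$phase_gap, x$seed))
  invisible(x)
}

# Phase of a contusion hour: 1 = 4-12 h, 2 = 16-32 h, 3 = 36-48 h.
phase_of <- function(hours) {
  ifelse(hours <= 12, 1L, ifelse(hours <= 32, 2L, 3L))
}

# Position of a time point within its phase, mapped linearly to [-0.5, 0.5].
.phase_position <- function(label, timepoints) {
  ph <- phase_of(label)
  members <- timepoints[phase_of(timepoints) == ph]
  if (length(members) == 1L) return(0)
  r <- match(label, members)
  (r - 1) / (length(members) - 1) - 0.5
}

#' Expected log peak area of a panel metabolite
#'
#' Deterministic group-mean trajectory for panel metabolite `metabolite_index`
#' at a given label.  Metabolites cycle through four trajectory archetypes
#' (early-peak, mid-peak, late-rise, monotone-fall); between-phase mean
#' differences exceed within-phase differences by the factor
#' `config$phase_gap`, and the control group sits at baseline.
#'
#' @param metabolite_index Position in the packaged panel (1-based).
#' @param label `"control"` or a configured contusion hour (numeric or its
#'   character form).
#' @param config A [synthetic_config()].
#' @return Log-scale mean area.
#' @export
trajectory_mean <- function(metabolite_index, label, config) {
  stopifnot(metabolite_index >= 1L)
  base <- 13 + 0.2 * ((metabolite_index - 1) %% 5)
  if (identical(label, "control")) return(base)
  hours <- suppressWarnings(as.numeric(label))
  if (is.na(hours) || !hours %in% config$timepoints) {
    stop("unknown label: ", label)
  }
  a <- ((metabolite_index - 1) %% 4) + 1
  s <- .phase_position(hours, config$timepoints)
  base + config$effect_scale *
    (.arch_profiles[a, phase_of(hours)] +
       .arch_dir[a] * s * .arch_gap / config$phase_gap)
}

.panel_feature_names <- function() load_panel()$name

.background_means <- function(config) {
  if (config$n_background == 0L) return(numeric(0))
  12 + 0.3 * ((seq_len(config$n_background) - 1) %% 7)
}

.feature_ids <- function(config) {
  c(.panel_feature_names(),
    if (config$n_background > 0L)
      sprintf("bg_%04d", seq_len(config$n_background)))
}

.new_peak_table <- function(sample_id, label, role, areas, feature_ids) {
  df <- data.frame(sample_id = sample_id, label = label, role = role,
                   stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.data.frame(areas, check.names = FALSE)
  names(m) <- feature_ids
  out <- cbind(df, m)
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Feature columns of a peak table
#'
#' @param table A peak table (data frame with `sample_id`, `label`, `role`
#'   metadata columns followed by one column per feature).
#' @return Character vector of feature names.
#' @export
peak_features <- function(table) {
  setdiff(names(table), c("sample_id", "label", "role"))
}

#' Peak-area matrix of a peak table
#'
#' @inheritParams peak_features
#' @param log Return natural-log areas?
#' @return Numeric matrix, samples x features, rownames = sample ids.
#' @export
peak_matrix <- function(table, log = FALSE) {
  m <- as.matrix(table[, peak_features(table), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$sample_id
  if (log) log(m) else m
}

#' Generate the synthetic study samples
#'
#' Draws the control group and every contusion group of the configured
#' design.  Areas are `exp(mean + N(0, within_sd))` per feature: panel
#' metabolites follow [trajectory_mean()], background features share one
#' label-independent log-normal law.  Output is bit-reproducible for a fixed
#' config.
#'
#' @param config A [synthetic_config()].
#' @return A `peak_table` with `(length(timepoints) + 1) * n_per_group` study
#'   rows.
#' @examples
#' tab <- generate_study(synthetic_config(n_background = 20, seed = 1))
#' nrow(tab)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  labels <- c("control", as.character(config$timepoints))
  feat <- .feature_ids(config)
  p_panel <- length(.panel_feature_names())
  bg_mu <- .background_means(config)
  n <- length(labels) * config$n_per_group
  mu <- matrix(0, n, length(feat))
  row_label <- rep(labels, each = config$n_per_group)
  for (lab in labels) {
    idx <- which(row_label == lab)
    panel_mu <- vapply(seq_len(p_panel), trajectory_mean, numeric(1),
                       label = lab, config = config)
    mu[idx, ] <- matrix(c(panel_mu, bg_mu), nrow = length(idx),
                        ncol = length(feat), byrow = TRUE)
  }
  areas <- with_seed(config$seed, {
    exp(mu + matrix(rnorm(n * length(feat), sd = config$within_sd),
                    n, length(feat)))
  })
  ids <- sprintf("%s_r%02d",
                 ifelse(row_label == "control", "ctrl",
                        paste0("h", row_label)),
                 rep(seq_len(config$n_per_group), times = length(labels)))
  .new_peak_table(ids, row_label, "study", areas, feat)
}

#' Append pooled quality-control samples
#'
#' Emulates pooled QC injections: each QC row's expected area vector is the
#' per-feature mean of all study rows, with multiplicative log-normal noise
#' of SD `within_sd / 4` (pooling averages away biological variation).
#'
#' @param table A peak table with at least one study row.
#' @param config A [synthetic_config()]; `qc_count` rows are appended.
#' @return The table with `role = "qc"` rows appended.
#' @export
add_qc <- function(table, config) {
  stopifnot(inherits(config, "synthetic_config"))
  study <- table[table$role == "study", , drop = FALSE]
  if (nrow(study) == 0L) stop("`table` must contain at least one study row")
  if (config$qc_count == 0L) return(table)
  pool <- colMeans(peak_matrix(study))
  k <- config$qc_count
  noise <- with_seed(config$seed + 1L, {
    matrix(rnorm(k * length(pool), sd = config$within_sd / 4), k)
  })
  areas <- sweep(exp(noise), 2L, pool, `*`)
  qc <- .new_peak_table(sprintf("qc_%02d", seq_len(k)), "control", "qc",
                        areas, peak_features(table))
  qc$label <- "qc"
  out <- rbind(table, qc)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Generate external test samples with a hidden answer key
#'
#' Draws `n` samples at time labels sampled uniformly from the configured
#' time points (the emulated 13 external animals).  Labels in the returned
#' table are masked as `"unknown"`; the truth is returned separately.
#'
#' @param config A [synthetic_config()].
#' @param n Number of external samples.
#' @return List with `table` (a `peak_table`, `role = "external"`) and `key`
#'   (data frame `sample_id`, `label`).
#' @export
generate_external <- function(config, n = 13L) {
  stopifnot(inherits(config, "synthetic_config"), n >= 1L)
  feat <- .feature_ids(config)
  p_panel <- length(.panel_feature_names())
  bg_mu <- .background_means(config)
  res <- with_seed(config$seed + 2L, {
    labs <- as.character(config$timepoints[
      sample.int(length(config$timepoints), n, replace = TRUE)])
    mu <- t(vapply(labs, function(lab) {
      c(vapply(seq_len(p_panel), trajectory_mean, numeric(1),
               label = lab, config = config), bg_mu)
    }, numeric(length(feat))))
    areas <- exp(mu + matrix(rnorm(n * length(feat), sd = config$within_sd),
                             n, length(feat)))
    list(labs = labs, areas = areas)
  })
  ids <- sprintf("ext_%02d", seq_len(n))
  tab <- .new_peak_table(ids, "unknown", "external", res$areas, feat)
  list(table = tab, key = data.frame(sample_id = ids, label = res$labs,
                                     stringsAsFactors = FALSE))
}

#' Write / read a peak table as CSV
#'
#' The first columns are `sample_id,label,role`, followed by one column per
#' feature.  The round trip is lossless to at least 12 significant digits.
#'
#' @param table A peak table.
#' @param path CSV path.
#' @return `write_peak_table` returns `path` invisibly; `read_peak_table`
#'   returns a `peak_table`.
#' @export
write_peak_table <- function(table, path) {
  out <- table
  for (f in peak_features(out)) out[[f]] <- format(out[[f]], digits = 15L)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = c(sample_id = "character", label = "character",
                                role = "character"))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path)
  class(df) <- c("peak_table", "data.frame")
  df
}
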