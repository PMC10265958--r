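# Shared fixtures: small synthetic designs and toy classification data,
# all generated in code under fixed seeds.

small_config <- function(...) {
  synthetic_config(n_background = 50L, ...)
}

# Default-design study table with a reduced background block (the panel
# block is always the full 43 metabolites).
small_study <- function(seed = 1L, ...) {
  generate_study(small_config(seed = seed, ...))
}

# A linearly separable two-class toy peak table: two "hour" labels whose
# log areas differ strongly in every feature.
toy_two_class <- function(n_per_class = 10L, p = 6L, shift = 4, seed = 1L) {
  withr_seed <- function(code) { set.seed(seed); code }
  m <- withr_seed({
    rbind(matrix(rnorm(n_per_class * p, mean = 8), n_per_class),
          matrix(rnorm(n_per_class * p, mean = 8 + shift), n_per_class))
  })
  df <- data.frame(
    sample_id = sprintf("s%02d", seq_len(2L * n_per_class)),
    label = rep(c("4", "8"), each = n_per_class),
    role = "study", stringsAsFactors = FALSE)
  areas <- as.data.frame(exp(m))
  names(areas) <- sprintf("f%02d", seq_len(p))
  out <- cbind(df, areas)
  class(out) <- c("peak_table", "data.frame")
  out
}

# Fixed panels bypassing the screen, for null-effect designs where no
# feature passes the thresholds.
fixed_panels <- function(table, k = 43L) {
  feats <- peak_features(table)[seq_len(k)]
  list(union = feats,
       groups = list(I = feats, II = feats, III = feats),
       counts = c(union = k, I = k, II = k, III = k))
}
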