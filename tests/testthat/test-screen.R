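# Differential screening: Welch p-values, BH adjustment, VIP+FDR selection,
# panel assembly and heatmap clustering.

test_that("feature-wise Welch test matches stats::t.test", {
  tab <- small_study(seed = 3)
  p <- univariate_p(tab, c("4", "8", "12"), "control")
  m <- peak_matrix(tab, log = TRUE)
  in_a <- tab$label %in% c("4", "8", "12")
  in_b <- tab$label == "control"
  for (j in c(1, 17, 44, 60)) {
    expect_equal(p[[j]], t.test(m[in_a, j], m[in_b, j])$p.value,
                 tolerance = 1e-10)
  }
  # symmetry in the group order
  expect_equal(p, univariate_p(tab, "control", c("4", "8", "12")),
               tolerance = 1e-12)
})

test_that("identical groups give p = 1 and shifted groups tiny p", {
  tab <- toy_two_class(n_per_class = 5, p = 4, shift = 0, seed = 2)
  # make the two groups exact copies of each other
  tab[tab$label == "8", 4:7] <- tab[tab$label == "4", 4:7]
  expect_equal(unname(univariate_p(tab, "4", "8")), rep(1, 4))
  # 5-sigma mean shift at n = 9 vs 9: p below 1e-4
  set.seed(3)
  a <- matrix(rnorm(9 * 3), 9)
  b <- matrix(rnorm(9 * 3, mean = 5), 9)
  expect_true(all(woundage:::welch_p(a, b) < 1e-4))
  expect_error(univariate_p(tab, "4", "nonexistent"), ">= 2")
})

test_that("BH adjustment matches hand computation and base properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.07), 0.07)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.04, 0.9, 0.012, 0.5)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  # permutation invariance (up to reordering)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("screening selects informative features and controls the null", {
  tab <- small_study(seed = 1)
  s <- screen_features(tab, c("4", "8", "12"), "control")
  expect_s3_class(s, "screen_table")
  expect_true(all(s$q >= s$p))
  expect_identical(s$selected, s$vip > 1 & s$q < 0.05)
  # early-phase informative metabolites are recovered
  panel_names <- load_panel()$name
  early <- panel_names[seq_along(panel_names) %% 4 == 1]  # early-peak archetype
  expect_true(all(early %in% s$feature[s$selected]))
  # background features stay mostly unselected
  bg_sel <- sum(s$selected & grepl("^bg_", s$feature))
  expect_lte(bg_sel, qbinom(0.99, sum(grepl("^bg_", s$feature)), 0.05))
  # infinite VIP threshold selects nothing
  s_inf <- screen_features(tab, c("4", "8", "12"), "control", vip_thr = Inf)
  expect_equal(sum(s_inf$selected), 0L)
})

test_that("a null-effect design selects at most the binomial false-positive bound", {
  tab0 <- generate_study(synthetic_config(effect_scale = 0, seed = 7,
                                          n_background = 200))
  s0 <- screen_features(tab0, c("4", "8", "12"), "control")
  expect_lte(sum(s0$selected), qbinom(0.99, nrow(s0), 0.05))
})

test_that("screening ignores QC and external rows", {
  cfg <- small_config(seed = 6)
  tab <- generate_study(cfg)
  with_extras <- add_qc(tab, cfg)
  ext <- generate_external(cfg, 4)$table
  with_extras <- rbind(with_extras, ext)
  class(with_extras) <- c("peak_table", "data.frame")
  s1 <- screen_features(tab, c("16", "20"), "control")
  s2 <- screen_features(with_extras, c("16", "20"), "control")
  expect_equal(s1, s2)
})

test_that("panel assembly nests node panels inside the union", {
  tab <- small_study(seed = 1)
  sch <- group_scheme()
  pan <- assemble_panels(tab, sch)
  expect_true(all(unlist(pan$groups) %in% pan$union))
  expect_equal(unname(pan$counts["union"]), length(pan$union))
  # node panels differ between nodes (archetypes favour different phases)
  expect_false(identical(pan$groups$I, pan$groups$II))
  # a null design has no selectable features at all
  tab0 <- generate_study(small_config(effect_scale = 0, seed = 8))
  expect_error(assemble_panels(tab0, sch), "effect size")
})

test_that("screen tables export to CSV", {
  tab <- small_study(seed = 2)
  s <- screen_features(tab, c("36", "40"), "control")
  f <- withr::local_tempfile(fileext = ".csv")
  write_screen_table(s, f)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(names(back), c("feature", "vip", "p", "q", "selected",
                              "direction"))
  expect_equal(nrow(back), nrow(s))
})

test_that("metabolite clustering orders profiles by archetype", {
  cfg <- small_config()
  labels <- c("control", as.character(cfg$timepoints))
  idx <- c(1, 5, 9, 2, 6, 10, 3, 7, 11)  # three archetype triplets
  m <- t(vapply(idx, function(j) {
    vapply(labels, function(l) trajectory_mean(j, l, cfg), numeric(1))
  }, numeric(length(labels))))
  hc <- hcluster_metabolites(m)
  expect_setequal(hc$order, seq_along(idx))
  groups <- cutree(hc$hclust, k = 3)
  expect_equal(length(unique(groups[1:3])), 1L)
  expect_equal(length(unique(groups[4:6])), 1L)
  expect_equal(length(unique(groups[7:9])), 1L)
  expect_equal(length(unique(groups[c(1, 4, 7)])), 3L)
  # identical profiles merge first at height zero
  m2 <- rbind(m[1, ], m[1, ], m[4, ] + 5)
  hc2 <- hcluster_metabolites(m2)
  expect_equal(sort(hc2$merge[1, ]), c(-2, -1))
  expect_equal(hc2$height[1], 0, tolerance = 1e-12)
  expect_error(hcluster_metabolites(m[1, , drop = FALSE]), ">= 2")
})
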