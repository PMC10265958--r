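# PCA, NIPALS PLS, OPLS-DA, VIP, Q2 cross-validation, permutation testing
# and CV-ANOVA.

test_that("pca returns ordered explained variance and reconstructs", {
  set.seed(1)
  # rank-1 matrix: one component explains everything
  u <- rnorm(12); v <- rnorm(5)
  x1 <- u %*% t(v)
  p1 <- pca(x1, k = 1)
  expect_equal(p1$explained[1], 1, tolerance = 1e-12)
  expect_error(pca(x1, k = 3), "rank")
  # full reconstruction equals the centered matrix
  x <- matrix(rnorm(60), 12)
  k <- qr(scale(x, scale = FALSE))$rank
  p <- pca(x, k = k)
  rec <- p$scores %*% t(p$loadings)
  expect_equal(rec, unname(scale(x, scale = FALSE)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)
})

test_that("QC samples cluster tightly in PCA score space", {
  cfg <- small_config(seed = 5)
  tab <- add_qc(generate_study(cfg), cfg)
  pc <- pca(peak_matrix(tab, log = TRUE), k = 2)
  rms <- function(m) sqrt(mean(rowSums(m^2)))
  expect_lt(rms(pc$scores[tab$role == "qc", ]),
            0.5 * rms(pc$scores[tab$role == "study", ]))
})

test_that("NIPALS PLS matches exact and least-squares oracles", {
  set.seed(2)
  # orthonormal predictor columns; y exactly linear in one of them, so a
  # single component gives the exact fit
  x <- qr.Q(qr(scale(matrix(rnorm(100), 20), center = TRUE, scale = FALSE)))
  y <- 3 * x[, 2]
  f1 <- pls_nipals(x, y, a = 1)
  expect_lt(max(abs(f1$fitted - y)), 1e-8)
  # full-rank PLS equals the normal-equations fit
  for (seed in 1:5) {
    set.seed(seed)
    xs <- matrix(rnorm(18 * 4), 18)
    ys <- cbind(rnorm(18), rnorm(18))
    fit <- pls_nipals(xs, ys, a = 4)
    xc <- scale(xs, scale = FALSE); yc <- scale(ys, scale = FALSE)
    ols <- xc %*% solve(crossprod(xc), crossprod(xc, yc))
    expect_equal(unname(fit$fitted), unname(sweep(ols, 2, colMeans(ys), `+`)),
                 tolerance = 1e-6)
  }
  expect_error(pls_nipals(matrix(0, 5, 3), rnorm(5), 1), "zero variance")
})

test_that("row permutation permutes PLS scores identically", {
  set.seed(3)
  x <- matrix(rnorm(48), 12); y <- rnorm(12)
  perm <- sample(12)
  f <- pls_nipals(x, y, a = 2)
  fp <- pls_nipals(x[perm, ], y[perm], a = 2)
  expect_equal(fp$scores, f$scores[perm, ], tolerance = 1e-10)
})

test_that("OPLS with no orthogonal components reduces to PLS", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(10:16, 1); p <- sample(4:8, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(n * p), n)
    labs <- sample(rep(letters[seq_len(k)], length.out = n))
    while (min(table(labs)) < 2) labs <- sample(rep(letters[seq_len(k)], length.out = n))
    a_pred <- k - 1L
    m <- opls_fit(x, labs, a_pred = a_pred, a_orth = 0L)
    oracle <- pls_nipals(x, woundage:::one_hot(labs), a = a_pred)
    expect_lt(max(abs(m$scores - oracle$scores)), 1e-8)
    expect_lt(max(abs(m$coef - oracle$coef)), 1e-8)
  }
})

test_that("OPLS score blocks are mutually orthogonal and R2Y is a fraction", {
  set.seed(11)
  x <- matrix(rnorm(30 * 8), 30)
  labs <- rep(c("a", "b", "c"), each = 10)
  x[labs == "a", 1:3] <- x[labs == "a", 1:3] + 1.5
  m <- opls_fit(x, labs, a_pred = 2, a_orth = 2)
  g <- crossprod(m$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_lt(max(abs(crossprod(m$scores, m$scores_orth))), 1e-8)
  expect_gte(m$r2y, 0)
  expect_lte(m$r2y, 1)
  expect_error(opls_fit(x, c("a", rep("b", 29))), "single sample")
})

test_that("OPLS-DA fits the synthetic three-phase study well", {
  tab <- generate_study(synthetic_config(seed = 1))
  xz <- zscore_apply(zscore_fit(peak_matrix(tab, log = TRUE)),
                     peak_matrix(tab, log = TRUE))
  m <- opls_fit(xz, tab$label, a_orth = 1)
  expect_gte(m$r2y, 0.7)
})

test_that("VIP satisfies its normalization identity and flags signal", {
  # identical feature copies share VIP 1
  set.seed(12)
  base <- rnorm(20)
  x <- matrix(rep(base, 6), 20) + 1e-8 * matrix(rnorm(120), 20)
  labs <- rep(c("a", "b"), each = 10)
  m <- opls_fit(x, labs, a_pred = 1, a_orth = 0)
  expect_equal(unname(vip(m)), rep(1, 6), tolerance = 1e-3)
  # sum of squared VIPs equals the feature count on any model
  set.seed(13)
  x2 <- matrix(rnorm(26 * 9), 26)
  labs2 <- sample(rep(c("a", "b"), 13))
  m2 <- opls_fit(x2, labs2, a_pred = 1, a_orth = 1)
  expect_equal(sum(vip(m2)^2), ncol(x2), tolerance = 1e-8)
  # one informative among nine noise features takes the maximum VIP
  set.seed(14)
  x3 <- matrix(rnorm(40 * 10), 40)
  labs3 <- rep(c("a", "b"), each = 20)
  x3[, 4] <- x3[, 4] + ifelse(labs3 == "a", 2, -2)
  m3 <- opls_fit(scale(x3), labs3, a_pred = 1, a_orth = 1)
  expect_equal(which.max(vip(m3)), 4L, ignore_attr = TRUE)
})

test_that("Q2 tracks class separability", {
  tab <- generate_study(small_config(within_sd = 0.05, seed = 2))
  study <- tab[tab$label != "control", ]
  xz <- scale(peak_matrix(study, log = TRUE))
  coarse <- coarse_of(group_scheme(), study$label)
  cv <- q2_crossval(xz, coarse, a_pred = 2, a_orth = 1, seed = 1)
  expect_gte(cv$q2, 0.9)
  # shuffled labels: no predictive power
  set.seed(15)
  cv0 <- q2_crossval(xz, sample(coarse), a_pred = 2, a_orth = 1, seed = 1)
  expect_lte(cv0$q2, 0.1)
  # Q2 never exceeds R2Y on the same data/model
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(36 * 7), 36)
    labs <- sample(rep(c("a", "b", "c"), 12))
    x[labs == "a", 1:2] <- x[labs == "a", 1:2] + seed / 2
    m <- opls_fit(x, labs, a_pred = 2, a_orth = 1)
    cvs <- q2_crossval(x, labs, a_pred = 2, a_orth = 1, seed = seed)
    expect_lte(cvs$q2, m$r2y + 1e-10)
  }
  # a class too small for the folds triggers the advisory error
  set.seed(18)
  x_rare <- matrix(rnorm(26 * 5), 26)
  labs_rare <- c(rep("a", 12), rep("b", 12), rep("c", 2))
  expect_error(q2_crossval(x_rare, labs_rare, a_pred = 1, folds = 7),
               "fewer folds")
})

test_that("Q2 weakly decreases as label noise increases", {
  tab <- generate_study(small_config(within_sd = 0.1, seed = 4))
  study <- tab[tab$label != "control", ]
  xz <- scale(peak_matrix(study, log = TRUE))
  coarse <- coarse_of(group_scheme(), study$label)
  q2_at <- function(noise_frac, seed) {
    labs <- coarse
    set.seed(seed)
    n_flip <- round(noise_frac * length(labs))
    if (n_flip > 0) {
      idx <- sample(seq_along(labs), n_flip)
      labs[idx] <- sample(unique(coarse), n_flip, replace = TRUE)
    }
    q2_crossval(xz, labs, a_pred = 2, a_orth = 1, seed = 1)$q2
  }
  q2s <- c(q2_at(0, 21), q2_at(0.3, 21), q2_at(0.7, 21))
  expect_true(all(diff(q2s) <= 0.02))
})

test_that("permutation test separates real structure from chance", {
  set.seed(16)
  x <- rbind(matrix(rnorm(15 * 8), 15), matrix(rnorm(15 * 8, 1.5), 15))
  labs <- rep(c("a", "b"), each = 15)
  pt_ <- permutation_test(x, labs, n_perm = 40, seed = 1)
  expect_equal(nrow(pt_$permuted), 40L)
  expect_true(all(abs(pt_$permuted$cor) <= 1 + 1e-12))
  expect_gte(mean(pt_$permuted$q2 < pt_$original["q2"], na.rm = TRUE), 0.95)
  # n_perm = 0: report with originals only
  pt0 <- permutation_test(x, labs, n_perm = 0, seed = 1)
  expect_equal(nrow(pt0$permuted), 0L)
  expect_false(anyNA(pt0$original))
})

test_that("CV-ANOVA flags strong models and not null ones", {
  tab <- generate_study(small_config(seed = 1))
  study <- tab[tab$label != "control", ]
  xz <- scale(peak_matrix(study, log = TRUE))
  coarse <- coarse_of(group_scheme(), study$label)
  cv <- q2_crossval(xz, coarse, a_pred = 2, a_orth = 1, seed = 1)
  expect_lt(cv_anova(cv), 0.001)
  # residuals as large as the total variation: p near 1
  cv_flat <- cv
  cv_flat$press <- cv_flat$ss_y
  expect_gt(cv_anova(cv_flat), 0.99)
  # null calibration: shuffled labels rarely reach significance
  set.seed(17)
  xn <- matrix(rnorm(30 * 10), 30)
  ps <- vapply(1:50, function(i) {
    set.seed(i)
    labs <- sample(rep(c("a", "b", "c"), each = 10))
    cv_anova(q2_crossval(xn, labs, a_pred = 2, a_orth = 1, seed = i))
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8)
})
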