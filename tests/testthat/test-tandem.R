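# Grouping scheme, stratified splitting, node training, tandem assembly,
# prediction routing and serialization.

test_that("the default scheme has three phases partitioned into 7 windows", {
  sch <- group_scheme()
  expect_equal(length(sch$coarse), 3L)
  expect_equal(scheme_leaves(sch),
               c("4", "8", "12", "16-20", "24-32", "36-40", "44-48"))
  expect_equal(coarse_of(sch, c("4", "20", "48")), c("I", "II", "III"))
  expect_equal(leaf_of(sch, c("28", "44")), c("24-32", "44-48"))
  expect_error(leaf_of(sch, "99"), "outside the scheme")
  # malformed schemes are rejected
  expect_error(group_scheme(coarse = list(I = c("4", "8"), II = c("8")),
                            leaves = list(I = list(`4` = "4", `8` = "8"),
                                          II = list(`8` = "8"))),
               "overlap")
})

test_that("train/validation split is stratified, seeded and guarded", {
  tab <- small_study(seed = 1)
  contused <- tab[tab$label != "control", ]
  sp <- split_train_val(contused, frac = 0.7, seed = 3)
  for (lab in unique(contused$label)) {
    n_tr <- sum(sp$train & contused$label == lab)
    expect_true(n_tr %in% c(6L, 7L))  # round(0.7 * 9)
  }
  expect_equal(sort(c(sp$train_ids, sp$validation_ids)),
               sort(contused$sample_id))
  expect_identical(sp, split_train_val(contused, frac = 0.7, seed = 3))
  expect_false(identical(sp$train,
                         split_train_val(contused, frac = 0.7, seed = 4)$train))
  expect_error(split_train_val(contused, frac = 1.0), "strictly")
  one <- contused[c(1, 10), ]
  expect_error(split_train_val(one, frac = 0.7), "single sample")
})

test_that("all four candidates solve a separable toy and ties favour the MLP", {
  tab <- toy_two_class(n_per_class = 12, p = 6, shift = 5, seed = 5)
  sp <- split_train_val(tab, frac = 0.7, seed = 1)
  node <- train_node(tab[sp$train, ], tab[!sp$train, ],
                     class_labels = setNames(c("early", "late"), c("4", "8")),
                     panel = peak_features(tab), seed = 1)
  expect_equal(unname(node$val_accuracy), rep(1, 4))
  expect_equal(node$chosen, "MLP")
  expect_true(all(node$val_accuracy >= 0 & node$val_accuracy <= 1))
  # a single training class is rejected
  single <- tab[tab$label == "4", ]
  expect_error(train_node(single, single,
                          class_labels = c(`4` = "x", `8` = "y"),
                          panel = peak_features(tab)),
               "single class")
})

test_that("node parameters are fitted from training rows only", {
  tab <- toy_two_class(n_per_class = 10, p = 5, shift = 4, seed = 6)
  sp <- split_train_val(tab, frac = 0.7, seed = 2)
  tr <- tab[sp$train, ]; va <- tab[!sp$train, ]
  va2 <- va
  va2[, peak_features(va2)] <- va2[, peak_features(va2)] * 3
  cls <- setNames(c("a", "b"), c("4", "8"))
  n1 <- train_node(tr, va, cls, peak_features(tab), seed = 1)
  n2 <- train_node(tr, va2, cls, peak_features(tab), seed = 1)
  expect_identical(n1$scaler, n2$scaler)
  expect_identical(n1$reducer, n2$reducer)
  expect_identical(n1$train_coords, n2$train_coords)
})

test_that("tandem fit on the default design assembles 7 leaves and performs", {
  tab <- small_study(seed = 1)
  fit <- tandem_fit(tab, seed = 1)
  expect_s3_class(fit, "wound_tandem")
  leaves <- unlist(lapply(fit$level2, function(n) {
    if (!is.null(n$passthrough)) n$passthrough else n$classes
  }), use.names = FALSE)
  expect_setequal(leaves, scheme_leaves(fit$scheme))
  rep_ <- run_internal_validation(fit, tab)
  expect_gte(rep_$accuracy, 0.9)
  expect_equal(rep_$n, 108L)
})

test_that("routing consistency holds for every prediction", {
  sch <- group_scheme()
  for (seed in c(1, 2)) {
    tab <- small_study(seed = seed)
    fit <- tandem_fit(tab, seed = seed)
    contused <- tab[tab$label != "control", ]
    routes <- predict(fit, contused)
    for (i in seq_len(nrow(routes))) {
      expect_true(routes$leaf[i] %in% names(sch$leaves[[routes$coarse[i]]]))
    }
    ext <- generate_external(small_config(seed = seed + 100), 6)
    routes_ext <- predict(fit, ext$table)
    expect_true(all(mapply(function(l, g) l %in% names(sch$leaves[[g]]),
                           routes_ext$leaf, routes_ext$coarse)))
  }
})

test_that("tandem predictions are deterministic under fixed seeds", {
  tab <- small_study(seed = 2)
  f1 <- tandem_fit(tab, seed = 5)
  f2 <- tandem_fit(tab, seed = 5)
  contused <- tab[tab$label != "control", ]
  expect_identical(predict(f1, contused), predict(f2, contused))
  expect_identical(f1$split, f2$split)
  expect_identical(predict(f1, contused[0, ]),
                   data.frame(sample_id = character(0),
                              coarse = character(0), leaf = character(0),
                              stringsAsFactors = FALSE))
})

test_that("a noise-free study is recovered perfectly", {
  tab <- generate_study(small_config(within_sd = 1e-9, seed = 2))
  fit <- tandem_fit(tab, seed = 3)
  expect_equal(run_internal_validation(fit, tab)$accuracy, 1.0)
})

test_that("planted group-mean samples are routed to their own leaf", {
  cfg <- small_config(seed = 4)
  tab <- generate_study(cfg)
  fit <- tandem_fit(tab, seed = 4)
  for (lab in c("8", "28", "44")) {
    mu <- c(vapply(1:43, trajectory_mean, numeric(1), label = lab,
                   config = cfg),
            woundage:::.background_means(cfg))
    planted <- tab[1, ]
    planted[1, peak_features(tab)] <- exp(mu)
    planted$sample_id <- "planted"
    expect_equal(predict(fit, planted)$leaf, leaf_of(group_scheme(), lab))
  }
})

test_that("single-coarse-group schemes degenerate to their level-2 node", {
  sch1 <- group_scheme(
    coarse = list(I = c("4", "8", "12")),
    leaves = list(I = list(`4` = "4", `8` = "8", `12` = "12")))
  cfg <- synthetic_config(timepoints = c(4, 8, 12), n_background = 30,
                          seed = 3)
  tab <- generate_study(cfg)
  pan <- list(union = peak_features(tab)[1:43],
              groups = list(I = peak_features(tab)[1:43]))
  fit <- tandem_fit(tab, scheme = sch1, seed = 1, panels = pan)
  expect_equal(names(fit$level2), "I")
  routes <- predict(fit, tab[tab$label != "control", ])
  expect_true(all(routes$coarse == "I"))
  expect_setequal(unique(routes$leaf), c("4", "8", "12"))
})

test_that("flat baselines share the tandem's split and report accuracies", {
  tab <- small_study(seed = 1)
  pan <- assemble_panels(tab, group_scheme())
  fit <- tandem_fit(tab, seed = 9, panels = pan)
  fl <- flat_baseline(tab, seed = 9, panels = pan)
  expect_identical(fl$split, fit$split)
  expect_named(fl$val_accuracy, c("LR", "SVM", "RF", "MLP"))
  expect_true(all(fl$val_accuracy >= 0 & fl$val_accuracy <= 1))
})

test_that("model bundles round-trip through the YAML/CSV serialization", {
  tab <- small_study(seed = 3)
  fit <- tandem_fit(tab, seed = 2)
  dir <- withr::local_tempdir()
  save_tandem(fit, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  back <- load_tandem(dir)
  contused <- tab[tab$label != "control", ]
  expect_identical(predict(back, contused), predict(fit, contused))
  expect_equal(back$panels$union, fit$panels$union)
  expect_equal(scheme_leaves(back$scheme), scheme_leaves(fit$scheme))
})

test_that("missing panel features are reported by name", {
  tab <- small_study(seed = 1)
  fit <- tandem_fit(tab, seed = 1)
  crippled <- tab[tab$label != "control",
                  !(names(tab) %in% fit$panels$union[1])]
  class(crippled) <- c("peak_table", "data.frame")
  expect_error(predict(fit, crippled), fit$panels$union[1], fixed = TRUE)
})
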