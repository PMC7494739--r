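no_elim <- eliminate_config(near_constant = FALSE, correlation = FALSE,
                            ttest = FALSE, pca = FALSE)

test_that("RBF kernel matches its closed form and is symmetric", {
  expect_identical(rbf_kernel(c(1, 2, 3), c(1, 2, 3), gamma = 0.7), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), gamma = 1), exp(-1))
  u <- c(0.3, -1.2, 2); v <- c(1, 0.5, -0.7)
  expect_identical(rbf_kernel(u, v, 0.2), rbf_kernel(v, u, 0.2))
  expect_error(rbf_kernel(1:3, 1:4, 1), "dimension")
})

test_that("all three configurations separate a linearly separable toy set", {
  set.seed(14)
  tab <- toy_separable()
  for (cfg in list(svm_config(), gbt_leafwise_config(min_child_samples = 4),
                   gbt_depthwise_config())) {
    fit <- screenml(tab, config = cfg, elim = no_elim, seed = 2)
    pred <- predict(fit, tab, type = "label")
    expect_identical(unname(pred), unname(tab$labels),
                     info = cfg$label)
  }
})

test_that("training and scoring are deterministic given the seed", {
  cmp <- generate_campaign(small_spec(seed = 44))
  ft <- campaign_features(cmp)
  for (cfg in list(svm_config(), gbt_depthwise_config(n_estimators = 30))) {
    f1 <- screenml(ft, config = cfg, seed = 9)
    f2 <- screenml(ft, config = cfg, seed = 9)
    expect_identical(predict(f1, ft), predict(f2, ft), info = cfg$label)
    # scoring the same compounds twice with one model is identical
    expect_identical(predict(f1, ft), predict(f1, ft), info = cfg$label)
  }
})

test_that("single-class training input is rejected", {
  tab <- toy_separable()
  tab$labels[] <- 1L
  expect_error(screenml(tab, elim = no_elim), "both classes")
})

test_that("predicted scores are probabilities and the threshold contract holds", {
  set.seed(15)
  tab <- toy_separable(n_per_class = 15, gap = 2)
  fit <- screenml(tab, elim = no_elim, seed = 3)
  sc <- predict(fit, tab)
  expect_true(all(sc >= 0 & sc <= 1))
  strict <- fit
  strict$threshold <- 1.0
  lab <- predict(strict, tab, type = "label")
  expect_true(all(lab[sc < 1] == 0L))
})

test_that("prediction rejects unknown and missing columns by name", {
  tab <- toy_separable()
  fit <- screenml(tab, elim = no_elim, seed = 1)
  extra <- feature_table(cbind(tab$x, MD_rogue = rnorm(nrow(tab$x))),
                         roles = c(tab$roles, "MD"))
  expect_error(predict(fit, extra), "MD_rogue")
  expect_error(predict(fit, tab[, "MD_a"]), "MD_b")
})

test_that("SVM decision surface is invariant to training row order", {
  set.seed(16)
  tab <- toy_separable(n_per_class = 25, gap = 3)
  # a tight solver tolerance pins the converged solution so the row
  # permutation cannot change it beyond numerical noise
  cfg <- svm_config(probability = FALSE, tolerance = 1e-8)
  f1 <- screenml(tab, config = cfg, elim = no_elim, seed = 4)
  perm <- sample(nrow(tab$x))
  f2 <- screenml(tab[perm, ], config = cfg, elim = no_elim, seed = 4)
  expect_equal(predict(f1, tab), predict(f2, tab), tolerance = 1e-6)
})

test_that("stratified folds partition rows and balance the classes", {
  cmp <- generate_campaign(small_spec(seed = 46))
  ft <- campaign_features(cmp)
  cv <- cross_validate(ft, k = 5, seed = 12)
  a <- cv$assignment
  expect_setequal(names(a), rownames(ft$x))
  expect_true(all(a %in% 1:5))
  for (f in 1:5) {
    n_act <- sum(ft$labels[a == f] == 1L)
    n_dec <- sum(ft$labels[a == f] == 0L)
    expect_lte(abs(n_act - n_dec), 1)
  }
  expect_equal(cv$folds$n_val, as.vector(table(a)))
  cv2 <- cross_validate(ft, k = 5, seed = 12)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$assignment, cv2$assignment)
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))
})

test_that("leave-one-out on a small toy set still partitions cleanly", {
  set.seed(17)
  tab <- toy_separable(n_per_class = 5, gap = 4)
  cv <- cross_validate(tab, k = 10, seed = 2, elim = no_elim)
  expect_equal(sort(unique(cv$assignment)), 1:10)
  expect_equal(unname(table(cv$assignment)), rep(1L, 10), ignore_attr = TRUE)
  expect_true(all(is.na(cv$folds$auc))) # one-compound folds have no ROC
  expect_false(is.na(cv$mean_acc))
})

test_that("null-campaign accuracy stays within the binomial band around 0.5", {
  cmp <- generate_campaign(null_spec(seed = 48, n_actives = 150,
                                     n_decoys = 150))
  cv <- cross_validate(campaign_features(cmp), k = 5, seed = 3)
  half_width <- 1.96 * sqrt(0.25 / 300)
  expect_lt(abs(cv$mean_acc - 0.5), half_width + 0.05)
})

test_that("ablation grid has the expected shape and is reproducible", {
  cmp <- generate_campaign(small_spec(seed = 51))
  ft <- campaign_features(cmp)
  configs <- list(SVM = svm_config())
  g1 <- ablation_compare(ft, configs = configs, k = 3, seed = 7)
  g2 <- ablation_compare(ft, configs = configs, k = 3, seed = 7)
  expect_identical(g1, g2)
  expect_equal(dim(g1), c(3L, 3L)) # 3 input sets x (input + AUC + ACC)
  expect_setequal(g1$input, c("DS+PS+MD", "PS+MD", "MD"))
  expect_error(ablation_compare(ft, configs = configs,
                                input_sets = list(XX = "XX")), "absent")
})

test_that("docking-only signal favours the full input set over descriptors alone", {
  wins <- 0L
  for (s in 1:10) {
    spec <- small_spec(seed = 300 + s, docking_effect = -2.5,
                       descriptor_effect = 0, map_prob_decoy = 0.95,
                       fit_mean_decoy = 2.5)
    ft <- campaign_features(generate_campaign(spec))
    g <- ablation_compare(ft, configs = list(SVM = svm_config()),
                          input_sets = list(`DS+PS+MD` = c("DS", "PS", "MD"),
                                            MD = "MD"),
                          k = 3, seed = s)
    if (g$SVM_AUC[g$input == "DS+PS+MD"] > g$SVM_AUC[g$input == "MD"]) {
      wins <- wins + 1L
    }
  }
  # sign test at the 1% level: 9+ wins out of 10 rejects "no difference"
  expect_gte(wins, 9L)
})
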