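make_blocks <- function(n = 4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("C%02d", seq_len(n))
  dk <- matrix(rnorm(n * 6), n, dimnames = list(ids, paste0("E", 1:6)))
  ft <- matrix(abs(rnorm(n * 9)), n, dimnames = list(ids, paste0("PH", 1:9)))
  md <- matrix(rnorm(n * 5), n, dimnames = list(ids, paste0("MD_x", 1:5)))
  list(ids = ids, dk = dk, ft = ft, md = md)
}

test_that("assembly stacks DS, PS, MD blocks in order with correct roles", {
  b <- make_blocks(n = 2)
  tab <- assemble_features(b$dk, b$ft, b$md)
  expect_equal(ncol(tab$x), 20)
  expect_equal(unname(table(factor(tab$roles, c("DS", "PS", "MD")))),
               c(6L, 9L, 5L), ignore_attr = TRUE)
  expect_identical(unname(tab$roles), rep(c("DS", "PS", "MD"), c(6, 9, 5)))
})

test_that("a fully unmapped compound keeps nine exact-zero fit entries", {
  b <- make_blocks(n = 3)
  b$ft[2, ] <- 0
  tab <- assemble_features(b$dk, b$ft, b$md)
  expect_identical(unname(tab$x[2, tab$roles == "PS"]), rep(0, 9))
})

test_that("assembly is equivariant under input id permutation", {
  b <- make_blocks(n = 6)
  tab <- assemble_features(b$dk, b$ft, b$md)
  perm <- c(4, 1, 6, 2, 5, 3)
  tab_p <- assemble_features(b$dk[perm, ], b$ft[perm, ], b$md[perm, ])
  expect_identical(tab_p$x, tab$x[perm, ])
})

test_that("id mismatches across blocks are reported", {
  b <- make_blocks(n = 3)
  rownames(b$md)[2] <- "ZZZ"
  expect_error(assemble_features(b$dk, b$ft, b$md), "ZZZ")
})

test_that("consensus docking average matches the published rescoring table", {
  expect_equal(average_docking(c(-10.25, -10.39, -11.06, -11.07, -8.1, -8.1)),
               -9.83)
  expect_equal(average_docking(c(-9.51, -7.27, -10.58, -10.68, -11.7, -11.7)),
               -10.24)
  expect_equal(average_docking(rep(-7.25, 6)), -7.25)
  expect_error(average_docking(numeric(0)))
  expect_error(average_docking(c(-1, NA)))
})

test_that("counting filter removes strictly-above-threshold modal columns", {
  x <- cbind(mostly0 = c(rep(0, 95), rnorm(5)),
             at90 = c(rep(1, 90), rnorm(10)),
             distinct = seq_len(100) + 0.5)
  rownames(x) <- sprintf("C%03d", 1:100)
  tab <- feature_table(x, roles = rep("MD", 3))
  out <- near_constant_filter(tab, threshold = 0.90)
  expect_identical(out$removed, "mostly0")
  expect_setequal(colnames(out$table$x), c("at90", "distinct"))
})

test_that("correlation filter performs the deterministic greedy scan", {
  set.seed(4)
  base <- rnorm(300)
  x <- cbind(a = base, b = base + 0.01 * rnorm(300),
             c = base + 0.01 * rnorm(300), d = rnorm(300))
  rownames(x) <- sprintf("C%03d", 1:300)
  tab <- feature_table(x, roles = rep("MD", 4))
  out <- correlation_filter(tab, cutoff = 0.85)
  # a, b, c are mutually correlated: only the first survives
  expect_identical(out$removed, c("b", "c"))
  expect_setequal(colnames(out$table$x), c("a", "d"))
})

test_that("independent columns pass the correlation filter", {
  set.seed(11)
  x <- matrix(rnorm(300 * 20), 300,
              dimnames = list(sprintf("C%03d", 1:300), paste0("V", 1:20)))
  out <- correlation_filter(feature_table(x, rep("MD", 20)))
  expect_length(out$removed, 0)
})

test_that("correlation filter rejects zero-variance columns", {
  x <- cbind(flat = rep(1, 50), ok = rnorm(50))
  rownames(x) <- sprintf("C%02d", 1:50)
  expect_error(correlation_filter(feature_table(x, rep("MD", 2))),
               "counting")
})

test_that("t-test screen keeps separating columns and applies the degenerate rule", {
  set.seed(2)
  labels <- rep(c(1L, 0L), each = 30)
  x <- cbind(sep = labels + 1e-3 * rnorm(60),   # near-perfect separation
             noise = rnorm(60),
             degen = ifelse(labels == 1L, 2, 5)) # zero within-class variance
  rownames(x) <- sprintf("C%02d", 1:60)
  tab <- feature_table(x, rep("MD", 3), labels = labels)
  out <- ttest_filter(tab, alpha = 0.05)
  expect_true(out$p_values["sep"] < 1e-10)
  expect_identical(unname(out$p_values["degen"]), 0)
  expect_true(all(c("sep", "degen") %in% colnames(out$table$x)))
  expect_error(ttest_filter(tab, labels = rep(1L, 60)), "class")
})

test_that("t-test screen p-values agree with the pooled-variance reference", {
  set.seed(3)
  labels <- rep(c(1L, 0L), each = 25)
  x <- matrix(rnorm(50 * 8), 50,
              dimnames = list(sprintf("C%02d", 1:50), paste0("V", 1:8)))
  tab <- feature_table(x, rep("MD", 8), labels = labels)
  out <- ttest_filter(tab, alpha = 1) # retain all; compare p-values
  ref <- apply(x, 2, function(col) {
    t.test(col[labels == 1], col[labels == 0], var.equal = TRUE)$p.value
  })
  expect_equal(out$p_values, ref, tolerance = 1e-12)
})

test_that("label-independent columns are removed at roughly rate 1 - alpha", {
  set.seed(6)
  labels <- rep(c(1L, 0L), each = 150)
  x <- matrix(rnorm(300 * 200), 300,
              dimnames = list(sprintf("C%03d", 1:300), paste0("V", 1:200)))
  out <- ttest_filter(feature_table(x, rep("MD", 200), labels = labels))
  expect_equal(length(out$removed) / 200, 0.95, tolerance = 0.05)
})

test_that("PCA reduction collapses collinearity and reconstructs exactly", {
  set.seed(8)
  base <- rnorm(40)
  x2 <- cbind(a = base, b = 2 * base + 1)
  rownames(x2) <- sprintf("C%02d", 1:40)
  red <- pca_reduce(feature_table(x2, rep("MD", 2)), variance_target = 0.95)
  expect_identical(red$k, 1L)
  expect_equal(red$explained[1], 1, tolerance = 1e-12)

  x <- matrix(rnorm(30 * 6), 30,
              dimnames = list(sprintf("C%02d", 1:30), paste0("V", 1:6)))
  tab <- feature_table(x, rep("MD", 6))
  full <- pca_reduce(tab, variance_target = 1.0)
  expect_identical(full$k, 6L) # min(n - 1, d) with n = 30, d = 6
  z <- apply_normalizer(full$normalizer, tab)$x
  expect_equal(full$scores$x %*% t(full$loadings), z, tolerance = 1e-10)
  expect_error(pca_reduce(tab, variance_target = 0), "variance_target")
  expect_error(pca_reduce(tab, variance_target = 1.5), "variance_target")
})

test_that("cascade recovers the planted blocks and reports consistently", {
  cmp <- generate_campaign(small_spec(seed = 13))
  ft <- campaign_features(cmp)
  el <- eliminate(ft)
  rep <- el$report
  expect_setequal(rep$removed$counting, cmp$truth$near_constant)
  for (pair in cmp$truth$collinear_pairs) {
    expect_identical(sum(pair %in% rep$removed$correlation), 1L)
  }
  expect_length(intersect(cmp$truth$informative, rep$removed$correlation), 0)
  # removal sets disjoint; counts non-increasing
  all_removed <- unlist(rep$removed)
  expect_identical(anyDuplicated(all_removed), 0L)
  expect_true(all(diff(rep$retained_after[c("counting", "correlation",
                                            "t_test")]) <= 0))
  expect_setequal(c(all_removed,
                    rownames(el$state$pca$loadings)),
                  colnames(ft$x))
})

test_that("identity configuration passes the table through untouched", {
  cmp <- generate_campaign(small_spec(seed = 17))
  ft <- campaign_features(cmp)
  el <- eliminate(ft, config = eliminate_config(near_constant = FALSE,
                                                correlation = FALSE,
                                                ttest = FALSE, pca = FALSE))
  expect_identical(el$table$x, ft$x)
  expect_true(all(lengths(el$report$removed) == 0))
})

test_that("counting and correlation steps are idempotent on filtered tables", {
  cmp <- generate_campaign(small_spec(seed = 29))
  ft <- campaign_features(cmp)
  cfg <- eliminate_config(ttest = FALSE, pca = FALSE)
  first <- eliminate(ft, config = cfg)
  second <- eliminate(first$table, config = cfg)
  expect_length(second$report$removed$counting, 0)
  expect_length(second$report$removed$correlation, 0)
})

test_that("batch normalisation uses training statistics only", {
  x <- matrix(c(0, 2, 10, 1, 3, -5), ncol = 2,
              dimnames = list(c("r1", "r2", "r3"), c("c1", "c2")))
  tab <- feature_table(x, rep("MD", 2))
  params <- fit_normalizer(tab, rows = c("r1", "r2"))
  z <- apply_normalizer(params, tab)
  expect_equal(unname(z$x[1:2, "c1"]), c(-1, 1)) # population sd on 2 points
  expect_false(abs(mean(z$x[, "c1"])) < 1e-12)   # held-out row shifts the mean
  # round trip
  back <- sweep(sweep(z$x, 2, params$scale, `*`), 2, params$center, `+`)
  expect_equal(back, x, tolerance = 1e-12)
})

test_that("zero-variance columns are rejected by name", {
  x <- cbind(flat = rep(2, 4), ok = c(1, 2, 3, 4))
  rownames(x) <- sprintf("r%d", 1:4)
  expect_error(fit_normalizer(feature_table(x, rep("MD", 2))), "flat")
})
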