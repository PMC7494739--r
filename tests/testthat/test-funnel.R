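test_that("rule-of-five violations are counted with tolerance semantics", {
  expect_true(lipinski_pass(400, 3.0, 2, 5))
  expect_false(lipinski_pass(600, 6.0, 2, 5, max_violations = 0))
  expect_false(lipinski_pass(600, 6.0, 2, 5, max_violations = 1))
  expect_true(lipinski_pass(600, 3.0, 2, 5, max_violations = 1))
  df <- data.frame(MW = c(400, 501), logP = c(3, 3), HBD = c(2, 2),
                   HBA = c(5, 11))
  expect_identical(lipinski_pass(df), c(TRUE, FALSE))
  expect_error(lipinski_pass(-10, 1, 1, 1))
})

test_that("rank_and_cut keeps the best n with stable id tie-breaks", {
  set.seed(31)
  sc <- setNames(round(rnorm(1000, -8), 1), sprintf("M%04d", 1:1000))
  top <- rank_and_cut(sc, 506, direction = "lower")
  expect_length(top, 506)
  worst_kept <- max(sc[top])
  expect_lte(worst_kept, min(sc[setdiff(names(sc), top)]))
  expect_identical(rank_and_cut(sc, 2000), names(sc)[order(sc, names(sc))])
  tied <- c(b = 1, a = 1, c = 0)
  expect_identical(rank_and_cut(tied, 3, "lower"), c("c", "a", "b"))
  expect_error(rank_and_cut(tied, 0), "at least 1")
  expect_error(rank_and_cut(unname(tied), 1), "named")
})

test_that("tanimoto similarity follows the bit-count definition", {
  a <- c(1, 1, 1, 1, 0, 0); b <- c(1, 1, 1, 1, 1, 0)
  expect_identical(tanimoto(a, a), 1)
  expect_identical(tanimoto(a, b), 0.8)
  expect_identical(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_identical(tanimoto(c(0, 0), c(0, 0)), 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "bit length")
})

test_that("similarity search returns exactly the planted neighbourhood", {
  set.seed(32)
  n_bits <- 128
  query <- runif(n_bits) < 0.4
  # 10 close neighbours (few flips) + 50 unrelated fingerprints
  close <- t(sapply(1:10, function(i) xor(query, runif(n_bits) < 0.02)))
  far <- matrix(runif(50 * n_bits) < 0.4, 50)
  deck <- rbind(close, far, query)
  rownames(deck) <- c(sprintf("near%02d", 1:10), sprintf("far%02d", 1:50),
                      "self")
  stopifnot(all(apply(close, 1, tanimoto, b = query) > 0.8),
            all(apply(far, 1, tanimoto, b = query) <= 0.8))
  hits <- similarity_search(query, deck, threshold = 0.8)
  expect_setequal(hits$id, c(sprintf("near%02d", 1:10), "self"))
  expect_identical(hits$id[1], "self")
  expect_identical(hits$similarity[1], 1)
  expect_true(all(diff(hits$similarity) <= 0))
  exact <- similarity_search(query, deck, threshold = 1 - 1e-12)
  expect_identical(exact$id, "self")
})

test_that("leader clustering is deterministic and recovers planted groups", {
  fps <- matrix(rep(c(TRUE, FALSE), each = 8), 4, 16, byrow = TRUE)
  rownames(fps) <- paste0("m", 1:4)
  expect_length(leader_cluster(fps, threshold = 0.6), 1)

  disjoint <- diag(6) == 1
  rownames(disjoint) <- paste0("d", 1:6)
  expect_length(leader_cluster(disjoint, threshold = 0.1), 6)

  set.seed(33)
  g1 <- t(sapply(1:5, function(i) xor(c(rep(TRUE, 20), rep(FALSE, 20)),
                                      runif(40) < 0.03)))
  g2 <- t(sapply(1:5, function(i) xor(c(rep(FALSE, 20), rep(TRUE, 20)),
                                      runif(40) < 0.03)))
  fps2 <- rbind(g1, g2)
  rownames(fps2) <- sprintf("c%02d", 1:10)
  cl <- leader_cluster(fps2, threshold = 0.6)
  expect_length(cl, 2)
  expect_setequal(cl[[1]]$members, sprintf("c%02d", 1:5))
  expect_setequal(cl[[2]]$members, sprintf("c%02d", 6:10))
  # representative = member with best auxiliary score
  sc <- setNames(c(5, 1, 4, 3, 2, 9, 8, 0, 7, 6), rownames(fps2))
  cl2 <- leader_cluster(fps2, threshold = 0.6, scores = sc)
  expect_identical(cl2[[1]]$representative, "c02")
  expect_identical(cl2[[2]]$representative, "c08")
})

test_that("classifier rescoring partitions candidates deterministically", {
  cmp <- generate_campaign(small_spec(seed = 61))
  fit <- screenml(campaign_features(cmp), seed = 2)
  deck <- generate_screening_deck(small_spec(seed = 62), n = 200,
                                  prevalence = 0.2)
  cand <- campaign_features(deck, labelled = FALSE)
  r1 <- ai_rescore(fit, cand)
  r2 <- ai_rescore(fit, cand)
  expect_identical(r1, r2)
  expect_setequal(c(r1$retained, r1$excluded), deck$ids)
  expect_equal(r1$exclusion_pct,
               round_half_up(100 * length(r1$excluded) / 200, 2))
  # a model that calls everything active excludes nothing
  all_active <- fit
  all_active$threshold <- 0
  expect_identical(ai_rescore(all_active, cand)$exclusion_pct, 0)
})

test_that("disabling every stage returns the input deck as one stage", {
  deck <- generate_screening_deck(small_spec(seed = 63), n = 50,
                                  prevalence = 0.1)
  cfg <- funnel_config(ro5 = FALSE, prescreen = FALSE, sp_cut = NULL,
                       xp_cut = NULL, cluster = FALSE)
  rep <- run_funnel(deck, cfg)
  expect_identical(rep$stages$stage, "input")
  expect_setequal(rep$ids$input, deck$ids)
})

test_that("funnel stage id sets are nested and counts match", {
  deck <- generate_screening_deck(small_spec(seed = 64), n = 600,
                                  prevalence = 0.1)
  cfg <- funnel_config(sp_cut = 150, xp_cut = 80, reps_per_cluster = 10)
  rep <- run_funnel(deck, cfg)
  ids <- rep$ids
  for (i in seq_along(ids)[-1]) {
    expect_true(all(ids[[i]] %in% ids[[i - 1]]))
  }
  expect_identical(unname(lengths(ids)), rep$stages$n)
  # missing stage inputs are reported by stage name
  broken <- deck
  broken$fingerprints <- NULL
  expect_error(run_funnel(broken, cfg), "clustering")
})

test_that("a null deck cannot be enriched beyond its prevalence", {
  prev <- 0.3
  survivors <- 0L; actives <- 0L
  for (s in 1:5) {
    deck <- generate_screening_deck(null_spec(seed = 70 + s), n = 800,
                                    prevalence = prev)
    cfg <- funnel_config(ro5 = FALSE, prescreen = FALSE, sp_cut = 200,
                         xp_cut = NULL, cluster = FALSE)
    rep <- run_funnel(deck, cfg)
    kept <- rep$ids$sp_docking
    survivors <- survivors + length(kept)
    actives <- actives + sum(deck$labels[kept] == 1L)
  }
  expect_equal(actives / survivors, prev, tolerance = 0.05)
})

test_that("precision rises through the funnel when signal is present", {
  diffs <- c()
  for (s in 1:6) {
    deck <- generate_screening_deck(small_spec(seed = 80 + s,
                                               docking_effect = -2),
                                    n = 1000, prevalence = 0.05)
    cfg <- funnel_config(sp_cut = 150, xp_cut = 80, cluster = FALSE)
    rep <- run_funnel(deck, cfg)
    prec <- rep$stages$precision
    names(prec) <- rep$stages$stage
    diffs <- c(diffs, prec["sp_docking"] - prec["input"],
               prec["xp_docking"] - prec["sp_docking"])
  }
  # aggregated over seeds, each docking cut concentrates true actives
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > -1e-9), 0.7)
})
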