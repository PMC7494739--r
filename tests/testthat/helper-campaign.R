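# Shared fixtures: small campaign specifications keep the test suite fast
# while preserving every planted structure class.

small_spec <- function(seed = 1, ...) {
  args <- list(n_actives = 50, n_decoys = 50, n_informative = 10,
               n_collinear_pairs = 6, n_near_constant = 6, n_noise = 40,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(campaign_spec, args)
}

# no class signal anywhere: identical docking, mapping and descriptor
# distributions for actives and decoys
null_spec <- function(seed = 1, ...) {
  small_spec(seed = seed, docking_effect = 0, descriptor_effect = 0,
             map_prob_decoy = 0.95, fit_mean_decoy = 2.5, ...)
}

# deterministic two-cluster toy: linearly separable in two dimensions
toy_separable <- function(n_per_class = 20, gap = 6) {
  x <- rbind(cbind(stats::rnorm(n_per_class), stats::rnorm(n_per_class)),
             cbind(stats::rnorm(n_per_class) + gap,
                   stats::rnorm(n_per_class) + gap))
  colnames(x) <- c("MD_a", "MD_b")
  rownames(x) <- sprintf("T%03d", seq_len(2 * n_per_class))
  feature_table(x, roles = c("MD", "MD"),
                labels = rep(c(0L, 1L), each = n_per_class))
}

# brute-force pair-counting AUC: fraction of (active, decoy) pairs ranked
# correctly with half credit for ties -- the independent oracle for the
# threshold-sweep implementation
pair_count_auc <- function(scores, labels, direction = "higher") {
  s <- if (direction == "lower") -scores else scores
  act <- s[labels == 1]
  dec <- s[labels == 0]
  tot <- 0
  for (a in act) tot <- tot + sum(a > dec) + 0.5 * sum(a == dec)
  tot / (length(act) * length(dec))
}
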