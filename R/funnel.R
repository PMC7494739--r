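# The virtual-screening funnel: rule-of-five filter, pharmacophore
# prescreen, ranked SP/XP docking cuts, fingerprint leader clustering,
# and classifier rescoring — plus the Tanimoto similarity operations.

#' Lipinski rule-of-five check
#'
#' Counts violations against MW <= 500 Da, logP <= 5, H-bond donors <= 5,
#' H-bond acceptors <= 10; a compound passes iff it has at most
#' `max_violations` violations. Vectorised over compounds.
#'
#' @param mw Molecular weight in Da (or a data frame with columns `MW`,
#'   `logP`, `HBD`, `HBA`).
#' @param logp,hbd,hba Octanol-water logP, H-bond donor and acceptor
#'   counts.
#' @param max_violations Violations tolerated (0 = strict rule).
#' @return Logical vector.
#' @examples
#' lipinski_pass(400, 3.0, 2, 5)
#' lipinski_pass(600, 3.0, 2, 5, max_violations = 1)
#' @export
lipinski_pass <- function(mw, logp = NULL, hbd = NULL, hba = NULL,
                          max_violations = 0) {
  if (is.data.frame(mw)) {
    df <- mw
    need <- c("MW", "logP", "HBD", "HBA")
    if (!all(need %in% names(df))) {
      stop("profile data frame needs columns MW, logP, HBD, HBA",
           call. = FALSE)
    }
    mw <- df$MW; logp <- df$logP; hbd <- df$HBD; hba <- df$HBA
  }
  if (any(mw <= 0) || any(hbd < 0) || any(hba < 0)) {
    stop("invalid rule-of-five profile (MW must be > 0, counts >= 0)",
         call. = FALSE)
  }
  violations <- (mw > 500) + (logp > 5) + (hbd > 5) + (hba > 10)
  violations <= max_violations
}

#' Rank compounds and keep the top n
#'
#' Sorts ids by score in the given direction, breaking score ties by
#' lexicographic id order (stable across runs), and returns the first
#' `min(n, total)` ids.
#'
#' @param scores Named numeric vector (names = compound ids).
#' @param n Cut size (>= 1).
#' @param direction `"lower"` (docking convention) or `"higher"`.
#' @return Character vector of surviving ids, best first.
#' @export
rank_and_cut <- function(scores, n, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  if (is.null(names(scores))) stop("scores must be named by compound id",
                                   call. = FALSE)
  if (n < 1) stop("cut size must be at least 1", call. = FALSE)
  key <- if (direction == "lower") scores else -scores
  ord <- order(key, names(scores))
  utils::head(names(scores)[ord], n)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` over bitsets; two empty fingerprints have
#' similarity 0 by convention.
#'
#' @param a,b Logical (or 0/1) vectors of equal length.
#' @return Similarity in [0, 1].
#' @examples
#' tanimoto(c(1, 1, 1, 1, 0), c(1, 1, 1, 1, 1)) # 0.8
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprints must have equal bit length", call. = FALSE)
  }
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

# All Tanimoto similarities of a query against the rows of a fingerprint
# matrix, vectorised.
tanimoto_many <- function(query, fps) {
  query <- as.logical(query)
  inter <- as.vector(fps %*% query)
  u <- rowSums(fps) + sum(query) - inter
  ifelse(u == 0, 0, inter / u)
}

#' Fingerprint similarity search
#'
#' Returns every deck member whose Tanimoto similarity to the query is
#' strictly above `threshold`, sorted by similarity (descending) then id.
#'
#' @param query Logical fingerprint vector.
#' @param deck Logical matrix of fingerprints with compound-id row names.
#' @param threshold Similarity threshold (strict).
#' @return Data frame with columns `id` and `similarity`.
#' @export
similarity_search <- function(query, deck, threshold = 0.8) {
  if (!is.matrix(deck) || is.null(rownames(deck))) {
    stop("deck must be a fingerprint matrix with id row names",
         call. = FALSE)
  }
  if (ncol(deck) != length(query)) {
    stop("fingerprints must have equal bit length", call. = FALSE)
  }
  sims <- tanimoto_many(query, deck)
  hit <- sims > threshold
  out <- data.frame(id = rownames(deck)[hit], similarity = sims[hit])
  out[order(-out$similarity, out$id), , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

#' Greedy leader clustering of fingerprints
#'
#' Iterates compounds in deterministic (input) order: a compound joins the
#' first existing cluster whose leader it resembles above `threshold`,
#' otherwise it founds a new cluster. Each cluster's representative is its
#' member with the best auxiliary score (by default the leader, when no
#' scores are given).
#'
#' @param fps Logical fingerprint matrix with id row names.
#' @param threshold Tanimoto threshold (strict) for joining a cluster.
#' @param scores Optional named auxiliary scores used to pick
#'   representatives (e.g. consensus docking scores).
#' @param direction `"lower"` if smaller auxiliary scores are better.
#' @return List of class `leader_clusters`: per cluster a list with
#'   `leader`, `members` and `representative`.
#' @export
leader_cluster <- function(fps, threshold = 0.6, scores = NULL,
                           direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  if (!is.matrix(fps) || is.null(rownames(fps)) || nrow(fps) == 0) {
    stop("fps must be a non-empty fingerprint matrix with id row names",
         call. = FALSE)
  }
  ids <- rownames(fps)
  leaders <- integer() # row indices of cluster leaders
  membership <- integer(length(ids))
  for (i in seq_along(ids)) {
    assigned <- 0L
    for (ci in seq_along(leaders)) {
      if (tanimoto(fps[i, ], fps[leaders[ci], ]) > threshold) {
        assigned <- ci
        break
      }
    }
    if (assigned == 0L) {
      leaders <- c(leaders, i)
      assigned <- length(leaders)
    }
    membership[i] <- assigned
  }
  clusters <- lapply(seq_along(leaders), function(ci) {
    members <- ids[membership == ci]
    rep_id <- if (is.null(scores)) {
      ids[leaders[ci]]
    } else {
      sc <- scores[members]
      members[order(if (direction == "lower") sc else -sc, members)][1]
    }
    list(leader = ids[leaders[ci]], members = members,
         representative = rep_id)
  })
  structure(clusters, class = "leader_clusters")
}

#' @export
print.leader_clusters <- function(x, ...) {
  sizes <- lengths(lapply(x, `[[`, "members"))
  cat(sprintf("Leader clustering: %d clusters (sizes %s)\n", length(x),
              paste(utils::head(sort(sizes, decreasing = TRUE), 10),
                    collapse = ", ")))
  invisible(x)
}

#' Classifier rescoring of funnel candidates
#'
#' Scores each candidate with a fitted [screenml()] model and partitions
#' them into retained (predicted active) and excluded (predicted
#' inactive), reporting the exclusion percentage.
#'
#' @param model A `screenml` model.
#' @param candidates A `feature_table` of candidate compounds, transform-
#'   compatible with the model.
#' @return List with `retained`, `excluded` (id vectors), and
#'   `exclusion_pct`.
#' @export
ai_rescore <- function(model, candidates) {
  stopifnot(inherits(model, "screenml"))
  pred <- predict(model, candidates, type = "both")
  list(retained = pred$id[pred$label == 1L],
       excluded = pred$id[pred$label == 0L],
       exclusion_pct = exclusion_rate(pred$label))
}

#' Configure the screening funnel
#'
#' Stage toggles and parameters for [run_funnel()]. The default cut sizes
#' mirror a campaign where 506 compounds enter extra-precision docking and
#' 353 survive it; scale them to the deck at hand.
#'
#' @param ro5 Apply the rule-of-five filter.
#' @param max_violations Violations tolerated by the rule-of-five stage.
#' @param prescreen Apply the pharmacophore prescreen.
#' @param min_fit Prescreen rule: a compound passes iff at least one fit
#'   value exceeds `min_fit` (the default 0 keeps every compound that
#'   mapped onto any pharmacophore at all).
#' @param sp_cut Number of compounds kept by the standard-precision
#'   docking rank, or `NULL` to skip.
#' @param xp_cut Number kept by the extra-precision rank (taken within
#'   the SP survivors), or `NULL` to skip.
#' @param cluster Cluster survivors by fingerprint and keep
#'   representatives.
#' @param cluster_threshold Tanimoto threshold for leader clustering.
#' @param reps_per_cluster Representatives kept per cluster.
#' @param model Optional `screenml` model for the rescoring stage.
#' @param purchasable_rate Optional probability that a candidate is
#'   purchasable (random masking stage standing in for vendor
#'   availability); `NULL` skips the stage.
#' @param seed Seed for the purchasability mask.
#' @return A list of class `funnel_config`.
#' @export
funnel_config <- function(ro5 = TRUE, max_violations = 0, prescreen = TRUE,
                          min_fit = 0, sp_cut = 506, xp_cut = 353,
                          cluster = TRUE, cluster_threshold = 0.6,
                          reps_per_cluster = 1, model = NULL,
                          purchasable_rate = NULL, seed = 1) {
  if (!is.null(sp_cut) && sp_cut < 1) stop("sp_cut must be >= 1", call. = FALSE)
  if (!is.null(xp_cut) && xp_cut < 1) stop("xp_cut must be >= 1", call. = FALSE)
  stopifnot(cluster_threshold >= 0, cluster_threshold <= 1)
  structure(list(ro5 = ro5, max_violations = max_violations,
                 prescreen = prescreen, min_fit = min_fit,
                 sp_cut = sp_cut, xp_cut = xp_cut, cluster = cluster,
                 cluster_threshold = cluster_threshold,
                 reps_per_cluster = reps_per_cluster, model = model,
                 purchasable_rate = purchasable_rate, seed = seed),
            class = "funnel_config")
}

#' Run the virtual-screening funnel
#'
#' Executes the enabled stages in the canonical order — rule-of-five
#' filter, pharmacophore prescreen, standard-precision rank/cut,
#' extra-precision rank/cut (within the SP survivors), fingerprint
#' leader clustering with representative picking, optional purchasability
#' mask, classifier rescoring — and reports per-stage counts, surviving
#' id sets and, when the deck carries ground-truth labels, per-stage
#' precision (fraction of survivors truly active).
#'
#' @param deck A `campaign` / `screening_deck` from
#'   [generate_screening_deck()].
#' @param config A [funnel_config()].
#' @return An object of class `funnel_report`: `stages` (data frame of
#'   stage, n, precision), `ids` (list of per-stage id sets),
#'   `exclusion_pct` (rescoring stage, or `NA`).
#' @export
run_funnel <- function(deck, config = funnel_config()) {
  stopifnot(inherits(deck, "campaign"), inherits(config, "funnel_config"))
  ids <- deck$ids
  labels <- deck$labels
  stages <- list(input = ids)

  survivors <- ids
  if (isTRUE(config$ro5)) {
    if (is.null(deck$ro5)) stop("rule-of-five stage: deck has no ro5 profiles",
                                call. = FALSE)
    prof <- deck$ro5[match(survivors, deck$ro5$id), ]
    survivors <- survivors[lipinski_pass(prof[, c("MW", "logP", "HBD", "HBA")],
                                         max_violations = config$max_violations)]
    stages$rule_of_five <- survivors
  }
  if (isTRUE(config$prescreen)) {
    if (is.null(deck$fits)) stop("pharmacophore prescreen: deck has no fit values",
                                 call. = FALSE)
    fmax <- apply(deck$fits[survivors, , drop = FALSE], 1, max)
    survivors <- survivors[fmax > config$min_fit]
    stages$pharmacophore <- survivors
  }
  sp_score <- consensus_scores(deck, survivors, tier = "SP")
  if (!is.null(config$sp_cut)) {
    survivors <- rank_and_cut(sp_score[survivors], config$sp_cut,
                              direction = "lower")
    stages$sp_docking <- survivors
  }
  if (!is.null(config$xp_cut)) {
    xp_score <- consensus_scores(deck, survivors, tier = "XP")
    survivors <- rank_and_cut(xp_score[survivors], config$xp_cut,
                              direction = "lower")
    stages$xp_docking <- survivors
  }
  if (isTRUE(config$cluster)) {
    if (is.null(deck$fingerprints)) {
      stop("clustering stage: deck has no fingerprints", call. = FALSE)
    }
    avg <- apply(deck$docking[survivors, , drop = FALSE], 1, average_docking,
                 digits = NULL)
    cl <- leader_cluster(deck$fingerprints[survivors, , drop = FALSE],
                         threshold = config$cluster_threshold,
                         scores = avg, direction = "lower")
    reps <- unlist(lapply(cl, function(cc) {
      sc <- avg[cc$members]
      utils::head(cc$members[order(sc, cc$members)], config$reps_per_cluster)
    }), use.names = FALSE)
    survivors <- survivors[survivors %in% reps]
    stages$clustering <- survivors
  }
  if (!is.null(config$purchasable_rate)) {
    mask <- with_substream(config$seed, "purchasable", {
      stats::runif(length(survivors)) < config$purchasable_rate
    })
    survivors <- survivors[mask]
    stages$purchasable <- survivors
  }
  exclusion_pct <- NA_real_
  if (!is.null(config$model)) {
    cand <- assemble_features(deck$docking[survivors, , drop = FALSE],
                              deck$fits[survivors, , drop = FALSE],
                              deck$descriptors[survivors, , drop = FALSE])
    res <- ai_rescore(config$model, cand)
    survivors <- survivors[survivors %in% res$retained]
    exclusion_pct <- res$exclusion_pct
    stages$ai_rescore <- survivors
  }

  precision <- vapply(stages, function(s) {
    if (is.null(labels) || length(s) == 0) NA_real_
    else mean(labels[s] == 1L)
  }, numeric(1))
  report <- data.frame(stage = names(stages),
                       n = lengths(stages),
                       precision = precision,
                       row.names = NULL)
  structure(list(stages = report, ids = stages,
                 exclusion_pct = exclusion_pct),
            class = "funnel_report")
}

# Mean score over the docking channels of one precision tier ("SP", "XP",
# "AD"); falls back to all channels when the tier is absent.
consensus_scores <- function(deck, ids, tier) {
  cols <- grep(paste0("^", tier), colnames(deck$docking))
  if (length(cols) == 0) cols <- seq_len(ncol(deck$docking))
  sc <- rowMeans(deck$docking[, cols, drop = FALSE])
  stats::setNames(sc, deck$ids)[ids]
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Virtual-screening funnel\n")
  df <- x$stages
  df$precision <- ifelse(is.na(df$precision), "",
                         sprintf("%.3f", df$precision))
  print(df, row.names = FALSE)
  if (!is.na(x$exclusion_pct)) {
    cat(sprintf("  rescoring exclusion rate: %.2f%%\n", x$exclusion_pct))
  }
  invisible(x)
}
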