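# Classifier configurations and the screenml() fitting function.

#' Support-vector classifier configuration
#'
#' Soft-margin SVM with an RBF kernel, `exp(-gamma * ||u - v||^2)`. The
#' defaults follow common virtual-screening practice: `C = 1`, solver
#' tolerance `1e-3`, shrinking heuristics and probability outputs on.
#' `gamma = NULL` selects the scale-stable rule
#' `1 / (d * mean column variance)` of the training matrix.
#'
#' @param C Regularisation (cost) parameter, > 0.
#' @param gamma RBF bandwidth, > 0, or `NULL` for the automatic rule.
#' @param tolerance Solver convergence tolerance.
#' @param shrinking Use shrinking heuristics.
#' @param probability Fit a probability model (Platt scaling).
#' @param degree,coef0 Passed through to the kernel machinery; inert for
#'   the RBF kernel but kept configurable.
#' @return A config object usable as `config` in [screenml()].
#' @export
svm_config <- function(C = 1, gamma = NULL, tolerance = 1e-3,
                       shrinking = TRUE, probability = TRUE,
                       degree = 3, coef0 = 0) {
  stopifnot(C > 0, is.null(gamma) || gamma > 0, tolerance > 0)
  structure(list(C = C, gamma = gamma, tolerance = tolerance,
                 shrinking = shrinking, probability = probability,
                 degree = degree, coef0 = coef0, label = "SVM"),
            class = c("svm_config", "screenml_config"))
}

#' Leaf-wise gradient-boosted-tree configuration
#'
#' Gradient boosting with leaf-wise (best-first) tree growth under a depth
#' limit: learning rate 0.1, 10 leaves, maximum depth 3, minimum of 31
#' samples per leaf. Backed by xgboost's `grow_policy = "lossguide"`; the
#' per-leaf sample minimum is enforced through the hessian bound
#' `min_child_weight = min_child_samples / 4` (the expected hessian of the
#' logistic loss at p = 0.5 is 1/4 per sample).
#'
#' @param learning_rate Shrinkage per boosting round.
#' @param n_leaves Maximum leaves per tree (>= 2).
#' @param max_depth Depth limit per tree (>= 1).
#' @param min_child_samples Minimum samples per leaf.
#' @param n_rounds Number of boosting rounds.
#' @return A config object usable as `config` in [screenml()].
#' @export
gbt_leafwise_config <- function(learning_rate = 0.1, n_leaves = 10,
                                max_depth = 3, min_child_samples = 31,
                                n_rounds = 100) {
  stopifnot(n_leaves >= 2, max_depth >= 1, n_rounds >= 1)
  structure(list(learning_rate = learning_rate, n_leaves = n_leaves,
                 max_depth = max_depth, min_child_samples = min_child_samples,
                 n_rounds = n_rounds, label = "GBT-leafwise"),
            class = c("gbt_leafwise_config", "screenml_config"))
}

#' Depth-wise gradient-boosted-tree configuration
#'
#' Gradient boosting with level-wise growth and binary-logistic loss: 150
#' estimators, maximum depth 3, minimum child weight 1, and 80% row / 80%
#' column subsampling per tree.
#'
#' @param n_estimators Number of boosting rounds (>= 1).
#' @param max_depth Depth limit per tree.
#' @param min_child_weight Minimum hessian sum per child.
#' @param subsample Row-subsampling fraction per tree.
#' @param colsample Column-subsampling fraction per tree.
#' @param learning_rate Shrinkage per round.
#' @return A config object usable as `config` in [screenml()].
#' @export
gbt_depthwise_config <- function(n_estimators = 150, max_depth = 3,
                                 min_child_weight = 1, subsample = 0.8,
                                 colsample = 0.8, learning_rate = 0.3) {
  stopifnot(n_estimators >= 1, max_depth >= 1)
  structure(list(n_estimators = n_estimators, max_depth = max_depth,
                 min_child_weight = min_child_weight, subsample = subsample,
                 colsample = colsample, learning_rate = learning_rate,
                 label = "GBT-depthwise"),
            class = c("gbt_depthwise_config", "screenml_config"))
}

#' RBF kernel
#'
#' `exp(-gamma * ||u - v||^2)`, the radial-basis similarity used by the
#' support-vector classifier; symmetric in its arguments and equal to 1
#' iff `u == v`.
#'
#' @param u,v Numeric vectors of equal length.
#' @param gamma Bandwidth, > 0.
#' @return Similarity in (0, 1].
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), gamma = 1) # exp(-1)
#' @export
rbf_kernel <- function(u, v, gamma) {
  if (length(u) != length(v)) stop("u and v must have equal dimension",
                                   call. = FALSE)
  stopifnot(is.numeric(gamma), gamma > 0)
  exp(-gamma * sum((u - v)^2))
}

#' Fit an actives-versus-decoys screening classifier
#'
#' The package's central fitting function: takes an assembled, labelled
#' [feature_table()], runs the four-step elimination cascade and batch
#' normalisation on it (all statistics from these rows only), trains the
#' requested classifier configuration on the transformed features, and
#' returns a model object that carries the complete transform state, so
#' new compounds are projected exactly as the training data was.
#'
#' @param table A labelled `feature_table` (or pass `labels`).
#' @param labels Binary labels (1 = active, 0 = decoy).
#' @param config One of [svm_config()], [gbt_leafwise_config()],
#'   [gbt_depthwise_config()].
#' @param elim An [eliminate_config()]; set the steps to `FALSE` to train
#'   on the table as-is (it is then only z-scored).
#' @param threshold Score threshold for hard labels.
#' @param seed Integer seed covering every stochastic training component
#'   (probability-model cross-validation, tree subsampling).
#' @return An object of class `screenml` with `print`, `summary` and
#'   [predict.screenml()] methods.
#' @examples
#' cmp <- generate_campaign(campaign_spec(n_actives = 40, n_decoys = 40,
#'                                        n_informative = 10, n_collinear_pairs = 5,
#'                                        n_near_constant = 5, n_noise = 30))
#' fit <- screenml(campaign_features(cmp))
#' fit
#' @export
screenml <- function(table, labels = NULL, config = svm_config(),
                     elim = eliminate_config(), threshold = 0.5,
                     seed = 1) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "screenml_config"))
  if (is.null(labels)) labels <- table$labels
  if (is.null(labels)) stop("labels are required for training", call. = FALSE)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }

  el <- eliminate(table, labels = labels, config = elim)
  feat_tab <- el$table
  normalizer <- NULL
  if (is.null(el$state$pca)) {
    # no PCA step: z-score the retained columns instead
    normalizer <- fit_normalizer(feat_tab)
    feat_tab <- apply_normalizer(normalizer, feat_tab)
  }
  x <- feat_tab$x

  fit <- with_substream(seed, "train", fit_backend(config, x, labels))

  model <- structure(list(config = config, fit = fit,
                          elimination = el$state, report = el$report,
                          normalizer = normalizer,
                          feature_names = colnames(x),
                          threshold = threshold, seed = seed,
                          n_train = nrow(x),
                          call = match.call()),
                     class = "screenml")
  model$train_scores <- predict(model, table, type = "response")
  model
}

fit_backend <- function(config, x, labels) UseMethod("fit_backend")

#' @export
fit_backend.svm_config <- function(config, x, labels) {
  gamma <- config$gamma %||% 1 / (ncol(x) * mean(apply(x, 2, stats::var)))
  e1071::svm(x = x, y = factor(labels, levels = c(0, 1)),
             scale = FALSE, kernel = "radial", cost = config$C,
             gamma = gamma, tolerance = config$tolerance,
             shrinking = config$shrinking,
             probability = config$probability,
             degree = config$degree, coef0 = config$coef0)
}

#' @export
fit_backend.gbt_leafwise_config <- function(config, x, labels) {
  dm <- xgboost::xgb.DMatrix(x, label = labels)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   eta = config$learning_rate,
                                   max_depth = config$max_depth,
                                   tree_method = "hist",
                                   grow_policy = "lossguide",
                                   max_leaves = config$n_leaves,
                                   min_child_weight = config$min_child_samples / 4,
                                   seed = sample.int(.Machine$integer.max, 1)),
                     data = dm, nrounds = config$n_rounds, verbose = 0)
}

#' @export
fit_backend.gbt_depthwise_config <- function(config, x, labels) {
  dm <- xgboost::xgb.DMatrix(x, label = labels)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   eta = config$learning_rate,
                                   max_depth = config$max_depth,
                                   min_child_weight = config$min_child_weight,
                                   subsample = config$subsample,
                                   colsample_bytree = config$colsample,
                                   tree_method = "hist",
                                   grow_policy = "depthwise",
                                   seed = sample.int(.Machine$integer.max, 1)),
                     data = dm, nrounds = config$n_estimators, verbose = 0)
}

# Transform a raw assembled table through the model's stored state.
model_transform <- function(object, table) {
  tab <- apply_elimination(object$elimination, table)
  if (!is.null(object$normalizer)) tab <- apply_normalizer(object$normalizer, tab)
  tab
}

#' Score new compounds with a fitted screening classifier
#'
#' Applies the stored elimination/normalisation state to `table` and
#' returns the classifier's activity score in `[0, 1]` (probability of
#' being active) and/or the hard label (`1` iff score >= the model's
#' threshold). Scoring is deterministic: the same model and table always
#' give the identical result.
#'
#' @param object A `screenml` model.
#' @param table A `feature_table` with exactly the columns the model was
#'   trained on (extra or missing columns raise an error listing them).
#' @param type `"response"` (scores), `"label"`, or `"both"` (data frame).
#' @param ... Ignored.
#' @return Named numeric scores, named integer labels, or a data frame
#'   with both.
#' @export
predict.screenml <- function(object, table, type = c("response", "label", "both"),
                             ...) {
  type <- match.arg(type)
  tab <- model_transform(object, table)
  x <- tab$x[, object$feature_names, drop = FALSE]
  score <- score_backend(object$config, object$fit, x)
  score <- stats::setNames(pmin(pmax(score, 0), 1), rownames(x))
  label <- stats::setNames(as.integer(score >= object$threshold), rownames(x))
  switch(type,
         response = score,
         label = label,
         both = data.frame(id = rownames(x), score = unname(score),
                           label = unname(label), row.names = NULL))
}

score_backend <- function(config, fit, x) UseMethod("score_backend")

#' @export
score_backend.svm_config <- function(config, fit, x) {
  if (isTRUE(config$probability)) {
    pr <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
    pr[, "1"]
  } else {
    # map the signed decision value through a logistic link
    dv <- attr(stats::predict(fit, x, decision.values = TRUE),
               "decision.values")[, 1]
    sgn <- if (colnames(attr(stats::predict(fit, x[1, , drop = FALSE],
                                            decision.values = TRUE),
                             "decision.values")) == "0/1") -1 else 1
    stats::plogis(sgn * dv)
  }
}

#' @export
score_backend.gbt_leafwise_config <- function(config, fit, x) {
  stats::predict(fit, xgboost::xgb.DMatrix(x))
}

#' @export
score_backend.gbt_depthwise_config <- function(config, fit, x) {
  stats::predict(fit, xgboost::xgb.DMatrix(x))
}

#' @export
print.screenml <- function(x, ...) {
  cat(sprintf("Screening classifier (%s), trained on %d compounds\n",
              x$config$label, x$n_train))
  cat(sprintf("  features after elimination: %d (threshold for 'active': %.2f)\n",
              length(x$feature_names), x$threshold))
  invisible(x)
}

#' @export
summary.screenml <- function(object, ...) {
  cat(sprintf("Screening classifier: %s\n", object$config$label))
  print(object$report)
  sc <- object$train_scores
  lab <- as.integer(sc >= object$threshold)
  cat(sprintf("Training compounds: %d; scored active at %.2f: %d (%.1f%%)\n",
              length(sc), object$threshold, sum(lab),
              100 * mean(lab)))
  invisible(object)
}

#' Stratified k-fold cross-validation
#'
#' Rows are shuffled with the given seed and assigned to folds round-robin
#' within each class, so every fold preserves the class balance to within
#' one compound. Per fold, the entire pipeline — elimination cascade,
#' normalisation, classifier — is refitted on the training rows only, the
#' held-out rows are scored, and AUC plus accuracy at the model threshold
#' are recorded. Validation rows never contribute to any transform
#' statistic.
#'
#' @param table A labelled `feature_table`.
#' @param config A classifier configuration.
#' @param k Number of folds (>= 2); each class needs at least `k` members
#'   for strict stratification, smaller classes fall back to spreading
#'   their members across folds.
#' @param seed Seed for the fold shuffle and per-fold training.
#' @param elim An [eliminate_config()].
#' @param threshold Hard-label threshold for accuracy.
#' @param keep_models Retain the per-fold `screenml` objects.
#' @return An object of class `screenml_cv`: per-fold data frame `folds`
#'   (`fold`, `n_val`, `auc`, `acc`), `assignment` (fold id per row),
#'   `mean_auc`, `mean_acc`, and optionally `models`.
#' @export
cross_validate <- function(table, config = svm_config(), k = 5, seed = 1,
                           elim = eliminate_config(), threshold = 0.5,
                           keep_models = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("labels are required", call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  labels <- table$labels
  n <- nrow(table$x)
  if (min(table(labels)) < 2) {
    stop("each class needs at least two members", call. = FALSE)
  }
  assignment <- with_substream(seed, "folds", {
    ord <- sample.int(n)
    a <- integer(n)
    offset <- 0L # continue the round-robin across classes so that every
                 # fold fills up even when a class has fewer than k members
    for (cls in c(1L, 0L)) {
      idx <- ord[labels[ord] == cls]
      a[idx] <- (offset + seq_along(idx) - 1L) %% k + 1L
      offset <- offset + length(idx)
    }
    a
  })
  names(assignment) <- rownames(table$x)

  folds <- data.frame(fold = seq_len(k), n_val = NA_integer_,
                      auc = NA_real_, acc = NA_real_)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(assignment != f)
    va <- which(assignment == f)
    if (length(va) == 0) next
    fit <- screenml(table[tr, ], config = config, elim = elim,
                    threshold = threshold,
                    seed = substream_seed(seed, paste0("fold", f)))
    pred <- predict(fit, table[va, ], type = "both")
    truth <- labels[va]
    folds$n_val[f] <- length(va)
    folds$acc[f] <- mean(pred$label == truth)
    folds$auc[f] <- if (length(unique(truth)) == 2) {
      roc_auc(pred$score, truth, direction = "higher")$auc
    } else NA_real_
    if (keep_models) models[[f]] <- fit
  }
  structure(list(folds = folds, assignment = assignment,
                 mean_auc = mean(folds$auc, na.rm = TRUE),
                 mean_acc = mean(folds$acc, na.rm = TRUE),
                 config = config, k = k, seed = seed,
                 models = if (keep_models) models),
            class = "screenml_cv")
}

#' @export
print.screenml_cv <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (%s)\n", x$k,
              x$config$label))
  print(x$folds, row.names = FALSE)
  cat(sprintf("  mean AUC %.4f, mean ACC %.4f\n", x$mean_auc, x$mean_acc))
  invisible(x)
}

#' Plot per-fold cross-validation metrics
#'
#' @param x A `screenml_cv` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.screenml_cv <- function(x, ...) {
  m <- t(as.matrix(x$folds[, c("auc", "acc")]))
  graphics::barplot(m, beside = TRUE, names.arg = x$folds$fold,
                    legend.text = c("AUC", "ACC"), ylim = c(0, 1),
                    xlab = "fold", ylab = "metric", ...)
  invisible(x)
}

#' Input-ablation comparison grid
#'
#' Cross-validates every classifier configuration on every requested
#' feature-role subset (by default the full DS+PS+MD table, PS+MD, and MD
#' only), rerunning the complete elimination/normalisation pipeline per
#' fold and per subset, and tabulates mean AUC and accuracy.
#'
#' @param table A labelled `feature_table` containing all requested roles.
#' @param configs Named list of classifier configurations.
#' @param input_sets List of role-character vectors.
#' @param k,seed,elim Passed to [cross_validate()].
#' @return A data frame with one row per input set and AUC/ACC columns
#'   per configuration.
#' @export
ablation_compare <- function(table,
                             configs = list(SVM = svm_config(),
                                            `GBT-leafwise` = gbt_leafwise_config(),
                                            `GBT-depthwise` = gbt_depthwise_config()),
                             input_sets = list(`DS+PS+MD` = c("DS", "PS", "MD"),
                                               `PS+MD` = c("PS", "MD"),
                                               MD = "MD"),
                             k = 5, seed = 1, elim = eliminate_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(names(configs))) {
    names(configs) <- vapply(configs, function(cf) cf$label, "")
  }
  if (is.null(names(input_sets))) {
    names(input_sets) <- vapply(input_sets, paste, "", collapse = "+")
  }
  out <- data.frame(input = names(input_sets))
  for (cn in names(configs)) {
    aucs <- accs <- numeric(length(input_sets))
    for (i in seq_along(input_sets)) {
      sub <- subset_roles(table, input_sets[[i]])
      cv <- cross_validate(sub, config = configs[[cn]], k = k, seed = seed,
                           elim = elim)
      aucs[i] <- cv$mean_auc
      accs[i] <- cv$mean_acc
    }
    out[[paste0(cn, "_AUC")]] <- aucs
    out[[paste0(cn, "_ACC")]] <- accs
  }
  out
}
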