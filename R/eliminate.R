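# The four-step feature-elimination cascade: counting (near-constant)
# filter, pairwise-correlation filter, two-sample t-test screen, and
# principal-component reduction — applied in exactly that order.

#' Near-constant (counting) filter
#'
#' Removes every column whose single most frequent value (exact equality
#' on stored floats) occurs in strictly more than `threshold` of the rows.
#' Such columns carry essentially no information across the library. With
#' the default threshold a column is dropped when more than 90% of
#' compounds share one value; a column at exactly 90% is retained.
#'
#' @param table A [feature_table()].
#' @param threshold Fraction of rows above which a modal value triggers
#'   removal (strict inequality).
#' @return List with `table` (filtered) and `removed` (column names).
#' @export
near_constant_filter <- function(table, threshold = 0.90) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$x) == 0 || ncol(table$x) == 0) {
    stop("feature table must be non-empty", call. = FALSE)
  }
  n <- nrow(table$x)
  modal_frac <- apply(table$x, 2, function(col) {
    max(tabulate(match(col, unique(col)))) / n
  })
  removed <- colnames(table$x)[modal_frac > threshold]
  keep <- setdiff(colnames(table$x), removed)
  if (length(keep) == 0) stop("counting filter removed every column",
                              call. = FALSE)
  list(table = table[, keep], removed = removed)
}

#' Pairwise-correlation filter
#'
#' Deterministic greedy collinearity filter: columns are scanned in table
#' order; for each ordered pair (i, j) with i < j, both still retained and
#' |Pearson r| > `cutoff`, the later column j is removed. Exactly one
#' member of every collinear pair therefore survives, and the outcome
#' depends only on column order.
#'
#' @param table A [feature_table()] with at least two columns and no
#'   zero-variance column (run [near_constant_filter()] first; truly
#'   constant columns have no defined correlation).
#' @param cutoff Absolute-correlation threshold (strict inequality).
#' @return List with `table` and `removed`.
#' @export
correlation_filter <- function(table, cutoff = 0.85) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x
  if (ncol(x) < 2) stop("correlation filter needs at least two columns",
                        call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance column(s) %s: run the counting filter first",
                 paste(utils::head(colnames(x)[sds == 0], 5), collapse = ", ")),
         call. = FALSE)
  }
  cmat <- abs(stats::cor(x))
  p <- ncol(x)
  keep <- rep(TRUE, p)
  for (i in seq_len(p - 1L)) {
    if (!keep[i]) next
    js <- which(keep & cmat[i, ] > cutoff)
    js <- js[js > i]
    keep[js] <- FALSE
  }
  removed <- colnames(x)[!keep]
  list(table = table[, colnames(x)[keep]], removed = removed)
}

#' Two-sample t-test feature screen
#'
#' Per-column pooled-variance (equal-variance) two-sample t-test of the
#' active-class mean against the decoy-class mean. A column is retained
#' iff its two-sided p-value is at most `alpha`; columns whose class means
#' do not differ detectably are removed. Degenerate convention: when the
#' pooled within-class variance is exactly zero, p is defined as 0 when
#' the class means differ (perfect separation, retained) and 1 when they
#' are equal (constant column, removed).
#'
#' @param table A [feature_table()].
#' @param labels Binary vector (1 = active, 0 = decoy); both classes need
#'   at least two members.
#' @param alpha Significance level for retention.
#' @return List with `table`, `removed` and `p_values` (named, all
#'   columns).
#' @export
ttest_filter <- function(table, labels = NULL, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(labels)) labels <- table$labels
  if (is.null(labels)) stop("labels are required for the t-test filter",
                            call. = FALSE)
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 < 2 || n0 < 2) {
    stop("both classes must be present with at least two members",
         call. = FALSE)
  }
  p <- pooled_ttest_p(table$x, labels)
  removed <- colnames(table$x)[p > alpha]
  keep <- setdiff(colnames(table$x), removed)
  if (length(keep) == 0) stop("t-test filter removed every column",
                              call. = FALSE)
  list(table = table[, keep], removed = removed, p_values = p)
}

pooled_ttest_p_checked <- function(x, labels) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) < 2 || sum(labels == 0L) < 2) {
    stop("both classes must be present with at least two members",
         call. = FALSE)
  }
  pooled_ttest_p(x, labels)
}

# Vectorised pooled-variance two-sample t-test p-values over the columns
# of x, with the degenerate zero-variance convention stated above.
pooled_ttest_p <- function(x, labels) {
  g1 <- x[labels == 1L, , drop = FALSE]
  g0 <- x[labels == 0L, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  m1 <- colMeans(g1); m0 <- colMeans(g0)
  v1 <- apply(g1, 2, stats::var); v0 <- apply(g0, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  p <- rep(NA_real_, ncol(x))
  zero <- se == 0
  p[zero & m1 != m0] <- 0
  p[zero & m1 == m0] <- 1
  ok <- !zero
  tstat <- (m1[ok] - m0[ok]) / se[ok]
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n1 + n0 - 2)
  stats::setNames(p, colnames(x))
}

#' Principal-component reduction
#'
#' Principal components of the column-standardised matrix. Columns are
#' z-scored internally (training-set population mean/sd via
#' [fit_normalizer()]); the smallest number of leading components whose
#' cumulative explained-variance fraction reaches `variance_target` is
#' kept, unless a fixed `k` is given.
#'
#' @param table A [feature_table()] with at least 2 rows and 1 column and
#'   no zero-variance column.
#' @param variance_target Cumulative explained-variance fraction in
#'   (0, 1] deciding how many components to keep.
#' @param k Optional fixed number of components, overriding
#'   `variance_target`.
#' @return An object of class `pca_reduction`: `scores` (a
#'   `feature_table` of component scores, role `"PC"`), `loadings`
#'   (columns x kept components), `explained` (explained-variance
#'   fractions of all components), `k`, and the `normalizer` used for
#'   standardisation.
#' @export
pca_reduce <- function(table, variance_target = 0.95, k = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(variance_target) || length(variance_target) != 1L ||
      variance_target <= 0 || variance_target > 1) {
    stop("invalid field 'variance_target': must lie in (0, 1]", call. = FALSE)
  }
  if (nrow(table$x) < 2 || ncol(table$x) < 1) {
    stop("PCA needs at least 2 rows and 1 column", call. = FALSE)
  }
  norm <- fit_normalizer(table)
  z <- apply_normalizer(norm, table)$x
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  explained <- ev / sum(ev)
  if (is.null(k)) {
    k <- which(cumsum(explained) >= variance_target - 1e-10)[1]
    if (is.na(k)) k <- length(explained)
  } else {
    if (k < 1 || k > length(explained)) {
      stop("invalid field 'k': out of component range", call. = FALSE)
    }
  }
  kept <- seq_len(k)
  scores <- pc$x[, kept, drop = FALSE]
  st <- feature_table(scores, roles = rep("PC", k), labels = table$labels)
  structure(list(scores = st, loadings = pc$rotation[, kept, drop = FALSE],
                 explained = explained, k = as.integer(k), normalizer = norm),
            class = "pca_reduction")
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat(sprintf("PCA reduction: %d components kept (%.1f%% variance explained)\n",
              x$k, 100 * sum(x$explained[seq_len(x$k)])))
  invisible(x)
}

#' Configure the elimination cascade
#'
#' @param near_constant,correlation,ttest,pca Logical toggles for the four
#'   steps.
#' @param nc_threshold Modal-fraction threshold of the counting step.
#' @param cor_cutoff Absolute-correlation cutoff.
#' @param alpha Significance level of the t-test screen.
#' @param variance_target PCA cumulative explained-variance target.
#' @param pca_k Optional fixed number of principal components.
#' @return A list of class `eliminate_config`.
#' @export
eliminate_config <- function(near_constant = TRUE, correlation = TRUE,
                             ttest = TRUE, pca = TRUE,
                             nc_threshold = 0.90, cor_cutoff = 0.85,
                             alpha = 0.05, variance_target = 0.95,
                             pca_k = NULL) {
  structure(list(near_constant = near_constant, correlation = correlation,
                 ttest = ttest, pca = pca, nc_threshold = nc_threshold,
                 cor_cutoff = cor_cutoff, alpha = alpha,
                 variance_target = variance_target, pca_k = pca_k),
            class = "eliminate_config")
}

#' Run the four-step elimination cascade
#'
#' Applies counting filter, correlation filter, t-test screen and PCA in
#' exactly that order (each step optional via the config) and returns the
#' reduced table together with a per-step report and the transform state
#' needed to project new compounds identically.
#'
#' @param table A labelled [feature_table()] (labels may be passed
#'   separately).
#' @param labels Binary labels; defaults to the table's own.
#' @param config An [eliminate_config()].
#' @return A list of class `elimination`: `table` (the reduced feature
#'   table — principal-component scores when the PCA step runs), `report`
#'   (an `elimination_report`) and `state` (for [apply_elimination()]).
#' @examples
#' cmp <- generate_campaign(campaign_spec(n_actives = 30, n_decoys = 30,
#'                                        n_informative = 5, n_collinear_pairs = 3,
#'                                        n_near_constant = 3, n_noise = 10))
#' el <- eliminate(campaign_features(cmp))
#' el$report
#' @export
eliminate <- function(table, labels = NULL, config = eliminate_config()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "eliminate_config"))
  if (is.null(labels)) labels <- table$labels
  initial <- colnames(table$x)
  removed <- list(counting = character(), correlation = character(),
                  t_test = character())
  retained_after <- integer()
  cur <- table

  if (isTRUE(config$near_constant)) {
    step <- near_constant_filter(cur, threshold = config$nc_threshold)
    cur <- step$table
    removed$counting <- step$removed
  }
  retained_after["counting"] <- ncol(cur$x)
  if (isTRUE(config$correlation) && ncol(cur$x) >= 2) {
    step <- correlation_filter(cur, cutoff = config$cor_cutoff)
    cur <- step$table
    removed$correlation <- step$removed
  }
  retained_after["correlation"] <- ncol(cur$x)
  if (isTRUE(config$ttest)) {
    p <- pooled_ttest_p_checked(cur$x, labels)
    keep <- names(p)[p <= config$alpha]
    # degenerate fallback: on signal-free data every column can fail the
    # screen; keep the single best column so the pipeline stays fittable
    if (length(keep) == 0) keep <- names(p)[which.min(p)]
    removed$t_test <- setdiff(colnames(cur$x), keep)
    cur <- cur[, keep]
  }
  retained_after["t_test"] <- ncol(cur$x)
  pre_pca_columns <- colnames(cur$x)

  pca_state <- NULL
  pca_info <- NULL
  if (isTRUE(config$pca)) {
    red <- pca_reduce(cur, variance_target = config$variance_target,
                      k = config$pca_k)
    pca_info <- list(k = red$k,
                     explained = red$explained[seq_len(red$k)],
                     pre_pca_columns = ncol(cur$x))
    pca_state <- list(normalizer = red$normalizer, loadings = red$loadings)
    cur <- red$scores
  }
  retained_after["pca"] <- ncol(cur$x)

  report <- structure(list(initial_columns = length(initial),
                           removed = removed,
                           retained_after = retained_after,
                           pca = pca_info),
                      class = "elimination_report")
  state <- structure(list(input_columns = initial,
                          keep_columns = pre_pca_columns,
                          pca = pca_state),
                     class = "elimination_state")
  structure(list(table = cur, report = report, state = state),
            class = "elimination")
}

#' Project new compounds through a fitted cascade
#'
#' Applies the column removals (and, when PCA ran, the stored
#' standardisation and loadings) of an [eliminate()] result to a new
#' feature table. The new table must contain exactly the columns the
#' cascade was fitted on.
#'
#' @param state The `state` element of an [eliminate()] result (or the
#'   result itself).
#' @param table A `feature_table` of new compounds.
#' @return The transformed `feature_table`.
#' @export
apply_elimination <- function(state, table) {
  if (inherits(state, "elimination")) state <- state$state
  stopifnot(inherits(state, "elimination_state"),
            inherits(table, "feature_table"))
  unknown <- setdiff(colnames(table$x), state$input_columns)
  missing_cols <- setdiff(state$input_columns, colnames(table$x))
  if (length(unknown)) {
    stop(sprintf("unknown column(s): %s",
                 paste(utils::head(unknown, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s",
                 paste(utils::head(missing_cols, 5), collapse = ", ")),
         call. = FALSE)
  }
  kept <- table[, state$keep_columns]
  if (is.null(state$pca)) return(kept)
  z <- apply_normalizer(state$pca$normalizer, kept)$x
  scores <- z %*% state$pca$loadings
  feature_table(scores, roles = rep("PC", ncol(scores)),
                labels = kept$labels)
}

#' @export
print.elimination_report <- function(x, ...) {
  cat("Feature-elimination report\n")
  cat(sprintf("  initial columns : %d\n", x$initial_columns))
  cat(sprintf("  counting step   : removed %4d -> %d retained\n",
              length(x$removed$counting), x$retained_after["counting"]))
  cat(sprintf("  correlation step: removed %4d -> %d retained\n",
              length(x$removed$correlation), x$retained_after["correlation"]))
  cat(sprintf("  t-test step     : removed %4d -> %d retained\n",
              length(x$removed$t_test), x$retained_after["t_test"]))
  if (!is.null(x$pca)) {
    cat(sprintf("  PCA step        : %d components (%.1f%% variance) from %d columns\n",
                x$pca$k, 100 * sum(x$pca$explained), x$pca$pre_pca_columns))
  } else {
    cat("  PCA step        : disabled\n")
  }
  invisible(x)
}
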