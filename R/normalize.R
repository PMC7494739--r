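#' Fit batch normalisation parameters
#'
#' Estimates per-column mean and standard deviation on a designated set of
#' training rows (the "batch"). Statistics are never taken from held-out
#' rows, so applying the fitted parameters to a validation set cannot leak
#' information. The population (divide-by-n) standard deviation is used.
#'
#' @param table A [feature_table()].
#' @param rows Training row ids or indices; defaults to all rows.
#' @return An object of class `normalizer` with fields `center`, `scale`
#'   and `columns`.
#' @export
fit_normalizer <- function(table, rows = NULL) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x
  if (!is.null(rows)) x <- x[rows, , drop = FALSE]
  if (nrow(x) == 0) stop("training rows must be non-empty", call. = FALSE)
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  bad <- colnames(x)[scale == 0]
  if (length(bad)) {
    stop(sprintf("zero standard deviation in column(s): %s (run the counting filter first)",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  structure(list(center = center, scale = scale, columns = colnames(x)),
            class = "normalizer")
}

#' Apply fitted normalisation parameters
#'
#' Transforms every column to `z = (x - mean) / sd` using the training
#' statistics stored in `params`, regardless of which rows are being
#' transformed.
#'
#' @param params A `normalizer` from [fit_normalizer()].
#' @param table A `feature_table` with exactly the columns the params were
#'   fitted on.
#' @return The z-scored `feature_table`.
#' @export
apply_normalizer <- function(params, table) {
  stopifnot(inherits(params, "normalizer"), inherits(table, "feature_table"))
  miss <- setdiff(params$columns, colnames(table$x))
  if (length(miss)) {
    stop(sprintf("table is missing column(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  tab <- table[, params$columns]
  z <- sweep(sweep(tab$x, 2, params$center), 2, params$scale, `/`)
  feature_table(z, roles = tab$roles, labels = tab$labels)
}

#' @export
print.normalizer <- function(x, ...) {
  cat(sprintf("Batch normalizer: %d columns (training mean/sd)\n",
              length(x$columns)))
  invisible(x)
}
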