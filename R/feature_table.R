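#' Construct a feature table
#'
#' A feature table is the package's central container: a numeric matrix of
#' compounds by named feature columns, each column tagged with a role —
#' `"DS"` (docking score), `"PS"` (pharmacophore fit) or `"MD"` (molecular
#' descriptor); principal-component scores produced by the elimination
#' cascade carry role `"PC"` — plus optional binary activity labels.
#'
#' @param x Numeric matrix with unique row names (compound ids) and unique
#'   column names.
#' @param roles Character vector of column roles, one per column.
#' @param labels Optional binary vector (1 = active, 0 = decoy), one per
#'   row.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(x, roles, labels = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop("feature table columns must have unique names", call. = FALSE)
  }
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop("feature table rows must have unique ids", call. = FALSE)
  }
  if (length(roles) != ncol(x)) {
    stop("one role must be given per column", call. = FALSE)
  }
  if (!all(roles %in% c("DS", "PS", "MD", "PC"))) {
    stop("roles must be one of 'DS', 'PS', 'MD', 'PC'", call. = FALSE)
  }
  if (anyNA(x)) stop("feature table must not contain missing values",
                     call. = FALSE)
  roles <- stats::setNames(as.character(roles), colnames(x))
  if (!is.null(labels)) {
    if (length(labels) != nrow(x)) {
      stop("one label must be given per row", call. = FALSE)
    }
    if (!all(labels %in% c(0L, 1L))) {
      stop("labels must be binary (0/1)", call. = FALSE)
    }
    labels <- stats::setNames(as.integer(labels), rownames(x))
  }
  structure(list(x = x, roles = roles, labels = labels),
            class = "feature_table")
}

#' Assemble docking, pharmacophore and descriptor blocks
#'
#' Joins the three per-compound feature blocks into one [feature_table()]
#' with roles DS, PS, MD in that order. All blocks must be indexed by the
#' same compound ids; row order follows the docking block. Pharmacophore
#' mapping failures are expected to be encoded as fit = 0 upstream, so the
#' assembled table never contains missing values.
#'
#' @param docking Numeric matrix of engine scores with compound-id row
#'   names.
#' @param fits Numeric matrix of pharmacophore fit values (same ids).
#' @param descriptors Numeric matrix of molecular descriptors (same ids).
#' @param labels Optional binary labels, named by id or in docking row
#'   order.
#' @return A `feature_table` with `ncol(docking) + ncol(fits) +
#'   ncol(descriptors)` columns.
#' @examples
#' cmp <- generate_campaign(campaign_spec(n_actives = 5, n_decoys = 5,
#'                                        n_informative = 3, n_collinear_pairs = 2,
#'                                        n_near_constant = 2, n_noise = 3))
#' ft <- assemble_features(cmp$docking, cmp$fits, cmp$descriptors, cmp$labels)
#' table(ft$roles)
#' @export
assemble_features <- function(docking, fits, descriptors, labels = NULL) {
  blocks <- list(docking = docking, fits = fits, descriptors = descriptors)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (!is.matrix(b) || is.null(rownames(b))) {
      stop(sprintf("'%s' must be a matrix with compound-id row names", nm),
           call. = FALSE)
    }
  }
  ids <- rownames(docking)
  for (nm in c("fits", "descriptors")) {
    other <- rownames(blocks[[nm]])
    missing_ids <- setdiff(ids, other)
    extra_ids <- setdiff(other, ids)
    if (length(missing_ids) || length(extra_ids)) {
      stop(sprintf("compound ids of '%s' do not match docking ids (missing: %s; extra: %s)",
                   nm,
                   paste(utils::head(missing_ids, 5), collapse = ", "),
                   paste(utils::head(extra_ids, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  x <- cbind(docking,
             fits[ids, , drop = FALSE],
             descriptors[ids, , drop = FALSE])
  colnames(x) <- c(paste0("DS_", colnames(docking)),
                   paste0("PS_", colnames(fits)),
                   colnames(descriptors))
  roles <- c(rep("DS", ncol(docking)), rep("PS", ncol(fits)),
             rep("MD", ncol(descriptors)))
  if (!is.null(labels) && !is.null(names(labels))) labels <- labels[ids]
  feature_table(x, roles, labels)
}

#' Build the feature table of a synthetic campaign
#'
#' Convenience wrapper applying [assemble_features()] to the blocks of a
#' [generate_campaign()] result, carrying the campaign's labels.
#'
#' @param campaign A `campaign` object.
#' @param labelled Attach the campaign's labels (set `FALSE` for decks
#'   whose truth labels must not reach the model).
#' @return A `feature_table`.
#' @export
campaign_features <- function(campaign, labelled = TRUE) {
  stopifnot(inherits(campaign, "campaign"))
  assemble_features(campaign$docking, campaign$fits, campaign$descriptors,
                    labels = if (labelled) campaign$labels else NULL)
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(factor(x$roles, levels = c("DS", "PS", "MD", "PC")))
  cat(sprintf("Feature table: %d compounds x %d features (DS %d, PS %d, MD %d, PC %d)\n",
              nrow(x$x), ncol(x$x), tab["DS"], tab["PS"], tab["MD"], tab["PC"]))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d active, %d decoy\n",
                sum(x$labels == 1L), sum(x$labels == 0L)))
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' Subset a feature table
#'
#' Rows and columns are selected as for a matrix; column roles and row
#' labels are carried along.
#'
#' @param x A `feature_table`.
#' @param i,j Row and column indices (ids/names, integers or logicals).
#' @param ... Ignored.
#' @return A `feature_table`.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$x))
  if (missing(j)) j <- seq_len(ncol(x$x))
  xx <- x$x[i, j, drop = FALSE]
  feature_table(xx, roles = x$roles[colnames(xx)],
                labels = if (!is.null(x$labels)) x$labels[rownames(xx)])
}

# Restrict to the given roles (used by the ablation comparison).
subset_roles <- function(table, roles) {
  stopifnot(inherits(table, "feature_table"))
  missing_roles <- setdiff(roles, unique(table$roles))
  if (length(missing_roles)) {
    stop(sprintf("requested role(s) absent from table: %s",
                 paste(missing_roles, collapse = ", ")), call. = FALSE)
  }
  table[, names(table$roles)[table$roles %in% roles]]
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  out <- data.frame(id = rownames(x$x), x$x, check.names = FALSE,
                    row.names = NULL)
  if (!is.null(x$labels)) out <- cbind(out[1], label = unname(x$labels),
                                       out[-1])
  out
}

#' Consensus (average) docking score
#'
#' Arithmetic mean of a compound's docking scores across engines and
#' receptor chains, the consensus value screening reports print next to
#' the per-engine scores. Reported values are rounded half away from zero
#' to `digits` decimals; use `digits = NULL` for full precision.
#'
#' @param scores Numeric vector of docking scores (at least one, all
#'   finite).
#' @param digits Decimal places for reporting (default 2); `NULL` for no
#'   rounding.
#' @return The consensus score.
#' @examples
#' average_docking(c(-10.25, -10.39, -11.06, -11.07, -8.1, -8.1))
#' @export
average_docking <- function(scores, digits = 2) {
  if (length(scores) < 1L) stop("at least one docking score is required",
                                call. = FALSE)
  if (!is.numeric(scores) || !all(is.finite(scores))) {
    stop("docking scores must be finite numbers", call. = FALSE)
  }
  m <- mean(scores)
  if (is.null(digits)) m else round_half_up(m, digits)
}
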