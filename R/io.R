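# Delimited-file and JSON/YAML I/O for campaigns, feature tables,
# reports and run configurations. CSV files are RFC-4180, UTF-8, '.'
# decimal separator, full float precision.

fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)

#' Write a feature table to CSV with a role sidecar
#'
#' The CSV has a mandatory `id` column, an optional `label` column, and
#' one column per feature; a sidecar JSON (same path with `.roles.json`
#' appended) maps each column to its role.
#'
#' @param table A [feature_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "label"
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(table$roles),
                       paste0(path, ".roles.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path; the `.roles.json` sidecar must sit next to it.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("feature CSV must have an 'id' column",
                                 call. = FALSE)
  roles_path <- paste0(path, ".roles.json")
  if (!file.exists(roles_path)) {
    stop(sprintf("missing role sidecar: %s", roles_path), call. = FALSE)
  }
  roles <- unlist(jsonlite::read_json(roles_path))
  labels <- NULL
  feat_cols <- setdiff(names(df), c("id", "label"))
  if ("label" %in% names(df)) labels <- as.integer(df$label)
  x <- as.matrix(df[, feat_cols, drop = FALSE])
  rownames(x) <- df$id
  feature_table(x, roles = roles[feat_cols], labels = labels)
}

# Hex encoding of fingerprint bitsets (bit 1 of the fingerprint is the
# most significant bit of the first hex byte).
fp_to_hex <- function(bits) {
  bits <- as.logical(bits)
  pad <- (8 - length(bits) %% 8) %% 8
  bits <- c(bits, rep(FALSE, pad))
  bytes <- vapply(seq_len(length(bits) / 8), function(i) {
    sum(bits[(8 * i - 7):(8 * i)] * 2^(7:0))
  }, numeric(1))
  paste(sprintf("%02x", as.integer(bytes)), collapse = "")
}

hex_to_fp <- function(hex, n_bits) {
  bytes <- strtoi(substring(hex, seq(1, nchar(hex), 2),
                            seq(2, nchar(hex), 2)), base = 16L)
  bits <- unlist(lapply(bytes, function(b) as.logical(bitwAnd(b, 2^(7:0)))))
  bits[seq_len(n_bits)]
}

#' Write fingerprints as id + hex-encoded bitset
#'
#' @param fps Logical fingerprint matrix with id row names.
#' @param path Output CSV path (columns `id`, `n_bits`, `hex`).
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  stopifnot(is.matrix(fps), !is.null(rownames(fps)))
  hex <- apply(fps, 1, fp_to_hex)
  utils::write.csv(data.frame(id = rownames(fps), n_bits = ncol(fps),
                              hex = hex, row.names = NULL),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fingerprints written by [write_fingerprints()]
#'
#' @param path CSV path.
#' @return Logical fingerprint matrix with id row names.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  n_bits <- df$n_bits[1]
  fps <- t(vapply(df$hex, hex_to_fp, logical(n_bits), n_bits = n_bits))
  rownames(fps) <- df$id
  fps
}

#' Write a campaign to disk
#'
#' Emits `<name>.features.csv` (id, label, DS_*, PS_*, MD_* columns, full
#' float precision), `<name>.truth.json` (planted-role ledger plus an
#' echo of the generating spec) and `<name>.fingerprints.csv`.
#'
#' @param campaign A `campaign`.
#' @param dir Output directory (created if needed).
#' @param name File-name stem.
#' @return Named vector of the written paths, invisibly.
#' @export
write_campaign <- function(campaign, dir, name = "campaign") {
  stopifnot(inherits(campaign, "campaign"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fpath <- file.path(dir, paste0(name, ".features.csv"))
  tpath <- file.path(dir, paste0(name, ".truth.json"))
  ppath <- file.path(dir, paste0(name, ".fingerprints.csv"))
  ft <- campaign_features(campaign)
  write_feature_table(ft, fpath)
  spec_echo <- unclass(campaign$spec)
  spec_echo$engine_means <- spec_echo$engine_means %||% "default"
  jsonlite::write_json(list(truth = campaign$truth, spec = spec_echo),
                       tpath, auto_unbox = TRUE, digits = NA)
  write_fingerprints(campaign$fingerprints, ppath)
  invisible(c(features = fpath, truth = tpath, fingerprints = ppath))
}

#' Read a campaign's feature table and truth ledger
#'
#' @param dir Directory holding the files from [write_campaign()].
#' @param name File-name stem.
#' @return List with `features` (a `feature_table`), `truth`,
#'   `fingerprints`.
#' @export
read_campaign <- function(dir, name = "campaign") {
  ft <- read_feature_table(file.path(dir, paste0(name, ".features.csv")))
  truth <- jsonlite::read_json(file.path(dir, paste0(name, ".truth.json")),
                               simplifyVector = TRUE)
  fps <- read_fingerprints(file.path(dir, paste0(name, ".fingerprints.csv")))
  list(features = ft, truth = truth$truth, fingerprints = fps,
       spec_echo = truth$spec)
}

#' Serialise an elimination report to JSON
#'
#' @param report An `elimination_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_elimination_report <- function(report, path) {
  stopifnot(inherits(report, "elimination_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML (or JSON) configuration with strict schema validation: the
#' recognised top-level keys are `campaign` ([campaign_spec()] arguments),
#' `eliminate` ([eliminate_config()] arguments), `classifier` (one of
#' `"svm"`, `"gbt_leafwise"`, `"gbt_depthwise"` plus overrides), `cv`
#' (`k`, `seed`), and `funnel` ([funnel_config()] arguments). Unknown
#' keys at the top level or inside a section are rejected.
#'
#' @param path YAML or JSON file.
#' @return A list of class `run_config` with fully constructed
#'   `campaign`, `eliminate`, `classifier`, `cv` and `funnel` entries.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("campaign", "eliminate", "classifier", "cv", "funnel")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  check_args <- function(args, fn, section) {
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) {
      stop(sprintf("unknown key(s) in '%s': %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    args
  }
  campaign <- do.call(campaign_spec,
                      check_args(cfg$campaign %||% list(), campaign_spec,
                                 "campaign"))
  elim <- do.call(eliminate_config,
                  check_args(cfg$eliminate %||% list(), eliminate_config,
                             "eliminate"))
  cls <- cfg$classifier %||% list(type = "svm")
  type <- cls$type %||% "svm"
  maker <- switch(type,
                  svm = svm_config,
                  gbt_leafwise = gbt_leafwise_config,
                  gbt_depthwise = gbt_depthwise_config,
                  stop(sprintf("unknown classifier type '%s'", type),
                       call. = FALSE))
  classifier <- do.call(maker, check_args(cls[setdiff(names(cls), "type")],
                                          maker, "classifier"))
  cv <- cfg$cv %||% list()
  bad_cv <- setdiff(names(cv), c("k", "seed"))
  if (length(bad_cv)) {
    stop(sprintf("unknown key(s) in 'cv': %s", paste(bad_cv, collapse = ", ")),
         call. = FALSE)
  }
  funnel <- do.call(funnel_config,
                    check_args(cfg$funnel %||% list(), funnel_config,
                               "funnel"))
  structure(list(campaign = campaign, eliminate = elim,
                 classifier = classifier,
                 cv = list(k = cv$k %||% 5, seed = cv$seed %||% 1),
                 funnel = funnel),
            class = "run_config")
}
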