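#' Specify a synthetic screening campaign
#'
#' A campaign specification fixes the statistical structure of a simulated
#' structure-based virtual-screening data set: correlated per-compound
#' docking scores from several engine/receptor-chain combinations (more
#' negative = better, actives shifted toward better scores), pharmacophore
#' fit values with stochastic mapping failure encoded as a fit of exactly
#' 0, and a molecular-descriptor block with planted near-constant columns,
#' collinear pairs, class-informative columns and pure noise. The default
#' block sizes reproduce the canonical layout of 6 docking scores, 9 fit
#' values and 1444 descriptors for a 150-active / 150-decoy training set.
#'
#' @param n_actives,n_decoys Number of active and decoy compounds.
#' @param n_engines Number of docking-score channels (engine x chain).
#' @param n_pharmacophores Number of pharmacophore models mapped.
#' @param n_informative Descriptor columns carrying class signal.
#' @param n_collinear_pairs Planted collinear descriptor pairs (2 columns
#'   each, sample |r| > 0.85 by construction).
#' @param n_near_constant Descriptor columns taking a single value on 95%
#'   of rows (strictly above the 90% counting-filter threshold).
#' @param n_noise Pure-noise descriptor columns.
#' @param docking_effect Signed shift added to actives' docking scores;
#'   negative values move actives toward better (more negative) scores.
#' @param docking_corr Pairwise inter-engine score correlation in [0, 1),
#'   induced by a shared latent binding-quality factor.
#' @param map_prob_active,map_prob_decoy Probability that a compound maps
#'   onto a pharmacophore at all; failures get fit = 0.
#' @param fit_mean_active,fit_mean_decoy,fit_sd Parameters of the
#'   truncated-at-zero normal from which successful fit values are drawn.
#' @param descriptor_effect Standardised mean shift of the informative
#'   descriptor columns for actives.
#' @param n_bits Fingerprint length in bits.
#' @param n_scaffolds Number of scaffold fingerprints compounds are
#'   derived from (controls cluster structure of the deck).
#' @param bit_density Expected fraction of set bits in a scaffold.
#' @param mutation_rate Per-bit flip probability applied to a compound's
#'   scaffold fingerprint.
#' @param engine_means Optional numeric vector of per-engine baseline
#'   score means (length `n_engines`); a Glide/AutoDock-like default is
#'   used when `NULL`.
#' @param seed Integer root seed; all blocks draw from named substreams of
#'   this seed, so regenerating with the same spec is bit-for-bit
#'   reproducible.
#' @return An object of class `campaign_spec`.
#' @seealso [generate_campaign()], [generate_screening_deck()]
#' @export
campaign_spec <- function(n_actives = 150, n_decoys = 150,
                          n_engines = 6, n_pharmacophores = 9,
                          n_informative = 60, n_collinear_pairs = 150,
                          n_near_constant = 120, n_noise = 964,
                          docking_effect = -2, docking_corr = 0.6,
                          map_prob_active = 0.95, map_prob_decoy = 0.6,
                          fit_mean_active = 2.5, fit_mean_decoy = 1.5,
                          fit_sd = 0.8, descriptor_effect = 1,
                          n_bits = 256, n_scaffolds = 8,
                          bit_density = 0.3, mutation_rate = 0.05,
                          engine_means = NULL, seed = 1) {
  spec <- list(
    n_actives = n_actives, n_decoys = n_decoys, n_engines = n_engines,
    n_pharmacophores = n_pharmacophores, n_informative = n_informative,
    n_collinear_pairs = n_collinear_pairs, n_near_constant = n_near_constant,
    n_noise = n_noise, docking_effect = docking_effect,
    docking_corr = docking_corr, map_prob_active = map_prob_active,
    map_prob_decoy = map_prob_decoy, fit_mean_active = fit_mean_active,
    fit_mean_decoy = fit_mean_decoy, fit_sd = fit_sd,
    descriptor_effect = descriptor_effect, n_bits = n_bits,
    n_scaffolds = n_scaffolds, bit_density = bit_density,
    mutation_rate = mutation_rate, engine_means = engine_means, seed = seed
  )
  class(spec) <- "campaign_spec"
  validate_campaign_spec(spec)
  spec
}

validate_campaign_spec <- function(spec) {
  counts <- c("n_actives", "n_decoys", "n_engines", "n_pharmacophores",
              "n_informative", "n_collinear_pairs", "n_near_constant",
              "n_noise", "n_bits", "n_scaffolds")
  for (f in counts) {
    v <- spec[[f]]
    stop_fields(is.numeric(v) && length(v) == 1L && !is.na(v) &&
                  v >= 0 && v == floor(v), f, "must be a non-negative integer")
  }
  probs <- c("map_prob_active", "map_prob_decoy", "bit_density",
             "mutation_rate")
  for (f in probs) {
    v <- spec[[f]]
    stop_fields(is.numeric(v) && length(v) == 1L && !is.na(v) &&
                  v >= 0 && v <= 1, f, "must be a probability in [0, 1]")
  }
  stop_fields(spec$docking_corr >= 0 && spec$docking_corr < 1,
              "docking_corr", "must lie in [0, 1)")
  stop_fields(is.numeric(spec$fit_sd) && spec$fit_sd > 0,
              "fit_sd", "must be > 0")
  stop_fields(is.numeric(spec$docking_effect) && length(spec$docking_effect) == 1L,
              "docking_effect", "must be a single number")
  stop_fields(is.numeric(spec$descriptor_effect) &&
                length(spec$descriptor_effect) == 1L,
              "descriptor_effect", "must be a single number")
  if (!is.null(spec$engine_means)) {
    stop_fields(is.numeric(spec$engine_means) &&
                  length(spec$engine_means) == spec$n_engines,
                "engine_means", "must have length n_engines")
  }
  stop_fields(is.numeric(spec$seed) && length(spec$seed) == 1L &&
                spec$seed == floor(spec$seed), "seed", "must be an integer")
  invisible(spec)
}

#' @export
print.campaign_spec <- function(x, ...) {
  n_md <- x$n_informative + 2L * x$n_collinear_pairs +
    x$n_near_constant + x$n_noise
  cat("Synthetic screening-campaign specification\n")
  cat(sprintf("  compounds: %d actives + %d decoys\n", x$n_actives, x$n_decoys))
  cat(sprintf("  features : %d docking scores, %d fit values, %d descriptors\n",
              x$n_engines, x$n_pharmacophores, n_md))
  cat(sprintf("  descriptor blocks: %d informative, %d collinear pairs, %d near-constant, %d noise\n",
              x$n_informative, x$n_collinear_pairs, x$n_near_constant, x$n_noise))
  cat(sprintf("  effects: docking %+.2f (corr %.2f), descriptor %+.2f sd\n",
              x$docking_effect, x$docking_corr, x$descriptor_effect))
  cat(sprintf("  seed: %d\n", as.integer(x$seed)))
  invisible(x)
}

default_engine_means <- function(n_engines) {
  # Baseline (decoy-population) score levels on a Glide/AutoDock-like
  # scale: two SP channels, two XP channels, two AutoDock channels.
  base <- c(-6.5, -6.3, -4.8, -4.6, -7.0, -6.8)
  rep_len(base, n_engines)
}

engine_names <- function(n_engines) {
  std <- c("SP_A", "SP_B", "XP_A", "XP_B", "AD_A", "AD_B")
  if (n_engines <= length(std)) std[seq_len(n_engines)]
  else c(std, sprintf("ENG_%d", seq_len(n_engines - length(std))))
}

#' Generate a labelled synthetic screening campaign
#'
#' Draws a complete campaign from a [campaign_spec()]: docking-score
#' matrix, pharmacophore fit values, descriptor block with planted
#' structure, fingerprints, rule-of-five property profiles, binary
#' activity labels, and a truth ledger recording the planted role of every
#' descriptor column. Docking scores follow
#' `s = mu_engine + effect * label + sqrt(rho) * z + sqrt(1 - rho) * eps`
#' with a shared latent binding-quality factor `z`, so any two engines
#' have pairwise score correlation approximately `docking_corr`.
#'
#' @param spec A [campaign_spec()].
#' @return An object of class `campaign`: a list with elements `ids`,
#'   `labels` (1 = active, 0 = decoy), `docking` (compounds x engines),
#'   `fits` (compounds x pharmacophores; exactly 0 encodes mapping
#'   failure), `descriptors`, `fingerprints` (logical matrix), `ro5`
#'   (data frame of MW, logP, HBD, HBA), `truth` (planted-role ledger)
#'   and `spec`.
#' @examples
#' cmp <- generate_campaign(campaign_spec(n_actives = 20, n_decoys = 20,
#'                                        n_collinear_pairs = 5,
#'                                        n_near_constant = 5, n_noise = 20,
#'                                        n_informative = 10, seed = 7))
#' table(cmp$labels)
#' @export
generate_campaign <- function(spec) {
  stopifnot(inherits(spec, "campaign_spec"))
  validate_campaign_spec(spec)
  n <- spec$n_actives + spec$n_decoys
  if (n == 0) stop("campaign has no compounds", call. = FALSE)
  ids <- sprintf("CPD%05d", seq_len(n))
  labels <- c(rep(1L, spec$n_actives), rep(0L, spec$n_decoys))
  names(labels) <- ids

  docking <- draw_docking(spec, labels)
  fits <- draw_fits(spec, labels)
  desc <- draw_descriptors(spec, labels)
  fps <- draw_fingerprints(spec, n)
  ro5 <- draw_ro5(spec, n)
  rownames(docking) <- rownames(fits) <- rownames(desc$x) <- ids
  rownames(fps) <- ids
  ro5$id <- ids

  structure(list(ids = ids, labels = labels, docking = docking,
                 fits = fits, descriptors = desc$x, truth = desc$truth,
                 fingerprints = fps, ro5 = ro5[, c("id", "MW", "logP", "HBD", "HBA")],
                 spec = spec),
            class = "campaign")
}

draw_docking <- function(spec, labels) {
  n <- length(labels)
  mu <- spec$engine_means %||% default_engine_means(spec$n_engines)
  rho <- spec$docking_corr
  with_substream(spec$seed, "docking", {
    z <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * spec$n_engines), n, spec$n_engines)
    s <- matrix(mu, n, spec$n_engines, byrow = TRUE) +
      spec$docking_effect * labels +
      sqrt(rho) * z + sqrt(1 - rho) * eps
    colnames(s) <- engine_names(spec$n_engines)
    s
  })
}

draw_fits <- function(spec, labels) {
  n <- length(labels)
  p <- spec$n_pharmacophores
  map_prob <- ifelse(labels == 1L, spec$map_prob_active, spec$map_prob_decoy)
  fit_mean <- ifelse(labels == 1L, spec$fit_mean_active, spec$fit_mean_decoy)
  with_substream(spec$seed, "fits", {
    mapped <- matrix(stats::runif(n * p) < map_prob, n, p)
    val <- matrix(rtruncnorm0(n * p, mean = rep(fit_mean, p), sd = spec$fit_sd),
                  n, p)
    out <- ifelse(mapped, val, 0)
    colnames(out) <- sprintf("PH%d", seq_len(p))
    out
  })
}

draw_descriptors <- function(spec, labels) {
  n <- length(labels)
  blocks <- list()
  truth <- list(informative = character(), collinear_pairs = list(),
                near_constant = character(), noise = character())

  if (spec$n_informative > 0) {
    xi <- with_substream(spec$seed, "descriptors_informative", {
      matrix(stats::rnorm(n * spec$n_informative), n) +
        spec$descriptor_effect * labels
    })
    colnames(xi) <- sprintf("MD_inf%03d", seq_len(spec$n_informative))
    truth$informative <- colnames(xi)
    blocks <- c(blocks, list(xi))
  }
  if (spec$n_collinear_pairs > 0) {
    xc <- with_substream(spec$seed, "descriptors_collinear", {
      a <- matrix(stats::rnorm(n * spec$n_collinear_pairs), n)
      sgn <- sample(c(-1, 1), spec$n_collinear_pairs, replace = TRUE)
      # affine copy plus small noise: |r| ~ 1/sqrt(1 + 0.3^2) ~ 0.96,
      # comfortably above the 0.85 filter cutoff at n >= 40
      b <- sweep(a, 2, sgn, `*`) +
        0.3 * matrix(stats::rnorm(n * spec$n_collinear_pairs), n)
      out <- matrix(0, n, 2L * spec$n_collinear_pairs)
      out[, seq(1, ncol(out), by = 2)] <- a
      out[, seq(2, ncol(out), by = 2)] <- b
      out
    })
    nm <- as.vector(rbind(sprintf("MD_col%03da", seq_len(spec$n_collinear_pairs)),
                          sprintf("MD_col%03db", seq_len(spec$n_collinear_pairs))))
    colnames(xc) <- nm
    truth$collinear_pairs <- lapply(seq_len(spec$n_collinear_pairs), function(i) {
      nm[c(2L * i - 1L, 2L * i)]
    })
    blocks <- c(blocks, list(xc))
  }
  if (spec$n_near_constant > 0) {
    xk <- with_substream(spec$seed, "descriptors_near_constant", {
      out <- matrix(0, n, spec$n_near_constant)
      n_var <- n - ceiling(0.95 * n) # 5% of rows deviate from the mode
      for (j in seq_len(spec$n_near_constant)) {
        const <- stats::rnorm(1)
        col <- rep(const, n)
        if (n_var > 0) {
          idx <- sample.int(n, n_var)
          col[idx] <- const + stats::rnorm(n_var)
        }
        out[, j] <- col
      }
      out
    })
    colnames(xk) <- sprintf("MD_nc%03d", seq_len(spec$n_near_constant))
    truth$near_constant <- colnames(xk)
    blocks <- c(blocks, list(xk))
  }
  if (spec$n_noise > 0) {
    xn <- with_substream(spec$seed, "descriptors_noise", {
      matrix(stats::rnorm(n * spec$n_noise), n)
    })
    colnames(xn) <- sprintf("MD_nse%03d", seq_len(spec$n_noise))
    truth$noise <- colnames(xn)
    blocks <- c(blocks, list(xn))
  }
  x <- if (length(blocks)) do.call(cbind, blocks) else matrix(0, n, 0)
  list(x = x, truth = truth)
}

draw_fingerprints <- function(spec, n) {
  with_substream(spec$seed, "fingerprints", {
    k <- max(spec$n_scaffolds, 1L)
    scaffolds <- matrix(stats::runif(k * spec$n_bits) < spec$bit_density,
                        k, spec$n_bits)
    assign_to <- sample.int(k, n, replace = TRUE)
    flips <- matrix(stats::runif(n * spec$n_bits) < spec$mutation_rate,
                    n, spec$n_bits)
    xor(scaffolds[assign_to, , drop = FALSE], flips)
  })
}

draw_ro5 <- function(spec, n) {
  with_substream(spec$seed, "ro5", {
    data.frame(
      MW = pmax(stats::rnorm(n, 400, 75), 100),
      logP = stats::rnorm(n, 3, 1.2),
      HBD = stats::rpois(n, 2),
      HBA = stats::rpois(n, 5)
    )
  })
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf("Synthetic screening campaign: %d compounds (%d actives, %d decoys)\n",
              length(x$ids), sum(x$labels == 1L), sum(x$labels == 0L)))
  cat(sprintf("  %d docking scores, %d fit values, %d descriptors, %d-bit fingerprints\n",
              ncol(x$docking), ncol(x$fits), ncol(x$descriptors),
              ncol(x$fingerprints)))
  invisible(x)
}

#' Generate an unlabelled screening deck
#'
#' Draws a deck of `n` compounds from the same generative model as
#' [generate_campaign()], with the active fraction controlled by
#' `prevalence`. The true labels are retained in the returned object for
#' funnel evaluation but are not used by any screening stage.
#'
#' @param spec A [campaign_spec()]; its `n_actives`/`n_decoys` are ignored
#'   in favour of `n` and `prevalence`.
#' @param n Deck size.
#' @param prevalence Probability that a deck compound is a true active.
#' @return A `campaign` object (subclass `screening_deck`) whose `labels`
#'   are ground truth for evaluation only.
#' @export
generate_screening_deck <- function(spec, n, prevalence) {
  stopifnot(inherits(spec, "campaign_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop("invalid field 'n': must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1) {
    stop("invalid field 'prevalence': must be a probability in [0, 1]",
         call. = FALSE)
  }
  n_act <- with_substream(spec$seed, "deck_prevalence", {
    stats::rbinom(1, n, prevalence)
  })
  dspec <- spec
  dspec$n_actives <- as.integer(n_act)
  dspec$n_decoys <- as.integer(n - n_act)
  class(dspec) <- "campaign_spec"
  deck <- generate_campaign(dspec)
  # shuffle rows so actives are not positionally identifiable
  ord <- with_substream(spec$seed, "deck_shuffle", sample.int(n))
  deck$ids <- sprintf("DECK%06d", seq_len(n))
  deck$labels <- stats::setNames(deck$labels[ord], deck$ids)
  deck$docking <- deck$docking[ord, , drop = FALSE]
  deck$fits <- deck$fits[ord, , drop = FALSE]
  deck$descriptors <- deck$descriptors[ord, , drop = FALSE]
  deck$fingerprints <- deck$fingerprints[ord, , drop = FALSE]
  deck$ro5 <- deck$ro5[ord, , drop = FALSE]
  deck$ro5$id <- deck$ids
  rownames(deck$docking) <- rownames(deck$fits) <-
    rownames(deck$descriptors) <- rownames(deck$fingerprints) <- deck$ids
  rownames(deck$ro5) <- NULL
  class(deck) <- c("screening_deck", "campaign")
  deck
}

`%||%` <- function(a, b) if (is.null(a)) b else a
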