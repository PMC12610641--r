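#' Configuration for the synthetic cultivar dataset generator
#'
#' Defaults emulate the statistical structure of a three-cultivar
#' volatile study: 49 compounds of which 19 are detected in every
#' cultivar and 1/7/4 are cultivar-specific, log-normal relative
#' abundances spanning roughly 0.04-34 percent, triplicate
#' measurements with a fractional replicate SD (`replicate_cv`),
#' log-uniform odor thresholds over 0.005-40 with an 80/20 air/water
#' mix, one planted cultivar-unique key odorant, and a 12-assessor,
#' 3-session, 7-attribute descriptive panel with additive assessor
#' bias and Gaussian residual noise truncated to the 0-10 scale.
#'
#' @param cultivars Cultivar (sample) names.
#' @param n_compounds Total number of compounds.
#' @param n_shared Number detected in every cultivar.
#' @param n_unique Integer vector (one per cultivar) of
#'   cultivar-unique compounds; the remainder is spread over
#'   two-cultivar overlaps.
#' @param class_mixture Named proportions over [aroma_classes]
#'   (must sum to 1).
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of
#'   the pre-normalization abundance draw.
#' @param replicate_cv Fractional SD across the triplicate
#'   measurements of one cultivar.
#' @param threshold_log10_range Range of log10 threshold magnitudes.
#' @param threshold_coverage Probability that a compound has any
#'   threshold entry at all (databases are incomplete; uncovered
#'   compounds exercise the exclusion path).
#' @param multi_entry_prob Probability of a second threshold entry.
#' @param air_prob Probability that an entry is an air threshold.
#' @param planted_markers Data frame (`cultivar`, `compound`, `tier`):
#'   compounds whose threshold is set so their analytic ROAV lands in
#'   the target tier with at least a two-fold margin from the tier
#'   boundaries. `compound = NA` auto-assigns a compound from the
#'   cultivar's unique set; a named compound must belong to it.
#' @param n_assessors,n_sessions Panel design.
#' @param attributes Attribute lexicon.
#' @param attribute_means Cultivar-by-attribute matrix of true panel
#'   means; default emulates a woody-pungent / sweet-aromatic /
#'   fresh-herbaceous contrast.
#' @param assessor_sd SD of the per-assessor additive bias.
#' @param residual_sd SD of the observation noise.
#' @param linked_pairs Data frame (`compound`, `attribute`, `slope`):
#'   compounds whose per-cultivar abundance is `slope` times the
#'   cultivar mean of the attribute, planting a sensory-chemical
#'   co-localization. `compound = NA` reuses the planted marker
#'   compounds in order.
#' @param letter_equiv_tol Planted mean differences at or below this
#'   are treated as sensorially equivalent when forming the expected
#'   post hoc letter pattern (a 0.1-point gap on a 0-10 scale is below
#'   panel resolution).
#' @param seed Integer seed making the whole dataset reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(cultivars = c("A", "B", "C"),
                       n_compounds = 49L,
                       n_shared = 19L,
                       n_unique = c(1L, 7L, 4L),
                       class_mixture = c(
                         monoterpene_hydrocarbon = 12, sesquiterpene_hydrocarbon = 20,
                         oxygenated_monoterpene = 4, oxygenated_sesquiterpene = 7,
                         aliphatic_ester = 2, aliphatic_alkene = 1,
                         aliphatic_alcohol = 1, aliphatic_aldehyde = 1,
                         lactone = 1) / 49,
                       abundance_meanlog = 0,
                       abundance_sdlog = 1.5,
                       replicate_cv = 0.15,
                       threshold_log10_range = c(-2.3, 1.6),
                       threshold_coverage = 0.8,
                       multi_entry_prob = 0.2,
                       air_prob = 0.8,
                       planted_markers = data.frame(
                         cultivar = "B", compound = NA_character_,
                         tier = "key", stringsAsFactors = FALSE),
                       n_assessors = 12L,
                       n_sessions = 3L,
                       attributes = c("citrus", "minty", "woody", "floral",
                                      "coconut_milk", "herbal", "spicy"),
                       attribute_means = NULL,
                       assessor_sd = 0.3,
                       residual_sd = 0.7,
                       linked_pairs = data.frame(
                         compound = NA_character_, attribute = "coconut_milk",
                         slope = 1, stringsAsFactors = FALSE),
                       letter_equiv_tol = 0.25,
                       seed = 1L) {
  if (is.null(attribute_means)) {
    if (length(cultivars) != 3L || length(attributes) != 7L) {
      stop("supply `attribute_means` explicitly for a non-default design")
    }
    attribute_means <- rbind(
      c(citrus = 2.0, minty = 2.0, woody = 8.5, floral = 2.0,
        coconut_milk = 2.9, herbal = 3.0, spicy = 7.6),
      c(2.8, 2.0, 2.9, 7.5, 8.2, 3.0, 2.5),
      c(7.3, 6.8, 5.5, 5.5, 3.0, 6.5, 3.0))
    dimnames(attribute_means) <- list(cultivars, attributes)
  }
  cfg <- list(cultivars = cultivars, n_compounds = as.integer(n_compounds),
              n_shared = as.integer(n_shared),
              n_unique = stats::setNames(as.integer(n_unique), cultivars),
              class_mixture = class_mixture,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              replicate_cv = replicate_cv,
              threshold_log10_range = threshold_log10_range,
              threshold_coverage = threshold_coverage,
              multi_entry_prob = multi_entry_prob,
              air_prob = air_prob,
              planted_markers = planted_markers,
              n_assessors = as.integer(n_assessors),
              n_sessions = as.integer(n_sessions),
              attributes = attributes,
              attribute_means = attribute_means,
              assessor_sd = assessor_sd,
              residual_sd = residual_sd,
              linked_pairs = linked_pairs,
              letter_equiv_tol = letter_equiv_tol,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$class_mixture) - 1) > 1e-8) {
    stop("class_mixture proportions must sum to 1")
  }
  if (!all(names(cfg$class_mixture) %in% aroma_classes)) {
    stop("unknown class in class_mixture")
  }
  if (any(c(cfg$replicate_cv, cfg$assessor_sd, cfg$residual_sd) < 0)) {
    stop("SD parameters must be >= 0")
  }
  if (length(cfg$n_unique) != length(cfg$cultivars)) {
    stop("n_unique must have one entry per cultivar")
  }
  if (cfg$n_shared + sum(cfg$n_unique) > cfg$n_compounds) {
    stop("n_shared + sum(n_unique) exceeds n_compounds")
  }
  if (!all(cfg$planted_markers$cultivar %in% cfg$cultivars)) {
    stop("planted marker cultivar not among cultivars")
  }
  if (!all(cfg$planted_markers$tier %in% c("key", "modifier", "negligible"))) {
    stop("planted marker tier must be key, modifier, or negligible")
  }
  if (!all(cfg$linked_pairs$attribute %in% cfg$attributes)) {
    stop("linked pair attribute not in the lexicon")
  }
  invisible(cfg)
}

#' Simulate a cultivar VOC + threshold + sensory dataset
#'
#' Draws a complete, seeded dataset with known ground truth: a
#' [voc_table()] of triplicate-derived means and SDs, a `threshold_db`
#' with multi-entry air/water records, a [sensory_panel()], and a
#' `GroundTruth` list holding the generating reference compounds,
#' ROAV tiers, expected letter patterns, and planted co-localization
#' geometry -- everything needed to score pipeline recovery with
#' [recovery_report()].
#'
#' Abundances are drawn log-normally per detected compound-cultivar
#' cell, converted to percent composition, and measured as three
#' replicates with fractional noise `replicate_cv`, each replicate
#' renormalized to 100 percent. Planted markers get a threshold chosen
#' so their noise-free ROAV lands in the target tier with a two-fold
#' margin; linked compounds get abundances proportional to the target
#' attribute's cultivar means. Panel scores are cultivar-attribute
#' mean + assessor bias + Gaussian noise, truncated to the 0-10 scale.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A list of class `aroma_sim` with elements `voc`,
#'   `thresholds`, `panel`, `truth`, `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 17))
#' sim$truth$reference
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  cv <- config$cultivars
  nK <- length(cv)
  ids <- sprintf("cmp%02d", seq_len(config$n_compounds))

  # chemical classes by largest remainder, preserving mixture exactly
  target <- config$class_mixture * config$n_compounds
  counts <- floor(target)
  rem <- config$n_compounds - sum(counts)
  if (rem > 0) {
    extra <- order(target - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  classes <- rep(names(counts), counts)

  # detection design: shared block, unique blocks, two-cultivar rest
  detected <- matrix(FALSE, config$n_compounds, nK,
                     dimnames = list(ids, cv))
  detected[seq_len(config$n_shared), ] <- TRUE
  pos <- config$n_shared
  unique_ids <- list()
  for (k in seq_len(nK)) {
    idx <- pos + seq_len(config$n_unique[k])
    if (length(idx)) detected[idx, k] <- TRUE
    unique_ids[[cv[k]]] <- ids[idx]
    pos <- pos + config$n_unique[k]
  }
  rest <- setdiff(seq_len(config$n_compounds), seq_len(pos))
  if (length(rest) && nK >= 2) {
    prs <- utils::combn(nK, 2)
    for (i in seq_along(rest)) {
      pr <- prs[, ((i - 1) %% ncol(prs)) + 1]
      detected[rest[i], pr] <- TRUE
    }
  }

  # resolve marker and linked-pair compound assignments
  markers <- config$planted_markers
  if (nrow(markers)) {
    taken <- character(0)
    for (i in seq_len(nrow(markers))) {
      kc <- markers$cultivar[i]
      if (is.na(markers$compound[i])) {
        avail <- setdiff(unique_ids[[kc]], taken)
        if (!length(avail)) stop("no unique compound left for a marker in ", kc)
        markers$compound[i] <- avail[1]
      } else if (!markers$compound[i] %in% unique_ids[[kc]]) {
        stop("planted marker compound must be unique to its cultivar")
      }
      taken <- c(taken, markers$compound[i])
    }
  }
  links <- config$linked_pairs
  if (nrow(links)) {
    for (i in seq_len(nrow(links))) {
      if (is.na(links$compound[i])) {
        if (!nrow(markers)) stop("linked pair with compound = NA needs a marker")
        links$compound[i] <- markers$compound[((i - 1) %% nrow(markers)) + 1]
      }
    }
  }

  # true mean composition (percent), then triplicate measurement
  mu <- matrix(0, config$n_compounds, nK, dimnames = list(ids, cv))
  mu[detected] <- stats::rlnorm(sum(detected), config$abundance_meanlog,
                                config$abundance_sdlog)
  am <- config$attribute_means
  for (i in seq_len(nrow(links))) {
    cmp <- links$compound[i]
    attr_mu <- am[, links$attribute[i]]
    det_k <- detected[cmp, ]
    mu[cmp, det_k] <- links$slope[i] * attr_mu[det_k]
  }
  mu <- sweep(mu, 2, colSums(mu), "/") * 100

  nrep <- 3L
  meanm <- sdm <- matrix(0, config$n_compounds, nK,
                         dimnames = list(ids, cv))
  for (k in seq_len(nK)) {
    reps <- matrix(0, config$n_compounds, nrep)
    for (r in seq_len(nrep)) {
      noise <- 1 + config$replicate_cv * stats::rnorm(config$n_compounds)
      v <- mu[, k] * pmax(noise, 0.05)
      v <- v / sum(v) * 100
      reps[, r] <- v
    }
    meanm[, k] <- rowMeans(reps)
    sdm[, k] <- apply(reps, 1, stats::sd)
  }
  sdm[meanm == 0] <- NA_real_

  voc <- voc_table(meanm, sd = sdm, n = nrep,
                   compounds = data.frame(compound = ids,
                                          formula = NA_character_,
                                          class = classes,
                                          rt = NA_real_,
                                          stringsAsFactors = FALSE),
                   sum_tol = 1e-6)

  # thresholds: log-uniform magnitudes, air/water mix, optional second entry
  lo <- config$threshold_log10_range[1]
  hi <- config$threshold_log10_range[2]
  covered <- stats::runif(config$n_compounds) < config$threshold_coverage
  covered[ids %in% c(markers$compound, links$compound)] <- TRUE
  entries <- list()
  for (i in which(covered)) {
    v1 <- 10^stats::runif(1, lo, hi)
    m1 <- if (stats::runif(1) < config$air_prob) "air" else "water"
    entries[[length(entries) + 1]] <-
      data.frame(compound = ids[i], value = v1, medium = m1,
                 source = "simulated", stringsAsFactors = FALSE)
    if (stats::runif(1) < config$multi_entry_prob) {
      v2 <- v1 * exp(stats::rnorm(1, 0, 0.3))
      m2 <- if (stats::runif(1) < config$air_prob) "air" else "water"
      entries[[length(entries) + 1]] <-
        data.frame(compound = ids[i], value = v2, medium = m2,
                   source = "simulated", stringsAsFactors = FALSE)
    }
  }
  thr <- do.call(rbind, entries)

  # plant marker tiers: overwrite the marker's threshold so that its
  # analytic ROAV (from noise-free mu) hits the target with 2x margin
  # targets sit at least two-fold inside their tier's boundaries
  tier_target <- c(key = 10, modifier = sqrt(0.1), negligible = 0.03)
  for (i in seq_len(nrow(markers))) {
    cmp <- markers$compound[i]
    kc <- markers$cultivar[i]
    res <- resolve_thresholds(threshold_db(thr))
    tv <- stats::setNames(res$value, res$compound)
    others <- setdiff(names(tv)[tv > 0], cmp)
    others <- others[mu[others, kc] > 0]
    if (!length(others)) {
      stop("infeasible planting: no reference candidate in ", kc)
    }
    rmax <- max(mu[others, kc] / tv[others])
    target_ratio <- tier_target[[markers$tier[i]]] / 100 * rmax
    t_m <- mu[cmp, kc] / target_ratio
    thr <- thr[thr$compound != cmp, , drop = FALSE]
    thr <- rbind(thr, data.frame(compound = cmp, value = t_m,
                                 medium = "air", source = "planted",
                                 stringsAsFactors = FALSE))
  }
  thresholds <- threshold_db(thr)

  # sensory panel
  recs <- expand.grid(assessor = sprintf("a%02d", seq_len(config$n_assessors)),
                      session = seq_len(config$n_sessions),
                      sample = cv,
                      attribute = config$attributes,
                      stringsAsFactors = FALSE)
  bias <- stats::setNames(stats::rnorm(config$n_assessors, 0,
                                       config$assessor_sd),
                          unique(recs$assessor))
  base <- am[cbind(recs$sample, recs$attribute)]
  score <- base + bias[recs$assessor] +
    stats::rnorm(nrow(recs), 0, config$residual_sd)
  recs$score <- pmin(10, pmax(0, score))
  panel <- sensory_panel(recs, lexicon = config$attributes)

  truth <- make_ground_truth(mu, thresholds, markers, links, config,
                             unique_ids)
  structure(list(voc = voc, thresholds = thresholds, panel = panel,
                 truth = truth, config = config),
            class = "aroma_sim")
}

make_ground_truth <- function(mu, thresholds, markers, links, config,
                              unique_ids) {
  res <- resolve_thresholds(thresholds)
  tv <- stats::setNames(res$value, res$compound)
  keep <- intersect(rownames(mu), names(tv))
  cvs <- config$cultivars
  reference <- character(0)
  tier <- matrix(NA_character_, length(keep), length(cvs),
                 dimnames = list(keep, cvs))
  for (k in cvs) {
    p <- compute_roav_profile(mu[, k], tv[keep], sample_id = k)
    reference[k] <- p$reference
    tier[, k] <- p$tier[keep]
  }

  # expected letter pattern per attribute from the planted means:
  # cultivars whose planted means differ by <= letter_equiv_tol are
  # expected to share a letter
  am <- config$attribute_means
  letters_true <- lapply(config$attributes, function(a) {
    m <- sort(am[, a], decreasing = TRUE)
    sig <- outer(m, m, function(x, y) abs(x - y) > config$letter_equiv_tol)
    cld_letters(sig, m)[cvs]
  })
  names(letters_true) <- config$attributes

  # analytic co-localization of linked compounds vs all attributes,
  # from the noise-free composition
  coloc_true <- NULL
  if (nrow(links)) {
    sens <- am[cvs, , drop = FALSE]
    comp <- t(mu[unique(links$compound), cvs, drop = FALSE])
    jp <- joint_pca(sens, comp)
    coloc_true <- colocalize(jp, pairs = expand.grid(
      compound = unique(links$compound),
      attribute = config$attributes,
      stringsAsFactors = FALSE))
  }

  list(reference = reference,
       tier = tier,
       letters = letters_true,
       coloc = coloc_true,
       markers = markers,
       linked_pairs = links,
       unique_ids = unique_ids,
       mu = mu)
}

#' Score pipeline recovery against simulation ground truth
#'
#' Compares pipeline outputs with the `truth` element of an
#' [simulate_dataset()] result: tier-recovery accuracy over all
#' (compound, cultivar) cells with a threshold, reference-compound
#' match rate, post hoc letter-pattern match rate, and
#' co-localization precision/recall over the pairs assessed in the
#' truth (predicted flag vs noise-free flag).
#'
#' @param truth The `truth` element of an `aroma_sim`.
#' @param roav Optional [roav_table()] computed from the simulated data.
#' @param letters Optional named list (attribute -> named letter
#'   vector) as from [posthoc_letters()].
#' @param coloc Optional [colocalize()] result over the same pairs as
#'   `truth$coloc`.
#' @return List of metrics (only those for which inputs were given):
#'   `tier_accuracy`, `reference_match`, `letter_match`,
#'   `coloc_precision`, `coloc_recall`.
#' @export
recovery_report <- function(truth, roav = NULL, letters = NULL,
                            coloc = NULL) {
  out <- list()
  if (!is.null(roav)) {
    stopifnot(inherits(roav, "roav_table"))
    if (!setequal(colnames(roav$roav), colnames(truth$tier))) {
      stop("sample sets of roav table and truth differ")
    }
    common <- intersect(rownames(roav$tier), rownames(truth$tier))
    est <- roav$tier[common, colnames(truth$tier), drop = FALSE]
    out$tier_accuracy <- mean(est == truth$tier[common, , drop = FALSE])
    out$reference_match <-
      mean(roav$reference[names(truth$reference)] == truth$reference)
  }
  if (!is.null(letters)) {
    hits <- vapply(names(truth$letters), function(a) {
      obs <- letters[[a]]
      tr <- truth$letters[[a]]
      !is.null(obs) && identical(unname(obs[names(tr)]), unname(tr))
    }, logical(1))
    out$letter_match <- mean(hits)
  }
  if (!is.null(coloc) && !is.null(truth$coloc)) {
    key <- function(d) paste(d$compound, d$attribute, sep = "\r")
    m <- match(key(truth$coloc), key(coloc))
    if (anyNA(m)) stop("coloc result does not cover the truth pairs")
    pred <- coloc$co_localized[m]
    tr <- truth$coloc$co_localized
    tp <- sum(pred & tr)
    out$coloc_precision <- if (sum(pred) == 0) 1 else tp / sum(pred)
    out$coloc_recall <- if (sum(tr) == 0) 1 else tp / sum(tr)
  }
  out
}
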