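#' Resolve multiple threshold entries for one compound
#'
#' Odor-threshold databases typically report several values per
#' compound, in more than one medium. Resolution follows a fixed rule:
#' thresholds determined in air take priority; water values are used
#' only when no air value exists; within the selected medium the
#' arithmetic mean of all entries is the representative threshold.
#' Magnitudes are kept in their source units (mg/m3 in air, mg/kg in
#' water) and never converted -- relative abundances are divided by them
#' directly, so only ratios within a sample matter.
#'
#' @param entries A `threshold_db` (or plain data frame with `value`
#'   and `medium` columns), all rows for a single compound.
#' @return A list with `value` (resolved threshold), `medium`,
#'   `n_sources` (number of entries supplied), and `rule` -- one of
#'   `"single"` (one air entry), `"air_priority"` (air chosen over
#'   water), `"water_fallback"` (no air entry), `"mean"` (several
#'   entries of the selected medium, no cross-medium choice).
#' @export
resolve_threshold <- function(entries) {
  entries <- as.data.frame(entries)
  if (nrow(entries) == 0L) {
    stop("no threshold entries to resolve; exclude the compound instead")
  }
  air <- entries$medium == "air"
  if (any(air)) {
    sel <- entries[air, , drop = FALSE]
    medium <- "air"
    rule <- if (nrow(entries) == 1L) "single"
            else if (any(!air)) "air_priority"
            else "mean"
  } else {
    sel <- entries
    medium <- "water"
    rule <- "water_fallback"
  }
  list(value = mean(sel$value), medium = medium,
       n_sources = nrow(entries), rule = rule)
}

#' Resolve a whole threshold database
#'
#' Applies [resolve_threshold()] compound by compound.
#'
#' @param db A `threshold_db`.
#' @return Data frame with one row per compound: `compound`, `value`,
#'   `medium`, `n_sources`, `rule`.
#' @export
resolve_thresholds <- function(db) {
  stopifnot(inherits(db, "threshold_db") || is.data.frame(db))
  ids <- unique(db$compound)
  res <- lapply(ids, function(id) {
    r <- resolve_threshold(db[db$compound == id, , drop = FALSE])
    data.frame(compound = id, value = r$value, medium = r$medium,
               n_sources = r$n_sources, rule = r$rule,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pick the reference (ROAV = 100) compound of a sample
#'
#' The reference is the compound against which all relative odor
#' activity values in a sample are normalized. Under the default
#' `"ct-max"` rule it is the detected, thresholded compound maximizing
#' the concentration/threshold ratio C/T -- i.e. the most odor-potent
#' compound, which by construction receives ROAV 100. The alternative
#' `"conc-max"` rule takes the compound of highest relative
#' concentration regardless of potency (a common textbook phrasing,
#' which can leave every ROAV above 100 when a low-abundance compound
#' is more potent). Ties are broken lexicographically (byte order) for
#' determinism.
#'
#' @param conc Named numeric vector of mean relative abundances
#'   (percent) for one sample; zeros mean not detected.
#' @param thresholds Named numeric vector of resolved thresholds.
#' @param rule `"ct-max"` (default) or `"conc-max"`.
#' @return The reference compound id (character scalar).
#' @export
find_reference <- function(conc, thresholds, rule = c("ct-max", "conc-max")) {
  rule <- match.arg(rule)
  eligible <- names(conc)[conc > 0 & names(conc) %in% names(thresholds)]
  if (length(eligible) == 0L) {
    stop("no detected compound with a resolved threshold")
  }
  score <- switch(rule,
    "ct-max" = conc[eligible] / thresholds[eligible],
    "conc-max" = conc[eligible]
  )
  best <- eligible[score == max(score)]
  sort(best, method = "radix")[1]
}

#' Classify a ROAV value into odor-impact tiers
#'
#' `key` odorants (ROAV >= 1) have decisive impact on the overall
#' aroma; `modifier` compounds (0.1 <= ROAV < 1) contribute nuance;
#' `negligible` (0 < ROAV < 0.1) are below sensory relevance; `absent`
#' is exactly 0 (not detected). Both cutoffs are inclusive at their
#' lower bound.
#'
#' @param value Numeric vector of ROAV values in \[0, 100\].
#' @return Character vector of tiers.
#' @examples
#' classify_roav(c(73.002, 0.316, 0.05, 0))
#' @export
classify_roav <- function(value) {
  if (any(!is.finite(value)) || any(value < 0 | value > 100 + 1e-9)) {
    stop("ROAV values must lie in [0, 100]")
  }
  ifelse(value >= 1, "key",
    ifelse(value >= 0.1, "modifier",
      ifelse(value > 0, "negligible", "absent")))
}

#' Compute the ROAV profile of one sample
#'
#' For every compound i with a resolved threshold T_i, the relative
#' odor activity value is
#' \deqn{ROAV_i = \frac{C_i / T_i}{C_{ref} / T_{ref}} \times 100}
#' where C is the relative abundance (percent of total peak area) and
#' the reference compound is chosen by [find_reference()]. Undetected
#' compounds score 0 (`absent`); compounds without any threshold entry
#' are excluded and reported rather than silently dropped.
#'
#' @param conc Named numeric vector of mean abundances for one sample.
#' @param thresholds Either a `threshold_db` or a named numeric vector
#'   of already-resolved thresholds.
#' @param sample_id Sample label carried into the result.
#' @param reference_rule Passed to [find_reference()].
#' @return An object of class `roav_profile`: list with `sample_id`,
#'   `reference`, `roav` (named vector over thresholded compounds),
#'   `tier`, `excluded` (compounds lacking thresholds).
#' @export
compute_roav_profile <- function(conc, thresholds, sample_id = "sample",
                                 reference_rule = c("ct-max", "conc-max")) {
  reference_rule <- match.arg(reference_rule)
  tvec <- as_threshold_vector(thresholds)
  if (is.null(names(conc))) stop("`conc` must be named by compound")
  names(conc) <- canonical_id(names(conc))
  excluded <- setdiff(names(conc), names(tvec))
  keep <- intersect(names(conc), names(tvec))
  ref <- find_reference(conc[keep], tvec, rule = reference_rule)
  ref_ratio <- conc[[ref]] / tvec[[ref]]
  roav <- (conc[keep] / tvec[keep]) / ref_ratio * 100
  roav[conc[keep] == 0] <- 0
  tier <- classify_roav(roav)
  names(tier) <- names(roav)
  structure(list(sample_id = sample_id, reference = ref,
                 roav = roav, tier = tier, excluded = excluded),
            class = "roav_profile")
}

as_threshold_vector <- function(thresholds) {
  if (inherits(thresholds, "threshold_db")) {
    r <- resolve_thresholds(thresholds)
    stats::setNames(r$value, r$compound)
  } else if (is.data.frame(thresholds)) {
    stats::setNames(thresholds$value, thresholds$compound)
  } else {
    stopifnot(is.numeric(thresholds), !is.null(names(thresholds)))
    stats::setNames(as.numeric(thresholds), canonical_id(names(thresholds)))
  }
}

#' ROAV matrix for all samples of a VOC table
#'
#' The main user-facing entry point of the odor-prioritization stage:
#' resolves the threshold database, picks a per-sample reference
#' compound, and computes [compute_roav_profile()] for every sample.
#'
#' @param voc A [voc_table()].
#' @param thresholds A `threshold_db`.
#' @param reference_rule Passed to [find_reference()].
#' @return An object of class `roav_table`: list with `roav`
#'   (thresholded-compound x sample matrix), `tier` (character matrix),
#'   `reference` (named vector per sample), `excluded` (compounds with
#'   no threshold entry), `resolved` (the resolved threshold table).
#' @examples
#' voc <- kadsura_voc()
#' db <- kadsura_thresholds()
#' rt <- roav_table(voc, db)
#' rt$reference
#' @export
roav_table <- function(voc, thresholds, reference_rule = c("ct-max", "conc-max")) {
  stopifnot(inherits(voc, "voc_table"))
  reference_rule <- match.arg(reference_rule)
  resolved <- resolve_thresholds(thresholds)
  tvec <- stats::setNames(resolved$value, resolved$compound)
  keep <- intersect(rownames(voc$mean), names(tvec))
  if (length(keep) == 0L) stop("no compound of the table has a threshold")
  excluded <- setdiff(rownames(voc$mean), keep)
  roav <- tier <- NULL
  refs <- character(0)
  for (s in voc$samples) {
    p <- compute_roav_profile(voc$mean[, s], tvec[keep], sample_id = s,
                              reference_rule = reference_rule)
    roav <- cbind(roav, p$roav[keep])
    tier <- cbind(tier, p$tier[keep])
    refs[s] <- p$reference
  }
  dimnames(roav) <- dimnames(tier) <- list(keep, voc$samples)
  structure(list(roav = roav, tier = tier, reference = refs,
                 excluded = excluded, resolved = resolved,
                 reference_rule = reference_rule),
            class = "roav_table")
}

#' @export
print.roav_table <- function(x, ...) {
  cat(sprintf("ROAV table: %d thresholded compounds x %d samples\n",
              nrow(x$roav), ncol(x$roav)))
  cat("  reference compounds:",
      paste(sprintf("%s=%s", names(x$reference), x$reference),
            collapse = ", "), "\n")
  cat(sprintf("  excluded (no threshold): %d compounds\n",
              length(x$excluded)))
  invisible(x)
}

#' Cross-sample comparison of ROAV profiles
#'
#' Flags, per compound: `universal_key` -- key odorant (ROAV >= 1) in
#' every sample; `specific_key_sample` -- key in exactly one sample
#' (that sample, else `NA`); `marker_sample` -- detected in exactly one
#' sample *and* key there, i.e. a candidate chemotaxonomic marker for
#' that cultivar.
#'
#' @param rt A [roav_table()] over at least two samples.
#' @return Data frame with one row per thresholded compound, the
#'   per-sample ROAVs, and the three flags.
#' @export
compare_cultivars <- function(rt) {
  stopifnot(inherits(rt, "roav_table"))
  if (ncol(rt$roav) < 2L) stop("need at least two samples to compare")
  is_key <- rt$tier == "key"
  detected <- rt$roav > 0
  n_key <- rowSums(is_key)
  n_det <- rowSums(detected)
  pick <- function(cond_matrix, sel) {
    ifelse(sel, colnames(cond_matrix)[max.col(cond_matrix, "first")],
           NA_character_)
  }
  out <- data.frame(compound = rownames(rt$roav),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(rt$roav))
  out$universal_key <- n_key == ncol(rt$roav)
  out$specific_key_sample <- pick(is_key, n_key == 1L)
  # key status is only possible where detected, so n_key == 1 suffices
  out$marker_sample <- pick(detected, n_det == 1L & n_key == 1L)
  rownames(out) <- NULL
  out
}
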