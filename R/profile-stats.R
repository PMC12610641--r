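#' Normalize raw peak areas to relative percentages
#'
#' Converts integrated chromatographic peak areas to the
#' relative-abundance scale used throughout the pipeline: each cell
#' becomes 100 x area / (total area of its sample), so every sample
#' column sums to exactly 100.
#'
#' @param areas Non-negative compound-by-sample matrix of peak areas
#'   with dimnames.
#' @param compounds Optional compound metadata (see [voc_table()]).
#' @return A [voc_table()] of percentages (no replicate SDs).
#' @export
normalize_peak_areas <- function(areas, compounds = NULL) {
  areas <- as.matrix(areas)
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("peak areas must be finite and non-negative")
  }
  totals <- colSums(areas)
  if (any(totals <= 0)) {
    stop("sample(s) with zero total area: ",
         paste(colnames(areas)[totals <= 0], collapse = ", "))
  }
  pct <- sweep(areas, 2, totals, "/") * 100
  voc_table(pct, compounds = compounds, sum_tol = 1e-6)
}

#' Detection-set accounting across samples
#'
#' Partitions the detected compounds of a multi-sample table into the
#' set shared by all samples, sets detected in some but not all, and
#' sets unique to a single sample; the unique sets are additionally
#' filtered to terpenoids (mono-/sesquiterpene hydrocarbons and their
#' oxygenated forms), the classes used to describe cultivar-specific
#' chemotypes.
#'
#' @param voc A [voc_table()].
#' @return An object of class `detection_report`: list with
#'   `per_sample_counts`, `shared_all`, `partial` (detected in >= 2
#'   samples but not all; equals `shared_all` for a single-sample
#'   table), `unique_per_sample`, `unique_terpenoids_per_sample`.
#' @export
detection_sets <- function(voc) {
  stopifnot(inherits(voc, "voc_table"))
  det <- voc$detected
  n_samples <- ncol(det)
  n_det <- rowSums(det)
  shared_all <- rownames(det)[n_det == n_samples]
  unique_per_sample <- lapply(colnames(det), function(s) {
    rownames(det)[det[, s] & n_det == 1L]
  })
  names(unique_per_sample) <- colnames(det)
  terp <- voc$compounds$compound[voc$compounds$class %in% terpenoid_classes]
  structure(list(
    per_sample_counts = as.integer(colSums(det)) |>
      stats::setNames(colnames(det)),
    shared_all = shared_all,
    partial = rownames(det)[n_det > 1L & n_det < n_samples],
    unique_per_sample = unique_per_sample,
    unique_terpenoids_per_sample = lapply(unique_per_sample, intersect,
                                          x = terp)
  ), class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat("Detection report\n")
  cat("  per-sample counts:",
      paste(sprintf("%s=%d", names(x$per_sample_counts),
                    x$per_sample_counts), collapse = ", "), "\n")
  cat(sprintf("  shared by all samples: %d compounds\n",
              length(x$shared_all)))
  for (s in names(x$unique_per_sample)) {
    cat(sprintf("  unique to %s: %d (%d terpenoids)\n", s,
                length(x$unique_per_sample[[s]]),
                length(x$unique_terpenoids_per_sample[[s]])))
  }
  invisible(x)
}

#' Chemical-class composition sums
#'
#' Sums mean relative abundances per chemical class within each
#' sample, and reports each sample's identified total (sum over all
#' detected compounds).
#'
#' @param voc A [voc_table()].
#' @return An object of class `composition_report`: list with
#'   `class_sums` (data frame `sample`, `class`, `percent`, including
#'   zero rows for empty classes) and `identified_total` (named
#'   vector).
#' @export
class_composition <- function(voc) {
  stopifnot(inherits(voc, "voc_table"))
  cls <- voc$compounds$class
  rows <- expand.grid(sample = voc$samples, class = aroma_classes,
                      stringsAsFactors = FALSE)
  rows$percent <- mapply(function(s, k) {
    sum(voc$mean[cls == k, s])
  }, rows$sample, rows$class)
  structure(list(class_sums = rows,
                 identified_total = colSums(voc$mean)),
            class = "composition_report")
}

#' Sum the abundances of a named compound set in one sample
#'
#' Used for "dominant compound" style statements, e.g. the collective
#' share of the six most abundant volatiles of a cultivar.
#'
#' @param voc A [voc_table()].
#' @param sample Sample id.
#' @param compounds Character vector of compound ids (all must exist).
#' @param label Optional label attached to the result.
#' @return Numeric scalar (percent), with attribute `label` if given.
#' @export
named_sum <- function(voc, sample, compounds, label = NULL) {
  stopifnot(inherits(voc, "voc_table"))
  if (!sample %in% voc$samples) stop("unknown sample: ", sample)
  compounds <- canonical_id(compounds)
  missing <- setdiff(compounds, rownames(voc$mean))
  if (length(missing)) {
    stop("unknown compound(s): ", paste(missing, collapse = ", "))
  }
  out <- sum(voc$mean[compounds, sample])
  if (!is.null(label)) attr(out, "label") <- label
  out
}
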