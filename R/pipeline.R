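#' Configuration for an end-to-end pipeline run
#'
#' @param voc,thresholds,scores Paths to the three input files (VOC
#'   composition table, odor-threshold table, long-format sensory
#'   scores).
#' @param out_dir Output directory (created if absent).
#' @param reference_rule Reference selection rule, see
#'   [find_reference()].
#' @param alpha Significance level for ANOVA/post hoc (in (0, 1)).
#' @param posthoc `"tukey"` or `"duncan"`.
#' @param theta_max,r_min Co-localization thresholds, see
#'   [colocalize()].
#' @param linkage,metric Heatmap clustering options, see [hcluster()].
#' @param seed Optional seed (the pipeline itself is deterministic;
#'   the seed is echoed into the manifest for provenance).
#' @return A list of class `run_config`.
#' @export
run_config <- function(voc, thresholds, scores, out_dir,
                       reference_rule = "ct-max", alpha = 0.05,
                       posthoc = "tukey", theta_max = 10, r_min = 0.9,
                       linkage = "average", metric = "euclidean",
                       seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, theta_max > 0, r_min >= -1, r_min <= 1)
  structure(list(voc = voc, thresholds = thresholds, scores = scores,
                 out_dir = out_dir, reference_rule = reference_rule,
                 alpha = alpha, posthoc = posthoc, theta_max = theta_max,
                 r_min = r_min, linkage = linkage, metric = metric,
                 seed = seed),
            class = "run_config")
}

#' Run the full aroma-prioritization pipeline
#'
#' Executes the four analysis stages -- ROAV prioritization, detection
#' and composition accounting, sensory aggregation with post hoc
#' letters, and joint multivariate analysis (Z-score cluster heatmap,
#' joint PCA, co-localization) -- and writes all result tables plus a
#' `manifest.json` with the echoed configuration and MD5 content
#' hashes of every artifact. Only key odorants (tier `key` in at
#' least one sample) enter the heatmap and joint PCA.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly. Any stage error aborts with a
#'   non-written or partial output directory; nothing is silently
#'   swallowed.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$voc, config$thresholds, config$scores)) {
    if (!file.exists(p)) stop("cannot read input file: ", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  written <- character(0)

  message("[aromarank] reading inputs")
  voc <- read_voc_table(config$voc)
  db <- read_threshold_table(config$thresholds)
  panel <- read_sensory_scores(config$scores)

  message("[aromarank] stage 1/4: ROAV prioritization")
  rt <- roav_table(voc, db, reference_rule = config$reference_rule)
  if (length(rt$excluded)) {
    message("  excluded (no threshold): ",
            paste(rt$excluded, collapse = ", "))
  }
  roav_df <- data.frame(compound = rownames(rt$roav),
                        as.data.frame(rt$roav), check.names = FALSE)
  write_csv_utf8(roav_df, out("roav.csv")); written <- c(written, "roav.csv")
  tier_df <- data.frame(compound = rownames(rt$tier),
                        as.data.frame(rt$tier), check.names = FALSE)
  write_csv_utf8(tier_df, out("tiers.csv")); written <- c(written, "tiers.csv")

  message("[aromarank] stage 2/4: detection and composition accounting")
  det <- detection_sets(voc)
  det_df <- data.frame(
    sample = names(det$per_sample_counts),
    n_detected = as.integer(det$per_sample_counts),
    n_unique = vapply(det$unique_per_sample, length, 1L),
    n_unique_terpenoids = vapply(det$unique_terpenoids_per_sample, length, 1L),
    n_shared_all = length(det$shared_all))
  write_csv_utf8(det_df, out("detection_report.csv"))
  written <- c(written, "detection_report.csv")
  comp <- class_composition(voc)
  write_csv_utf8(comp$class_sums, out("composition_report.csv"))
  written <- c(written, "composition_report.csv")

  message("[aromarank] stage 3/4: sensory aggregation and post hoc letters")
  sens <- sensory_summary(panel, method = config$posthoc,
                          alpha = config$alpha)
  write_csv_utf8(sens, out("sensory_summary.csv"))
  written <- c(written, "sensory_summary.csv")

  message("[aromarank] stage 4/4: multivariate analysis")
  agg <- aggregate_scores(panel)
  samples <- sort(unique(agg$sample))
  sens_mat <- matrix(agg$mean[match(
    paste(rep(samples, length(attr(panel, "lexicon"))),
          rep(attr(panel, "lexicon"), each = length(samples))),
    paste(agg$sample, agg$attribute))],
    nrow = length(samples),
    dimnames = list(samples, attr(panel, "lexicon")))
  key_cmp <- rownames(rt$tier)[rowSums(rt$tier == "key") > 0]
  key_mat <- t(voc$mean[key_cmp, samples, drop = FALSE])
  jp <- joint_pca(sens_mat, key_mat)
  pca_df <- data.frame(variable = rownames(jp$loadings),
                       block = jp$blocks,
                       as.data.frame(jp$loadings[, 1:2, drop = FALSE]),
                       check.names = FALSE)
  write_csv_utf8(pca_df, out("pca.csv")); written <- c(written, "pca.csv")
  cl <- colocalize(jp, theta_max = config$theta_max, r_min = config$r_min)
  write_csv_utf8(as.data.frame(cl), out("coloc.csv"))
  written <- c(written, "coloc.csv")
  hm <- cluster_heatmap(voc$mean[key_cmp, samples, drop = FALSE],
                        linkage = config$linkage, metric = config$metric)
  hm_df <- data.frame(compound = rownames(hm$zmatrix),
                      as.data.frame(hm$zmatrix),
                      display_rank = match(seq_len(nrow(hm$zmatrix)),
                                           hm$row_order),
                      check.names = FALSE)
  write_csv_utf8(hm_df, out("heatmap.csv")); written <- c(written, "heatmap.csv")

  manifest <- list(
    config = unclass(config),
    inputs = as.list(tools::md5sum(c(config$voc, config$thresholds,
                                     config$scores))),
    outputs = as.list(tools::md5sum(file.path(config$out_dir, written))),
    diagnostics = list(
      reference = as.list(rt$reference),
      excluded_no_threshold = rt$excluded,
      explained_variance_ratio = jp$explained_variance_ratio[1:2],
      per_sample_detected = as.list(det_df$n_detected)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  message("[aromarank] wrote ", length(written) + 1, " artifacts to ",
          config$out_dir)
  invisible(manifest)
}
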