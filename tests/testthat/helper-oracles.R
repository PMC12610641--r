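# Independent brute-force oracles, kept free of the package's own
# computational paths.

# ROAV by direct enumeration: odor activity C/T for every detected,
# thresholded compound, then rescale by the maximum.
oracle_roav <- function(conc, thr) {
  common <- intersect(names(conc), names(thr))
  oav <- conc[common] / thr[common]
  oav[conc[common] == 0] <- 0
  oav / max(oav) * 100
}

# One-way ANOVA F from the textbook sums of squares.
oracle_anova_F <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Exhaustive agglomeration under a given linkage, from the raw
# distance matrix; returns merge heights and the partition after each
# merge (as a list of membership vectors).
oracle_agglomerate <- function(x, linkage = "average") {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  partitions <- list()
  cluster_dist <- function(a, b) {
    vals <- d[a, b, drop = FALSE]
    switch(linkage,
           average = mean(vals),
           single = min(vals),
           complete = max(vals))
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        dd <- cluster_dist(clusters[[i]], clusters[[j]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters <- c(clusters, list(merged))
    heights <- c(heights, bestd)
    memb <- integer(nrow(d))
    for (ci in seq_along(clusters)) memb[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1]] <- memb
  }
  list(heights = heights, partitions = partitions)
}

# Verify that a compact letter display exactly encodes a significance
# graph: two groups share a letter iff they are NOT significantly
# different.
cld_encodes_graph <- function(letters_vec, signif) {
  g <- names(letters_vec)
  for (i in seq_along(g)[-length(g)]) {
    for (j in (i + 1):length(g)) {
      share <- length(intersect(strsplit(letters_vec[[g[i]]], "")[[1]],
                                strsplit(letters_vec[[g[j]]], "")[[1]])) > 0
      if (share == signif[g[i], g[j]]) return(FALSE)
    }
  }
  TRUE
}

# Normalized partition signature (cluster labels up to renaming).
partition_signature <- function(memb) {
  as.integer(factor(memb, levels = unique(memb)))
}

# Build a sensory panel with a planted per-sample mean structure:
# 12 assessors x `n_sessions` sessions, Gaussian noise, clipped to
# the 0-10 scale.
make_panel <- function(means, sd = 0.7, n_assessors = 12, n_sessions = 3,
                       attribute = "attr1") {
  samples <- names(means)
  recs <- expand.grid(assessor = sprintf("a%02d", seq_len(n_assessors)),
                      session = seq_len(n_sessions),
                      sample = samples,
                      attribute = attribute,
                      stringsAsFactors = FALSE)
  recs$score <- pmin(10, pmax(0, means[recs$sample] +
                                rnorm(nrow(recs), 0, sd)))
  sensory_panel(recs)
}

# Write test fixture lines as UTF-8 regardless of locale.
write_utf8 <- function(lines, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
}

# Predicted co-localization over the truth pairs of a simulated
# dataset: panel-estimated sensory means joined with the measured
# abundances of the linked compounds.
coloc_prediction <- function(sim) {
  cfg <- sim$config
  agg <- aggregate_scores(sim$panel)
  sm <- with(agg, tapply(mean, list(sample, attribute),
                         identity))[cfg$cultivars, cfg$attributes]
  cm <- t(sim$voc$mean[unique(sim$truth$linked_pairs$compound),
                       cfg$cultivars, drop = FALSE])
  cl <- colocalize(joint_pca(sm, cm), pairs = data.frame(
    compound = sim$truth$coloc$compound,
    attribute = sim$truth$coloc$attribute,
    stringsAsFactors = FALSE))
  list(pred = cl$co_localized, coloc = cl)
}
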