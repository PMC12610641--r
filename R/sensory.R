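#' Aggregate panel scores per sample and attribute
#'
#' Pools all assessor-by-session observations of a quantitative
#' descriptive panel into per-(sample, attribute) means and standard
#' deviations (denominator n - 1). Sessions are treated as independent
#' replicate observations; no assessor random effect is fitted.
#'
#' @param panel A [sensory_panel()].
#' @return Data frame with columns `sample`, `attribute`, `mean`,
#'   `sd`, `n`, covering the full sample-by-lexicon grid.
#' @export
aggregate_scores <- function(panel) {
  stopifnot(inherits(panel, "sensory_panel"))
  samples <- unique(as.character(panel$sample))
  attributes <- attr(panel, "lexicon")
  grid <- expand.grid(sample = samples, attribute = attributes,
                      stringsAsFactors = FALSE)
  res <- mapply(function(s, a) {
    x <- panel$score[panel$sample == s & panel$attribute == a]
    if (length(x) == 0L) {
      stop(sprintf("no observations for cell (%s, %s)", s, a))
    }
    c(mean(x), stats::sd(x), length(x))
  }, grid$sample, grid$attribute)
  grid$mean <- res[1, ]
  grid$sd <- res[2, ]
  grid$n <- as.integer(res[3, ])
  grid
}

#' One-way ANOVA on a sensory attribute
#'
#' Fixed-effects one-way analysis of variance of the attribute's
#' scores grouped by sample, fitted with [stats::aov()]. When every
#' group has zero internal variance but the group means differ, F is
#' infinite; the p-value is then reported as the 0 limit and the
#' result is flagged `degenerate`.
#'
#' @param panel A [sensory_panel()].
#' @param attribute Attribute name (must be in the lexicon).
#' @return List with `F`, `p`, `df_between`, `df_within`, `ms_within`,
#'   `degenerate`, and `fit` (the `aov` object).
#' @export
anova_attribute <- function(panel, attribute) {
  stopifnot(inherits(panel, "sensory_panel"))
  d <- panel[panel$attribute == attribute, , drop = FALSE]
  if (nrow(d) == 0L) stop("unknown attribute: ", attribute)
  d$sample <- factor(d$sample)
  if (nlevels(d$sample) < 2L) stop("need at least two samples")
  if (min(table(d$sample)) < 2L) stop("need >= 2 observations per sample")
  fit <- stats::aov(score ~ sample, data = d)
  tab <- summary(fit)[[1]]
  ss_within <- tab["Residuals", "Sum Sq"]
  ss_between <- tab["sample", "Sum Sq"]
  degenerate <- ss_within <= .Machine$double.eps * max(1, ss_between)
  if (degenerate && ss_between > 0) {
    Fv <- Inf; p <- 0
  } else if (degenerate) {
    Fv <- 0; p <- 1
  } else {
    Fv <- tab["sample", "F value"]
    p <- tab["sample", "Pr(>F)"]
  }
  list(F = Fv, p = p,
       df_between = tab["sample", "Df"],
       df_within = tab["Residuals", "Df"],
       ms_within = ss_within / tab["Residuals", "Df"],
       degenerate = degenerate,
       fit = fit)
}

#' Pairwise post hoc comparisons of samples on one attribute
#'
#' Either Tukey's honestly-significant-difference test (via
#' [stats::TukeyHSD()]) or Duncan's multiple range test. Duncan
#' compares ordered means with a studentized-range critical value
#' whose protection level depends on the span p of the comparison
#' (alpha_p = 1 - (1 - alpha)^(p - 1)); a pair is declared
#' non-significant whenever it lies inside a wider non-significant
#' range (the containment rule of multiple range tests). Unequal group
#' sizes use the harmonic mean.
#'
#' @param panel A [sensory_panel()].
#' @param attribute Attribute name.
#' @param method `"tukey"` (default) or `"duncan"`.
#' @param alpha Significance level (default 0.05).
#' @return List with `signif` (logical sample-by-sample matrix, TRUE =
#'   significantly different), `means` (named, descending), `method`,
#'   `alpha`, and `p` (Tukey-adjusted p-value matrix; `NA` for Duncan,
#'   which is decision- rather than p-value-based).
#' @export
posthoc_pairs <- function(panel, attribute, method = c("tukey", "duncan"),
                          alpha = 0.05) {
  method <- match.arg(method)
  an <- anova_attribute(panel, attribute)
  d <- panel[panel$attribute == attribute, , drop = FALSE]
  means <- sort(tapply(d$score, as.character(d$sample), mean),
                decreasing = TRUE)
  ns <- tapply(d$score, as.character(d$sample), length)[names(means)]
  g <- names(means)
  k <- length(g)
  sig <- matrix(FALSE, k, k, dimnames = list(g, g))
  pmat <- matrix(NA_real_, k, k, dimnames = list(g, g))

  if (an$degenerate) {
    # no within-group variance: any mean difference is significant
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      sig[i, j] <- sig[j, i] <- means[i] != means[j]
      pmat[i, j] <- pmat[j, i] <- if (means[i] != means[j]) 0 else 1
    }
  } else if (method == "tukey") {
    tk <- stats::TukeyHSD(an$fit, conf.level = 1 - alpha)$sample
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (r in seq_along(pairs)) {
      a <- pairs[[r]][1]; b <- pairs[[r]][2]
      pmat[a, b] <- pmat[b, a] <- tk[r, "p adj"]
      sig[a, b] <- sig[b, a] <- tk[r, "p adj"] < alpha
    }
  } else {
    sig <- duncan_signif(means, ns, an$ms_within, an$df_within, alpha)
  }
  list(signif = sig, means = means, method = method, alpha = alpha, p = pmat)
}

# Duncan's multiple range test on means sorted in descending order.
# Ranges are examined from widest to narrowest; once a range tests
# non-significant it is declared homogeneous and every pair inside it
# is protected from being declared significant (containment rule).
duncan_signif <- function(means, ns, mse, df, alpha) {
  k <- length(means)
  g <- names(means)
  sig <- matrix(FALSE, k, k, dimnames = list(g, g))
  homog <- matrix(FALSE, k, k)
  for (span in seq(k, 2)) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      if (homog[i, j]) next
      alpha_p <- 1 - (1 - alpha)^(span - 1)
      qcrit <- stats::qtukey(1 - alpha_p, span, df)
      nh <- 2 / (1 / ns[i] + 1 / ns[j])
      lsr <- qcrit * sqrt(mse / nh)
      if ((means[i] - means[j]) > lsr) {
        sig[i, j] <- sig[j, i] <- TRUE
      } else {
        for (a in i:(j - 1)) for (b in (a + 1):j) homog[a, b] <- TRUE
      }
    }
  }
  sig
}

#' Compact letter display from a significance matrix
#'
#' Implements the insert-and-absorb algorithm: starting from a single
#' letter covering all groups, every significantly different pair
#' splits the letters containing both, and redundant (subset) letters
#' are absorbed. Two groups share a letter if and only if they are not
#' significantly different. Letters are ordered so that `"a"` attaches
#' to the highest mean.
#'
#' @param signif Logical symmetric matrix (TRUE = the pair differs
#'   significantly), dimnames = group names.
#' @param means Named numeric vector of group means (used only for
#'   letter ordering).
#' @return Named character vector of letter strings.
#' @export
cld_letters <- function(signif, means) {
  g <- names(sort(means, decreasing = TRUE))
  cols <- list(stats::setNames(rep(TRUE, length(g)), g))
  for (i in seq_along(g)[-length(g)]) {
    for (j in (i + 1):length(g)) {
      if (!signif[g[i], g[j]]) next
      for (ci in rev(seq_along(cols))) {
        col <- cols[[ci]]
        if (col[g[i]] && col[g[j]]) {
          c1 <- col; c1[g[i]] <- FALSE
          c2 <- col; c2[g[j]] <- FALSE
          cols[[ci]] <- NULL
          cols <- c(cols, list(c1), list(c2))
        }
      }
      # absorb columns that are subsets of another column
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) for (b in seq_along(cols)) {
        if (a != b && keep[b] && all(cols[[a]] >= cols[[b]]) &&
            any(cols[[a]] > cols[[b]])) {
          keep[b] <- FALSE
        }
      }
      # drop exact duplicates too
      sig_str <- vapply(cols, function(cc) paste(cc, collapse = ""), "")
      keep <- keep & !duplicated(sig_str)
      cols <- cols[keep]
    }
  }
  first_rank <- vapply(cols, function(col) min(match(g[col[g]], g)), 1)
  cols <- cols[order(first_rank)]
  letters_used <- letters[seq_along(cols)]
  out <- vapply(g, function(grp) {
    paste(letters_used[vapply(cols, function(col) col[[grp]], TRUE)],
          collapse = "")
  }, "")
  out[names(means)]
}

#' Post hoc grouping letters for one attribute
#'
#' Runs [posthoc_pairs()] and condenses all pairwise comparisons into
#' a compact letter display via [cld_letters()].
#'
#' @inheritParams posthoc_pairs
#' @return Named character vector: one letter string per sample;
#'   samples sharing a letter do not differ significantly.
#' @export
posthoc_letters <- function(panel, attribute, method = c("tukey", "duncan"),
                            alpha = 0.05) {
  pp <- posthoc_pairs(panel, attribute, method = method, alpha = alpha)
  cld_letters(pp$signif, pp$means)
}

#' Full per-attribute sensory summary
#'
#' Aggregates scores, runs the one-way ANOVA, and attaches post hoc
#' grouping letters for every attribute of the lexicon.
#'
#' @inheritParams posthoc_pairs
#' @return Data frame with columns `attribute`, `sample`, `mean`,
#'   `sd`, `n`, `F`, `p`, `letters`.
#' @export
sensory_summary <- function(panel, method = c("tukey", "duncan"),
                            alpha = 0.05) {
  method <- match.arg(method)
  agg <- aggregate_scores(panel)
  out <- lapply(attr(panel, "lexicon"), function(a) {
    an <- anova_attribute(panel, a)
    lt <- posthoc_letters(panel, a, method = method, alpha = alpha)
    block <- agg[agg$attribute == a, ]
    block$F <- an$F
    block$p <- an$p
    block$letters <- lt[as.character(block$sample)]
    block
  })
  res <- do.call(rbind, out)
  res <- res[, c("attribute", "sample", "mean", "sd", "n", "F", "p",
                 "letters")]
  rownames(res) <- NULL
  res
}
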