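#' Chemical classes recognised by the package
#'
#' Class labels used for volatile organic compounds (VOCs). Terpenoid
#' hydrocarbons and their oxygenated forms are distinguished because
#' cultivar-specificity statistics (unique-terpenoid counts) and
#' composition sums are computed per class.
#'
#' @format Character vector of the ten recognised class labels.
#' @export
aroma_classes <- c(
  "monoterpene_hydrocarbon", "sesquiterpene_hydrocarbon",
  "oxygenated_monoterpene", "oxygenated_sesquiterpene",
  "aliphatic_ester", "aliphatic_alkene", "aliphatic_alcohol",
  "aliphatic_aldehyde", "lactone", "other"
)

#' @rdname aroma_classes
#' @export
terpenoid_classes <- c(
  "monoterpene_hydrocarbon", "sesquiterpene_hydrocarbon",
  "oxygenated_monoterpene", "oxygenated_sesquiterpene"
)

# Canonical compound identifier: UTF-8, trimmed. Matching between the
# composition table and the threshold table is exact and case-sensitive;
# fuzzy matching is deliberately not offered because a silent mismatch
# corrupts every downstream odor-activity value.
canonical_id <- function(x) trimws(enc2utf8(as.character(x)))

#' Classify a compound from its molecular formula
#'
#' Assigns one of [aroma_classes] from an empirical formula of the form
#' `CxHyOz`. C10 and C15 hydrocarbons map to mono-/sesquiterpene
#' hydrocarbons (C10H14 aromatics such as p-cymene are grouped with the
#' monoterpenes), their mono-oxygenated forms to the oxygenated classes,
#' and small aliphatics are resolved by degree of saturation:
#' CnH2nO2 esters, CnH2n-2O2 lactones, CnH2n+2O alcohols, CnH2nO
#' aldehydes, and oxygen-free short chains as alkenes/polyenes.
#' Anything else is `"other"`.
#'
#' @param formula Character vector of molecular formulas (e.g. `"C15H24"`).
#' @return Character vector of class labels.
#' @examples
#' classify_formula(c("C10H16", "C15H24", "C12H22O2"))
#' @export
classify_formula <- function(formula) {
  vapply(formula, function(f) {
    f <- gsub("[ _]", "", as.character(f))
    nC <- formula_count(f, "C")
    nH <- formula_count(f, "H")
    nO <- formula_count(f, "O")
    if (is.na(nC) || is.na(nH)) return("other")
    if (nO == 2L) {
      if (nH == 2L * nC) return("aliphatic_ester")
      if (nH == 2L * nC - 2L) return("lactone")
      return("other")
    }
    if (nO == 1L) {
      if (nC == 10L) return("oxygenated_monoterpene")
      if (nC == 15L) return("oxygenated_sesquiterpene")
      if (nH == 2L * nC + 2L) return("aliphatic_alcohol")
      if (nH == 2L * nC) return("aliphatic_aldehyde")
      return("other")
    }
    if (nO == 0L) {
      if (nC == 10L && nH %in% c(14L, 16L)) return("monoterpene_hydrocarbon")
      if (nC == 15L && nH == 24L) return("sesquiterpene_hydrocarbon")
      if (nC < 10L) return("aliphatic_alkene")
    }
    "other"
  }, character(1), USE.NAMES = FALSE)
}

formula_count <- function(f, elem) {
  m <- regmatches(f, regexec(paste0(elem, "([0-9]*)"), f))[[1]]
  if (length(m) == 0L) return(if (elem == "O") 0L else NA_integer_)
  if (m[2] == "") 1L else as.integer(m[2])
}

#' Construct a VOC relative-abundance table
#'
#' The central chemical container: a compound-by-sample matrix of
#' relative abundances (percent of total chromatographic peak area),
#' stored as replicate means with standard deviations, plus compound
#' metadata. A cell with abundance 0 is "not detected" (ND): relative
#' quantitation cannot distinguish a structural absence from a signal
#' below the detection criteria, and both carry zero odor activity.
#'
#' @param mean Numeric compound-by-sample matrix of mean relative
#'   abundances in percent, with compound rownames and sample colnames.
#' @param sd Optional matrix of the same shape holding replicate
#'   standard deviations (`NA` where only a point value is known).
#' @param n Number of replicates behind each mean (default 3).
#' @param compounds Optional data frame with columns `compound`,
#'   `formula`, `class`, `rt`; missing classes are inferred from the
#'   formula via [classify_formula()], or set to `"other"`.
#' @param sum_tol Allowed excess of a per-sample abundance sum over
#'   100 percent (rounding of printed means can push a normalized
#'   column slightly past 100).
#' @return An object of class `voc_table`: a list with elements
#'   `compounds`, `samples`, `mean`, `sd`, `n`, `detected`.
#' @export
voc_table <- function(mean, sd = NULL, n = 3L, compounds = NULL,
                      sum_tol = 1.0) {
  mean <- as.matrix(mean)
  if (is.null(rownames(mean))) stop("`mean` must have compound rownames")
  if (is.null(colnames(mean))) stop("`mean` must have sample colnames")
  rownames(mean) <- canonical_id(rownames(mean))
  if (anyDuplicated(rownames(mean))) {
    dup <- rownames(mean)[duplicated(rownames(mean))][1]
    stop("duplicate compound row: ", dup)
  }
  if (any(!is.finite(mean)) || any(mean < 0)) {
    stop("abundances must be finite and non-negative")
  }
  if (is.null(sd)) {
    sd <- matrix(NA_real_, nrow(mean), ncol(mean), dimnames = dimnames(mean))
  } else {
    sd <- as.matrix(sd)
    dimnames(sd) <- dimnames(mean)
  }
  if (is.null(compounds)) {
    compounds <- data.frame(compound = rownames(mean),
                            formula = NA_character_,
                            class = "other",
                            rt = NA_real_,
                            stringsAsFactors = FALSE)
  } else {
    compounds <- as.data.frame(compounds)
    compounds$compound <- canonical_id(compounds$compound)
    if (is.null(compounds$formula)) compounds$formula <- NA_character_
    if (is.null(compounds$rt)) compounds$rt <- NA_real_
    if (is.null(compounds$class)) {
      compounds$class <- ifelse(is.na(compounds$formula), "other",
                                classify_formula(compounds$formula))
    }
    bad <- !(compounds$class %in% aroma_classes)
    if (any(bad)) {
      warning("unknown chemical class label(s): ",
              paste(unique(compounds$class[bad]), collapse = ", "),
              "; using \"other\"")
      compounds$class[bad] <- "other"
    }
    compounds <- compounds[match(rownames(mean), compounds$compound),
                           c("compound", "formula", "class", "rt")]
    if (anyNA(compounds$compound)) stop("compound metadata incomplete")
  }
  rownames(compounds) <- NULL
  detected <- mean > 0
  sums <- colSums(mean)
  if (any(sums > 100 + sum_tol)) {
    stop("per-sample abundance sum exceeds 100%: ",
         paste(colnames(mean)[sums > 100 + sum_tol], collapse = ", "))
  }
  structure(list(compounds = compounds,
                 samples = colnames(mean),
                 mean = mean, sd = sd, n = n,
                 detected = detected),
            class = "voc_table")
}

#' @export
print.voc_table <- function(x, ...) {
  cat(sprintf("VOC table: %d compounds x %d samples (%s)\n",
              nrow(x$mean), length(x$samples),
              paste(x$samples, collapse = ", ")))
  cat(sprintf("  detected cells: %d / %d; per-sample identified totals: %s\n",
              sum(x$detected), length(x$detected),
              paste(sprintf("%.2f%%", colSums(x$mean)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.voc_table <- function(x) dim(x$mean)
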