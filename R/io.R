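#' Read a VOC composition table
#'
#' Parses a delimited text file (comma or tab, auto-detected from the
#' header) with one row per compound. Metadata columns `compound`,
#' `formula`, `class`, `rt` are recognised when present; every other
#' column is a sample. Abundance cells may be a bare number, a
#' `"mean ± sd"` pair, or the not-detected token.
#'
#' @param path Path to the file (UTF-8).
#' @param nd_token Token marking a not-detected cell (default `"ND"`).
#' @param n_replicates Replicate count behind a `mean ± sd` cell.
#' @param zero_as_nd Treat a literal 0 abundance as not detected
#'   (default `TRUE`): an undetected compound must carry zero odor
#'   activity, and relative-area quantitation reports no true zeros.
#' @param sep Field separator; `NULL` (default) sniffs `,` vs tab from
#'   the header line.
#' @return A [voc_table()].
#' @export
read_voc_table <- function(path, nd_token = "ND", n_replicates = 3L,
                           zero_as_nd = TRUE, sep = NULL) {
  df <- read_delim_utf8(path, sep)
  names(df)[1] <- sub("^\ufeff", "", names(df)[1])
  meta_cols <- intersect(c("compound", "formula", "class", "rt"), names(df))
  if (!"compound" %in% meta_cols) stop("no `compound` column in ", path)
  sample_cols <- setdiff(names(df), meta_cols)
  if (length(sample_cols) == 0L) stop("no sample columns in ", path)

  ids <- canonical_id(df$compound)
  if (anyDuplicated(ids)) {
    stop("duplicate compound row: ", ids[duplicated(ids)][1])
  }
  m <- s <- matrix(NA_real_, length(ids), length(sample_cols),
                   dimnames = list(ids, sample_cols))
  for (j in sample_cols) {
    cells <- vapply(as.character(df[[j]]), parse_abundance_cell,
                    numeric(2), nd_token = nd_token, USE.NAMES = FALSE)
    m[, j] <- cells[1, ]
    s[, j] <- cells[2, ]
  }
  if (any(m < 0, na.rm = TRUE)) {
    bad <- ids[which(rowSums(m < 0, na.rm = TRUE) > 0)][1]
    stop("negative abundance for compound: ", bad)
  }
  if (zero_as_nd) s[m == 0] <- NA_real_ else if (any(m == 0)) {
    stop("abundance 0 with zero_as_nd = FALSE is ambiguous; ",
         "use the ND token for undetected cells")
  }
  compounds <- data.frame(
    compound = ids,
    formula = if ("formula" %in% meta_cols) as.character(df$formula) else NA_character_,
    rt = if ("rt" %in% meta_cols) as.numeric(df$rt) else NA_real_,
    stringsAsFactors = FALSE
  )
  if ("class" %in% meta_cols) compounds$class <- as.character(df$class)
  voc_table(m, sd = s, n = n_replicates, compounds = compounds)
}

# Returns c(mean, sd); sd NA for bare numbers, 0/0 for ND.
parse_abundance_cell <- function(cell, nd_token = "ND") {
  cell <- trimws(cell)
  if (identical(cell, nd_token) || is.na(cell) || cell == "") {
    return(c(0, NA_real_))
  }
  parts <- strsplit(cell, "\u00b1", fixed = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(trimws(parts)))
  if (length(vals) == 1L && !is.na(vals)) return(c(vals, NA_real_))
  if (length(vals) == 2L && !anyNA(vals)) return(vals)
  stop("unparseable abundance cell: \"", cell, "\"")
}

#' Write a VOC composition table
#'
#' Inverse of [read_voc_table()]: fixed column order
#' (`compound,formula,class,rt`, then samples), undetected cells as the
#' ND token, detected cells as `"mean ± sd"` (or a bare number when
#' no SD is stored), numbers at 6 significant digits.
#'
#' @param x A [voc_table()].
#' @param path Output path.
#' @param nd_token Token for not-detected cells.
#' @return `path`, invisibly.
#' @export
write_voc_table <- function(x, path, nd_token = "ND") {
  stopifnot(inherits(x, "voc_table"))
  out <- x$compounds
  for (j in x$samples) {
    cell <- character(nrow(x$mean))
    for (i in seq_len(nrow(x$mean))) {
      if (!x$detected[i, j]) {
        cell[i] <- nd_token
      } else if (is.na(x$sd[i, j])) {
        cell[i] <- fmt6(x$mean[i, j])
      } else {
        cell[i] <- paste(fmt6(x$mean[i, j]), "\u00b1", fmt6(x$sd[i, j]))
      }
    }
    out[[j]] <- cell
  }
  write_csv_utf8(out, path)
}

fmt6 <- function(v) formatC(signif(v, 6), format = "g", digits = 6)

#' Read an odor-threshold table
#'
#' Parses a delimited file with columns `compound`, `threshold`, and
#' optionally `medium` and `source`. A threshold cell may carry a
#' medium annotation, e.g. `"0.14 (OW)"` for a water threshold or
#' `"(OA)"` for air; without annotation or medium column the entry is
#' tagged `air`. Several rows per compound are allowed -- the database
#' is a multimap and resolution (air priority, arithmetic mean) happens
#' later, in [resolve_threshold()].
#'
#' @param path Path to the file.
#' @param sep Field separator; `NULL` sniffs from the header.
#' @return A `threshold_db`: data frame with columns
#'   `compound`, `value`, `medium`, `source`.
#' @export
read_threshold_table <- function(path, sep = NULL) {
  df <- read_delim_utf8(path, sep)
  if (!all(c("compound", "threshold") %in% names(df))) {
    stop("threshold table needs `compound` and `threshold` columns")
  }
  n <- nrow(df)
  value <- numeric(n)
  medium <- character(n)
  for (i in seq_len(n)) {
    cell <- trimws(as.character(df$threshold[i]))
    ann <- regmatches(cell, regexec("\\((O?[AW])\\)\\s*$", cell))[[1]]
    if (length(ann)) {
      medium[i] <- if (grepl("W", ann[2])) "water" else "air"
      cell <- trimws(sub("\\((O?[AW])\\)\\s*$", "", cell))
    } else if (!is.null(df$medium) && !is.na(df$medium[i]) &&
               nzchar(trimws(df$medium[i]))) {
      med <- tolower(trimws(df$medium[i]))
      if (!med %in% c("air", "water")) {
        stop(sprintf("line %d: unknown medium \"%s\"", i + 1L, df$medium[i]))
      }
      medium[i] <- med
    } else {
      medium[i] <- "air"
    }
    v <- suppressWarnings(as.numeric(cell))
    if (is.na(v)) {
      stop(sprintf("line %d: unparseable threshold cell \"%s\"",
                   i + 1L, df$threshold[i]))
    }
    if (v <= 0) {
      stop(sprintf("line %d: non-positive threshold %g for %s",
                   i + 1L, v, df$compound[i]))
    }
    value[i] <- v
  }
  threshold_db(data.frame(
    compound = canonical_id(df$compound),
    value = value,
    medium = medium,
    source = if (is.null(df$source)) NA_character_ else as.character(df$source),
    stringsAsFactors = FALSE
  ))
}

#' Construct an odor-threshold database
#'
#' @param entries Data frame with columns `compound`, `value`
#'   (threshold magnitude: mg/m3 for air, mg/kg for water, kept in
#'   source units and never converted), `medium` (`"air"`/`"water"`),
#'   and optionally `source`.
#' @return A `threshold_db` data frame (multiple rows per compound
#'   allowed).
#' @export
threshold_db <- function(entries) {
  entries <- as.data.frame(entries)
  stopifnot(all(c("compound", "value", "medium") %in% names(entries)))
  if (is.null(entries$source)) entries$source <- NA_character_
  entries$compound <- canonical_id(entries$compound)
  if (any(!is.finite(entries$value)) || any(entries$value <= 0)) {
    stop("threshold values must be finite and positive")
  }
  if (!all(entries$medium %in% c("air", "water"))) {
    stop("medium must be \"air\" or \"water\"")
  }
  rownames(entries) <- NULL
  structure(entries[, c("compound", "value", "medium", "source")],
            class = c("threshold_db", "data.frame"))
}

#' @rdname read_threshold_table
#' @param db A `threshold_db`.
#' @param path Output path.
#' @export
write_threshold_table <- function(db, path) {
  stopifnot(inherits(db, "threshold_db"))
  out <- as.data.frame(db)
  out$threshold <- fmt6(out$value)
  write_csv_utf8(out[, c("compound", "threshold", "medium", "source")], path)
}

#' Read long-format sensory panel scores
#'
#' Parses a delimited file with columns
#' `assessor,session,sample,attribute,score` -- one row per elementary
#' observation of a quantitative descriptive analysis (QDA) panel on a
#' 0-10 intensity scale.
#'
#' @param path Path to the file.
#' @param lexicon Optional character vector of admissible attribute
#'   names; a record with an attribute outside the lexicon is an error.
#' @param sep Field separator; `NULL` sniffs from the header.
#' @return A [sensory_panel()].
#' @export
read_sensory_scores <- function(path, lexicon = NULL, sep = NULL) {
  df <- read_delim_utf8(path, sep)
  need <- c("assessor", "session", "sample", "attribute", "score")
  if (!all(need %in% names(df))) {
    stop("sensory table needs columns ", paste(need, collapse = ", "))
  }
  df$score <- as.numeric(df$score)
  sensory_panel(df[, need], lexicon = lexicon)
}

#' Construct a sensory panel object
#'
#' @param records Data frame with columns
#'   `assessor,session,sample,attribute,score`.
#' @param lexicon Optional attribute lexicon (character vector); the
#'   attribute set of the records must be a subset of it. Defaults to
#'   the attributes present, in order of first appearance.
#' @return A `sensory_panel` data frame with a `lexicon` attribute.
#' @export
sensory_panel <- function(records, lexicon = NULL) {
  records <- as.data.frame(records)
  records$score <- as.numeric(records$score)
  if (any(!is.finite(records$score)) ||
      any(records$score < 0 | records$score > 10)) {
    bad <- which(!is.finite(records$score) |
                 records$score < 0 | records$score > 10)[1]
    stop("score outside [0, 10] at record ", bad, ": ", records$score[bad])
  }
  if (is.null(lexicon)) {
    lexicon <- unique(as.character(records$attribute))
  } else if (!all(records$attribute %in% lexicon)) {
    stop("attribute(s) outside the lexicon: ",
         paste(setdiff(unique(records$attribute), lexicon), collapse = ", "))
  }
  key <- paste(records$assessor, records$session, records$sample,
               records$attribute, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate observation: ",
         gsub("\r", " / ", key[duplicated(key)][1]))
  }
  rownames(records) <- NULL
  structure(records, lexicon = lexicon,
            class = c("sensory_panel", "data.frame"))
}

#' @rdname read_sensory_scores
#' @param panel A `sensory_panel`.
#' @export
write_sensory_scores <- function(panel, path) {
  stopifnot(inherits(panel, "sensory_panel"))
  out <- as.data.frame(panel)
  out$score <- fmt6(out$score)
  write_csv_utf8(out, path)
}

read_delim_utf8 <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L, encoding = "UTF-8")
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8", comment.char = "")
}

write_csv_utf8 <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = ",", quote = TRUE, row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}
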