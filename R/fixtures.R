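#' Packaged Kadsura coccinea study tables
#'
#' Accessors for the bundled CSV transcriptions of the published
#' *Kadsura coccinea* cultivar study tables that motivate this
#' package: the 49-compound GC-MS relative-abundance table for
#' cultivars F023, F054 and F055 (`kadsura_voc()`), the 24-compound
#' odor-threshold column with air/water medium tags
#' (`kadsura_thresholds()`), and the seven-attribute sensory lexicon
#' (`kadsura_lexicon()`).
#'
#' @return `kadsura_voc()` a [voc_table()]; `kadsura_thresholds()` a
#'   `threshold_db`; `kadsura_lexicon()` a data frame with columns
#'   `attribute`, `reference`, `definition`.
#' @examples
#' voc <- kadsura_voc()
#' detection_sets(voc)
#' @export
kadsura_voc <- function() {
  read_voc_table(system.file("extdata", "kadsura_voc.csv",
                             package = "aromarank", mustWork = TRUE))
}

#' @rdname kadsura_voc
#' @export
kadsura_thresholds <- function() {
  read_threshold_table(system.file("extdata", "kadsura_thresholds.csv",
                                   package = "aromarank", mustWork = TRUE))
}

#' @rdname kadsura_voc
#' @export
kadsura_lexicon <- function() {
  read_delim_utf8(system.file("extdata", "kadsura_lexicon.csv",
                              package = "aromarank", mustWork = TRUE))
}
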