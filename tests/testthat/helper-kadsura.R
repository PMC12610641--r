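# Compound names of the packaged cultivar study, written with unicode
# escapes so the test sources stay ASCII-clean.
gk <- function(x) {
  x <- gsub("alpha-", "\u03b1-", x, fixed = TRUE)
  x <- gsub("beta-", "\u03b2-", x, fixed = TRUE)
  x <- gsub("gamma-", "\u03b3-", x, fixed = TRUE)
  gsub("delta-", "\u03b4-", x, fixed = TRUE)
}

# Published per-cultivar ROAV values for the 24 thresholded compounds
# (the values the prioritization stage must reproduce from the
# composition means and thresholds).
published_roav <- function() {
  rows <- list(
    c("1-Hexanol", 0, 0.316, 0),
    c("alpha-Pinene", 0.904, 1.711, 0.433),
    c("Sabinene", 0.432, 0.095, 0),
    c("beta-Pinene", 90.307, 36.577, 100),
    c("beta-Myrcene", 97.586, 100, 88.5),
    c("Butyl butanoate", 0, 18.811, 0),
    c("alpha-Terpinene", 0.02, 0, 0.026),
    c("P-Cymene", 0.015, 0, 0.011),
    c("D-Limonene", 31.066, 30.239, 0),
    c("beta-Phellandrene", 0, 0, 4.178),
    c("beta-Ocimene", 14.32, 20.225, 14.765),
    c("gamma-Terpinene", 0.007, 0.002, 0.01),
    c("Terpinolene", 1.335, 0.805, 2.238),
    c("Linalool", 0, 23.636, 0),
    c("Nonanal", 0, 0.827, 0),
    c("Terpinen-4-ol", 0.665, 0.347, 0.414),
    c("Butyl caproate", 0, 0.627, 0),
    c("alpha-Terpineol", 0.843, 0.428, 0),
    c("beta-Caryophyllene", 35.618, 27.838, 11.578),
    c("Humulene", 100, 51.854, 31.034),
    c("Elemol", 4.084, 0, 10.038),
    c("E-Nerolidol", 1.721, 1.147, 0),
    c("Caryophyllene oxide", 0.596, 0.213, 0.091),
    c("gamma-Dodecalactone", 0, 73.002, 0))
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[2:4])))
  dimnames(m) <- list(gk(vapply(rows, `[`, "", 1)),
                      c("F023", "F054", "F055"))
  m
}

# The six quantitatively dominant F055 volatiles.
f055_dominants <- function() {
  gk(c("beta-Selinene", "gamma-Maaliene", "beta-Pinene",
       "gamma-Muurolene", "beta-Elemene", "beta-Caryophyllene"))
}
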