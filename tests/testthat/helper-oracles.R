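# Independent oracles and small fixture builders shared across tests.

# Cohen's kappa computed from expanded per-item rating lists: each table
# cell becomes that many paired present/absent ratings, observed agreement
# is the fraction of identical pairs, and chance agreement comes from the
# two raters' marginal frequencies. Deliberately naive.
kappa_per_item <- function(tp, fn, fp, tn) {
  manifest <- c(rep(TRUE, tp + fn), rep(FALSE, fp + tn))
  tool <- c(rep(TRUE, tp), rep(FALSE, fn), rep(TRUE, fp), rep(FALSE, tn))
  po <- mean(manifest == tool)
  p1 <- mean(manifest); p2 <- mean(tool)
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

# Quadratic-scan membership oracle: normalized (chrom, pos) comparison of
# every query against every manifest row.
brute_membership <- function(queries, manifest) {
  vapply(seq_len(nrow(queries)), function(i) {
    any(normalize_chrom(manifest$chrom) == normalize_chrom(queries$chrom[i]) &
          manifest$pos == queries$pos[i])
  }, logical(1))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# The published-style audit tables the fixture is shaped to reproduce:
# per-trait marginals and printed kappas for the two reference panels.
printed_tables <- function() {
  list(
    HapMap3 = tibble::tribble(
      ~group, ~n, ~concordances, ~concordance_pct, ~discordances,
      ~discordance_pct, ~kappa,
      "Blood pressure",  37,  28, 75.7,   9, 24.3, 0.469,
      "Fasting glucose", 39,  20, 51.3,  19, 48.7, 0.000,
      "BMI",             69,  35, 50.7,  34, 49.3, 0.166,
      "Lipids",         276, 185, 67.0,  91, 33.0, 0.295,
      "TOTAL",          415, 263, 63.4, 152, 36.6, 0.250),
    `1000Genomes` = tibble::tribble(
      ~group, ~n, ~concordances, ~concordance_pct, ~discordances,
      ~discordance_pct, ~kappa,
      "Blood pressure",  37,  35, 94.6,   2,  5.4, 0.841,
      "Fasting glucose", 39,  39, 100.0,  0,  0.0, 1.000,
      "BMI",             69,  42, 60.9,  27, 39.1, 0.242,
      "Lipids",         276, 231, 83.7,  45, 16.3, 0.525,
      "TOTAL",          415, 342, 82.4,  73, 17.6, 0.487))
}
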