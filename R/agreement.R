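#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement between the two membership methods,
#' `kappa = (Pr(a) - Pr(e)) / (1 - Pr(e))`, where `Pr(a) = (tp + tn) / n`
#' is the observed proportion of agreement and
#' `Pr(e) = ((tp + fn)(tp + fp) + (tn + fp)(tn + fn)) / n^2` the proportion
#' expected under independent marginals. When the table is concentrated in
#' one diagonal cell both proportions equal 1 and the ratio is 0/0; by
#' convention kappa is then exactly 1 (the raters agree on every item).
#'
#' @param table a [contingency_table()].
#' @return kappa, a real in `[-1, 1]` (unrounded).
#' @export
#' @examples
#' cohen_kappa(contingency_table(214, 152, 0, 49))  # ~0.2495
#' cohen_kappa(contingency_table(39, 0, 0, 0))      # 1 by convention
cohen_kappa <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  n <- ct_n(table)
  if (n == 0L) config_error("cohen_kappa is undefined for an empty table")
  tp <- table$tp; fn <- table$fn; fp <- table$fp; tn <- table$tn
  pr_a <- (tp + tn) / n
  pr_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  if (pr_e == 1) return(1)
  (pr_a - pr_e) / (1 - pr_e)
}

#' False-negative rate of the audited tool
#'
#' Two denominators are in circulation for this audit. The textbook
#' definition (`mode = "formula"`) divides the false negatives by the SNPs
#' truly on the chip, `100 * fn / (tp + fn)`. Published per-trait and
#' overall values are instead routinely quoted against all SNPs tested in
#' the group (`mode = "reported"`), `100 * fn / n` -- e.g. 152 false
#' negatives out of 415 SNPs quoted as 36.6%. Both are provided;
#' `"reported"` is the default so that printed tables reproduce.
#'
#' @param table a [contingency_table()].
#' @param mode `"reported"` (denominator `n`) or `"formula"`
#'   (denominator `tp + fn`).
#' @return a percentage (unrounded).
#' @export
false_negative_rate <- function(table, mode = c("reported", "formula")) {
  stopifnot(inherits(table, "contingency_table"))
  mode <- match.arg(mode)
  den <- if (mode == "reported") ct_n(table) else table$tp + table$fn
  if (den == 0L) {
    config_error(sprintf(
      "false_negative_rate(mode = \"%s\") is undefined: zero denominator",
      mode))
  }
  100 * table$fn / den
}

#' False-positive rate of the audited tool
#'
#' `100 * fp / (fp + tn)`: of the SNPs truly absent from the chip, the
#' percentage the tool nevertheless claimed present.
#'
#' @param table a [contingency_table()].
#' @return a percentage (unrounded).
#' @export
false_positive_rate <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  den <- table$fp + table$tn
  if (den == 0L) {
    config_error("false_positive_rate is undefined: fp + tn = 0")
  }
  100 * table$fp / den
}

#' Landis-Koch verbal band for a kappa value
#'
#' Conventional interpretation bands: below 0 no agreement, 0-0.20 slight,
#' 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial, and over
#' 0.81 perfect. Band edges are resolved on the 2-decimal grid the labels
#' are printed on: any kappa above 0.80 is at least substantial and any
#' kappa of 0.81 or more is perfect. kappa = 0 falls in the slight band
#' per the tabulated thresholds (some prose calls exactly zero "no
#' agreement"; that reading is noted, not adopted).
#'
#' @param kappa a real in `[-1, 1]`.
#' @return one of `"no agreement"`, `"slight"`, `"fair"`, `"moderate"`,
#'   `"substantial"`, `"perfect"`.
#' @export
#' @examples
#' landis_band(0.469)  # "moderate"
#' landis_band(0.841)  # "perfect"
landis_band <- function(kappa) {
  stopifnot(is.numeric(kappa), kappa >= -1 - 1e-12, kappa <= 1 + 1e-12)
  vapply(kappa, function(k) {
    if (k < 0) "no agreement"
    else if (k <= 0.20) "slight"
    else if (k <= 0.40) "fair"
    else if (k <= 0.60) "moderate"
    else if (k < 0.81) "substantial"
    else "perfect"
  }, character(1))
}

#' Full agreement summary for a 2x2 table
#'
#' Bundles the table with its derived statistics, rounded for reporting:
#' concordance/discordance percentages to 1 decimal, kappa to 3 decimals
#' (both half-away-from-zero), the Landis-Koch band of the rounded kappa,
#' both false-negative rates, and the false-positive rate (`NA` when no
#' SNP is truly off-chip, since its denominator is then zero).
#'
#' @param table a [contingency_table()].
#' @return an object of class `agreement_summary`.
#' @export
agreement_summary <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  n <- ct_n(table)
  if (n == 0L) config_error("agreement_summary is undefined for an empty table")
  conc <- table$tp + table$tn
  kappa <- round_half_away(cohen_kappa(table), 3)
  on_chip <- table$tp + table$fn
  off_chip <- table$fp + table$tn
  structure(list(
    table = table, n = n,
    concordances = conc, discordances = n - conc,
    concordance_pct = round_half_away(100 * conc / n, 1),
    discordance_pct = round_half_away(100 * (n - conc) / n, 1),
    kappa = kappa, band = landis_band(kappa),
    fnr_reported = round_half_away(100 * table$fn / n, 1),
    fnr_formula = if (on_chip > 0L)
      round_half_away(100 * table$fn / on_chip, 1) else NA_real_,
    fpr = if (off_chip > 0L)
      round_half_away(100 * table$fp / off_chip, 1) else NA_real_),
    class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(
    "<agreement_summary> n=%d | concordant %d (%.1f%%), discordant %d (%.1f%%)\n",
    x$n, x$concordances, x$concordance_pct, x$discordances,
    x$discordance_pct))
  cat(sprintf("  kappa = %.3f (%s); FNR = %.1f%% (reported), %s (formula); FPR = %s\n",
              x$kappa, x$band, x$fnr_reported,
              if (is.na(x$fnr_formula)) "NA" else
                sprintf("%.1f%%", x$fnr_formula),
              if (is.na(x$fpr)) "NA" else sprintf("%.1f%%", x$fpr)))
  invisible(x)
}

#' Reconstruct 2x2 cells from published marginals and a printed kappa
#'
#' Published agreement tables often print only the group size, the
#' concordance/discordance counts and a rounded kappa -- not the individual
#' `tp`/`tn` cells. Given the discordant cells (`fn`, `fp`) and the total
#' concordances, this enumerates every integer split `tp + tn =
#' concordances` and keeps those whose kappa rounds (half away from zero)
#' to the printed value; an empty result means the printed values are
#' mutually inconsistent.
#'
#' Because the chance-agreement term is symmetric in the diagonal cells,
#' kappa is invariant under swapping `tp` with `tn` (at fixed `fn`, `fp`),
#' so admissible splits come in mirror pairs `(tp, tn)` / `(tn, tp)`: a
#' single row pins the cells only up to that reflection. The ambiguity
#' resolves across rows -- in a two-reference audit a trait's off-chip
#' count `tn` is reference-independent and its on-chip count `tp + fn` is
#' constant, which selects one member of each pair (see the package tests
#' for the full cross-table argument).
#'
#' @param n group size.
#' @param concordances number of concordant SNPs (`tp + tn`).
#' @param fn,fp discordant cell counts.
#' @param kappa_printed the published kappa.
#' @param decimals precision at which the published kappa was rounded
#'   (default 3).
#' @return a tibble with columns `tp`, `tn`, `kappa` (unrounded), one row
#'   per admissible split.
#' @export
#' @examples
#' reconstruct_split(37, 28, fn = 9, fp = 0, kappa_printed = 0.469)
reconstruct_split <- function(n, concordances, fn, fp, kappa_printed,
                              decimals = 3) {
  stopifnot(n >= 0, concordances >= 0, fn >= 0, fp >= 0)
  if (concordances + fn + fp != n) {
    config_error(sprintf(
      "marginals are inconsistent: concordances (%d) + fn (%d) + fp (%d) != n (%d)",
      concordances, fn, fp, n))
  }
  tp <- 0:concordances
  kappa <- vapply(tp, function(t) {
    cohen_kappa(contingency_table(t, fn, fp, concordances - t))
  }, numeric(1))
  keep <- round_half_away(kappa, decimals) == kappa_printed
  if (!any(keep)) {
    validation_error(sprintf(
      "no tp/tn split of %d concordances reproduces kappa = %.*f: printed values irreconcilable",
      concordances, decimals, kappa_printed))
  }
  tp_keep <- tp[keep]
  tibble::tibble(tp = tp_keep, tn = concordances - tp_keep,
                 kappa = kappa[keep])
}
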