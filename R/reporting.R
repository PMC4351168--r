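#' Per-trait agreement summary table
#'
#' Builds the familiar audit layout -- one row per trait plus a `TOTAL`
#' row -- from concordance records for a single reference panel. Trait rows
#' count every SNP associated with the trait, so a pleiotropic SNP appears
#' in each of its traits' rows; the `TOTAL` row is computed on
#' deduplicated records, counting each rsID once.
#'
#' @param records a `concordance_records` tibble (one reference).
#' @param trait_order traits to report, in row order; defaults to order of
#'   first appearance in the records. An unknown label is a validation
#'   error.
#' @return a tibble of class `trait_summary` with columns `group`, `n`,
#'   `concordances`, `concordance_pct`, `discordances`, `discordance_pct`,
#'   `kappa` (3 decimals), `band`, `fnr_reported`, `fpr`.
#' @export
trait_summary <- function(records, trait_order = NULL) {
  rec <- tibble::as_tibble(records)
  if (nrow(rec) == 0L) validation_error("trait_summary needs at least one record")
  seen <- unique(unlist(rec$traits))
  trait_order <- trait_order %||% seen
  unknown <- setdiff(trait_order, seen)
  if (length(unknown) > 0L) {
    validation_error(sprintf("unknown trait label(s) in trait_order: %s",
                             paste(unknown, collapse = ", ")))
  }
  rows <- lapply(c(trait_order, "ALL"), function(g) {
    s <- agreement_summary(tabulate_records(records, group = g))
    tibble::tibble(group = if (g == "ALL") "TOTAL" else g,
                   n = s$n, concordances = s$concordances,
                   concordance_pct = s$concordance_pct,
                   discordances = s$discordances,
                   discordance_pct = s$discordance_pct,
                   kappa = s$kappa, band = s$band,
                   fnr_reported = s$fnr_reported, fpr = s$fpr)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("trait_summary", class(out)))
}

fmt_count_pct <- function(count, pct) sprintf("%d (%.1f%%)", count, pct)

#' Render a trait summary as text
#'
#' `format = "tsv"` writes a machine-readable table (counts and
#' percentages in separate columns, kappa to 3 decimals); `format = "txt"`
#' renders an aligned table with `count (pct%)` cells, mirroring the
#' typography of published audit tables.
#'
#' @param summary a [trait_summary()] result.
#' @param format `"tsv"` or `"txt"`.
#' @return a character vector of lines.
#' @export
render_summary <- function(summary, format = c("tsv", "txt")) {
  format <- match.arg(format)
  if (format == "tsv") {
    header <- paste(c("group", "n", "concordances", "concordance_pct",
                      "discordances", "discordance_pct", "kappa", "band"),
                    collapse = "\t")
    body <- paste(summary$group, summary$n, summary$concordances,
                  sprintf("%.1f", summary$concordance_pct),
                  summary$discordances,
                  sprintf("%.1f", summary$discordance_pct),
                  sprintf("%.3f", summary$kappa), summary$band,
                  sep = "\t")
    return(c(header, body))
  }
  cells <- cbind(
    c("Trait", summary$group),
    c("Number of SNPs", as.character(summary$n)),
    c("Concordances",
      fmt_count_pct(summary$concordances, summary$concordance_pct)),
    c("Discordances",
      fmt_count_pct(summary$discordances, summary$discordance_pct)),
    c("Cohen's Kappa", sprintf("%.3f", summary$kappa)))
  widths <- apply(nchar(cells), 2L, max)
  padded <- vapply(seq_along(widths), function(j) {
    formatC(cells[, j], width = widths[j], flag = "-")
  }, character(nrow(cells)))
  apply(padded, 1L, function(r) {
    trimws(paste(r, collapse = "  "), which = "right")
  })
}

#' Write / read a trait summary (TSV)
#'
#' Writing then reading reproduces counts and kappa exactly, so summaries
#' can be exchanged between pipeline stages as files.
#'
#' @param summary a [trait_summary()] result.
#' @param path file path.
#' @param format passed to [render_summary()] (only `"tsv"` round-trips).
#' @return `write_summary`: `path`, invisibly. `read_summary`: a
#'   `trait_summary` tibble.
#' @export
write_summary <- function(summary, path, format = "tsv") {
  writeLines(render_summary(summary, format), path)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  out <- tibble::tibble(
    group = df$group, n = as.integer(df$n),
    concordances = as.integer(df$concordances),
    concordance_pct = as.numeric(df$concordance_pct),
    discordances = as.integer(df$discordances),
    discordance_pct = as.numeric(df$discordance_pct),
    kappa = as.numeric(df$kappa), band = df$band)
  structure(out, class = c("trait_summary", class(out)))
}

chrom_rank <- function(chrom) match(chrom, chrom_alphabet())

#' Per-SNP comparison report
#'
#' A SNP-by-SNP listing of the positional ground truth against the tool's
#' claims, with one pair of `tool_present` / `status` columns per
#' reference panel, sorted by chromosome then position. This is the
#' record-level companion to the summary tables: every summary cell is
#' recomputable from it.
#'
#' @param records `concordance_records`, possibly spanning several
#'   reference panels (rows for the same rsID are merged into one).
#' @return a tibble with columns `rsid`, `traits` (comma-joined), `chrom`,
#'   `pos`, `manifest_present`, then `tool_present_<ref>` and
#'   `status_<ref>` per reference.
#' @export
per_snp_report <- function(records) {
  rec <- tibble::as_tibble(records)
  if (nrow(rec) == 0L) {
    return(tibble::tibble(rsid = character(), traits = character(),
                          chrom = character(), pos = integer(),
                          manifest_present = logical()))
  }
  rec$traits <- vapply(rec$traits, function(t) paste(sort(t), collapse = ","),
                       character(1))
  wide <- rec |>
    dplyr::select("rsid", "traits", "chrom", "pos", "manifest_present",
                  "reference", "tool_present", "status") |>
    tidyr::pivot_wider(names_from = "reference",
                       values_from = c("tool_present", "status"))
  wide[order(chrom_rank(wide$chrom), wide$pos), , drop = FALSE]
}

#' Write a per-SNP report as TSV
#'
#' @param report a [per_snp_report()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_per_snp_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
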