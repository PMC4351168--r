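#' Classify a membership/claim pair
#'
#' The manifest is the ground truth and the audited tool supplies the
#' claim. A SNP the tool reports as absent although the product file
#' carries it is a false negative; a SNP the tool reports as present
#' although the product file lacks it is a false positive:
#'
#' | manifest | tool  | status |
#' |----------|-------|--------|
#' | present  | present | `TP` |
#' | present  | absent  | `FN` |
#' | absent   | present | `FP` |
#' | absent   | absent  | `TN` |
#'
#' @param manifest_present,tool_present logical vectors (recycled to a
#'   common length).
#' @return a character vector over `{"TP","FN","FP","TN"}`.
#' @export
#' @examples
#' classify_status(TRUE, FALSE)   # "FN"
#' classify_status(FALSE, TRUE)   # "FP"
classify_status <- function(manifest_present, tool_present) {
  stopifnot(is.logical(manifest_present), is.logical(tool_present),
            !anyNA(manifest_present), !anyNA(tool_present))
  ifelse(manifest_present,
         ifelse(tool_present, "TP", "FN"),
         ifelse(tool_present, "FP", "TN"))
}

#' Join membership calls with tool claims and classify every SNP
#'
#' Pairs each query SNP's positional ground truth with the audited tool's
#' availability claim for one reference panel, producing one concordance
#' record per rsID. Every rsID in `calls` must have exactly one claim under
#' the chosen reference: missing or duplicated claims are validation
#' errors naming the rsIDs involved.
#'
#' @param calls a `membership_calls` tibble from [check_batch()].
#' @param claims a `tool_claims` tibble from [read_tool_output()].
#' @param reference reference-panel label to audit (rows of `claims` with a
#'   non-`NA` `reference` field must match it).
#' @return a tibble of class `concordance_records` with columns `rsid`,
#'   `chrom`, `pos`, `traits`, `reference`, `manifest_present`,
#'   `tool_present`, `warning`, `status`.
#' @export
join_and_classify <- function(calls, claims, reference) {
  stopifnot(is.character(reference), length(reference) == 1L)
  cl <- tibble::as_tibble(claims)
  cl <- cl[is.na(cl$reference) | cl$reference == reference, , drop = FALSE]
  missing <- setdiff(calls$rsid, cl$rsid)
  if (length(missing) > 0L) {
    validation_error(sprintf(
      "no %s claim for %d rsID(s): %s", reference, length(missing),
      paste(utils::head(missing, 10L), collapse = ", ")))
  }
  dup <- unique(cl$rsid[duplicated(cl$rsid)])
  dup <- intersect(dup, calls$rsid)
  if (length(dup) > 0L) {
    validation_error(sprintf(
      "multiple %s claims for rsID(s): %s", reference,
      paste(utils::head(dup, 10L), collapse = ", ")))
  }
  i <- match(calls$rsid, cl$rsid)
  out <- tibble::tibble(
    rsid = calls$rsid, chrom = calls$chrom, pos = calls$pos,
    traits = calls$traits, reference = reference,
    manifest_present = calls$on_chip,
    tool_present = cl$claimed_present[i],
    warning = cl$warning[i])
  out$status <- classify_status(out$manifest_present, out$tool_present)
  structure(out, class = c("concordance_records", class(out)))
}

#' A 2x2 agreement contingency table
#'
#' Counts of true positives, false negatives, false positives and true
#' negatives from comparing the tool's claims against positional ground
#' truth. Concordances are `tp + tn`, discordances `fn + fp`.
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    validation_error("contingency cells must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn)),
            class = "contingency_table")
}

ct_n <- function(tab) tab$tp + tab$fn + tab$fp + tab$tn

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf(
    "<contingency_table> n=%d | TP=%d FN=%d FP=%d TN=%d | concordances=%d discordances=%d\n",
    ct_n(x), x$tp, x$fn, x$fp, x$tn, x$tp + x$tn, x$fn + x$fp))
  invisible(x)
}

#' Tabulate concordance records into a 2x2 table
#'
#' For `group = "ALL"` every rsID is counted exactly once -- pleiotropic
#' SNPs (associated with more than one trait) enter the pooled table only
#' once. For a trait label, records whose trait set contains the label are
#' counted, so a pleiotropic SNP contributes to each of its traits'
#' tables; per-trait counts therefore deliberately sum to more than the
#' pooled n.
#'
#' @param records a `concordance_records` tibble (one reference panel).
#' @param group `"ALL"` or a trait label.
#' @return a [contingency_table()].
#' @export
tabulate_records <- function(records, group = "ALL") {
  stopifnot(is.character(group), length(group) == 1L)
  rec <- tibble::as_tibble(records)
  if (length(unique(rec$reference)) > 1L) {
    validation_error("tabulate_records expects records for a single reference; split first")
  }
  status_per_rsid <- tapply(rec$status, rec$rsid,
                            function(s) length(unique(s)))
  if (any(status_per_rsid > 1L)) {
    bad <- names(status_per_rsid)[status_per_rsid > 1L]
    validation_error(sprintf(
      "inconsistent status across rows for rsID(s): %s (status is chip- and tool-level, so it must agree)",
      paste(utils::head(bad, 10L), collapse = ", ")))
  }
  rec <- rec[!duplicated(rec$rsid), , drop = FALSE]
  if (group != "ALL") {
    rec <- rec[purrr::map_lgl(rec$traits, ~ group %in% .x), , drop = FALSE]
  }
  s <- factor(rec$status, levels = c("TP", "FN", "FP", "TN"))
  counts <- table(s)
  contingency_table(tp = counts[["TP"]], fn = counts[["FN"]],
                    fp = counts[["FP"]], tn = counts[["TN"]])
}
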