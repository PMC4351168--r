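#' Run the full membership-validation pipeline
#'
#' Wires the stages end to end: positional membership of every query SNP
#' on the array (ground truth), join with the audited tool's claims for
#' each reference panel, per-SNP classification into TP/FN/FP/TN,
#' per-trait and pooled 2x2 tables, and agreement statistics (Cohen's
#' kappa, FNR, FPR, Landis-Koch band). Inputs may be file paths (read with
#' the default dialects) or already-parsed objects. With `out_dir` set,
#' writes `per_snp.tsv` (SNP-by-SNP comparison across references),
#' `summary_<reference>.tsv` and `summary_<reference>.txt` (the per-trait
#' tables), and `stats.json` (all statistics, machine-readable). Identical
#' inputs produce byte-identical outputs.
#'
#' @param queries an `snp_queries` tibble or a query-list path.
#' @param manifest an `array_manifest` tibble or a manifest path.
#' @param claims a named list (by reference panel) of `tool_claims`
#'   tibbles or of tool-output paths.
#' @param build genome-build tag the comparison is pinned to.
#' @param trait_order row order for the summaries (default: order of first
#'   appearance).
#' @param out_dir optional output directory (created if missing).
#' @return (invisibly) a list with `calls`, `records` (named by
#'   reference), `summaries` (named by reference), `report` (the per-SNP
#'   table) and `stats` (the list serialised to `stats.json`).
#' @export
run_validate <- function(queries, manifest, claims, build = "GRCh37",
                         trait_order = NULL, out_dir = NULL) {
  if (is.character(queries)) queries <- read_query_list(queries, build = build)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(names(claims)) || any(!nzchar(names(claims)))) {
    config_error("claims must be a named list, one entry per reference panel")
  }
  claims <- lapply(names(claims), function(ref) {
    x <- claims[[ref]]
    if (is.character(x)) read_tool_output(x, reference = ref) else x
  }) |> stats::setNames(names(claims))

  index <- build_position_index(manifest, build = build)
  calls <- check_batch(queries, index)
  records <- lapply(names(claims), function(ref) {
    join_and_classify(calls, claims[[ref]], reference = ref)
  }) |> stats::setNames(names(claims))
  summaries <- lapply(records, trait_summary, trait_order = trait_order)
  report <- per_snp_report(dplyr::bind_rows(records))

  stats <- list(build = build, n_queries = nrow(queries),
                n_probes = nrow(manifest),
                references = lapply(summaries, function(s) {
                  rows <- split(tibble::as_tibble(s), seq_len(nrow(s)))
                  stats::setNames(lapply(rows, as.list), s$group)
                }))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_per_snp_report(report, file.path(out_dir, "per_snp.tsv"))
    for (ref in names(summaries)) {
      write_summary(summaries[[ref]],
                    file.path(out_dir, sprintf("summary_%s.tsv", ref)))
      writeLines(render_summary(summaries[[ref]], "txt"),
                 file.path(out_dir, sprintf("summary_%s.txt", ref)))
    }
    jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(calls = calls, records = records, summaries = summaries,
                 report = report, stats = stats))
}
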