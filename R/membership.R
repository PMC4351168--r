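#' Build a positional index over an array manifest
#'
#' The independent standard for deciding whether a SNP is on a chip is the
#' vendor's product file queried by chromosome and chromosomal position --
#' never by rs number, which drifts across database versions (merged or
#' reassigned accessions, SNPs with several rs numbers). This constructs a
#' hash from normalized `(chrom, pos)` keys to the probe names at that
#' locus; several probes at one locus are aggregated, never overwritten.
#'
#' @param manifest an `array_manifest` tibble (see [read_manifest()]).
#' @param build genome-build tag of the manifest coordinates
#'   (default `"GRCh37"`).
#' @return an object of class `position_index`.
#' @export
build_position_index <- function(manifest, build = "GRCh37") {
  stopifnot(all(c("probe_name", "chrom", "pos") %in% names(manifest)))
  keys <- paste(normalize_chrom(manifest$chrom), manifest$pos, sep = ":")
  map <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(16L, nrow(manifest)))
  probes_by_key <- split(manifest$probe_name, keys)
  for (k in names(probes_by_key)) assign(k, probes_by_key[[k]], envir = map)
  structure(list(map = map, build = build, n_probes = nrow(manifest),
                 n_loci = length(probes_by_key)),
            class = "position_index")
}

#' @export
print.position_index <- function(x, ...) {
  cat(sprintf("<position_index> %d probe(s) at %d locus/loci [%s]\n",
              x$n_probes, x$n_loci, x$build))
  invisible(x)
}

#' Positional membership of query SNPs on an array
#'
#' For each query, `on_chip` is `TRUE` exactly when the manifest carries a
#' probe at the same normalized chromosome and 1-based position. Matching is
#' exact -- no tolerance window -- and rsIDs are never consulted: a probe at
#' the query's locus counts even if it is annotated with a different rs
#' number. The query and index build tags must agree; coordinates are never
#' lifted over silently.
#'
#' `check_membership()` is the single-query form; `check_batch()` maps it
#' over a query collection, preserving order, and reports on/off-chip
#' totals.
#'
#' @param queries,query an `snp_queries` tibble (one row for
#'   `check_membership`).
#' @param index a [build_position_index()] result.
#' @return a tibble of class `membership_calls`: the query columns plus
#'   `on_chip` (logical) and `matched_probes` (list of character vectors,
#'   empty when off-chip).
#' @export
check_batch <- function(queries, index) {
  stopifnot(inherits(index, "position_index"))
  builds <- unique(queries$build)
  if (nrow(queries) > 0L && !identical(builds, index$build)) {
    validation_error(sprintf(
      "genome build mismatch: queries are %s but the index is %s; refusing to compare positions across builds",
      paste(builds, collapse = "/"), index$build))
  }
  keys <- paste(normalize_chrom(queries$chrom), queries$pos, sep = ":")
  hits <- mget(keys, envir = index$map, ifnotfound = list(character(0)))
  out <- tibble::as_tibble(queries)
  out$on_chip <- unname(lengths(hits) > 0L)
  out$matched_probes <- unname(hits)
  dup_locus <- unique(keys[duplicated(keys)])
  if (length(dup_locus) > 0L) {
    message(sprintf("check_batch: %d locus/loci shared by multiple queries (possibly multi-allelic): %s",
                    length(dup_locus),
                    paste(utils::head(dup_locus, 5L), collapse = ", ")))
  }
  message(sprintf("check_batch: %d query/queries, %d on-chip, %d off-chip",
                  nrow(out), sum(out$on_chip), sum(!out$on_chip)))
  structure(out, class = c("membership_calls", class(out)))
}

#' @rdname check_batch
#' @export
check_membership <- function(query, index) {
  stopifnot(nrow(query) == 1L)
  suppressMessages(check_batch(query, index))
}
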