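#' Dialect descriptions for tabular inputs
#'
#' Query lists and tool outputs are tab-separated by default; manifests are
#' comma-separated, following array-vendor convention. Both are configurable:
#' a dialect is just the delimiter plus a mapping from the logical field
#' names to the column headers actually present in the file.
#'
#' @param rsid,chrom,pos,trait,probe_name column-header names in the file.
#' @param delim single-character field delimiter.
#' @return a named list of class `cc_dialect`.
#' @export
#' @examples
#' query_dialect()
#' manifest_dialect(probe_name = "IlmnID", pos = "Position")
query_dialect <- function(rsid = "rsid", chrom = "chrom", pos = "pos",
                          trait = "trait", delim = "\t") {
  structure(list(rsid = rsid, chrom = chrom, pos = pos, trait = trait,
                 delim = delim), class = "cc_dialect")
}

#' @rdname query_dialect
#' @export
manifest_dialect <- function(probe_name = "Name", chrom = "Chr",
                             pos = "MapInfo", rsid = "RsID", delim = ",") {
  structure(list(probe_name = probe_name, chrom = chrom, pos = pos,
                 rsid = rsid, delim = delim), class = "cc_dialect")
}

# Split a small delimited text file into header + data rows while keeping
# the raw line and the original line number of every row, so rejected rows
# can be reported verbatim. Lines starting with "#" are comments; the first
# non-comment line is the header. Fields are plain (unquoted) text, which is
# what SNP query lists, SNAP-style outputs and the positional columns of
# vendor manifests contain.
parse_delim_lines <- function(path, delim) {
  if (!file.exists(path)) {
    config_error(sprintf("input file does not exist: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(list(header = character(), rows = list(),
                raw = character(), line_no = integer()))
  }
  header <- trimws(strsplit(lines[idx[1L]], delim, fixed = TRUE)[[1L]])
  data_idx <- idx[-1L]
  rows <- lapply(lines[data_idx], function(l) {
    trimws(strsplit(l, delim, fixed = TRUE)[[1L]])
  })
  list(header = header, rows = rows, raw = lines[data_idx], line_no = data_idx)
}

require_columns <- function(header, needed, path) {
  missing <- setdiff(needed, header)
  if (length(missing) > 0L) {
    config_error(sprintf(
      "'%s' is missing mandatory column(s): %s (have: %s)",
      path, paste(missing, collapse = ", "), paste(header, collapse = ", ")))
  }
}

new_rejected <- function(line = integer(), raw = character(),
                         reason = character()) {
  tibble::tibble(line = as.integer(line), raw = raw, reason = reason)
}

#' Rejected-row report of a parsed collection
#'
#' Parsing is total: every input row is either parsed or carried in the
#' rejected-row report with its line number, raw text and a reason. This
#' accessor returns that report.
#'
#' @param x an object returned by [read_query_list()], [read_manifest()] or
#'   [read_tool_output()].
#' @return a tibble with columns `line`, `raw`, `reason` (zero rows if
#'   nothing was rejected).
#' @export
rejected_rows <- function(x) {
  attr(x, "rejected") %||% new_rejected()
}

#' Write a rejected-row report
#'
#' @param x a parsed collection (or a rejected-row tibble).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_error_report <- function(x, path) {
  rej <- if (is.data.frame(x) && all(c("line", "raw", "reason") %in% names(x)))
    x else rejected_rows(x)
  utils::write.table(rej, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

valid_rsid <- function(x) grepl("^rs[0-9]+$", x)

parse_pos <- function(x) {
  ok <- grepl("^[0-9]+$", x)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(x[ok])
  out
}

#' Read a SNP query list
#'
#' Reads a table of trait-associated SNPs: one row per (rsID, trait) pair,
#' with GRCh37 chromosome and 1-based position. Rows sharing an rsID (a
#' pleiotropic SNP, associated with more than one trait) merge into a single
#' query whose `traits` entry is the union of trait labels; the same rsID
#' with conflicting coordinates is a validation error. Malformed rows
#' (bad rsID, unknown chromosome, non-positive or non-numeric position,
#' empty trait) are not silently dropped: they are collected into the
#' rejected-row report available via [rejected_rows()].
#'
#' @param path path to a delimited text file.
#' @param dialect a [query_dialect()] giving the delimiter and column names.
#' @param build genome-build tag stamped on every query (default `"GRCh37"`);
#'   positional matching later refuses to compare across differing tags.
#' @return a tibble of class `snp_queries` with columns `rsid`, `chrom`
#'   (normalized), `pos` (integer), `build`, and `traits` (list column of
#'   character vectors), in order of first appearance; the rejected-row
#'   report is attached as an attribute.
#' @export
read_query_list <- function(path, dialect = query_dialect(),
                            build = "GRCh37") {
  parsed <- parse_delim_lines(path, dialect$delim)
  if (length(parsed$header) == 0L) {
    out <- empty_queries(build)
    attr(out, "rejected") <- new_rejected()
    return(out)
  }
  needed <- c(dialect$rsid, dialect$chrom, dialect$pos, dialect$trait)
  require_columns(parsed$header, needed, path)
  col <- match(needed, parsed$header)

  n <- length(parsed$rows)
  rsid <- chrom <- trait <- character(n)
  pos <- integer(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    f <- parsed$rows[[i]]
    if (length(f) < max(col)) {
      reason[i] <- sprintf("expected >= %d fields, found %d", max(col),
                           length(f))
      next
    }
    rsid[i] <- f[col[1L]]
    chrom[i] <- normalize_chrom(f[col[2L]])
    pos[i] <- parse_pos(f[col[3L]])
    trait[i] <- f[col[4L]]
    reason[i] <- row_problem(rsid[i], chrom[i], pos[i], trait[i])
  }
  ok <- is.na(reason)
  rejected <- new_rejected(parsed$line_no[!ok], parsed$raw[!ok],
                           reason[!ok])

  df <- tibble::tibble(rsid = rsid[ok], chrom = chrom[ok], pos = pos[ok],
                       trait = trait[ok])
  coords <- dplyr::distinct(df, .data$rsid, .data$chrom, .data$pos)
  dup <- coords$rsid[duplicated(coords$rsid)]
  if (length(dup) > 0L) {
    validation_error(sprintf(
      "conflicting coordinates for rsID(s): %s",
      paste(unique(dup), collapse = ", ")))
  }
  merged <- df |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::summarise(
      chrom = .data$chrom[1L], pos = .data$pos[1L],
      traits = list(unique(.data$trait)), .ord = min(.data$.ord),
      .by = "rsid") |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord") |>
    dplyr::mutate(build = build, .after = "pos")
  out <- structure(merged, class = c("snp_queries", class(merged)))
  attr(out, "rejected") <- rejected
  out
}

row_problem <- function(rsid, chrom, pos, trait) {
  if (!valid_rsid(rsid)) return(sprintf("invalid rsID '%s'", rsid))
  if (!chrom %in% chrom_alphabet()) {
    return(sprintf("unknown chromosome '%s'", chrom))
  }
  if (is.na(pos) || pos < 1L) return("position is not a positive integer")
  if (!nzchar(trait)) return("empty trait label")
  NA_character_
}

empty_queries <- function(build) {
  q <- tibble::tibble(rsid = character(), chrom = character(),
                      pos = integer(), build = character(),
                      traits = list())
  structure(q, class = c("snp_queries", class(q)))
}

#' Write a SNP query list
#'
#' Inverse of [read_query_list()]: each query is expanded back to one row
#' per trait, so a read of the written file reproduces the collection
#' field for field.
#'
#' @param queries an `snp_queries` tibble.
#' @param path output path.
#' @param dialect a [query_dialect()].
#' @return `path`, invisibly.
#' @export
write_query_list <- function(queries, path, dialect = query_dialect()) {
  long <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(queries), "rsid", "chrom", "pos",
                  "traits"),
    "traits")
  header <- paste(c(dialect$rsid, dialect$chrom, dialect$pos, dialect$trait),
                  collapse = dialect$delim)
  body <- paste(long$rsid, long$chrom, long$pos, long$traits,
                sep = dialect$delim)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an array manifest (product file)
#'
#' Reads the vendor's probe table. Only the positional columns are used:
#' probe name, chromosome and position, plus an optional rsID column --
#' vendor files do not carry rs numbers for every probe, and membership is
#' decided by position alone, so entries without an rsID are retained.
#' Several probes may share a locus (they are all kept); a duplicated probe
#' name is a validation error.
#'
#' @param path path to the manifest file.
#' @param dialect a [manifest_dialect()] mapping the file's column headers
#'   (defaults `Name`, `Chr`, `MapInfo`, `RsID`) onto the logical fields.
#' @return a tibble of class `array_manifest` with columns `probe_name`,
#'   `chrom` (normalized), `pos` (integer) and `rsid` (`NA` where absent),
#'   plus the rejected-row report as an attribute.
#' @export
read_manifest <- function(path, dialect = manifest_dialect()) {
  parsed <- parse_delim_lines(path, dialect$delim)
  empty <- tibble::tibble(probe_name = character(), chrom = character(),
                          pos = integer(), rsid = character())
  empty <- structure(empty, class = c("array_manifest", class(empty)))
  if (length(parsed$header) == 0L || length(parsed$rows) == 0L) {
    rlang::warn(sprintf("manifest '%s' has no data rows", path))
    attr(empty, "rejected") <- new_rejected()
    return(empty)
  }
  require_columns(parsed$header, c(dialect$probe_name, dialect$chrom,
                                   dialect$pos), path)
  col <- match(c(dialect$probe_name, dialect$chrom, dialect$pos),
               parsed$header)
  rs_col <- match(dialect$rsid, parsed$header)  # NA if the column is absent

  n <- length(parsed$rows)
  probe <- chrom <- rsid <- character(n)
  pos <- integer(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    f <- parsed$rows[[i]]
    if (length(f) < max(col)) {
      reason[i] <- sprintf("expected >= %d fields, found %d", max(col),
                           length(f))
      next
    }
    probe[i] <- f[col[1L]]
    chrom[i] <- normalize_chrom(f[col[2L]])
    pos[i] <- parse_pos(f[col[3L]])
    rsid[i] <- if (!is.na(rs_col) && length(f) >= rs_col && nzchar(f[rs_col]))
      f[rs_col] else NA_character_
    if (!nzchar(probe[i])) {
      reason[i] <- "empty probe name"
    } else if (!chrom[i] %in% chrom_alphabet()) {
      reason[i] <- sprintf("unknown chromosome '%s'", chrom[i])
    } else if (is.na(pos[i]) || pos[i] < 1L) {
      reason[i] <- "position is not a positive integer"
    }
  }
  ok <- is.na(reason)
  dup <- unique(probe[ok][duplicated(probe[ok])])
  if (length(dup) > 0L) {
    validation_error(sprintf("duplicate probe name(s) in manifest: %s",
                             paste(dup, collapse = ", ")))
  }
  out <- tibble::tibble(probe_name = probe[ok], chrom = chrom[ok],
                        pos = pos[ok], rsid = rsid[ok])
  out <- structure(out, class = c("array_manifest", class(out)))
  attr(out, "rejected") <- new_rejected(parsed$line_no[!ok], parsed$raw[!ok],
                                        reason[!ok])
  message(sprintf("read_manifest: parsed %d probe(s) from '%s'",
                  nrow(out), path))
  out
}

#' Write an array manifest
#'
#' @param manifest an `array_manifest` tibble.
#' @param path output path.
#' @param dialect a [manifest_dialect()].
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, dialect = manifest_dialect()) {
  header <- paste(c(dialect$probe_name, dialect$chrom, dialect$pos,
                    dialect$rsid), collapse = dialect$delim)
  rs <- ifelse(is.na(manifest$rsid), "", manifest$rsid)
  body <- paste(manifest$probe_name, manifest$chrom, manifest$pos, rs,
                sep = dialect$delim)
  writeLines(c(header, body), path)
  invisible(path)
}

# Canonical warning strings written by write_tool_output(); read_tool_output
# maps any "not in <reference>" text back onto the category + panel label.
warning_text <- function(warning, reference) {
  token <- c(HapMap3 = "HapMap3_r2", `1000Genomes` = "1000GenomesPilot1")
  ref <- ifelse(reference %in% names(token), token[reference], reference)
  out <- rep("", length(warning))
  out[warning == "not_in_reference"] <-
    paste("WARNING Query snp not in", ref[warning == "not_in_reference"])
  out[warning == "not_on_array"] <-
    "WARNING Query snp not in any selected array"
  out
}

classify_warning <- function(text) {
  cat_ <- rep("none", length(text))
  ref <- rep(NA_character_, length(text))
  has <- grepl("WARNING", text, ignore.case = TRUE) | nzchar(trimws(text))
  arrayish <- grepl("array", text, ignore.case = TRUE)
  notin <- grepl("not\\s+in", text, ignore.case = TRUE) & !arrayish
  cat_[has & arrayish] <- "not_on_array"
  cat_[notin] <- "not_in_reference"
  cat_[has & !arrayish & !notin] <- "not_in_reference"
  ref[grepl("hapmap", text, ignore.case = TRUE)] <- "HapMap3"
  ref[grepl("1000\\s*genomes", text, ignore.case = TRUE)] <- "1000Genomes"
  list(category = cat_, reference = ref)
}

#' Read a tool-output (claims) file
#'
#' Reads per-SNP availability claims in the shape a proxy-search tool such
#' as SNAP emits: one row per rsID with an availability flag and, for
#' unavailable SNPs, a free-text `WARNING` explaining why. Warning text of
#' the form "Query snp not in <panel>" is categorised as
#' `not_in_reference` (the tool's reference panel lacks the SNP); text
#' mentioning the array is categorised as `not_on_array`. Any warning
#' forces `claimed_present = FALSE`: these tools report a warned SNP as
#' missing even when the chip carries it.
#'
#' @param path path to a TSV with columns `rsid`, `array`, `available`
#'   (0/1), `warning` (free text, may be empty).
#' @param reference label of the reference panel the tool was run against
#'   (e.g. `"HapMap3"`); if `NULL`, inferred per row from the warning text
#'   where possible.
#' @return a tibble of class `tool_claims` with columns `rsid`,
#'   `array_name`, `claimed_present`, `warning` (one of `none`,
#'   `not_in_reference`, `not_on_array`) and `reference`; rejected rows
#'   attached as an attribute.
#' @export
read_tool_output <- function(path, reference = NULL) {
  parsed <- parse_delim_lines(path, "\t")
  empty <- tibble::tibble(rsid = character(), array_name = character(),
                          claimed_present = logical(), warning = character(),
                          reference = character())
  empty <- structure(empty, class = c("tool_claims", class(empty)))
  if (length(parsed$header) == 0L) {
    attr(empty, "rejected") <- new_rejected()
    return(empty)
  }
  require_columns(parsed$header, c("rsid", "array"), path)
  col_rsid <- match("rsid", parsed$header)
  col_array <- match("array", parsed$header)
  col_avail <- match("available", parsed$header)
  col_warn <- match("warning", parsed$header)

  n <- length(parsed$rows)
  rsid <- array_name <- warn_text <- character(n)
  avail <- rep(NA, n)
  for (i in seq_len(n)) {
    f <- parsed$rows[[i]]
    rsid[i] <- if (length(f) >= col_rsid) f[col_rsid] else ""
    array_name[i] <- if (length(f) >= col_array) f[col_array] else ""
    avail[i] <- if (!is.na(col_avail) && length(f) >= col_avail &&
                    f[col_avail] %in% c("0", "1")) f[col_avail] == "1" else NA
    warn_text[i] <- if (!is.na(col_warn) && length(f) >= col_warn)
      f[col_warn] else ""
  }
  w <- classify_warning(warn_text)
  no_signal <- is.na(avail) & w$category == "none"
  if (any(no_signal)) {
    validation_error(sprintf(
      "tool-output row(s) with neither availability flag nor warning: line(s) %s",
      paste(parsed$line_no[no_signal], collapse = ", ")))
  }
  bad_rsid <- !valid_rsid(rsid)
  rejected <- new_rejected(parsed$line_no[bad_rsid], parsed$raw[bad_rsid],
                           sprintf("invalid rsID '%s'", rsid[bad_rsid]))
  keep <- !bad_rsid
  claimed <- ifelse(w$category[keep] != "none", FALSE,
                    ifelse(is.na(avail[keep]), FALSE, avail[keep]))
  ref <- if (is.null(reference)) w$reference[keep]
         else rep(reference, sum(keep))
  out <- tibble::tibble(rsid = rsid[keep], array_name = array_name[keep],
                        claimed_present = claimed,
                        warning = w$category[keep], reference = ref)
  out <- structure(out, class = c("tool_claims", class(out)))
  attr(out, "rejected") <- rejected
  out
}

#' Write a tool-output (claims) file
#'
#' @param claims a `tool_claims` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tool_output <- function(claims, path) {
  header <- paste(c("rsid", "array", "available", "warning"),
                  collapse = "\t")
  body <- paste(claims$rsid, claims$array_name,
                as.integer(claims$claimed_present),
                warning_text(claims$warning, claims$reference),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
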