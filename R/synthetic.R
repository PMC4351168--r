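# Approximate GRCh37 chromosome lengths (bp), autosomes + X, used as the
# coordinate space for simulated loci.
grch37_lengths <- c(
  `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
  `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
  `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
  `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
  `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
  `21` = 48129895, `22` = 51304566, X = 155270560)

#' Configuration for the synthetic audit generator
#'
#' Describes the world the generator draws from. Defaults mirror the
#' structure of a GWAS follow-up audit of the Illumina Cardio-Metabochip
#' (~196,725 probes): 415 query SNPs of which about 88% (366/415) are truly
#' on the chip, an audited tool that misses on-chip SNPs at a
#' reference-dependent rate (about 41.5% = 152/366 with an older
#' HapMap3-like panel, 19.9% = 73/366 with a 1000-Genomes-like panel),
#' never claims an off-chip SNP present, and a trait mix of 37 blood
#' pressure, 39 fasting glucose, 69 BMI and 276 lipids memberships with 6
#' pleiotropic SNPs carrying two traits.
#'
#' @param n_probes manifest size (default 196725).
#' @param n_queries number of query SNPs (default 415).
#' @param frac_on_chip probability a query SNP is on the manifest.
#' @param miss_rates named per-reference probabilities that an on-chip SNP
#'   is claimed absent.
#' @param fp_rate probability an off-chip SNP is claimed present
#'   (default 0).
#' @param trait_weights named sampling weights over trait labels.
#' @param pleiotropy_count number of query SNPs given a second trait.
#' @param prob_probe_rsid fraction of manifest probes annotated with an
#'   rsID (vendor files do not carry rs numbers for every probe).
#' @param array_name,build metadata stamped on the outputs.
#' @param seed PRNG seed; a fixed seed gives byte-identical outputs.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_probes = 196725, n_queries = 415,
                             frac_on_chip = 366 / 415,
                             miss_rates = c(HapMap3 = 152 / 366,
                                            `1000Genomes` = 73 / 366),
                             fp_rate = 0,
                             trait_weights = c(`Blood pressure` = 37,
                                               `Fasting glucose` = 39,
                                               BMI = 69, Lipids = 276),
                             pleiotropy_count = 6,
                             prob_probe_rsid = 0.9,
                             array_name = "Cardio-Metabochip",
                             build = "GRCh37", seed = 1L) {
  probs <- c(frac_on_chip, miss_rates, fp_rate, prob_probe_rsid)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    config_error("all probabilities must lie in [0, 1]")
  }
  if (n_probes < 0 || n_queries < 0 || pleiotropy_count < 0) {
    config_error("counts must be non-negative")
  }
  if (pleiotropy_count > 0 && length(trait_weights) < 2L) {
    config_error("pleiotropy needs at least two trait labels")
  }
  if (is.null(names(miss_rates)) || any(!nzchar(names(miss_rates)))) {
    config_error("miss_rates must be named by reference panel")
  }
  structure(list(n_probes = n_probes, n_queries = n_queries,
                 frac_on_chip = frac_on_chip, miss_rates = miss_rates,
                 fp_rate = fp_rate, trait_weights = trait_weights,
                 pleiotropy_count = pleiotropy_count,
                 prob_probe_rsid = prob_probe_rsid,
                 array_name = array_name, build = build,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Draw n distinct loci from the GRCh37-like space, optionally avoiding a
# set of existing "chrom:pos" keys.
draw_loci <- function(n, avoid = character()) {
  out_chrom <- character(0); out_pos <- integer(0)
  taken <- avoid
  while (length(out_chrom) < n) {
    k <- n - length(out_chrom)
    chrom <- sample(names(grch37_lengths), k, replace = TRUE,
                    prob = grch37_lengths)
    pos <- floor(stats::runif(k, min = 1, max = grch37_lengths[chrom])) + 0L
    key <- paste(chrom, pos, sep = ":")
    new <- !duplicated(key) & !(key %in% taken)
    out_chrom <- c(out_chrom, chrom[new])
    out_pos <- c(out_pos, as.integer(pos[new]))
    taken <- c(taken, key[new])
  }
  tibble::tibble(chrom = out_chrom, pos = out_pos)
}

#' Generate a synthetic audit dataset with known ground truth
#'
#' Draws a manifest, a query list and per-reference tool claims from a
#' [synthetic_config()], together with a truth table recording every
#' query's real membership and every injected claim, so the pipeline's
#' output can be scored exactly. All randomness flows through one seeded
#' generator: the same config and seed reproduce the dataset exactly.
#'
#' On-chip queries are placed on loci sampled (without replacement) from
#' the manifest; off-chip queries get fresh loci absent from it. For each
#' reference panel an on-chip query is claimed absent with the panel's
#' miss rate (warning `not_in_reference`, the tool's reference panel
#' lacking the SNP); an off-chip query is claimed present with `fp_rate`
#' and otherwise claimed absent with warning `not_on_array`.
#'
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed` when given.
#' @return a list with elements `manifest`, `queries`, `claims` (a named
#'   list of `tool_claims`, one per reference), `truth` (a tibble with
#'   `rsid`, `chrom`, `pos`, `on_chip` and one `claimed_<reference>`
#'   column per panel) and `config`.
#' @export
simulate_audit <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- seed %||% config$seed
  withr::with_seed(seed, simulate_audit_impl(config))
}

simulate_audit_impl <- function(config) {
  probe_loci <- draw_loci(config$n_probes)
  manifest <- tibble::tibble(
    probe_name = sprintf("chip_%07d", seq_len(config$n_probes)),
    chrom = probe_loci$chrom, pos = probe_loci$pos,
    rsid = ifelse(stats::runif(config$n_probes) < config$prob_probe_rsid,
                  sprintf("rs%d", 10000000L + seq_len(config$n_probes)),
                  NA_character_))
  manifest <- structure(manifest,
                        class = c("array_manifest", class(manifest)))

  n <- config$n_queries
  on_chip <- stats::runif(n) < config$frac_on_chip
  n_on <- sum(on_chip)
  chrom <- character(n); pos <- integer(n)
  if (n_on > 0L) {
    pick <- sample.int(config$n_probes, n_on)
    chrom[on_chip] <- manifest$chrom[pick]
    pos[on_chip] <- manifest$pos[pick]
  }
  if (n_on < n) {
    off <- draw_loci(n - n_on,
                     avoid = paste(manifest$chrom, manifest$pos, sep = ":"))
    chrom[!on_chip] <- off$chrom
    pos[!on_chip] <- off$pos
  }
  trait1 <- sample(names(config$trait_weights), n, replace = TRUE,
                   prob = config$trait_weights)
  traits <- as.list(trait1)
  if (config$pleiotropy_count > 0L) {
    pleio <- sample.int(n, min(config$pleiotropy_count, n))
    for (i in pleio) {
      others <- setdiff(names(config$trait_weights), trait1[i])
      traits[[i]] <- c(trait1[i], sample(others, 1L))
    }
  }
  queries <- tibble::tibble(rsid = sprintf("rs%d", seq_len(n)),
                            chrom = chrom, pos = pos,
                            build = config$build, traits = traits)
  queries <- structure(queries, class = c("snp_queries", class(queries)))

  truth <- tibble::tibble(rsid = queries$rsid, chrom = chrom, pos = pos,
                          on_chip = on_chip)
  claims <- list()
  for (ref in names(config$miss_rates)) {
    miss <- on_chip & stats::runif(n) < config$miss_rates[[ref]]
    ghost <- !on_chip & stats::runif(n) < config$fp_rate
    claimed <- (on_chip & !miss) | ghost
    warning <- rep("none", n)
    warning[miss] <- "not_in_reference"
    warning[!on_chip & !ghost] <- "not_on_array"
    cl <- tibble::tibble(rsid = queries$rsid,
                         array_name = config$array_name,
                         claimed_present = claimed, warning = warning,
                         reference = ref)
    claims[[ref]] <- structure(cl, class = c("tool_claims", class(cl)))
    truth[[paste0("claimed_", ref)]] <- claimed
  }
  list(manifest = manifest, queries = queries, claims = claims,
       truth = truth, config = config)
}

# Deterministic fixture layout. Each block is a run of SNPs for one trait
# with one cross-reference claim pattern:
#   tptp - on chip, claimed present under both references
#   fntp - on chip, missed under reference A only
#   fnfn - on chip, missed under both references
#   tn   - off chip, (correctly) claimed absent under both
fixture_blocks <- function() {
  list(`Blood pressure`  = c(tptp = 20, fntp = 7,  fnfn = 2,  tn = 6),
       `Fasting glucose` = c(tptp = 19, fntp = 19, fnfn = 0,  tn = 0),
       BMI               = c(tptp = 25, fntp = 7,  fnfn = 26, tn = 8),
       Lipids            = c(tptp = 147, fntp = 46, fnfn = 44, tn = 33))
}

fixture_pleiotropic <- function() {
  tibble::tibble(
    trait2 = c("Blood pressure", "BMI", "Fasting glucose",
               "Blood pressure", "BMI", "BMI"),
    pattern = c("tptp", "tptp", "tptp", "tn", "tn", "fnfn"))
}

#' Deterministic Cardio-Metabochip-shaped example dataset
#'
#' A constructed (not sampled) dataset of 415 query SNPs across four trait
#' groups -- 37 blood pressure, 39 fasting glucose, 69 BMI and 276 lipids
#' memberships (421 in total, 6 SNPs pleiotropic and carrying two traits)
#' -- with a matching manifest and tool claims for two reference panels,
#' `HapMap3` and `1000Genomes`. Statuses are assigned in fixed
#' trait/status blocks so that classification yields exactly the 2x2
#' tables recoverable from a published audit of this design: pooled
#' tp/fn/fp/tn of 214/152/0/49 under HapMap3 (kappa 0.250) and
#' 293/73/0/49 under 1000 Genomes (kappa 0.487), with the per-trait
#' splits uniquely determined by [reconstruct_split()]. No randomness is
#' involved; every call returns the identical dataset.
#'
#' The manifest additionally carries 120 background probes not targeted by
#' any query, and emulates vendor-file quirks: some probes lack an rsID
#' and some carry an rsID different from the query's (membership is
#' positional, so neither affects the result).
#'
#' @return a list with `manifest`, `queries`, `claims` (named list with
#'   `HapMap3` and `1000Genomes` entries) and `truth`, as in
#'   [simulate_audit()].
#' @export
metabochip_fixture <- function() {
  blocks <- fixture_blocks()
  trait <- character(0); pattern <- character(0)
  for (tr in names(blocks)) {
    trait <- c(trait, rep(tr, sum(blocks[[tr]])))
    pattern <- c(pattern, rep(names(blocks[[tr]]), blocks[[tr]]))
  }
  traits <- as.list(trait)
  pl <- fixture_pleiotropic()  # all pleiotropic SNPs primarily lipids
  pattern <- c(pattern, pl$pattern)
  traits <- c(traits, purrr::map(seq_len(nrow(pl)),
                                 ~ c("Lipids", pl$trait2[.x])))
  n <- length(pattern)
  stopifnot(n == 415L)

  idx <- seq_len(n)
  chrom <- as.character(((idx - 1L) %% 22L) + 1L)
  pos <- 1000000L + idx * 137L
  rsid <- sprintf("rs%d", 500000L + idx)
  on_chip <- pattern != "tn"

  queries <- tibble::tibble(rsid = rsid, chrom = chrom, pos = pos,
                            build = "GRCh37", traits = traits)
  queries <- structure(queries, class = c("snp_queries", class(queries)))

  on_idx <- which(on_chip)
  probe_rsid <- rsid[on_idx]
  probe_rsid[on_idx %% 7L == 0L] <- NA_character_          # vendor gap
  drift <- on_idx %% 11L == 0L                             # rs-number drift
  probe_rsid[drift] <- sprintf("rs%d", 900000L + on_idx[drift])
  extra <- 120L
  manifest <- tibble::tibble(
    probe_name = sprintf("cmc_%06d", seq_len(length(on_idx) + extra)),
    chrom = c(chrom[on_idx], as.character(((seq_len(extra) - 1L) %% 22L) + 1L)),
    pos = c(pos[on_idx], 50000000L + seq_len(extra) * 911L),
    rsid = c(probe_rsid,
             ifelse(seq_len(extra) %% 2L == 0L, NA_character_,
                    sprintf("rs%d", 700000L + seq_len(extra)))))
  manifest <- structure(manifest,
                        class = c("array_manifest", class(manifest)))

  make_claims <- function(ref, present_patterns) {
    claimed <- pattern %in% present_patterns
    warning <- rep("none", n)
    warning[on_chip & !claimed] <- "not_in_reference"
    warning[!on_chip] <- "not_on_array"
    cl <- tibble::tibble(rsid = rsid, array_name = "Cardio-Metabochip",
                         claimed_present = claimed, warning = warning,
                         reference = ref)
    structure(cl, class = c("tool_claims", class(cl)))
  }
  claims <- list(
    HapMap3 = make_claims("HapMap3", "tptp"),
    `1000Genomes` = make_claims("1000Genomes", c("tptp", "fntp")))
  truth <- tibble::tibble(rsid = rsid, chrom = chrom, pos = pos,
                          on_chip = on_chip,
                          claimed_HapMap3 = claims$HapMap3$claimed_present,
                          claimed_1000Genomes =
                            claims$`1000Genomes`$claimed_present)
  list(manifest = manifest, queries = queries, claims = claims,
       truth = truth)
}
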