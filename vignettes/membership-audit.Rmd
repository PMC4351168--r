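---
title: "Auditing SNP-array membership claims against the product file"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing SNP-array membership claims against the product file}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipconcord)
```

## The problem

GWAS follow-up studies routinely ask whether a list of trait-associated
SNPs can be genotyped on a given array. Web tools that answer this
question (proxy-search services such as SNAP) first look the SNP up in a
reference panel (HapMap 3, 1000 Genomes) and only then interrogate the
array: a SNP absent from the panel is reported as unavailable *even when
the chip carries a probe for it*. The rs number itself is also an
unreliable join key — accessions get merged and reassigned, and vendor
product files do not annotate every probe with one.

`chipconcord` implements the independent standard that exposes this
failure mode: decide membership **positionally**, by exact match of
normalized chromosome and 1-based position (a single build, no liftover,
no tolerance window) against the vendor's product file, then score the
tool's claims against that ground truth and summarise agreement.

## The model

For each query SNP, two binary raters are compared: the manifest
(ground truth) and the audited tool. Each SNP falls into one cell of a
2×2 table — `TP` (both say present), `FN` (on the chip but claimed
absent), `FP` (claimed present but not on the chip), `TN` (both say
absent). Agreement is summarised by Cohen's kappa,

$$\kappa = \frac{\Pr(a) - \Pr(e)}{1 - \Pr(e)}, \qquad
\Pr(a) = \frac{tp + tn}{n}, \qquad
\Pr(e) = \frac{(tp+fn)(tp+fp) + (tn+fp)(tn+fn)}{n^2},$$

with the Landis–Koch verbal bands (below 0 no agreement, 0–0.20 slight,
0.21–0.40 fair, 0.41–0.60 moderate, 0.61–0.80 substantial, over 0.81
perfect). Error rates are the false-negative rate and false-positive
rate; see "Numerical choices" for the two FNR denominators.

```{r model}
tab <- contingency_table(tp = 214, fn = 152, fp = 0, tn = 49)
agreement_summary(tab)
```

## The pipeline

`run_validate()` wires the stages together: parse the query list,
manifest and per-reference tool outputs; index the manifest by locus;
call membership per query; join with claims and classify; tabulate per
trait and pooled; and emit summary tables, a per-SNP report and a
machine-readable `stats.json`.

```{r pipeline}
fx <- metabochip_fixture()
res <- run_validate(fx$queries, fx$manifest, fx$claims)
res$summaries$HapMap3
```

A pleiotropic SNP (associated with more than one trait) contributes to
each of its traits' rows but is counted once in the `TOTAL` row, so
per-trait `n` intentionally sums to more than the pooled `n` (421 trait
memberships over 415 SNPs in the example dataset).

## Tunable parameters

* **Build tag** (`build`, default `"GRCh37"`): pure metadata checked for
  equality; a mismatch is an error, never a silent liftover. All
  positions are 1-based and fully closed, the dbSNP/manifest convention.
* **Chromosome normalization**: `chr` prefixes stripped, `X/Y/MT`
  uppercased, numeric aliases `23/24/26` mapped to `X/Y/MT`. Applied at
  parse time and defensively inside the index, so the two sources'
  conventions can differ freely.
* **Dialects** (`query_dialect()`, `manifest_dialect()`): delimiter and
  column-name mappings. Defaults: TSV `rsid/chrom/pos/trait` for query
  lists, CSV `Name/Chr/MapInfo/RsID` for manifests (the vendor-file
  shape), TSV `rsid/array/available/warning` for tool outputs. The exact
  layout of real SNAP output is not standardised; the schema here is a
  configurable reconstruction.
* **Trait order** (`trait_order`): row order of summary tables; defaults
  to order of first appearance.

## The synthetic generator

`simulate_audit()` draws a world whose defaults are the audit's stated
conditions: a 196,725-probe manifest on a GRCh37-sized coordinate space
(22 autosomes + X, length-weighted), 415 query SNPs of which 366/415 are
truly on the chip, per-reference miss rates of 152/366 (HapMap3-like)
and 73/366 (1000-Genomes-like) on on-chip SNPs, zero false positives, a
37/39/69/276 trait mix and 6 pleiotropic SNPs; 90% of probes carry an
rsID (a value we chose as realistic for vendor files, which the audit
only describes qualitatively). One seeded generator drives every draw,
so a fixed seed gives byte-identical outputs, and a truth table records
each SNP's real membership and injected claim for exact scoring.

What it does **not** emulate: LD structure, allele frequencies, strand,
indels, or genotype data. A green simulation test therefore establishes
that the pipeline's bookkeeping and statistics are correct under the
stated membership/claim structure — not that any particular real tool
behaves this way.

`metabochip_fixture()` is different in kind: a *constructed*, fully
deterministic dataset whose trait/status blocks are laid out so that
classification reproduces the target 2×2 tables exactly. It exists so
the end-to-end acceptance checks are exact rather than stochastic.

## Numerical choices

* **FNR duality.** The textbook false-negative rate divides by the SNPs
  truly on the chip (`fn / (tp + fn)`); published audit tables of this
  design instead quote `fn / n` (152/415 = 36.6%). Both are computed
  (`false_negative_rate(mode =)`); reporting defaults to the
  all-SNPs-denominator so printed tables reproduce, and the summary
  object carries both.
* **Degenerate kappa.** When the table is concentrated in a single
  diagonal cell, `Pr(a) = Pr(e) = 1` and the ratio is 0/0; we define
  kappa = 1: the raters agree on every item, and the convention is
  required for an all-concordant trait group to report 1.000.
* **Rounding** is half-away-from-zero (`round_half_away()`): kappa to 3
  decimals, percentages to 1 decimal, matching agreement-table
  typography; base R's round-half-to-even would misprint boundary cases
  such as 0.2495.
* **Band edges.** Bands are applied to the rounded kappa; "over 0.81"
  is read as κ ≥ 0.81 perfect, with 0.80 < κ < 0.81 still substantial.
  κ = 0 falls in the slight band per the threshold table, although prose
  descriptions sometimes call exactly zero "no agreement" — only
  negative values get that label here.
* **Zero denominators.** Direct calls to `false_positive_rate()` or the
  formula-mode FNR with an empty denominator are errors; inside
  `agreement_summary()` they degrade to `NA` so an all-on-chip trait
  group can still be summarised.
* **Ties and degenerate inputs.** Several probes at one locus are all
  reported (`matched_probes`); two query SNPs at one position are both
  matched and flagged in the log; an empty record set tabulates to an
  all-zero table, for which kappa is undefined (error).

## Reconstructing cells from published marginals

Audit tables often print only `n`, concordances, discordances and a
rounded kappa. `reconstruct_split()` enumerates every integer split
`tp + tn = concordances` and keeps those whose kappa rounds to the
printed value. A structural fact limits what one row can tell you:
`Pr(e)` is symmetric in the diagonal cells, so kappa is invariant under
swapping `tp` and `tn` — admissible splits come in mirror pairs, and a
row alone determines the cells only up to that reflection.

```{r reconstruct}
reconstruct_split(n = 37, concordances = 28, fn = 9, fp = 0,
                  kappa_printed = 0.469)
```

In a two-reference audit the reflection is resolved by structure: a
trait's off-chip count `tn` cannot depend on the reference panel, and
its on-chip count `tp + fn` is constant, so intersecting the candidate
`tn` sets across references pins almost every row; an all-concordant
row (where every split has kappa 1) is finally pinned by the pleiotropy
bookkeeping, since per-trait `tn` must sum to the pooled `tn` plus at
most the number of duplicated trait memberships. The acceptance tests
walk through exactly this argument.

## Design choices on open points

* Tool-output schema: reconstructed as TSV with an `available` flag and
  free-text warning column, dialect-tolerant on the warning text (any
  "not in <panel>" maps to `not_in_reference`, mentions of the array to
  `not_on_array`); any warning forces a claimed-absent reading.
* Multiple query SNPs at one locus (tri-allelic sites) are each matched
  and logged, not deduplicated.
* The classifier's ground-truth side is always the manifest; kappa
  itself is symmetric, but the FN/FP vocabulary is anchored to the
  audited tool.
* Pleiotropic SNPs in the fixture all have lipids as the primary trait
  and carry statuses 3 TP, 2 TN, 1 FN — the unique assignment
  compatible with the per-trait/pooled cell differences.

## Limitations

Membership is exact-position on a single build: no liftover, no
allele/strand reconciliation, no indel awareness, and no LD-proxy
search (the audited feature, deliberately not reimplemented). Kappa is
unweighted binary agreement without confidence intervals. The package
audits membership claims; it does not judge why a specific tool fails.
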