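#' Germline subtraction against the matched normal
#'
#' Removes from a tumour sample every variant whose key is observed in the
#' matched normal with alt-supporting read count above the configured
#' tolerance (`max_normal_alt`, default 9: normal support of 10 or more
#' reads marks a germline variant). Tumour variants absent from the normal
#' table, or present with only trace support, are retained unchanged.
#'
#' @param tumour Variant data frame for one tumour site.
#' @param normal Variant data frame for the matched normal; required — the
#'   pipeline operates on trios, never on tumour-only samples.
#' @param cfg A [filter_config()].
#' @return The somatic subset of `tumour`.
#' @export
subtract_germline <- function(tumour, normal, cfg = filter_config()) {
  if (is.null(normal))
    stop("germline subtraction requires the matched normal sample")
  tumour <- as.data.frame(tumour)
  normal <- as.data.frame(normal)
  if (nrow(tumour) == 0) return(tumour)
  germline_keys <- variant_key(normal[normal$alt_count > cfg$max_normal_alt, ,
                                      drop = FALSE])
  keep <- !(variant_key(tumour) %in% germline_keys)
  out <- tumour[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-variant evidence verdict; returns "" for a pass or the first failing
# criterion. Vectorised over rows.
evidence_reason <- function(variants, cfg) {
  n <- nrow(variants)
  if (n == 0) return(character(0))
  balance <- ifelse(variants$alt_count > 0,
                    pmin(variants$alt_fwd, variants$alt_rev) / variants$alt_count,
                    0)
  vaf <- ifelse(variants$depth > 0, variants$alt_count / variants$depth, NA_real_)
  reason <- character(n)
  reason[is.na(vaf)] <- "no_coverage"
  ok <- reason == ""
  reason[ok & variants$alt_count < cfg$min_alt_count] <- "low_alt_count"
  ok <- reason == ""
  reason[ok & variants$depth < cfg$min_depth] <- "low_depth"
  ok <- reason == ""
  reason[ok & vaf < cfg$min_vaf] <- "low_vaf"
  ok <- reason == ""
  reason[ok & balance <= cfg$strand_balance_min] <- "strand_bias"
  reason
}

annotation_reason <- function(variants, cfg) {
  n <- nrow(variants)
  if (n == 0) return(character(0))
  reason <- character(n)
  unknown <- !variants$consequence %in% CONSEQUENCE_LEVELS
  reason[unknown] <- "unknown_consequence"
  ok <- reason == ""
  reason[ok & variants$pop_freq >= cfg$max_population_freq] <- "common_polymorphism"
  ok <- reason == ""
  reason[ok & !variants$consequence %in% cfg$kept_consequences] <- "consequence_class"
  ok <- reason == ""
  reason[ok & !variants$pathogenicity %in% cfg$kept_pathogenicity] <- "pathogenicity"
  reason
}

#' Evidence filters: read support, depth, VAF, strand balance
#'
#' Keeps variants with `alt_count >= min_alt_count` (default "more than
#' 5"), `depth >= min_depth` ("more than 9"), `vaf >= min_vaf`, and a
#' per-strand alt-read balance `min(alt_fwd, alt_rev)/alt_count` strictly
#' greater than `strand_balance_min`.
#'
#' @param variants Germline-subtracted variant data frame.
#' @param cfg A [filter_config()].
#' @return The passing subset. The excluded rows, together with the first
#'   failing criterion, are attached as a data frame in
#'   `attr(, "excluded")` (columns of the input plus `reason`).
#' @export
apply_evidence_filters <- function(variants, cfg = filter_config()) {
  variants <- as.data.frame(variants)
  reason <- evidence_reason(variants, cfg)
  out <- variants[reason == "", , drop = FALSE]
  rownames(out) <- NULL
  excl <- variants[reason != "", , drop = FALSE]
  if (nrow(excl) > 0) excl$reason <- reason[reason != ""]
  attr(out, "excluded") <- excl
  out
}

#' Annotation filters: population frequency, consequence, pathogenicity
#'
#' Keeps variants that are rare in the population
#' (`pop_freq < max_population_freq`, default "below 1%"), carry a
#' protein-changing consequence from `kept_consequences`, and are
#' annotated `pathogenic` or `likely_pathogenic`. A consequence string
#' outside the known vocabulary is excluded with a warning and tallied
#' under its own reason, never silently kept.
#'
#' @param variants Evidence-filtered variant data frame.
#' @param cfg A [filter_config()].
#' @return The passing subset, excluded rows in `attr(, "excluded")`.
#' @export
apply_annotation_filters <- function(variants, cfg = filter_config()) {
  variants <- as.data.frame(variants)
  reason <- annotation_reason(variants, cfg)
  if (any(reason == "unknown_consequence")) {
    warning(sum(reason == "unknown_consequence"),
            " variant(s) with unknown consequence string excluded")
  }
  out <- variants[reason == "", , drop = FALSE]
  rownames(out) <- NULL
  excl <- variants[reason != "", , drop = FALSE]
  if (nrow(excl) > 0) excl$reason <- reason[reason != ""]
  attr(out, "excluded") <- excl
  out
}

#' Run the full somatic filtering cascade on one tumour site
#'
#' Germline subtraction, then evidence filters, then annotation filters.
#' Variants failing a filter are not discarded: they are retained in a
#' side ledger with the failing criterion, so the pair classifier can
#' later inspect sub-threshold evidence at the counterpart site (the
#' programmatic equivalent of re-examining low-frequency calls by eye).
#' Germline-subtracted variants do not enter the ledger — a germline
#' variant must never be rescued as a shared somatic call.
#'
#' @param tumour Variant data frame for one tumour site.
#' @param normal Matched normal variant data frame.
#' @param cfg A [filter_config()].
#' @return A list with elements `pass` (variants surviving all filters)
#'   and `ledger` (somatic variants that failed, with a `reason` column).
#' @export
filter_somatic <- function(tumour, normal, cfg = filter_config()) {
  somatic <- subtract_germline(tumour, normal, cfg)
  ev <- apply_evidence_filters(somatic, cfg)
  ann <- suppressWarnings(apply_annotation_filters(ev, cfg))
  ledger <- rbind(attr(ev, "excluded"), attr(ann, "excluded"))
  if (is.null(ledger) || nrow(ledger) == 0) {
    ledger <- cbind(empty_variant_table(),
                    data.frame(reason = character(0), stringsAsFactors = FALSE))
  }
  rownames(ledger) <- NULL
  pass <- ann
  attr(pass, "excluded") <- NULL
  list(pass = pass, ledger = ledger)
}
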