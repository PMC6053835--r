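#' Somatic filter configuration
#'
#' Bundles every threshold used by the filtering cascade and the
#' shared/private classifier. Defaults reproduce a conventional
#' tumour/normal exome filtering scheme: alt-supporting reads > 5,
#' normal-sample alt support < 10, coverage > 9, variant allele frequency
#' (VAF) and per-strand alt-read balance both above 0.2, population
#' frequency below 1%, and restriction to protein-changing consequences
#' annotated as pathogenic or likely pathogenic.
#'
#' Strictly-greater / strictly-less thresholds are stored as inclusive
#' integer bounds ("> 5" becomes `min_alt_count = 6`) so boundary behaviour
#' is unambiguous: a variant passes when `alt_count >= min_alt_count`,
#' `depth >= min_depth`, and is removed by germline subtraction when the
#' matched-normal alt count exceeds `max_normal_alt`.
#'
#' @param min_alt_count Minimum alt-supporting reads in the tumour sample
#'   (inclusive; default 6, i.e. "more than 5").
#' @param max_normal_alt Maximum tolerated alt-supporting reads in the
#'   matched normal (inclusive; default 9, i.e. "fewer than 10").
#' @param min_depth Minimum total depth at the site (inclusive; default 10).
#' @param strand_balance_min Each variant must have
#'   `min(alt_fwd, alt_rev) / alt_count` strictly greater than this
#'   (default 0.2), guarding against strand-biased artefacts.
#' @param min_vaf Minimum variant allele frequency (inclusive; default 0.2).
#' @param max_population_freq Variants at or above this population
#'   frequency are treated as common polymorphisms and removed
#'   (exclusive bound; default 0.01).
#' @param kept_consequences Character vector of consequence classes
#'   retained by the annotation filter.
#' @param kept_pathogenicity Character vector of pathogenicity labels
#'   retained by the annotation filter.
#' @param rescue_min_alt Minimum alt-supporting reads in the counterpart
#'   site's sub-threshold ledger for a one-site variant to be rescued as
#'   shared (default 2: the smallest evidence distinguishable from a lone
#'   sequencing error).
#' @param counterpart_min_depth Minimum counterpart depth required before a
#'   one-site variant may be called private rather than unevaluable
#'   (default 10, matching the coverage filter).
#'
#' @return An object of class `filter_config` (a named list).
#' @seealso [read_filter_config()] to load a configuration from YAML/JSON.
#' @export
#' @examples
#' cfg <- filter_config()
#' cfg$min_alt_count
#' strict <- filter_config(min_vaf = 0.1)
filter_config <- function(min_alt_count = 6L,
                          max_normal_alt = 9L,
                          min_depth = 10L,
                          strand_balance_min = 0.2,
                          min_vaf = 0.2,
                          max_population_freq = 0.01,
                          kept_consequences = c("loss_of_function", "frameshift",
                                                "inframe", "stop_codon", "missense"),
                          kept_pathogenicity = c("pathogenic", "likely_pathogenic"),
                          rescue_min_alt = 2L,
                          counterpart_min_depth = 10L) {
  cfg <- list(
    min_alt_count = as.integer(min_alt_count),
    max_normal_alt = as.integer(max_normal_alt),
    min_depth = as.integer(min_depth),
    strand_balance_min = as.numeric(strand_balance_min),
    min_vaf = as.numeric(min_vaf),
    max_population_freq = as.numeric(max_population_freq),
    kept_consequences = as.character(kept_consequences),
    kept_pathogenicity = as.character(kept_pathogenicity),
    rescue_min_alt = as.integer(rescue_min_alt),
    counterpart_min_depth = as.integer(counterpart_min_depth)
  )
  counts <- c("min_alt_count", "max_normal_alt", "min_depth",
              "rescue_min_alt", "counterpart_min_depth")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop("filter_config: '", f, "' must be a non-negative integer")
  }
  for (f in c("strand_balance_min", "min_vaf", "max_population_freq")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("filter_config: '", f, "' must be a fraction in [0, 1]")
  }
  structure(cfg, class = "filter_config")
}

#' Read a filter configuration from YAML or JSON
#'
#' Unknown fields are rejected so typos in a config file fail loudly
#' rather than silently falling back to a default threshold.
#'
#' @param path Path to a YAML or JSON file whose top-level keys are
#'   arguments of [filter_config()].
#' @return A `filter_config` object.
#' @export
read_filter_config <- function(path) {
  if (!file.exists(path)) stop("filter config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(filter_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown filter config field(s): ", paste(bad, collapse = ", "))
  do.call(filter_config, raw)
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
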