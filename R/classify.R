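#' Classify somatic variants as shared or private across the tumour pair
#'
#' Every variant passing the filtering cascade in at least one tumour site
#' is assigned a cross-site status on the exact variant key
#' (chrom, pos, ref, alt):
#'
#' * **shared** — the key passes in both sites; or it passes in one site
#'   and the counterpart's sub-threshold ledger holds the same key with at
#'   least `rescue_min_alt` alt-supporting reads (`rescued = TRUE`). The
#'   rescue rule formalises the manual re-inspection of low-frequency
#'   calls: a variant must not be labelled private merely because it sat
#'   just under a filter threshold at the other site.
#' * **private_primary / private_metastasis** — the key passes in exactly
#'   one site, the counterpart ledger shows no rescuable support, and the
#'   counterpart is adequately covered at the position
#'   (depth >= `counterpart_min_depth`). The coverage guard prevents
#'   "private" calls that are artefacts of the other site being unsequenced.
#' * **unevaluable** — a one-site variant whose counterpart coverage is
#'   below the guard (or unknown). Reported, but excluded from every
#'   concordance denominator.
#'
#' @param primary_pass,metastasis_pass Variants passing all filters in
#'   each site.
#' @param primary_ledger,metastasis_ledger Sub-threshold observations for
#'   each site (the `ledger` component of [filter_somatic()]); rows with
#'   `alt_count = 0` act as pure coverage observations.
#' @param cfg A [filter_config()].
#' @return A data frame of paired variants: `chrom, pos, ref, alt, gene,
#'   sift, status, rescued, vaf_primary, vaf_metastasis, delta_vaf`
#'   (`delta_vaf` in percentage points, metastasis minus primary).
#' @export
classify_pair <- function(primary_pass, metastasis_pass,
                          primary_ledger = NULL, metastasis_ledger = NULL,
                          cfg = filter_config()) {
  p_pass <- as.data.frame(primary_pass)
  m_pass <- as.data.frame(metastasis_pass)
  p_led <- if (is.null(primary_ledger)) empty_variant_table() else as.data.frame(primary_ledger)
  m_led <- if (is.null(metastasis_ledger)) empty_variant_table() else as.data.frame(metastasis_ledger)

  pk <- variant_key(p_pass)
  mk <- variant_key(m_pass)
  plk <- variant_key(p_led)
  mlk <- variant_key(m_led)

  keys <- union(pk, mk)
  n <- length(keys)
  if (n == 0) return(empty_paired_table())

  # annotation columns from whichever site passed (identical keys carry
  # identical annotations in well-formed input; primary wins on ties)
  src <- rbind(
    p_pass[, c("chrom", "pos", "ref", "alt", "gene", "sift"), drop = FALSE],
    m_pass[, c("chrom", "pos", "ref", "alt", "gene", "sift"), drop = FALSE]
  )
  src <- src[!duplicated(variant_key(src)), , drop = FALSE]
  src <- src[match(keys, variant_key(src)), , drop = FALSE]

  vaf_of <- function(tab, tab_keys, keys) {
    idx <- match(keys, tab_keys)
    ifelse(is.na(idx), NA_real_, tab$vaf[idx])
  }
  alt_of <- function(tab, tab_keys, keys) {
    idx <- match(keys, tab_keys)
    ifelse(is.na(idx), NA_integer_, tab$alt_count[idx])
  }
  depth_of <- function(tab, tab_keys, keys) {
    idx <- match(keys, tab_keys)
    ifelse(is.na(idx), NA_integer_, tab$depth[idx])
  }

  in_p <- keys %in% pk
  in_m <- keys %in% mk

  vaf_p <- vaf_of(p_pass, pk, keys)
  vaf_m <- vaf_of(m_pass, mk, keys)

  led_alt_p <- alt_of(p_led, plk, keys)
  led_alt_m <- alt_of(m_led, mlk, keys)
  led_vaf_p <- vaf_of(p_led, plk, keys)
  led_vaf_m <- vaf_of(m_led, mlk, keys)
  led_depth_p <- depth_of(p_led, plk, keys)
  led_depth_m <- depth_of(m_led, mlk, keys)

  status <- character(n)
  rescued <- logical(n)

  both <- in_p & in_m
  status[both] <- "shared"

  p_only <- in_p & !in_m
  m_only <- in_m & !in_p

  # rescue: counterpart ledger holds sub-threshold support for the key
  resc_m <- p_only & !is.na(led_alt_m) & led_alt_m >= cfg$rescue_min_alt
  resc_p <- m_only & !is.na(led_alt_p) & led_alt_p >= cfg$rescue_min_alt
  status[resc_m | resc_p] <- "shared"
  rescued[resc_m | resc_p] <- TRUE
  vaf_m[resc_m] <- led_vaf_m[resc_m]
  vaf_p[resc_p] <- led_vaf_p[resc_p]

  # coverage guard for the remaining one-site calls
  rem_p <- p_only & !resc_m
  rem_m <- m_only & !resc_p
  cov_m <- !is.na(led_depth_m) & led_depth_m >= cfg$counterpart_min_depth
  cov_p <- !is.na(led_depth_p) & led_depth_p >= cfg$counterpart_min_depth
  status[rem_p & cov_m] <- "private_primary"
  status[rem_p & !cov_m] <- "unevaluable"
  status[rem_m & cov_p] <- "private_metastasis"
  status[rem_m & !cov_p] <- "unevaluable"
  n_unknown_cov <- sum((rem_p & is.na(led_depth_m)) | (rem_m & is.na(led_depth_p)))
  if (n_unknown_cov > 0)
    warning(n_unknown_cov, " one-site variant(s) with unknown counterpart ",
            "coverage classified as unevaluable")

  out <- data.frame(
    chrom = src$chrom, pos = src$pos, ref = src$ref, alt = src$alt,
    gene = src$gene, sift = src$sift,
    status = status, rescued = rescued,
    vaf_primary = vaf_p, vaf_metastasis = vaf_m,
    delta_vaf = ifelse(status == "shared", (vaf_m - vaf_p) * 100, NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

empty_paired_table <- function() {
  data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), gene = character(0), sift = character(0),
    status = character(0), rescued = logical(0),
    vaf_primary = numeric(0), vaf_metastasis = numeric(0),
    delta_vaf = numeric(0), clonality_shift = logical(0),
    stringsAsFactors = FALSE
  )
}

#' Flag clonality shifts among shared variants
#'
#' A shared variant whose allele frequency rises by strictly more than
#' `threshold` percentage points from the primary tumour to the metastasis
#' is flagged as a clonality shift — the signature of a subclone in the
#' primary expanding to (near-)clonality in the metastasis. A rise of
#' exactly `threshold` points is not flagged.
#'
#' VAFs are compared raw by default; when both `purity_primary` and
#' `purity_metastasis` are supplied, each VAF is divided by its sample's
#' purity first, correcting for normal-cell dilution.
#'
#' @param paired Output of [classify_pair()].
#' @param threshold Shift threshold in percentage points (default 30).
#' @param purity_primary,purity_metastasis Optional tumour-cell fractions
#'   in (0, 1] used to scale the VAFs before differencing.
#' @return `paired` with a logical `clonality_shift` column (NA for
#'   non-shared rows) and `delta_vaf` recomputed on the compared scale.
#' @export
detect_clonality_shifts <- function(paired, threshold = 30,
                                    purity_primary = NULL,
                                    purity_metastasis = NULL) {
  paired <- as.data.frame(paired)
  if (nrow(paired) == 0) {
    paired$clonality_shift <- logical(0)
    return(paired)
  }
  vp <- paired$vaf_primary
  vm <- paired$vaf_metastasis
  if (!is.null(purity_primary) && !is.null(purity_metastasis)) {
    stopifnot(purity_primary > 0, purity_primary <= 1,
              purity_metastasis > 0, purity_metastasis <= 1)
    vp <- vp / purity_primary
    vm <- vm / purity_metastasis
  }
  delta <- (vm - vp) * 100
  shared <- paired$status == "shared"
  paired$delta_vaf <- ifelse(shared, delta, NA_real_)
  # strict inequality, robust to binary representation of the VAF ratio:
  # a rise of exactly `threshold` points never flags
  paired$clonality_shift <- ifelse(shared, delta > threshold + 1e-9, NA)
  paired
}
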