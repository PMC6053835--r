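VARIANT_COLUMNS <- c("chrom", "pos", "ref", "alt", "depth", "alt_count",
                     "alt_fwd", "alt_rev", "gene", "consequence", "pop_freq",
                     "sift", "pathogenicity")

CONSEQUENCE_LEVELS <- c("loss_of_function", "frameshift", "inframe",
                        "stop_codon", "missense", "other")
SIFT_LEVELS <- c("tolerated", "damaging", "activating", "unknown")
PATHOGENICITY_LEVELS <- c("pathogenic", "likely_pathogenic", "other")

#' Variant key
#'
#' Variants are identified across samples and sites by the tuple
#' (chrom, pos, ref, alt) — the exact nucleotide change, never merely the
#' gene. All set operations in the pipeline run on this key.
#'
#' @param variants A variant data frame.
#' @return Character vector of keys, `"chrom:pos:ref>alt"`.
#' @export
variant_key <- function(variants) {
  if (nrow(variants) == 0) return(character(0))
  paste0(variants$chrom, ":", variants$pos, ":", variants$ref, ">", variants$alt)
}

empty_variant_table <- function() {
  data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), depth = integer(0), alt_count = integer(0),
    alt_fwd = integer(0), alt_rev = integer(0), gene = character(0),
    consequence = character(0), pop_freq = numeric(0), sift = character(0),
    pathogenicity = character(0), vaf = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Validate and finalise a variant call table
#'
#' Checks the evidence-consistency invariants (`alt_count <= depth`,
#' `alt_fwd + alt_rev == alt_count`, non-negative counts), normalises
#' indel representation (left trims shared suffix/prefix bases so the same
#' indel written two ways gets one key), recomputes the VAF column, and
#' rejects duplicate keys within the sample.
#'
#' @param variants Data frame with the columns of the trio TSV dialect.
#' @param sample_label Label used in error messages.
#' @return The validated data frame with a `vaf` column (NA when depth 0).
#' @export
as_variant_table <- function(variants, sample_label = "sample") {
  missing_cols <- setdiff(VARIANT_COLUMNS, names(variants))
  if (length(missing_cols) > 0)
    stop("variant table for '", sample_label, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  v <- as.data.frame(variants)[, VARIANT_COLUMNS]
  if (nrow(v) == 0) return(empty_variant_table())

  v$chrom <- as.character(v$chrom)
  v$pos <- as.integer(v$pos)
  v$ref <- toupper(as.character(v$ref))
  v$alt <- toupper(as.character(v$alt))
  for (col in c("depth", "alt_count", "alt_fwd", "alt_rev"))
    v[[col]] <- as.integer(v[[col]])
  v$gene <- as.character(v$gene)
  v$gene[is.na(v$gene)] <- ""
  v$consequence <- as.character(v$consequence)
  v$pop_freq <- as.numeric(v$pop_freq)
  v$sift <- as.character(v$sift)
  v$pathogenicity <- as.character(v$pathogenicity)

  if (anyNA(v$pos) || any(v$pos < 1))
    stop("'", sample_label, "': positions must be 1-based positive integers")
  counts <- c("depth", "alt_count", "alt_fwd", "alt_rev")
  for (col in counts) {
    if (anyNA(v[[col]]) || any(v[[col]] < 0))
      stop("'", sample_label, "': column '", col, "' must be non-negative counts")
  }
  bad <- v$alt_count > v$depth
  if (any(bad))
    stop("'", sample_label, "': alt_count exceeds depth at ",
         paste(variant_key(v[bad, , drop = FALSE]), collapse = ", "),
         " (evidence-consistency violation)")
  bad <- (v$alt_fwd + v$alt_rev) != v$alt_count
  if (any(bad))
    stop("'", sample_label, "': alt_fwd + alt_rev must equal alt_count at ",
         paste(variant_key(v[bad, , drop = FALSE]), collapse = ", "))
  if (anyNA(v$pop_freq) || any(v$pop_freq < 0 | v$pop_freq > 1))
    stop("'", sample_label, "': pop_freq must lie in [0, 1]")

  norm <- normalize_allele(v$pos, v$ref, v$alt)
  v$pos <- norm$pos
  v$ref <- norm$ref
  v$alt <- norm$alt

  v$vaf <- ifelse(v$depth > 0, v$alt_count / v$depth, NA_real_)

  keys <- variant_key(v)
  if (anyDuplicated(keys))
    stop("'", sample_label, "': duplicate variant key(s) within one sample: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  rownames(v) <- NULL
  v
}

# Minimal indel normalization for cross-site identity: drop common
# trailing bases, then common leading bases (advancing pos), keeping at
# least one base on each allele. Equivalent representations of the same
# left-aligned indel collapse to one key; SNVs are untouched.
normalize_allele <- function(pos, ref, alt) {
  n <- length(pos)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]
    if (nchar(r) == 1 && nchar(a) == 1) next
    rr <- strsplit(r, "")[[1]]; aa <- strsplit(a, "")[[1]]
    while (length(rr) > 1 && length(aa) > 1 &&
           rr[length(rr)] == aa[length(aa)]) {
      rr <- rr[-length(rr)]; aa <- aa[-length(aa)]
    }
    while (length(rr) > 1 && length(aa) > 1 && rr[1] == aa[1]) {
      rr <- rr[-1]; aa <- aa[-1]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(rr, collapse = ""); alt[i] <- paste(aa, collapse = "")
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Read a variant table from the trio TSV dialect
#'
#' The dialect is a plain tab-separated file with header columns
#' `chrom, pos, ref, alt, depth, alt_count, alt_fwd, alt_rev, gene,
#' consequence, pop_freq, sift, pathogenicity`. Positions are 1-based.
#'
#' @param path File path.
#' @param sample_label Label used in error messages (defaults to the file name).
#' @return A validated variant data frame.
#' @export
read_variant_tsv <- function(path, sample_label = basename(path)) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0) {
    missing_cols <- setdiff(VARIANT_COLUMNS, names(raw))
    if (length(missing_cols) > 0)
      stop("variant table for '", sample_label,
           "' is missing required column(s): ",
           paste(missing_cols, collapse = ", "))
    return(empty_variant_table())
  }
  as_variant_table(raw, sample_label = sample_label)
}

#' Write a variant table in the trio TSV dialect
#'
#' @param variants Variant data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variant_tsv <- function(variants, path) {
  out <- as.data.frame(variants)[, VARIANT_COLUMNS, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant table from a VCF file
#'
#' Supports VCF 4.x files carrying per-variant evidence and annotations in
#' INFO: `DP` (total depth), `AO` (alt-supporting reads, one value per alt
#' allele), `SAF`/`SAR` (alt-supporting reads on the forward/reverse
#' strand, per alt allele), and annotation keys `GENE`, `CSQ`
#' (consequence class), `PF` (population frequency), `SIFT`, `PATHO`.
#' Multi-allelic records are split into one row per alternate allele;
#' per-allele INFO values are taken positionally.
#'
#' @param path Path to a (possibly uncompressed) VCF file.
#' @param sample_label Label used in error messages.
#' @return A validated variant data frame.
#' @export
read_variant_vcf <- function(path, sample_label = basename(path)) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the 'vcfR' package")
  if (!file.exists(path)) stop("variant file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_variant_table())
  info_field <- function(key) vcfR::extract.info(vcf, element = key)

  need <- c("DP", "AO", "SAF", "SAR", "GENE", "CSQ", "PF", "SIFT", "PATHO")
  info <- lapply(need, info_field)
  names(info) <- need
  for (key in need) {
    if (all(is.na(info[[key]])))
      stop("VCF '", sample_label, "' is missing required INFO field: ", key)
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    nalt <- length(alts)
    per_allele <- function(key) {
      vals <- strsplit(as.character(info[[key]][i]), ",", fixed = TRUE)[[1]]
      if (length(vals) == 1) vals <- rep(vals, nalt)
      if (length(vals) != nalt)
        stop("VCF '", sample_label, "': INFO/", key, " has ", length(vals),
             " values for ", nalt, " alt allele(s) at ",
             fix$CHROM[i], ":", fix$POS[i])
      vals
    }
    rows[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = fix$REF[i],
      alt = alts,
      depth = as.integer(per_allele("DP")[1]),
      alt_count = as.integer(per_allele("AO")),
      alt_fwd = as.integer(per_allele("SAF")),
      alt_rev = as.integer(per_allele("SAR")),
      gene = per_allele("GENE"),
      consequence = per_allele("CSQ"),
      pop_freq = as.numeric(per_allele("PF")),
      sift = per_allele("SIFT"),
      pathogenicity = per_allele("PATHO"),
      stringsAsFactors = FALSE
    )
  }
  as_variant_table(do.call(rbind, rows), sample_label = sample_label)
}

read_variant_file <- function(path, sample_label = basename(path)) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_variant_vcf(path, sample_label)
  } else {
    read_variant_tsv(path, sample_label)
  }
}

#' Assemble a patient trio
#'
#' A trio is the unit of analysis: the variant calls of the primary
#' tumour, the synchronous metastasis, and the matched normal sample of
#' one patient, plus the clinical covariates used by the cohort contrasts.
#'
#' @param patient_id Patient identifier.
#' @param primary,metastasis,normal Variant data frames (validated with
#'   [as_variant_table()]).
#' @param sidedness `"right"` or `"left"` primary tumour location.
#' @param neoadjuvant Logical; neoadjuvant chemotherapy given.
#' @param resection_order One of `"concurrent"`, `"liver_first"`,
#'   `"primary_first"`.
#' @return An object of class `patient_trio`.
#' @export
patient_trio <- function(patient_id, primary, metastasis, normal,
                         sidedness = c("right", "left"),
                         neoadjuvant = FALSE,
                         resection_order = c("concurrent", "liver_first",
                                             "primary_first")) {
  sidedness <- match.arg(sidedness)
  resection_order <- match.arg(resection_order)
  structure(list(
    patient_id = as.character(patient_id),
    primary = as_variant_table(primary, "primary"),
    metastasis = as_variant_table(metastasis, "metastasis"),
    normal = as_variant_table(normal, "normal"),
    sidedness = sidedness,
    neoadjuvant = isTRUE(neoadjuvant),
    resection_order = resection_order
  ), class = "patient_trio")
}

#' @export
print.patient_trio <- function(x, ...) {
  cat(sprintf(
    "<patient_trio %s> primary: %d, metastasis: %d, normal: %d variants; %s-sided, %s%s\n",
    x$patient_id, nrow(x$primary), nrow(x$metastasis), nrow(x$normal),
    x$sidedness, x$resection_order,
    if (x$neoadjuvant) ", neoadjuvant" else ""))
  invisible(x)
}

#' Load a patient trio from files
#'
#' @param primary_path,metastasis_path,normal_path Paths to variant files,
#'   each in the trio TSV dialect or VCF (by extension).
#' @param metadata_row A one-row data frame (or named list) with fields
#'   `patient_id`, `sidedness`, `neoadjuvant`, `resection_order`.
#' @return A `patient_trio`.
#' @export
load_trio <- function(primary_path, metastasis_path, normal_path, metadata_row) {
  md <- as.list(metadata_row)
  need <- c("patient_id", "sidedness", "neoadjuvant", "resection_order")
  missing_md <- setdiff(need, names(md))
  if (length(missing_md) > 0)
    stop("trio metadata is missing field(s): ", paste(missing_md, collapse = ", "))
  patient_trio(
    patient_id = md$patient_id,
    primary = read_variant_file(primary_path, paste0(md$patient_id, ":primary")),
    metastasis = read_variant_file(metastasis_path, paste0(md$patient_id, ":metastasis")),
    normal = read_variant_file(normal_path, paste0(md$patient_id, ":normal")),
    sidedness = as.character(md$sidedness),
    neoadjuvant = as.logical(md$neoadjuvant),
    resection_order = as.character(md$resection_order)
  )
}

#' Read a cohort metadata table
#'
#' @param path TSV with columns `patient_id, sidedness, neoadjuvant,
#'   resection_order`.
#' @return Data frame, one row per patient.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "sidedness", "neoadjuvant", "resection_order")
  missing_md <- setdiff(need, names(md))
  if (length(missing_md) > 0)
    stop("metadata table is missing column(s): ",
         paste(missing_md, collapse = ", "))
  md$patient_id <- as.character(md$patient_id)
  md$neoadjuvant <- as.logical(md$neoadjuvant)
  bad <- !md$sidedness %in% c("right", "left")
  if (any(bad)) stop("metadata: sidedness must be 'right' or 'left'")
  bad <- !md$resection_order %in% c("concurrent", "liver_first", "primary_first")
  if (any(bad))
    stop("metadata: resection_order must be concurrent/liver_first/primary_first")
  md
}
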