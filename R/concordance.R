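TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

is_snv <- function(ref, alt) {
  nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
}

#' Transition/transversion counts and ratio
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine
#' substitutions (A<->G, C<->T); every other single-base substitution is a
#' transversion. Classification is strand-symmetric: complementing
#' ref and alt never changes the class. Indels and multi-nucleotide
#' changes are excluded from both counts and reported separately.
#'
#' @param variants Data frame with `ref` and `alt` columns.
#' @return List with `ti_count`, `tv_count`, `indel_count` (non-SNV rows),
#'   and `ratio` (`NA` when there are no transversions).
#' @export
#' @examples
#' titv(data.frame(ref = c("A", "C", "A"), alt = c("G", "T", "T")))
titv <- function(variants) {
  variants <- as.data.frame(variants)
  snv <- is_snv(variants$ref, variants$alt)
  sub <- paste0(variants$ref[snv], ">", variants$alt[snv])
  ti <- sum(sub %in% TRANSITIONS)
  tv <- sum(!sub %in% TRANSITIONS)
  list(
    ti_count = ti,
    tv_count = tv,
    indel_count = nrow(variants) - (ti + tv),
    ratio = if (tv > 0) ti / tv else NA_real_
  )
}

#' Per-patient concordance summary
#'
#' Aggregates one patient's classified pair list into the quantities the
#' cohort analysis runs on: shared/private counts, mutational burden
#' (shared + private, unevaluable excluded), shared fraction,
#' transition/transversion counts over evaluable SNVs, the SIFT class
#' composition within each status group, and overlap with a supplied
#' driver-gene list (matched by gene symbol, never used as a filter).
#'
#' @param paired Output of [classify_pair()] (optionally after
#'   [detect_clonality_shifts()]).
#' @param driver_genes Character vector of driver gene symbols, or `NULL`.
#' @param patient_id Identifier carried into the summary.
#' @return A `patient_summary` list. `as.data.frame()` yields its scalar
#'   fields as one row.
#' @export
summarize_patient <- function(paired, driver_genes = NULL, patient_id = NA_character_) {
  paired <- as.data.frame(paired)
  ev <- paired[paired$status != "unevaluable", , drop = FALSE]
  n_shared <- sum(ev$status == "shared")
  n_pp <- sum(ev$status == "private_primary")
  n_pm <- sum(ev$status == "private_metastasis")
  burden <- n_shared + n_pp + n_pm
  tt <- titv(ev)

  sift_comp <- sapply(c("shared", "private_primary", "private_metastasis"),
                      function(st) {
    grp <- ev$sift[ev$status == st]
    n <- length(grp)
    classes <- c("tolerated", "damaging", "activating")
    if (n == 0) return(stats::setNames(rep(NA_real_, 3), classes))
    stats::setNames(vapply(classes, function(cl) mean(grp == cl), numeric(1)),
                    classes)
  })

  drv <- if (is.null(driver_genes)) rep(FALSE, nrow(ev)) else ev$gene %in% driver_genes
  n_shift <- if ("clonality_shift" %in% names(ev)) {
    sum(ev$clonality_shift, na.rm = TRUE)
  } else {
    NA_integer_
  }

  structure(list(
    patient_id = as.character(patient_id),
    n_shared = n_shared,
    n_private_primary = n_pp,
    n_private_metastasis = n_pm,
    n_unevaluable = sum(paired$status == "unevaluable"),
    n_rescued = sum(ev$rescued),
    burden = burden,
    shared_fraction = if (burden > 0) n_shared / burden else NA_real_,
    ti_count = tt$ti_count,
    tv_count = tt$tv_count,
    indel_count = tt$indel_count,
    ti_tv_ratio = tt$ratio,
    n_clonality_shift = n_shift,
    n_driver_variants = sum(drv),
    n_driver_private = sum(drv & ev$status != "shared"),
    sift_composition = sift_comp
  ), class = "patient_summary")
}

#' @export
as.data.frame.patient_summary <- function(x, ...) {
  scalars <- x[setdiff(names(x), "sift_composition")]
  as.data.frame(scalars, stringsAsFactors = FALSE)
}

#' @export
print.patient_summary <- function(x, ...) {
  cat(sprintf(
    "<patient_summary %s> burden %d (S %d / PP %d / PM %d, unevaluable %d); shared %.1f%%; TI/TV %s\n",
    x$patient_id, x$burden, x$n_shared, x$n_private_primary,
    x$n_private_metastasis, x$n_unevaluable,
    100 * x$shared_fraction,
    if (is.na(x$ti_tv_ratio)) "NA" else sprintf("%.2f", x$ti_tv_ratio)))
  invisible(x)
}

#' Cohort summary table
#'
#' @param paired_list Named list (by patient id) of classified pair data
#'   frames.
#' @param driver_genes Optional driver gene symbols.
#' @return Data frame with one row per patient (the scalar fields of
#'   [summarize_patient()]).
#' @export
summarize_cohort <- function(paired_list, driver_genes = NULL) {
  stopifnot(!is.null(names(paired_list)))
  rows <- lapply(names(paired_list), function(pid) {
    as.data.frame(summarize_patient(paired_list[[pid]], driver_genes, pid))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-by-patient mutation status matrix
#'
#' The oncoprint-style recurrence matrix: for each gene and patient the
#' cell records `"shared"` when any variant of the gene is shared between
#' the two sites, `"both_private"` when the gene carries (different)
#' private variants at both sites but none shared, `"private_primary"` /
#' `"private_metastasis"` for one-sided private variants, and `"none"`
#' otherwise. Genes are ordered by the number of mutated patients,
#' descending, ties broken alphabetically. Unevaluable variants and
#' variants without a gene symbol are ignored.
#'
#' @param paired_list Named list (by patient id) of classified pair data
#'   frames.
#' @return Character matrix, genes in rows, patients in columns.
#' @export
gene_matrix <- function(paired_list) {
  stopifnot(!is.null(names(paired_list)))
  patients <- names(paired_list)
  per_patient <- lapply(paired_list, function(p) {
    p <- as.data.frame(p)
    p[p$status != "unevaluable" & p$gene != "", , drop = FALSE]
  })
  genes <- sort(unique(unlist(lapply(per_patient, function(p) p$gene))))
  if (length(genes) == 0) {
    return(matrix(character(0), nrow = 0, ncol = length(patients),
                  dimnames = list(character(0), patients)))
  }
  mat <- matrix("none", nrow = length(genes), ncol = length(patients),
                dimnames = list(genes, patients))
  for (pid in patients) {
    p <- per_patient[[pid]]
    for (g in unique(p$gene)) {
      st <- p$status[p$gene == g]
      cell <- if (any(st == "shared")) {
        "shared"
      } else if (any(st == "private_primary") && any(st == "private_metastasis")) {
        "both_private"
      } else if (any(st == "private_primary")) {
        "private_primary"
      } else {
        "private_metastasis"
      }
      mat[g, pid] <- cell
    }
  }
  freq <- rowSums(mat != "none")
  mat[order(-freq, rownames(mat)), , drop = FALSE]
}
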