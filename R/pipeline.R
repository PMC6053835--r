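#' Run the full filter-classify-shift analysis for one trio
#'
#' Applies the somatic filtering cascade to both tumour sites of a trio
#' (germline subtraction against the matched normal, evidence filters,
#' annotation filters), classifies every surviving variant as shared or
#' private with rescue and coverage guards, and flags clonality shifts.
#'
#' @param trio A [patient_trio()].
#' @param cfg A [filter_config()].
#' @param shift_threshold Clonality-shift threshold in VAF percentage
#'   points (default 30).
#' @return A classified pair data frame (see [classify_pair()]) with the
#'   `clonality_shift` column.
#' @export
analyze_trio <- function(trio, cfg = filter_config(), shift_threshold = 30) {
  p <- filter_somatic(trio$primary, trio$normal, cfg)
  m <- filter_somatic(trio$metastasis, trio$normal, cfg)
  paired <- classify_pair(p$pass, m$pass, p$ledger, m$ledger, cfg)
  detect_clonality_shifts(paired, threshold = shift_threshold)
}

default_pipeline_config <- function() {
  list(
    simulate = NULL,      # sim_scenario() arguments, or NULL
    trios = NULL,         # data frame/list: patient_id, primary, metastasis, normal paths
    metadata = NULL,      # path to metadata TSV (file-based cohorts)
    driver_genes = NULL,  # path to a plain-text gene list, or NULL for default
    filter = list(),      # filter_config() arguments
    shift_threshold = 30,
    cna = TRUE,           # run the CNA stage (simulated cohorts)
    seed = 1L
  )
}

#' Run the end-to-end cohort pipeline
#'
#' Orchestrates every stage over a cohort — simulate (or load) trios,
#' filter, classify, summarise, contrast, and compare copy-number
#' profiles — and writes versioned stage outputs plus one aggregate
#' `cohort.json` to the output directory:
#'
#' * `paired_variants.tsv` — per-variant status for every patient;
#' * `cohort_summary.tsv` — one row per patient;
#' * `gene_matrix.tsv` — oncoprint-style gene x patient matrix;
#' * `contrasts.json` — burden and shared-fraction contrasts by
#'   sidedness, neoadjuvant status, and resection order;
#' * `cna_segments.tsv`, `cna_pair_counts.tsv` (when the CNA stage runs);
#' * `cohort.json` — the aggregate report;
#' * `run.log` — every threshold in effect.
#'
#' A configured seed makes the whole run reproducible: two runs with the
#' same config produce byte-identical `cohort.json`.
#'
#' @param config Path to a YAML config, or an equivalent named list.
#'   Recognised fields: `simulate` (list of [sim_scenario()] arguments —
#'   presence selects simulation), `trios` + `metadata` (file-based
#'   cohort), `driver_genes`, `filter` (list of [filter_config()]
#'   arguments), `shift_threshold`, `cna`, `seed`.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, the cohort report list (the content of `cohort.json`).
#' @export
run_pipeline <- function(config = list(simulate = list()), out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("pipeline config not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg_full <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(..., "\n", sep = "", file = log_path,
                                append = TRUE)
  cat("", file = log_path)

  fcfg <- do.call(filter_config, cfg_full$filter)
  log_line("stage=config filter thresholds:")
  for (nm in names(fcfg)) log_line("  ", nm, " = ",
                                   paste(fcfg[[nm]], collapse = ","))

  drivers <- if (is.null(cfg_full$driver_genes)) {
    default_driver_genes()
  } else {
    if (!file.exists(cfg_full$driver_genes))
      stop("stage=input driver gene list not found: ", cfg_full$driver_genes)
    readLines(cfg_full$driver_genes)
  }

  # --- load or simulate ---------------------------------------------------
  cna_sim <- NULL
  scenario <- NULL
  if (!is.null(cfg_full$simulate)) {
    scenario <- do.call(sim_scenario, cfg_full$simulate)
    cohort <- simulate_cohort(scenario, seed = cfg_full$seed)
    trios <- cohort$trios
    metadata <- cohort$metadata
    truth <- cohort$truth
    if (isTRUE(cfg_full$cna))
      cna_sim <- simulate_cna_profiles(scenario, seed = cfg_full$seed)
    log_line("stage=simulate patients=", length(trios),
             " seed=", cfg_full$seed)
  } else {
    if (is.null(cfg_full$trios) || is.null(cfg_full$metadata))
      stop("stage=input config must provide either a 'simulate' block or ",
           "'trios' and 'metadata'")
    if (!file.exists(cfg_full$metadata))
      stop("stage=input metadata file not found: ", cfg_full$metadata)
    metadata <- read_metadata(cfg_full$metadata)
    trio_spec <- cfg_full$trios
    if (is.list(trio_spec) && !is.data.frame(trio_spec))
      trio_spec <- do.call(rbind, lapply(trio_spec, as.data.frame))
    trios <- list()
    for (i in seq_len(nrow(trio_spec))) {
      pid <- as.character(trio_spec$patient_id[i])
      md <- metadata[metadata$patient_id == pid, , drop = FALSE]
      if (nrow(md) != 1)
        stop("stage=input metadata row missing for patient ", pid)
      trios[[pid]] <- load_trio(trio_spec$primary[i], trio_spec$metastasis[i],
                                trio_spec$normal[i], md)
    }
    truth <- NULL
    log_line("stage=load patients=", length(trios))
  }

  # --- filter + classify --------------------------------------------------
  paired_list <- lapply(trios, analyze_trio, cfg = fcfg,
                        shift_threshold = cfg_full$shift_threshold)
  paired_tsv <- do.call(rbind, lapply(names(paired_list), function(pid) {
    p <- paired_list[[pid]]
    if (nrow(p) == 0) return(NULL)
    cbind(data.frame(patient_id = pid, stringsAsFactors = FALSE), p)
  }))
  utils::write.table(paired_tsv, file.path(out_dir, "paired_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("stage=classify variants=", nrow(paired_tsv))

  # --- summarise ----------------------------------------------------------
  summary_df <- summarize_cohort(paired_list, drivers)
  summary_df <- merge(summary_df, metadata, by = "patient_id", sort = TRUE)
  utils::write.table(summary_df, file.path(out_dir, "cohort_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- gene_matrix(paired_list)
  utils::write.table(cbind(gene = rownames(gm), as.data.frame(gm)),
                     file.path(out_dir, "gene_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("stage=summarize patients=", nrow(summary_df),
           " genes=", nrow(gm))

  # --- contrasts ----------------------------------------------------------
  by_group <- function(metric, grouping) {
    vals <- split(summary_df[[metric]], summary_df[[grouping]])
    vals <- lapply(vals, function(v) v[!is.na(v)])
    vals[lengths(vals) > 0]
  }
  contrasts <- list()
  safe_contrast <- function(groups, kind) {
    if (length(groups) < 2) return(NULL)
    ct <- contrast(groups, kind)
    ct$group_medians <- lapply(groups, stats::median)
    ct
  }
  contrasts$burden_by_sidedness <-
    safe_contrast(by_group("burden", "sidedness"), "mann_whitney")
  contrasts$shared_fraction_by_sidedness <-
    safe_contrast(by_group("shared_fraction", "sidedness"), "mann_whitney")
  contrasts$burden_by_neoadjuvant <-
    safe_contrast(by_group("burden", "neoadjuvant"), "mann_whitney")
  contrasts$shared_fraction_by_resection_order <-
    safe_contrast(by_group("shared_fraction", "resection_order"),
                  "kruskal_wallis")
  contrasts <- contrasts[!vapply(contrasts, is.null, logical(1))]
  jsonlite::write_json(contrasts, file.path(out_dir, "contrasts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("stage=contrast tests=", length(contrasts))

  # --- CNA ----------------------------------------------------------------
  cna_report <- NULL
  if (!is.null(cna_sim)) {
    params <- cna_params()
    chrom_lengths <- stats::setNames(
      rep(scenario$chrom_length, length(scenario$chromosomes)),
      scenario$chromosomes)
    seg_rows <- list(); count_rows <- list()
    for (pid in names(cna_sim$bins)) {
      sp <- classify_span(segment_profile(cna_sim$bins[[pid]]$primary, params),
                          chrom_lengths, params)
      sm <- classify_span(segment_profile(cna_sim$bins[[pid]]$metastasis, params),
                          chrom_lengths, params)
      rep_pair <- compare_pair(sp, sm)
      seg_rows[[pid]] <- rbind(sp, sm)
      cc <- rep_pair$counts
      cc$patient_id <- pid
      count_rows[[pid]] <- cc
    }
    all_seg <- do.call(rbind, seg_rows)
    write_seg(all_seg, file.path(out_dir, "cna_segments.tsv"))
    all_counts <- do.call(rbind, count_rows)
    rownames(all_counts) <- NULL
    utils::write.table(all_counts, file.path(out_dir, "cna_pair_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    agg <- stats::aggregate(n ~ category + span_class + call, all_counts, sum)
    cna_report <- list(
      n_pairs = length(cna_sim$bins),
      event_counts = agg,
      pairs_with_difference = sum(vapply(count_rows, function(cc) {
        sum(cc$n[cc$category %in% c("novel", "lost")]) > 0
      }, logical(1)))
    )
    log_line("stage=cna pairs=", cna_report$n_pairs)
  }

  # --- aggregate report ---------------------------------------------------
  ev_snv <- paired_tsv[paired_tsv$status != "unevaluable", , drop = FALSE]
  tt <- titv(ev_snv)
  report <- list(
    n_patients = length(trios),
    n_variants_classified = nrow(paired_tsv),
    n_shared = sum(ev_snv$status == "shared"),
    n_private_primary = sum(ev_snv$status == "private_primary"),
    n_private_metastasis = sum(ev_snv$status == "private_metastasis"),
    n_unevaluable = nrow(paired_tsv) - nrow(ev_snv),
    median_shared_fraction = stats::median(summary_df$shared_fraction,
                                           na.rm = TRUE),
    shared_fraction_range = range(summary_df$shared_fraction, na.rm = TRUE),
    median_burden = stats::median(summary_df$burden),
    cohort_ti_tv_ratio = tt$ratio,
    n_clonality_shifts = sum(ev_snv$clonality_shift, na.rm = TRUE),
    contrasts = contrasts,
    cna = cna_report,
    truth_available = !is.null(truth)
  )
  if (!is.null(truth)) {
    report$truth_median_truncal_fraction <-
      stats::median(vapply(truth, function(t) t$truncal_fraction, numeric(1)))
  }
  jsonlite::write_json(report, file.path(out_dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("stage=report done")
  invisible(report)
}
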