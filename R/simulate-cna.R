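#' Default copy-number scenario
#'
#' Event counts and magnitudes for [simulate_cna_profiles()]. Per patient
#' pair: two numerical and two segmental events shared between primary and
#' metastasis, one numerical and one segmental event novel to the
#' metastasis, and one of each present only in the primary (lost).
#' Gains sit at log2(3/2) = 0.58 (one extra copy), losses at
#' log2(1/2) = -1, with Gaussian bin noise. Losses carry loss of
#' heterozygosity: the B-allele fraction departs from 0.5 by `baf_loh_dev`.
#'
#' @return Named list of copy-number simulation parameters.
#' @export
default_cna_spec <- function() {
  list(
    bin_size = 1e5,
    shared_numerical = 2L, shared_segmental = 2L,
    novel_numerical = 1L, novel_segmental = 1L,
    lost_numerical = 1L, lost_segmental = 1L,
    gain_log2 = log2(3 / 2), loss_log2 = log2(1 / 2),
    noise_sd = 0.15,
    min_segment_bins = 10L, max_segment_bins = 40L,
    baf_loh_dev = 0.2, baf_noise_sd = 0.03
  )
}

place_events <- function(n_events, kinds, category, chroms_free, spec,
                         n_bins_per_chrom) {
  if (n_events == 0) {
    return(list(events = NULL, chroms_free = chroms_free))
  }
  if (n_events > length(chroms_free))
    stop("cannot place ", n_events, " more event(s) on ",
         length(chroms_free), " free chromosome(s); ",
         "simulated events are kept disjoint")
  chosen <- sample(chroms_free, n_events)
  call <- sample(c("gain", "loss"), n_events, replace = TRUE)
  start_bin <- integer(n_events); end_bin <- integer(n_events)
  for (i in seq_len(n_events)) {
    if (kinds[i] == "numerical") {
      start_bin[i] <- 1L
      end_bin[i] <- n_bins_per_chrom
    } else {
      len <- sample(spec$min_segment_bins:spec$max_segment_bins, 1)
      start_bin[i] <- sample.int(n_bins_per_chrom - len + 1L, 1)
      end_bin[i] <- start_bin[i] + len - 1L
    }
  }
  ev <- data.frame(chrom = chosen, start_bin = start_bin, end_bin = end_bin,
                   call = call, span_class = kinds, category = category,
                   loh = call == "loss", stringsAsFactors = FALSE)
  list(events = ev, chroms_free = setdiff(chroms_free, chosen))
}

render_track <- function(sample_id, events, scenario, spec, n_bins_per_chrom) {
  chroms <- scenario$chromosomes
  n_chrom <- length(chroms)
  n_bins <- n_chrom * n_bins_per_chrom
  chrom <- rep(chroms, each = n_bins_per_chrom)
  bin_idx <- rep(seq_len(n_bins_per_chrom), times = n_chrom)
  start <- as.integer((bin_idx - 1L) * spec$bin_size + 1L)
  end <- as.integer(bin_idx * spec$bin_size)
  mu <- numeric(n_bins)
  baf_dev <- numeric(n_bins)
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      sel <- chrom == events$chrom[i] &
        bin_idx >= events$start_bin[i] & bin_idx <= events$end_bin[i]
      mu[sel] <- if (events$call[i] == "gain") spec$gain_log2 else spec$loss_log2
      if (events$loh[i]) baf_dev[sel] <- spec$baf_loh_dev
    }
  }
  log2r <- mu + stats::rnorm(n_bins, 0, spec$noise_sd)
  baf <- 0.5 + baf_dev + stats::rnorm(n_bins, 0, spec$baf_noise_sd)
  baf <- pmin(pmax(baf, 0), 1)
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             log2 = log2r, baf = baf, stringsAsFactors = FALSE)
}

#' Simulate paired binned copy-number profiles with event truth
#'
#' For each patient, draws disjoint copy-number events (each on its own
#' chromosome) split into shared, novel-in-metastasis and
#' lost-in-metastasis groups, each either numerical (whole chromosome) or
#' segmental (a contiguous sub-interval of at least the configured band
#' scale), renders piecewise-constant log2 copy-ratio tracks (0 at
#' neutral bins) plus Gaussian noise, and a B-allele-fraction track
#' shifted away from 0.5 over LOH events.
#'
#' @param scenario A [sim_scenario()]; the `cna_spec` element controls
#'   event counts, magnitudes, and noise.
#' @param seed Integer seed (defaults to `scenario$seed`).
#' @return A `sim_cna` list with `bins` (named list per patient with
#'   `primary` and `metastasis` bin tracks: `sample_id, chrom, start, end,
#'   log2, baf`) and `truth` (data frame of events with bp coordinates,
#'   call, span class, LOH flag, and category).
#' @export
simulate_cna_profiles <- function(scenario = sim_scenario(),
                                  seed = scenario$seed) {
  set.seed(seed + 1L)
  spec <- scenario$cna_spec
  if (scenario$chrom_length %% spec$bin_size != 0)
    stop("bin_size must divide chrom_length")
  n_bins_per_chrom <- as.integer(scenario$chrom_length / spec$bin_size)
  if (spec$max_segment_bins >= n_bins_per_chrom)
    stop("segmental events must be shorter than a chromosome")

  ids <- sprintf("P%02d", seq_len(scenario$n_patients))
  bins <- vector("list", length(ids)); names(bins) <- ids
  truth_rows <- list()
  for (pid in ids) {
    free <- scenario$chromosomes
    groups <- list(
      shared = c(rep("numerical", spec$shared_numerical),
                 rep("segmental", spec$shared_segmental)),
      novel = c(rep("numerical", spec$novel_numerical),
                rep("segmental", spec$novel_segmental)),
      lost = c(rep("numerical", spec$lost_numerical),
               rep("segmental", spec$lost_segmental))
    )
    events <- list()
    for (cat in names(groups)) {
      placed <- place_events(length(groups[[cat]]), groups[[cat]], cat,
                             free, spec, n_bins_per_chrom)
      events[[cat]] <- placed$events
      free <- placed$chroms_free
    }
    ev_all <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
    prim_ev <- ev_all[ev_all$category %in% c("shared", "lost"), , drop = FALSE]
    meta_ev <- ev_all[ev_all$category %in% c("shared", "novel"), , drop = FALSE]
    bins[[pid]] <- list(
      primary = render_track(paste0(pid, "_primary"), prim_ev,
                             scenario, spec, n_bins_per_chrom),
      metastasis = render_track(paste0(pid, "_metastasis"), meta_ev,
                                scenario, spec, n_bins_per_chrom)
    )
    if (!is.null(ev_all) && nrow(ev_all) > 0) {
      ev_all$patient_id <- pid
      ev_all$start <- as.integer((ev_all$start_bin - 1L) * spec$bin_size + 1L)
      ev_all$end <- as.integer(ev_all$end_bin * spec$bin_size)
      truth_rows[[pid]] <- ev_all
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  structure(list(bins = bins, truth = truth, scenario = scenario),
            class = "sim_cna")
}
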