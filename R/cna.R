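#' Segmentation and calling parameters
#'
#' @param t_thresh Minimum absolute two-sample t-statistic at a candidate
#'   change-point for a split to be accepted (default 5).
#' @param min_bins Minimum bins per segment (default 3).
#' @param merge_eps Adjacent segments whose mean log2 differ by less than
#'   this are merged back (default 0.1).
#' @param gain_thresh,loss_thresh Mean log2 thresholds for gain/loss calls
#'   (defaults +0.2 / -0.2).
#' @param whole_chrom_fraction A called event spanning at least this
#'   fraction of its chromosome is classed numerical (default 0.95).
#' @param band_size Minimum span in bp for a segmental event; smaller
#'   events are `sub_band` and excluded from event counts. Defaults to
#'   1/20 of the chromosome length — a proxy for single-cytoband
#'   resolution in the scaled model genome.
#' @param baf_thresh A segment whose mean |BAF - 0.5| exceeds this is
#'   flagged LOH (default 0.15), when a BAF track is present.
#' @return Named list of parameters.
#' @export
cna_params <- function(t_thresh = 5, min_bins = 3L, merge_eps = 0.1,
                       gain_thresh = 0.2, loss_thresh = -0.2,
                       whole_chrom_fraction = 0.95, band_size = NULL,
                       baf_thresh = 0.15) {
  list(t_thresh = t_thresh, min_bins = as.integer(min_bins),
       merge_eps = merge_eps, gain_thresh = gain_thresh,
       loss_thresh = loss_thresh,
       whole_chrom_fraction = whole_chrom_fraction,
       band_size = band_size, baf_thresh = baf_thresh)
}

# Best candidate interval of x[lo..hi] by the two-sample t statistic of
# the interval against the remainder of the window (circular binary
# segmentation statistic); boundary-touching intervals reduce to a plain
# binary split. O(n^2) via cumulative sums, vectorised over the interval
# end for each start.
best_split <- function(x, lo, hi, min_bins) {
  n <- hi - lo + 1
  if (n < 2 * min_bins) return(NULL)
  xs <- x[lo:hi]
  cs <- c(0, cumsum(xs)); css <- c(0, cumsum(xs^2))
  best <- list(t = -Inf)
  # every resulting part (interval and non-empty flanks) must hold at
  # least min_bins bins
  starts <- c(1, seq.int(min_bins + 1, length.out = max(0, n - 2 * min_bins + 1)))
  for (i in starts) {
    js <- (i + min_bins - 1):n
    js <- js[js <= n - min_bins | js == n]
    js <- js[!(i == 1 & js == n)]           # interval must be a strict subset
    if (length(js) == 0) next
    n1 <- js - i + 1; n2 <- n - n1
    s1 <- cs[js + 1] - cs[i]
    q1 <- css[js + 1] - css[i]
    s2 <- cs[n + 1] - s1
    q2 <- css[n + 1] - q1
    m1 <- s1 / n1; m2 <- s2 / n2
    ss <- pmax((q1 - s1^2 / n1) + (q2 - s2^2 / n2), 0)
    pooled <- ss / pmax(n - 2, 1)
    tt <- (m1 - m2) / sqrt(pooled * (1 / n1 + 1 / n2))
    tt[is.nan(tt)] <- 0        # zero variance, equal means: no evidence
    k <- which.max(abs(tt))    # +/-Inf (zero-variance step) wins here
    if (abs(tt[k]) > best$t) {
      best <- list(t = abs(tt[k]), i = lo + i - 1, j = lo + js[k] - 1)
    }
  }
  if (identical(best$t, -Inf)) return(NULL)
  best
}

segment_chrom <- function(x, params) {
  bounds <- integer(0)                      # last index of each segment
  recurse <- function(lo, hi) {
    sp <- best_split(x, lo, hi, params$min_bins)
    if (is.null(sp) || sp$t <= params$t_thresh) {
      bounds <<- c(bounds, hi)
      return(invisible())
    }
    if (sp$i > lo) recurse(lo, sp$i - 1)
    recurse(sp$i, sp$j)
    if (sp$j < hi) recurse(sp$j + 1, hi)
  }
  recurse(1, length(x))
  bounds <- sort(bounds)
  # merge adjacent segments with near-equal means, re-checking after
  # each merge so chains collapse
  repeat {
    starts <- c(1, utils::head(bounds, -1) + 1)
    means <- mapply(function(s, e) mean(x[s:e]), starts, bounds)
    if (length(bounds) < 2) break
    d <- abs(diff(means))
    if (all(d >= params$merge_eps)) break
    i <- which.min(d)
    bounds <- bounds[-i]
  }
  starts <- c(1, utils::head(bounds, -1) + 1)
  data.frame(start_bin = starts, end_bin = bounds,
             mean_log2 = mapply(function(s, e) mean(x[s:e]), starts, bounds))
}

#' Segment a binned log2 copy-ratio profile
#'
#' Recursive binary segmentation per chromosome with a circular-style
#' statistic: within the current window the candidate interval maximising
#' the two-sample t-statistic of its mean log2 against the remainder of
#' the window is located (a boundary-touching interval is an ordinary
#' binary split; an interior interval catches focal events that no single
#' split point can expose), the split is accepted when |t| exceeds
#' `t_thresh` and every resulting part holds at least `min_bins` bins,
#' and the procedure recurses into each part. Adjacent segments whose
#' means differ by less than `merge_eps` are then merged. Segments are called gain when the
#' mean log2 ratio reaches `gain_thresh`, loss at or below `loss_thresh`,
#' neutral otherwise. Deterministic for fixed input and parameters.
#'
#' @param bins Data frame `chrom, start, end, log2` (optional `baf`,
#'   `sample_id`), bins sorted and non-overlapping within each chromosome
#'   with constant width.
#' @param params A [cna_params()].
#' @return Data frame of segments: `sample_id, chrom, start, end, n_bins,
#'   mean_log2, call, baf_dev, loh`; segments within a chromosome are
#'   disjoint and cover every bin.
#' @export
segment_profile <- function(bins, params = cna_params()) {
  bins <- as.data.frame(bins)
  stopifnot(all(c("chrom", "start", "end", "log2") %in% names(bins)))
  sample_id <- if ("sample_id" %in% names(bins)) bins$sample_id[1] else NA_character_
  has_baf <- "baf" %in% names(bins)
  out <- list()
  for (chr in unique(bins$chrom)) {
    b <- bins[bins$chrom == chr, , drop = FALSE]
    if (is.unsorted(b$start, strictly = TRUE))
      stop("bins on ", chr, " are not sorted by start position")
    if (any(b$start[-1] <= b$end[-nrow(b)]))
      stop("bins on ", chr, " overlap")
    widths <- b$end - b$start + 1
    if (length(unique(widths)) != 1)
      stop("bins on ", chr, " do not have constant width")
    seg <- segment_chrom(b$log2, params)
    seg$sample_id <- sample_id
    seg$chrom <- chr
    seg$start <- b$start[seg$start_bin]
    seg$end <- b$end[seg$end_bin]
    seg$n_bins <- seg$end_bin - seg$start_bin + 1L
    seg$baf_dev <- if (has_baf) {
      mapply(function(s, e) mean(abs(b$baf[s:e] - 0.5)),
             seg$start_bin, seg$end_bin)
    } else NA_real_
    out[[chr]] <- seg
  }
  seg <- do.call(rbind, out)
  seg$call <- ifelse(seg$mean_log2 >= params$gain_thresh, "gain",
              ifelse(seg$mean_log2 <= params$loss_thresh, "loss", "neutral"))
  seg$loh <- if (has_baf) seg$baf_dev > params$baf_thresh else NA
  rownames(seg) <- NULL
  seg[, c("sample_id", "chrom", "start", "end", "n_bins", "mean_log2",
          "call", "baf_dev", "loh")]
}

#' Classify the span of called segments
#'
#' A gain/loss segment spanning at least `whole_chrom_fraction` of its
#' chromosome is a **numerical** aberration (whole-chromosome); one
#' spanning at least `band_size` bp is **segmental** (at least a
#' chromosomal-band-scale interval); anything smaller is `sub_band` and
#' excluded from pairwise event counting. Neutral segments get `NA`.
#'
#' @param segments Output of [segment_profile()].
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param params A [cna_params()]; a `NULL` `band_size` defaults to 1/20
#'   of each chromosome's length.
#' @return `segments` with a `span_class` column.
#' @export
classify_span <- function(segments, chrom_lengths, params = cna_params()) {
  segments <- as.data.frame(segments)
  len <- chrom_lengths[segments$chrom]
  if (anyNA(len))
    stop("missing chromosome length for: ",
         paste(unique(segments$chrom[is.na(len)]), collapse = ", "))
  band <- if (is.null(params$band_size)) len / 20 else params$band_size
  span <- segments$end - segments$start + 1
  cls <- ifelse(span >= params$whole_chrom_fraction * len, "numerical",
         ifelse(span >= band, "segmental", "sub_band"))
  segments$span_class <- ifelse(segments$call == "neutral", NA_character_, cls)
  segments
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1
  ifelse(ov <= 0, 0, pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1)))
}

# Greedy symmetric 1-1 matching of events by reciprocal overlap within
# (chrom, call) strata.
match_events <- function(a, b, min_overlap = 0.5) {
  pairs <- NULL
  if (nrow(a) > 0 && nrow(b) > 0) {
    cand <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    cand <- cand[a$chrom[cand$i] == b$chrom[cand$j] &
                 a$call[cand$i] == b$call[cand$j], , drop = FALSE]
    if (nrow(cand) > 0) {
      cand$ov <- reciprocal_overlap(a$start[cand$i], a$end[cand$i],
                                    b$start[cand$j], b$end[cand$j])
      cand <- cand[cand$ov >= min_overlap, , drop = FALSE]
      cand <- cand[order(-cand$ov, a$chrom[cand$i], a$start[cand$i],
                         b$start[cand$j]), , drop = FALSE]
      used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (!used_a[i] && !used_b[j]) {
          used_a[i] <- TRUE; used_b[j] <- TRUE
          pairs <- rbind(pairs, data.frame(i = i, j = j))
        }
      }
    }
  }
  pairs
}

#' Compare the copy-number aberrations of a tumour pair
#'
#' Called events (gain/loss segments of class numerical or segmental) are
#' matched across the two samples by chromosome and call direction with
#' reciprocal overlap of at least `min_overlap`. Matched events are
#' **shared**; metastasis-only events are **novel**, primary-only events
#' **lost**. Counts are reported by span class and call direction.
#' Optionally, a gene panel (`name, chrom, start, end`) is projected onto
#' each sample's segments for gene-level calls.
#'
#' @param primary_segments,metastasis_segments Span-classified segments
#'   (from [classify_span()]) of the two samples.
#' @param genes Optional data frame `name, chrom, start, end`.
#' @param min_overlap Reciprocal-overlap threshold (default 0.5).
#' @return A `cna_pair_report` list: `counts` (data frame with category x
#'   span_class x call counts), `events` (all events with a `category`
#'   column), and `gene_level` (or `NULL`).
#' @export
compare_pair <- function(primary_segments, metastasis_segments, genes = NULL,
                         min_overlap = 0.5) {
  evt <- function(seg) {
    seg <- as.data.frame(seg)
    seg[!is.na(seg$span_class) & seg$span_class %in% c("numerical", "segmental") &
          seg$call %in% c("gain", "loss"), , drop = FALSE]
  }
  p <- evt(primary_segments)
  m <- evt(metastasis_segments)
  pairs <- match_events(p, m, min_overlap)
  p_matched <- if (is.null(pairs)) integer(0) else pairs$i
  m_matched <- if (is.null(pairs)) integer(0) else pairs$j

  tag <- function(seg, idx_matched, cat_matched, cat_unmatched) {
    if (nrow(seg) == 0) return(seg)
    seg$category <- cat_unmatched
    seg$category[idx_matched] <- cat_matched
    seg
  }
  p <- tag(p, p_matched, "shared", "lost")
  m <- tag(m, m_matched, "shared", "novel")
  # shared events are counted once, from the primary side
  events <- rbind(p, m[m$category == "novel", , drop = FALSE])

  grid <- expand.grid(category = c("shared", "novel", "lost"),
                      span_class = c("numerical", "segmental"),
                      call = c("gain", "loss"), stringsAsFactors = FALSE)
  grid$n <- mapply(function(cat, sc, cl) {
    sum(events$category == cat & events$span_class == sc & events$call == cl)
  }, grid$category, grid$span_class, grid$call)

  gene_level <- NULL
  if (!is.null(genes)) {
    gene_level <- gene_calls(genes, primary_segments, metastasis_segments)
  }
  structure(list(counts = grid, events = events, gene_level = gene_level),
            class = "cna_pair_report")
}

gene_calls <- function(genes, primary_segments, metastasis_segments) {
  call_at <- function(seg, chrom, start, end) {
    seg <- as.data.frame(seg)
    hit <- seg$chrom == chrom & seg$start <= end & seg$end >= start
    if (!any(hit)) return(NA_character_)
    hits <- seg[hit, , drop = FALSE]
    ov <- pmin(hits$end, end) - pmax(hits$start, start) + 1
    hits$call[which.max(ov)]
  }
  res <- genes
  res$primary_call <- NA_character_
  res$metastasis_call <- NA_character_
  for (i in seq_len(nrow(genes))) {
    pc <- call_at(primary_segments, genes$chrom[i], genes$start[i], genes$end[i])
    mc <- call_at(metastasis_segments, genes$chrom[i], genes$start[i], genes$end[i])
    if (is.na(pc) || is.na(mc))
      warning("gene '", genes$name[i], "' lies outside the segmented genome")
    res$primary_call[i] <- pc
    res$metastasis_call[i] <- mc
  }
  res$concordant <- res$primary_call == res$metastasis_call
  res
}

#' Co-occurrence of private damaging mutations with CNAs
#'
#' For each metastasis-private damaging variant, reports the copy-number
#' call and LOH flag of the metastasis segment containing its position —
#' the variants most likely to alter function are those whose remaining
#' wild-type allele is also lost.
#'
#' @param paired Classified pair data frame (see [classify_pair()]); rows
#'   are filtered to `status == "private_metastasis"` and
#'   `sift == "damaging"`.
#' @param metastasis_segments Segments of the metastasis sample
#'   (from [segment_profile()], with `loh` present when a BAF track was
#'   supplied; without BAF the LOH column is `NA`, never `FALSE`).
#' @return Data frame `chrom, pos, gene, overlapping_call, loh`.
#' @export
cooccur_mutation_cna <- function(paired, metastasis_segments) {
  paired <- as.data.frame(paired)
  seg <- as.data.frame(metastasis_segments)
  v <- paired[paired$status == "private_metastasis" &
                paired$sift == "damaging", , drop = FALSE]
  if (nrow(v) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      gene = character(0),
                      overlapping_call = character(0), loh = logical(0),
                      stringsAsFactors = FALSE))
  }
  call <- character(nrow(v)); loh <- rep(NA, nrow(v))
  for (i in seq_len(nrow(v))) {
    hit <- seg$chrom == v$chrom[i] & seg$start <= v$pos[i] & seg$end >= v$pos[i]
    if (any(hit)) {
      call[i] <- seg$call[which(hit)[1]]
      loh[i] <- seg$loh[which(hit)[1]]
    } else {
      call[i] <- NA_character_
      warning("variant at ", v$chrom[i], ":", v$pos[i],
              " lies outside the segmented genome")
    }
  }
  data.frame(chrom = v$chrom, pos = v$pos, gene = v$gene,
             overlapping_call = call, loh = loh, stringsAsFactors = FALSE)
}

#' Per-bin aberration frequencies across a cohort
#'
#' The data behind a cohort frequency plot: for each genomic bin, the
#' fraction of samples whose covering segment is called gain and loss.
#'
#' @param segments_list List of segment data frames (one per sample).
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return Data frame `chrom, start, end, frac_gain, frac_loss`.
#' @export
cna_bin_frequencies <- function(segments_list, bin_size, chrom_lengths) {
  chroms <- names(chrom_lengths)
  rows <- list()
  for (chr in chroms) {
    n_bins <- as.integer(chrom_lengths[[chr]] / bin_size)
    start <- (seq_len(n_bins) - 1) * bin_size + 1
    end <- seq_len(n_bins) * bin_size
    gain <- loss <- numeric(n_bins)
    for (seg in segments_list) {
      seg <- as.data.frame(seg)
      s <- seg[seg$chrom == chr, , drop = FALSE]
      for (j in seq_len(nrow(s))) {
        if (s$call[j] == "neutral") next
        sel <- start <= s$end[j] & end >= s$start[j]
        if (s$call[j] == "gain") gain[sel] <- gain[sel] + 1
        if (s$call[j] == "loss") loss[sel] <- loss[sel] + 1
      }
    }
    rows[[chr]] <- data.frame(chrom = chr, start = start, end = end,
                              frac_gain = gain / length(segments_list),
                              frac_loss = loss / length(segments_list),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read segments in SEG format
#'
#' Tab-separated with columns `sample, chrom, start, end, n_bins,
#' mean_log2` (extra columns are preserved on write, ignored on read).
#'
#' @param segments Segment data frame.
#' @param path File path.
#' @return `write_seg` returns `path` invisibly; `read_seg` the data frame.
#' @export
write_seg <- function(segments, path) {
  out <- as.data.frame(segments)
  cols <- c("sample_id", "chrom", "start", "end", "n_bins", "mean_log2")
  out <- out[, c(cols, setdiff(names(out), cols)), drop = FALSE]
  names(out)[1] <- "sample"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) stop("SEG file not found: ", path)
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "n_bins", "mean_log2")
  missing_cols <- setdiff(need, names(seg))
  if (length(missing_cols) > 0)
    stop("SEG file is missing column(s): ", paste(missing_cols, collapse = ", "))
  names(seg)[names(seg) == "sample"] <- "sample_id"
  seg
}
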