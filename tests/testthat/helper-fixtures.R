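# Row builder for variant tables; defaults describe a clean passing
# somatic SNV so tests only state the field under scrutiny.
make_variant <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                         depth = 50L, alt_count = 20L,
                         alt_fwd = NULL, alt_rev = NULL,
                         gene = "GENE1", consequence = "missense",
                         pop_freq = 0.001, sift = "damaging",
                         pathogenicity = "pathogenic") {
  if (is.null(alt_fwd)) alt_fwd <- alt_count %/% 2L
  if (is.null(alt_rev)) alt_rev <- alt_count - alt_fwd
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             depth = depth, alt_count = alt_count,
             alt_fwd = alt_fwd, alt_rev = alt_rev,
             gene = gene, consequence = consequence, pop_freq = pop_freq,
             sift = sift, pathogenicity = pathogenicity,
             stringsAsFactors = FALSE)
}

bind_variants <- function(...) do.call(rbind, list(...))

# n distinct passing variants at consecutive positions
variant_block <- function(n, pos0 = 100L, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_variant(pos = pos0 + i - 1L, ...)
  }))
}

# random variant table with evidence spread around the filter thresholds
random_variants <- function(n, pos0 = 1000L) {
  depth <- sample(0:60, n, replace = TRUE)
  alt <- vapply(depth, function(d) sample(0:d, 1), integer(1))
  fwd <- vapply(alt, function(a) if (a > 0) sample(0:a, 1) else 0L, integer(1))
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_variant(pos = pos0 + i - 1L, depth = depth[i], alt_count = alt[i],
                 alt_fwd = fwd[i], alt_rev = alt[i] - fwd[i],
                 consequence = sample(c("missense", "other", "frameshift"), 1),
                 pop_freq = sample(c(0.001, 0.05), 1, prob = c(0.8, 0.2)),
                 pathogenicity = sample(c("pathogenic", "other"), 1,
                                        prob = c(0.8, 0.2)))
  }))
}

write_vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alt observations\">",
    "##INFO=<ID=SAF,Number=A,Type=Integer,Description=\"Alt obs forward\">",
    "##INFO=<ID=SAR,Number=A,Type=Integer,Description=\"Alt obs reverse\">",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=PF,Number=A,Type=Float,Description=\"Population frequency\">",
    "##INFO=<ID=SIFT,Number=A,Type=String,Description=\"SIFT class\">",
    "##INFO=<ID=PATHO,Number=A,Type=String,Description=\"Pathogenicity\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("chr1", "101", ".", "A", "C,T", "50", "PASS",
          paste0("DP=60;AO=20,9;SAF=11,4;SAR=9,5;GENE=APC,APC;",
                 "CSQ=missense,stop_codon;PF=0.001,0.0;",
                 "SIFT=damaging,damaging;PATHO=pathogenic,likely_pathogenic"),
          sep = "\t"),
    paste("chr2", "555", ".", "G", "A", "50", "PASS",
          paste0("DP=44;AO=18;SAF=10;SAR=8;GENE=TP53;CSQ=missense;",
                 "PF=0.002;SIFT=activating;PATHO=pathogenic"),
          sep = "\t"),
    paste("chr3", "777", ".", "TAC", "T", "50", "PASS",
          paste0("DP=30;AO=12;SAF=6;SAR=6;GENE=KRAS;CSQ=frameshift;",
                 "PF=0.0;SIFT=unknown;PATHO=likely_pathogenic"),
          sep = "\t")
  ), path)
  path
}

# uniform-width bin track builder for CNA tests
make_bins <- function(log2_by_chrom, bin_size = 1e5, sample_id = "S1",
                      baf_by_chrom = NULL) {
  rows <- lapply(names(log2_by_chrom), function(chr) {
    v <- log2_by_chrom[[chr]]
    df <- data.frame(sample_id = sample_id, chrom = chr,
                     start = as.integer((seq_along(v) - 1) * bin_size + 1),
                     end = as.integer(seq_along(v) * bin_size),
                     log2 = v, stringsAsFactors = FALSE)
    if (!is.null(baf_by_chrom)) df$baf <- baf_by_chrom[[chr]]
    df
  })
  do.call(rbind, rows)
}

# interval matching of called non-neutral events against truth events:
# a truth event is recovered when a called event of the same chromosome
# and direction overlaps it reciprocally by >= 0.5
event_recall <- function(truth_events, called_segments) {
  called <- called_segments[called_segments$call != "neutral", , drop = FALSE]
  hit <- logical(nrow(truth_events))
  class_ok <- logical(nrow(truth_events))
  for (i in seq_len(nrow(truth_events))) {
    te <- truth_events[i, ]
    cand <- called[called$chrom == te$chrom & called$call == te$call, ,
                   drop = FALSE]
    if (nrow(cand) == 0) next
    ov <- pmin(cand$end, te$end) - pmax(cand$start, te$start) + 1
    rec <- pmin(ov / (cand$end - cand$start + 1), ov / (te$end - te$start + 1))
    j <- which.max(rec)
    if (rec[j] >= 0.5) {
      hit[i] <- TRUE
      class_ok[i] <- identical(cand$span_class[j], te$span_class)
    }
  }
  list(recall = mean(hit), class_accuracy = mean(class_ok[hit]), hit = hit)
}
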