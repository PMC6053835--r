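params <- cna_params()

test_that("flat noiseless tracks give one neutral segment per chromosome", {
  bins <- make_bins(list(chr1 = rep(0, 100), chr2 = rep(0, 80)))
  seg <- segment_profile(bins, params)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$call, c("neutral", "neutral"))
  expect_equal(seg$n_bins, c(100L, 80L))
})

test_that("a noiseless step is split exactly at the change-point", {
  bins <- make_bins(list(chr1 = c(rep(0, 50), rep(0.6, 50))))
  seg <- segment_profile(bins, params)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$end[1], 50 * 1e5)
  expect_equal(seg$start[2], 50 * 1e5 + 1)
  expect_equal(seg$mean_log2, c(0, 0.6))
  expect_equal(seg$call, c("neutral", "gain"))
})

test_that("malformed bin tracks are rejected", {
  bins <- make_bins(list(chr1 = rep(0, 10)))
  expect_error(segment_profile(bins[c(2, 1, 3:10), ], params), "sorted")
  overlapping <- bins
  overlapping$start[2] <- overlapping$end[1]
  expect_error(segment_profile(overlapping, params), "overlap")
  uneven <- bins
  uneven$end[10] <- uneven$end[10] + 10
  expect_error(segment_profile(uneven, params), "constant width")
})

test_that("segments cover every bin disjointly and deterministically", {
  set.seed(47)
  for (rep in 1:5) {
    x <- rnorm(120, 0, 0.15)
    x[30:60] <- x[30:60] + 0.6
    x[90:110] <- x[90:110] - 1
    bins <- make_bins(list(chr1 = x))
    seg <- segment_profile(bins, params)
    expect_equal(sum(seg$n_bins), 120)
    expect_equal(seg$start[1], 1)
    expect_equal(seg$end[nrow(seg)], 120 * 1e5)
    if (nrow(seg) > 1)
      expect_equal(seg$start[-1], seg$end[-nrow(seg)] + 1)
    expect_identical(seg, segment_profile(bins, params))
  }
})

test_that("span classification follows the whole-chromosome and band rules", {
  len <- c(chr1 = 1e7)
  seg <- data.frame(sample_id = "S", chrom = "chr1",
                    start = c(1, 1, 1), end = c(1e7, 3e6, 3e5),
                    n_bins = c(100L, 30L, 3L), mean_log2 = 0.6,
                    call = "gain", baf_dev = NA_real_, loh = NA)
  cls <- classify_span(seg, len, params)
  expect_equal(cls$span_class, c("numerical", "segmental", "sub_band"))
  neutral <- seg; neutral$call <- "neutral"
  expect_true(all(is.na(classify_span(neutral, len, params)$span_class)))
  expect_error(classify_span(seg, c(chr2 = 1e7), params), "chr1")
})

test_that("pair comparison finds identical, novel, and lost events", {
  len <- c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7)
  x <- list(chr1 = c(rep(0.6, 100)), chr2 = rep(0, 100), chr3 = rep(0, 100))
  y <- list(chr1 = c(rep(0.6, 100)), chr2 = rep(0, 100),
            chr3 = c(rep(0, 40), rep(-1, 30), rep(0, 30)))
  sp <- classify_span(segment_profile(make_bins(x, sample_id = "P"), params),
                      len, params)
  sm <- classify_span(segment_profile(make_bins(y, sample_id = "M"), params),
                      len, params)
  same <- compare_pair(sp, sp)
  expect_equal(sum(same$counts$n[same$counts$category != "shared"]), 0)
  rep_pm <- compare_pair(sp, sm)
  cts <- rep_pm$counts
  expect_equal(cts$n[cts$category == "shared" & cts$span_class == "numerical" &
                       cts$call == "gain"], 1)
  expect_equal(cts$n[cts$category == "novel" & cts$span_class == "segmental" &
                       cts$call == "loss"], 1)
  expect_equal(sum(cts$n[cts$category == "lost"]), 0)
})

test_that("pair comparison is anti-symmetric under sample swap", {
  set.seed(53)
  sc <- sim_scenario(n_patients = 6)
  sim <- simulate_cna_profiles(sc, seed = 53)
  len <- setNames(rep(sc$chrom_length, length(sc$chromosomes)),
                  sc$chromosomes)
  for (pid in names(sim$bins)) {
    sp <- classify_span(segment_profile(sim$bins[[pid]]$primary, params),
                        len, params)
    sm <- classify_span(segment_profile(sim$bins[[pid]]$metastasis, params),
                        len, params)
    fwd <- compare_pair(sp, sm)$counts
    rev <- compare_pair(sm, sp)$counts
    expect_equal(sum(fwd$n[fwd$category == "shared"]),
                 sum(rev$n[rev$category == "shared"]))
    expect_equal(fwd$n[fwd$category == "novel"],
                 rev$n[rev$category == "lost"])
    expect_equal(fwd$n[fwd$category == "lost"],
                 rev$n[rev$category == "novel"])
  }
})

test_that("gene-level projection reports per-sample calls and concordance", {
  len <- c(chr1 = 1e7, chr2 = 1e7)
  x <- list(chr1 = rep(0.6, 100), chr2 = rep(0, 100))
  y <- list(chr1 = rep(0, 100), chr2 = rep(0, 100))
  sp <- classify_span(segment_profile(make_bins(x), params), len, params)
  sm <- classify_span(segment_profile(make_bins(y), params), len, params)
  genes <- data.frame(name = c("AURKA", "SMAD4"), chrom = c("chr1", "chr2"),
                      start = c(2e6, 5e6), end = c(2.1e6, 5.1e6))
  rep_pm <- compare_pair(sp, sm, genes = genes)
  gl <- rep_pm$gene_level
  expect_equal(gl$primary_call, c("gain", "neutral"))
  expect_equal(gl$metastasis_call, c("neutral", "neutral"))
  expect_equal(gl$concordant, c(FALSE, TRUE))
  bad <- data.frame(name = "OFFMAP", chrom = "chr9", start = 1, end = 100)
  expect_warning(compare_pair(sp, sm, genes = bad), "OFFMAP")
})

test_that("mutation-CNA co-occurrence joins calls and LOH", {
  seg <- data.frame(
    sample_id = "M", chrom = c("chr1", "chr1", "chr2"),
    start = c(1, 5e6 + 1, 1), end = c(5e6, 1e7, 1e7),
    n_bins = c(50L, 50L, 100L), mean_log2 = c(-1, 0, 0),
    call = c("loss", "neutral", "neutral"),
    baf_dev = c(0.2, 0.02, 0.02), loh = c(TRUE, FALSE, FALSE))
  paired <- data.frame(
    chrom = c("chr1", "chr2", "chr1"), pos = c(1e6L, 3e6L, 2e6L),
    ref = "A", alt = "G", gene = c("TP53", "GENE2", "GENE3"),
    sift = c("damaging", "damaging", "tolerated"),
    status = c("private_metastasis", "private_metastasis", "private_metastasis"),
    rescued = FALSE, vaf_primary = NA, vaf_metastasis = 0.4,
    delta_vaf = NA_real_, stringsAsFactors = FALSE)
  tab <- cooccur_mutation_cna(paired, seg)
  # only damaging private-metastasis variants are assessed
  expect_equal(tab$gene, c("TP53", "GENE2"))
  expect_equal(tab$overlapping_call, c("loss", "neutral"))
  expect_equal(tab$loh, c(TRUE, FALSE))
  # without a BAF track LOH is absent, never FALSE
  seg_nobaf <- seg; seg_nobaf$loh <- NA
  expect_true(all(is.na(cooccur_mutation_cna(paired, seg_nobaf)$loh)))
})

test_that("cohort bin frequencies accumulate gains and losses", {
  seg1 <- data.frame(sample_id = "A", chrom = "chr1", start = 1, end = 5e6,
                     n_bins = 50L, mean_log2 = 0.6, call = "gain",
                     baf_dev = NA, loh = NA)
  seg2 <- data.frame(sample_id = "B", chrom = "chr1", start = 1, end = 1e7,
                     n_bins = 100L, mean_log2 = -1, call = "loss",
                     baf_dev = NA, loh = NA)
  fr <- cna_bin_frequencies(list(seg1, seg2), 1e5, c(chr1 = 1e7))
  expect_equal(fr$frac_gain[1], 0.5)
  expect_equal(fr$frac_gain[100], 0)
  expect_true(all(fr$frac_loss == 0.5))
})

test_that("SEG files round-trip", {
  seg <- data.frame(sample_id = "S1", chrom = "chr1", start = 1L, end = 100L,
                    n_bins = 10L, mean_log2 = 0.5, call = "gain",
                    baf_dev = 0.1, loh = FALSE, span_class = "segmental")
  p <- withr::local_tempfile(fileext = ".seg")
  write_seg(seg, p)
  back <- read_seg(p)
  expect_equal(back$sample_id, "S1")
  expect_equal(back$mean_log2, 0.5)
  expect_error(read_seg(withr::local_tempfile(fileext = ".seg")), "not found")
})
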