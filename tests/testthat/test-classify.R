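cfg <- filter_config()

pass_v <- function(pos, vaf = 0.4, depth = 50L, ...) {
  alt <- as.integer(round(vaf * depth))
  as_variant_table(make_variant(pos = as.integer(pos), depth = depth,
                                alt_count = alt, alt_fwd = alt %/% 2L,
                                alt_rev = alt - alt %/% 2L, ...))
}

ledger_v <- function(pos, alt = 0L, depth = 40L, ...) {
  v <- as_variant_table(make_variant(pos = as.integer(pos), depth = depth,
                                     alt_count = as.integer(alt),
                                     alt_fwd = as.integer(alt) %/% 2L,
                                     alt_rev = as.integer(alt) - as.integer(alt) %/% 2L,
                                     ...))
  v$reason <- "low_alt_count"
  v
}

test_that("same gene, different position is private, never shared", {
  p <- pass_v(100, gene = "PIK3CA")
  m <- pass_v(200, gene = "PIK3CA")
  out <- classify_pair(p, m, ledger_v(200), ledger_v(100), cfg)
  expect_setequal(out$status, c("private_primary", "private_metastasis"))
  expect_equal(sum(out$status == "shared"), 0)
})

test_that("sub-threshold counterpart support rescues a one-site call", {
  m <- pass_v(100)
  out <- classify_pair(empty_led <- pass_v(1)[0, ], m,
                       ledger_v(100, alt = 3L, depth = 45L), NULL, cfg)
  expect_equal(out$status, "shared")
  expect_true(out$rescued)
  expect_equal(out$vaf_primary, 3 / 45)
  # one supporting read is indistinguishable from error: no rescue, and
  # the metastasis-passing call stays private to the metastasis
  out1 <- classify_pair(pass_v(1)[0, ], m,
                        ledger_v(100, alt = 1L, depth = 45L), NULL, cfg)
  expect_equal(out1$status, "private_metastasis")
})

test_that("the coverage guard separates private from unevaluable", {
  p <- pass_v(100)
  deep <- classify_pair(p, pass_v(1)[0, ], NULL, ledger_v(100, depth = 10L), cfg)
  expect_equal(deep$status, "private_primary")
  shallow <- classify_pair(p, pass_v(1)[0, ], NULL, ledger_v(100, depth = 9L), cfg)
  expect_equal(shallow$status, "unevaluable")
  expect_warning(
    unknown <- classify_pair(p, pass_v(1)[0, ], NULL, NULL, cfg),
    "unknown counterpart")
  expect_equal(unknown$status, "unevaluable")
})

test_that("statuses partition evaluable keys and swap symmetrically", {
  set.seed(23)
  sc <- sim_scenario(n_patients = 3, germline_het_count = 60)
  co <- simulate_cohort(sc, seed = 23)
  for (pid in names(co$trios)) {
    trio <- co$trios[[pid]]
    p <- filter_somatic(trio$primary, trio$normal, cfg)
    m <- filter_somatic(trio$metastasis, trio$normal, cfg)
    fwd <- classify_pair(p$pass, m$pass, p$ledger, m$ledger, cfg)
    # partition
    expect_true(all(fwd$status %in% c("shared", "private_primary",
                                      "private_metastasis", "unevaluable")))
    expect_equal(sum(fwd$status != "unevaluable"),
                 sum(fwd$status == "shared") +
                   sum(fwd$status == "private_primary") +
                   sum(fwd$status == "private_metastasis"))
    expect_false(anyDuplicated(variant_key(fwd)) > 0)
    # swapping the tumour samples swaps PP<->PM and negates delta_vaf
    rev <- classify_pair(m$pass, p$pass, m$ledger, p$ledger, cfg)
    key_f <- variant_key(fwd); key_r <- variant_key(rev)
    expect_setequal(key_f, key_r)
    idx <- match(key_f, key_r)
    swap <- c(shared = "shared", private_primary = "private_metastasis",
              private_metastasis = "private_primary",
              unevaluable = "unevaluable")
    expect_equal(unname(swap[fwd$status]), rev$status[idx])
    both <- fwd$status == "shared"
    expect_equal(fwd$delta_vaf[both], -rev$delta_vaf[idx][both])
  }
})

test_that("raising the rescue threshold never increases shared calls", {
  set.seed(29)
  sc <- sim_scenario(n_patients = 2, germline_het_count = 40)
  co <- simulate_cohort(sc, seed = 29)
  trio <- co$trios[[1]]
  shared_at <- function(k) {
    c2 <- filter_config(rescue_min_alt = k)
    p <- filter_somatic(trio$primary, trio$normal, c2)
    m <- filter_somatic(trio$metastasis, trio$normal, c2)
    sum(classify_pair(p$pass, m$pass, p$ledger, m$ledger, c2)$status == "shared")
  }
  counts <- vapply(c(1L, 2L, 4L, 8L, 1000L), shared_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clonality shifts follow the strict 30-point rule", {
  paired <- data.frame(
    chrom = "chr17", pos = c(1L, 2L, 3L, 4L), ref = "C", alt = "T",
    gene = c("TP53", "SMAD4", "GENE1", "GENE2"), sift = "damaging",
    status = c("shared", "shared", "shared", "private_primary"),
    rescued = FALSE,
    vaf_primary = c(0.36, 0.24, 0.50, 0.40),
    vaf_metastasis = c(0.78, 0.73, 0.80, NA),
    delta_vaf = NA_real_, stringsAsFactors = FALSE)
  out <- detect_clonality_shifts(paired)
  # worked examples: 36% -> 78% (delta 42) and 24% -> 73% (delta 49) flag
  expect_equal(out$clonality_shift[1:2], c(TRUE, TRUE))
  expect_equal(out$delta_vaf[1:2], c(42, 49))
  # a rise of exactly 30 points does not flag
  expect_false(out$clonality_shift[3])
  expect_true(is.na(out$clonality_shift[4]))
})

test_that("purity adjustment rescales the compared VAFs", {
  paired <- data.frame(
    chrom = "chr1", pos = 1L, ref = "A", alt = "G", gene = "G1",
    sift = "tolerated", status = "shared", rescued = FALSE,
    vaf_primary = 0.20, vaf_metastasis = 0.40, delta_vaf = NA_real_,
    stringsAsFactors = FALSE)
  raw <- detect_clonality_shifts(paired)
  expect_false(raw$clonality_shift)         # delta 20 on the raw scale
  adj <- detect_clonality_shifts(paired, purity_primary = 0.8,
                                 purity_metastasis = 0.5)
  expect_equal(adj$delta_vaf, (0.4 / 0.5 - 0.2 / 0.8) * 100)
  expect_true(adj$clonality_shift)          # delta 55 after purity scaling
})
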