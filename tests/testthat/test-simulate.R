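test_that("identical seeds reproduce the cohort byte-for-byte", {
  sc <- sim_scenario(n_patients = 3, germline_het_count = 30)
  a <- simulate_cohort(sc, seed = 5)
  b <- simulate_cohort(sc, seed = 5)
  expect_identical(a$trios, b$trios)
  expect_identical(a$truth, b$truth)
  da <- withr::local_tempdir(); db <- withr::local_tempdir()
  write_cohort(a, da); write_cohort(b, db)
  for (f in list.files(da)) {
    expect_identical(readLines(file.path(da, f)), readLines(file.path(db, f)))
  }
  c2 <- simulate_cohort(sc, seed = 6)
  expect_false(identical(a$trios, c2$trios))
})

test_that("truth keys partition the somatic keys at the configured rates", {
  sc <- sim_scenario(n_patients = 4, private_primary_rate = 0.1,
                     private_metastasis_rate = 0.1, germline_het_count = 20,
                     sidedness_effect = NULL)
  co <- simulate_cohort(sc, seed = 9)
  for (tr in co$truth) {
    somatic <- c(tr$truncal, tr$private_primary, tr$private_metastasis)
    expect_false(anyDuplicated(c(somatic, tr$germline)) > 0)
    expect_equal(length(somatic), tr$burden)
    # largest-remainder apportionment puts the truncal fraction within
    # one variant of 1 - (private rates)
    expect_lt(abs(tr$truncal_fraction - 0.8), 1 / tr$burden)
    expect_true(all(tr$shifts %in% tr$truncal))
    expect_true(all(tr$annotation_pass %in% somatic))
  }
})

test_that("truncal VAFs concentrate at purity/2 and germline at 0.5", {
  sc <- sim_scenario(n_patients = 2, burden_mean = 400, subclonal_fraction = 0,
                     germline_het_count = 300, sidedness_effect = NULL)
  co <- simulate_cohort(sc, seed = 15)
  trio <- co$trios[[1]]
  tr <- co$truth[[1]]
  keys_p <- variant_key(trio$primary)
  truncal <- trio$primary[keys_p %in% tr$truncal, ]
  expect_equal(mean(truncal$vaf, na.rm = TRUE), 0.35, tolerance = 0.02)
  germ <- trio$normal[variant_key(trio$normal) %in% tr$germline, ]
  expect_equal(mean(germ$vaf, na.rm = TRUE), 0.5, tolerance = 0.02)
})

test_that("the simulated substitution spectrum matches ti_fraction", {
  # ti_fraction 2/3 over >= 10^4 substitutions gives TI/TV = 2 within
  # binomial error (delta-method sd of the ratio ~ 0.04)
  sc <- sim_scenario(n_patients = 1, burden_mean = 12000,
                     burden_dispersion = 1e6, indel_fraction = 0,
                     germline_het_count = 0, sidedness_effect = NULL)
  co <- simulate_cohort(sc, seed = 17)
  tt <- titv(co$trios[[1]]$primary)
  expect_gte(tt$ti_count + tt$tv_count, 1e4)
  expect_equal(tt$ratio, 2.0, tolerance = 0.15)
})

test_that("zero metastasis purity leaves no shared calls", {
  sc <- sim_scenario(n_patients = 2, purity_metastasis = 0, error_rate = 0,
                     germline_het_count = 20, sidedness_effect = NULL,
                     subclonal_fraction = 0)
  co <- simulate_cohort(sc, seed = 19)
  for (trio in co$trios) {
    paired <- analyze_trio(trio)
    expect_equal(sum(paired$status == "shared"), 0)
    expect_gt(sum(paired$status == "private_primary"), 0)
  }
})

test_that("zero private rates give a fully truncal, fully shared cohort", {
  sc <- sim_scenario(n_patients = 2, private_primary_rate = 0,
                     private_metastasis_rate = 0, subclonal_fraction = 0,
                     error_rate = 0, germline_het_count = 20,
                     sidedness_effect = NULL)
  co <- simulate_cohort(sc, seed = 25)
  for (pid in names(co$trios)) {
    expect_equal(length(co$truth[[pid]]$private_primary), 0)
    expect_equal(co$truth[[pid]]$truncal_fraction, 1)
    paired <- analyze_trio(co$trios[[pid]])
    s <- summarize_patient(paired, patient_id = pid)
    expect_equal(s$shared_fraction, 1)
  }
})

test_that("written cohorts reload as identical keyed collections", {
  sc <- sim_scenario(n_patients = 2, germline_het_count = 25)
  co <- simulate_cohort(sc, seed = 27)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  pid <- md$patient_id[1]
  trio <- load_trio(file.path(dir, paste0(pid, "_primary.tsv")),
                    file.path(dir, paste0(pid, "_metastasis.tsv")),
                    file.path(dir, paste0(pid, "_normal.tsv")),
                    md[md$patient_id == pid, ])
  orig <- co$trios[[pid]]
  expect_equal(trio$primary, orig$primary)
  expect_equal(trio$metastasis, orig$metastasis)
  expect_equal(trio$normal, orig$normal)
  expect_equal(trio$sidedness, orig$sidedness)
})

test_that("noiseless CNA tracks are exact and event placement is disjoint", {
  sc <- sim_scenario(n_patients = 1, cna_spec = list(
    noise_sd = 0, baf_noise_sd = 0, shared_numerical = 1L,
    shared_segmental = 0L, novel_numerical = 0L, novel_segmental = 0L,
    lost_numerical = 0L, lost_segmental = 0L))
  sim <- simulate_cna_profiles(sc, seed = 33)
  truth <- sim$truth
  expect_equal(nrow(truth), 1)
  bins <- sim$bins[[1]]$primary
  on_ev <- bins$chrom == truth$chrom[1]
  expected <- if (truth$call[1] == "gain") log2(3 / 2) else log2(1 / 2)
  expect_true(all(bins$log2[on_ev] == expected))
  expect_true(all(bins$log2[!on_ev] == 0))
  # more events than chromosomes cannot be placed disjointly
  sc_bad <- sim_scenario(n_patients = 1, chromosomes = c("chr1", "chr2"),
                         cna_spec = list(shared_numerical = 3L))
  expect_error(simulate_cna_profiles(sc_bad, seed = 1), "disjoint")
})

test_that("scenario validation rejects impossible settings", {
  expect_error(sim_scenario(depth_primary_mean = 0), "positive")
  expect_error(sim_scenario(private_primary_rate = 0.6,
                            private_metastasis_rate = 0.5), "sum")
  expect_error(sim_scenario(ti_fraction = 1.2), "\\[0, 1\\]")
})
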