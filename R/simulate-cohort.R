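#' Default colorectal-cancer driver gene symbols
#'
#' A compact list of recurrently mutated colorectal-cancer driver genes
#' used as the default driver panel by the simulator and the summaries.
#' Driver membership is only ever used for overlap reporting, never as a
#' filter.
#'
#' @return Character vector of gene symbols.
#' @export
default_driver_genes <- function() {
  c("APC", "TP53", "KRAS", "NRAS", "BRAF", "PIK3CA", "SMAD4", "SMAD2",
    "FBXW7", "TCF7L2", "SOX9", "ARID1A", "ATM", "AMER1", "CTNNB1",
    "POLE", "PTEN", "AKT1", "MAPK1", "ERBB2")
}

sim_gene_universe <- function(n_passenger = 980) {
  c(default_driver_genes(), sprintf("GENE%04d", seq_len(n_passenger)))
}

#' Simulation scenario for a paired tumour/metastasis cohort
#'
#' Defines the generative model for matched primary/metastasis/normal
#' trios under branched clonal evolution: truncal (pre-divergence) somatic
#' variants appear in both tumour sites, private variants in exactly one,
#' and germline heterozygous variants in all three samples. Read evidence
#' is drawn per sample: depth from an overdispersed negative-binomial
#' around the sample mean, alt-supporting reads binomially at the expected
#' VAF (purity x clonal fraction / 2 for heterozygous somatic variants on
#' copy-neutral loci), and the forward/reverse strand split binomially at
#' one half.
#'
#' Defaults mirror a 21-patient synchronous colorectal-liver-metastasis
#' exome cohort: mean coverage 47/44/40 (primary/metastasis/normal), 70%
#' tumour purity, 11% of the burden private to each site, a transition
#' probability of 2/3 among substitutions (TI/TV 2), and roughly 7%
#' indels. The generated burden is the pre-annotation-filter somatic
#' count: at the default 0.7 annotation pass rate, `burden_mean = 94`
#' for left-sided patients (x1.55 for right-sided ones) produces
#' *observed* per-patient mutation counts with medians near 66 and 102,
#' the scale on which such cohorts are reported.
#'
#' @param n_patients Number of patients (default 21).
#' @param seed Default seed used by [simulate_cohort()].
#' @param burden_mean Mean somatic burden per left-sided patient.
#' @param burden_dispersion Negative-binomial size of the burden draw.
#' @param private_primary_rate,private_metastasis_rate Fractions of the
#'   burden private to each site (truncal fraction is one minus their sum).
#' @param germline_het_count Germline heterozygous variants per patient.
#' @param depth_primary_mean,depth_metastasis_mean,depth_normal_mean Mean
#'   sequencing depths.
#' @param depth_dispersion Negative-binomial size of the depth draw.
#' @param purity_primary,purity_metastasis Tumour-cell fractions in \[0, 1\].
#' @param subclonal_fraction Fraction of truncal variants that are
#'   subclonal in the primary and fully expanded in the metastasis — the
#'   true clonality-shift events. The default 0.04 yields a median of two
#'   detectable shift variants per pair at the default burden and
#'   annotation pass rate.
#' @param subclonal_vaf Expected primary-tumour VAF of a shift variant at
#'   the default 0.7 purity (scaled proportionally for other purities).
#' @param shift_loh Logical; shift variants reach clonality in the
#'   metastasis with loss of the wild-type allele, doubling their expected
#'   metastasis VAF to the sample purity.
#' @param sidedness_effect List with `burden_factor` (multiplicative
#'   burden increase for right-sided patients) and `shared_deficit`
#'   (additive drop in their shared fraction), or `NULL` to disable.
#' @param right_fraction Fraction of right-sided patients (default 9/21).
#' @param ti_fraction Probability a simulated substitution is a transition.
#' @param indel_fraction Probability a somatic variant is a small indel.
#' @param annotation_pass_rate Fraction of somatic variants drawn with
#'   annotations that survive the consequence/pathogenicity/population
#'   filters.
#' @param sift_damaging,sift_activating SIFT class probabilities for
#'   somatic variants (remainder is `tolerated`).
#' @param germline_rare_rate Fraction of germline variants that are rare
#'   and protein-changing (and so must be caught by germline subtraction,
#'   not by the population filter).
#' @param error_rate Per-base sequencing error rate generating
#'   alt-supporting noise reads at variant-free sites.
#' @param chromosomes,chrom_length Model genome: chromosome names and the
#'   common chromosome length in bp (scaled down for desk-scale runs).
#' @param cna_spec Copy-number scenario, see [simulate_cna_profiles()].
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_patients = 21L,
                         seed = 1L,
                         burden_mean = 94,
                         burden_dispersion = 12,
                         private_primary_rate = 0.11,
                         private_metastasis_rate = 0.11,
                         germline_het_count = 200L,
                         depth_primary_mean = 47,
                         depth_metastasis_mean = 44,
                         depth_normal_mean = 40,
                         depth_dispersion = 10,
                         purity_primary = 0.7,
                         purity_metastasis = 0.7,
                         subclonal_fraction = 0.04,
                         subclonal_vaf = 0.15,
                         shift_loh = TRUE,
                         sidedness_effect = list(burden_factor = 1.55,
                                                 shared_deficit = 0.07),
                         right_fraction = 9 / 21,
                         ti_fraction = 2 / 3,
                         indel_fraction = 0.068,
                         annotation_pass_rate = 0.7,
                         sift_damaging = 0.36,
                         sift_activating = 0.02,
                         germline_rare_rate = 0.05,
                         error_rate = 0.001,
                         chromosomes = paste0("chr", c(1:22, "X", "Y")),
                         chrom_length = 1e7,
                         cna_spec = list()) {
  sc <- as.list(environment())
  sc$cna_spec <- utils::modifyList(default_cna_spec(), cna_spec)
  for (f in c("private_primary_rate", "private_metastasis_rate",
              "purity_primary", "purity_metastasis", "subclonal_fraction",
              "subclonal_vaf", "right_fraction", "ti_fraction",
              "indel_fraction", "annotation_pass_rate", "germline_rare_rate",
              "error_rate")) {
    if (sc[[f]] < 0 || sc[[f]] > 1)
      stop("sim_scenario: '", f, "' must lie in [0, 1]")
  }
  if (sc$private_primary_rate + sc$private_metastasis_rate >= 1)
    stop("sim_scenario: private rates must sum to less than 1")
  for (f in c("depth_primary_mean", "depth_metastasis_mean",
              "depth_normal_mean", "burden_mean")) {
    if (sc[[f]] <= 0) stop("sim_scenario: '", f, "' must be positive")
  }
  if (sc$n_patients < 1) stop("sim_scenario: need at least one patient")
  structure(sc, class = "sim_scenario")
}

#' Read a simulation scenario from YAML
#'
#' @param path YAML file whose keys are arguments of [sim_scenario()].
#' @return A `sim_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(sim_scenario)))
  if (length(bad) > 0)
    stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
  do.call(sim_scenario, raw)
}

# Largest-remainder apportionment of n into parts proportional to w.
apportion <- function(n, w) {
  w <- w / sum(w)
  base <- floor(n * w)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * w - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  as.integer(base)
}

# Unique variant loci and alleles over the model genome.
draw_variant_sites <- function(n, scenario) {
  repeat {
    chrom <- sample(scenario$chromosomes, n, replace = TRUE)
    pos <- sample.int(as.integer(scenario$chrom_length - 1L), n, replace = TRUE)
    if (!anyDuplicated(paste0(chrom, ":", pos))) break
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- character(n)
  is_indel <- stats::runif(n) < scenario$indel_fraction
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(n)) {
    if (is_indel[i]) {
      if (stats::runif(1) < 0.5) {           # insertion
        alt[i] <- paste0(ref[i], sample(bases, 1))
      } else {                               # deletion
        extra <- sample(bases, 1)
        alt[i] <- ref[i]
        ref[i] <- paste0(ref[i], extra)
      }
    } else if (stats::runif(1) < scenario$ti_fraction) {
      alt[i] <- transition_of[[ref[i]]]
    } else {
      alt[i] <- sample(setdiff(bases, c(ref[i], transition_of[[ref[i]]])), 1)
    }
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# Annotation columns: 'passing' rows survive the population, consequence
# and pathogenicity filters; failing rows are knocked out by exactly one
# of the three, chosen at random.
draw_annotations <- function(n, pass, scenario, universe) {
  kept_cons <- c("missense", "stop_codon", "frameshift", "loss_of_function",
                 "inframe")
  cons_probs <- c(0.75, 0.08, 0.08, 0.05, 0.04)
  gene <- sample(universe, n, replace = TRUE)
  consequence <- sample(kept_cons, n, replace = TRUE, prob = cons_probs)
  pop_freq <- stats::runif(n, 0, 0.009)
  pathogenicity <- sample(c("pathogenic", "likely_pathogenic"), n,
                          replace = TRUE, prob = c(0.6, 0.4))
  fail <- which(!pass)
  if (length(fail) > 0) {
    mode <- sample(c("common", "consequence", "pathogenicity"),
                   length(fail), replace = TRUE)
    pop_freq[fail[mode == "common"]] <-
      stats::runif(sum(mode == "common"), 0.01, 0.5)
    consequence[fail[mode == "consequence"]] <- "other"
    pathogenicity[fail[mode == "pathogenicity"]] <- "other"
  }
  sift <- sample(c("damaging", "activating", "tolerated"), n, replace = TRUE,
                 prob = c(scenario$sift_damaging, scenario$sift_activating,
                          1 - scenario$sift_damaging - scenario$sift_activating))
  data.frame(gene = gene, consequence = consequence, pop_freq = pop_freq,
             sift = sift, pathogenicity = pathogenicity,
             stringsAsFactors = FALSE)
}

# Draw depth / alt / strand evidence for one sample; rows with
# expected VAF 0 see alt reads only through sequencing error.
draw_evidence <- function(sites, expected_vaf, depth_mean, scenario) {
  n <- nrow(sites)
  depth <- stats::rnbinom(n, mu = depth_mean, size = scenario$depth_dispersion)
  p <- ifelse(expected_vaf > 0, pmin(expected_vaf, 1), scenario$error_rate)
  alt <- stats::rbinom(n, depth, p)
  fwd <- stats::rbinom(n, alt, 0.5)
  cbind(sites,
        data.frame(depth = depth, alt_count = alt, alt_fwd = fwd,
                   alt_rev = alt - fwd, stringsAsFactors = FALSE))
}

simulate_patient <- function(pid, sidedness, neoadjuvant, resection_order,
                             scenario, universe) {
  eff <- scenario$sidedness_effect
  right <- sidedness == "right"
  b_mean <- scenario$burden_mean *
    if (right && !is.null(eff)) eff$burden_factor else 1
  pp_rate <- scenario$private_primary_rate
  pm_rate <- scenario$private_metastasis_rate
  if (right && !is.null(eff)) {
    pp_rate <- pp_rate + eff$shared_deficit / 2
    pm_rate <- pm_rate + eff$shared_deficit / 2
  }
  burden <- max(10L, stats::rnbinom(1, mu = b_mean,
                                    size = scenario$burden_dispersion))
  counts <- apportion(burden, c(1 - pp_rate - pm_rate, pp_rate, pm_rate))
  n_truncal <- counts[1]; n_pp <- counts[2]; n_pm <- counts[3]
  n_germ <- scenario$germline_het_count
  n_total <- burden + n_germ

  sites <- draw_variant_sites(n_total, scenario)
  class_lab <- c(rep("truncal", n_truncal), rep("private_primary", n_pp),
                 rep("private_metastasis", n_pm), rep("germline", n_germ))
  somatic <- class_lab != "germline"
  pass <- logical(n_total)
  pass[somatic] <- stats::runif(burden) < scenario$annotation_pass_rate
  pass[!somatic] <- stats::runif(n_germ) < scenario$germline_rare_rate
  ann <- draw_annotations(n_total, pass, scenario, universe)
  sites <- cbind(sites, ann)

  n_shift <- stats::rbinom(1, n_truncal, scenario$subclonal_fraction)
  shift <- logical(n_total)
  if (n_shift > 0) shift[sample.int(n_truncal, n_shift)] <- TRUE

  # expected VAFs under the clonal model (copy-neutral heterozygous loci)
  clonal_p <- scenario$purity_primary / 2
  clonal_m <- scenario$purity_metastasis / 2
  ev_p <- ifelse(class_lab == "germline", 0.5,
          ifelse(class_lab == "private_metastasis", 0,
          ifelse(shift, scenario$subclonal_vaf * scenario$purity_primary / 0.7,
                 clonal_p)))
  ev_m <- ifelse(class_lab == "germline", 0.5,
          ifelse(class_lab == "private_primary", 0,
          ifelse(shift,
                 if (scenario$shift_loh) scenario$purity_metastasis else clonal_m,
                 clonal_m)))
  ev_n <- ifelse(class_lab == "germline", 0.5, 0)

  prim <- draw_evidence(sites, ev_p, scenario$depth_primary_mean, scenario)
  meta <- draw_evidence(sites, ev_m, scenario$depth_metastasis_mean, scenario)
  norm <- draw_evidence(sites, ev_n, scenario$depth_normal_mean, scenario)

  # tumour tables keep zero-alt rows at somatic sites as coverage
  # observations (real pipelines obtain counterpart coverage from the
  # alignments); the normal table reports only sites with alt support
  prim <- prim[prim$alt_count >= 1 | somatic, , drop = FALSE]
  meta <- meta[meta$alt_count >= 1 | somatic, , drop = FALSE]
  norm <- norm[norm$alt_count >= 1, , drop = FALSE]

  trio <- patient_trio(pid, prim, meta, norm,
                       sidedness = sidedness, neoadjuvant = neoadjuvant,
                       resection_order = resection_order)
  keys <- variant_key(as_variant_table(sites_with_zero_evidence(sites)))
  truth <- list(
    truncal = keys[class_lab == "truncal"],
    private_primary = keys[class_lab == "private_primary"],
    private_metastasis = keys[class_lab == "private_metastasis"],
    germline = keys[class_lab == "germline"],
    shifts = keys[shift],
    annotation_pass = keys[somatic & pass],
    truncal_fraction = n_truncal / burden,
    burden = burden
  )
  list(trio = trio, truth = truth)
}

# key computation wants a full variant table; evidence columns are dummies
sites_with_zero_evidence <- function(sites) {
  cbind(sites, data.frame(depth = 1L, alt_count = 0L, alt_fwd = 0L,
                          alt_rev = 0L, stringsAsFactors = FALSE))
}

#' Simulate a matched tumour/metastasis/normal cohort with ground truth
#'
#' Draws `scenario$n_patients` patient trios under the branched
#' clonal-evolution model of [sim_scenario()] and records, per patient,
#' the true partition of somatic keys into truncal, private-primary and
#' private-metastasis sets, the germline keys, the true clonality-shift
#' keys, and the keys whose annotations pass the downstream filters.
#' Identical seeds give identical cohorts.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed (defaults to `scenario$seed`).
#' @return A `sim_cohort` list with `trios` (named list of
#'   [patient_trio()]), `metadata` (data frame), `truth` (named list per
#'   patient), and `scenario`.
#' @export
simulate_cohort <- function(scenario = sim_scenario(), seed = scenario$seed) {
  set.seed(seed)
  n <- scenario$n_patients
  universe <- sim_gene_universe()
  n_right <- round(n * scenario$right_fraction)
  sidedness <- sample(c(rep("right", n_right), rep("left", n - n_right)))
  orders <- sample(c("concurrent", "liver_first", "primary_first"), n,
                   replace = TRUE, prob = c(5, 5, 11) / 21)
  neo <- stats::runif(n) < 10 / 21
  ids <- sprintf("P%02d", seq_len(n))

  trios <- vector("list", n); truth <- vector("list", n)
  names(trios) <- ids; names(truth) <- ids
  for (i in seq_len(n)) {
    sim <- simulate_patient(ids[i], sidedness[i], neo[i], orders[i],
                            scenario, universe)
    trios[[i]] <- sim$trio
    truth[[i]] <- sim$truth
  }
  metadata <- data.frame(patient_id = ids, sidedness = sidedness,
                         neoadjuvant = neo, resection_order = orders,
                         stringsAsFactors = FALSE)
  structure(list(trios = trios, metadata = metadata, truth = truth,
                 scenario = scenario), class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits per-patient variant tables in the trio TSV dialect
#' (`<id>_primary.tsv`, `<id>_metastasis.tsv`, `<id>_normal.tsv`), the
#' cohort `metadata.tsv`, and the ground truth as `truth.json`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pid in names(cohort$trios)) {
    trio <- cohort$trios[[pid]]
    write_variant_tsv(trio$primary, file.path(dir, paste0(pid, "_primary.tsv")))
    write_variant_tsv(trio$metastasis, file.path(dir, paste0(pid, "_metastasis.tsv")))
    write_variant_tsv(trio$normal, file.path(dir, paste0(pid, "_normal.tsv")))
  }
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
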