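# Synthetic-cohort generator. Produces genotypes, pileups, VCFs, depth
# tables, patient lists, a population AF table and a clinical/survival
# table with the statistical structure the pipeline assumes: HWE
# genotypes at set allele frequencies, negative-binomial depth, binomial
# alt-read counts, and genotype-dependent exponential survival hazard.
# It does not simulate read sequences, alignment or RNA editing.

#' Synthetic cohort configuration
#'
#' Defaults mirror a small three-data-type test cohort: 7 patients of
#' whom 5 have a normal exome sample and all have tumor exome and tumor
#' RNA-seq samples. Depth is negative-binomial with means 60 / 80 / 30
#' for wxs-normal / wxs-tumor / rnaseq-tumor; the wxs-normal dispersion
#' (size 1.0) puts ~15% of sites below the 10-read status threshold, and
#' rnaseq is shallower and more dispersed, so the rescue path is
#' exercised. Alternate-read counts are Binomial(depth, v) with v = 0.5
#' for heterozygotes, 0.98 for alt-homozygotes and a 0.005 error rate for
#' ref-homozygotes.
#'
#' @param n_patients Number of patients (default 7).
#' @param n_variants Number of simulated SNVs (default 120).
#' @param allele_freq True allele frequencies per variant; default drawn
#'   Uniform(0.05, 0.5).
#' @param depth_mean,depth_size Named vectors (normal/tumor/rnaseq) of
#'   negative-binomial mean and size (dispersion) parameters.
#' @param availability Named vector of per-data-type probabilities that a
#'   patient has that sample; realised as `round(p * n_patients)`
#'   patients chosen at random, so the default reproduces 5/7/7.
#' @param alt_vaf Named vector of per-genotype alternate-read fractions.
#' @param qual_fail_rate Probability that a read fails each of the MQ and
#'   BQ filters (default 0.025 each, ~5% combined).
#' @param dup_rate Duplicate-read injection rate (default 0.08).
#' @param beta Per-allele log hazard ratio of the causal variant
#'   (default 0.7).
#' @param causal_variant Index of the causal variant (default 1).
#' @param baseline_hazard Exponential baseline hazard per month (default
#'   `log(2)/24`: 24-month baseline median survival).
#' @param censor_rate Independent exponential censoring rate per month.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 7L, n_variants = 120L,
                          allele_freq = NULL,
                          depth_mean = c(normal = 60, tumor = 80, rnaseq = 30),
                          depth_size = c(normal = 1.0, tumor = 1.5, rnaseq = 0.8),
                          availability = c(normal = 5 / 7, tumor = 1, rnaseq = 1),
                          alt_vaf = c(hom_ref = 0.005, het = 0.5, hom_alt = 0.98),
                          qual_fail_rate = 0.025, dup_rate = 0.08,
                          beta = 0.7, causal_variant = 1L,
                          baseline_hazard = log(2) / 24, censor_rate = 0.015,
                          seed = 1L) {
  stopifnot(n_patients >= 1, n_variants >= 1,
            all(availability >= 0 & availability <= 1),
            all(alt_vaf >= 0 & alt_vaf <= 1),
            qual_fail_rate >= 0, qual_fail_rate < 1,
            dup_rate >= 0, dup_rate < 1,
            baseline_hazard > 0, censor_rate >= 0,
            causal_variant >= 1, causal_variant <= n_variants)
  structure(list(
    n_patients = as.integer(n_patients), n_variants = as.integer(n_variants),
    allele_freq = allele_freq, depth_mean = depth_mean, depth_size = depth_size,
    availability = availability, alt_vaf = alt_vaf,
    qual_fail_rate = qual_fail_rate, dup_rate = dup_rate,
    beta = beta, causal_variant = as.integer(causal_variant),
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    seed = as.integer(seed)), class = "cohort_config")
}

status_from_geno <- c(hom_ref = "Homozygous_ref", het = "Heterozygous",
                      hom_alt = "Homozygous_alt")

sim_variant_keys <- function(n_variants) {
  # evenly spread positions over a few chromosomes; ref/alt fixed pairs
  chroms <- paste0("chr", rep(c(1, 2, 7, 17), length.out = n_variants))
  pos <- 10000L + 500L * seq_len(n_variants)
  refs <- rep(c("A", "C", "G", "T"), length.out = n_variants)
  alts <- rep(c("G", "T", "A", "C"), length.out = n_variants)
  data.table::data.table(CHROM = chroms, POS = pos, REF = refs, ALT = alts)
}

#' Simulate true genotypes under Hardy-Weinberg equilibrium
#'
#' For each variant with true allele frequency p, each patient draws
#' hom_ref / het / hom_alt with probabilities (1-p)^2, 2p(1-p), p^2.
#'
#' @param config A [cohort_config()]. Uses `config$seed` unless the RNG
#'   state is already set by a caller (`set_seed = FALSE`).
#' @param set_seed Seed the RNG from the config (default TRUE).
#' @return A list: `keys` (variant key table with true `af` column) and
#'   `genotypes` (n_patients x n_variants character matrix of
#'   `hom_ref`/`het`/`hom_alt`, rows named by Case_ID).
#' @export
simulate_genotypes <- function(config, set_seed = TRUE) {
  if (set_seed) set.seed(config$seed)
  keys <- sim_variant_keys(config$n_variants)
  p <- config$allele_freq
  if (is.null(p)) p <- stats::runif(config$n_variants, 0.05, 0.5)
  if (length(p) == 1L) p <- rep(p, config$n_variants)
  stopifnot(length(p) == config$n_variants, all(p >= 0 & p <= 1))
  keys$af <- p
  case_ids <- sprintf("CASE-%03d", seq_len(config$n_patients))
  geno <- matrix(NA_character_, config$n_patients, config$n_variants,
                 dimnames = list(case_ids, NULL))
  for (j in seq_len(config$n_variants)) {
    geno[, j] <- sample(c("hom_ref", "het", "hom_alt"), config$n_patients,
                        replace = TRUE,
                        prob = c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2))
  }
  list(keys = keys, genotypes = geno)
}

# Which patients have a sample of each data type: round(p * n) patients,
# chosen at random (reproduces the 5/7/7 default exactly).
sample_availability <- function(config) {
  case_ids <- sprintf("CASE-%03d", seq_len(config$n_patients))
  lapply(c(normal = "normal", tumor = "tumor", rnaseq = "rnaseq"), function(dtype) {
    k <- round(config$availability[[dtype]] * config$n_patients)
    sort(sample(case_ids, k))
  })
}

barcode_of <- function(case_id, dtype) {
  paste0(case_id, c(normal = "-N", tumor = "-T", rnaseq = "-R")[[dtype]])
}

# Draw one sample's read-level pileup for all variants.
simulate_sample_pileup <- function(truth, config, dtype, case_id) {
  keys <- truth$keys
  n <- nrow(keys)
  depth <- stats::rnbinom(n, size = config$depth_size[[dtype]],
                          mu = config$depth_mean[[dtype]])
  geno <- truth$genotypes[case_id, ]
  vaf <- config$alt_vaf[c(hom_ref = "hom_ref", het = "het", hom_alt = "hom_alt")[geno]]
  alt_n <- stats::rbinom(n, depth, vaf)
  rows <- vector("list", n)
  for (j in seq_len(n)) {
    d <- depth[j]
    if (d == 0L) next
    base <- c(rep(keys$ALT[j], alt_n[j]), rep(keys$REF[j], d - alt_n[j]))
    base <- sample(base)
    mq_fail <- stats::runif(d) < config$qual_fail_rate
    bq_fail <- stats::runif(d) < config$qual_fail_rate
    obs <- data.table::data.table(
      chrom = keys$CHROM[j], pos = keys$POS[j], ref = keys$REF[j],
      base = base,
      baseq = ifelse(bq_fail, sample(5:25, d, replace = TRUE),
                     sample(26:40, d, replace = TRUE)),
      mapq = ifelse(mq_fail, sample(10:30, d, replace = TRUE),
                    sample(31:60, d, replace = TRUE)),
      read_start = keys$POS[j] - sample(0:999, d, replace = TRUE),
      strand = sample(c("+", "-"), d, replace = TRUE))
    dup <- obs[stats::runif(d) < config$dup_rate]
    rows[[j]] <- rbind(obs, dup)
  }
  data.table::rbindlist(rows)
}

#' Simulate read-level pileups for every available sample
#'
#' @param truth Output of [simulate_genotypes()].
#' @param config A [cohort_config()].
#' @param available Output of the availability draw (internal); computed
#'   if `NULL`.
#' @return Nested list `pileups[[dtype]][[barcode]]` of pileup tables.
#' @export
simulate_reads <- function(truth, config, available = NULL) {
  if (is.null(available)) available <- sample_availability(config)
  out <- list()
  for (dtype in names(available)) {
    out[[dtype]] <- list()
    for (case_id in available[[dtype]]) {
      out[[dtype]][[barcode_of(case_id, dtype)]] <-
        simulate_sample_pileup(truth, config, dtype, case_id)
    }
  }
  out
}

#' Simulate the clinical / survival table
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(beta * label)` where label is the 0/1/2 dose of
#' the causal variant's alternate allele; censoring is independent
#' exponential. Covariates are drawn within their ordinal ranges,
#' independent of genotype and outcome.
#'
#' @param truth Output of [simulate_genotypes()].
#' @param config A [cohort_config()].
#' @return A `data.table` clinical table, one row per patient.
#' @export
simulate_survival <- function(truth, config) {
  n <- config$n_patients
  label <- c(hom_ref = 0, het = 1, hom_alt = 2)[
    truth$genotypes[, config$causal_variant]]
  hazard <- config$baseline_hazard * exp(config$beta * label)
  t_event <- stats::rexp(n, hazard)
  t_cens <- if (config$censor_rate > 0) stats::rexp(n, config$censor_rate) else rep(Inf, n)
  data.table::data.table(
    Case_ID = rownames(truth$genotypes),
    OS_months = round(pmin(t_event, t_cens), 3),
    OS_status = as.integer(t_event <= t_cens),
    Age = sample(20:80, n, replace = TRUE),
    Percent_aneuploidy = round(stats::runif(n), 4),
    Histology = sample(1:3, n, replace = TRUE),
    Grade = sample(1:2, n, replace = TRUE),
    IDH_status = sample(1:2, n, replace = TRUE),
    Mutation_count = stats::rpois(n, 50),
    Chr7gainORChr10loss = sample(1:2, n, replace = TRUE),
    MGMT_promoter_status = sample(1:2, n, replace = TRUE),
    Chr1OR19q_codeletion = sample(1:2, n, replace = TRUE),
    Treatment_site = sample(1:3, n, replace = TRUE),
    PC3 = round(stats::rnorm(n), 4))
}

#' Count-level status-matrix simulation
#'
#' A lighter alternative to read-level simulation for statistical
#' studies: per (patient, variant, data type) draws depth and alt-read
#' counts directly, applies the caller thresholds to the counts and the
#' 10-read status rule, and returns the three per-data-type status
#' matrices plus the truth. No pileups, VCFs or files are produced.
#'
#' @param config A [cohort_config()].
#' @param params [caller_params()] applied to the counts.
#' @param policy [status_policy()] for the coverage correction.
#' @return A list: `truth`, `available`, and status matrices `normal`,
#'   `tumor`, `rnaseq` (columns = sample barcodes), plus `patient_map`.
#' @export
simulate_status_matrices <- function(config, params = caller_params(),
                                     policy = status_policy()) {
  set.seed(config$seed)
  truth <- simulate_genotypes(config, set_seed = FALSE)
  available <- sample_availability(config)
  keys <- truth$keys[, KEY_COLS, with = FALSE]
  n <- nrow(keys)
  mats <- list()
  for (dtype in names(available)) {
    mat <- data.table::copy(keys)
    for (case_id in available[[dtype]]) {
      depth <- stats::rnbinom(n, size = config$depth_size[[dtype]],
                              mu = config$depth_mean[[dtype]])
      geno <- truth$genotypes[case_id, ]
      vaf <- config$alt_vaf[c(hom_ref = "hom_ref", het = "het", hom_alt = "hom_alt")[geno]]
      alt_n <- stats::rbinom(n, depth, vaf)
      emitted <- alt_n >= params$min_alt_reads & depth > 0 &
        alt_n / pmax(depth, 1L) >= params$min_vaf
      call <- ifelse(emitted,
                     ifelse(alt_n / pmax(depth, 1L) >= params$homalt_vaf,
                            "Homozygous_alt", "Heterozygous"),
                     NA_character_)
      mat[, (barcode_of(case_id, dtype)) := determine_status(call, depth, policy)]
    }
    mats[[dtype]] <- mat
  }
  map <- data.table::data.table(Case_ID = sprintf("CASE-%03d", seq_len(config$n_patients)))
  for (dtype in names(available)) {
    map[[dtype]] <- ifelse(map$Case_ID %in% available[[dtype]],
                           barcode_of(map$Case_ID, dtype), NA_character_)
  }
  c(list(truth = truth, available = available, patient_map = map), mats)
}

#' Write a complete synthetic cohort to disk
#'
#' Emits the full input tree the pipeline consumes: per-sample pileup
#' tables, called single-sample VCFs, mapping-quality-filtered depth
#' TSVs, the three patient lists, a population AF table (true AF plus
#' bounded noise), the clinical CSV, and the ground-truth genotype table
#' for downstream assertions. Reproducible byte-for-byte from the seed.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created).
#' @param params [caller_params()] used to call the simulated pileups.
#' @return `out_dir`, invisibly.
#' @export
emit_cohort <- function(config, out_dir, params = caller_params()) {
  set.seed(config$seed)
  truth <- simulate_genotypes(config, set_seed = FALSE)
  available <- sample_availability(config)
  pileups <- simulate_reads(truth, config, available)
  clinical <- simulate_survival(truth, config)

  for (sub in c("pileups", "vcfs", "depth")) {
    for (dtype in c("normal", "tumor", "rnaseq")) {
      dir.create(file.path(out_dir, sub, dtype), recursive = TRUE, showWarnings = FALSE)
    }
  }
  dir.create(file.path(out_dir, "patients"), recursive = TRUE, showWarnings = FALSE)

  positions <- truth$keys[, c("CHROM", "POS"), with = FALSE]
  for (dtype in names(pileups)) {
    for (bc in names(pileups[[dtype]])) {
      pu <- pileups[[dtype]][[bc]]
      write_pileup(pu, file.path(out_dir, "pileups", dtype, paste0(bc, ".pileup.tsv")))
      calls <- call_pileup(pu, params)
      write_vcf(calls, file.path(out_dir, "vcfs", dtype, paste0(bc, ".vcf")), sample_id = bc)
      cov <- depth_at_positions(pu, positions, min_mapq = params$min_mapq)
      cov <- cov[cov[["depth"]] > 0]  # depth tools omit zero-coverage rows
      write_depth_tsv(cov, file.path(out_dir, "depth", dtype, paste0(bc, ".depth.tsv")))
    }
  }
  for (dtype in c("normal", "tumor", "rnaseq")) {
    lst <- data.table::data.table(Case_ID = available[[dtype]])
    lst[[dtype]] <- barcode_of(lst$Case_ID, dtype)
    data.table::fwrite(lst, file.path(out_dir, "patients", paste0(dtype, ".tsv")), sep = "\t")
  }
  pop <- truth$keys[, KEY_COLS, with = FALSE]
  pop$af <- round(pmin(0.999, pmax(0.001,
    truth$keys$af + stats::rnorm(nrow(pop), 0, 0.01))), 4)
  write_population_af(pop, file.path(out_dir, "population_af.tsv"))
  data.table::fwrite(clinical, file.path(out_dir, "clinical.csv"))
  truth_tab <- data.table::as.data.table(truth$genotypes, keep.rownames = "Case_ID")
  data.table::setnames(truth_tab, c("Case_ID", sprintf("V%04d", seq_len(config$n_variants))))
  data.table::fwrite(truth$keys, file.path(out_dir, "truth_keys.tsv"), sep = "\t")
  data.table::fwrite(truth_tab, file.path(out_dir, "truth_genotypes.tsv"), sep = "\t")
  invisible(out_dir)
}
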