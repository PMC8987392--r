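# Allele-frequency estimation from genotype-status counts, the
# population minor-allele-frequency filter, and concordance between call
# sets.

#' Genotype-status counts for one variant
#'
#' @param statuses Character vector of per-patient status values.
#' @return A named list `n_HR`, `n_HT`, `n_HA`, `n_unknown`.
#' @export
allele_counts <- function(statuses) {
  bad <- !statuses %in% STATUS_LEVELS
  if (any(bad)) stop("unrecognized status value: ", statuses[which(bad)[1]])
  list(n_HR = sum(statuses == "Homozygous_ref"),
       n_HT = sum(statuses == "Heterozygous"),
       n_HA = sum(statuses == "Homozygous_alt"),
       n_unknown = sum(statuses == "unknown"))
}

#' Cohort allele frequency from genotype counts
#'
#' AF = (2 #HA + #HT) / (2 #HR + 2 #HT + 2 #HA), where #HR, #HT, #HA are
#' the numbers of patients called homozygous-reference, heterozygous and
#' homozygous-alternate. Patients with `unknown` status enter neither the
#' numerator nor the denominator.
#'
#' @param counts A list as returned by [allele_counts()], or a status
#'   character vector.
#' @return The allele frequency in `[0, 1]`.
#' @export
allele_frequency <- function(counts) {
  if (is.character(counts)) counts <- allele_counts(counts)
  with(counts, {
    if (n_HR < 0 || n_HT < 0 || n_HA < 0) stop("negative genotype counts")
    n_typed <- n_HR + n_HT + n_HA
    if (n_typed == 0) stop("allele frequency undefined: no genotyped patients")
    (2 * n_HA + n_HT) / (2 * n_typed)
  })
}

#' Per-variant allele frequencies of a status matrix
#'
#' @param mat A status matrix.
#' @return The key columns plus `n_HR`, `n_HT`, `n_HA`, `n_unknown` and
#'   `af` (`NA` where no patient is genotyped).
#' @export
variant_allele_frequencies <- function(mat) {
  dt <- data.table::as.data.table(mat)
  cols <- sample_cols(dt)
  if (!length(cols)) stop("status matrix has no sample columns")
  st <- as.matrix(dt[, cols, with = FALSE])
  out <- dt[, KEY_COLS, with = FALSE]
  out$n_HR <- rowSums(st == "Homozygous_ref")
  out$n_HT <- rowSums(st == "Heterozygous")
  out$n_HA <- rowSums(st == "Homozygous_alt")
  out$n_unknown <- rowSums(st == "unknown")
  typed <- out$n_HR + out$n_HT + out$n_HA
  out$af <- ifelse(typed > 0, (2 * out$n_HA + out$n_HT) / (2 * typed), NA_real_)
  out[]
}

#' Population minor-allele-frequency filter
#'
#' Keeps variants known in the general population with minor allele
#' frequency at or above the threshold. Variants absent from the
#' population table are removed (they are not known population
#' polymorphisms — this is what removes somatic mutations and RNA-editing
#' artifacts introduced by the tumor-derived rescue calls).
#'
#' @param mat A status matrix (or any table keyed by the variant key).
#' @param pop_af Population table with `CHROM`, `POS`, `REF`, `ALT`, `af`.
#' @param threshold Minimum minor allele frequency (default 0.05).
#' @return The surviving rows of `mat`.
#' @export
maf_filter <- function(mat, pop_af, threshold = 0.05) {
  dt <- data.table::as.data.table(mat)
  pop <- data.table::as.data.table(pop_af)[, c(KEY_COLS, "af"), with = FALSE]
  merged <- merge(dt[, KEY_COLS, with = FALSE], pop, by = KEY_COLS, all.x = TRUE)
  merged <- sort_variant_keys(merged)
  dt2 <- sort_variant_keys(dt)
  maf <- pmin(merged$af, 1 - merged$af)
  dt2[!is.na(maf) & maf >= threshold]
}

#' Allele-frequency concordance between two call sets
#'
#' Pearson product-moment correlation of two allele-frequency vectors
#' over shared variants; pairs with an undefined AF are dropped.
#'
#' @param af_a,af_b Numeric vectors of equal length (aligned on shared
#'   variant keys).
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
af_concordance <- function(af_a, af_b) {
  if (length(af_a) != length(af_b)) stop("AF vectors must be aligned (equal length)")
  ok <- !is.na(af_a) & !is.na(af_b)
  a <- af_a[ok]; b <- af_b[ok]
  if (length(a) < 3L) stop("need at least 3 shared variants with defined AF")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: zero variance in an AF vector")
  }
  stats::cor(a, b)
}

#' Read / write a population allele-frequency table
#'
#' Five tab-separated columns with header: `CHROM`, `POS`, `REF`, `ALT`,
#' `af` — the dialect of a site-level extract from a population database.
#'
#' @param path File path.
#' @export
read_population_af <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = 1))
  if (!all(c(KEY_COLS, "af") %in% names(dt))) {
    stop("population AF table must have columns CHROM, POS, REF, ALT, af")
  }
  if (any(dt$af < 0 | dt$af > 1)) stop("population af must lie in [0, 1]")
  dt$POS <- as.integer(dt$POS)
  dt[]
}

#' @rdname read_population_af
#' @param tab Table to write.
#' @export
write_population_af <- function(tab, path) {
  data.table::fwrite(data.table::as.data.table(tab), path, sep = "\t")
  invisible(path)
}
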