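# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths and the survival package's internals.

# Mantel-Haenszel log-rank chi-square for exactly two groups, computed
# by direct evaluation of O, E and the hypergeometric variance at every
# distinct event time.
logrank_bruteforce2 <- function(group, time, event) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2L)
  O1 <- E1 <- V1 <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1L)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V1 <- V1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V1
}

# Allele frequency by direct allele enumeration: write out every
# genotyped patient's two alleles and take the alt fraction.
af_enumerate <- function(n_hr, n_ht, n_ha) {
  alleles <- c(rep(0, 2 * n_hr), rep(c(0, 1), n_ht), rep(1, 2 * n_ha))
  if (!length(alleles)) return(NA_real_)
  mean(alleles)
}

# The coverage-correction rule, restated independently as literal
# branches.
status_rule_table <- function(call, depth, min_depth = 10L) {
  if (depth < min_depth) return("unknown")
  if (is.na(call)) return("Homozygous_ref")
  call
}

# Build a single-site pileup from read counts: alt_n alt reads and
# (depth - alt_n) ref reads, all passing quality, unique start positions.
make_site <- function(depth, alt_n, chrom = "chr1", pos = 1000L,
                      ref = "A", alt = "G", mapq = 60L, baseq = 40L) {
  if (depth == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), base = character(),
                                  baseq = integer(), mapq = integer(),
                                  read_start = integer(), strand = character()))
  }
  data.table::data.table(
    chrom = chrom, pos = as.integer(pos), ref = ref,
    base = c(rep(alt, alt_n), rep(ref, depth - alt_n)),
    baseq = as.integer(baseq), mapq = as.integer(mapq),
    read_start = as.integer(pos) - seq_len(depth),
    strand = "+")
}

# A small status matrix built directly from a status-string matrix.
make_status_matrix <- function(status, samples = NULL) {
  status <- as.matrix(status)
  n <- nrow(status)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(status)))
  dt <- data.table::data.table(
    CHROM = "chr1", POS = 100L + seq_len(n),
    REF = "A", ALT = "G")
  for (j in seq_along(samples)) dt[[samples[j]]] <- status[, j]
  dt
}
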