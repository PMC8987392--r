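random_keys <- function(n, seed) {
  set.seed(seed)
  unique(data.table::data.table(
    CHROM = sample(c("chr1", "chr2", "chr10", "chrX"), n, replace = TRUE),
    POS = sample.int(1e4, n, replace = TRUE),
    REF = "A", ALT = "G"))
}

test_that("unique_variants equals brute-force set union and reports totals", {
  a <- data.table::data.table(CHROM = "chr1", POS = c(1L, 2L), REF = "A", ALT = "G")
  b <- data.table::data.table(CHROM = "chr1", POS = c(2L, 3L), REF = "A", ALT = "G")
  uv <- unique_variants(list(a, b))
  expect_equal(uv$POS, 1:3)
  expect_equal(attr(uv, "total"), 4L)

  single <- unique_variants(list(a))
  expect_equal(single[, .(CHROM, POS, REF, ALT)], a)

  # many random samples against a string-set oracle
  samples <- lapply(1:50, function(i) random_keys(30, seed = 100 + i))
  uv <- unique_variants(samples)
  oracle <- unique(unlist(lapply(samples, function(s) paste(s$CHROM, s$POS, s$REF, s$ALT))))
  expect_equal(nrow(uv), length(oracle))
  expect_setequal(paste(uv$CHROM, uv$POS, uv$REF, uv$ALT), oracle)
})

test_that("union across data types is a full outer union on the variant key", {
  n <- variant_keys("chr1", 1:2, "A", "G")
  t <- variant_keys("chr1", 3:5, "A", "G")
  r <- variant_keys("chr2", 1:4, "A", "G")
  expect_equal(nrow(union_across_datatypes(n, t, r)), 9L)
  expect_equal(nrow(union_across_datatypes(n, n, n)), 2L)
  expect_equal(nrow(union_across_datatypes(n, NULL, NULL)), 2L)
})

test_that("canonical key order is natural by chromosome then position", {
  keys <- variant_keys(c("chr10", "chr2", "chrX", "chr2"), c(5, 9, 1, 3),
                       "A", "G")
  expect_equal(keys$CHROM, c("chr2", "chr2", "chr10", "chrX"))
  expect_equal(keys$POS, c(3L, 9L, 5L, 1L))
  expect_error(variant_keys("chr1", 1, "A", "A"), "differ")
  expect_error(variant_keys("chr1", 1, "AT", "A"), "single-nucleotide")
})

test_that("the coverage-correction rule matches its rule table exhaustively", {
  grid <- expand.grid(depth = 0:30, call = c(NA, "Heterozygous", "Homozygous_alt"),
                      stringsAsFactors = FALSE)
  got <- determine_status(grid$call, grid$depth)
  want <- mapply(status_rule_table, grid$call, grid$depth)
  expect_equal(got, unname(want))
  # directed: a call at depth 9 is not trusted
  expect_equal(determine_status("Heterozygous", 9L), "unknown")
  # no call at depth 25 is a reference genotype
  expect_equal(determine_status(NA_character_, 25L), "Homozygous_ref")
  # a call at sufficient depth passes through
  expect_equal(determine_status("Homozygous_alt", 30L), "Homozygous_alt")
  # the boundary depth of exactly 10 reads counts as sufficient
  expect_equal(determine_status(NA_character_, 10L), "Homozygous_ref")
  # fuzz: no call at depth below threshold ever survives
  set.seed(3)
  calls <- sample(c(NA, "Heterozygous", "Homozygous_alt"), 500, replace = TRUE)
  depths <- sample(0:9, 500, replace = TRUE)
  expect_true(all(determine_status(calls, depths) == "unknown"))
})

test_that("per-sample status tables merge calls with coverage over the union", {
  union <- variant_keys("chr1", 1:4, "A", "G")
  calls <- data.table::data.table(CHROM = "chr1", POS = c(1L, 3L), REF = "A", ALT = "G",
                                  call = c("Heterozygous", "Homozygous_alt"))
  cov <- data.table::data.table(CHROM = "chr1", POS = 1:4,
                                depth = c(50L, 5L, 9L, 20L))
  st <- sample_status_table(calls, cov, union)
  expect_equal(st$status, c("Heterozygous", "unknown", "unknown", "Homozygous_ref"))
  # coverage missing a union position is an error
  expect_error(sample_status_table(calls, cov[1:3], union), "chr1:4")
})

test_that("combine_samples builds the matrix in input column order", {
  union <- variant_keys("chr1", 1:5, "A", "G")
  tabs <- lapply(1:3, function(i) {
    data.table::data.table(union, status = rep("Homozygous_ref", 5))
  })
  names(tabs) <- c("S3", "S1", "S2")
  mat <- combine_samples(tabs, union)
  expect_equal(dim(mat), c(5L, 7L))
  expect_equal(names(mat), c("CHROM", "POS", "REF", "ALT", "S3", "S1", "S2"))
  # single sample: column equals its table
  one <- combine_samples(tabs["S1"], union)
  expect_equal(one$S1, tabs$S1$status)
  # a sample missing a union key is an error naming the key
  short <- tabs
  short$S2 <- short$S2[1:4]
  expect_error(combine_samples(short, union), "S2.*chr1:5")
})

test_that("chunked processing equals unchunked and writes 4-digit chunk files", {
  set.seed(17)
  mat <- make_status_matrix(matrix(sample(c("unknown", "Homozygous_ref",
                                            "Heterozygous", "Homozygous_alt"),
                                          303 * 3, replace = TRUE), 303, 3))
  path <- withr::local_tempfile(fileext = ".txt")
  write_status_table(mat, path)
  chunk_dir <- withr::local_tempdir()
  chunked <- process_chunked(path, filter_potential_snps, chunk_rows = 100L,
                             chunk_dir = chunk_dir)
  unchunked <- filter_potential_snps(read_status_table(path))
  expect_equal(chunked, unchunked)
  files <- list.files(chunk_dir)
  expect_equal(files, c("segment_0000.txt", "segment_0001.txt",
                        "segment_0002.txt", "segment_0003.txt"))
  expect_equal(length(readLines(file.path(chunk_dir, "segment_0003.txt"))), 3L)
  # everything in one chunk when rows fit
  one <- process_chunked(path, identity, chunk_rows = 10000L)
  expect_equal(one, read_status_table(path))
  # conservation: identity op preserves every row through chunking
  merged <- process_chunked(path, identity, chunk_rows = 100L)
  expect_equal(merged, read_status_table(path))
})

test_that("potential-SNP filter keeps rows with at least one alternate call", {
  mat <- make_status_matrix(rbind(
    c("unknown", "Homozygous_ref", "unknown"),
    c("Homozygous_ref", "Heterozygous", "Homozygous_ref"),
    c("Homozygous_ref", "Homozygous_ref", "Homozygous_ref"),
    c("unknown", "unknown", "Homozygous_alt")))
  out <- filter_potential_snps(mat)
  expect_equal(out$POS, mat$POS[c(2, 4)])
  # idempotent; all-het matrix is identity
  expect_equal(filter_potential_snps(out), out)
  hets <- make_status_matrix(matrix("Heterozygous", 4, 2))
  expect_equal(filter_potential_snps(hets), hets)
})
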