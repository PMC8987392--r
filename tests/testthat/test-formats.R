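test_that("VCF writer and reader round-trip generated records", {
  set.seed(11)
  n <- 40
  recs <- data.table::data.table(
    CHROM = sample(c("chr1", "chr2", "chrX"), n, replace = TRUE),
    POS = sample.int(1e6, n),
    REF = sample(c("A", "C", "G", "T"), n, replace = TRUE))
  recs$ALT <- vapply(recs$REF, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  recs$total_depth <- sample(10:100, n, replace = TRUE)
  recs$variant_depth <- pmin(recs$total_depth, sample(3:50, n, replace = TRUE))
  recs$call <- ifelse(recs$variant_depth / recs$total_depth >= 0.75,
                      "Homozygous_alt", "Heterozygous")
  recs <- sort_variant_keys(recs)

  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(recs, path, sample_id = "S1")
  back <- read_vcf(path)
  expect_equal(back$CHROM, recs$CHROM)
  expect_equal(back$POS, recs$POS)
  expect_equal(back$REF, recs$REF)
  expect_equal(back$ALT, recs$ALT)
  expect_equal(back$call, recs$call)
  expect_equal(back$total_depth, recs$total_depth)
  expect_equal(back$variant_depth, recs$variant_depth)
  expect_true(all(back$FILTER == "PASS"))
  expect_true(all(back$sample_id == "S1"))

  # second round trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(back, path2, sample_id = "S1")
  expect_identical(readLines(path), readLines(path2))
})

test_that("read_vcf maps fields, handles empty files and rejects bad headers", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1"), collapse = "\t"),
               "chr1\t100\t.\tG\tC\t.\tPASS\t.\tGT:DP:VD\t0/1:40:20"), path)
  rec <- read_vcf(path)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$CHROM, "chr1")
  expect_equal(rec$POS, 100L)
  expect_equal(rec$REF, "G")
  expect_equal(rec$ALT, "C")
  expect_equal(rec$FILTER, "PASS")
  expect_equal(rec$call, "Heterozygous")
  expect_equal(rec$total_depth, 40L)
  expect_equal(rec$variant_depth, 20L)

  # header-only file -> empty sequence
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1"), collapse = "\t")), path)
  expect_equal(nrow(read_vcf(path)), 0L)

  # AD fallback when VD is absent; 1/1 -> hom alt
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1"), collapse = "\t"),
               "chr1\t100\t.\tG\tC\t.\tPASS\t.\tGT:DP:AD\t1/1:40:2,38"), path)
  rec <- read_vcf(path)
  expect_equal(rec$call, "Homozygous_alt")
  expect_equal(rec$variant_depth, 38L)

  # no #CHROM line -> format error
  writeLines("not a vcf at all", path)
  expect_error(read_vcf(path), "#CHROM")
})

test_that("filter_pass keeps exactly the PASS records in order", {
  recs <- data.table::data.table(CHROM = "chr1", POS = 1:3, REF = "A", ALT = "G",
                                 FILTER = c("PASS", "q25", "PASS"))
  expect_equal(filter_pass(recs)$POS, c(1L, 3L))
  all_pass <- data.table::copy(recs)[, FILTER := "PASS"]
  expect_equal(filter_pass(all_pass), all_pass)
  none <- data.table::copy(recs)[, FILTER := "q25"]
  expect_equal(nrow(filter_pass(none)), 0L)
})

test_that("depth TSV round-trips and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t100\t12", path)
  d <- read_depth_tsv(path)
  expect_equal(d, data.table::data.table(CHROM = "chr1", POS = 100L, depth = 12L))

  set.seed(4)
  tab <- data.table::data.table(CHROM = "chr2", POS = sort(sample.int(1e5, 50)),
                                depth = sample(0:200, 50, replace = TRUE))
  write_depth_tsv(tab, path)
  expect_equal(read_depth_tsv(path), tab)

  writeLines(character(), path)
  expect_equal(nrow(read_depth_tsv(path)), 0L)

  writeLines("chr1\t100\ttwelve", path)
  expect_error(read_depth_tsv(path), "depth")
})

test_that("BED export is 0-based half-open and deduplicates positions", {
  keys <- variant_keys(c("chr1", "chr1", "chr2"), c(100, 100, 5), c("G", "G", "A"),
                       c("C", "T", "G"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(keys, path)
  lines <- readLines(path)
  expect_equal(lines, c("chr1\t99\t100", "chr2\t4\t5"))
})

test_that("VCF -> BED -> coverage lookup has no off-by-one on random positions", {
  set.seed(21)
  pos <- sort(sample.int(1e7, 1000))
  keys <- variant_keys("chr3", pos, "A", "G")
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(keys, path)
  bed <- data.table::fread(path, header = FALSE)
  expect_equal(bed$V2, pos - 1L)   # 0-based start
  expect_equal(bed$V3, pos)        # half-open end recovers the 1-based position
})

test_that("avinput export uses 1-based inclusive SNV coordinates and round-trips keys", {
  mat <- make_status_matrix(cbind(c("unknown", "Heterozygous"),
                                  c("Homozygous_ref", "Homozygous_alt")))
  path <- withr::local_tempfile(fileext = ".txt")
  write_annovar_input(mat, path)
  back <- data.table::fread(path, header = FALSE)
  expect_equal(nrow(back), nrow(mat))
  expect_equal(back$V2, mat$POS)
  expect_equal(back$V3, mat$POS)
  expect_equal(back$V4, mat$REF)
  expect_equal(back$V5, mat$ALT)
  expect_equal(back$V6, mat$S1)
})

test_that("patient map outer-joins the three lists and validates them", {
  dir <- withr::local_tempdir()
  np <- file.path(dir, "n.tsv"); tp <- file.path(dir, "t.tsv"); rp <- file.path(dir, "r.tsv")
  writeLines(c("Case_ID\tnormal", "P1\tP1-N", "P2\tP2-N"), np)
  writeLines(c("Case_ID\ttumor", "P1\tP1-T", "P3\tP3-T"), tp)
  writeLines(c("Case_ID\trnaseq", "P1\tP1-R"), rp)
  map <- read_patient_map(np, tp, rp)
  expect_equal(map$Case_ID, c("P1", "P2", "P3"))
  expect_equal(map[map$Case_ID == "P1"], data.table::data.table(
    Case_ID = "P1", normal = "P1-N", tumor = "P1-T", rnaseq = "P1-R"),
    ignore_attr = TRUE)
  expect_true(is.na(map$tumor[map$Case_ID == "P2"]))
  expect_true(is.na(map$normal[map$Case_ID == "P3"]))

  writeLines(c("Case_ID\tBarcode", "P1\tP1-N"), np)
  expect_error(read_patient_map(np, tp, rp), "normal")

  writeLines(c("Case_ID\tnormal", "P1\tP1-N", "P1\tP1-Nb"), np)
  expect_error(read_patient_map(np, tp, rp), "duplicate Case_ID")
})

test_that("status tables round-trip through the TSV dialect", {
  mat <- make_status_matrix(matrix(sample(c("unknown", "Homozygous_ref",
                                            "Heterozygous", "Homozygous_alt"),
                                          30, replace = TRUE), 10, 3))
  path <- withr::local_tempfile(fileext = ".txt")
  write_status_table(mat, path)
  expect_equal(read_status_table(path), mat)
})
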