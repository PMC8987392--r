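# One patient, one variant per row; statuses abbreviated in comments as
# HR/HT/HA/unk.

simple_map <- data.table::data.table(
  Case_ID = "P1", normal = "P1-N", tumor = "P1-T", rnaseq = "P1-R")

one_cell <- function(normal, tumor, rnaseq, map = simple_map) {
  nm <- make_status_matrix(cbind(normal), samples = "P1-N")
  tm <- make_status_matrix(cbind(tumor), samples = "P1-T")
  rm_ <- make_status_matrix(cbind(rnaseq), samples = "P1-R")
  fill_unknown(nm, tm, rm_, map, reapply_filter = FALSE)
}

test_that("the rescue priority chain fills unknowns from tumor then rnaseq", {
  # unknown normal takes the tumor status
  expect_equal(one_cell("unknown", "Heterozygous", "Homozygous_alt")$final$P1,
               "Heterozygous")
  # a known normal status is immutable, even when tumor disagrees
  expect_equal(one_cell("Homozygous_ref", "Homozygous_alt", "Homozygous_alt")$final$P1,
               "Homozygous_ref")
  # still unknown after tumor -> rnaseq fills, including with hom-ref
  expect_equal(one_cell("unknown", "unknown", "Homozygous_ref")$final$P1,
               "Homozygous_ref")
  # nothing known anywhere stays unknown
  expect_equal(one_cell("unknown", "unknown", "unknown")$final$P1, "unknown")
  # tumor wins over rnaseq when both could fill
  expect_equal(one_cell("unknown", "Homozygous_alt", "Heterozygous")$final$P1,
               "Homozygous_alt")
})

test_that("patients without donor samples keep their unknowns", {
  map <- data.table::data.table(Case_ID = "P1", normal = "P1-N",
                                tumor = NA_character_, rnaseq = NA_character_)
  nm <- make_status_matrix(cbind(c("unknown", "Heterozygous")), samples = "P1-N")
  out <- fill_unknown(nm, NULL, NULL, map, reapply_filter = FALSE)
  expect_equal(out$final$P1, c("unknown", "Heterozygous"))
  expect_equal(out$report$filled_from_tumor, 0L)
})

test_that("patients without a normal sample start all-unknown and are filled", {
  map <- data.table::data.table(Case_ID = "P9", normal = NA_character_,
                                tumor = "P9-T", rnaseq = "P9-R")
  tm <- make_status_matrix(cbind(c("Heterozygous", "unknown")), samples = "P9-T")
  rm_ <- make_status_matrix(cbind(c("Homozygous_ref", "Homozygous_alt")), samples = "P9-R")
  out <- fill_unknown(NULL, tm, rm_, map, reapply_filter = FALSE)
  expect_equal(out$final$P9, c("Heterozygous", "Homozygous_alt"))
  expect_equal(out$report$unknowns_before, 2L)
})

test_that("variants absent from a donor matrix are treated as unknown there", {
  nm <- make_status_matrix(cbind(c("unknown", "unknown")), samples = "P1-N")
  tm <- make_status_matrix(cbind("Homozygous_alt"), samples = "P1-T")  # first variant only
  out <- fill_unknown(nm, tm, NULL,
                      data.table::data.table(Case_ID = "P1", normal = "P1-N",
                                             tumor = "P1-T", rnaseq = NA_character_),
                      reapply_filter = FALSE)
  expect_equal(out$final$P1, c("Homozygous_alt", "unknown"))
})

test_that("a mapped barcode absent from its matrix is an error naming it", {
  nm <- make_status_matrix(cbind("unknown"), samples = "OTHER-N")
  expect_error(one_cell_err <- fill_unknown(nm, NULL, NULL, simple_map,
                                            reapply_filter = FALSE),
               "P1-N")
})

test_that("rescue never loses information and is idempotent", {
  set.seed(31)
  states <- c("unknown", "Homozygous_ref", "Heterozygous", "Homozygous_alt")
  n_var <- 60; n_pat <- 8
  cases <- sprintf("P%02d", seq_len(n_pat))
  map <- data.table::data.table(Case_ID = cases,
                                normal = paste0(cases, "-N"),
                                tumor = paste0(cases, "-T"),
                                rnaseq = paste0(cases, "-R"))
  rand_mat <- function(suffix, p_unknown) {
    make_status_matrix(matrix(sample(states, n_var * n_pat, replace = TRUE,
                                     prob = c(p_unknown, rep((1 - p_unknown) / 3, 3))),
                              n_var, n_pat),
                       samples = paste0(cases, suffix))
  }
  nm <- rand_mat("-N", 0.4); tm <- rand_mat("-T", 0.2); rm_ <- rand_mat("-R", 0.3)
  out <- fill_unknown(nm, tm, rm_, map, reapply_filter = FALSE)

  # cell-wise: known normal statuses unchanged, unknown count non-increasing
  for (i in seq_len(n_pat)) {
    before <- nm[[paste0(cases[i], "-N")]]
    after <- out$final[[cases[i]]]
    known <- before != "unknown"
    expect_equal(after[known], before[known])
    expect_lte(sum(after == "unknown"), sum(before == "unknown"))
  }

  # report accounting identity
  with(out$report, expect_equal(
    unknowns_before, filled_from_tumor + filled_from_rnaseq + unknowns_remaining))

  # idempotence: a second fill with the same donors changes nothing
  renamed <- data.table::copy(out$final)
  data.table::setnames(renamed, cases, paste0(cases, "-N"))
  again <- fill_unknown(renamed, tm, rm_, map, reapply_filter = FALSE)
  expect_equal(again$final, out$final)
})

test_that("export writes four consistent files", {
  set.seed(33)
  nm <- make_status_matrix(matrix(sample(c("unknown", "Heterozygous"), 20, replace = TRUE),
                                  10, 2), samples = c("P1-N", "P2-N"))
  tm <- make_status_matrix(matrix("Homozygous_ref", 10, 2), samples = c("P1-T", "P2-T"))
  map <- data.table::data.table(Case_ID = c("P1", "P2"),
                                normal = c("P1-N", "P2-N"),
                                tumor = c("P1-T", "P2-T"),
                                rnaseq = NA_character_)
  out <- fill_unknown(nm, tm, NULL, map)
  dir <- withr::local_tempdir()
  paths <- export_outputs(out, dir)
  expect_true(all(file.exists(paths)))
  final_back <- read_status_table(paths[["final"]])
  expect_equal(final_back, out$final)
  annovar <- data.table::fread(paths[["annovar"]], header = FALSE)
  expect_equal(nrow(annovar), nrow(out$final))
  expect_equal(annovar$V2, out$final$POS)
})
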