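# Unknown-status rescue: fill unknown statuses in the wxs-normal sample
# from the matched wxs-tumor sample, then from the matched rnaseq-tumor
# sample. Known normal statuses are never touched; tumor always takes
# priority over rnaseq. Somatic-only tumor calls that leak in are removed
# downstream by the population MAF filter.

#' Fill unknown normal-sample statuses from tumor and RNA-seq
#'
#' For each patient in the map: the baseline column is the normal
#' sample's statuses (all-`unknown` when the patient has no normal
#' sample); cells still `unknown` are filled from the matched tumor
#' sample, then from the matched rnaseq sample. Variants absent from a
#' donor matrix count as `unknown` in that donor. Columns of the result
#' are keyed by `Case_ID`; rows are the union of the three matrices'
#' variant keys.
#'
#' @param normal,tumor,rnaseq Status matrices for the three data types
#'   (sample-barcode columns); any may be `NULL`.
#' @param patient_map A [read_patient_map()] table.
#' @param reapply_filter Re-apply [filter_potential_snps()] to the final
#'   matrix (default TRUE).
#' @return A list: `final` (rescued, optionally re-filtered matrix),
#'   `tumor_filled` (intermediate after the tumor pass only),
#'   `report` (per-patient `data.table`: `Case_ID`, `unknowns_before`,
#'   `filled_from_tumor`, `filled_from_rnaseq`, `unknowns_remaining`).
#' @export
fill_unknown <- function(normal, tumor, rnaseq, patient_map,
                         reapply_filter = TRUE) {
  map <- data.table::as.data.table(patient_map)
  mats <- list(normal = normal, tumor = tumor, rnaseq = rnaseq)
  for (dtype in names(mats)) {
    m <- mats[[dtype]]
    if (is.null(m)) next
    barcodes <- map[[dtype]][!is.na(map[[dtype]])]
    missing <- setdiff(barcodes, sample_cols(m))
    if (length(missing)) {
      stop("sample barcode(s) in the ", dtype,
           " patient list not found in the ", dtype, " status matrix: ",
           paste(missing, collapse = ", "))
    }
  }
  keys <- unique_variants(Filter(Negate(is.null), mats))
  data.table::setattr(keys, "total", NULL)
  n_var <- nrow(keys)

  # donor lookup: per data type, matrix aligned to the union keys with
  # absent variants as unknown
  aligned <- lapply(mats, function(m) {
    if (is.null(m)) return(NULL)
    merged <- merge(keys, data.table::as.data.table(m), by = KEY_COLS, all.x = TRUE)
    merged <- sort_variant_keys(merged)
    for (cn in sample_cols(merged)) {
      v <- merged[[cn]]
      v[is.na(v)] <- "unknown"
      merged[, (cn) := v]
    }
    merged
  })

  column_of <- function(dtype, barcode) {
    if (is.na(barcode) || is.null(aligned[[dtype]])) return(rep("unknown", n_var))
    aligned[[dtype]][[barcode]]
  }

  tumor_filled <- data.table::copy(keys)
  final <- data.table::copy(keys)
  report <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    case_id <- map$Case_ID[i]
    base <- column_of("normal", map$normal[i])
    unknowns_before <- sum(base == "unknown")
    tum <- column_of("tumor", map$tumor[i])
    rna <- column_of("rnaseq", map$rnaseq[i])
    step1 <- ifelse(base == "unknown" & tum != "unknown", tum, base)
    filled_tumor <- sum(step1 != "unknown" & base == "unknown")
    step2 <- ifelse(step1 == "unknown" & rna != "unknown", rna, step1)
    filled_rna <- sum(step2 != "unknown" & step1 == "unknown")
    tumor_filled[, (case_id) := step1]
    final[, (case_id) := step2]
    report[[i]] <- data.table::data.table(
      Case_ID = case_id,
      unknowns_before = unknowns_before,
      filled_from_tumor = filled_tumor,
      filled_from_rnaseq = filled_rna,
      unknowns_remaining = sum(step2 == "unknown"))
  }
  if (reapply_filter) final <- filter_potential_snps(final)
  list(final = final, tumor_filled = tumor_filled,
       report = data.table::rbindlist(report))
}

#' Write the four rescue output files
#'
#' Emits, under `prefix`:
#' `combined_normal_unknown_filled.txt` (tumor-pass intermediate),
#' `combined_normal_unknown_filled_arranged.txt` (the same, rows and
#' patient columns sorted), `final_merged_wxs_rnaseq_variants.txt` (the
#' final combined wxs + rnaseq status table) and
#' `final_variantsForAnnovar.txt` (avinput format).
#'
#' @param rescued The list returned by [fill_unknown()].
#' @param prefix Directory (created if needed) the files are written into.
#' @return Named character vector of the four paths, invisibly.
#' @export
export_outputs <- function(rescued, prefix) {
  dir.create(prefix, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tumor_filled = file.path(prefix, "combined_normal_unknown_filled.txt"),
    arranged = file.path(prefix, "combined_normal_unknown_filled_arranged.txt"),
    final = file.path(prefix, "final_merged_wxs_rnaseq_variants.txt"),
    annovar = file.path(prefix, "final_variantsForAnnovar.txt"))
  write_status_table(rescued$tumor_filled, paths[["tumor_filled"]])
  arranged <- sort_variant_keys(rescued$tumor_filled)
  data.table::setcolorder(arranged, c(KEY_COLS, sort(sample_cols(arranged))))
  write_status_table(arranged, paths[["arranged"]])
  write_status_table(rescued$final, paths[["final"]])
  write_annovar_input(rescued$final, paths[["annovar"]])
  invisible(paths)
}
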