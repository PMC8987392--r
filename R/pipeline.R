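# Pipeline orchestration. Runs the stages — call, pass, unique, union,
# coverage, status, combine, filter, rescue, af, survival — over the
# directory layout the synthetic-cohort generator emits (or equivalent
# user-supplied inputs), writing each stage's outputs to its own
# subdirectory so stages are resumable and idempotent.

DATATYPE_DIRS <- c(normal = "normal", tumor = "tumor", rnaseq = "rnaseq")
STAGES <- c("call", "pass", "unique", "union", "coverage", "status",
            "combine", "filter", "rescue", "af", "survival")

#' Pipeline configuration
#'
#' @param input_dir Directory holding the inputs: `pileups/<dtype>/` (or
#'   `vcfs/<dtype>/` to skip calling), `depth/<dtype>/` (optional;
#'   recomputed from pileups when absent), `patients/<dtype>.tsv`,
#'   `population_af.tsv`, `clinical.csv`.
#' @param out_dir Directory stage outputs are written under.
#' @param params [caller_params()].
#' @param policy [status_policy()].
#' @param maf_threshold Population minor-allele-frequency threshold
#'   (default 0.05).
#' @param chunk_rows Chunk size for the combined-table processing
#'   (default 50000).
#' @param covariates Covariates for the survival scan (default none:
#'   genotype-only models; supply [DEFAULT_COVARIATES] when the clinical
#'   table carries the full covariate set).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            params = caller_params(),
                            policy = status_policy(),
                            maf_threshold = 0.05,
                            chunk_rows = 50000L,
                            covariates = character()) {
  if (!dir.exists(input_dir)) stop("input_dir does not exist: ", input_dir)
  structure(list(input_dir = input_dir, out_dir = out_dir, params = params,
                 policy = policy, maf_threshold = maf_threshold,
                 chunk_rows = as.integer(chunk_rows), covariates = covariates),
            class = "pipeline_config")
}

stage_dir <- function(config, ...) {
  d <- file.path(config$out_dir, ...)
  dir.create(dirname(d), recursive = TRUE, showWarnings = FALSE)
  d
}

require_stage <- function(path, stage_needed) {
  if (!file.exists(path) && !dir.exists(path)) {
    stop("missing prerequisite output ", path,
         "; run stage '", stage_needed, "' first")
  }
  path
}

list_samples <- function(dir, pattern) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  stats::setNames(files, sub(pattern, "", basename(files)))
}

#' Run one pipeline stage (or all of them)
#'
#' Stages mirror the pipeline parts: `call` (candidate calling on
#' pileups, per data type), `pass` (PASS extraction), `unique`
#' (per-data-type unique variants), `union` (union across the three data
#' types, plus BED export), `coverage` (depth at union positions),
#' `status` (coverage-corrected per-sample status), `combine`
#' (multi-sample status matrix per data type), `filter` (potential-SNP
#' filter, chunked), `rescue` (unknown-fill from tumor then rnaseq),
#' `af` (allele frequencies, MAF filter, concordance), `survival`
#' (per-variant Cox scan). `"all"` runs them in order.
#'
#' @param config A [pipeline_config()].
#' @param stage One of the stage names or `"all"`.
#' @return The stage's primary result, invisibly (the `all` stage
#'   returns a named list of every stage result).
#' @export
run_stage <- function(config, stage = "all") {
  if (identical(stage, "all")) {
    res <- lapply(STAGES, function(s) run_stage(config, s))
    return(invisible(stats::setNames(res, STAGES)))
  }
  if (!stage %in% STAGES) {
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(c(STAGES, "all"), collapse = ", "))
  }
  switch(stage,
         call = stage_call(config),
         pass = stage_pass(config),
         unique = stage_unique(config),
         union = stage_union(config),
         coverage = stage_coverage(config),
         status = stage_status(config),
         combine = stage_combine(config),
         filter = stage_filter(config),
         rescue = stage_rescue(config),
         af = stage_af(config),
         survival = stage_survival(config))
}

stage_call <- function(config) {
  out <- list()
  for (dtype in DATATYPE_DIRS) {
    pu_dir <- file.path(config$input_dir, "pileups", dtype)
    vcf_out <- stage_dir(config, "VCFs_from_VarDict", dtype)
    dir.create(vcf_out, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(pu_dir)) next
    files <- list_samples(pu_dir, "\\.pileup\\.tsv$")
    for (bc in names(files)) {
      calls <- call_pileup(read_pileup(files[[bc]]), config$params)
      write_vcf(calls, file.path(vcf_out, paste0(bc, ".vcf")), sample_id = bc)
      message("call[", dtype, "/", bc, "]: ", nrow(calls), " candidate records")
    }
    out[[dtype]] <- length(files)
  }
  invisible(out)
}

# VCFs come from the call stage, or directly from input vcfs/ when the
# user supplies caller output instead of pileups.
vcf_source_dir <- function(config, dtype) {
  called <- file.path(config$out_dir, "VCFs_from_VarDict", dtype)
  supplied <- file.path(config$input_dir, "vcfs", dtype)
  if (dir.exists(called) && length(list.files(called, pattern = "\\.vcf$"))) return(called)
  if (dir.exists(supplied)) return(supplied)
  require_stage(called, "call")
}

stage_pass <- function(config) {
  out <- list()
  for (dtype in DATATYPE_DIRS) {
    src <- vcf_source_dir(config, dtype)
    pass_out <- stage_dir(config, "PASS_variants", dtype)
    dir.create(pass_out, recursive = TRUE, showWarnings = FALSE)
    files <- list_samples(src, "\\.vcf$")
    for (bc in names(files)) {
      recs <- read_vcf(files[[bc]])
      pass <- filter_pass(recs)
      data.table::fwrite(pass, file.path(pass_out, paste0(bc, ".pass.tsv")), sep = "\t")
      message("pass[", dtype, "/", bc, "]: ", nrow(pass), " of ", nrow(recs), " records PASS")
    }
    out[[dtype]] <- length(files)
  }
  invisible(out)
}

read_pass_tables <- function(config, dtype) {
  dir <- require_stage(file.path(config$out_dir, "PASS_variants", dtype), "pass")
  files <- list_samples(dir, "\\.pass\\.tsv$")
  lapply(files, function(f) {
    data.table::fread(f, colClasses = list(character = 1))
  })
}

stage_unique <- function(config) {
  out <- list()
  for (dtype in DATATYPE_DIRS) {
    tabs <- read_pass_tables(config, dtype)
    if (!length(tabs)) next
    uv <- unique_variants(tabs)
    path <- stage_dir(config, "PASS_variants", paste0("unique_variants_", dtype, ".tsv"))
    data.table::fwrite(uv, path, sep = "\t")
    message("unique[", dtype, "]: ", nrow(uv), " unique of ",
            attr(uv, "total"), " total variants")
    out[[dtype]] <- uv
  }
  invisible(out)
}

read_unique <- function(config, dtype) {
  path <- file.path(config$out_dir, "PASS_variants",
                    paste0("unique_variants_", dtype, ".tsv"))
  if (!file.exists(path)) return(NULL)
  data.table::fread(path, colClasses = list(character = 1))
}

stage_union <- function(config) {
  sets <- lapply(DATATYPE_DIRS, function(d) read_unique(config, d))
  if (all(vapply(sets, is.null, logical(1)))) {
    require_stage(file.path(config$out_dir, "PASS_variants", "unique_variants_normal.tsv"),
                  "unique")
  }
  un <- union_across_datatypes(sets$normal, sets$tumor, sets$rnaseq)
  data.table::fwrite(un, stage_dir(config, "union_wxs_rnaseq_variants.txt"), sep = "\t")
  write_bed(un, stage_dir(config, "union_wxs_rnaseq_variants.bed"))
  message("union: ", nrow(un), " variants across data types")
  invisible(un)
}

read_union <- function(config) {
  path <- require_stage(file.path(config$out_dir, "union_wxs_rnaseq_variants.txt"), "union")
  data.table::fread(path, colClasses = list(character = 1))
}

stage_coverage <- function(config) {
  un <- read_union(config)
  out <- list()
  for (dtype in DATATYPE_DIRS) {
    cov_out <- stage_dir(config, "variant_coverage", dtype)
    dir.create(cov_out, recursive = TRUE, showWarnings = FALSE)
    depth_dir <- file.path(config$input_dir, "depth", dtype)
    pu_dir <- file.path(config$input_dir, "pileups", dtype)
    if (dir.exists(depth_dir) && length(list.files(depth_dir))) {
      files <- list_samples(depth_dir, "\\.depth\\.tsv$")
      for (bc in names(files)) {
        cov <- load_external_depth(files[[bc]], un)
        write_depth_tsv(cov, file.path(cov_out, paste0(bc, ".depth.tsv")))
      }
      out[[dtype]] <- length(files)
    } else if (dir.exists(pu_dir)) {
      files <- list_samples(pu_dir, "\\.pileup\\.tsv$")
      for (bc in names(files)) {
        cov <- depth_at_positions(read_pileup(files[[bc]]), un,
                                  min_mapq = config$params$min_mapq)
        write_depth_tsv(cov, file.path(cov_out, paste0(bc, ".depth.tsv")))
      }
      out[[dtype]] <- length(files)
    }
    message("coverage[", dtype, "]: ", out[[dtype]] %||% 0, " samples")
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_status <- function(config) {
  un <- read_union(config)
  out <- list()
  for (dtype in DATATYPE_DIRS) {
    cov_dir <- file.path(config$out_dir, "variant_coverage", dtype)
    if (!dir.exists(cov_dir) || !length(list.files(cov_dir))) next
    require_stage(cov_dir, "coverage")
    st_out <- stage_dir(config, "variant_status", dtype)
    dir.create(st_out, recursive = TRUE, showWarnings = FALSE)
    pass_dir <- require_stage(file.path(config$out_dir, "PASS_variants", dtype), "pass")
    cov_files <- list_samples(cov_dir, "\\.depth\\.tsv$")
    for (bc in names(cov_files)) {
      calls <- data.table::fread(file.path(pass_dir, paste0(bc, ".pass.tsv")),
                                 colClasses = list(character = 1))
      cov <- load_external_depth(cov_files[[bc]], un)
      st <- sample_status_table(calls, cov, un, config$policy)
      data.table::fwrite(st, file.path(st_out, paste0(bc, "_GT_samdepth_merged.tsv")),
                         sep = "\t")
    }
    message("status[", dtype, "]: ", length(cov_files), " samples x ", nrow(un), " variants")
    out[[dtype]] <- length(cov_files)
  }
  invisible(out)
}

stage_combine <- function(config) {
  un <- read_union(config)
  out <- list()
  for (dtype in DATATYPE_DIRS) {
    st_dir <- file.path(config$out_dir, "variant_status", dtype)
    if (!dir.exists(st_dir) || !length(list.files(st_dir))) next
    files <- list_samples(st_dir, "_GT_samdepth_merged\\.tsv$")
    tabs <- lapply(files, read_status_table)
    mat <- combine_samples(tabs, un)
    comb_out <- stage_dir(config, "combined_variant_status", dtype)
    dir.create(comb_out, recursive = TRUE, showWarnings = FALSE)
    write_status_table(mat, file.path(comb_out, "combinedVariantStatusFromAllSamples.txt"))
    message("combine[", dtype, "]: ", nrow(mat), " variants x ", length(files), " samples")
    out[[dtype]] <- mat
  }
  invisible(out)
}

stage_filter <- function(config) {
  out <- list()
  for (dtype in DATATYPE_DIRS) {
    comb <- file.path(config$out_dir, "combined_variant_status", dtype,
                      "combinedVariantStatusFromAllSamples.txt")
    if (!file.exists(comb)) next
    snps <- process_chunked(comb, filter_potential_snps,
                            chunk_rows = config$chunk_rows)
    path <- file.path(dirname(comb), "processed_CombinedPotentialSNPs.txt")
    write_status_table(snps, path)
    message("filter[", dtype, "]: ", nrow(snps), " potential SNPs")
    out[[dtype]] <- snps
  }
  if (!length(out)) {
    require_stage(file.path(config$out_dir, "combined_variant_status"), "combine")
  }
  invisible(out)
}

read_potential_snps <- function(config, dtype) {
  path <- file.path(config$out_dir, "combined_variant_status", dtype,
                    "processed_CombinedPotentialSNPs.txt")
  if (!file.exists(path)) return(NULL)
  read_status_table(path)
}

read_map <- function(config) {
  p <- function(d) {
    f <- file.path(config$input_dir, "patients", paste0(d, ".tsv"))
    if (file.exists(f)) f else NULL
  }
  read_patient_map(p("normal"), p("tumor"), p("rnaseq"))
}

stage_rescue <- function(config) {
  mats <- lapply(DATATYPE_DIRS, function(d) read_potential_snps(config, d))
  if (all(vapply(mats, is.null, logical(1)))) {
    require_stage(file.path(config$out_dir, "combined_variant_status", "normal",
                            "processed_CombinedPotentialSNPs.txt"), "filter")
  }
  rescued <- fill_unknown(mats$normal, mats$tumor, mats$rnaseq, read_map(config))
  final_dir <- stage_dir(config, "final")
  export_outputs(rescued, final_dir)
  data.table::fwrite(rescued$report, file.path(final_dir, "rescue_report.tsv"), sep = "\t")
  message("rescue: ", nrow(rescued$final), " variants in final matrix; filled ",
          sum(rescued$report$filled_from_tumor), " cells from tumor, ",
          sum(rescued$report$filled_from_rnaseq), " from rnaseq")
  invisible(rescued)
}

stage_af <- function(config) {
  final_path <- require_stage(
    file.path(config$out_dir, "final", "final_merged_wxs_rnaseq_variants.txt"), "rescue")
  final <- read_status_table(final_path)
  af_final <- variant_allele_frequencies(final)
  pop_path <- file.path(config$input_dir, "population_af.tsv")
  filtered <- final
  if (file.exists(pop_path)) {
    filtered <- maf_filter(final, read_population_af(pop_path), config$maf_threshold)
  }
  af_dir <- stage_dir(config, "popgen")
  dir.create(af_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(af_final, file.path(af_dir, "allele_frequencies.tsv"), sep = "\t")
  write_status_table(filtered, file.path(af_dir, "final_MAF_filtered.txt"))
  # concordance of the per-data-type call sets with the final merged set
  conc <- list()
  for (dtype in DATATYPE_DIRS) {
    m <- read_potential_snps(config, dtype)
    if (is.null(m)) next
    af_d <- variant_allele_frequencies(m)
    shared <- merge(af_final[, c(KEY_COLS, "af"), with = FALSE],
                    af_d[, c(KEY_COLS, "af"), with = FALSE], by = KEY_COLS)
    conc[[dtype]] <- tryCatch(af_concordance(shared$af.x, shared$af.y),
                              error = function(e) NA_real_)
  }
  conc_dt <- data.table::data.table(datatype = names(conc),
                                    r = unlist(conc, use.names = FALSE))
  data.table::fwrite(conc_dt, file.path(af_dir, "af_concordance.tsv"), sep = "\t")
  message("af: ", nrow(filtered), " of ", nrow(final), " variants pass the MAF filter")
  invisible(list(af = af_final, filtered = filtered, concordance = conc_dt))
}

stage_survival <- function(config) {
  filt_path <- require_stage(file.path(config$out_dir, "popgen", "final_MAF_filtered.txt"), "af")
  mat <- read_status_table(filt_path)
  clinical <- read_clinical(file.path(config$input_dir, "clinical.csv"))
  scan <- variant_survival_scan(mat, clinical, config$covariates)
  surv_dir <- stage_dir(config, "survival")
  dir.create(surv_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(scan, file.path(surv_dir, "variant_survival_results.tsv"), sep = "\t")
  message("survival: ", sum(!is.na(scan$p_value)), " of ", nrow(scan), " variants tested")
  invisible(scan)
}
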