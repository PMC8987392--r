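# Core bespoke computation of the pipeline: per-sample variant status
# with the 10-read coverage correction, unions of unique variants,
# multi-sample combination (with chunked processing for large tables) and
# the potential-SNP filter.

#' Coverage-correction policy
#'
#' @param min_depth Minimum read depth for a genotype status to be
#'   trusted; sites below it are `unknown` (default 10).
#' @export
status_policy <- function(min_depth = 10L) {
  stopifnot(min_depth >= 1)
  structure(list(min_depth = as.integer(min_depth)), class = "status_policy")
}

#' Unique variants across the samples of one data type
#'
#' Set union of variant keys over a list of per-sample PASS call tables,
#' deterministically sorted. The total (non-unique) record count is
#' attached as attribute `"total"` for audit logging.
#'
#' @param records_list A list of tables each carrying `CHROM`, `POS`,
#'   `REF`, `ALT` (a single table is also accepted).
#' @return Sorted unique key `data.table` with attribute `total`.
#' @export
unique_variants <- function(records_list) {
  if (data.table::is.data.table(records_list) || is.data.frame(records_list)) {
    records_list <- list(records_list)
  }
  keys <- data.table::rbindlist(lapply(records_list, function(r) {
    data.table::as.data.table(r)[, KEY_COLS, with = FALSE]
  }))
  out <- sort_variant_keys(unique(keys))
  data.table::setattr(out, "total", nrow(keys))
  out
}

#' Union of unique variants across the three data types
#'
#' Full outer union on (CHROM, POS, REF, ALT) of the per-data-type unique
#' variant sets.
#'
#' @param normal,tumor,rnaseq Key tables (each already unique); any may
#'   be `NULL`.
#' @return Sorted unique key `data.table`.
#' @export
union_across_datatypes <- function(normal = NULL, tumor = NULL, rnaseq = NULL) {
  parts <- Filter(Negate(is.null), list(normal, tumor, rnaseq))
  if (!length(parts)) stop("no variant sets supplied")
  unique_variants(parts)
}

#' Coverage-corrected variant status
#'
#' The status rule: depth below `min_depth` reads makes the status
#' `unknown` regardless of any call; at sufficient depth a site with no
#' alternate-allele call is `Homozygous_ref`; otherwise the call stands.
#'
#' @param call Character vector of calls (`"Heterozygous"`,
#'   `"Homozygous_alt"`) with `NA` where no variant was reported.
#' @param depth Integer vector of read depths at the site (from the
#'   coverage table, which governs this rule).
#' @param policy A [status_policy()].
#' @return Character vector of the four status values.
#' @export
determine_status <- function(call, depth, policy = status_policy()) {
  if (length(call) != length(depth)) stop("call and depth lengths differ")
  if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
  bad <- !is.na(call) & !call %in% CALL_LEVELS
  if (any(bad)) stop("unrecognized call value: ", call[which(bad)[1]])
  out <- ifelse(depth < policy$min_depth, "unknown",
                ifelse(is.na(call), "Homozygous_ref", call))
  as.character(out)
}

#' Per-sample status column over the union variants
#'
#' Merges one sample's PASS calls with its coverage at every union
#' position and applies [determine_status()].
#'
#' @param calls The sample's call table (`CHROM`, `POS`, `REF`, `ALT`,
#'   `call`); variant keys not in `union_keys` are ignored.
#' @param coverage The sample's coverage table (`CHROM`, `POS`, `depth`)
#'   covering every union position.
#' @param union_keys The union variant keys.
#' @param policy A [status_policy()].
#' @return A `data.table` `CHROM`, `POS`, `REF`, `ALT`, `status`.
#' @export
sample_status_table <- function(calls, coverage, union_keys, policy = status_policy()) {
  keys <- data.table::as.data.table(union_keys)[, KEY_COLS, with = FALSE]
  calls <- data.table::as.data.table(calls)
  cov <- data.table::as.data.table(coverage)[, c("CHROM", "POS", "depth"), with = FALSE]
  merged <- merge(keys, calls[, c(KEY_COLS, "call"), with = FALSE],
                  by = KEY_COLS, all.x = TRUE)
  merged <- merge(merged, cov, by = c("CHROM", "POS"), all.x = TRUE)
  if (anyNA(merged$depth)) {
    miss <- merged[is.na(merged$depth)][1L]
    stop("coverage table lacks union position ", miss$CHROM, ":", miss$POS)
  }
  merged$status <- determine_status(merged$call, merged$depth, policy)
  sort_variant_keys(merged[, c(KEY_COLS, "status"), with = FALSE])
}

#' Combine per-sample status tables into a status matrix
#'
#' Rows are the sorted union variant keys; from the fifth column onward
#' the columns are the sample barcodes, in the input order.
#'
#' @param status_tables Named list of per-sample tables from
#'   [sample_status_table()]; names are the sample barcodes.
#' @param union_keys The union variant keys every table must cover.
#' @return A status matrix `data.table`.
#' @export
combine_samples <- function(status_tables, union_keys) {
  if (is.null(names(status_tables)) || any(names(status_tables) == "")) {
    stop("status_tables must be a named list (names = sample barcodes)")
  }
  mat <- sort_variant_keys(data.table::as.data.table(union_keys)[, KEY_COLS, with = FALSE])
  for (sm in names(status_tables)) {
    tab <- data.table::as.data.table(status_tables[[sm]])
    merged <- merge(mat[, KEY_COLS, with = FALSE], tab[, c(KEY_COLS, "status"), with = FALSE],
                    by = KEY_COLS, all.x = TRUE, sort = FALSE)
    merged <- sort_variant_keys(merged)
    if (anyNA(merged$status)) {
      miss <- merged[is.na(merged$status)][1L]
      stop("sample ", sm, " is missing union variant ",
           miss$CHROM, ":", miss$POS, ":", miss$REF, ">", miss$ALT)
    }
    mat[, (sm) := merged$status]
  }
  mat[]
}

#' Row-chunked processing of a large status table
#'
#' Splits a tab-separated table (header + data rows) into chunks of
#' `chunk_rows` data rows, written as `segment_0000.txt`,
#' `segment_0001.txt`, ... without headers, applies a row-wise operation
#' to each chunk and merges the results. Equivalent by construction to
#' applying the operation unchunked; exists so very large cohort tables
#' can be processed within memory bounds.
#'
#' @param path Input TSV with header.
#' @param op A function `data.table -> data.table` that treats rows
#'   independently.
#' @param chunk_rows Rows per chunk (default 50000).
#' @param chunk_dir Where chunk files are written (default: a fresh
#'   temporary directory).
#' @param prefix Chunk file prefix (default `"segment_"`).
#' @return The merged result `data.table`.
#' @export
process_chunked <- function(path, op, chunk_rows = 50000L, chunk_dir = NULL,
                            prefix = "segment_") {
  stopifnot(chunk_rows >= 1)
  if (is.null(chunk_dir)) chunk_dir <- tempfile("chunks_")
  dir.create(chunk_dir, showWarnings = FALSE, recursive = TRUE)
  header <- data.table::fread(path, nrows = 0L, header = TRUE, sep = "\t")
  col_names <- names(header)
  lines <- readLines(path)
  body <- lines[-1L]
  n <- length(body)
  n_chunks <- max(1L, ceiling(n / chunk_rows))
  results <- vector("list", n_chunks)
  for (i in seq_len(n_chunks)) {
    lo <- (i - 1L) * chunk_rows + 1L
    hi <- min(i * chunk_rows, n)
    chunk_file <- file.path(chunk_dir, sprintf("%s%04d.txt", prefix, i - 1L))
    writeLines(body[seq(lo, hi)], chunk_file)
    chunk <- if (hi >= lo) {
      data.table::fread(chunk_file, header = FALSE, sep = "\t",
                        col.names = col_names, colClasses = list(character = 1))
    } else {
      header
    }
    results[[i]] <- op(chunk)
  }
  data.table::rbindlist(results)
}

#' Keep potential SNPs
#'
#' Removes variants that are `unknown` or `Homozygous_ref` across every
#' sample — i.e. keeps rows carrying at least one observed alternate
#' allele in the cohort.
#'
#' @param mat A status matrix.
#' @return The surviving rows.
#' @export
filter_potential_snps <- function(mat) {
  dt <- data.table::as.data.table(mat)
  cols <- sample_cols(dt)
  if (!length(cols)) stop("status matrix has no sample columns")
  has_alt <- Reduce(`|`, lapply(cols, function(cn) {
    dt[[cn]] %in% c("Heterozygous", "Homozygous_alt")
  }))
  dt[has_alt]
}
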