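# Readers and writers for every on-disk artifact the pipeline touches:
# single-sample VCF, samtools-depth TSV, BED3, status tables, patient
# lists, clinical CSV, Annovar avinput.

#' Read a single-sample VCF
#'
#' Parses a VCF 4.x file (plain or gzipped) holding one sample and returns
#' one row per (site, alternate allele). Genotype is derived from the GT
#' field (`0/1` or `0|1` -> Heterozygous, `1/1` -> Homozygous_alt), total
#' depth from `DP`, and variant depth from `VD` if present (VarDict) else
#' from the alternate entry of `AD`. Multi-allelic records are split into
#' one row per alternate allele. Non-SNV alleles are dropped with a
#' warning (the pipeline is SNV-only).
#'
#' @param path Path to a VCF file with a `#CHROM` header line.
#' @return A `data.table` with columns `CHROM`, `POS`, `REF`, `ALT`,
#'   `FILTER`, `sample_id`, `call`, `total_depth`, `variant_depth`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  head_lines <- readLines(con, n = 500L)
  close(con)
  if (!any(startsWith(head_lines, "#CHROM"))) {
    stop("not a valid VCF (no #CHROM header line): ", path)
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  gt <- v@gt
  empty <- data.table::data.table(
    CHROM = character(), POS = integer(), REF = character(), ALT = character(),
    FILTER = character(), sample_id = character(), call = character(),
    total_depth = integer(), variant_depth = integer())
  if (is.null(fix) || nrow(fix) == 0L) return(empty)
  if (is.null(gt) || ncol(gt) != 2L) {
    stop("expected a single-sample VCF (one genotype column): ", path)
  }
  sample_id <- colnames(gt)[2L]
  fmt_keys <- strsplit(gt[, 1L], ":", fixed = TRUE)
  fmt_vals <- strsplit(gt[, 2L], ":", fixed = TRUE)

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    keys <- fmt_keys[[i]]
    vals <- fmt_vals[[i]]
    field <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    gt_str <- field("GT")
    dp_str <- field("DP")
    if (is.na(gt_str) || !grepl("^[0-9.]+[/|][0-9.]+$", gt_str)) {
      stop("unparseable GT field at VCF data line ", i, " of ", path)
    }
    dp <- suppressWarnings(as.integer(dp_str))
    if (is.na(dp)) stop("unparseable DP field at VCF data line ", i, " of ", path)
    alleles <- as.integer(strsplit(gt_str, "[/|]")[[1]])
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ad <- field("AD")
    ad_vec <- if (!is.na(ad)) suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]])) else NULL
    vd <- suppressWarnings(as.integer(field("VD")))
    rows <- vector("list", length(alts))
    for (a in seq_along(alts)) {
      n_copies <- sum(alleles == a)
      call <- if (n_copies >= 2L) "Homozygous_alt" else if (n_copies == 1L) "Heterozygous" else NA_character_
      vdepth <- if (!is.null(ad_vec) && length(ad_vec) >= a + 1L) ad_vec[a + 1L] else vd
      rows[[a]] <- data.table::data.table(
        CHROM = fix[i, "CHROM"], POS = as.integer(fix[i, "POS"]),
        REF = fix[i, "REF"], ALT = alts[a],
        FILTER = fix[i, "FILTER"], sample_id = sample_id, call = call,
        total_depth = dp, variant_depth = vdepth)
    }
    out[[i]] <- data.table::rbindlist(rows)
  }
  res <- data.table::rbindlist(out)
  non_snv <- nchar(res$REF) != 1L | nchar(res$ALT) != 1L | !grepl("^[ACGT]$", res$ALT)
  if (any(non_snv)) {
    warning(sum(non_snv), " non-SNV allele(s) dropped from ", basename(path))
    res <- res[!non_snv]
  }
  res[]
}

#' Write variant records as a single-sample VCF
#'
#' @param records A table with `CHROM`, `POS`, `REF`, `ALT`, `call`,
#'   `total_depth`, `variant_depth`, and optionally `FILTER` (default PASS).
#' @param path Output path.
#' @param sample_id Name for the single genotype column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_id = "SAMPLE") {
  dt <- data.table::as.data.table(records)
  filt <- if ("FILTER" %in% names(dt)) dt$FILTER else rep("PASS", nrow(dt))
  gt <- ifelse(dt$call == "Homozygous_alt", "1/1", "0/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gvpipe",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=VD,Number=1,Type=Integer,Description=\"Variant depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t"))
  body <- if (nrow(dt)) {
    paste(dt$CHROM, dt$POS, ".", dt$REF, dt$ALT, ".", filt, ".",
          "GT:DP:VD", paste(gt, dt$total_depth, dt$variant_depth, sep = ":"),
          sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Keep only PASS variants
#'
#' @param records A table with a `FILTER` column.
#' @return The rows whose `FILTER` equals `"PASS"`, order preserved.
#' @export
filter_pass <- function(records) {
  dt <- data.table::as.data.table(records)
  if (!"FILTER" %in% names(dt)) stop("records carry no FILTER column")
  dt[dt$FILTER == "PASS"]
}

#' Read a samtools-depth style TSV
#'
#' Three tab-separated columns, no header: chromosome, 1-based position,
#' depth.
#'
#' @param path Input path.
#' @return A `data.table` with columns `CHROM`, `POS`, `depth`.
#' @export
read_depth_tsv <- function(path) {
  dt <- suppressWarnings(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1),
                      col.names = c("CHROM", "POS", "depth")))
  if (nrow(dt) == 0L) {
    return(data.table::data.table(CHROM = character(), POS = integer(), depth = integer()))
  }
  if (ncol(dt) != 3L) stop("depth TSV must have exactly 3 columns: ", path)
  if (!is.numeric(dt$depth) || any(dt$depth != floor(dt$depth)) || any(dt$depth < 0)) {
    stop("non-integer or negative depth values in ", path)
  }
  dt$POS <- as.integer(dt$POS)
  dt$depth <- as.integer(dt$depth)
  dt[]
}

#' @rdname read_depth_tsv
#' @param records A table with `CHROM`, `POS`, `depth`.
#' @export
write_depth_tsv <- function(records, path) {
  dt <- data.table::as.data.table(records)[, c("CHROM", "POS", "depth"), with = FALSE]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write variant positions as a BED3 file
#'
#' Emits standard 0-based half-open intervals, one line per unique
#' (chromosome, position): `chrom  pos-1  pos`.
#'
#' @param keys A sorted variant-key table.
#' @param path Output path.
#' @export
write_bed <- function(keys, path) {
  dt <- unique(data.table::as.data.table(keys)[, c("CHROM", "POS"), with = FALSE])
  bed <- data.table::data.table(chrom = dt$CHROM, start = dt$POS - 1L, end = dt$POS)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write an Annovar avinput file
#'
#' SNV convention: `chrom  start  end  ref  alt` with start = end = the
#' 1-based position, followed by any per-sample status columns present.
#'
#' @param rows A table with the key columns and optional status columns.
#' @param path Output path.
#' @export
write_annovar_input <- function(rows, path) {
  dt <- data.table::as.data.table(rows)
  out <- data.table::data.table(chrom = dt$CHROM, start = dt$POS, end = dt$POS,
                                ref = dt$REF, alt = dt$ALT)
  extra <- sample_cols(dt)
  if (length(extra)) out <- cbind(out, dt[, extra, with = FALSE])
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read the three per-data-type patient lists
#'
#' Each file is a two-column table mapping `Case_ID` to the sample barcode
#' for one data type; the second column must be named `normal`, `tumor` or
#' `rnaseq` respectively. The three lists are outer-joined on `Case_ID`;
#' a patient absent from a list gets `NA` for that data type.
#'
#' @param normal_path,tumor_path,rnaseq_path Paths to the lists; any may
#'   be `NULL`.
#' @return A `data.table` with columns `Case_ID`, `normal`, `tumor`,
#'   `rnaseq`.
#' @export
read_patient_map <- function(normal_path = NULL, tumor_path = NULL, rnaseq_path = NULL) {
  read_one <- function(path, col) {
    if (is.null(path)) {
      dt <- data.table::data.table(Case_ID = character(), V = character())
      data.table::setnames(dt, "V", col)
      return(dt)
    }
    dt <- data.table::fread(path, header = TRUE, sep = "\t", colClasses = "character")
    if (!identical(names(dt), c("Case_ID", col))) {
      stop("patient list ", path, " must have exactly the columns 'Case_ID' and '",
           col, "', found: ", paste(names(dt), collapse = ", "))
    }
    if (anyDuplicated(dt$Case_ID)) {
      stop("duplicate Case_ID in patient list ", path, ": ",
           paste(unique(dt$Case_ID[duplicated(dt$Case_ID)]), collapse = ", "))
    }
    dt
  }
  n <- read_one(normal_path, "normal")
  t <- read_one(tumor_path, "tumor")
  r <- read_one(rnaseq_path, "rnaseq")
  out <- merge(merge(n, t, by = "Case_ID", all = TRUE), r, by = "Case_ID", all = TRUE)
  if (nrow(out) && any(is.na(out$normal) & is.na(out$tumor) & is.na(out$rnaseq))) {
    stop("patient map row with no sample barcode at all")
  }
  data.table::setorder(out, Case_ID)
  out[]
}

#' Read / write a tab-separated status table
#'
#' The pipeline's status dialect: header `CHROM POS REF ALT <sample...>`,
#' one row per variant, cells drawn from the four status values.
#'
#' @param path File path.
#' @return A status `data.table`.
#' @export
read_status_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = 1))
  if (!all(KEY_COLS %in% names(dt))) {
    stop("status table ", path, " lacks the CHROM/POS/REF/ALT key columns")
  }
  dt$POS <- as.integer(dt$POS)
  dt[]
}

#' @rdname read_status_table
#' @param mat A status table to write.
#' @export
write_status_table <- function(mat, path) {
  data.table::fwrite(data.table::as.data.table(mat), path, sep = "\t")
  invisible(path)
}

#' Read the clinical / survival table
#'
#' Comma-separated with a header; must contain `OS_months` and
#' `OS_status` (0 censored / 1 death) plus any covariate columns.
#'
#' @param path CSV path.
#' @return A `data.table`, one row per patient.
#' @export
read_clinical <- function(path) {
  dt <- data.table::fread(path, header = TRUE, strip.white = TRUE)
  need <- c("OS_months", "OS_status")
  if (!all(need %in% names(dt))) {
    stop("clinical table must contain columns OS_months and OS_status")
  }
  if (any(!dt$OS_status %in% c(0L, 1L))) stop("OS_status must be 0 or 1")
  if (any(dt$OS_months < 0)) stop("OS_months must be non-negative")
  dt[]
}
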