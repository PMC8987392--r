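# Simplified count-based candidate caller. Applies the same per-site
# thresholds a production caller would be configured with (MQ > 30,
# BQ > 25, >= 3 alt reads, VAF >= 5%, duplicate removal, SNVs only) to a
# pileup table, so the whole pipeline is exercisable without BAM files.
# Users with BAMs run a full caller upstream and feed its VCFs in instead.

#' Caller thresholds
#'
#' @param min_mapq Reads with mapping quality `<= min_mapq` are discarded
#'   (strict inequality; default 30).
#' @param min_baseq Reads with base quality `<= min_baseq` are discarded
#'   (strict; default 25).
#' @param min_alt_reads Minimum reads supporting the alternate allele
#'   (default 3).
#' @param min_vaf Minimum variant allele fraction (default 0.05), computed
#'   on quality-surviving reads.
#' @param homalt_vaf VAF at or above which a call is Homozygous_alt rather
#'   than Heterozygous (default 0.75, the conventional diploid cutoff).
#' @param dedup Remove duplicate reads before calling (default TRUE).
#' @return A named list of class `caller_params`.
#' @export
caller_params <- function(min_mapq = 30L, min_baseq = 25L, min_alt_reads = 3L,
                          min_vaf = 0.05, homalt_vaf = 0.75, dedup = TRUE) {
  stopifnot(min_vaf > 0, min_vaf < homalt_vaf, homalt_vaf <= 1,
            min_alt_reads >= 1, min_mapq >= 0, min_baseq >= 0)
  structure(list(min_mapq = min_mapq, min_baseq = min_baseq,
                 min_alt_reads = min_alt_reads, min_vaf = min_vaf,
                 homalt_vaf = homalt_vaf, dedup = isTRUE(dedup)),
            class = "caller_params")
}

#' Remove duplicate reads from a pileup
#'
#' PCR duplicates are reads with identical start position; within each
#' site, at most one observation per (read start, strand) is kept — the
#' one with the highest base quality, first encountered on ties.
#'
#' @param pileup A pileup table: `chrom`, `pos`, `ref`, `base`, `baseq`,
#'   `mapq`, `read_start`, `strand`.
#' @param by_strand Include strand in the duplicate key (default TRUE), so
#'   reverse-strand coverage is not collapsed with forward-strand reads.
#' @return The deduplicated pileup, original row order preserved.
#' @export
dedup_reads <- function(pileup, by_strand = TRUE) {
  dt <- data.table::as.data.table(pileup)
  if (nrow(dt) == 0L) return(dt)
  dt$.idx <- seq_len(nrow(dt))
  key <- c("chrom", "pos", "read_start", if (by_strand) "strand")
  ord <- order(-dt$baseq, dt$.idx, method = "radix")
  best_first <- dt[ord]
  kept <- best_first[!duplicated(best_first, by = key)]
  kept <- kept[order(kept$.idx)]
  kept$.idx <- NULL
  kept[]
}

#' Call candidate variants from a pileup table
#'
#' Per site: discard observations failing the quality thresholds
#' (strictly greater-than comparisons), count surviving reads as total
#' depth, take the most frequent non-reference base (ties broken A<C<G<T)
#' as the candidate allele, and emit a PASS record when the supporting
#' read count and allele fraction clear `min_alt_reads` and `min_vaf`.
#' Calls with VAF at or above `homalt_vaf` are Homozygous_alt, otherwise
#' Heterozygous.
#'
#' @param pileup A pileup table (see [dedup_reads()] for columns); may
#'   cover many sites.
#' @param params A [caller_params()] object.
#' @return A `data.table` of emitted records: `CHROM`, `POS`, `REF`,
#'   `ALT`, `FILTER`, `call`, `total_depth`, `variant_depth`. Sites with
#'   no qualifying variant produce no row.
#' @export
call_pileup <- function(pileup, params = caller_params()) {
  dt <- data.table::as.data.table(pileup)
  empty <- data.table::data.table(
    CHROM = character(), POS = integer(), REF = character(), ALT = character(),
    FILTER = character(), call = character(),
    total_depth = integer(), variant_depth = integer())
  if (nrow(dt) == 0L) return(empty)
  if (params$dedup) dt <- dedup_reads(dt)
  dt <- dt[dt$mapq > params$min_mapq & dt$baseq > params$min_baseq]
  if (nrow(dt) == 0L) return(empty)
  calls <- dt[, {
    depth <- .N
    alt_tab <- table(factor(base[base != ref[1L]], levels = c("A", "C", "G", "T")))
    if (sum(alt_tab) == 0L) {
      NULL
    } else {
      alt <- names(alt_tab)[which.max(alt_tab)]  # ties -> base order A<C<G<T
      vd <- as.integer(alt_tab[alt])
      vaf <- vd / depth
      if (vd >= params$min_alt_reads && vaf >= params$min_vaf) {
        list(REF = ref[1L],
             ALT = alt,
             FILTER = "PASS",
             call = if (vaf >= params$homalt_vaf) "Homozygous_alt" else "Heterozygous",
             total_depth = depth,
             variant_depth = vd)
      } else NULL
    }
  }, by = c("chrom", "pos")]
  if (nrow(calls) == 0L) return(empty)
  data.table::setnames(calls, c("chrom", "pos"), c("CHROM", "POS"))
  calls$POS <- as.integer(calls$POS)
  sort_variant_keys(calls)
}

#' Call a single pileup site
#'
#' Convenience wrapper around [call_pileup()] for one site; returns `NULL`
#' when no record is emitted.
#'
#' @inheritParams call_pileup
#' @param site A pileup table restricted to one (chrom, pos).
#' @export
call_site <- function(site, params = caller_params()) {
  res <- call_pileup(site, params)
  if (nrow(res) == 0L) NULL else res
}

#' Read / write the internal pileup table dialect
#'
#' Tab-separated with header: `chrom`, `pos`, `ref`, `base`, `baseq`,
#' `mapq`, `read_start`, `strand`.
#'
#' @param path File path.
#' @export
read_pileup <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = c("chrom", "ref", "base", "strand")))
  need <- c("chrom", "pos", "ref", "base", "baseq", "mapq", "read_start", "strand")
  if (!all(need %in% names(dt))) {
    stop("pileup table ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  dt[]
}

#' @rdname read_pileup
#' @param pileup Table to write.
#' @export
write_pileup <- function(pileup, path) {
  data.table::fwrite(data.table::as.data.table(pileup), path, sep = "\t")
  invisible(path)
}
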