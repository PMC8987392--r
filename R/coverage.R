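# Per-sample sequencing depth at the union-variant positions, with
# mapping-quality filtering. Depth here governs the 10-read status rule,
# so a position absent from the source is depth 0, never missing.

#' Depth at a set of positions from a pileup
#'
#' Counts observations with mapping quality strictly greater than
#' `min_mapq` at each requested (chromosome, position). Base quality is
#' not filtered for coverage, and reads are not deduplicated by default,
#' matching the behaviour of a plain `samtools depth -q/-Q` pass.
#'
#' @param pileup A pileup table (`chrom`, `pos`, `mapq`, ...).
#' @param positions A table with `CHROM`, `POS` (extra columns ignored);
#'   must be non-empty.
#' @param min_mapq Strict mapping-quality threshold (default 30).
#' @param dedup Deduplicate reads before counting (default FALSE).
#' @return A `data.table` `CHROM`, `POS`, `depth`, one row per requested
#'   position (duplicated query positions collapsed); uncovered positions
#'   get depth 0.
#' @export
depth_at_positions <- function(pileup, positions, min_mapq = 30L, dedup = FALSE) {
  pos_dt <- unique(data.table::as.data.table(positions)[, c("CHROM", "POS"), with = FALSE])
  if (nrow(pos_dt) == 0L) stop("positions must be non-empty")
  dt <- data.table::as.data.table(pileup)
  if (dedup && nrow(dt)) dt <- dedup_reads(dt)
  dt <- dt[dt$mapq > min_mapq]
  counts <- dt[, list(depth = .N), by = c("chrom", "pos")]
  data.table::setnames(counts, c("chrom", "pos"), c("CHROM", "POS"))
  out <- merge(pos_dt, counts, by = c("CHROM", "POS"), all.x = TRUE)
  out$depth[is.na(out$depth)] <- 0L
  out$depth <- as.integer(out$depth)
  data.table::setorder(out, CHROM, POS)
  out[order(chrom_rank(out$CHROM), out$CHROM, out$POS)]
}

#' Load an external depth file at a set of positions
#'
#' Accepts real `samtools depth` output (3-column TSV) for users who ran
#' the depth tool on BAMs themselves. Positions absent from the file get
#' depth 0 (the tool omits zero-coverage rows by default).
#'
#' @param path Path to a 3-column depth TSV.
#' @param positions Table with `CHROM`, `POS`.
#' @return A `data.table` `CHROM`, `POS`, `depth` covering every
#'   requested position.
#' @export
load_external_depth <- function(path, positions) {
  pos_dt <- unique(data.table::as.data.table(positions)[, c("CHROM", "POS"), with = FALSE])
  if (nrow(pos_dt) == 0L) stop("positions must be non-empty")
  depth <- read_depth_tsv(path)
  if (anyDuplicated(depth, by = c("CHROM", "POS"))) {
    stop("duplicate position rows in depth file ", path)
  }
  out <- merge(pos_dt, depth, by = c("CHROM", "POS"), all.x = TRUE)
  out$depth[is.na(out$depth)] <- 0L
  out$depth <- as.integer(out$depth)
  out[order(chrom_rank(out$CHROM), out$CHROM, out$POS)]
}
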