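# Variant identity: (CHROM, POS, REF, ALT), SNVs only.
# All joins and unions in the pipeline key on these four columns.

KEY_COLS <- c("CHROM", "POS", "REF", "ALT")
STATUS_LEVELS <- c("Homozygous_ref", "Heterozygous", "Homozygous_alt", "unknown")
CALL_LEVELS <- c("Heterozygous", "Homozygous_alt")

#' Construct a table of variant keys
#'
#' A variant key identifies a single-nucleotide variant by chromosome,
#' 1-based position, reference allele and alternate allele. Keys are the
#' join identity for every union, merge and rescue operation in the
#' pipeline; indels and structural variants are rejected.
#'
#' @param chrom Character vector of chromosome names (e.g. `"chr1"`).
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Single-base alleles (A/C/G/T); `ref != alt` row-wise.
#' @return A `data.table` with columns `CHROM`, `POS`, `REF`, `ALT`,
#'   sorted in the canonical order (see [sort_variant_keys()]).
#' @export
variant_keys <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("variant positions must be positive integers (1-based)")
  }
  bad <- !grepl("^[ACGT]$", ref) | !grepl("^[ACGT]$", alt)
  if (any(bad)) {
    stop("only single-nucleotide A/C/G/T alleles are supported (no indels); ",
         "offending entries: ", paste(which(bad)[seq_len(min(5, sum(bad)))], collapse = ", "))
  }
  if (any(ref == alt)) stop("REF and ALT must differ")
  sort_variant_keys(data.table::data.table(CHROM = chrom, POS = pos, REF = ref, ALT = alt))
}

# Natural chromosome order: chr1..chr22, chrX, chrY, then anything else
# lexicographically. Works with or without the "chr" prefix.
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  rank <- suppressWarnings(as.numeric(core))
  rank[core == "X"] <- 23
  rank[core == "Y"] <- 24
  rank[is.na(rank)] <- 25
  rank
}

#' Sort variant keys canonically
#'
#' Total deterministic order: chromosome (natural numeric order of
#' chr1..chr22, chrX, chrY), then position, REF, ALT.
#'
#' @param keys A data.table/data.frame carrying `CHROM`, `POS`, `REF`, `ALT`.
#' @return The sorted table (a copy).
#' @export
sort_variant_keys <- function(keys) {
  dt <- data.table::as.data.table(keys)
  ord <- order(chrom_rank(dt$CHROM), dt$CHROM, dt$POS, dt$REF, dt$ALT, method = "radix")
  dt[ord]
}

# Sample columns of a status matrix: everything after the four key columns.
sample_cols <- function(mat) setdiff(names(mat), KEY_COLS)
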