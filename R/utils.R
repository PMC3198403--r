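#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Run code under a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# chrom_sizes may be a named numeric vector or a two-column data frame.
as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    stats::setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  } else if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes
  } else {
    abort("`chrom_sizes` must be a named numeric vector or a (chrom, size) data frame.")
  }
}

check_intervals <- function(x, what = "interval") {
  if (any(x$start < 0) || any(x$end <= x$start)) {
    abort(sprintf("invalid %s: need 0 <= start < end", what))
  }
  invisible(x)
}

# Exons of a gene set as a GRanges (0-based half-open in, 1-based in GRanges).
exons_as_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    gene_id = genes$gene_id
  )
}

intervals_as_granges <- function(x, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = rep_len(if (is.null(strand)) "*" else strand, nrow(x))
  )
}

# Equal-fraction bin index for positions 1..len split into n_bins bins.
position_bins <- function(len, n_bins) {
  pmin(floor((seq_len(len) - 1L) * n_bins / len) + 1L, n_bins)
}
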