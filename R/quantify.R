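#' Read alignments from SAM/BAM or BED6
#'
#' Returns a tidy alignment table with 0-based half-open coordinates. For
#' SAM/BAM input only mapped, primary alignments are kept by default (the
#' counting convention for uniquely mapped reads); the reference span is
#' taken from the CIGAR.
#'
#' @param path SAM, BAM or BED6 file (`.bed` extension selects BED).
#' @param format `"auto"`, `"bam"`, `"sam"` or `"bed"`.
#' @param primary_only Drop secondary/supplementary alignments (SAM/BAM).
#' @return Tibble: `read_id`, `chrom`, `start`, `end`, `strand`, `replicate`
#'   (filled with `"rep1"` when the source carries no replicate tag).
#' @export
read_alignments <- function(path, format = c("auto", "bam", "sam", "bed"),
                            primary_only = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, bed = "bed", bam = "bam", sam = "sam",
                     abort(sprintf("cannot infer alignment format from '%s'", path)))
  }
  if (format == "bed") {
    bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                               "name", "score", "strand"),
                           col_types = "ciicdc", progress = FALSE)
    out <- tibble(read_id = bed$name, chrom = bed$chrom, start = bed$start,
                  end = bed$end, strand = bed$strand)
  } else {
    if (format == "sam") {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    } else {
      bam <- path
    }
    flag <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = if (primary_only) FALSE else NA,
      isSupplementaryAlignment = if (primary_only) FALSE else NA
    )
    ga <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(flag = flag, what = "qname")
    )
    out <- tibble(
      read_id = S4Vectors::mcols(ga)$qname,
      chrom = as.character(GenomicAlignments::seqnames(ga)),
      start = GenomicAlignments::start(ga) - 1L,
      end = GenomicAlignments::end(ga),
      strand = as.character(GenomicAlignments::strand(ga))
    )
  }
  # replicate tag, when present, is encoded as "...:rep=<name>" in read ids
  rep_tag <- stringr::str_match(out$read_id, "rep=([^:\\s]+)")[, 2]
  out$replicate <- dplyr::coalesce(rep_tag, "rep1")
  check_intervals(out, "alignment")
  out
}

#' Classify a read as sense or antisense to a gene
#'
#' Under the dUTP strand-specific chemistry (the default `"reverse"`
#' orientation) surviving reads derive from first-strand cDNA, so a read
#' maps to the strand opposite its source transcript: alignment strand
#' opposite to the gene strand means sense. `"forward"` orientation flips
#' the rule for protocols that sequence the transcript strand directly.
#'
#' @param read_strand,gene_strand `"+"`/`"-"` vectors (recycled).
#' @param orientation `"reverse"` (dUTP, default) or `"forward"`.
#' @return Character vector `"sense"`/`"antisense"`.
#' @export
assign_read_strand <- function(read_strand, gene_strand,
                               orientation = c("reverse", "forward")) {
  orientation <- match.arg(orientation)
  opposite <- read_strand != gene_strand
  sense <- if (orientation == "reverse") opposite else !opposite
  ifelse(sense, "sense", "antisense")
}

# Unique gene assignment: reads overlapping exon space of >1 gene dropped.
# Returns tibble(aln_row, gene_id, exon_row) for unambiguous read-gene pairs.
assign_reads_to_genes <- function(alignments, genes) {
  agr <- intervals_as_granges(alignments)
  egr <- exons_as_granges(genes)
  hits <- GenomicRanges::findOverlaps(agr, egr, ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(tibble(aln_row = integer(), gene_id = character(), exon_row = integer()))
  }
  h <- tibble(aln_row = S4Vectors::queryHits(hits),
              exon_row = S4Vectors::subjectHits(hits),
              gene_id = genes$gene_id[S4Vectors::subjectHits(hits)])
  ambiguous <- h |>
    distinct(.data$aln_row, .data$gene_id) |>
    count(.data$aln_row) |>
    filter(.data$n > 1) |>
    pull(.data$aln_row)
  filter(h, !.data$aln_row %in% ambiguous)
}

#' Count reads per gene, split by strand
#'
#' A read counts toward a gene when its alignment overlaps the gene's exonic
#' bases by at least 1 bp; reads overlapping the exon space of more than one
#' gene are discarded as ambiguous. In stranded mode sense and antisense
#' reads are counted separately; unstranded mode reports their sum.
#'
#' @param alignments Alignment tibble from [read_alignments()] (columns
#'   `chrom`, `start`, `end`, `strand`, optional `replicate`).
#' @param genes Gene models from [read_gene_models()].
#' @param orientation Library orientation, see [assign_read_strand()].
#' @param mode `"stranded"` or `"unstranded"`.
#' @return Tibble of class `ss_counts`: `gene_id`, `replicate`, `sense`,
#'   `antisense` (stranded) or `count` (unstranded), zero-filled over all
#'   genes x replicates. Attribute `library_sizes`: tibble of per-replicate
#'   total mapped reads.
#' @export
count_gene_reads <- function(alignments, genes,
                             orientation = c("reverse", "forward"),
                             mode = c("stranded", "unstranded")) {
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  alignments <- check_alignments(alignments, genes)
  lib <- alignments |> count(.data$replicate, name = "total_mapped")
  asg <- assign_reads_to_genes(alignments, genes) |>
    distinct(.data$aln_row, .data$gene_id)
  gstrand <- gene_lengths(genes)
  asg <- asg |>
    mutate(replicate = alignments$replicate[.data$aln_row],
           read_strand = alignments$strand[.data$aln_row]) |>
    left_join(select(gstrand, "gene_id", gene_strand = "strand"), by = "gene_id") |>
    mutate(class = assign_read_strand(.data$read_strand, .data$gene_strand, orientation))
  counts <- asg |>
    count(.data$gene_id, .data$replicate, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0L)
  for (col in c("sense", "antisense")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- counts |>
    tidyr::complete(gene_id = gstrand$gene_id,
                    replicate = unique(alignments$replicate),
                    fill = list(sense = 0L, antisense = 0L)) |>
    arrange(.data$gene_id, .data$replicate)
  if (mode == "unstranded") {
    counts <- counts |>
      mutate(count = .data$sense + .data$antisense) |>
      select("gene_id", "replicate", "count")
  }
  structure(counts, class = c("ss_counts", class(counts)), library_sizes = lib)
}

check_alignments <- function(alignments, regions) {
  alignments <- as_tibble(alignments)
  if (is.null(alignments$replicate)) alignments$replicate <- "rep1"
  known <- unique(regions$chrom)
  bad <- !alignments$chrom %in% known
  if (any(bad)) {
    warn(sprintf("%d alignment(s) on chromosomes absent from the annotation skipped",
                 sum(bad)))
    alignments <- alignments[!bad, , drop = FALSE]
  }
  alignments
}

#' Count sense reads per intron
#'
#' Counts reads supporting intron retention: a read counts to an intron only
#' when at least `min_overlap_frac` of its length lies inside the intron
#' (default one half), so exon-intron junction reads are not taken as
#' retention evidence. Only reads sense to the host gene are counted. Reads
#' meeting the threshold for more than one intron are discarded.
#'
#' @inheritParams count_gene_reads
#' @param introns Intron table from [build_intron_db()].
#' @param min_overlap_frac Minimum fraction of the read length inside the
#'   intron.
#' @return Tibble: `gene_id`, `intron_index`, `length`, `count` (pooled over
#'   replicates), zero-filled.
#' @export
count_intron_reads <- function(alignments, introns,
                               orientation = c("reverse", "forward"),
                               min_overlap_frac = 0.5) {
  orientation <- match.arg(orientation)
  alignments <- check_alignments(alignments, introns)
  agr <- intervals_as_granges(alignments)
  igr <- intervals_as_granges(introns)
  hits <- GenomicRanges::findOverlaps(agr, igr, ignore.strand = TRUE)
  h <- tibble(aln_row = S4Vectors::queryHits(hits),
              intron_row = S4Vectors::subjectHits(hits))
  if (nrow(h) > 0) {
    ov_start <- pmax(alignments$start[h$aln_row], introns$start[h$intron_row])
    ov_end <- pmin(alignments$end[h$aln_row], introns$end[h$intron_row])
    read_len <- alignments$end[h$aln_row] - alignments$start[h$aln_row]
    h <- h[(ov_end - ov_start) >= min_overlap_frac * read_len, , drop = FALSE]
    dup <- h |> count(.data$aln_row) |> filter(.data$n > 1) |> pull(.data$aln_row)
    h <- filter(h, !.data$aln_row %in% dup)
    h <- h |>
      mutate(class = assign_read_strand(alignments$strand[.data$aln_row],
                                        introns$strand[.data$intron_row],
                                        orientation)) |>
      filter(.data$class == "sense")
  }
  counts <- h |> count(.data$intron_row, name = "count")
  introns |>
    mutate(.row = dplyr::row_number()) |>
    left_join(counts, by = c(".row" = "intron_row")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    select("gene_id", "intron_index", "length", "count")
}

#' Count reads per non-coding region
#'
#' Strand-agnostic counting against the NCR set. A read spanning an NCR
#' boundary counts toward the NCR it overlaps most (ties discarded).
#'
#' @inheritParams count_gene_reads
#' @param ncrs NCR table from [derive_ncrs()].
#' @return Tibble: `ncr_id`, `length`, `count` (both strands pooled).
#' @export
count_ncr_reads <- function(alignments, ncrs) {
  alignments <- check_alignments(alignments, ncrs)
  agr <- intervals_as_granges(alignments)
  ngr <- intervals_as_granges(ncrs)
  hits <- GenomicRanges::findOverlaps(agr, ngr, ignore.strand = TRUE)
  h <- tibble(aln_row = S4Vectors::queryHits(hits),
              ncr_row = S4Vectors::subjectHits(hits))
  if (nrow(h) > 0) {
    h$overlap <- pmin(alignments$end[h$aln_row], ncrs$end[h$ncr_row]) -
      pmax(alignments$start[h$aln_row], ncrs$start[h$ncr_row])
    h <- h |>
      group_by(.data$aln_row) |>
      filter(.data$overlap == max(.data$overlap)) |>
      filter(dplyr::n() == 1) |>
      ungroup()
  }
  counts <- h |> count(.data$ncr_row, name = "count")
  ncrs |>
    mutate(.row = dplyr::row_number()) |>
    left_join(counts, by = c(".row" = "ncr_row")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    select("ncr_id", "length", "count")
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' `RPKM = 1e9 * count / (length * total_mapped)`.
#'
#' @param count Read count(s).
#' @param exonic_length Exon-model length(s), bp.
#' @param total_mapped Total mapped reads in the library.
#' @return Numeric RPKM values.
#' @export
compute_rpkm <- function(count, exonic_length, total_mapped) {
  if (any(exonic_length <= 0)) abort("exonic_length must be > 0")
  if (any(total_mapped <= 0)) abort("total_mapped must be > 0")
  1e9 * count / (exonic_length * total_mapped)
}

#' Per-gene, per-replicate RPKM table
#'
#' @param counts `ss_counts` from [count_gene_reads()].
#' @param genes Gene models (for exonic lengths), or a `gene_id`/
#'   `exonic_length` tibble.
#' @param strand Which counts to convert: `"sense"` (default),
#'   `"antisense"`, or `"count"` for unstranded tables.
#' @return Tibble: `gene_id`, `replicate`, `count`, `rpkm`; attribute
#'   `expression`: tibble of per-gene `E` = sum of RPKM across replicates.
#' @export
rpkm_table <- function(counts, genes, strand = c("sense", "antisense", "count")) {
  strand <- match.arg(strand)
  lens <- if ("exonic_length" %in% names(genes)) {
    select(genes, "gene_id", "exonic_length")
  } else {
    select(gene_lengths(genes), "gene_id", "exonic_length")
  }
  lib <- attr(counts, "library_sizes")
  if (is.null(lib)) abort("`counts` lacks the library_sizes attribute")
  if (!strand %in% names(counts)) {
    abort(sprintf("column '%s' not present in counts", strand))
  }
  out <- counts |>
    as_tibble() |>
    left_join(lens, by = "gene_id") |>
    left_join(lib, by = "replicate") |>
    mutate(rpkm = compute_rpkm(.data[[strand]], .data$exonic_length,
                               .data$total_mapped)) |>
    select("gene_id", "replicate", count = dplyr::all_of(strand), "rpkm")
  expr <- out |> group_by(.data$gene_id) |> summarise(E = sum(.data$rpkm), .groups = "drop")
  structure(out, expression = expr)
}

#' Per-gene expression values E (sum of RPKM across replicates)
#'
#' @param rpkm Output of [rpkm_table()].
#' @return Tibble: `gene_id`, `E`.
#' @export
gene_expression <- function(rpkm) {
  attr(rpkm, "expression")
}

# Project unambiguous alignments onto spliced transcript coordinates
# (0-based, 5'->3'). One row per alignment-exon overlap.
project_to_transcripts <- function(alignments, genes, orientation = "reverse") {
  ex <- genes |>
    arrange(.data$gene_id, .data$start) |>
    group_by(.data$gene_id) |>
    mutate(exon_len = .data$end - .data$start,
           offset = cumsum(dplyr::lag(.data$exon_len, default = 0L)),
           tx_len = sum(.data$exon_len)) |>
    ungroup()
  asg <- assign_reads_to_genes(alignments, ex)
  if (nrow(asg) == 0) {
    return(tibble(gene_id = character(), tstart = integer(), tend = integer(),
                  class = character()))
  }
  e <- ex[asg$exon_row, ]
  a_start <- alignments$start[asg$aln_row]
  a_end <- alignments$end[asg$aln_row]
  ov_s <- pmax(a_start, e$start)
  ov_e <- pmin(a_end, e$end)
  p1 <- e$offset + (ov_s - e$start)
  p2 <- e$offset + (ov_e - e$start)
  minus <- e$strand == "-"
  tstart <- ifelse(minus, e$tx_len - p2, p1)
  tend <- ifelse(minus, e$tx_len - p1, p2)
  tibble(
    gene_id = asg$gene_id,
    tx_len = e$tx_len,
    tstart = as.integer(tstart),
    tend = as.integer(tend),
    class = assign_read_strand(alignments$strand[asg$aln_row], e$strand, orientation)
  )
}

# Binned coverage (sum of per-base coverage per bin) for one gene's
# projected fragments.
binned_coverage <- function(tstart, tend, tx_len, n_bins) {
  cov <- IRanges::coverage(IRanges::IRanges(start = tstart + 1L, end = tend),
                           width = tx_len)
  v <- as.numeric(cov)
  as.numeric(tapply(v, position_bins(tx_len, n_bins), mean))
}

#' Gene-body coverage metagene profile
#'
#' Per gene, base-level coverage over the spliced transcript (5' to 3') is
#' averaged within equal-fraction bins and divided by the gene's mean
#' coverage; the profile is the mean over genes. Eligible genes have exonic
#' length of at least `n_bins` and at least one mapped read of the selected
#' strand class.
#'
#' @inheritParams count_gene_reads
#' @param n_bins Number of bins along the gene body.
#' @param strand_filter `"sense"`, `"antisense"` or `"both"`.
#' @return Tibble: `bin`, `position` (fraction of gene body), `coverage`
#'   (mean normalized coverage; 1 = the gene-average), `n_genes`.
#' @export
gene_body_coverage_profile <- function(alignments, genes, n_bins = 100,
                                       strand_filter = c("sense", "antisense", "both"),
                                       orientation = c("reverse", "forward")) {
  strand_filter <- match.arg(strand_filter)
  orientation <- match.arg(orientation)
  alignments <- check_alignments(alignments, genes)
  lens <- gene_lengths(genes)
  proj <- project_to_transcripts(alignments, genes, orientation)
  if (strand_filter != "both") proj <- filter(proj, .data$class == strand_filter)
  proj <- proj |>
    left_join(select(lens, "gene_id", "exonic_length"), by = "gene_id") |>
    filter(.data$exonic_length >= n_bins)
  if (nrow(proj) == 0) abort("no eligible gene (length >= n_bins with mapped reads)")
  profs <- proj |>
    group_by(.data$gene_id) |>
    group_map(function(df, key) {
      b <- binned_coverage(df$tstart, df$tend, df$tx_len[1], n_bins)
      b / mean(b)
    })
  mat <- do.call(rbind, profs)
  tibble(bin = seq_len(n_bins),
         position = (seq_len(n_bins) - 0.5) / n_bins,
         coverage = colMeans(mat),
         n_genes = nrow(mat))
}

#' Antisense-fraction metagene profile
#'
#' Percentage of antisense coverage per gene-body bin, pooled over genes:
#' `100 * antisense / (sense + antisense)` per bin. Bins with zero total
#' coverage are reported as `NA`.
#'
#' @inheritParams gene_body_coverage_profile
#' @return Tibble: `bin`, `position`, `percent_antisense`, `n_genes`.
#' @export
antisense_fraction_profile <- function(alignments, genes, n_bins = 100,
                                       orientation = c("reverse", "forward")) {
  orientation <- match.arg(orientation)
  alignments <- check_alignments(alignments, genes)
  lens <- gene_lengths(genes)
  proj <- project_to_transcripts(alignments, genes, orientation) |>
    left_join(select(lens, "gene_id", "exonic_length"), by = "gene_id") |>
    filter(.data$exonic_length >= n_bins)
  if (nrow(proj) == 0) abort("no eligible gene (length >= n_bins with mapped reads)")
  pool <- function(df) {
    out <- matrix(0, nrow = 2, ncol = n_bins,
                  dimnames = list(c("sense", "antisense"), NULL))
    for (cl in c("sense", "antisense")) {
      d <- df[df$class == cl, , drop = FALSE]
      if (nrow(d) > 0) {
        out[cl, ] <- out[cl, ] + binned_coverage(d$tstart, d$tend, d$tx_len[1], n_bins)
      }
    }
    out
  }
  mats <- proj |> group_by(.data$gene_id) |> group_map(function(df, key) pool(df))
  tot <- Reduce(`+`, mats)
  denom <- colSums(tot)
  tibble(bin = seq_len(n_bins),
         position = (seq_len(n_bins) - 0.5) / n_bins,
         percent_antisense = ifelse(denom > 0, 100 * tot["antisense", ] / denom, NA_real_),
         n_genes = length(mats))
}

#' Export per-strand genome coverage as bedGraph
#'
#' @param alignments Alignment tibble.
#' @param path Output file.
#' @param strand Restrict to `"+"`, `"-"`, or use both (`NULL`).
#' @export
write_bedgraph <- function(alignments, path, strand = NULL) {
  if (!is.null(strand)) alignments <- filter(alignments, .data$strand == !!strand)
  gr <- intervals_as_granges(alignments)
  cov <- GenomicRanges::coverage(gr)
  rows <- purrr::map_dfr(names(cov), function(ch) {
    r <- cov[[ch]]
    tibble(chrom = ch,
           start = cumsum(c(0, S4Vectors::runLength(r)))[seq_along(S4Vectors::runLength(r))],
           end = cumsum(S4Vectors::runLength(r)),
           value = S4Vectors::runValue(r))
  }) |> filter(.data$value > 0)
  readr::write_tsv(rows, path, col_names = FALSE)
  invisible(path)
}
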