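#' Read gene models from a GFF3 or GTF annotation
#'
#' Builds one gene model per gene: the exon union of its longest transcript
#' (default, the "unique gene model" convention) or of all isoforms. Exons are
#' merged where they overlap, and coordinates are returned 0-based half-open.
#'
#' @param path Annotation file (GFF3 or GTF; gzip transparent).
#' @param dialect `"auto"` (by file extension), `"gff3"` or `"gtf"`.
#' @param isoform `"longest"` uses the exons of the transcript with the
#'   largest summed exon length; `"union"` pools exons across all isoforms.
#' @return A tibble with one row per merged exon: `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @export
read_gene_models <- function(path, dialect = c("auto", "gff3", "gtf"),
                             isoform = c("longest", "union")) {
  dialect <- match.arg(dialect)
  isoform <- match.arg(isoform)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3"),
    error = function(e) abort(sprintf("failed to parse %s (%s): %s", path, dialect,
                                      conditionMessage(e)))
  )
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0) abort(sprintf("no exon features found in %s", path))

  if (dialect == "gtf") {
    if (is.null(ex$gene_id) || is.null(ex$transcript_id)) {
      abort("GTF exons must carry gene_id and transcript_id attributes")
    }
    tx_id <- as.character(ex$transcript_id)
    gene_of_tx <- tapply(as.character(ex$gene_id), tx_id, function(x) x[[1]])
  } else {
    parent <- ex$Parent
    if (is.null(parent) || any(lengths(parent) == 0)) {
      abort("GFF3 exon without a Parent attribute")
    }
    tx_id <- vapply(parent, function(p) as.character(p)[[1]], character(1))
    # map transcript -> gene via mRNA/transcript features; exons parented
    # directly on a gene keep that gene id
    tx_feats <- gr[tolower(as.character(gr$type)) %in%
                     c("mrna", "transcript", "ncrna", "lnc_rna", "trna", "rrna")]
    tx_parent <- stats::setNames(
      vapply(tx_feats$Parent, function(p) if (length(p)) as.character(p)[[1]] else NA_character_,
             character(1)),
      as.character(tx_feats$ID)
    )
    gene_of_tx <- ifelse(tx_id %in% names(tx_parent), tx_parent[tx_id], tx_id)
    gene_of_tx <- tapply(gene_of_tx, tx_id, function(x) x[[1]])
  }

  exons <- tibble(
    tx_id = tx_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex))
  ) |>
    mutate(gene_id = as.character(gene_of_tx[.data$tx_id]))

  bad <- exons |>
    group_by(.data$gene_id) |>
    summarise(k = dplyr::n_distinct(paste(.data$chrom, .data$strand)), .groups = "drop") |>
    filter(.data$k > 1)
  if (nrow(bad) > 0) {
    abort(sprintf("gene(s) with exons on multiple chromosomes/strands: %s",
                  paste(utils::head(bad$gene_id, 3), collapse = ", ")))
  }

  if (isoform == "longest") {
    keep_tx <- exons |>
      group_by(.data$gene_id, .data$tx_id) |>
      summarise(len = sum(.data$end - .data$start), .groups = "drop") |>
      group_by(.data$gene_id) |>
      arrange(dplyr::desc(.data$len), .data$tx_id, .by_group = TRUE) |>
      slice(1) |>
      pull(.data$tx_id)
    exons <- filter(exons, .data$tx_id %in% keep_tx)
  }
  merge_exons(select(exons, "gene_id", "chrom", "start", "end", "strand"))
}

# Merge overlapping/contiguous exon records within each gene.
merge_exons <- function(exons) {
  check_intervals(exons, "exon")
  exons |>
    arrange(.data$gene_id, .data$start) |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    group_modify(function(df, key) {
      ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
      tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) |>
    ungroup() |>
    select("gene_id", "chrom", "start", "end", "strand") |>
    arrange(.data$gene_id, .data$start)
}

#' Exonic length per gene
#'
#' @param genes Gene-model tibble from [read_gene_models()].
#' @return Tibble with `gene_id`, `chrom`, `strand`, `exonic_length`,
#'   `span_start`, `span_end`, `n_exons`.
#' @export
gene_lengths <- function(genes) {
  genes |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      exonic_length = sum(.data$end - .data$start),
      span_start = min(.data$start), span_end = max(.data$end),
      n_exons = dplyr::n(), .groups = "drop"
    )
}

#' Build the intron database from gene models
#'
#' Introns are the gaps between consecutive merged exons of each gene;
#' `intron_index` counts 5' to 3' in transcript orientation, so on the minus
#' strand the genomically last gap gets index 1.
#'
#' @inheritParams gene_lengths
#' @return Tibble: `gene_id`, `intron_index`, `chrom`, `start`, `end`,
#'   `strand`, `length`.
#' @export
build_intron_db <- function(genes) {
  genes |>
    arrange(.data$gene_id, .data$start) |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    group_modify(function(df, key) {
      k <- nrow(df)
      if (k < 2) return(tibble(intron_index = integer(), start = integer(), end = integer()))
      s <- df$end[-k]
      e <- df$start[-1]
      idx <- if (key$strand == "-") rev(seq_len(k - 1L)) else seq_len(k - 1L)
      tibble(intron_index = idx, start = s, end = e)
    }) |>
    ungroup() |>
    mutate(length = .data$end - .data$start) |>
    select("gene_id", "intron_index", "chrom", "start", "end", "strand", "length") |>
    arrange(.data$gene_id, .data$intron_index)
}

#' Derive non-coding regions (NCRs)
#'
#' NCRs are the intervals of the genome at least `min_distance` (default
#' 5 kb) from any annotated exon. With `pad = "gene"` whole gene spans are
#' padded instead of individual exons.
#'
#' @inheritParams gene_lengths
#' @param chrom_sizes Named numeric vector (or two-column data frame) of
#'   chromosome lengths in bp.
#' @param min_distance Minimum distance to any exon, bp.
#' @param pad Pad `"exon"` intervals (default) or whole `"gene"` spans.
#' @return Tibble: `ncr_id`, `chrom`, `start`, `end` (0-based half-open),
#'   `length`.
#' @export
derive_ncrs <- function(genes, chrom_sizes, min_distance = 5000,
                        pad = c("exon", "gene")) {
  pad <- match.arg(pad)
  sizes <- as_chrom_sizes(chrom_sizes)
  src <- if (pad == "gene") {
    gene_lengths(genes) |>
      transmute(.data$gene_id, .data$chrom, start = .data$span_start, end = .data$span_end)
  } else {
    genes
  }
  beyond <- src |>
    mutate(csize = sizes[.data$chrom]) |>
    filter(is.na(.data$csize) | .data$end > .data$csize)
  if (nrow(beyond) > 0) {
    abort(sprintf("exon beyond chromosome end (or unknown chromosome) for gene(s): %s",
                  paste(unique(utils::head(beyond$gene_id, 3)), collapse = ", ")))
  }
  padded <- src |>
    mutate(start = pmax(.data$start - min_distance, 0),
           end = pmin(.data$end + min_distance, sizes[.data$chrom]))
  out <- purrr::map_dfr(names(sizes), function(ch) {
    csize <- sizes[[ch]]
    p <- filter(padded, .data$chrom == ch)
    if (nrow(p) == 0) return(tibble(chrom = ch, start = 0, end = csize))
    cov <- IRanges::reduce(IRanges::IRanges(start = p$start + 1L, end = p$end))
    gaps <- IRanges::gaps(cov, start = 1L, end = csize)
    tibble(chrom = ch, start = IRanges::start(gaps) - 1, end = IRanges::end(gaps))
  })
  out |>
    filter(.data$end > .data$start) |>
    mutate(length = .data$end - .data$start,
           ncr_id = sprintf("NCR_%s_%d", .data$chrom,
                            stats::ave(.data$start, .data$chrom, FUN = seq_along))) |>
    select("ncr_id", "chrom", "start", "end", "length")
}

# Spliced transcript sequence of one gene (5'->3'), given exons in genomic order.
spliced_sequence <- function(exons, genome) {
  ch <- exons$chrom[1]
  if (!ch %in% names(genome)) abort(sprintf("chromosome %s absent from genome", ch))
  parts <- Biostrings::DNAStringSet(lapply(seq_len(nrow(exons)), function(i) {
    Biostrings::subseq(genome[[ch]], start = exons$start[i] + 1L, end = exons$end[i])
  }))
  s <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (exons$strand[1] == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Base-composition metagene profile
#'
#' Splits each gene's spliced transcript (5' to 3') into `n_bins`
#' equal-fraction bins and reports the mean percentage of the selected bases
#' per bin, averaged over genes. Genes shorter than `n_bins` nt are skipped.
#'
#' @inheritParams gene_lengths
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param bases Character vector of bases to count, subset of A/C/G/T
#'   (e.g. `c("G", "C")` for percent GC, `"T"` for percent T).
#' @param n_bins Number of bins along the gene body.
#' @return Tibble: `bin`, `position` (bin midpoint as fraction of gene body),
#'   `percent`, `n_genes`.
#' @export
sequence_composition_profile <- function(genes, genome, bases = c("G", "C"),
                                         n_bins = 100) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  bases <- toupper(bases)
  if (!all(bases %in% c("A", "C", "G", "T"))) abort("`bases` must be a subset of A,C,G,T")
  lens <- gene_lengths(genes)
  eligible <- lens$gene_id[lens$exonic_length >= n_bins]
  if (length(eligible) == 0) abort("no gene with exonic length >= n_bins")
  profs <- purrr::map(eligible, function(g) {
    ex <- filter(genes, .data$gene_id == g) |> arrange(.data$start)
    s <- spliced_sequence(ex, genome)
    hit <- as.integer(strsplit(as.character(s), "")[[1]] %in% bases)
    as.numeric(tapply(hit, position_bins(length(hit), n_bins), mean)) * 100
  })
  mat <- do.call(rbind, profs)
  tibble(
    bin = seq_len(n_bins),
    position = (seq_len(n_bins) - 0.5) / n_bins,
    percent = colMeans(mat),
    n_genes = length(eligible)
  )
}

#' Write intervals as BED6
#'
#' Accepts the intron table (names become `gene_id.intron_<i>`), the NCR
#' table, or any tibble with `chrom`, `start`, `end` and optional `name`,
#' `score`, `strand` columns. Coordinates are written as-is (BED is 0-based
#' half-open, matching the internal convention).
#'
#' @param x Interval tibble.
#' @param path Output file.
#' @export
write_bed6 <- function(x, path) {
  has <- function(col) col %in% names(x)
  name <- if (has("name")) x$name
  else if (has("intron_index")) sprintf("%s.intron_%d", x$gene_id, x$intron_index)
  else if (has("ncr_id")) x$ncr_id
  else if (has("gene_id")) x$gene_id
  else sprintf("region_%d", seq_len(nrow(x)))
  bed <- tibble(
    chrom = x$chrom, start = x$start, end = x$end, name = name,
    score = if (has("score")) x$score else 0,
    strand = if (has("strand")) x$strand else "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
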