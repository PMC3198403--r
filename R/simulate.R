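#' Simulate a gene annotation and genome
#'
#' Lays out non-overlapping multi-exon genes along one chromosome with
#' intergenic gaps wide enough (default at least 12 kb) that non-coding
#' regions survive the 5 kb exon padding. Gene structure defaults emulate a
#' compact plant genome: 1-5 exons of 200-500 bp (about 1.1 kb of exonic
#' model on average) separated by 100-400 bp introns. The genome sequence
#' is uniform random ACGT.
#'
#' @param n_genes Number of genes.
#' @param chrom_size Chromosome length, bp.
#' @param n_exons,exon_length,intron_length,gap Two-element (min, max)
#'   ranges sampled uniformly per gene/feature.
#' @param chrom_name Chromosome name.
#' @param seed Random seed (annotation is deterministic given it).
#' @return List: `genes` (exon tibble as from [read_gene_models()]),
#'   `chrom_sizes` (named vector), `genome` ([Biostrings::DNAStringSet]).
#' @export
simulate_annotation <- function(n_genes = 100, chrom_size = 1e6,
                                n_exons = c(1, 5), exon_length = c(200, 500),
                                intron_length = c(100, 400),
                                gap = c(12000, 16000),
                                chrom_name = "chr1", seed = NULL) {
  runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1L))
  with_seed(seed, {
    rows <- vector("list", n_genes)
    pos <- runif_int(1, gap[1], gap[2])
    for (g in seq_len(n_genes)) {
      k <- runif_int(1, n_exons[1], n_exons[2])
      exl <- runif_int(k, exon_length[1], exon_length[2])
      inl <- if (k > 1) runif_int(k - 1, intron_length[1], intron_length[2]) else integer()
      starts <- pos + cumsum(c(0, exl[-k] + inl))
      strand <- sample(c("+", "-"), 1)
      rows[[g]] <- tibble(
        gene_id = sprintf("gene_%03d", g), chrom = chrom_name,
        start = as.integer(starts), end = as.integer(starts + exl), strand = strand
      )
      pos <- max(rows[[g]]$end) + runif_int(1, gap[1], gap[2])
    }
    genes <- dplyr::bind_rows(rows)
    if (max(genes$end) + gap[1] > chrom_size) {
      abort(sprintf("cannot pack %d genes into %g bp with the requested gaps",
                    n_genes, chrom_size))
    }
    genome <- Biostrings::DNAStringSet(paste(
      sample(c("A", "C", "G", "T"), chrom_size, replace = TRUE), collapse = ""))
    names(genome) <- chrom_name
    list(genes = genes,
         chrom_sizes = stats::setNames(chrom_size, chrom_name),
         genome = genome)
  })
}

#' Write gene models as GFF3 or GTF
#'
#' Each gene is written as gene + mRNA/transcript + exon features (1-based
#' inclusive coordinates, per the formats).
#'
#' @param genes Exon tibble.
#' @param path Output file.
#' @param dialect `"gff3"` or `"gtf"`.
#' @export
write_annotation <- function(genes, path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  lens <- gene_lengths(genes)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "gff3") writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(lens))) {
    g <- lens[i, ]
    ex <- genes |> filter(.data$gene_id == g$gene_id) |> arrange(.data$start)
    tx <- paste0(g$gene_id, ".1")
    if (dialect == "gff3") {
      writeLines(c(
        sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                g$chrom, g$span_start + 1L, g$span_end, g$strand, g$gene_id),
        sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                g$chrom, g$span_start + 1L, g$span_end, g$strand, tx, g$gene_id),
        sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                ex$chrom, ex$start + 1L, ex$end, ex$strand, tx,
                seq_len(nrow(ex)), tx)
      ), con)
    } else {
      writeLines(sprintf(
        "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        ex$chrom, ex$start + 1L, ex$end, ex$strand, g$gene_id, tx), con)
    }
  }
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Simulate per-gene replicate counts from the two-component model
#'
#' Each gene is non-expressed with probability `pi0` (true rate `lambda0`
#' reads/bp) or expressed with rate drawn from Gamma(shape, rate). Replicate
#' counts are `Y_gj ~ Pois(L_g * lambda_g / n)` so the pooled count has mean
#' `L_g * lambda_g`. Defaults encode the studied library conditions: a
#' background of 0.0015 reads/bp (the NCR diagnostic), three technical
#' replicates, about 40% of annotated genes silent, and a right-skewed
#' expressed-rate distribution (prior mean 0.23 reads/bp).
#'
#' @param lengths Tibble with `gene_id` and `exonic_length` (or `length`)
#'   columns, or a named numeric vector of lengths.
#' @param lambda0 Background rate, reads/bp.
#' @param pi0 Proportion of non-expressed genes.
#' @param shape,rate Gamma parameters of the expressed rates.
#' @param n_replicates Number of technical replicates.
#' @param seed Random seed.
#' @return List: `counts` (tibble `gene_id`, `replicate`, `count`), `truth`
#'   (tibble `gene_id`, `length`, `expressed`, `lambda`).
#' @export
simulate_counts <- function(lengths, lambda0 = 0.0015, pi0 = 0.4,
                            shape = 0.7, rate = 3, n_replicates = 3,
                            seed = NULL) {
  lens <- normalize_lengths(lengths)
  with_seed(seed, {
    G <- nrow(lens)
    expressed <- stats::runif(G) >= pi0
    lambda <- ifelse(expressed, stats::rgamma(G, shape = shape, rate = rate), lambda0)
    counts <- tidyr::expand_grid(gene_id = lens$gene_id,
                                 replicate = sprintf("rep%d", seq_len(n_replicates))) |>
      left_join(lens, by = "gene_id") |>
      left_join(tibble(gene_id = lens$gene_id, lambda = lambda), by = "gene_id") |>
      mutate(count = stats::rpois(dplyr::n(), .data$length * .data$lambda / n_replicates)) |>
      select("gene_id", "replicate", "count")
    list(counts = counts,
         truth = tibble(gene_id = lens$gene_id, length = lens$length,
                        expressed = expressed, lambda = lambda))
  })
}

normalize_lengths <- function(lengths) {
  if (is.numeric(lengths)) {
    tibble(gene_id = names(lengths) %||% sprintf("gene_%03d", seq_along(lengths)),
           length = unname(lengths))
  } else if ("exonic_length" %in% names(lengths)) {
    transmute(lengths, .data$gene_id, length = .data$exonic_length)
  } else if ("length" %in% names(lengths)) {
    select(lengths, "gene_id", "length")
  } else if (all(c("start", "end") %in% names(lengths))) {
    transmute(gene_lengths(lengths), .data$gene_id, length = .data$exonic_length)
  } else abort("cannot interpret `lengths`")
}

#' Simulate intron counts from the retention model
#'
#' An intron is retained with probability `1 - pi0` and then accumulates
#' reads at rate `E_g * r` per bp with `r ~ Gamma(shape, rate)`; otherwise
#' it sits at the background rate `lambda0`. `X_gi ~ Pois(L_i * rate)`,
#' pooled over replicates.
#'
#' @param introns Tibble with `gene_id`, `intron_index`, `length`, and `E`
#'   (host-gene expression, sum of RPKM across replicates).
#' @param lambda0 Background rate, reads/bp.
#' @param pi0 Proportion of non-retained introns.
#' @param shape,rate Gamma parameters of the retention rate `r` (per unit
#'   of `E` per bp).
#' @param seed Random seed.
#' @return List: `counts` (introns tibble + `count`), `truth` (+ `retained`,
#'   `r`).
#' @export
simulate_intron_counts <- function(introns, lambda0 = 0.0015, pi0 = 0.87,
                                   shape = 1, rate = 5, seed = NULL) {
  with_seed(seed, {
    n <- nrow(introns)
    retained <- stats::runif(n) >= pi0 & introns$E > 0
    r <- ifelse(retained, stats::rgamma(n, shape = shape, rate = rate), 0)
    mean_rate <- ifelse(retained, introns$E * r, lambda0)
    counts <- introns |>
      mutate(count = stats::rpois(n, .data$length * mean_rate))
    list(counts = counts,
         truth = mutate(introns, retained = retained, r = r))
  })
}

#' Simulate stranded single-end alignments
#'
#' Places each counted read inside one exon of its gene (positions weighted
#' by an optional positional-bias function over the 5'->3' gene body),
#' orients it by the dUTP convention (sense reads align opposite the gene
#' strand) with antisense contamination at `antisense_rate`, scatters
#' unstranded background reads over intergenic space at `background_rate`
#' reads/bp (pooled over replicates), and places intron counts inside their
#' introns.
#'
#' @param gene_counts Tibble `gene_id`, `replicate`, `count` (sense reads),
#'   e.g. from [simulate_counts()].
#' @param genes Exon tibble.
#' @param chrom_sizes Named vector of chromosome sizes.
#' @param read_length Read length, nt (the 35-nt single-end design).
#' @param antisense_rate Probability a gene read is flipped to the
#'   antisense strand.
#' @param background_rate Intergenic background density, reads/bp (pooled).
#' @param intron_counts Optional tibble `gene_id`, `intron_index`, `count`
#'   (pooled) from [simulate_intron_counts()].
#' @param introns Intron table (required with `intron_counts`).
#' @param bias Optional function of gene-body fraction in \[0,1\] returning
#'   a non-negative placement weight (e.g. `function(x) x` for 3' bias);
#'   `NULL` = uniform.
#' @param seed Random seed.
#' @return Alignment tibble: `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `replicate`, `source` (`gene`/`background`/`intron`), `truth_strand`
#'   (`sense`/`antisense` for gene reads).
#' @export
simulate_alignments <- function(gene_counts, genes, chrom_sizes,
                                read_length = 35, antisense_rate = 0.02,
                                background_rate = 0, intron_counts = NULL,
                                introns = NULL, bias = NULL, seed = NULL) {
  sizes <- as_chrom_sizes(chrom_sizes)
  with_seed(seed, {
    parts <- list()
    parts$gene <- place_gene_reads(gene_counts, genes, read_length,
                                   antisense_rate, bias)
    if (background_rate > 0) {
      parts$background <- place_background_reads(
        genes, sizes, background_rate, read_length,
        replicates = unique(gene_counts$replicate))
    }
    if (!is.null(intron_counts)) {
      if (is.null(introns)) introns <- intron_counts
      parts$intron <- place_intron_reads(intron_counts, introns, read_length,
                                         replicates = unique(gene_counts$replicate))
    }
    out <- dplyr::bind_rows(parts)
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

place_gene_reads <- function(gene_counts, genes, read_length, antisense_rate, bias) {
  ex <- genes |>
    arrange(.data$gene_id, .data$start) |>
    group_by(.data$gene_id) |>
    mutate(exon_len = .data$end - .data$start,
           offset = cumsum(dplyr::lag(.data$exon_len, default = 0L)),
           tx_len = sum(.data$exon_len)) |>
    ungroup()
  per_gene <- split(ex, ex$gene_id)
  pooled <- gene_counts |> filter(.data$count > 0)
  rows <- purrr::pmap(pooled, function(gene_id, replicate, count, ...) {
    e <- per_gene[[gene_id]]
    if (is.null(e)) abort(sprintf("counts for unknown gene %s", gene_id))
    eligible <- e[e$exon_len >= read_length, , drop = FALSE]
    if (nrow(eligible) == 0) {
      warn(sprintf("all exons of %s shorter than the read length; reads shortened",
                   gene_id))
      eligible <- e
    }
    # candidate transcript-space start positions (read fits in one exon)
    cand <- purrr::pmap(eligible, function(start, end, offset, exon_len, ...) {
      offset + seq(0L, max(exon_len - read_length, 0L))
    })
    cand <- unlist(cand)
    w <- if (is.null(bias)) NULL else {
      tl <- e$tx_len[1]
      frac <- if (e$strand[1] == "-") 1 - cand / tl else cand / tl
      pmax(bias(frac), 0)
    }
    t0 <- cand[sample.int(length(cand), count, replace = TRUE, prob = w)]
    # back to genomic coordinates
    ei <- findInterval(t0, eligible$offset)
    gstart <- eligible$start[ei] + (t0 - eligible$offset[ei])
    rl <- pmin(read_length, eligible$exon_len[ei])
    anti <- stats::runif(count) < antisense_rate
    gene_strand <- e$strand[1]
    read_strand <- ifelse(anti,
                          gene_strand,
                          ifelse(gene_strand == "+", "-", "+"))
    tibble(
      read_id = sprintf("%s:%d:rep=%s:%s", gene_id, seq_len(count), replicate,
                        ifelse(anti, "anti", "sense")),
      chrom = e$chrom[1], start = gstart, end = gstart + rl,
      strand = read_strand, replicate = replicate, source = "gene",
      truth_strand = ifelse(anti, "antisense", "sense")
    )
  })
  dplyr::bind_rows(rows)
}

place_background_reads <- function(genes, sizes, rate, read_length, replicates) {
  spans <- gene_lengths(genes)
  rows <- purrr::map(names(sizes), function(ch) {
    csize <- sizes[[ch]]
    sp <- spans |> filter(.data$chrom == ch)
    cov <- IRanges::reduce(IRanges::IRanges(start = sp$span_start + 1L, end = sp$span_end))
    gaps <- IRanges::gaps(cov, start = 1L, end = csize)
    gs <- IRanges::start(gaps) - 1L
    ge <- IRanges::end(gaps)
    glen <- ge - gs
    ok <- glen >= read_length
    gs <- gs[ok]; ge <- ge[ok]; glen <- glen[ok]
    if (length(gs) == 0) return(NULL)
    n <- stats::rpois(1, sum(glen) * rate)
    if (n == 0) return(NULL)
    gi <- sample.int(length(gs), n, replace = TRUE, prob = glen)
    pos <- gs[gi] + floor(stats::runif(n) * (glen[gi] - read_length + 1))
    tibble(
      read_id = sprintf("bg:%s:%d", ch, seq_len(n)),
      chrom = ch, start = pos, end = pos + read_length,
      strand = sample(c("+", "-"), n, replace = TRUE),
      replicate = sample(replicates, n, replace = TRUE),
      source = "background", truth_strand = NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

place_intron_reads <- function(intron_counts, introns, read_length, replicates) {
  d <- intron_counts |> filter(.data$count > 0)
  if (nrow(d) == 0) return(NULL)
  key <- introns |> select("gene_id", "intron_index", "chrom", "start", "end", "strand")
  d <- left_join(d |> select("gene_id", "intron_index", "count"),
                 key, by = c("gene_id", "intron_index"))
  rows <- purrr::pmap(d, function(gene_id, intron_index, count, chrom, start, end, strand) {
    ilen <- end - start
    rl <- min(read_length, ilen)
    pos <- start + floor(stats::runif(count) * (ilen - rl + 1))
    read_strand <- if (strand == "+") "-" else "+"  # sense under dUTP
    tibble(
      read_id = sprintf("%s.intron_%d:%d", gene_id, intron_index, seq_len(count)),
      chrom = chrom, start = pos, end = pos + rl, strand = read_strand,
      replicate = sample(replicates, count, replace = TRUE),
      source = "intron", truth_strand = "sense"
    )
  })
  dplyr::bind_rows(rows)
}

#' Write alignments as BED6 or SAM
#'
#' BED6 carries the read id as name and the alignment strand; SAM writes
#' ungapped `<n>M` records with N-filled sequence.
#'
#' @param alignments Alignment tibble.
#' @param path Output file.
#' @param chrom_sizes Required for SAM headers.
#' @export
write_alignments_bed <- function(alignments, path) {
  readr::write_tsv(
    tibble(chrom = alignments$chrom, start = alignments$start,
           end = alignments$end, name = alignments$read_id, score = 0,
           strand = alignments$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_alignments_bed
#' @export
write_sam <- function(alignments, chrom_sizes, path) {
  sizes <- as_chrom_sizes(chrom_sizes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(sizes), as.integer(sizes)), con)
  len <- alignments$end - alignments$start
  writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                     alignments$read_id,
                     ifelse(alignments$strand == "-", 16L, 0L),
                     alignments$chrom, alignments$start + 1L, len,
                     strrep("N", len)), con)
  invisible(path)
}

#' Simulate indexed multiplexed FASTQ reads
#'
#' Each read is the sample index plus the common base(s) plus a random
#' insert, with substitution errors injected per base at `error_rate`.
#'
#' @param reads_per_index Named integer vector (names = index sequences) or
#'   tibble `index`, `n`.
#' @param index_set An [index_set()].
#' @param error_rate Per-base substitution probability.
#' @param read_length Total read length, nt.
#' @param seed Random seed.
#' @return List: `reads` (named character vector), `truth` (tibble
#'   `read_id`, `index`, `index_errors`).
#' @export
simulate_indexed_fastq <- function(reads_per_index, index_set, error_rate = 0.01,
                                   read_length = 35, seed = NULL) {
  if (is.data.frame(reads_per_index)) {
    reads_per_index <- stats::setNames(reads_per_index$n, reads_per_index$index)
  }
  k <- index_set$index_length
  with_seed(seed, {
    all <- purrr::imap(reads_per_index, function(n, idx) {
      if (n == 0) return(NULL)
      insert_len <- read_length - index_set$prefix_length
      inserts <- vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T"), insert_len, replace = TRUE),
              collapse = "")
      }, character(1))
      seqs <- paste0(idx, index_set$common_bases, inserts)
      mutated <- inject_substitutions(seqs, error_rate)
      idx_errors <- vapply(seq_len(n), function(i) {
        sum(strsplit(substr(mutated[i], 1, k), "")[[1]] !=
              strsplit(idx, "")[[1]])
      }, integer(1))
      tibble(read_id = sprintf("%s:%d", idx, seq_len(n)), index = idx,
             seq = mutated, index_errors = idx_errors)
    })
    d <- dplyr::bind_rows(all)
    d <- d[sample.int(nrow(d)), , drop = FALSE]
    list(reads = stats::setNames(d$seq, d$read_id),
         truth = select(d, "read_id", "index", "index_errors"))
  })
}

inject_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < error_rate)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads Named character vector of sequences.
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  out <- Biostrings::DNAStringSet(unname(reads))
  names(out) <- names(reads)
  Biostrings::writeXStringSet(out, path, format = "fastq",
                              qualities = Biostrings::PhredQuality(
                                strrep("I", nchar(reads))))
  invisible(path)
}

#' A balanced example index set
#'
#' Eleven 5-nt indices with minimum pairwise Hamming distance 2 and
#' per-position base balance, for the 5+T read design. (The published index
#' sequences are not reproduced in the accessible material, so the package
#' ships its own balanced set.)
#'
#' @param n Number of indices (up to 11).
#' @return An [index_set()].
#' @export
example_index_set <- function(n = 11) {
  idx <- c("ACGTA", "CATGC", "GTACG", "TGCAT", "AGATC", "CTCGA",
           "GAGCT", "TCTAG", "AACCG", "CCGAT", "GGTTA")
  index_set(idx[seq_len(min(n, length(idx)))])
}
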