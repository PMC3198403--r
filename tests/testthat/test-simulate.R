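test_that("simulated annotation is valid, packable and reproducible", {
  ann <- simulate_annotation(n_genes = 30, chrom_size = 1e6, seed = 80)
  lens <- gene_lengths(ann$genes)
  expect_equal(nrow(lens), 30)
  # genes do not overlap and sit at least 12 kb apart
  spans <- lens[order(lens$span_start), ]
  expect_true(all(spans$span_start[-1] - spans$span_end[-nrow(spans)] >= 12000))
  # GFF3 + FASTA round-trip
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fa")
  write_annotation(ann$genes, gff); write_genome_fasta(ann$genome, fa)
  back <- read_gene_models(gff)
  expect_equal(as.data.frame(back),
               as.data.frame(dplyr::arrange(ann$genes, gene_id, start)))
  expect_equal(Biostrings::width(Biostrings::readDNAStringSet(fa)),
               unname(ann$chrom_sizes))
  # same seed, byte-identical files
  ann2 <- simulate_annotation(n_genes = 30, chrom_size = 1e6, seed = 80)
  gff2 <- tempfile(); write_annotation(ann2$genes, gff2)
  expect_identical(readLines(gff), readLines(gff2))
  expect_identical(as.character(ann$genome), as.character(ann2$genome))

  expect_error(simulate_annotation(n_genes = 500, chrom_size = 1e5, seed = 1),
               "pack")
})

test_that("NCR extent matches the analytic layout for fixed spacing", {
  # single-exon genes of fixed length with fixed 14 kb gaps: every intergenic
  # gap contributes gap - 2*5000 of NCR, the chromosome tail the remainder
  ann <- simulate_annotation(n_genes = 10, chrom_size = 4e5,
                             n_exons = c(1, 1), exon_length = c(1000, 1000),
                             gap = c(14000, 14000), seed = 81)
  ncrs <- derive_ncrs(ann$genes, ann$chrom_sizes)
  lens <- gene_lengths(ann$genes)
  first_start <- min(lens$span_start)
  last_end <- max(lens$span_end)
  expected <- (first_start - 5000) +          # before the first gene
    9 * (14000 - 10000) +                     # the nine fixed gaps
    (4e5 - last_end - 5000)                   # chromosome tail
  expect_equal(sum(ncrs$length), expected)
})

test_that("count simulation obeys the two-component model", {
  lens <- tibble::tibble(gene_id = sprintf("g%03d", 1:500),
                         length = sample(600:2000, 500, TRUE))
  # pi0 = 1: everything background
  all_bg <- simulate_counts(lens, pi0 = 1, seed = 82)
  expect_false(any(all_bg$truth$expressed))
  expect_true(all(all_bg$truth$lambda == 0.0015))

  # pooled LNC of expressed genes averages to the prior mean a/b
  sim <- simulate_counts(lens, pi0 = 0.3, shape = 2, rate = 10, seed = 83)
  pooled <- dplyr::summarise(dplyr::group_by(sim$counts, gene_id),
                             y = sum(count))
  d <- dplyr::inner_join(pooled, sim$truth, by = "gene_id")
  ex <- d[d$expressed, ]
  est <- mean(ex$y / ex$length)
  se <- sd(ex$y / ex$length) / sqrt(nrow(ex))
  expect_lt(abs(est - 2 / 10), 3 * se)

  # replicate structure and reproducibility
  expect_equal(dplyr::n_distinct(sim$counts$replicate), 3)
  sim2 <- simulate_counts(lens, pi0 = 0.3, shape = 2, rate = 10, seed = 83)
  expect_identical(sim$counts, sim2$counts)
})

test_that("alignment placement respects strand, bias and background truth", {
  ann <- simulate_annotation(n_genes = 25, chrom_size = 7e5, seed = 84)
  lens <- gene_lengths(ann$genes)
  sim <- simulate_counts(lens, seed = 85)

  # zero antisense rate: quantification sees no antisense gene reads
  aln0 <- simulate_alignments(sim$counts, ann$genes, ann$chrom_sizes,
                              antisense_rate = 0, seed = 86)
  cnt0 <- count_gene_reads(aln0, ann$genes)
  expect_equal(sum(cnt0$antisense), 0L)
  # and every simulated gene read is recovered as a sense count
  expect_equal(sum(cnt0$sense), nrow(aln0))

  # uniform placement of deeply covered genes gives a flat metagene profile
  deep <- simulate_counts(lens, pi0 = 0, shape = 20, rate = 20, seed = 89)
  alnd <- simulate_alignments(deep$counts, ann$genes, ann$chrom_sizes,
                              antisense_rate = 0, seed = 86)
  prof <- gene_body_coverage_profile(alnd, ann$genes, n_bins = 20)
  # terminal bins ramp down over one read length (reads must start inside
  # the transcript), so flatness is asserted on the interior
  expect_lt(max(abs(prof$coverage[2:19] - 1)), 0.15)
  expect_lt(abs(mean(prof$coverage) - 1), 0.05)
  expect_true(all(prof$coverage[c(1, 20)] <= 1))

  # a 3'-biased placement density is recovered by the coverage profile
  aln3 <- simulate_alignments(deep$counts, ann$genes, ann$chrom_sizes,
                              antisense_rate = 0, bias = function(x) x^2,
                              seed = 87)
  p3 <- gene_body_coverage_profile(aln3, ann$genes, n_bins = 20)
  expect_gt(mean(p3$coverage[16:20]), 2 * mean(p3$coverage[1:5]))
  expect_gt(cor(p3$coverage, (seq(0.025, 0.975, 0.05))^2), 0.9)

  # the global antisense fraction recovers the generating rate within 3 SE
  aln2 <- simulate_alignments(sim$counts, ann$genes, ann$chrom_sizes,
                              antisense_rate = 0.05, seed = 88)
  cnt2 <- count_gene_reads(aln2, ann$genes)
  n <- sum(cnt2$sense + cnt2$antisense)
  phat <- sum(cnt2$antisense) / n
  expect_lt(abs(phat - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("the full pipeline closes over its own simulation", {
  ann <- simulate_annotation(n_genes = 50, chrom_size = 1.2e6, seed = 90)
  lens <- gene_lengths(ann$genes)
  introns <- build_intron_db(ann$genes)
  sim <- simulate_counts(lens, seed = 91)
  aln <- simulate_alignments(sim$counts, ann$genes, ann$chrom_sizes,
                             antisense_rate = 0.02, background_rate = 0.0015,
                             seed = 92)
  ncrs <- derive_ncrs(ann$genes, ann$chrom_sizes)
  bg <- estimate_lambda0(count_ncr_reads(aln, ncrs))
  # the background estimate recovers the generating density
  expect_lt(abs(bg$lambda0 - 0.0015) / 0.0015, 0.35)

  cnt <- count_gene_reads(aln, ann$genes)
  det <- detect_expressed(cnt, lens, bg)
  truth <- sim$truth
  agree <- det$detected == truth$expressed[match(det$gene_id, truth$gene_id)]
  # genes whose true rate sits near the background are genuinely ambiguous;
  # the clearly separated ones must be classified correctly
  clear <- !truth$expressed | truth$lambda > 10 * 0.0015
  expect_gt(mean(agree), 0.85)
  expect_gt(mean(agree[match(det$gene_id, truth$gene_id)][clear]), 0.95)
})

test_that("indexed FASTQ simulation supports demultiplexing truth checks", {
  iset <- example_index_set(6)
  counts <- stats::setNames(rep(50L, 6), iset$indices)

  # no errors: perfect recovery (tested via demux in test-demux.R too)
  clean <- simulate_indexed_fastq(counts, iset, error_rate = 0, seed = 93)
  expect_true(all(clean$truth$index_errors == 0))
  expect_true(all(startsWith(unname(clean$reads[clean$truth$read_id]),
                             paste0(clean$truth$index, "T"))))

  # reproducibility
  clean2 <- simulate_indexed_fastq(counts, iset, error_rate = 0, seed = 93)
  expect_identical(clean$reads, clean2$reads)

  # error injection hits the index prefix at the nominal per-base rate
  noisy <- simulate_indexed_fastq(stats::setNames(rep(2000L, 6), iset$indices),
                                  iset, error_rate = 0.05, seed = 94)
  exact <- mean(noisy$truth$index_errors == 0)
  expect_lt(abs(exact - (1 - 0.05)^5), 3 * sqrt(0.95^5 * (1 - 0.95^5) / 12000))

  # deliberately constructed tie reads stay unassigned
  tie_set <- index_set(c("AAAAA", "AAATT"))
  res <- demultiplex(c(tie = paste0("AAAAT", "T", strrep("C", 29))), tie_set)
  expect_equal(attr(res, "unassigned"), 1L)
})
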