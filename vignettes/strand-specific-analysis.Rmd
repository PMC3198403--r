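---
title: "Detecting expressed transcripts and retained introns from strand-specific RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting expressed transcripts and retained introns from strand-specific RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandtools)
library(dplyr)
```

## The problem

Strand-specific (SS) RNA-seq libraries built with the dUTP method preserve
which genomic strand each read's source RNA came from: the second cDNA
strand is synthesized with dUTP and destroyed before amplification, so the
surviving reads derive from first-strand cDNA and align *antisense* to
their transcript. This single property changes what can be quantified: sense
and antisense transcription separate cleanly, RPKM values are no longer
inflated by convergent or overlapping gene models, and reads inside introns
can be interpreted against the host gene's own expression.

strandtools implements the analysis half of such an experiment:
demultiplexing of index-tagged reads, strand-aware counting, background
estimation from intergenic "non-coding regions", an empirical Bayes
Poisson–Gamma test for significantly expressed (sense or antisense)
transcripts, an analogous intron-retention test, metagene diagnostics, and
a normalization comparison. A synthetic-data module generates annotation,
counts, alignments and FASTQ under the same models the tests assume, so
every stage is verifiable without external data.

## The detection model

Let $Y_{gj}$ be the reads assigned to gene $g$ in technical replicate $j$,
and $Y_g = \sum_j Y_{gj}$ the pooled count (Poisson counts are closed under
summation, and technical replicates are treated as exchangeable). With
$L_g$ the exonic length of the gene model, the pooled count is modelled as

$$Y_g \sim \mathrm{Poisson}(L_g \lambda_g),$$

where $\lambda_g$ is a per-bp read density. The hypotheses are

* $H_0$: $\lambda_g = \lambda_0$, the *background* density — reads that
  appear without transcription (DNA contamination, mapping artifacts);
* $H_1$: $\lambda_g \sim \mathrm{Gamma}(a, b)$ (shape/rate; prior mean
  $a/b$), an empirical prior over expressed-gene densities.

Under $H_1$ the marginal of $Y_g$ is negative binomial,
$$P(Y_g = y) = \frac{\Gamma(y+a)}{\Gamma(a)\,y!}
  \left(\frac{b}{b+L}\right)^{a}\left(\frac{L}{b+L}\right)^{y},$$
implemented in log space (`nb_marginal()`); tests verify it against both
`dnbinom()` and adaptive quadrature of the Poisson–Gamma integrand. The
evidence summary is the posterior odds of the null,

$$B_g = \frac{\pi_0\,\mathrm{Pois}(y;\,L_g\lambda_0)}
  {(1-\pi_0)\,\mathrm{NB}(y;\,L_g, a, b)},$$

with $\pi_0$ the prior fraction of non-expressed genes. A gene is called
expressed when $B_g < 1$ (posterior probability of expression above 1/2),
and the FDR of a detected set is estimated as the mean posterior null
probability $B/(1+B)$ over that set. The same machinery applied to the
antisense count column, with its own $(\pi_0, a, b)$, tests for antisense
transcription.

### Parameter estimation

* $\lambda_0$ — from **non-coding regions** (NCRs): intervals at least 5 kb
  from any annotated exon. Each NCR's length-normalized coverage
  (LNC = reads/bp) is computed; regions above the 99th LNC percentile are
  excluded (they are typically unannotated genes, and the sorted LNC curve
  from `lnc_percentile_curve()` makes the break visible); $\lambda_0$ is
  the pooled ratio $\sum \text{reads} / \sum \text{bp}$ over the retained
  regions — the maximum-likelihood estimate of a shared Poisson rate, not a
  mean of ratios. The percentile cutoff uses the inverse-ECDF quantile
  (an observed order statistic), so the estimate is invariant to arbitrary
  inflation of the excluded top fraction; an interpolated quantile would
  let a single extreme region drag the cutoff upward.
* $\pi_0$ — the fraction of genes with LNC below $\lambda_0$.
* $(a, b)$ — maximize the negative-binomial marginal likelihood over the
  genes with LNC $\ge \lambda_0$, in log-parameter space from a
  method-of-moments start (convergence tolerance $10^{-10}$ on the
  objective, BFGS).

### A calibration caveat worth knowing

Given the true mixture parameters, the posterior-probability FDR estimator
is exactly calibrated: over simulations from the generative model the mean
estimated FDR of the $B<1$ set matches the realized false-discovery
proportion (this is one of the package's acceptance checks). The *plug-in*
$\pi_0$ estimator, however, is biased downward whenever background genes
have non-negligible expected counts: with $L\lambda_0 \approx 1.6$ reads, a
background gene has LNC $\ge \lambda_0$ whenever it collects at least two
reads (probability $\approx 0.5$), so roughly half the background mass is
not counted into $\pi_0$. Smaller $\pi_0$ means smaller prior odds, smaller
$B$, and an anticonservative estimated FDR. This is a property of the
estimator itself, visible in the pipeline-closure simulations; users who
need strict FDR control should treat the reported FDR as optimistic, or
supply an externally calibrated prior via the `prior` argument.

## The intron-retention test

For intron $i$ of gene $g$, with pooled count $X_{gi}$ and length $L_i$,
the null is again background, $X_{gi} \sim \mathrm{Pois}(L_i\lambda_0)$.
Under the alternative the Poisson mean is $L_i E_g r_{gi}$: the retention
rate $r_{gi} \sim \mathrm{Gamma}(a,b)$ is *normalized by the host gene's
expression* $E_g$ (the sum of its RPKM values across replicates), encoding
the assumption that pre-mRNA and retained-intron reads scale with
transcription. Two introns with identical counts therefore receive
different odds: the same evidence is weaker on a highly expressed gene.
Genes with $E_g = 0$ (configurable floor) are untestable and excluded.

Because the mean combines background and signal in principle, a second
variant is available behind `model = "additive"`: Poisson mean
$L_i(E_g r + \lambda_0)$, whose marginal is the convolution of a Poisson
background with the negative-binomial signal, evaluated by finite sum. The
multiplicative form is the default; the two coincide as
$\lambda_0 \to 0$ and differ negligibly when signal dominates background.

Note on units: $r$ is "per unit of $E_g$ per bp", and $E_g$ is on the RPKM
scale, so the natural magnitude of $r$ depends on library size. When
simulating realistic *read* data, a Gamma rate of about
$10^9 a / (\rho \bar N)$ gives retained introns an average read density of
$\rho$ times their host gene's (the acceptance script uses $\rho = 0.2$).

## Counting conventions

* Orientation: `reverse` (dUTP) by default — an alignment on the strand
  opposite the gene is sense; `forward` flips the rule for protocols that
  read the transcript strand.
* A read counts toward a gene if it overlaps the gene's exonic bases by at
  least 1 bp; reads overlapping the exon space of more than one gene are
  discarded as ambiguous. Only primary, mapped alignments are read from
  SAM/BAM by default. Both rules are configurable; the literature rarely
  states them, so they are explicit here.
* A read counts toward an intron only if at least half its length lies
  inside the intron, so exon–intron junction reads (spliced molecules) are
  not taken as retention evidence.
* NCR counting is strand-agnostic; a boundary-spanning read goes to the
  region it overlaps most.
* Metagene profiles (coverage, antisense fraction, base composition) are
  computed over *spliced* transcript coordinates, 5′→3′, in equal-fraction
  bins (default 100); genes shorter than the bin count are skipped so no
  bin is empty. Coverage profiles are normalized per gene by its mean
  coverage before averaging, so each gene contributes shape, not depth.

## Demultiplexing

Multiplex indices are fixed-length prefixes (default five nt followed by a
common T). Index sets are validated for minimum pairwise Hamming distance
$\ge 2$ — one sequencing error then still identifies a unique sample — and
per-position base balance; an optional Levenshtein check supports index
design. A read is assigned to the unique index within `max_mismatch`
(default 1) of its prefix; equidistant ties are always unassigned, because
distance 2 does not guarantee unambiguous one-error correction. The common
base is trimmed but never used for assignment (published descriptions of
the design are ambiguous about its exact position, so it is configurable).
With per-base error rate $\varepsilon$, the exact-match fraction is
$(1-\varepsilon)^k$ — a property the simulator reproduces and the test
suite checks binomially.

## Normalization comparison

`normalization_factors()` implements total-count, upper-quartile (75th
percentile of nonzero counts), TMM (trimmed mean of M-values with the
published defaults: 30% log-ratio trim, 5% intensity trim, precision
weights, reference column by upper quartile; verified against an
independent implementation to $10^{-6}$), and spike-in (column sums over
spike-in units), all rescaled to geometric mean one. The diagnostic is a
chi-square homogeneity statistic per gene,
$\sum_j (Y_{gj}-\hat Y_{gj})^2/\hat Y_{gj}$ with
$\hat Y_{gj} = d_j \sum_k Y_{gk} / \sum_k d_k$, compared to its
$\chi^2_{n-1}$ reference by QQ slope: a slope near 1 means the factors
explain between-replicate differences up to Poisson noise. With noisy
spike-in capture, spike-in normalization visibly underperforms the other
methods — reproduced qualitatively in the test suite.

## What the simulator does and does not emulate

`simulate_annotation()` lays out non-overlapping genes (1–5 exons of
200–500 bp, introns of 100–400 bp — about 1.1 kb of exonic model on
average, a compact plant-like architecture) with intergenic gaps of at
least 12 kb so NCRs survive the 5 kb padding. `simulate_counts()` draws
from exactly the two-component model above; its defaults are the studied
library conditions: $\lambda_0 = 0.0015$ reads/bp, three technical
replicates, $\pi_0 = 0.4$, and a right-skewed expressed-rate prior
(Gamma(0.7, 3), mean 0.23 reads/bp). `simulate_alignments()` places 35-nt
single-end reads uniformly (or with a positional-bias curve) within single
exons, flips strands at the antisense-contamination rate (default 2%), and
scatters unstranded intergenic background. `simulate_indexed_fastq()`
prefixes reads with indices and injects substitution errors.

Deliberately not emulated: reads spanning splice junctions (each simulated
read sits inside one exon), indels and quality-score structure, multimapping
and mappability variation, GC bias, biological-replicate overdispersion,
and paired ends. Passing tests therefore demonstrate correctness of the
statistical machinery under its own assumptions — not robustness to every
artifact of real libraries.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GFF3/GTF (1-based
  inclusive) are converted on I/O. BED output is half-open as the format
  requires.
* One gene model per gene: the exon union of the longest transcript
  (configurable to the all-isoform union). NCRs pad *exons*, not gene
  spans (the operational definition; padding spans is available).
* All likelihoods and odds are computed in log space; `posterior_odds()`
  returns $+\infty$ when $\pi_0 = 1$ and 0 (with a warning) when
  $\pi_0 = 0$.
* Degenerate backgrounds ($\lambda_0 = 0$ after exclusion) are floored at
  one read over the retained length, with a warning, to keep the null
  proper.
* Ties: reads equidistant between indices are unassigned; reads meeting
  the half-length rule for two introns are discarded; NCR boundary ties are
  discarded.
* Problem sizes in the test suite (hundreds of genes, $10^3$–$10^4$ units,
  200 calibration replicates, $10^5$ demultiplexed reads) were chosen so
  each Monte-Carlo check has enough resolution for its stated tolerance
  while the whole suite stays quick on a laptop.

## A compact worked run

```{r pipeline, eval = FALSE}
ann <- simulate_annotation(n_genes = 100, chrom_size = 2e6, seed = 1)
lens <- gene_lengths(ann$genes)
sim <- simulate_counts(lens, seed = 2)
aln <- simulate_alignments(sim$counts, ann$genes, ann$chrom_sizes,
                           antisense_rate = 0.02, background_rate = 0.0015,
                           seed = 3)

ncrs <- derive_ncrs(ann$genes, ann$chrom_sizes)
bg <- estimate_lambda0(count_ncr_reads(aln, ncrs))
autoplot(bg)                      # the sorted NCR LNC curve and lambda0

cnt <- count_gene_reads(aln, ann$genes)
det <- detect_expressed(cnt, lens, bg)
glance(det)                       # n detected, FDR, pi0, (a, b), lambda0
autoplot(det)                     # threshold-vs-FDR curve
plot_metagene(antisense_fraction_profile(aln, ann$genes))
```

## Limitations

The package tests *expression against background*, not differential
expression between conditions; overdispersion across biological replicates
is out of scope (pooled technical replicates only). Intron calls do not
distinguish regulated retention from pre-mRNA contamination or annotation
error — the test only says the intronic density is incompatible with
background after expression normalization. Alignment itself is upstream:
strandtools consumes SAM/BAM/BED produced by any spliced or unspliced
aligner.
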