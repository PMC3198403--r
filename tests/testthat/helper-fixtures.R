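# Shared fixtures, all built in code.

# A tiny two-gene annotation on one 100 kb chromosome (coordinates chosen by
# hand so expected introns/NCRs can be enumerated).
tiny_genes <- function() {
  tibble::tribble(
    ~gene_id, ~chrom,  ~start, ~end,  ~strand,
    "gA",     "chr1",  40000L, 40200L, "+",
    "gA",     "chr1",  40300L, 40400L, "+",
    "gB",     "chr1",  70000L, 70150L, "-",
    "gB",     "chr1",  70250L, 70400L, "-",
    "gB",     "chr1",  70500L, 70700L, "-"
  )
}

tiny_chrom_sizes <- function() c(chr1 = 100000)

# Brute-force overlap counting oracle: for each region, count alignments with
# >= 1 bp overlap by a quadratic double loop (no interval trees).
brute_force_overlaps <- function(alignments, regions) {
  sapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    sum(alignments$chrom == r$chrom &
          pmin(alignments$end, r$end) > pmax(alignments$start, r$start))
  })
}

# Careful quadrature of the Poisson-Gamma marginal: the integrand is
# proportional to a Gamma(a + y, b + L) posterior kernel, so integrate over
# that support with a log-scale shift at the mode to avoid underflow.
quadrature_marginal <- function(y, L, a, b) {
  logf <- function(l) stats::dpois(y, L * l, log = TRUE) +
    stats::dgamma(l, a, rate = b, log = TRUE)
  mode <- max((a + y - 1) / (b + L), 1e-12)
  m <- logf(mode)
  lo <- stats::qgamma(1e-16, a + y, rate = b + L) * 0.5
  hi <- stats::qgamma(1 - 1e-15, a + y, rate = b + L) * 1.5 + 1e-9
  v <- stats::integrate(function(l) exp(logf(l) - m), lo, hi,
                        rel.tol = 1e-12, subdivisions = 2000L)$value
  v * exp(m)
}

# An ss_prior built from known parameters (bypasses fitting).
fixed_prior <- function(pi0, shape, rate, lambda0) {
  structure(list(pi0 = pi0, shape = shape, rate = rate, mean = shape / rate,
                 lambda0 = lambda0, logLik = NA_real_, n_fit = NA_integer_),
            class = "ss_prior")
}
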