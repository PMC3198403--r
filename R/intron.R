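#' Posterior odds for intron retention
#'
#' The intron test mirrors the gene test but normalizes the retention rate
#' by the host gene's expression: under the null the intron count is
#' background, `X ~ Pois(L_i * lambda0)`; under the alternative the
#' retention rate `r` has a Gamma(shape, rate) prior and the Poisson mean is
#' `L_i * E_g * r` (multiplicative model, the default), so the marginal is
#' negative binomial with exposure `L_i * E_g`. The additive variant uses
#' mean `L_i * (E_g * r + lambda0)` and evaluates the Poisson-NB convolution
#' by finite sum.
#'
#' @param x Pooled intron count(s).
#' @param L_i Intron length(s), bp.
#' @param E_g Host-gene expression (sum of RPKM across replicates).
#' @param prior An `ss_prior` (fitted on introns; `lambda0` inside it is the
#'   shared background rate).
#' @param model `"multiplicative"` (default) or `"additive"`.
#' @param log Return log odds.
#' @return Posterior odds `B` (or log B). Untestable introns (`E_g` = 0)
#'   yield `NA`.
#' @export
intron_posterior_odds <- function(x, L_i, E_g, prior,
                                  model = c("multiplicative", "additive"),
                                  log = FALSE) {
  model <- match.arg(model)
  n <- max(length(x), length(L_i), length(E_g))
  x <- rep_len(x, n); L_i <- rep_len(L_i, n); E_g <- rep_len(E_g, n)
  lb <- rep(NA_real_, n)
  testable <- E_g > 0
  if (any(testable)) {
    if (model == "multiplicative") {
      lb[testable] <- posterior_odds(x[testable], L_i[testable], prior,
                                     exposures = L_i[testable] * E_g[testable],
                                     log = TRUE)
    } else {
      l_h1 <- vapply(which(testable), function(i) {
        additive_log_marginal(x[i], L_i[i], E_g[i], prior)
      }, numeric(1))
      pi0 <- prior$pi0
      lb[testable] <- base::log(pi0) - base::log(1 - pi0) +
        stats::dpois(x[testable], L_i[testable] * prior$lambda0, log = TRUE) - l_h1
    }
  }
  if (log) lb else exp(lb)
}

# log P(X = x) under mean L*(E*r + lambda0), r ~ Gamma: the convolution of
# Pois(L*lambda0) background reads with NB(shape, L*E) signal reads.
additive_log_marginal <- function(x, L, E, prior) {
  k <- 0:x
  lp <- stats::dpois(x - k, L * prior$lambda0, log = TRUE) +
    nb_marginal(k, L * E, prior$shape, prior$rate, log = TRUE)
  m <- max(lp)
  m + base::log(sum(exp(lp - m)))
}

#' Detect significantly retained introns
#'
#' Estimates the intron-specific prior (`pi0` = fraction of testable introns
#' with LNC below `lambda0`; Gamma shape/rate by marginal likelihood on the
#' introns with LNC at or above `lambda0`, with exposures `L_i * E_g`) and
#' calls retention where the posterior odds `B` fall below `threshold`.
#' Introns of genes at or below `expression_floor` are reported untestable
#' (`B = NA`, never detected).
#'
#' @param intron_inputs Tibble with `gene_id`, `intron_index`, `length`
#'   (intron bp), `count` (pooled reads), `E` (host-gene expression, sum of
#'   RPKM across replicates) — e.g. [count_intron_reads()] joined with
#'   [gene_expression()].
#' @param background `ss_background` or numeric `lambda0`.
#' @param threshold Detection threshold on `B`.
#' @param model See [intron_posterior_odds()].
#' @param expression_floor Genes with `E` at or below this are untestable.
#' @param prior Optional pre-fitted `ss_prior`.
#' @return An `ss_detection` tibble (class also `ss_intron_detection`) with
#'   `gene_id`, `intron_index`, `length`, `count`, `E`, `lnc`, `testable`,
#'   `log_B`, `B`, `p0`, `detected`.
#' @export
detect_retained_introns <- function(intron_inputs, background, threshold = 1,
                                    model = c("multiplicative", "additive"),
                                    expression_floor = 0, prior = NULL) {
  model <- match.arg(model)
  lambda0 <- if (inherits(background, "ss_background")) background$lambda0 else background
  d <- as_tibble(intron_inputs)
  req <- c("gene_id", "intron_index", "length", "count", "E")
  if (!all(req %in% names(d))) {
    abort(sprintf("intron_inputs must have columns %s", paste(req, collapse = ", ")))
  }
  d$testable <- d$E > expression_floor
  if (!any(d$testable)) abort("no testable introns (all host genes below the expression floor)")
  t_ <- d[d$testable, ]
  if (is.null(prior)) {
    pi0 <- mean(t_$count / t_$length < lambda0)
    prior <- fit_gamma_prior(t_$count, t_$length, lambda0, pi0 = pi0,
                             exposures = t_$length * t_$E)
  }
  lb <- intron_posterior_odds(d$count, d$length, ifelse(d$testable, d$E, 0),
                              prior, model = model, log = TRUE)
  tbl <- d |>
    mutate(lnc = .data$count / .data$length,
           log_B = lb, B = exp(lb), p0 = stats::plogis(lb),
           detected = !is.na(.data$B) & .data$B < threshold)
  out <- new_detection(tbl, prior, threshold, "intron")
  class(out) <- c("ss_intron_detection", class(out))
  out
}
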