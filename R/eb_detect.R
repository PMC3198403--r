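#' Negative-binomial marginal likelihood of a count under the Gamma prior
#'
#' Marginal probability of observing `y` reads on a unit of length `L` when
#' the per-bp Poisson rate is drawn from Gamma(shape, rate):
#' `P(y) = Gamma(y+a)/(Gamma(a) y!) * (b/(b+L))^a * (L/(b+L))^y`
#' with `a = shape`, `b = rate`. Evaluated in log space throughout.
#'
#' @param y Non-negative integer count(s).
#' @param L Unit length(s) in bp (more generally, the Poisson exposure).
#' @param shape,rate Gamma prior parameters (prior mean `shape/rate`).
#' @param log Return the log probability.
#' @return Numeric vector of (log) probabilities.
#' @export
nb_marginal <- function(y, L, shape, rate, log = FALSE) {
  if (any(y < 0) || any(y != round(y))) abort("`y` must be non-negative integers")
  if (any(L <= 0) || any(shape <= 0) || any(rate <= 0)) {
    abort("`L`, `shape` and `rate` must be positive")
  }
  lp <- lgamma(y + shape) - lgamma(shape) - lfactorial(y) +
    shape * (base::log(rate) - base::log(rate + L)) +
    y * (base::log(L) - base::log(rate + L))
  if (log) lp else exp(lp)
}

#' Estimate the proportion of non-expressed units
#'
#' `pi0` is the fraction of units whose length-normalized coverage
#' (count/length) falls below the background rate `lambda0`.
#'
#' @param counts Pooled counts per unit.
#' @param lengths Unit lengths, bp.
#' @param lambda0 Background rate (reads/bp), or an `ss_background`.
#' @return `pi0` in \[0, 1\].
#' @export
estimate_pi0 <- function(counts, lengths, lambda0) {
  if (inherits(lambda0, "ss_background")) lambda0 <- lambda0$lambda0
  if (length(counts) == 0) abort("no units")
  mean(counts / lengths < lambda0)
}

#' Fit the Gamma prior of expressed-unit rates by marginal likelihood
#'
#' Maximizes the negative-binomial marginal log-likelihood of the units with
#' LNC at or above `lambda0` (the plausibly expressed ones) over the Gamma
#' shape and rate, in log-parameter space from a method-of-moments start.
#'
#' @inheritParams estimate_pi0
#' @param pi0 Optional pre-computed `pi0`; estimated from the data when
#'   `NULL`.
#' @param exposures Optional Poisson exposures used in the marginal (default
#'   `lengths`; the intron test passes `length * E_g`).
#' @return Object of class `ss_prior`: `pi0`, `shape`, `rate`, `mean`
#'   (= shape/rate), `lambda0`, `logLik`, `n_fit`.
#' @export
fit_gamma_prior <- function(counts, lengths, lambda0, pi0 = NULL,
                            exposures = NULL) {
  if (inherits(lambda0, "ss_background")) lambda0 <- lambda0$lambda0
  if (is.null(pi0)) pi0 <- estimate_pi0(counts, lengths, lambda0)
  if (is.null(exposures)) exposures <- lengths
  keep <- counts / lengths >= lambda0
  if (sum(keep) < 10) abort("fewer than 10 units with LNC >= lambda0; cannot fit prior")
  y <- counts[keep]
  off <- exposures[keep]
  if (all(y == 0)) abort("all retained counts are zero; prior is degenerate")

  r <- y / off
  m1 <- mean(r)
  v <- stats::var(r)
  # under the marginal, Var(Y/off) = a/b^2 + (a/b) * E[1/off]
  v_excess <- max(v - m1 * mean(1 / off), m1^2 / 100)
  b0 <- m1 / v_excess
  a0 <- m1 * b0

  nll <- function(p) {
    -sum(nb_marginal(y, off, exp(p[1]), exp(p[2]), log = TRUE))
  }
  fit <- stats::optim(c(log(a0), log(b0)), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  if (fit$convergence != 0) {
    abort(sprintf("gamma prior fit did not converge (code %d; last iterate shape=%.4g rate=%.4g)",
                  fit$convergence, exp(fit$par[1]), exp(fit$par[2])))
  }
  shape <- exp(fit$par[1]); rate <- exp(fit$par[2])
  structure(
    list(pi0 = pi0, shape = shape, rate = rate, mean = shape / rate,
         lambda0 = lambda0, logLik = -fit$value, n_fit = sum(keep),
         start = c(shape = a0, rate = b0)),
    class = "ss_prior"
  )
}

#' @export
print.ss_prior <- function(x, ...) {
  cat(sprintf(
    "<ss_prior> pi0 = %.3f, Gamma(shape = %.3g, rate = %.3g), prior mean %.3g; lambda0 = %.3g\n",
    x$pi0, x$shape, x$rate, x$mean, x$lambda0))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy ss_prior
#' @export
tidy.ss_prior <- function(x, ...) {
  tibble(pi0 = x$pi0, shape = x$shape, rate = x$rate, prior_mean = x$mean,
         lambda0 = x$lambda0, logLik = x$logLik, n_fit = x$n_fit)
}

#' Posterior odds of the null (background) for observed counts
#'
#' `B = pi0 * Pois(y; L*lambda0) / ((1 - pi0) * NB(y; L, shape, rate))`,
#' computed in log space. `B < 1` favours expression. The posterior null
#' probability is `B/(1+B)`.
#'
#' @param y Pooled count(s).
#' @param L Unit length(s), bp.
#' @param prior An `ss_prior` from [fit_gamma_prior()].
#' @param exposures Optional H1 Poisson exposures (default `L`).
#' @param log Return `log(B)`.
#' @return Posterior odds (or log odds).
#' @export
posterior_odds <- function(y, L, prior, exposures = NULL, log = FALSE) {
  if (is.null(exposures)) exposures <- L
  pi0 <- prior$pi0
  if (pi0 >= 1) {
    lb <- rep(Inf, length(y))
  } else if (pi0 <= 0) {
    warn("pi0 = 0: posterior odds are 0 everywhere (all units detected)")
    lb <- rep(-Inf, length(y))
  } else {
    lb <- base::log(pi0) - base::log(1 - pi0) +
      stats::dpois(y, L * prior$lambda0, log = TRUE) -
      nb_marginal(y, exposures, prior$shape, prior$rate, log = TRUE)
  }
  if (log) lb else exp(lb)
}

new_detection <- function(tbl, prior, threshold, unit_col) {
  detected <- if (!is.null(tbl$detected)) tbl$detected else tbl$B < threshold
  detected[is.na(detected)] <- FALSE
  fdr <- if (any(detected)) mean(tbl$p0[detected]) else NA_real_
  structure(tbl,
            class = c("ss_detection", class(tbl)),
            prior = prior, threshold = threshold,
            n_detected = sum(detected), fdr = fdr, unit_col = unit_col)
}

#' Detect significantly expressed transcripts
#'
#' The empirical Bayes Poisson-Gamma test: replicate counts are pooled per
#' gene, the null is background expression at rate `lambda0` (per bp), the
#' alternative draws the true rate from a Gamma prior fitted to the
#' plausibly expressed genes, and a gene is called expressed when the
#' posterior odds of the null, `B`, fall below `threshold` (default 1). The
#' set-level FDR is the mean posterior null probability `B/(1+B)` over the
#' detected set.
#'
#' @param counts An `ss_counts` tibble from [count_gene_reads()], or any
#'   tibble with a unit id column, a `count` column of pooled counts, and
#'   optionally `length`.
#' @param lengths Gene models (exon tibble), a `gene_id`/`exonic_length`
#'   tibble, or `NULL` when `counts` carries a `length` column.
#' @param background `ss_background` or numeric `lambda0` (reads/bp).
#' @param strand Count column for `ss_counts` input: `"sense"`,
#'   `"antisense"` or `"count"`.
#' @param threshold Detection threshold on `B` (strict `<`).
#' @param prior Optional pre-fitted `ss_prior`; estimated when `NULL`.
#' @return An `ss_detection` tibble: `gene_id`, `count`, `length`, `lnc`,
#'   `log_B`, `B`, `p0`, `detected`, with the fitted prior, the detected-set
#'   size and FDR as attributes (see [glance.ss_detection()],
#'   [fdr_curve()], [autoplot.ss_detection()]).
#' @export
detect_expressed <- function(counts, lengths = NULL, background,
                             strand = c("sense", "antisense", "count"),
                             threshold = 1, prior = NULL) {
  strand <- match.arg(strand)
  lambda0 <- if (inherits(background, "ss_background")) background$lambda0 else background
  pooled <- pool_counts(counts, lengths, strand)
  if (is.null(prior)) {
    prior <- fit_gamma_prior(pooled$count, pooled$length, lambda0)
  }
  lb <- posterior_odds(pooled$count, pooled$length, prior, log = TRUE)
  tbl <- pooled |>
    mutate(lnc = .data$count / .data$length,
           log_B = lb, B = exp(lb),
           p0 = stats::plogis(lb),
           detected = .data$B < threshold)
  new_detection(tbl, prior, threshold, "gene_id")
}

#' @rdname detect_expressed
#' @export
detect_antisense <- function(counts, lengths = NULL, background,
                             threshold = 1, prior = NULL) {
  detect_expressed(counts, lengths, background, strand = "antisense",
                   threshold = threshold, prior = prior)
}

# Pool replicate counts and attach lengths; returns gene_id, count, length.
pool_counts <- function(counts, lengths, strand) {
  counts <- as_tibble(counts)
  id_col <- intersect(c("gene_id", "unit_id"), names(counts))[1]
  if (is.na(id_col)) abort("counts must have a gene_id or unit_id column")
  col <- if (strand %in% names(counts)) strand
  else if ("count" %in% names(counts)) "count"
  else abort(sprintf("no '%s' or 'count' column in counts", strand))
  pooled <- counts |>
    group_by(gene_id = .data[[id_col]]) |>
    summarise(count = sum(.data[[col]]),
              length = if ("length" %in% names(counts)) .data$length[1] else NA_real_,
              .groups = "drop")
  if (all(is.na(pooled$length))) {
    if (is.null(lengths)) abort("`lengths` required when counts carry no length column")
    lens <- if ("exonic_length" %in% names(lengths)) {
      transmute(lengths, .data$gene_id, length = .data$exonic_length)
    } else if (all(c("start", "end") %in% names(lengths))) {
      transmute(gene_lengths(lengths), .data$gene_id, length = .data$exonic_length)
    } else if ("length" %in% names(lengths)) {
      select(lengths, "gene_id", "length")
    } else abort("cannot interpret `lengths`")
    pooled <- pooled |> select(-"length") |> inner_join(lens, by = "gene_id")
  }
  if (any(is.na(pooled$length))) abort("length missing for some units")
  pooled
}

#' Threshold-vs-FDR curve
#'
#' Estimated FDR (mean posterior null probability of the detected set) and
#' detected-set size over a grid of posterior-odds thresholds.
#'
#' @param detection An `ss_detection` (or `ss_intron_detection`).
#' @param thresholds Threshold grid; defaults to the observed `B` values.
#' @return Tibble: `threshold`, `n_detected`, `fdr` (both non-decreasing in
#'   the threshold).
#' @export
fdr_curve <- function(detection, thresholds = NULL) {
  ok <- !is.na(detection$B)
  B <- detection$B[ok]
  p0 <- detection$p0[ok]
  o <- order(B)
  B <- B[o]; p0 <- p0[o]
  cum_fdr <- cumsum(p0) / seq_along(p0)
  if (is.null(thresholds)) {
    idx <- unique(round(seq(1, length(B), length.out = min(length(B), 512))))
    tibble(threshold = B[idx], n_detected = idx, fdr = cum_fdr[idx])
  } else {
    n_det <- findInterval(thresholds, B, left.open = TRUE)
    tibble(threshold = thresholds, n_detected = n_det,
           fdr = ifelse(n_det > 0, cum_fdr[pmax(n_det, 1)], NA_real_))
  }
}

#' @export
print.ss_detection <- function(x, ...) {
  cat(sprintf("<ss_detection> %d/%d units detected (B < %g), estimated FDR %s\n",
              attr(x, "n_detected"), nrow(x), attr(x, "threshold"),
              if (is.na(attr(x, "fdr"))) "NA" else sprintf("%.3g", attr(x, "fdr"))))
  NextMethod()
}

#' @method tidy ss_detection
#' @export
tidy.ss_detection <- function(x, ...) {
  as_tibble(x)
}

#' Detection run summary
#'
#' @param x An `ss_detection`.
#' @param ... Unused.
#' @return One-row tibble: `n_units`, `n_detected`, `fdr`, `pi0`, `shape`,
#'   `rate`, `prior_mean`, `lambda0`, `threshold`.
#' @method glance ss_detection
#' @export
glance.ss_detection <- function(x, ...) {
  pr <- attr(x, "prior")
  tibble(n_units = nrow(x), n_detected = attr(x, "n_detected"),
         fdr = attr(x, "fdr"), pi0 = pr$pi0, shape = pr$shape,
         rate = pr$rate, prior_mean = pr$mean, lambda0 = pr$lambda0,
         threshold = attr(x, "threshold"))
}

#' @method autoplot ss_detection
#' @export
autoplot.ss_detection <- function(object, ...) {
  crv <- fdr_curve(object)
  ggplot2::ggplot(crv, ggplot2::aes(x = .data$threshold, y = .data$fdr)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "threshold"), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Posterior odds threshold (B)", y = "Estimated FDR",
                  title = sprintf("%d units detected at B < %g (FDR %.2g)",
                                  attr(object, "n_detected"),
                                  attr(object, "threshold"), attr(object, "fdr"))) +
    ggplot2::theme_minimal()
}

#' Write a detection table with its run-level parameters
#'
#' The per-unit table goes to `<path>` as TSV and the run-level parameters
#' (`lambda0`, `pi0`, `shape`, `rate`, `n_detected`, `fdr`) to
#' `<path>.json`.
#'
#' @param detection An `ss_detection`.
#' @param path Output TSV path.
#' @export
write_detection <- function(detection, path) {
  readr::write_tsv(as_tibble(detection), path)
  jsonlite::write_json(as.list(glance(detection)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
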