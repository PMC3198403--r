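#' Length-normalized coverage percentile curve for NCRs
#'
#' Sorts the per-NCR length-normalized coverage (LNC = reads/bp) ascending
#' against the cumulative fraction of NCRs — the diagnostic used to pick the
#' background exclusion percentile (regions above it are typically
#' unannotated genes, not background).
#'
#' @param ncr_counts Tibble with `count` and `length` columns (e.g. from
#'   [count_ncr_reads()]).
#' @return Tibble: `fraction` (cumulative fraction of NCRs), `lnc`
#'   (reads/bp), both non-decreasing.
#' @export
lnc_percentile_curve <- function(ncr_counts) {
  if (nrow(ncr_counts) == 0) abort("empty NCR set")
  lnc <- sort(ncr_counts$count / ncr_counts$length)
  tibble(fraction = seq_along(lnc) / length(lnc), lnc = lnc)
}

#' Estimate the background read density from NCR counts
#'
#' Regions with LNC above the `percentile`-th empirical quantile (default
#' the 99th) are excluded as likely unannotated transcription; the
#' background rate is the pooled ratio of total retained reads to total
#' retained length (the maximum-likelihood estimate of a common Poisson
#' rate), not the mean of per-region ratios. Ties at the threshold are
#' retained.
#'
#' @inheritParams lnc_percentile_curve
#' @param percentile Exclusion quantile in (0, 1].
#' @return Object of class `ss_background`: `lambda0` (reads/bp),
#'   `percentile`, `n_retained`, `retained_length`, `curve` (the
#'   [lnc_percentile_curve()] tibble), `cutoff_lnc`.
#' @export
estimate_lambda0 <- function(ncr_counts, percentile = 0.99) {
  if (nrow(ncr_counts) == 0) abort("empty NCR set")
  if (nrow(ncr_counts) < 10) warn("fewer than 10 NCRs: background estimate is unstable")
  lnc <- ncr_counts$count / ncr_counts$length
  # inverse-ECDF quantile (type 1): the cutoff is an observed order statistic,
  # so arbitrarily inflating the excluded top fraction cannot move it
  cutoff <- stats::quantile(lnc, percentile, names = FALSE, type = 1)
  keep <- lnc <= cutoff
  if (!any(keep)) abort("all NCRs excluded by the percentile rule")
  lambda0 <- sum(ncr_counts$count[keep]) / sum(ncr_counts$length[keep])
  retained_length <- sum(ncr_counts$length[keep])
  if (lambda0 == 0) {
    warn("zero background counts: lambda0 floored at 1/total retained length")
    lambda0 <- 1 / retained_length
  }
  structure(
    list(lambda0 = lambda0, percentile = percentile,
         n_retained = sum(keep), retained_length = retained_length,
         cutoff_lnc = cutoff, curve = lnc_percentile_curve(ncr_counts)),
    class = "ss_background"
  )
}

#' @export
print.ss_background <- function(x, ...) {
  cat(sprintf(
    "<ss_background> lambda0 = %.3g reads/bp (percentile %.2f; %d regions, %.3g bp retained)\n",
    x$lambda0, x$percentile, x$n_retained, x$retained_length))
  invisible(x)
}

#' @importFrom generics glance
#' @method glance ss_background
#' @export
glance.ss_background <- function(x, ...) {
  tibble(lambda0 = x$lambda0, percentile = x$percentile,
         n_retained = x$n_retained, retained_length = x$retained_length,
         cutoff_lnc = x$cutoff_lnc)
}

#' @importFrom ggplot2 autoplot
#' @method autoplot ss_background
#' @export
autoplot.ss_background <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fraction, y = .data$lnc)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$lambda0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$percentile, linetype = "dotted") +
    ggplot2::labs(x = "Fraction of NCRs",
                  y = "Length-normalized coverage (reads/bp)",
                  title = sprintf("Background rate lambda0 = %.3g reads/bp",
                                  object$lambda0)) +
    ggplot2::theme_minimal()
}
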