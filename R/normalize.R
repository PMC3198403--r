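#' Normalization factors for replicate count columns
#'
#' Four methods, all rescaled so the factors have geometric mean 1:
#' * `total` — column sums (total-count / library-size normalization);
#' * `upper_quartile` — 75th percentile of each column's nonzero counts;
#' * `tmm` — trimmed mean of M-values with the standard published defaults
#'   (30% two-sided trim on log-ratios, 5% on average intensity, precision
#'   weights, reference = column whose upper quartile is closest to the mean
#'   upper quartile);
#' * `spikein` — column sums over the spike-in units only.
#'
#' @param counts Tibble with a unit id column (`gene_id` or `unit_id`) and
#'   one numeric column per replicate, or a numeric matrix with unit
#'   rownames.
#' @param method One of `"total"`, `"upper_quartile"`, `"tmm"`, `"spikein"`.
#' @param spikein_ids Unit ids of the spike-ins (required for `"spikein"`).
#' @return Tibble: `replicate`, `method`, `factor` (geometric mean 1).
#' @export
normalization_factors <- function(counts,
                                  method = c("total", "upper_quartile",
                                             "tmm", "spikein"),
                                  spikein_ids = NULL) {
  method <- match.arg(method)
  m <- counts_as_matrix(counts)
  if (ncol(m) < 2) abort("need at least two replicate columns")
  if (any(colSums(m) == 0)) abort("all-zero replicate column")
  raw <- switch(
    method,
    total = colSums(m),
    upper_quartile = apply(m, 2, function(x) {
      nz <- x[x > 0]
      if (length(nz) == 0) abort("column with no nonzero counts")
      stats::quantile(nz, 0.75, names = FALSE)
    }),
    tmm = {
      N <- colSums(m)
      x <- m[rowSums(m > 0) > 0, , drop = FALSE]
      f75 <- apply(x, 2, function(xx) stats::quantile(xx, 0.75, names = FALSE)) / N
      ref <- which.min(abs(f75 - mean(f75)))
      f <- vapply(seq_len(ncol(m)), function(j) {
        tmm_pair(x[, j], x[, ref], N[j], N[ref])
      }, numeric(1))
      N * f  # effective library sizes; rescaled below
    },
    spikein = {
      if (is.null(spikein_ids)) abort("spikein method requires spikein_ids")
      hit <- rownames(m) %in% spikein_ids
      if (sum(hit) == 0) abort("no spike-in units found in the count table")
      colSums(m[hit, , drop = FALSE])
    }
  )
  if (any(raw <= 0)) abort("non-positive normalization factor")
  factor <- raw / exp(mean(base::log(raw)))
  tibble(replicate = colnames(m), method = method, factor = unname(factor))
}

# TMM factor of column y against reference r (Robinson & Oshlack 2010):
# weighted trimmed mean of M = log2((y/Ny)/(r/Nr)) over genes surviving a
# 30% two-sided trim on M and a 5% trim on A, weights = inverse
# delta-method variances.
tmm_pair <- function(y, r, Ny, Nr, logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- y > 0 & r > 0
  y <- y[keep]; r <- r[keep]
  M <- log2((y / Ny) / (r / Nr))
  A <- 0.5 * log2((y / Ny) * (r / Nr))
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; y <- y[fin]; r <- r[fin]
  if (length(M) == 0) return(1)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  w <- (Ny - y) / (Ny * y) + (Nr - r) / (Nr * r)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

counts_as_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  counts <- as_tibble(counts)
  id_col <- intersect(c("gene_id", "unit_id"), names(counts))[1]
  num <- names(counts)[vapply(counts, is.numeric, logical(1))]
  m <- as.matrix(counts[num])
  rownames(m) <- if (!is.na(id_col)) counts[[id_col]] else NULL
  m
}

#' Chi-square goodness-of-fit of technical replicates under normalization
#'
#' With normalization factors `d_j`, the expected count for gene g in
#' replicate j is `d_j * sum_k(Y_gk) / sum_k(d_k)`; the per-gene statistic is
#' `sum_j (Y_gj - E_gj)^2 / E_gj`, which is approximately chi-square with
#' n-1 degrees of freedom when replicates are Poisson and no gene is
#' differentially represented. Observed quantiles tracking the theoretical
#' ones indicates the normalization explains between-replicate differences.
#'
#' @inheritParams normalization_factors
#' @param factors Output of [normalization_factors()] (or a numeric vector,
#'   one factor per replicate column).
#' @return Object of class `ss_gof`: per-gene `statistic` tibble, `df`
#'   (n - 1), and `qq` tibble of (theoretical, observed) quantile pairs.
#' @export
gof_statistics <- function(counts, factors) {
  m <- counts_as_matrix(counts)
  d <- if (is.data.frame(factors)) {
    stats::setNames(factors$factor, factors$replicate)[colnames(m)]
  } else {
    rep_len(factors, ncol(m))
  }
  if (any(is.na(d))) abort("factors missing for some replicate columns")
  pooled <- rowSums(m)
  keep <- pooled > 0
  mk <- m[keep, , drop = FALSE]
  expected <- outer(rowSums(mk), d / sum(d))
  stat <- rowSums((mk - expected)^2 / expected)
  ids <- rownames(mk)
  df <- ncol(m) - 1
  probs <- stats::ppoints(length(stat))
  qq <- tibble(theoretical = stats::qchisq(probs, df = df),
               observed = sort(stat))
  structure(
    list(statistics = tibble(unit_id = ids %||% seq_along(stat), statistic = unname(stat)),
         df = df, qq = qq,
         method = if (is.data.frame(factors)) factors$method[1] else "custom"),
    class = "ss_gof"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ss_gof <- function(x, ...) {
  cat(sprintf("<ss_gof> %d genes, chi-square df = %d, median statistic %.3g (theoretical %.3g)\n",
              nrow(x$statistics), x$df, stats::median(x$statistics$statistic),
              stats::qchisq(0.5, x$df)))
  invisible(x)
}

#' @method glance ss_gof
#' @export
glance.ss_gof <- function(x, ...) {
  fit <- stats::lm(observed ~ 0 + theoretical, data = x$qq)
  tibble(n_genes = nrow(x$statistics), df = x$df,
         median_statistic = stats::median(x$statistics$statistic),
         qq_slope = unname(stats::coef(fit)[1]), method = x$method)
}

#' @method autoplot ss_gof
#' @export
autoplot.ss_gof <- function(object, ...) {
  ggplot2::ggplot(object$qq, ggplot2::aes(x = .data$theoretical, y = .data$observed)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("Chi-square(%d) quantiles", object$df),
                  y = "Observed goodness-of-fit quantiles",
                  title = sprintf("Replicate homogeneity under %s normalization",
                                  object$method)) +
    ggplot2::theme_minimal()
}

#' Compare normalization methods by goodness-of-fit
#'
#' Runs [normalization_factors()] and [gof_statistics()] for each method and
#' returns their [glance()] rows; a QQ slope near 1 indicates replicate
#' variation consistent with Poisson noise under that normalization.
#'
#' @inheritParams normalization_factors
#' @param methods Methods to compare.
#' @return Tibble of glance rows, one per method.
#' @export
compare_normalizations <- function(counts,
                                   methods = c("total", "upper_quartile", "tmm"),
                                   spikein_ids = NULL) {
  if (!is.null(spikein_ids)) methods <- union(methods, "spikein")
  purrr::map_dfr(methods, function(me) {
    f <- normalization_factors(counts, me, spikein_ids = spikein_ids)
    glance(gof_statistics(counts, f))
  })
}
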