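#' Define a multiplex index set
#'
#' Reads start with a variable index of `k` bases followed by fixed common
#' base(s) (a single T in the standard design) and then the insert. The
#' common base is checked during demultiplexing but mismatches there do not
#' affect assignment.
#'
#' @param indices Character vector of index sequences (A/C/G/T, equal length).
#' @param common_bases Fixed base(s) following the index (`"T"` by default;
#'   `""` for none).
#' @return An object of class `ss_index_set`.
#' @export
index_set <- function(indices, common_bases = "T") {
  indices <- toupper(indices)
  if (length(indices) < 1) abort("need at least one index")
  k <- unique(nchar(indices))
  if (length(k) != 1) abort("indices have mixed lengths")
  if (any(grepl("[^ACGT]", indices))) abort("indices contain non-ACGT symbols")
  if (anyDuplicated(indices)) abort("duplicate index sequences")
  structure(
    list(indices = indices, index_length = k,
         common_bases = toupper(common_bases),
         prefix_length = k + nchar(common_bases)),
    class = "ss_index_set"
  )
}

#' @export
print.ss_index_set <- function(x, ...) {
  cat(sprintf("<ss_index_set> %d indices of length %d, common base(s) '%s'\n",
              length(x$indices), x$index_length, x$common_bases))
  invisible(x)
}

# Pairwise Hamming distances between equal-length strings.
hamming_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(seqs, seqs))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(m[i, ] != m[j, ])
  }
  d
}

#' Validate a multiplex index set
#'
#' Checks the design requirements: minimum pairwise Hamming distance
#' (substitutions only) of at least 2, so a single sequencing error in the
#' index still identifies a unique sample, and per-position base balance.
#' An optional Levenshtein distance (allowing indels) is reported for index
#' design.
#'
#' @param indices Character vector of indices, or an [index_set()].
#' @param levenshtein Also compute the minimum pairwise Levenshtein distance.
#' @return A list: `min_distance`, `valid` (min distance >= 2),
#'   `base_balance` (position x base frequency tibble), `distance_matrix`,
#'   and `min_levenshtein` if requested.
#' @export
validate_index_set <- function(indices, levenshtein = FALSE) {
  if (inherits(indices, "ss_index_set")) indices <- indices$indices
  indices <- toupper(indices)
  if (length(indices) < 2) abort("need at least two indices to validate")
  if (length(unique(nchar(indices))) != 1) abort("indices have mixed lengths")
  if (any(grepl("[^ACGT]", indices))) abort("indices contain non-ACGT symbols")
  d <- hamming_matrix(indices)
  min_d <- min(d[upper.tri(d)])
  m <- do.call(rbind, strsplit(indices, ""))
  balance <- purrr::map_dfr(seq_len(ncol(m)), function(p) {
    tab <- table(factor(m[, p], levels = c("A", "C", "G", "T")))
    tibble(position = p, base = names(tab),
           frequency = as.numeric(tab) / length(indices))
  })
  out <- list(min_distance = min_d, valid = min_d >= 2,
              base_balance = balance, distance_matrix = d)
  if (levenshtein) {
    ld <- utils::adist(indices)
    out$min_levenshtein <- min(ld[upper.tri(ld)])
  }
  out
}

#' Demultiplex indexed FASTQ reads
#'
#' Assigns each read to the unique index at Hamming distance at most
#' `max_mismatch` from its first `k` bases; reads at equal minimal distance
#' to two indices (ties) or beyond `max_mismatch` from all are unassigned.
#' Assigned reads are trimmed of the index prefix and the fixed common
#' base(s) before being written.
#'
#' @param reads Path to a FASTQ file, or a named character vector of read
#'   sequences (names = read ids).
#' @param index_set An [index_set()] (or character vector of indices).
#' @param max_mismatch Maximum Hamming distance for assignment (default 1).
#' @param out_dir If non-NULL, per-index trimmed FASTQ files
#'   `<out_dir>/<index>.fastq` are written.
#' @return A tibble of class `ss_demux` with one row per index: `index`,
#'   `reads`, `exact`, `rescued`, `fraction` (of total input reads).
#'   Attributes: `total`, `unassigned`, `assignments` (per-read index or NA).
#' @export
demultiplex <- function(reads, index_set, max_mismatch = 1, out_dir = NULL) {
  if (is.character(index_set)) index_set <- index_set(index_set)
  quals <- NULL
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    # readQualityScaledDNAStringSet warns about dropping its own internal
    # metadata columns; nothing user-visible is lost
    fq <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(reads),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    quals <- as.character(Biostrings::quality(fq))
    seqs <- as.character(fq)
    names(seqs) <- sub("\\s.*", "", names(fq))
  } else {
    seqs <- stats::setNames(as.character(reads), names(reads))
    if (is.null(names(seqs))) names(seqs) <- sprintf("read_%d", seq_along(seqs))
  }
  idx <- index_set$indices
  k <- index_set$index_length
  total <- length(seqs)

  assignment <- rep(NA_character_, total)
  dist_used <- rep(NA_integer_, total)
  long_enough <- nchar(seqs) >= index_set$prefix_length
  if (any(long_enough)) {
    prefix <- substr(seqs[long_enough], 1L, k)
    # distance of every prefix to every index, one position at a time
    dmat <- matrix(0L, nrow = sum(long_enough), ncol = length(idx))
    for (p in seq_len(k)) {
      pc <- substr(prefix, p, p)
      for (i in seq_along(idx)) {
        dmat[, i] <- dmat[, i] + (pc != substr(idx[i], p, p))
      }
    }
    best <- apply(dmat, 1, min)
    n_best <- rowSums(dmat == best)
    ok <- best <= max_mismatch & n_best == 1L
    assignment[long_enough][ok] <- idx[apply(dmat[ok, , drop = FALSE], 1, which.min)]
    dist_used[long_enough][ok] <- best[ok]
  }

  summary <- tibble(index = idx) |>
    left_join(
      tibble(index = assignment[!is.na(assignment)],
             exact0 = dist_used[!is.na(assignment)] == 0L) |>
        group_by(.data$index) |>
        summarise(reads = dplyr::n(), exact = sum(.data$exact0),
                  rescued = sum(!.data$exact0), .groups = "drop"),
      by = "index"
    ) |>
    mutate(across(c("reads", "exact", "rescued"), ~ dplyr::coalesce(.x, 0L)),
           fraction = if (total > 0) .data$reads / total else 0)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in idx) {
      sel <- which(!is.na(assignment) & assignment == i)
      trimmed <- substring(seqs[sel], index_set$prefix_length + 1L)
      out <- Biostrings::DNAStringSet(trimmed)
      names(out) <- names(seqs)[sel]
      path <- file.path(out_dir, paste0(i, ".fastq"))
      if (!is.null(quals)) {
        q <- Biostrings::PhredQuality(substring(quals[sel], index_set$prefix_length + 1L))
        out <- Biostrings::QualityScaledDNAStringSet(out, q)
        Biostrings::writeQualityScaledXStringSet(out, path)
      } else {
        Biostrings::writeXStringSet(
          out, path, format = "fastq",
          qualities = Biostrings::PhredQuality(strrep("I", nchar(trimmed)))
        )
      }
    }
  }

  structure(summary,
            class = c("ss_demux", class(summary)),
            total = total,
            unassigned = total - sum(summary$reads),
            assignments = stats::setNames(assignment, names(seqs)))
}

#' Summarise index balance across lanes
#'
#' Per-index mean of within-lane read fractions with the standard error of
#' the mean, as used to check that a balanced index design yields an even
#' spread of reads across multiplexed samples.
#'
#' @param lanes A list of `ss_demux` results (one per lane), or a tibble with
#'   columns `lane`, `index`, `fraction`.
#' @return Tibble: `index`, `mean_fraction`, `se`, `n_lanes`.
#' @export
summarize_index_balance <- function(lanes) {
  if (is.data.frame(lanes)) {
    df <- as_tibble(lanes)
  } else {
    keep <- purrr::map_lgl(lanes, function(l) {
      tot <- attr(l, "total")
      if (is.null(tot) || tot == 0) {
        warn("lane with zero total reads excluded")
        FALSE
      } else TRUE
    })
    df <- purrr::imap_dfr(lanes[keep], function(l, i) {
      tibble(lane = i, index = l$index, fraction = l$fraction)
    })
  }
  if (nrow(df) == 0) abort("no usable lanes")
  df |>
    group_by(.data$index) |>
    summarise(
      mean_fraction = mean(.data$fraction),
      se = if (dplyr::n() > 1) stats::sd(.data$fraction) / sqrt(dplyr::n()) else 0,
      n_lanes = dplyr::n(), .groups = "drop"
    )
}
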