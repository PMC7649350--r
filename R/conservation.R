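#' Read an aligned FASTA file as an MSA matrix
#'
#' Rows are case-folded to upper case; both `.` and `-` are read as the
#' gap character `-`. Ragged rows or residues outside the 20 standard
#' amino acids are format errors.
#'
#' @param path Path to an aligned FASTA file.
#' @return A character matrix of class `msa` (rows = sequences).
#' @export
read_msa <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    abort(sprintf("could not parse FASTA: %s",
                                  conditionMessage(e)),
                          class = "curvesense_format_error")
                  })
  ids <- names(set)
  seqs <- toupper(gsub("\\.", "-", as.character(set)))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    abort("rows have unequal lengths: not an alignment.",
          class = "curvesense_format_error")
  }
  ok_chars <- c(AA_ALPHABET, "-")
  mat <- matrix("", length(seqs), widths[1])
  for (i in seq_along(seqs)) {
    row <- strsplit(seqs[[i]], "")[[1]]
    bad <- setdiff(unique(row), ok_chars)
    if (length(bad) > 0) {
      abort(sprintf("illegal character(s) %s in sequence '%s'.",
                    paste(bad, collapse = ", "), ids[i]),
            class = "curvesense_format_error")
    }
    mat[i, ] <- row
  }
  rownames(mat) <- ids
  structure(mat, class = c("msa", "matrix", "array"))
}

#' Write an MSA matrix as aligned FASTA
#'
#' @param msa A character matrix (class `msa`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  ids <- rownames(msa) %||% sprintf("seq%04d", seq_len(nrow(msa)))
  rows <- apply(unclass(msa), 1, paste, collapse = "")
  set <- Biostrings::BStringSet(setNames(rows, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

column_counts <- function(msa, column_index) {
  col <- unclass(msa)[, column_index]
  col[col != "-"]
}

#' Per-column information content of an alignment
#'
#' The sequence-logo height: `log2(20)` minus the Shannon entropy of the
#' residue frequencies among non-gap symbols at the column,
#' \deqn{R = \log_2 20 + \sum_a f_a \log_2 f_a ,}
#' ranging from 0 bits (uniform over all residues) to about 4.32 bits (a
#' perfectly conserved column). The optional small-sample correction
#' subtracts \eqn{19 / (2 \ln 2 \cdot n)} with `n` the non-gap count;
#' negative corrected values are clipped to 0.
#'
#' @param msa An `msa` matrix.
#' @param column_index 1-based column index.
#' @param small_sample_correction Apply the finite-`n` entropy bias
#'   correction (default `FALSE`; with hundreds of rows it is
#'   negligible).
#' @return Information content in bits.
#' @export
column_information <- function(msa, column_index,
                               small_sample_correction = FALSE) {
  res <- column_counts(msa, column_index)
  if (length(res) == 0L) {
    abort("all-gap column: information undefined.",
          class = "curvesense_undefined_column")
  }
  f <- table(res) / length(res)
  h <- -sum(f * log2(f))
  r <- log2(20) - h
  if (small_sample_correction) {
    r <- r - (20 - 1) / (2 * log(2) * length(res))
  }
  max(r, 0)
}

#' Per-column weight (fraction of existence)
#'
#' The fraction of sequences with a residue (non-gap) at the column: the
#' logo "width", a proxy for how often the position is spliced out.
#'
#' @inheritParams column_information
#' @return Fraction in \[0, 1\].
#' @export
column_weight <- function(msa, column_index) {
  length(column_counts(msa, column_index)) / nrow(msa)
}

#' Information and weight over a named region
#'
#' @param msa An `msa` matrix.
#' @param region 0-based half-open column interval `c(start, end)`.
#' @param name Region label.
#' @param small_sample_correction See [column_information()].
#' @return A tibble of class `region_stats` with one row per column:
#'   `region`, `column` (0-based), `information_bits` (NA for all-gap
#'   columns), `weight`.
#' @export
region_stats <- function(msa, region, name = "region",
                         small_sample_correction = FALSE) {
  if (region[1] < 0 || region[2] > ncol(msa) || region[1] >= region[2]) {
    abort("region interval empty or outside the alignment.",
          class = "curvesense_invalid_parameters")
  }
  cols <- (region[1] + 1):region[2]
  info <- vapply(cols, function(j) {
    w <- column_weight(msa, j)
    if (w == 0) NA_real_ else {
      column_information(msa, j, small_sample_correction)
    }
  }, numeric(1))
  wts <- vapply(cols, function(j) column_weight(msa, j), numeric(1))
  out <- tibble::tibble(region = name, column = cols - 1L,
                        information_bits = info, weight = wts)
  class(out) <- c("region_stats", class(out))
  out
}

#' Compare two alignment regions with a Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on per-column values
#' of the chosen metric, the standard non-parametric contrast between the
#' conservation profiles of two regions (e.g. the alternatively spliced
#' disordered region of one paralog versus another). Exact enumeration is
#' used for small groups (both below 20 columns, no ties); otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param a,b `region_stats` tibbles (or data frames with
#'   `information_bits` / `weight` columns). Columns with missing
#'   information (all-gap) are dropped; at least 5 usable columns per
#'   region are required.
#' @param metric `"information"` or `"weight"`.
#' @return A one-row tibble of class `region_comparison`: `metric`,
#'   `U` (for the first region), `p.value` (two-sided), `n_a`, `n_b`,
#'   `exact`.
#' @export
compare_regions <- function(a, b, metric = c("information", "weight")) {
  metric <- match.arg(metric)
  pick <- function(s) {
    v <- if (metric == "information") s$information_bits else s$weight
    v[is.finite(v)]
  }
  va <- pick(a); vb <- pick(b)
  if (length(va) < 5L || length(vb) < 5L) {
    abort("need at least 5 usable columns per region.",
          class = "curvesense_insufficient_data")
  }
  use_exact <- length(va) < 20L && length(vb) < 20L &&
    !anyDuplicated(c(va, vb))
  wt <- suppressWarnings(
    wilcox.test(va, vb, alternative = "two.sided", exact = use_exact,
                correct = TRUE))
  out <- tibble::tibble(metric = metric, U = unname(wt$statistic),
                        p.value = wt$p.value,
                        n_a = length(va), n_b = length(vb),
                        exact = use_exact)
  class(out) <- c("region_comparison", class(out))
  out
}
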