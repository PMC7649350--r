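AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parameters for a simulated protein multiple sequence alignment
#'
#' Emulates the cross-species conservation structure of an alignment of
#' orthologous proteins: each row starts from a consensus sequence, every
#' column is substituted with a (possibly region-specific) probability, and
#' whole named regions are deleted per sequence with a region-specific
#' probability, mimicking alternative splicing of that region (deleted
#' residues become gaps).
#'
#' @param consensus Consensus amino-acid string (the 20 standard residues).
#' @param n_sequences Number of rows (species) to simulate.
#' @param p_substitution Per-column substitution probability: a single
#'   number, or a named vector with one entry per region (columns outside
#'   any region use `p_background`). A substitution replaces the consensus
#'   residue with one of the other 19, uniformly.
#' @param p_background Substitution probability outside named regions when
#'   `p_substitution` is region-specific.
#' @param p_region_deletion Named vector: per-sequence probability each
#'   region is absent entirely.
#' @param regions Named list of 0-based half-open column intervals
#'   `c(start, end)`.
#' @param seed Integer seed.
#' @return A validated `msa_params` list.
#' @export
msa_params <- function(consensus, n_sequences = 200,
                       p_substitution = 0.05, p_background = 0.05,
                       p_region_deletion = NULL, regions = list(),
                       seed = 1L) {
  if (!is.character(consensus) || length(consensus) != 1L ||
      nchar(consensus) == 0L) {
    abort("`consensus` must be a non-empty amino-acid string.",
          class = "curvesense_invalid_parameters")
  }
  cons <- strsplit(toupper(consensus), "")[[1]]
  if (!all(cons %in% AA_ALPHABET)) {
    abort("`consensus` contains non-standard residues.",
          class = "curvesense_invalid_parameters")
  }
  L <- length(cons)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (r[1] < 0 || r[2] > L || r[1] >= r[2]) {
      abort(sprintf("region '%s' is outside the consensus.", nm),
            class = "curvesense_invalid_parameters")
    }
  }
  probs <- c(p_substitution, p_background, p_region_deletion)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1].",
          class = "curvesense_invalid_parameters")
  }
  structure(list(consensus = cons, n_sequences = as.integer(n_sequences),
                 p_substitution = p_substitution,
                 p_background = p_background,
                 p_region_deletion = p_region_deletion,
                 regions = regions, seed = as.integer(seed)),
            class = "msa_params")
}

#' Simulate a multiple sequence alignment with region-specific conservation
#'
#' @param params An [msa_params()] object.
#' @return A character matrix of single residues (rows = sequences,
#'   columns = alignment positions, gaps as `"-"`) of class `msa`, with
#'   the generating parameters attached as `ground_truth`.
#' @examples
#' p <- msa_params(random_consensus(40, seed = 1), n_sequences = 50,
#'                 seed = 2)
#' aln <- simulate_msa(p)
#' @export
simulate_msa <- function(params) {
  stopifnot(inherits(params, "msa_params"))
  L <- length(params$consensus)
  n <- params$n_sequences
  local_seed(params$seed)

  ## per-column substitution probability
  p_col <- rep(if (length(params$p_substitution) == 1L &&
                   is.null(names(params$p_substitution))) {
    params$p_substitution
  } else params$p_background, L)
  if (!is.null(names(params$p_substitution))) {
    for (nm in names(params$p_substitution)) {
      r <- params$regions[[nm]]
      if (is.null(r)) {
        abort(sprintf("`p_substitution` names unknown region '%s'.", nm),
              class = "curvesense_invalid_parameters")
      }
      p_col[(r[1] + 1):r[2]] <- params$p_substitution[[nm]]
    }
  }

  aln <- matrix(rep(params$consensus, each = n), nrow = n)
  ## substitutions: uniform over the 19 non-consensus residues
  sub_mask <- matrix(runif(n * L), n, L) <
    matrix(p_col, n, L, byrow = TRUE)
  if (any(sub_mask)) {
    idx <- which(sub_mask)
    orig <- aln[idx]
    pick <- AA_ALPHABET[sample.int(19L, length(idx), replace = TRUE)]
    ## shift picks that landed on the original residue to the 20th letter
    shift <- pick == orig
    pick[shift] <- AA_ALPHABET[20L]
    ## when the original *is* the 20th letter, redraw deterministically
    still <- pick == orig
    pick[still] <- AA_ALPHABET[1L]
    aln[idx] <- pick
  }
  ## region deletions (splicing): whole region gapped per sequence
  for (nm in names(params$p_region_deletion)) {
    r <- params$regions[[nm]]
    if (is.null(r)) {
      abort(sprintf("`p_region_deletion` names unknown region '%s'.", nm),
            class = "curvesense_invalid_parameters")
    }
    gone <- runif(n) < params$p_region_deletion[[nm]]
    aln[gone, (r[1] + 1):r[2]] <- "-"
  }
  rownames(aln) <- sprintf("seq%04d", seq_len(n))
  structure(aln, class = c("msa", "matrix", "array"),
            ground_truth = params)
}

#' Draw a random consensus sequence
#'
#' @param length Number of residues.
#' @param seed Integer seed.
#' @return A single amino-acid string, uniform over the 20 residues.
#' @export
random_consensus <- function(length, seed = 1L) {
  local_seed(seed)
  paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
}
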