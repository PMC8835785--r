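# Entropy measures, reading-type label counts, codon-block extraction.

plogp_sum <- function(x) {
  x <- x[x > 0]  # 0 * log(0) := 0
  -sum(x * log(x))
}

#' Code-matrix entropy Hc
#'
#' Sum of the Shannon entropies of the 64 codon rows, in nats:
#' `Hc = -sum_c sum_l p[c, l] * ln p[c, l]` with `0 ln 0 = 0`. Ranges from 0
#' (every codon deterministically assigned) to `64 * ln 21` (about 194.87,
#' all assignments uniform).
#'
#' @param code 64 x 21 row-stochastic code matrix.
#' @return Non-negative entropy in nats.
#' @export
#' @examples
#' code_entropy(make_fixture("uniform")$code)  # 64 * log(21)
code_entropy <- function(code) {
  code <- validate_code_matrix(code)
  plogp_sum(code)
}

#' Reading-matrix entropy Hr
#'
#' Sum of the Shannon entropies of the 21 label rows of the reading matrix,
#' in nats: `Hr = -sum_l sum_j r[l, j] * ln r[l, j]`. Ranges from 0 (one
#' mechanism fixed per label) to `21 * ln 3` (about 23.07).
#'
#' @param reading 21 x 3 row-stochastic reading matrix.
#' @return Non-negative entropy in nats.
#' @export
reading_entropy <- function(reading) {
  reading <- validate_reading_matrix(reading)
  plogp_sum(reading)
}

#' Expected number of labels read by each mechanism
#'
#' `E_j = sum_l r[l, j]` for j in M1, M2, M3; the three components always sum
#' to 21. A homogeneous reading system (every label fixed on M1) gives
#' `(21, 0, 0)`.
#'
#' @param reading 21 x 3 row-stochastic reading matrix.
#' @return Named numeric vector `c(M1 = , M2 = , M3 = )`.
#' @export
expected_label_counts <- function(reading) {
  reading <- validate_reading_matrix(reading)
  setNames(colSums(reading), model_names())
}

#' Extract codon blocks from a code matrix
#'
#' For each label, the set of codons assigning it probability strictly above
#' `threshold`. With `threshold > 0.5` blocks are pairwise disjoint (a
#' stochastic row can exceed 0.5 at most once). Labels with no confident
#' codon receive empty blocks.
#'
#' @param code 64 x 21 row-stochastic code matrix.
#' @param threshold Probability cutoff in `(0, 1]`; membership is strict
#'   (`p > threshold`). Default 0.8.
#' @return Object of class `"block_structure"`: list with `blocks` (list of
#'   21 character vectors of codon triplets, named `label_0` ...
#'   `label_20`) and `threshold`.
#' @export
extract_blocks <- function(code, threshold = 0.8) {
  code <- validate_code_matrix(code)
  stopifnot(length(threshold) == 1L, threshold > 0, threshold <= 1)
  blocks <- lapply(seq_len(N_LABELS), function(l) {
    .CODONS[code[, l] > threshold]
  })
  names(blocks) <- label_names()
  structure(list(blocks = blocks, threshold = threshold),
            class = "block_structure")
}

#' @export
print.block_structure <- function(x, ...) {
  sizes <- lengths(x$blocks)
  cat(sprintf("Codon blocks at threshold %g: %d of 21 labels non-empty\n",
              x$threshold, sum(sizes > 0)))
  for (l in which(sizes > 0)) {
    cat(sprintf("  %s: %s\n", names(x$blocks)[l],
                paste(x$blocks[[l]], collapse = " ")))
  }
  invisible(x)
}

#' Distribution of codon-block sizes over labels
#'
#' Counts labels by the size of their codon block; all 21 labels appear in
#' the histogram, size-0 labels included.
#'
#' @param blocks A `block_structure` from [extract_blocks()].
#' @return Named integer vector; name `"k"` gives the number of labels whose
#'   block has exactly `k` codons. Counts sum to 21.
#' @export
block_size_distribution <- function(blocks) {
  stopifnot(inherits(blocks, "block_structure"))
  sizes <- lengths(blocks$blocks)
  tab <- table(factor(sizes, levels = sort(unique(sizes))))
  setNames(as.integer(tab), names(tab))
}

#' Fraction of blocks consistent with wobble-like (M1) reading
#'
#' The fraction of non-empty codon blocks that lie inside a single M1
#' neighborhood, i.e. whose codons are all identical at the first two
#' positions and differ only at the third — the block shape the standard
#' genetic code's synonymous groups mostly take.
#'
#' @param blocks A `block_structure` from [extract_blocks()].
#' @return Fraction in `[0, 1]`; `NaN` when every block is empty.
#' @export
m1_consistency <- function(blocks) {
  stopifnot(inherits(blocks, "block_structure"))
  nonempty <- Filter(length, blocks$blocks)
  if (!length(nonempty)) return(NaN)
  ok <- vapply(nonempty, function(b) {
    length(unique(substr(b, 1L, 2L))) == 1L
  }, logical(1))
  mean(ok)
}
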