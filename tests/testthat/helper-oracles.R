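# Independent oracles used across test files.

# exhaustive column-wise argmax with lowest-index tie-break
argmax_path_oracle <- function(code) {
  vapply(seq_len(ncol(code)), function(l) {
    col <- code[, l]
    which(col == max(col))[1L] - 1L
  }, integer(1))
}

# element-by-element entropy summation (0 log 0 = 0)
entropy_oracle <- function(m) {
  total <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      p <- m[i, j]
      if (p > 0) total <- total - p * log(p)
    }
  }
  total
}

# flat Dirichlet row via normalized exponentials (independent of the
# package's gamma-based sampler)
rdirichlet_exp_oracle <- function(k) {
  e <- -log(runif(k))
  e / sum(e)
}

# total-variation distance between two probability rows
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# product of per-label factors over a label subset (the factorized fitness
# restricted to `labels`)
factorized_subset <- function(code, labels, path, j, p_j) {
  prod(vapply(seq_along(labels), function(i) {
    per_label_term(code, labels[i], path[i], c("M1", "M2", "M3")[j[i]],
                   p_j[i])
  }, numeric(1)))
}
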