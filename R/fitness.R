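# Coding-strength fitness F.
#
# For each label l the Bayes codon c_l = argmax_c p[c, l] anchors a reading
# neighborhood N_j(c_l); the fitness is the product over labels of
#   (p_j / |N_j(c_l)|) * sum_{c' in N_j(c_l)} p[c', l],
# where j is the reading mechanism for label l and p_j its draw probability.
# This product equals the literal sum over all combinations of one codon per
# label (the factors range over independent index sets), which
# brute_force_fitness() enumerates on small label subsets. All arithmetic is
# accumulated in log space: random 21-factor products underflow otherwise.

#' Bayes codon path of a code matrix
#'
#' For each label, the codon maximizing the posterior probability of the
#' codon given the label under a uniform prior over codons — equivalently the
#' codon with the largest assignment probability in the label's column. Ties
#' are broken toward the lowest codon index.
#'
#' @param code 64 x 21 row-stochastic code matrix.
#' @return Integer vector of 21 codon indices (0-based), named by label.
#' @export
#' @examples
#' ind <- random_individual(seed = 1)
#' bayes_path(ind$code)
bayes_path <- function(code) {
  code <- validate_code_matrix(code)
  zero <- which(colSums(code) == 0)
  if (length(zero)) {
    stop("degenerate code matrix: label(s) ",
         paste(zero - 1L, collapse = ", "), " have all-zero columns",
         call. = FALSE)
  }
  # column-wise argmax; max.col(ties.method = "first") gives lowest index
  path <- max.col(t(code), ties.method = "first") - 1L
  names(path) <- label_names()
  path
}

#' Per-label fitness factor
#'
#' The contribution of one label to the coding-strength fitness:
#' `(p_j / |N_model(ref_codon)|) * sum of code[c', label]` over the
#' neighborhood `N_model(ref_codon)`.
#'
#' @param code 64 x 21 code matrix.
#' @param label Label id in `[0, 20]`.
#' @param ref_codon Reference codon (triplet or 0-based index), normally the
#'   Bayes-path codon of `label`.
#' @param model Reading mechanism, `"M1"`, `"M2"` or `"M3"`.
#' @param p_j Probability in `[0, 1]` that this mechanism is the one reading
#'   the label.
#' @return A factor in `[0, 1]`.
#' @export
per_label_term <- function(code, label, ref_codon, model = c("M1", "M2", "M3"),
                           p_j = 1) {
  model <- match.arg(model)
  stopifnot(length(label) == 1L, label >= 0, label <= 20,
            length(p_j) == 1L, p_j >= 0, p_j <= 1)
  idx <- if (is.character(ref_codon)) codon_index(ref_codon)
         else as.integer(ref_codon)
  nb <- nb_tables()[[model]][idx + 1L, ]
  (p_j / length(nb)) * sum(code[nb, label + 1L])
}

draw_reading_assignment <- function(reading) {
  u <- runif(N_LABELS)
  # inverse-CDF draw per row
  j <- 1L + (u > reading[, 1L]) + (u > reading[, 1L] + reading[, 2L])
  as.integer(j)
}

fitness_terms <- function(code, assignment, p_j, path = NULL) {
  if (is.null(path)) path <- bayes_path(code)
  tabs <- nb_tables()
  sizes <- c(4, 7, 10)
  vapply(seq_len(N_LABELS), function(l) {
    nb <- tabs[[assignment[l]]][path[l] + 1L, ]
    (p_j[l] / sizes[assignment[l]]) * sum(code[nb, l])
  }, numeric(1))
}

#' Sampled-reading coding-strength fitness
#'
#' The stochastic evaluation used during evolution: computes the Bayes codon
#' path, draws one
#' reading mechanism per label from the individual's reading matrix, and
#' returns the log of the product of per-label factors
#' `(r[l, j_l] / |N_{j_l}|) * sum over the neighborhood of code[c', l]`.
#' A factor of exactly 0 yields `log_f = -Inf` (such individuals rank below
#' every finite-fitness individual in selection).
#'
#' @param ind A `coding_system` (or list with `$code`, `$reading`).
#' @param seed Optional seed for the reading draw.
#' @param assignment Optional fixed reading assignment: integer vector of 21
#'   values in `{1, 2, 3}` (1 = M1), overriding the random draw.
#' @return List with `log_f` (natural log of F), `terms` (the 21 factors),
#'   and `assignment` (the reading mechanisms used, 1/2/3).
#' @export
#' @examples
#' ind <- make_fixture("deterministic_disjoint")
#' fitness_sampled(ind)$log_f  # 21 * log(1/10): reading fixed on M3
fitness_sampled <- function(ind, seed = NULL, assignment = NULL) {
  ind <- as_individual(ind)
  if (is.null(assignment)) {
    assignment <- with_seed(seed, draw_reading_assignment(ind$reading))
  } else {
    assignment <- as.integer(assignment)
    stopifnot(length(assignment) == N_LABELS, all(assignment %in% 1:3))
  }
  p_j <- ind$reading[cbind(seq_len(N_LABELS), assignment)]
  terms <- fitness_terms(ind$code, assignment, p_j)
  list(log_f = sum(log(terms)), terms = terms, assignment = assignment)
}

#' Expected coding-strength fitness
#'
#' Deterministic variant: each label's factor is replaced by its expectation
#' over the reading draw, `sum_j r[l, j] * (r[l, j] / |N_j|) * sum over
#' N_j(c_l) of code[c', l]` — the draw probability enters once as the
#' sampling weight and once as the factor's own weight, so each mechanism
#' contributes with weight `r[l, j]^2`. Useful for regression tests and for
#' monotone elitist trajectories.
#'
#' @inheritParams fitness_sampled
#' @return List with `log_f` and `terms` (21 expected factors).
#' @export
fitness_expected <- function(ind) {
  ind <- as_individual(ind)
  path <- bayes_path(ind$code)
  tabs <- nb_tables()
  sizes <- c(4, 7, 10)
  terms <- vapply(seq_len(N_LABELS), function(l) {
    sum(vapply(1:3, function(j) {
      nb <- tabs[[j]][path[l] + 1L, ]
      ind$reading[l, j]^2 / sizes[j] * sum(ind$code[nb, l])
    }, numeric(1)))
  }, numeric(1))
  list(log_f = sum(log(terms)), terms = terms)
}

#' Brute-force fitness on a small label subset
#'
#' Literal enumeration of the coding-strength sum: one codon per label drawn
#' from that label's reading neighborhood, summing the products of
#' `code[c', l] * p_j[l] / |N_j(c_l)|` over every combination. Exponential in
#' the number of labels, hence capped at 4; serves as the independent oracle
#' for the factorized fitness.
#'
#' @param code 64 x 21 code matrix.
#' @param labels Integer vector (at most 4) of label ids in `[0, 20]`.
#' @param path Codon indices (0-based), one per entry of `labels`.
#' @param j Reading mechanisms, one per label: integers in `{1, 2, 3}` or
#'   `"M1"`/`"M2"`/`"M3"`.
#' @param p_j Draw probabilities, one per label (default all 1).
#' @return The enumerated fitness (plain scale, not log).
#' @export
brute_force_fitness <- function(code, labels, path, j, p_j = rep(1, length(labels))) {
  if (length(labels) > 4L) {
    stop("brute_force_fitness is capped at 4 labels (combinatorial explosion)",
         call. = FALSE)
  }
  if (is.character(j)) j <- match(j, model_names())
  j <- as.integer(j)
  stopifnot(length(path) == length(labels), length(j) == length(labels),
            length(p_j) == length(labels), all(j %in% 1:3))
  code <- validate_code_matrix(code)
  tabs <- nb_tables()
  sizes <- c(4, 7, 10)
  nbs <- lapply(seq_along(labels), function(i) tabs[[j[i]]][path[i] + 1L, ])
  combos <- as.matrix(expand.grid(nbs, KEEP.OUT.ATTRS = FALSE))
  prod_terms <- rep(1, nrow(combos))
  for (i in seq_along(labels)) {
    prod_terms <- prod_terms *
      code[combos[, i], labels[i] + 1L] * p_j[i] / sizes[j[i]]
  }
  sum(prod_terms)
}
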