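test_that("bayes_path maximizes each label column with lowest-index ties", {
  # identity layout: label l sits deterministically on codon l
  ind <- make_fixture("deterministic_disjoint")
  expect_identical(unname(bayes_path(ind$code)[1:21]), 0:20)
  # uniform columns tie everywhere -> codon 0 wins
  expect_identical(unname(bayes_path(make_fixture("uniform")$code)),
                   rep(0L, 21))
  # random matrices agree with an exhaustive per-column scan
  for (s in 1:5) {
    code <- random_individual(seed = s)$code
    expect_identical(unname(bayes_path(code)), argmax_path_oracle(code))
    # the selection is scale-free in each column: rescaling columns of the
    # raw matrix leaves the exhaustive argmax unchanged
    scaled <- sweep(code, 2L, runif(21, 0.1, 10), `*`)
    expect_identical(argmax_path_oracle(scaled), argmax_path_oracle(code))
  }
})

test_that("bayes_path rejects an all-zero label column", {
  code <- make_fixture("deterministic_disjoint")$code
  # move codon 7 (the only carrier of label 7) onto label 8: column 7 empties
  code[8, 8] <- 0
  code[8, 9] <- 1
  expect_error(bayes_path(code), "7")  # names the degenerate label
})

test_that("per-label factors match closed forms and a direct-summation loop", {
  # a full M1 family coding its label with probability 1 gives a factor of 1
  perfect <- make_fixture("m1_perfect_smallL")
  expect_equal(per_label_term(perfect$code, 0, 0, "M1", 1), 1)
  # a lone codon read through M3 is diluted by the neighborhood size
  lone <- make_fixture("deterministic_disjoint")
  expect_equal(per_label_term(lone$code, 5, 5, "M3", 1), 0.1)
  # random rows: equality with a hand-summed loop over the neighborhood
  for (s in 1:5) {
    code <- random_individual(seed = s)$code
    lab <- s %% 21
    ref <- (7 * s) %% 64
    for (m in c("M1", "M2", "M3")) {
      nb <- codon_index(codon_neighborhood(ref, m))
      hand <- 0
      for (cp in nb) hand <- hand + code[cp + 1L, lab + 1L]
      hand <- 0.37 * hand / length(nb)
      expect_equal(per_label_term(code, lab, ref, m, 0.37), hand,
                   tolerance = 1e-15)
    }
  }
})

test_that("per-label factor is monotone in neighborhood probabilities", {
  set.seed(11)
  for (rep in 1:10) {
    code <- random_individual()$code
    lab <- sample(0:20, 1)
    ref <- sample(0:63, 1)
    nb <- codon_index(codon_neighborhood(ref, "M2"))
    base <- per_label_term(code, lab, ref, "M2", 1)
    bumped <- code  # unnormalized on purpose: isolates the monotonicity
    target <- sample(nb, 1) + 1L
    bumped[target, lab + 1L] <- bumped[target, lab + 1L] + 0.2
    expect_gte(per_label_term(bumped, lab, ref, "M2", 1), base)
  }
})

test_that("sampled fitness hits the disjoint-code closed form and stays <= 1", {
  ind <- make_fixture("deterministic_disjoint")  # reading fixed on M3
  fv <- fitness_sampled(ind)
  expect_equal(fv$log_f, 21 * log(0.1), tolerance = 1e-12)
  expect_equal(fv$terms, rep(0.1, 21), tolerance = 1e-15)
  expect_identical(fv$assignment, rep(3L, 21))
  for (s in 1:10) {
    ind <- random_individual(seed = s)
    expect_lte(fitness_sampled(ind, seed = s)$log_f, 0)
    expect_lte(fitness_expected(ind)$log_f, 0)
  }
})

test_that("factorized fitness equals brute-force enumeration on label subsets", {
  # every combination of reading mechanisms on random 3-label subsystems
  set.seed(3)
  assignments <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  for (rep in 1:20) {
    ind <- random_individual()
    labels <- sample(0:20, 3)
    path <- bayes_path(ind$code)[labels + 1L]
    for (a in seq_len(nrow(assignments))) {
      j <- assignments[a, ]
      p_j <- ind$reading[cbind(labels + 1L, j)]
      bf <- brute_force_fitness(ind$code, labels, path, j, p_j)
      fact <- factorized_subset(ind$code, labels, path, j, p_j)
      expect_equal(bf, fact, tolerance = 1e-12)
    }
  }
})

test_that("brute force reduces to the single-factor and product cases", {
  ind <- random_individual(seed = 9)
  path <- bayes_path(ind$code)
  # 1 label: literal sum equals the per-label factor
  expect_equal(brute_force_fitness(ind$code, 4, path[5], 2, 0.5),
               per_label_term(ind$code, 4, path[5], "M2", 0.5),
               tolerance = 1e-15)
  # 2 labels with disjoint neighborhoods: product of the two factors
  lab2 <- c(0, 20)
  expect_equal(
    brute_force_fitness(ind$code, lab2, path[lab2 + 1L], c(1, 1), c(1, 1)),
    factorized_subset(ind$code, lab2, path[lab2 + 1L], c(1, 1), c(1, 1)),
    tolerance = 1e-15)
  expect_error(brute_force_fitness(ind$code, 0:4, path[1:5], rep(1, 5)),
               "4 labels")
})

test_that("expected fitness is the reading-draw average of sampled fitness", {
  # degenerate reading rows: expectation over a point mass = forced draw
  ind <- make_fixture("deterministic_disjoint")
  expect_equal(fitness_expected(ind)$log_f,
               fitness_sampled(ind, assignment = rep(3L, 21))$log_f,
               tolerance = 1e-12)
  # 3-label slice: expectation term-by-term equals the 27-assignment
  # enumeration weighted by the draw probabilities
  set.seed(5)
  assignments <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  for (rep in 1:5) {
    ind <- random_individual()
    labels <- sample(0:20, 3)
    path <- bayes_path(ind$code)[labels + 1L]
    enum <- 0
    for (a in seq_len(nrow(assignments))) {
      j <- assignments[a, ]
      p_j <- ind$reading[cbind(labels + 1L, j)]
      draw_prob <- prod(p_j)
      enum <- enum + draw_prob *
        factorized_subset(ind$code, labels, path, j, p_j)
    }
    exp_terms <- fitness_expected(ind)$terms[labels + 1L]
    expect_equal(prod(exp_terms), enum, tolerance = 1e-12)
  }
})

test_that("fitness reaches 1 exactly on fully-owned M1 neighborhoods", {
  perfect <- make_fixture("m1_perfect_smallL")
  path <- bayes_path(perfect$code)
  expect_identical(unname(path[1:3]), c(0L, 4L, 8L))
  expect_equal(
    brute_force_fitness(perfect$code, 0:2, path[1:3], rep(1, 3), rep(1, 3)),
    1, tolerance = 1e-12)
  expect_equal(fitness_expected(perfect)$terms[1:3], rep(1, 3),
               tolerance = 1e-12)
})

test_that("the C++ population evaluator matches the R reference fitness", {
  tabs <- codonevol:::nb_tables()
  for (s in 1:8) {
    ind <- random_individual(seed = s)
    cpp <- codonevol:::eval_population_cpp(
      array(ind$code, c(64, 21, 1)), array(ind$reading, c(21, 3, 1)), 1L,
      tabs$M1, tabs$M2, tabs$M3, 1L)
    expect_equal(cpp, fitness_expected(ind)$log_f, tolerance = 1e-12)
  }
  # sampled mode with degenerate reading rows (the draw is forced)
  ind <- make_fixture("deterministic_disjoint")
  cpp <- codonevol:::eval_population_cpp(
    array(ind$code, c(64, 21, 1)), array(ind$reading, c(21, 3, 1)), 1L,
    tabs$M1, tabs$M2, tabs$M3, 0L)
  expect_equal(cpp, 21 * log(0.1), tolerance = 1e-12)
})
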