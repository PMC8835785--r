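test_that("configuration validation catches out-of-range parameters", {
  expect_s3_class(evolution_config(population_size = 2, generations = 0),
                  "evolution_config")
  expect_error(evolution_config(population_size = 1), "population_size")
  expect_error(evolution_config(mutation_row_prob = 1.2), "mutation_row_prob")
  expect_error(evolution_config(elite_count = 10, population_size = 10),
               "elite_count")
  expect_error(evolution_config(tournament_size = 0), "tournament_size")
  expect_error(evolution_config(mutation_concentration = 0),
               "mutation_concentration")
})

test_that("mutation is a seeded no-op at probability zero and shrinks with kappa", {
  ind <- random_individual(seed = 1)
  expect_identical(mutate_individual(ind, 0, 0, 200, seed = 2)$code, ind$code)
  # huge concentration: resampled rows stay within 1e-3 total variation
  m <- mutate_individual(ind, 1, 1, 1e10, seed = 3)
  tv_code <- vapply(1:64, function(r) tv_dist(m$code[r, ], ind$code[r, ]),
                    numeric(1))
  tv_read <- vapply(1:21, function(r) tv_dist(m$reading[r, ], ind$reading[r, ]),
                    numeric(1))
  expect_lt(max(tv_code, tv_read), 1e-3)
})

test_that("mutation is deterministic under seed and preserves the simplex", {
  ind <- random_individual(seed = 4)
  expect_identical(mutate_individual(ind, 0.5, 0.5, 50, seed = 9),
                   mutate_individual(ind, 0.5, 0.5, 50, seed = 9))
  set.seed(10)
  for (trial in 1:1000) {
    m <- mutate_individual(ind, 0.1, 0.1, 20)
    expect_true(all(abs(rowSums(m$code) - 1) < 1e-9))
    expect_true(all(abs(rowSums(m$reading) - 1) < 1e-9))
    expect_true(all(m$code >= 0) && all(m$reading >= 0))
  }
})

test_that("tournament selection reproduces the closed-form win probability", {
  # one finite-fitness individual among n = 10, tournament size 2: each slot
  # copies it with probability 1 - (1 - 1/n)^2
  n <- 10
  logf <- rep(-Inf, n)
  logf[4] <- -1
  set.seed(12)
  slots <- 0L
  total <- 0L
  for (rep in 1:250) {
    sel <- select_indices(logf, tournament_size = 2, elite_count = 0)
    slots <- slots + sum(sel$offspring == 4L)
    total <- total + length(sel$offspring)
  }
  p_hat <- slots / total
  p_closed <- 1 - (1 - 1 / n)^2
  expect_equal(p_hat, p_closed, tolerance = 0.05)
})

test_that("selection edge cases: drift, elitism guarantee, all-infinite fallback", {
  set.seed(13)
  logf <- c(-5, -1, -20, -3)
  # tournament size 1 is uniform drift: all indices appear over many draws
  drawn <- table(unlist(replicate(300, {
    select_indices(logf, tournament_size = 1, elite_count = 0)$offspring
  }, simplify = FALSE)))
  expect_setequal(names(drawn), as.character(1:4))
  expect_equal(as.vector(drawn) / sum(drawn), rep(0.25, 4), tolerance = 0.1)
  # elitism: the best index always fills the elite slots
  sel <- select_indices(logf, tournament_size = 2, elite_count = 3)
  expect_identical(sel$elite, c(2L, 4L, 1L))  # sorted by fitness
  expect_false(sel$fallback)
  # all -Inf: uniform fallback, flagged
  sel <- select_indices(rep(-Inf, 4), tournament_size = 2, elite_count = 1)
  expect_true(sel$fallback)
  expect_length(sel$offspring, 3L)
})

test_that("zero generations yields a single record of the initial population", {
  res <- evolve_code(evolution_config(population_size = 10, generations = 0,
                                      seed = 5))
  expect_identical(nrow(res$trajectory), 1L)
  expect_identical(res$trajectory$generation, 0)
  expect_equal(res$best$log_fitness, max(res$final$log_fitness))
  expect_identical(res$best_ever$generation, 0L)
})

test_that("runs are reproducible and keep every individual on the simplex", {
  cfg <- evolution_config(population_size = 12, generations = 120, seed = 6,
                          record_every = 30)
  a <- evolve_code(cfg)
  b <- evolve_code(cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$best$code, b$best$code)
  expect_identical(dim(a$final$code), c(64L, 21L, 12L))
  for (k in 1:12) {
    expect_true(all(abs(rowSums(a$final$code[, , k]) - 1) < 1e-9))
    expect_true(all(abs(rowSums(a$final$reading[, , k]) - 1) < 1e-9))
  }
})

test_that("elitist expected-mode best fitness is non-decreasing", {
  res <- evolve_code(evolution_config(population_size = 30, generations = 400,
                                      seed = 7, fitness_mode = "expected",
                                      record_every = 20))
  best <- res$trajectory$best_log_fitness
  expect_true(all(diff(best) >= -1e-12))
})

test_that("selection drives fitness up and both entropies down", {
  res <- evolve_code(evolution_config(population_size = 60,
                                      generations = 1500, seed = 8,
                                      record_every = 100))
  tr <- res$trajectory
  first <- tr[1, ]
  last <- tr[nrow(tr), ]
  expect_gt(last$mean_log_fitness, first$mean_log_fitness)
  expect_lt(last$mean_Hc, first$mean_Hc)
  expect_lt(last$mean_Hr, first$mean_Hr)
  # reading entropy collapses faster than code entropy (relative to start)
  expect_lt(last$mean_Hr / first$mean_Hr, last$mean_Hc / first$mean_Hc)
})
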