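# The generational loop: Dirichlet row mutation, tournament selection with
# elitism, trajectory recording.

MUTATION_EPS <- 0.01  # floor added to every Dirichlet concentration

#' Evolution run configuration
#'
#' Collects and validates the parameters of an evolutionary run. Defaults
#' reproduce the full study protocol (1000 coding systems, 100,000
#' generations); scaled-down runs pass smaller `population_size` and
#' `generations`.
#'
#' @param population_size Number of coding systems (>= 2). Default 1000.
#' @param generations Number of generations (>= 0). Default 100000.
#' @param seed Integer master seed; every source of randomness in the run
#'   derives from it.
#' @param mutation_row_prob Per-generation probability that a given code row
#'   is resampled. Default 0.02.
#' @param mutation_reading_prob Same for reading rows. Default 0.2 — reading
#'   rows need frequent re-testing against the evolving code for the
#'   homogeneous wobble-like end state to be reached.
#' @param mutation_concentration Dirichlet concentration scale kappa: a hit
#'   row is resampled from `Dirichlet(kappa * row + 0.01)`. Larger values
#'   perturb less; large values are absorbing at simplex vertices and freeze
#'   the reading system (see the package vignette). Default 0.2, the
#'   bold-resampling regime.
#' @param tournament_size Individuals drawn (with replacement) per selection
#'   tournament; 1 gives neutral drift. Default 6.
#' @param elite_count Top individuals copied unchanged (no mutation) into the
#'   next generation. Default 1.
#' @param fitness_mode `"sampled"` (one reading draw per individual per
#'   generation; the study's regime) or `"expected"` (deterministic).
#' @param record_every Generations between trajectory records. Default 100.
#' @return Object of class `"evolution_config"` (a validated named list).
#' @export
#' @examples
#' cfg <- evolution_config(population_size = 200, generations = 20000, seed = 1)
evolution_config <- function(population_size = 1000L,
                             generations = 100000L,
                             seed = 1L,
                             mutation_row_prob = 0.02,
                             mutation_reading_prob = 0.2,
                             mutation_concentration = 0.2,
                             tournament_size = 6L,
                             elite_count = 1L,
                             fitness_mode = c("sampled", "expected"),
                             record_every = 100L) {
  cfg <- list(
    population_size = as.integer(population_size),
    generations = as.integer(generations),
    seed = as.integer(seed),
    mutation_row_prob = as.numeric(mutation_row_prob),
    mutation_reading_prob = as.numeric(mutation_reading_prob),
    mutation_concentration = as.numeric(mutation_concentration),
    tournament_size = as.integer(tournament_size),
    elite_count = as.integer(elite_count),
    fitness_mode = match.arg(fitness_mode),
    record_every = as.integer(record_every)
  )
  stopifnot(
    "population_size must be >= 2" = cfg$population_size >= 2L,
    "generations must be >= 0" = cfg$generations >= 0L,
    "mutation_row_prob must be in [0, 1]" =
      cfg$mutation_row_prob >= 0 && cfg$mutation_row_prob <= 1,
    "mutation_reading_prob must be in [0, 1]" =
      cfg$mutation_reading_prob >= 0 && cfg$mutation_reading_prob <= 1,
    "mutation_concentration must be > 0" = cfg$mutation_concentration > 0,
    "tournament_size must be >= 1" = cfg$tournament_size >= 1L,
    "elite_count must be in [0, population_size)" =
      cfg$elite_count >= 0L && cfg$elite_count < cfg$population_size,
    "record_every must be >= 1" = cfg$record_every >= 1L
  )
  structure(cfg, class = "evolution_config")
}

#' @export
print.evolution_config <- function(x, ...) {
  cat("Evolution configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Tournament selection with elitism
#'
#' Picks the individuals forming the next generation. The `elite_count`
#' individuals with highest log-fitness (ties resolved toward lower index)
#' fill the first slots unchanged; each remaining slot is filled by drawing
#' `tournament_size` individuals uniformly with replacement and copying the
#' one with the highest log-fitness, ties broken uniformly at random. If
#' every individual has `-Inf` log-fitness, offspring slots fall back to
#' uniform random copying and the result is flagged.
#'
#' @param log_fitness Numeric vector of log-fitness values (may contain
#'   `-Inf`), one per individual.
#' @param tournament_size Contestants per tournament (>= 1); 1 gives neutral
#'   drift.
#' @param elite_count Number of elite slots (`0 <= elite_count < n`).
#' @return List with `elite` (indices of elite copies), `offspring` (indices
#'   filling the remaining slots, to be mutated) and `fallback` (`TRUE` when
#'   uniform fallback was used).
#' @export
select_indices <- function(log_fitness, tournament_size = 2L, elite_count = 1L) {
  n <- length(log_fitness)
  tournament_size <- as.integer(tournament_size)
  elite_count <- as.integer(elite_count)
  stopifnot(n >= 2L, tournament_size >= 1L,
            elite_count >= 0L, elite_count < n,
            !anyNA(log_fitness))
  elite <- if (elite_count > 0L) {
    order(log_fitness, decreasing = TRUE)[seq_len(elite_count)]
  } else integer(0)
  n_off <- n - elite_count
  fallback <- all(!is.finite(log_fitness))
  if (fallback) {
    offspring <- sample.int(n, n_off, replace = TRUE)
  } else {
    draws <- matrix(sample.int(n, n_off * tournament_size, replace = TRUE),
                    nrow = n_off)
    if (tournament_size == 1L) {
      offspring <- draws[, 1L]
    } else {
      vals <- matrix(log_fitness[draws], nrow = n_off)
      vals[!is.finite(vals)] <- -.Machine$double.xmax  # max.col dislikes -Inf
      win <- max.col(vals, ties.method = "random")
      offspring <- draws[cbind(seq_len(n_off), win)]
    }
  }
  list(elite = elite, offspring = offspring, fallback = fallback)
}

#' Mutate a coding system
#'
#' Independently, each of the 64 code rows is resampled with probability
#' `row_prob` and each of the 21 reading rows with probability
#' `reading_prob`, from a Dirichlet centered on the current row:
#' `Dirichlet(kappa * row + 0.01)`. The 0.01 floor keeps the support full so
#' no assignment is ever permanently lost. Untouched rows are copied
#' verbatim.
#'
#' @param ind A `coding_system`.
#' @param row_prob Per-row mutation probability for the code matrix.
#' @param reading_prob Per-row mutation probability for the reading matrix.
#' @param concentration Dirichlet concentration scale kappa (> 0); larger
#'   values keep the resampled row closer to the original.
#' @param seed Optional seed (caller's RNG state preserved).
#' @return The mutated `coding_system`.
#' @export
mutate_individual <- function(ind, row_prob = 0.02, reading_prob = 0.02,
                              concentration = 200, seed = NULL) {
  ind <- as_individual(ind)
  stopifnot(row_prob >= 0, row_prob <= 1, reading_prob >= 0,
            reading_prob <= 1, concentration > 0)
  with_seed(seed, {
    out <- mutate_population_cpp(
      array(ind$code, dim = c(N_CODONS, N_LABELS, 1L)),
      array(ind$reading, dim = c(N_LABELS, N_MODELS, 1L)),
      1L, row_prob, reading_prob, concentration, MUTATION_EPS, 0L)
    new_individual(matrix(out$code, N_CODONS, N_LABELS),
                   matrix(out$reading, N_LABELS, N_MODELS))
  })
}

#' Run the evolutionary simulation
#'
#' Initializes `population_size` random coding systems (flat-Dirichlet rows)
#' and iterates the generational loop: evaluate the coding-strength fitness
#' of every individual (in `"sampled"` mode with a fresh reading draw per
#' individual each generation, elites included), record the trajectory,
#' select (tournament + elitism), and mutate the non-elite offspring. Fully
#' reproducible from the configuration's seed.
#'
#' @param config An [evolution_config()]; alternatively arguments passed on
#'   to [evolution_config()] via `...`.
#' @param ... Used only when `config` is missing.
#' @return Object of class `"code_evolution"`: list with
#'   \describe{
#'     \item{trajectory}{data.frame with one row per recorded generation:
#'       `generation`, `mean_log_fitness`, `best_log_fitness`, `mean_Hc`,
#'       `mean_Hr`, `expected_labels_M1/M2/M3` (population means).}
#'     \item{best}{the highest final-generation-fitness individual of the
#'       final population, a `coding_system` with `log_fitness` set.}
#'     \item{best_ever}{the individual with the highest log-fitness observed
#'       in any generation, with `log_fitness` and `generation`.}
#'     \item{final}{final population as arrays `code` (64 x 21 x n),
#'       `reading` (21 x 3 x n) and `log_fitness` (length n).}
#'     \item{config}{the effective configuration.}
#'     \item{fallback_generations}{generations where selection fell back to
#'       uniform copying (all-infinite fitness), normally empty.}
#'   }
#' @export
#' @examples
#' res <- evolve_code(evolution_config(population_size = 20,
#'                                     generations = 50, seed = 1))
#' res$trajectory[nrow(res$trajectory), ]
evolve_code <- function(config, ...) {
  if (missing(config)) config <- evolution_config(...)
  stopifnot(inherits(config, "evolution_config"))
  n <- config$population_size
  gens <- config$generations
  mode <- if (config$fitness_mode == "sampled") 0L else 1L
  tabs <- nb_tables()

  old_seed_exists <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (old_seed_exists) old_seed <- get(".Random.seed", globalenv())
  on.exit(if (old_seed_exists) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  code_pop <- array(0, dim = c(N_CODONS, N_LABELS, n))
  reading_pop <- array(0, dim = c(N_LABELS, N_MODELS, n))
  for (k in seq_len(n)) {
    code_pop[, , k] <- rdirichlet_rows(N_CODONS, N_LABELS)
    reading_pop[, , k] <- rdirichlet_rows(N_LABELS, N_MODELS)
  }

  rec_gens <- unique(c(seq(0L, gens, by = config$record_every), gens))
  traj <- matrix(NA_real_, nrow = length(rec_gens), ncol = 8L)
  colnames(traj) <- c("generation", "mean_log_fitness", "best_log_fitness",
                      "mean_Hc", "mean_Hr", "expected_labels_M1",
                      "expected_labels_M2", "expected_labels_M3")
  ri <- 1L
  best_ever <- list(log_fitness = -Inf)
  fallback_gens <- integer(0)

  for (gen in 0:gens) {
    logf <- eval_population_cpp(code_pop, reading_pop, n,
                                tabs$M1, tabs$M2, tabs$M3, mode)
    gen_best <- which.max(logf)
    if (logf[gen_best] > best_ever$log_fitness) {
      best_ever <- list(code = code_pop[, , gen_best],
                        reading = reading_pop[, , gen_best],
                        log_fitness = logf[gen_best], generation = gen)
    }
    if (gen %% config$record_every == 0L || gen == gens) {
      traj[ri, ] <- c(
        gen, mean(logf), max(logf),
        pop_mean_entropy(code_pop), pop_mean_entropy(reading_pop),
        rowSums(colSums(reading_pop)) / n)
      ri <- ri + 1L
    }
    if (gen < gens) {
      sel <- select_indices(logf, config$tournament_size, config$elite_count)
      if (sel$fallback) fallback_gens <- c(fallback_gens, gen)
      idx <- c(sel$elite, sel$offspring)
      mut <- next_generation_cpp(code_pop, reading_pop, n, idx,
                                 config$mutation_row_prob,
                                 config$mutation_reading_prob,
                                 config$mutation_concentration,
                                 MUTATION_EPS, length(sel$elite))
      code_pop <- mut$code
      reading_pop <- mut$reading
    }
  }

  final_best <- which.max(logf)
  best <- new_individual(as.matrix(code_pop[, , final_best]),
                         as.matrix(reading_pop[, , final_best]),
                         logf[final_best])
  best_ever_ind <- new_individual(as.matrix(best_ever$code),
                                  as.matrix(best_ever$reading),
                                  best_ever$log_fitness)
  best_ever_ind$generation <- best_ever$generation

  structure(list(
    trajectory = as.data.frame(traj),
    best = best,
    best_ever = best_ever_ind,
    final = list(code = code_pop, reading = reading_pop, log_fitness = logf),
    config = config,
    fallback_generations = fallback_gens
  ), class = "code_evolution")
}

# mean (over individuals) of the row-entropy sum of a (r, c, n) array
pop_mean_entropy <- function(arr) {
  plogp_sum(arr) / dim(arr)[3L]
}
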