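# TSV/JSON serialization, run configuration, run artifacts, analysis of
# saved matrices, and deterministic test fixtures.

SIG_DIGITS <- 12L  # significant digits in TSV output; round-trips stably

fmt_num <- function(x) formatC(x, digits = SIG_DIGITS, format = "g")

#' Write / read a code matrix as TSV
#'
#' Plain TSV with the codon triplet in the first column and one column per
#' label (`label_0` ... `label_20`), probabilities at 12 significant digits.
#' Reading validates shape and row sums and reorders rows into codon-index
#' order, so write/read round-trips to 12 significant digits.
#'
#' @param code 64 x 21 row-stochastic code matrix.
#' @param path File path.
#' @return `write_code_matrix()`: `path`, invisibly. `read_code_matrix()`:
#'   the validated matrix.
#' @export
write_code_matrix <- function(code, path) {
  code <- validate_code_matrix(code)
  df <- data.frame(codon = .CODONS, apply(code, 2L, fmt_num),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_code_matrix
#' @export
read_code_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != N_LABELS + 1L || names(df)[1L] != "codon") {
    stop("malformed code TSV: expected columns codon, label_0..label_20",
         call. = FALSE)
  }
  idx <- codon_index(df$codon)
  if (anyDuplicated(idx) || length(idx) != N_CODONS) {
    stop("malformed code TSV: need each of the 64 codons exactly once",
         call. = FALSE)
  }
  m <- as.matrix(df[order(idx), -1L])
  validate_code_matrix(unname(m))
}

#' Write / read a reading matrix as TSV
#'
#' Plain TSV with the label id (0-20) in the first column and columns `M1`,
#' `M2`, `M3`, probabilities at 12 significant digits.
#'
#' @param reading 21 x 3 row-stochastic reading matrix.
#' @param path File path.
#' @return `write_reading_matrix()`: `path`, invisibly.
#'   `read_reading_matrix()`: the validated matrix.
#' @export
write_reading_matrix <- function(reading, path) {
  reading <- validate_reading_matrix(reading)
  df <- data.frame(label = 0:(N_LABELS - 1L), apply(reading, 2L, fmt_num),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reading_matrix
#' @export
read_reading_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != N_MODELS + 1L || names(df)[1L] != "label" ||
      !identical(sort(as.integer(df$label)), 0:(N_LABELS - 1L))) {
    stop("malformed reading TSV: expected columns label, M1, M2, M3 and ",
         "labels 0..20", call. = FALSE)
  }
  m <- as.matrix(df[order(df$label), -1L])
  validate_reading_matrix(unname(m))
}

run_config_defaults <- function() {
  c(unclass(evolution_config()),
    list(block_threshold = 0.8, output_directory = "."))
}

#' Read a run configuration file
#'
#' A flat YAML file whose keys are the [evolution_config()] fields plus
#' `block_threshold` (coding-probability cutoff for block extraction, default
#' 0.8) and `output_directory`. Missing keys take the documented defaults;
#' unknown keys are rejected.
#'
#' @param path Path to a YAML file, or a named list of overrides.
#' @return List with `evolution` (an `evolution_config`), `block_threshold`
#'   and `output_directory`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else as.list(path)
  if (is.null(raw)) raw <- list()
  defaults <- run_config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, raw)
  evo <- do.call(evolution_config,
                 cfg[setdiff(names(cfg), c("block_threshold",
                                           "output_directory"))])
  stopifnot("block_threshold must be in (0, 1]" =
              cfg$block_threshold > 0 && cfg$block_threshold <= 1)
  list(evolution = evo, block_threshold = cfg$block_threshold,
       output_directory = cfg$output_directory)
}

blocks_to_list <- function(blocks) {
  lapply(blocks$blocks, as.list)
}

hist_to_list <- function(h) as.list(setNames(as.integer(h), names(h)))

#' Run a simulation and write its artifacts
#'
#' Runs [evolve_code()] under the supplied configuration and writes, into
#' `out_dir`: `trajectory.tsv` (one row per recorded generation),
#' `best_code.tsv` / `best_reading.tsv` (the best final-generation
#' individual), `summary.json` (config echo, final metrics, block structure,
#' block-size histogram, M1 consistency) and `run.log` (timestamped
#' milestones). TSV and JSON artifacts are byte-identical across runs with
#' the same configuration and seed.
#'
#' @param config A YAML path, named list or `evolution_config` (the latter
#'   uses `block_threshold` 0.8).
#' @param out_dir Output directory, created if needed; default the
#'   configuration's `output_directory`.
#' @param quiet Suppress console milestones. Default `TRUE`.
#' @return The `code_evolution` result, invisibly, with `$artifacts` naming
#'   the files written.
#' @export
simulate_run <- function(config, out_dir = NULL, quiet = TRUE) {
  rc <- if (inherits(config, "evolution_config")) {
    list(evolution = config, block_threshold = 0.8, output_directory = ".")
  } else {
    read_run_config(config)
  }
  if (is.null(out_dir)) out_dir <- rc$output_directory
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  cat("", file = log_path)  # truncate
  log_line("run start: population %d, generations %d, seed %d, %s fitness",
           rc$evolution$population_size, rc$evolution$generations,
           rc$evolution$seed, rc$evolution$fitness_mode)

  res <- evolve_code(rc$evolution)
  tr <- res$trajectory
  for (i in seq_len(nrow(tr))) {
    log_line("generation %d: mean ln F %.4f, best ln F %.4f",
             tr$generation[i], tr$mean_log_fitness[i], tr$best_log_fitness[i])
  }

  traj_path <- file.path(out_dir, "trajectory.tsv")
  tr_out <- tr
  tr_out[-1L] <- lapply(tr_out[-1L], fmt_num)
  utils::write.table(tr_out, traj_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  code_path <- write_code_matrix(res$best$code,
                                 file.path(out_dir, "best_code.tsv"))
  reading_path <- write_reading_matrix(res$best$reading,
                                       file.path(out_dir, "best_reading.tsv"))

  blocks <- extract_blocks(res$best$code, rc$block_threshold)
  last <- tr[nrow(tr), ]
  summary_obj <- list(
    config = c(unclass(rc$evolution),
               list(block_threshold = rc$block_threshold)),
    seed = rc$evolution$seed,
    final = list(
      mean_log_fitness = last$mean_log_fitness,
      best_log_fitness = last$best_log_fitness,
      mean_Hc = last$mean_Hc,
      mean_Hr = last$mean_Hr,
      expected_labels = list(M1 = last$expected_labels_M1,
                             M2 = last$expected_labels_M2,
                             M3 = last$expected_labels_M3)
    ),
    best = list(
      log_fitness = res$best$log_fitness,
      Hc = code_entropy(res$best$code),
      Hr = reading_entropy(res$best$reading),
      expected_labels = as.list(expected_label_counts(res$best$reading)),
      block_threshold = rc$block_threshold,
      blocks = blocks_to_list(blocks),
      block_histogram = hist_to_list(block_size_distribution(blocks)),
      m1_consistency = m1_consistency(blocks)
    )
  )
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_obj, summary_path, auto_unbox = TRUE,
                       digits = I(SIG_DIGITS), pretty = TRUE)
  log_line("run end: artifacts in %s", normalizePath(out_dir))

  res$artifacts <- c(trajectory = traj_path, code = code_path,
                     reading = reading_path, summary = summary_path,
                     log = log_path)
  invisible(res)
}

#' Analyze a saved coding system
#'
#' Recomputes every observable for a code/reading matrix pair: entropies,
#' expected label counts, codon blocks with histogram and M1 consistency,
#' the expected-mode log-fitness, and (when `seed` is given) one
#' sampled-mode log-fitness.
#'
#' @param code A 64 x 21 matrix or path to a code TSV.
#' @param reading A 21 x 3 matrix or path to a reading TSV.
#' @param threshold Block-extraction cutoff, default 0.8.
#' @param seed Optional seed for the sampled-fitness reading draw.
#' @return Named list of observables (see Details); serialize with
#'   [jsonlite::toJSON()] for the CLI report.
#' @export
analyze_code <- function(code, reading, threshold = 0.8, seed = NULL) {
  if (is.character(code)) code <- read_code_matrix(code)
  if (is.character(reading)) reading <- read_reading_matrix(reading)
  ind <- new_individual(validate_code_matrix(code),
                        validate_reading_matrix(reading))
  blocks <- extract_blocks(ind$code, threshold)
  out <- list(
    Hc = code_entropy(ind$code),
    Hr = reading_entropy(ind$reading),
    expected_labels = as.list(expected_label_counts(ind$reading)),
    block_threshold = threshold,
    blocks = blocks_to_list(blocks),
    block_histogram = hist_to_list(block_size_distribution(blocks)),
    m1_consistency = m1_consistency(blocks),
    log_fitness_expected = fitness_expected(ind)$log_f
  )
  if (!is.null(seed)) {
    out$log_fitness_sampled <- fitness_sampled(ind, seed = seed)$log_f
    out$sampled_seed <- seed
  }
  out
}

#' Deterministic test fixtures
#'
#' Small constructed coding systems with known observables:
#' \describe{
#'   \item{`uniform`}{every code entry 1/21, every reading entry 1/3 —
#'     maximum entropies `64 ln 21` and `21 ln 3`.}
#'   \item{`deterministic_disjoint`}{codon `i` encodes label `i` with
#'     probability 1 for labels 0-20; the remaining codons are assigned (with
#'     probability 1) to a label whose Bayes codon is at Hamming distance of
#'     at least 2, so no Bayes-path neighborhood picks up stray mass. Reading
#'     fixed on M3. `Hc = 0` and the sampled fitness is exactly `0.1^21`.}
#'   \item{`m1_perfect_smallL`}{labels 0, 1, 2 each own a full M1 codon
#'     family with probability 1 and read through M1 with probability 1 —
#'     their per-label factors are exactly 1. Remaining codons spread
#'     uniformly over the remaining labels.}
#'   \item{`random`}{a seeded [random_individual()].}
#' }
#'
#' @param kind One of `"uniform"`, `"deterministic_disjoint"`,
#'   `"m1_perfect_smallL"`, `"random"`.
#' @param seed Seed for `kind = "random"` (ignored otherwise). Default 1.
#' @return A `coding_system`.
#' @export
#' @examples
#' code_entropy(make_fixture("deterministic_disjoint")$code)  # 0
make_fixture <- function(kind = c("uniform", "deterministic_disjoint",
                                  "m1_perfect_smallL", "random"),
                         seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    uniform = new_individual(
      matrix(1 / N_LABELS, N_CODONS, N_LABELS),
      matrix(1 / N_MODELS, N_LABELS, N_MODELS)),
    deterministic_disjoint = {
      code <- matrix(0, N_CODONS, N_LABELS)
      code[cbind(1:21, 1:21)] <- 1
      # codons 21..63: all mass on label 0 unless within one substitution of
      # codon AAA (label 0's Bayes codon), in which case label 1; keeps every
      # Bayes-path M3 neighborhood sum at exactly 1
      near0 <- codon_index(codon_neighborhood("AAA", "M3"))
      for (c in 21:63) {
        code[c + 1L, if (c %in% near0) 2L else 1L] <- 1
      }
      reading <- matrix(0, N_LABELS, N_MODELS)
      reading[, 3L] <- 1
      new_individual(code, reading)
    },
    m1_perfect_smallL = {
      code <- matrix(0, N_CODONS, N_LABELS)
      for (l in 0:2) code[(4L * l + 1L):(4L * l + 4L), l + 1L] <- 1
      code[13:64, 4:21] <- 1 / 18
      reading <- matrix(1 / N_MODELS, N_LABELS, N_MODELS)
      reading[1:3, ] <- rep(c(1, 0, 0), each = 3)
      new_individual(code, reading)
    },
    random = random_individual(seed = seed)
  )
}
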