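#' @export
print.code_evolution <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  cat(sprintf("Genetic code evolution: %d individuals, %d generations (%s fitness)\n",
              x$config$population_size, x$config$generations,
              x$config$fitness_mode))
  cat(sprintf("  seed %d; %d trajectory records\n", x$config$seed, nrow(tr)))
  cat(sprintf("  final best ln F = %.3f (mean %.3f)\n",
              last$best_log_fitness, last$mean_log_fitness))
  cat(sprintf("  final mean Hc = %.3f nats, mean Hr = %.3f nats\n",
              last$mean_Hc, last$mean_Hr))
  cat(sprintf("  expected labels per reading type: M1 %.2f, M2 %.2f, M3 %.2f\n",
              last$expected_labels_M1, last$expected_labels_M2,
              last$expected_labels_M3))
  invisible(x)
}

#' Summarize an evolutionary run
#'
#' Start/end trajectory values plus the block structure of the best
#' final-generation individual.
#'
#' @param object A `code_evolution` result.
#' @param block_threshold Coding-probability cutoff for block extraction.
#' @param ... Unused.
#' @return Object of class `"summary.code_evolution"`: a list with `initial`
#'   and `final` trajectory rows, the best individual's entropies, block
#'   structure, block-size histogram and M1-consistency fraction.
#' @export
summary.code_evolution <- function(object, block_threshold = 0.8, ...) {
  tr <- object$trajectory
  blocks <- extract_blocks(object$best$code, block_threshold)
  out <- list(
    config = object$config,
    initial = tr[1L, ],
    final = tr[nrow(tr), ],
    best_log_fitness = object$best$log_fitness,
    best_Hc = code_entropy(object$best$code),
    best_Hr = reading_entropy(object$best$reading),
    best_label_counts = expected_label_counts(object$best$reading),
    blocks = blocks,
    block_histogram = block_size_distribution(blocks),
    m1_consistency = m1_consistency(blocks),
    fallback_generations = object$fallback_generations
  )
  class(out) <- "summary.code_evolution"
  out
}

#' @export
print.summary.code_evolution <- function(x, ...) {
  cat(sprintf("Run of %d generations, population %d, seed %d (%s fitness)\n",
              x$config$generations, x$config$population_size, x$config$seed,
              x$config$fitness_mode))
  cat(sprintf("  ln F (best): %.3f -> %.3f\n",
              x$initial$best_log_fitness, x$final$best_log_fitness))
  cat(sprintf("  mean Hc: %.2f -> %.2f nats; mean Hr: %.2f -> %.2f nats\n",
              x$initial$mean_Hc, x$final$mean_Hc,
              x$initial$mean_Hr, x$final$mean_Hr))
  cat(sprintf("  final expected labels: M1 %.2f, M2 %.2f, M3 %.2f\n",
              x$final$expected_labels_M1, x$final$expected_labels_M2,
              x$final$expected_labels_M3))
  cat(sprintf("  best code: Hc = %.3f, Hr = %.3f, ln F = %.3f\n",
              x$best_Hc, x$best_Hr, x$best_log_fitness))
  hist <- x$block_histogram
  cat(sprintf("  blocks (threshold %g): sizes {%s} with counts {%s}; M1-consistent %.0f%%\n",
              x$blocks$threshold, paste(names(hist), collapse = ", "),
              paste(hist, collapse = ", "), 100 * x$m1_consistency))
  if (length(x$fallback_generations)) {
    cat("  NOTE: uniform-selection fallback at generation(s) ",
        paste(x$fallback_generations, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot an evolutionary trajectory
#'
#' Four base-graphics panels: best/mean log-fitness, mean code entropy Hc,
#' mean reading entropy Hr, and expected labels per reading type, all
#' against generation.
#'
#' @param x A `code_evolution` result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.code_evolution <- function(x, ...) {
  tr <- x$trajectory
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  finite <- is.finite(tr$mean_log_fitness)
  graphics::plot(tr$generation, tr$best_log_fitness, type = "l",
                 xlab = "generation", ylab = "ln F", main = "Fitness", ...)
  graphics::lines(tr$generation[finite], tr$mean_log_fitness[finite],
                  lty = 2)
  graphics::legend("bottomright", c("best", "mean"), lty = 1:2, bty = "n")
  graphics::plot(tr$generation, tr$mean_Hc, type = "l", xlab = "generation",
                 ylab = "mean Hc (nats)", main = "Code entropy", ...)
  graphics::plot(tr$generation, tr$mean_Hr, type = "l", xlab = "generation",
                 ylab = "mean Hr (nats)", main = "Reading entropy", ...)
  graphics::matplot(tr$generation,
                    tr[, c("expected_labels_M1", "expected_labels_M2",
                           "expected_labels_M3")],
                    type = "l", lty = 1, col = c("black", "red", "blue"),
                    xlab = "generation", ylab = "expected labels",
                    main = "Reading types")
  graphics::legend("right", c("M1", "M2", "M3"), lty = 1,
                   col = c("black", "red", "blue"), bty = "n")
  invisible(x)
}
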