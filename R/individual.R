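# Coding-system individuals: a 64 x 21 code matrix plus a 21 x 3 reading
# matrix, both row-stochastic.

N_CODONS <- 64L
N_LABELS <- 21L
N_MODELS <- 3L
ROW_TOL <- 1e-9

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One flat-Dirichlet (all concentrations `alpha`) draw per row of an n x k
# matrix, via independent gammas normalized per row.
rdirichlet_rows <- function(n, k, alpha = 1) {
  g <- matrix(rgamma(n * k, shape = alpha, rate = 1), nrow = n)
  s <- rowSums(g)
  zero <- s == 0  # only reachable for very small shapes
  if (any(zero)) {
    g[zero, ] <- 1
    s[zero] <- k
  }
  g / s
}

label_names <- function() paste0("label_", 0:(N_LABELS - 1L))
model_names <- function() c("M1", "M2", "M3")

#' Draw a random coding system
#'
#' Initializes one individual: every code row (64 codons over 21 labels) and
#' every reading row (21 labels over M1/M2/M3) is drawn from the flat
#' Dirichlet — the maximum-entropy distribution on the simplex, matching the
#' assumption that primordial coding systems were highly ambiguous.
#'
#' @param seed Optional integer seed; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return An object of class `"coding_system"`: a list with elements `code`
#'   (64 x 21 row-stochastic matrix, rownames the codon triplets, colnames
#'   `label_0` ... `label_20`) and `reading` (21 x 3 row-stochastic matrix,
#'   rownames `label_0` ... `label_20`, colnames `M1`, `M2`, `M3`).
#' @export
#' @examples
#' ind <- random_individual(seed = 1)
#' range(rowSums(ind$code))  # all rows sum to 1
random_individual <- function(seed = NULL) {
  with_seed(seed, {
    code <- rdirichlet_rows(N_CODONS, N_LABELS)
    reading <- rdirichlet_rows(N_LABELS, N_MODELS)
    new_individual(code, reading)
  })
}

new_individual <- function(code, reading, log_fitness = NULL) {
  dimnames(code) <- list(.CODONS, label_names())
  dimnames(reading) <- list(label_names(), model_names())
  structure(list(code = code, reading = reading, log_fitness = log_fitness),
            class = "coding_system")
}

#' Validate a code matrix
#'
#' Checks that `code` is a 64 x 21 numeric matrix with non-negative entries
#' and rows summing to 1 within `1e-9`.
#'
#' @param code Matrix to check.
#' @return `code`, invisibly, with codon/label dimnames attached.
#' @export
validate_code_matrix <- function(code) {
  if (!is.matrix(code) || !is.numeric(code) ||
      nrow(code) != N_CODONS || ncol(code) != N_LABELS) {
    stop("code matrix must be numeric 64 x 21", call. = FALSE)
  }
  if (any(code < 0)) stop("code matrix has negative entries", call. = FALSE)
  bad <- which(abs(rowSums(code) - 1) > ROW_TOL)
  if (length(bad)) {
    stop("code matrix rows not summing to 1 (tolerance 1e-9): codon(s) ",
         paste(.CODONS[utils::head(bad, 5L)], collapse = ", "), call. = FALSE)
  }
  dimnames(code) <- list(.CODONS, label_names())
  invisible(code)
}

#' Validate a reading matrix
#'
#' Checks that `reading` is a 21 x 3 numeric matrix with non-negative entries
#' and rows summing to 1 within `1e-9`.
#'
#' @param reading Matrix to check.
#' @return `reading`, invisibly, with label/model dimnames attached.
#' @export
validate_reading_matrix <- function(reading) {
  if (!is.matrix(reading) || !is.numeric(reading) ||
      nrow(reading) != N_LABELS || ncol(reading) != N_MODELS) {
    stop("reading matrix must be numeric 21 x 3", call. = FALSE)
  }
  if (any(reading < 0)) stop("reading matrix has negative entries", call. = FALSE)
  bad <- which(abs(rowSums(reading) - 1) > ROW_TOL)
  if (length(bad)) {
    stop("reading matrix rows not summing to 1 (tolerance 1e-9): label(s) ",
         paste(bad - 1L, collapse = ", "), call. = FALSE)
  }
  dimnames(reading) <- list(label_names(), model_names())
  invisible(reading)
}

as_individual <- function(x) {
  if (inherits(x, "coding_system")) return(x)
  if (is.list(x) && !is.null(x$code) && !is.null(x$reading)) {
    return(new_individual(validate_code_matrix(x$code),
                          validate_reading_matrix(x$reading),
                          x$log_fitness))
  }
  stop("expected a coding_system (list with $code and $reading)", call. = FALSE)
}

#' @export
print.coding_system <- function(x, ...) {
  cat("Coding system: 64 x 21 code matrix + 21 x 3 reading matrix\n")
  hc <- code_entropy(x$code)
  hr <- reading_entropy(x$reading)
  cat(sprintf("  code entropy Hc  = %.3f nats (max %.2f)\n", hc,
              N_CODONS * log(N_LABELS)))
  cat(sprintf("  reading entropy Hr = %.3f nats (max %.2f)\n", hr,
              N_LABELS * log(N_MODELS)))
  if (!is.null(x$log_fitness)) {
    cat(sprintf("  cached ln F = %.4f\n", x$log_fitness))
  }
  invisible(x)
}
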