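# Codon indexing and reading-model neighborhoods.
#
# Fixed base order A=0, C=1, G=2, T=3; codon index = 16*b1 + 4*b2 + b3,
# so indices run 0 ("AAA") .. 63 ("TTT") and each run of four consecutive
# indices shares its first two bases (an M1 family).

BASES <- c("A", "C", "G", "T")

#' All 64 codon triplets in index order
#'
#' @return Character vector of length 64; element `i` is the triplet with
#'   codon index `i - 1` under the fixed ordering A, C, G, T and
#'   `index = 16*b1 + 4*b2 + b3`.
#' @export
#' @examples
#' codons()[1]   # "AAA", index 0
#' codons()[64]  # "TTT", index 63
codons <- function() {
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

.CODONS <- local({
  g <- expand.grid(b3 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                   b1 = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
})

#' Convert a codon triplet to its index
#'
#' Maps a 3-base string over `{A, C, G, T}` (case-insensitive, `U` accepted as
#' an alias of `T`) to its codon index in `[0, 63]` using the fixed base order
#' A=0, C=1, G=2, T=3 and `index = 16*b1 + 4*b2 + b3`.
#'
#' @param triplet Character vector of 3-base strings.
#' @return Integer vector of codon indices in `[0, 63]`.
#' @seealso [codon_triplet()] for the inverse.
#' @export
#' @examples
#' codon_index("AAA")  # 0
#' codon_index("GGG")  # 42
#' codon_index("uuu")  # 63 (RNA alphabet accepted)
codon_index <- function(triplet) {
  triplet <- toupper(as.character(triplet))
  triplet <- gsub("U", "T", triplet, fixed = TRUE)
  bad <- nchar(triplet) != 3L | grepl("[^ACGT]", triplet)
  if (any(bad)) {
    stop("invalid codon triplet(s): ",
         paste(unique(triplet[bad]), collapse = ", "),
         " (need 3 bases over A, C, G, T/U)", call. = FALSE)
  }
  b <- matrix(match(unlist(strsplit(triplet, "")), BASES) - 1L,
              ncol = 3L, byrow = TRUE)
  as.integer(16L * b[, 1L] + 4L * b[, 2L] + b[, 3L])
}

#' Convert a codon index to its triplet
#'
#' @param index Integer vector of codon indices in `[0, 63]`.
#' @return Character vector of triplets.
#' @seealso [codon_index()]
#' @export
#' @examples
#' codon_triplet(42)  # "GGG"
codon_triplet <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index) | index < 0L | index > 63L)) {
    stop("codon index must be an integer in [0, 63]", call. = FALSE)
  }
  .CODONS[index + 1L]
}

#' Reading-model neighborhood of a codon
#'
#' The neighborhood of a reference codon under reading mechanism M1, M2 or M3:
#' the reference codon itself plus every codon differing from it at exactly
#' one position among the varied positions of the model. By default M1 varies
#' position 3 only (the wobble-like rule resolved by the canonical GGG
#' example), M2 varies positions 1 and 2, and M3 varies all three positions;
#' sizes are always 4, 7 and 10 (reference included). `m1_position` relocates
#' the single position varied by M1 (M2 then varies the other two).
#'
#' @param codon A codon triplet (string) or codon index in `[0, 63]`.
#' @param model One of `"M1"`, `"M2"`, `"M3"`.
#' @param m1_position Which codon position (1, 2 or 3) M1 varies; default 3.
#' @return Character vector of triplets, reference codon first, the rest in
#'   codon-index order.
#' @export
#' @examples
#' codon_neighborhood("GGG", "M1")  # GGG GGA GGC GGT
#' length(codon_neighborhood("AAA", "M3"))  # 10
codon_neighborhood <- function(codon, model = c("M1", "M2", "M3"),
                               m1_position = 3L) {
  model <- match.arg(model)
  idx <- if (is.character(codon)) codon_index(codon) else as.integer(codon)
  if (length(idx) != 1L) stop("one codon at a time", call. = FALSE)
  if (idx < 0L || idx > 63L) stop("codon index must be in [0, 63]", call. = FALSE)
  m1_position <- as.integer(m1_position)
  if (!m1_position %in% 1:3) stop("m1_position must be 1, 2 or 3", call. = FALSE)
  vary <- switch(model,
                 M1 = m1_position,
                 M2 = setdiff(1:3, m1_position),
                 M3 = 1:3)
  b <- c(idx %/% 16L, (idx %/% 4L) %% 4L, idx %% 4L)
  out <- idx
  for (pos in vary) {
    for (alt in setdiff(0:3, b[pos])) {
      bb <- b
      bb[pos] <- alt
      out <- c(out, 16L * bb[1L] + 4L * bb[2L] + bb[3L])
    }
  }
  codon_triplet(c(idx, sort(setdiff(out, idx))))
}

# 64 x size matrix of 1-based codon row indices, row c+1 = neighborhood of
# codon index c (reference first). Used by the fitness code and the C++ core.
neighborhood_table <- function(model = c("M1", "M2", "M3"), m1_position = 3L) {
  model <- match.arg(model)
  size <- c(M1 = 4L, M2 = 7L, M3 = 10L)[[model]]
  t(vapply(0:63, function(i) {
    codon_index(codon_neighborhood(i, model, m1_position)) + 1L
  }, integer(size)))
}

.nb_cache <- new.env(parent = emptyenv())

nb_tables <- function() {
  if (is.null(.nb_cache$tabs)) {
    .nb_cache$tabs <- list(M1 = neighborhood_table("M1"),
                           M2 = neighborhood_table("M2"),
                           M3 = neighborhood_table("M3"))
  }
  .nb_cache$tabs
}

#' Neighborhood sizes of the three reading models
#'
#' @return Named integer vector `c(M1 = 4, M2 = 7, M3 = 10)` (reference codon
#'   included).
#' @export
neighborhood_sizes <- function() c(M1 = 4L, M2 = 7L, M3 = 10L)
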