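# The standard genetic code (NCBI transl_table = 1), DNA alphabet, and its
# codon-block spectrum.

#' The standard genetic code table
#'
#' The canonical assignment of all 64 DNA codons to the 20 amino acids (three
#' letter codes) and the stop signal (`"Stop"`), NCBI translation table 1.
#'
#' @return Named character vector of length 64; names are codon triplets in
#'   index order, values the encoded item.
#' @export
#' @examples
#' sgc_table()[["ATG"]]  # "Met"
#' names(which(sgc_table() == "Stop"))  # TAA TAG TGA
sgc_table <- function() {
  aa <- c(
    AAA = "Lys", AAC = "Asn", AAG = "Lys", AAT = "Asn",
    ACA = "Thr", ACC = "Thr", ACG = "Thr", ACT = "Thr",
    AGA = "Arg", AGC = "Ser", AGG = "Arg", AGT = "Ser",
    ATA = "Ile", ATC = "Ile", ATG = "Met", ATT = "Ile",
    CAA = "Gln", CAC = "His", CAG = "Gln", CAT = "His",
    CCA = "Pro", CCC = "Pro", CCG = "Pro", CCT = "Pro",
    CGA = "Arg", CGC = "Arg", CGG = "Arg", CGT = "Arg",
    CTA = "Leu", CTC = "Leu", CTG = "Leu", CTT = "Leu",
    GAA = "Glu", GAC = "Asp", GAG = "Glu", GAT = "Asp",
    GCA = "Ala", GCC = "Ala", GCG = "Ala", GCT = "Ala",
    GGA = "Gly", GGC = "Gly", GGG = "Gly", GGT = "Gly",
    GTA = "Val", GTC = "Val", GTG = "Val", GTT = "Val",
    TAA = "Stop", TAC = "Tyr", TAG = "Stop", TAT = "Tyr",
    TCA = "Ser", TCC = "Ser", TCG = "Ser", TCT = "Ser",
    TGA = "Stop", TGC = "Cys", TGG = "Trp", TGT = "Cys",
    TTA = "Leu", TTC = "Phe", TTG = "Leu", TTT = "Phe"
  )
  aa[.CODONS]
}

#' Codon-block spectrum of the standard genetic code
#'
#' Classifies the 21 encoded items of the standard genetic code by the number
#' of codons assigned to them: five amino acids have four-codon blocks, nine
#' have two-codon blocks, two (Met, Trp) a single codon, three (Leu, Ser,
#' Arg) six codons — each six-codon family splitting into a four-codon and a
#' two-codon wobble subgroup — and the two three-codon items are Ile and the
#' stop signal.
#'
#' @return List with `codons_per_item` (named integer vector, 21 items),
#'   `four_codon_aa`, `two_codon_aa`, `one_codon_aa`, `six_codon_aa`
#'   (counts of amino acids per block size), `three_codon_items` (character
#'   vector, one amino acid plus `"Stop"`), `six_codon_subgroups` (for each
#'   six-codon amino acid, its split into third-position subgroup sizes) and
#'   `total_codons` (always 64).
#' @export
#' @examples
#' sgc_block_spectrum()$four_codon_aa  # 5
sgc_block_spectrum <- function() {
  tab <- sgc_table()
  counts <- table(tab)
  counts_aa <- counts[names(counts) != "Stop"]
  items3 <- names(counts)[counts == 3]
  items3 <- c(setdiff(items3, "Stop"), intersect(items3, "Stop"))
  six <- names(counts_aa)[counts_aa == 6]
  subgroups <- lapply(six, function(a) {
    cods <- names(tab)[tab == a]
    sort(as.integer(table(substr(cods, 1L, 2L))), decreasing = TRUE)
  })
  names(subgroups) <- six
  list(
    codons_per_item = setNames(as.integer(counts), names(counts)),
    four_codon_aa = sum(counts_aa == 4),
    two_codon_aa = sum(counts_aa == 2),
    one_codon_aa = sum(counts_aa == 1),
    six_codon_aa = sum(counts_aa == 6),
    three_codon_items = items3,
    six_codon_subgroups = subgroups,
    total_codons = as.integer(sum(counts))
  )
}
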