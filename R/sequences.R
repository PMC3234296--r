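# Low-level DNA string utilities shared by the feature extractors.
#
# Sequences are plain character scalars over the alphabet {A,C,G,T}.
# Lower-case input is accepted and normalized; IUPAC ambiguity codes are
# rejected because every downstream feature (G+C, triplet hybridization,
# melting temperature) is only defined on a concrete base call.

#' Validate and normalize a DNA sequence
#'
#' Upper-cases the input and checks it is a nonempty string over
#' \{A,C,G,T\}. All feature extractors call this first, so malformed input
#' fails early with the offending character named.
#'
#' @param seq Character scalar, DNA sequence (case-insensitive).
#' @param what Label used in error messages.
#' @return The normalized (upper-case) sequence.
#' @export
#' @examples
#' dna_validate("acgT")
dna_validate <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    qe_stop(sprintf("%s must be a single character string", what),
            "qe_invalid_input")
  seq <- toupper(seq)
  if (nchar(seq) == 0L)
    qe_stop(sprintf("%s is empty", what), "qe_invalid_input")
  bad <- regmatches(seq, regexpr("[^ACGT]", seq))
  if (length(bad) > 0L)
    qe_stop(sprintf("%s contains non-ACGT character '%s'", what, bad),
            "qe_invalid_input")
  seq
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string.
#' @return The reverse complement, 5'->3'.
#' @export
#' @examples
#' reverse_complement("GAATTC")
reverse_complement <- function(seq) {
  seq <- dna_validate(seq)
  comp <- chartr("ACGT", "TGCA", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' G+C fraction of a sequence
#'
#' @param seq DNA string.
#' @return Fraction of G or C bases, in \[0, 1\].
#' @export
#' @examples
#' gc_content("ATGC")  # 0.5
gc_content <- function(seq) {
  seq <- dna_validate(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(b == "G" | b == "C") / length(b)
}

#' Absolute G+C imbalance between two primers
#'
#' The absolute difference in G+C fraction between the forward and reverse
#' primer; a model covariate interacting with the primer-dimer score.
#'
#' @param forward,reverse Primer sequences.
#' @return Nonnegative fraction.
#' @export
gc_imbalance <- function(forward, reverse) {
  abs(gc_content(forward) - gc_content(reverse))
}

#' Longest homopolymer runs per base
#'
#' For each base, the length of its longest run and whether the run reaches
#' 6 or more (the "N6 or above" repeat flag used as an amplicon feature).
#'
#' @param seq DNA string.
#' @return Named list with integer `aCount`, `tCount`, `cCount`, `gCount`
#'   and logical `aRepeats`, `tRepeats`, `cRepeats`, `gRepeats`.
#' @export
#' @examples
#' homopolymer_runs("AAAAAAC")$aRepeats  # TRUE: run of 6
homopolymer_runs <- function(seq) {
  seq <- dna_validate(seq)
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  longest <- function(base) {
    len <- r$lengths[r$values == base]
    if (length(len) == 0L) 0L else max(len)
  }
  counts <- vapply(c(A = "A", T = "T", C = "C", G = "G"), longest, integer(1))
  list(aCount = counts[["A"]], tCount = counts[["T"]],
       cCount = counts[["C"]], gCount = counts[["G"]],
       aRepeats = counts[["A"]] >= 6L, tRepeats = counts[["T"]] >= 6L,
       cRepeats = counts[["C"]] >= 6L, gRepeats = counts[["G"]] >= 6L)
}

#' Overlapping triplets of a sequence
#'
#' Sliding-window decomposition into 3-mers (step 1, order preserved); the
#' primitive behind the self-complementarity and primer-dimer scores.
#'
#' @param seq DNA string of length >= 3.
#' @return Character vector of `nchar(seq) - 2` triplets.
#' @export
#' @examples
#' extract_triplets("ACGTA")  # "ACG" "CGT" "GTA"
extract_triplets <- function(seq) {
  seq <- dna_validate(seq)
  n <- nchar(seq)
  if (n < 3L)
    qe_stop("sequence shorter than 3 nt has no triplets", "qe_invalid_input")
  substring(seq, 1:(n - 2L), 3:n)
}

#' Count reverse-complement palindromes in a sequence
#'
#' A reverse-complement palindrome is a substring equal to its own reverse
#' complement (necessarily of even length, e.g. the EcoRI site GAATTC).
#' Each start position contributes at most one palindrome, taken at its
#' maximal extent; the count is the number of start positions whose maximal
#' palindrome reaches `min_len`.
#'
#' @param seq DNA string.
#' @param min_len Minimum palindrome length; must be even. Default 6,
#'   matching the N6 convention of the repeat features.
#' @return Integer count.
#' @export
#' @examples
#' find_palindromes("GAATTC")  # 1
find_palindromes <- function(seq, min_len = 6L) {
  seq <- dna_validate(seq)
  if (length(min_len) != 1L || min_len < 4L || min_len %% 2L != 0L)
    qe_stop("min_len must be a single even integer >= 4", "qe_config_error")
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- chartr("ACGT", "TGCA", seq)
  cb <- strsplit(comp, "", fixed = TRUE)[[1]]
  n <- length(b)
  if (n < min_len) return(0L)
  hit <- logical(n)
  half <- min_len %/% 2L
  # expand around each inter-base center; palindrome of radius r spans
  # [c - r + 1, c + r] and seeds start positions c - r + 1 .. c - half + 1
  for (cen in 1:(n - 1L)) {
    r <- 0L
    while (cen - r >= 1L && cen + r + 1L <= n &&
           b[cen - r] == cb[cen + r + 1L]) r <- r + 1L
    if (r >= half) hit[(cen - r + 1L):(cen - half + 1L)] <- TRUE
  }
  sum(hit)
}

#' 3'-terminal features of a primer
#'
#' The terminal dinucleotide, the last nucleotide, and its purine (U) or
#' pyrimidine (Y) class — covariates examined in the univariate analysis of
#' 3' primer termini.
#'
#' @param primer Primer sequence, length >= 2.
#' @return List with `trap3` (last two bases), `last` (last base) and
#'   `class` ("U" for A/G, "Y" for C/T).
#' @export
#' @examples
#' terminal_features("ACGTTG")
terminal_features <- function(primer) {
  primer <- dna_validate(primer, "primer")
  n <- nchar(primer)
  if (n < 2L)
    qe_stop("primer shorter than 2 nt has no terminal dinucleotide",
            "qe_invalid_input")
  last2 <- substr(primer, n - 1L, n)
  last1 <- substr(primer, n, n)
  list(trap3 = last2, last = last1,
       class = if (last1 %in% c("A", "G")) "U" else "Y")
}
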