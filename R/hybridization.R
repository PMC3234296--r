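# Triplet-based hybridization scores.
#
# Both scores reduce each oligo to its overlapping triplets and count how
# many triplets one strand shares with the reverse complement of the other
# (multiset intersection: a triplet occurring twice in one list and three
# times in the other contributes two matches). The raw count is the default
# covariate; a normalized variant (count divided by the smaller triplet
# count, in [0, 1]) is available for cross-length comparisons.

triplet_overlap <- function(ta, tb, normalize) {
  counts_a <- table(ta)
  counts_b <- table(tb)
  shared <- intersect(names(counts_a), names(counts_b))
  score <- sum(pmin(counts_a[shared], counts_b[shared]))
  if (normalize) score / min(length(ta), length(tb)) else as.integer(score)
}

#' Primer self-complementarity score
#'
#' Counts triplets shared between a primer and its own reverse complement —
#' an estimate of the oligo's tendency to fold back or self-dimerize. A
#' perfect reverse-complement palindrome such as GAATTC matches all of its
#' triplets; a homopolymer matches none.
#'
#' @param primer Primer sequence, length >= 3.
#' @param normalize If `TRUE`, divide by the triplet count so the score is
#'   in \[0, 1\]; default `FALSE` (raw integer, the model covariate scale).
#' @return Nonnegative score (`primersSelfcom`).
#' @export
#' @examples
#' primer_selfcom("GAATTC")  # 4: self-palindromic
#' primer_selfcom("AAAAAA")  # 0
primer_selfcom <- function(primer, normalize = FALSE) {
  primer <- dna_validate(primer, "primer")
  triplet_overlap(extract_triplets(primer),
                  extract_triplets(reverse_complement(primer)),
                  normalize)
}

#' Primer-dimer hybridization score
#'
#' Counts triplets shared between the forward primer and the reverse
#' complement of the reverse primer, predicting the pair's tendency to
#' cross-hybridize and form primer dimers. When the reverse primer is the
#' exact reverse complement of the forward one, every triplet matches.
#'
#' @param forward,reverse Primer sequences, each length >= 3.
#' @param normalize As in [primer_selfcom()].
#' @return Nonnegative score (`primerDimers`).
#' @export
#' @examples
#' primer_dimers("AAAAAA", "TTTTTT")  # 4: fully complementary
#' primer_dimers("AAAAAA", "AAAAAA")  # 0
primer_dimers <- function(forward, reverse, normalize = FALSE) {
  forward <- dna_validate(forward, "forward primer")
  reverse <- dna_validate(reverse, "reverse primer")
  triplet_overlap(extract_triplets(forward),
                  extract_triplets(reverse_complement(reverse)),
                  normalize)
}
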