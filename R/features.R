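# Feature extraction: from an amplicon sequence and a primer pair to the
# flat covariate record used by the univariate battery and the GAM.

#' Construct a primer pair with derived per-primer attributes
#'
#' @param forward,reverse Primer sequences, 5'->3', each >= 3 nt.
#' @param tm_method Melting-temperature method, see [melting_temperature()].
#' @return Object of class `primer_pair`: normalized sequences, lengths,
#'   melting temperatures and 3'-terminal features for both primers.
#' @export
#' @examples
#' primer_pair("ATGGCTAGCTAGGTCAAC", "TTGCAGCTAGCTCAGGAT")
primer_pair <- function(forward, reverse, tm_method = "nearest_neighbor") {
  forward <- dna_validate(forward, "forward primer")
  reverse <- dna_validate(reverse, "reverse primer")
  if (nchar(forward) < 3L || nchar(reverse) < 3L)
    qe_stop("primers must be at least 3 nt", "qe_invalid_input")
  tf <- terminal_features(forward)
  tr <- terminal_features(reverse)
  structure(list(
    forward = forward, reverse = reverse,
    forLength = nchar(forward), revLength = nchar(reverse),
    tmForward = melting_temperature(forward, tm_method),
    tmReverse = melting_temperature(reverse, tm_method),
    trap3For = tf$trap3, trap3Rev = tr$trap3,
    trap3LastFor = tf$last, trap3LastRev = tr$last,
    classFor = tf$class, classRev = tr$class
  ), class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("primer pair\n")
  cat(sprintf("  forward: %s (%d nt, Tm %.1f)\n",
              x$forward, x$forLength, x$tmForward))
  cat(sprintf("  reverse: %s (%d nt, Tm %.1f)\n",
              x$reverse, x$revLength, x$tmReverse))
  invisible(x)
}

#' Construct an amplicon with derived sequence attributes
#'
#' @param sequence Template (amplicon) sequence.
#' @param min_palindrome Minimum palindrome length, see [find_palindromes()].
#' @return Object of class `amplicon`: sequence, length, G+C fraction,
#'   homopolymer counts/flags and palindrome count.
#' @export
amplicon <- function(sequence, min_palindrome = 6L) {
  sequence <- dna_validate(sequence, "amplicon")
  runs <- homopolymer_runs(sequence)
  structure(c(list(
    sequence = sequence,
    lengthSequence = nchar(sequence),
    gcSequence = gc_content(sequence),
    sequencePalindromes = find_palindromes(sequence, min_palindrome)
  ), runs), class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("amplicon: %d bp, G+C %.3f, %d palindrome(s)\n",
              x$lengthSequence, x$gcSequence, x$sequencePalindromes))
  invisible(x)
}

# column order of the canonical feature table
FEATURE_COLUMNS <- c(
  "lengthSequence", "gcSequence", "forLength", "revLength", "gcPrimers",
  "aRepeats", "tRepeats", "cRepeats", "gRepeats",
  "aCount", "tCount", "cCount", "gCount",
  "tmForward", "tmReverse", "primerDimers", "primersSelfcom",
  "trap3For", "trap3Rev", "trap3LastFor", "trap3LastRev",
  "sequencePalindromes", "primersLength", "gcImbalance",
  "machine", "template", "source", "operator", "species", "var",
  "efficiency")

#' Extract the full covariate record for one amplicon / primer-pair combination
#'
#' Populates every column of the canonical feature schema: amplicon length,
#' G+C content of amplicon and (pooled) primers, homopolymer repeats,
#' palindromes, per-primer lengths, melting temperatures and 3' termini,
#' the triplet hybridization scores, the combined primer length
#' (`primersLength`, the mean of the two lengths) and the absolute primer
#' G+C imbalance. Metadata strings are carried through untouched and never
#' used by the model. No check is made that the primers actually anneal to
#' the amplicon.
#'
#' @param amp An [amplicon()] (or a raw sequence, coerced).
#' @param pair A [primer_pair()].
#' @param metadata Named list/character with any of `machine`, `template`,
#'   `source`, `operator`, `species`, `var`.
#' @param efficiency Measured efficiency in \[1, 2\], or `NA` for
#'   prediction-only records.
#' @param id Optional record id (first column of the returned row).
#' @return One-row tibble with the canonical columns.
#' @export
#' @examples
#' extract_features("ATGGCCAATTGGCATGCATTACGGATCGGATAGGCTA",
#'                  primer_pair("ATGGCCAAT", "TAGCCTATC"))
extract_features <- function(amp, pair, metadata = list(),
                             efficiency = NA_real_, id = NA_character_) {
  if (is.character(amp)) amp <- amplicon(amp)
  if (!inherits(amp, "amplicon")) qe_stop("amp must be an amplicon",
                                          "qe_invalid_input")
  if (!inherits(pair, "primer_pair")) qe_stop("pair must be a primer_pair",
                                              "qe_invalid_input")
  if (amp$lengthSequence < pair$forLength + pair$revLength)
    qe_stop("amplicon shorter than the two primers combined",
            "qe_invalid_input")
  if (!is.na(efficiency) && (efficiency < 1 || efficiency > 2))
    qe_stop("measured efficiency must lie in [1, 2]", "qe_invalid_input")
  meta <- function(key) as.character(metadata[[key]] %||% NA_character_)
  tibble::tibble(
    id = as.character(id),
    lengthSequence = amp$lengthSequence,
    gcSequence = amp$gcSequence,
    forLength = pair$forLength,
    revLength = pair$revLength,
    gcPrimers = gc_content(paste0(pair$forward, pair$reverse)),
    aRepeats = amp$aRepeats, tRepeats = amp$tRepeats,
    cRepeats = amp$cRepeats, gRepeats = amp$gRepeats,
    aCount = amp$aCount, tCount = amp$tCount,
    cCount = amp$cCount, gCount = amp$gCount,
    tmForward = pair$tmForward, tmReverse = pair$tmReverse,
    primerDimers = primer_dimers(pair$forward, pair$reverse),
    primersSelfcom = primer_selfcom(pair$forward) +
      primer_selfcom(pair$reverse),
    trap3For = pair$trap3For, trap3Rev = pair$trap3Rev,
    trap3LastFor = pair$trap3LastFor, trap3LastRev = pair$trap3LastRev,
    sequencePalindromes = amp$sequencePalindromes,
    primersLength = (pair$forLength + pair$revLength) / 2,
    gcImbalance = gc_imbalance(pair$forward, pair$reverse),
    machine = meta("machine"), template = meta("template"),
    source = meta("source"), operator = meta("operator"),
    species = meta("species"), var = meta("var"),
    efficiency = as.numeric(efficiency)
  )
}

#' Read amplicons from a FASTA file
#'
#' @param path FASTA file; record ids become amplicon ids.
#' @return Named character vector of upper-cased sequences.
#' @export
read_amplicons <- function(path) {
  if (!file.exists(path))
    qe_stop(sprintf("FASTA file not found: %s", path), "qe_io_error")
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) qe_stop(
                    sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
                    "qe_io_error"))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Read primer pairs from CSV
#'
#' @param path CSV with header columns `id`, `forward`, `reverse`.
#' @return Tibble with those three character columns.
#' @export
read_primer_pairs <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("id", "forward", "reverse")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    qe_stop(sprintf("primer CSV lacks column(s): %s",
                    paste(missing, collapse = ", ")), "qe_schema_error")
  df[need]
}

#' Build a feature table for amplicon / primer-pair combinations
#'
#' Joins amplicons and primer pairs by id and extracts one feature record
#' per pair.
#'
#' @param amplicons Named character vector, as from [read_amplicons()].
#' @param primers Tibble with `id`, `forward`, `reverse`.
#' @param metadata Optional tibble with an `id` column plus metadata columns.
#' @inheritParams primer_pair
#' @return Tibble, one row per primer pair, canonical feature columns.
#' @export
feature_table <- function(amplicons, primers, metadata = NULL,
                          tm_method = "nearest_neighbor") {
  orphans <- setdiff(primers$id, names(amplicons))
  if (length(orphans) > 0L)
    qe_stop(sprintf("primer id(s) without matching amplicon: %s",
                    paste(orphans, collapse = ", ")), "qe_schema_error")
  rows <- lapply(seq_len(nrow(primers)), function(i) {
    id <- primers$id[i]
    meta <- list()
    if (!is.null(metadata) && "id" %in% names(metadata)) {
      m <- metadata[metadata$id == id, , drop = FALSE]
      if (nrow(m) > 0L) meta <- as.list(m[1L, setdiff(names(m), "id")])
    }
    extract_features(amplicon(amplicons[[id]]),
                     primer_pair(primers$forward[i], primers$reverse[i],
                                 tm_method = tm_method),
                     metadata = meta, id = id)
  })
  dplyr::bind_rows(rows)
}

#' Write / read a feature table CSV (canonical schema)
#'
#' @param features Tibble from [feature_table()] or [generate_dataset()].
#' @param path Output CSV path.
#' @export
write_feature_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(setdiff(FEATURE_COLUMNS, "efficiency"), names(df))
  if (length(missing) > 0L)
    qe_stop(sprintf("feature CSV lacks column(s): %s",
                    paste(missing, collapse = ", ")), "qe_schema_error")
  df
}
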