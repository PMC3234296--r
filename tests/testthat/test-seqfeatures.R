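test_that("gc_content counts G+C fractions and rejects bad input", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATATAT"), 0.0)
  expect_equal(gc_content("atgc"), 0.5)  # case-normalized
  expect_error(gc_content(""), class = "qe_invalid_input")
  expect_error(gc_content("ACGN"), class = "qe_invalid_input")
  expect_error(gc_content("ACGN"), "N")
})

test_that("gc_content is invariant under reverse complement", {
  set.seed(11)
  for (i in 1:25) {
    s <- random_primer(sample(10:60, 1))
    expect_equal(gc_content(s), gc_content(reverse_complement(s)))
  }
})

test_that("reverse_complement matches Biostrings", {
  set.seed(12)
  for (i in 1:20) {
    s <- random_primer(sample(5:80, 1))
    expect_identical(reverse_complement(s), oracle_revcomp(s))
  }
})

test_that("homopolymer runs and N6 flags", {
  r <- homopolymer_runs("AAAAAA")
  expect_equal(r$aCount, 6L)
  expect_true(r$aRepeats)
  r <- homopolymer_runs("AAAAA")
  expect_equal(r$aCount, 5L)
  expect_false(r$aRepeats)  # boundary: five is not a repeat
  r <- homopolymer_runs("ACGT")
  expect_equal(unlist(r[c("aCount", "tCount", "cCount", "gCount")]),
               c(aCount = 1L, tCount = 1L, cCount = 1L, gCount = 1L))
  expect_false(any(unlist(r[c("aRepeats", "tRepeats", "cRepeats",
                              "gRepeats")])))
})

test_that("appending a base to a run never decreases its count", {
  set.seed(13)
  for (i in 1:20) {
    s <- random_primer(sample(10:40, 1))
    before <- homopolymer_runs(s)$gCount
    after <- homopolymer_runs(paste0(s, "G"))$gCount
    expect_gte(after, before)
  }
})

test_that("triplet extraction slides one base at a time", {
  expect_identical(extract_triplets("ACGTA"), c("ACG", "CGT", "GTA"))
  expect_identical(extract_triplets("ACG"), "ACG")
  expect_length(extract_triplets(random_primer(24)), 22L)
  expect_error(extract_triplets("AC"), class = "qe_invalid_input")
})

test_that("palindrome counting: known sites, boundaries, config errors", {
  expect_equal(find_palindromes("GAATTC"), 1L)  # EcoRI site
  expect_equal(find_palindromes("AAAAAA"), 0L)
  expect_equal(find_palindromes("TTGAATTCTT"), 1L)
  expect_equal(find_palindromes("GAATTCGAATTC", min_len = 6L),
               oracle_palindromes("GAATTCGAATTC"))
  expect_error(find_palindromes("GAATTC", min_len = 5L),
               class = "qe_config_error")
})

test_that("palindrome counts match the quadratic oracle on random sequences", {
  set.seed(14)
  for (len in c(30, 80, 150, 300)) {
    s <- random_primer(len)
    expect_equal(find_palindromes(s), oracle_palindromes(s),
                 info = paste("length", len))
  }
  # GC-rich sequences carry more palindromes; check those too
  set.seed(15)
  for (i in 1:5) {
    s <- paste(sample(c("G", "C", "A"), 120, replace = TRUE,
                      prob = c(.45, .45, .1)), collapse = "")
    expect_equal(find_palindromes(s), oracle_palindromes(s))
  }
})

test_that("3'-terminal features: dinucleotide, last base, purine class", {
  f <- terminal_features("ACGTTG")
  expect_identical(f, list(trap3 = "TG", last = "G", class = "U"))
  f <- terminal_features("ACGTTC")
  expect_identical(f, list(trap3 = "TC", last = "C", class = "Y"))
  f <- terminal_features("AT")
  expect_identical(f, list(trap3 = "AT", last = "T", class = "Y"))
  expect_error(terminal_features("A"), class = "qe_invalid_input")
})

test_that("gc_imbalance is a symmetric absolute difference", {
  expect_equal(gc_imbalance("GGGG", "ATAT"), 1.0)
  expect_equal(gc_imbalance("ACGT", "ACGT"), 0)
  set.seed(16)
  for (i in 1:10) {
    p <- random_primer(20)
    q <- random_primer(18)
    expect_equal(gc_imbalance(p, q), gc_imbalance(q, p))
  }
})

test_that("wallace rule and nearest-neighbor Tm", {
  expect_equal(melting_temperature("ACGT", method = "wallace"), 12)
  expect_equal(melting_temperature("GGCC", method = "wallace"), 16)
  expect_error(melting_temperature("ACGT", method = "bogus"),
               class = "qe_config_error")

  # manual table-lookup oracle for a 20-mer: per-step duplex enthalpies
  # (kcal/mol) and entropies (cal/mol/K) from the unified parameter set,
  # written out step by step, plus terminal initiation, salt entropy
  # 0.368*(N-1)*ln[Na+] and the CT/4 concentration term
  seq20 <- "AGCGTAGCTGATCGATTAGC"
  dH_tab <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
              TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
              GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
              CC = -8.0)
  dS_tab <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
              TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
              GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
              CC = -19.9)
  steps <- c("AG", "GC", "CG", "GT", "TA", "AG", "GC", "CT", "TG", "GA",
             "AT", "TC", "CG", "GA", "AT", "TT", "TA", "AG", "GC")
  dH <- sum(dH_tab[steps]) + 2.3 + 0.1   # 5' A (A.T init), 3' C (G.C init)
  dS <- sum(dS_tab[steps]) + 4.1 - 2.8
  dS <- dS + 0.368 * 19 * log(0.05)
  expected <- dH * 1000 / (dS + 1.9872 * log(240e-9 / 4)) - 273.15
  expect_equal(melting_temperature(seq20), expected, tolerance = 1e-10)
  expect_equal(expected, 54.0985, tolerance = 1e-4)  # frozen
})

test_that("extract_features populates every column consistently", {
  # hand-computable trio: 40-bp amplicon, 9-nt primers
  amp_seq <- "ATGGCCAATTGGCATGCATTACGGATCGGAAAAAATAGGC"
  fwd <- "ATGGCCAAT"
  rev <- "GCCTATTTT"
  rec <- extract_features(amplicon(amp_seq), primer_pair(fwd, rev),
                          metadata = list(species = "E.coli"),
                          efficiency = 1.8, id = "x1")
  expect_equal(rec$lengthSequence, 40L)
  expect_equal(rec$gcSequence, gc_content(amp_seq))
  expect_equal(rec$forLength, 9L)
  expect_equal(rec$revLength, 9L)
  expect_equal(rec$primersLength, 9)
  expect_equal(rec$gcPrimers, gc_content(paste0(fwd, rev)))
  expect_equal(rec$gcImbalance, abs(gc_content(fwd) - gc_content(rev)))
  expect_true(rec$aRepeats)   # AAAAAA run in the amplicon
  expect_equal(rec$aCount, 6L)
  expect_false(rec$gRepeats)
  expect_equal(rec$primerDimers, oracle_triplet_match(fwd, oracle_revcomp(rev)))
  expect_equal(rec$primersSelfcom,
               oracle_triplet_match(fwd, oracle_revcomp(fwd)) +
                 oracle_triplet_match(rev, oracle_revcomp(rev)))
  expect_equal(rec$trap3For, "AT")
  expect_equal(rec$trap3LastRev, "T")
  expect_equal(rec$species, "E.coli")
  expect_true(is.na(rec$operator))
  expect_equal(rec$efficiency, 1.8)
  # determinism
  rec2 <- extract_features(amplicon(amp_seq), primer_pair(fwd, rev),
                           metadata = list(species = "E.coli"),
                           efficiency = 1.8, id = "x1")
  expect_identical(rec, rec2)
})

test_that("all-AT inputs give zero GC everywhere", {
  amp_seq <- paste(rep("AT", 50), collapse = "")
  rec <- extract_features(amplicon(amp_seq),
                          primer_pair("ATATTATA", "TTATATAT"))
  expect_equal(rec$gcSequence, 0)
  expect_equal(rec$gcPrimers, 0)
  expect_equal(rec$gcImbalance, 0)
})

test_that("extract_features validates lengths and efficiency range", {
  expect_error(extract_features(amplicon("ACGTACGT"),
                                primer_pair("ACGTA", "TACGT")),
               class = "qe_invalid_input")
  expect_error(
    extract_features(amplicon(paste(rep("ACGT", 20), collapse = "")),
                     primer_pair("ACGTACGT", "ACGTACGT"), efficiency = 2.5),
    class = "qe_invalid_input")
})

test_that("FASTA + primer CSV round through feature_table", {
  fa <- tempfile(fileext = ".fa")
  set.seed(17)
  seqs <- c(amp1 = random_primer(120), amp2 = random_primer(200))
  writeLines(c(">amp1 first test amplicon", seqs[["amp1"]],
               ">amp2", substr(seqs[["amp2"]], 1, 80),
               substr(seqs[["amp2"]], 81, 200)), fa)
  prm <- tempfile(fileext = ".csv")
  writeLines(c("id,forward,reverse",
               paste0("amp1,", substr(seqs[["amp1"]], 1, 20), ",",
                      oracle_revcomp(substr(seqs[["amp1"]], 101, 120))),
               paste0("amp2,", substr(seqs[["amp2"]], 1, 22), ",",
                      oracle_revcomp(substr(seqs[["amp2"]], 180, 200)))),
             prm)
  amps <- read_amplicons(fa)
  expect_identical(amps, seqs)  # wrapped lines joined, ids trimmed
  feats <- feature_table(amps, read_primer_pairs(prm))
  expect_equal(nrow(feats), 2L)
  expect_identical(feats$id, c("amp1", "amp2"))
  expect_setequal(setdiff(qpcrEff:::FEATURE_COLUMNS, names(feats)),
                  character(0))
  # orphan primer id errors
  bad <- read_primer_pairs(prm)
  bad$id[2] <- "nope"
  expect_error(feature_table(amps, bad), class = "qe_schema_error")
  # csv round trip preserves values
  out <- tempfile(fileext = ".csv")
  write_feature_csv(feats, out)
  back <- read_feature_csv(out)
  expect_equal(back$primerDimers, feats$primerDimers)
  expect_equal(back$gcSequence, feats$gcSequence)
})
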