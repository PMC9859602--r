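test_that("readFasta uppercases, preserves order, handles empty files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT"), f)
  x <- readFasta(f)
  expect_equal(as.character(x), c(a = "ACGT"))

  writeLines(c(">b desc", "acgt", ">a", "ttnn"), f)
  x <- readFasta(f)
  expect_equal(names(x), c("b", "a"))
  expect_equal(unname(as.character(x)), c("ACGT", "TTNN"))

  writeLines(character(), f)
  expect_length(readFasta(f), 0)
})

test_that("readFasta reports the offending line of malformed input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">a", "ACGT"), f)
  expect_error(readFasta(f), "line 1")
  writeLines(c(">a", "ACGT", ">", "ACGT"), f)
  expect_error(readFasta(f), "line 3")
})

test_that("FASTA round-trips through writeFasta with 60-column wrapping", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(long = strrep("ACGT", 40), short = "TTAGGG")
  writeFasta(seqs, f)
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- readFasta(f)
  expect_equal(as.character(back), seqs)
})

test_that("atContent counts A+T over unambiguous bases only", {
  expect_equal(atContent("ATAT"), 1.0)
  expect_equal(atContent("ACGT"), 0.5)
  expect_equal(atContent("AANTT"), 1.0)  # N excluded from both sides
  expect_equal(atContent("GCGC"), 0.0)
  expect_error(atContent(""), "empty")
  expect_error(atContent("NNN"), "unambiguous")
})

test_that("revComp is the standard complement and an involution", {
  expect_equal(revComp("ACGT"), "ACGT")
  expect_equal(revComp("AAC"), "GTT")
  expect_error(revComp("AXZ"), "IUPAC")
  set.seed(7)
  for (i in 1:20) {
    x <- rand_dna(sample(1:80, 1))
    expect_equal(revComp(revComp(x)), x)
    expect_equal(atContent(revComp(x)), atContent(x))
  }
})

test_that("buildReference makes dimers for large monomers, ~200 bp tilings for small", {
  m183 <- rand_dna(183)
  expect_equal(buildReference(m183), strrep(m183, 2))
  expect_equal(nchar(buildReference(m183)), 366)
  expect_equal(buildReference("TTAGGG"), strrep("TTAGGG", 34))
  expect_equal(nchar(buildReference("TTAGGG")), 204)
  m3102 <- rand_dna(3102)
  expect_equal(nchar(buildReference(m3102)), 6204)
  # length contract: in [target, target + monomer) for small monomers
  set.seed(11)
  for (len in c(2, 5, 17, 49, 99)) {
    m <- rand_dna(len)
    L <- nchar(buildReference(m))
    expect_gte(L, 200)
    expect_lt(L, 200 + len)
  }
})

test_that("telomericReference is 50 exact copies of TTAGGG", {
  tel <- telomericReference()
  expect_equal(nchar(tel), 300)
  expect_equal(substr(tel, 1, 6), "TTAGGG")
  expect_equal(tel, strrep("TTAGGG", 50))
  expect_false(grepl("[^TAG]", tel))
})

test_that("majorityConsensus takes column majorities, drops gap-majority columns, ties go A<C<G<T", {
  expect_equal(majorityConsensus(c("ACGT", "ACGT", "ACGA")), "ACGT")
  expect_equal(majorityConsensus(c("A-GT", "AC-T", "ACGT")), "ACGT")
  expect_equal(majorityConsensus(c("AT", "TA")), "AA")
  # gap-majority column dropped
  expect_equal(majorityConsensus(c("A-C", "A-C", "AGC")), "AC")
  expect_error(majorityConsensus("ACGT"), "at least 2")
  expect_error(majorityConsensus(c("AC", "ACG")), "equal length")
  # k identical rows reproduce the row
  x <- rand_dna(40)
  expect_equal(majorityConsensus(rep(x, 5)), x)
})

test_that("SatLibrary validates ranks, lengths and metadata round-trips as TSV", {
  lib <- SatLibrary(c(rand_dna(183), rand_dna(60)), speciesTag = "Tst")
  expect_equal(familyNames(lib), c("TstSat1-183", "TstSat2-60"))
  expect_equal(libraryInfo(lib)$rank, 1:2)
  expect_equal(libraryInfo(lib)$monomer_length, c(183L, 60L))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLibraryTsv(lib, f)
  back <- readLibraryTsv(f)
  expect_equal(familyNames(back), familyNames(lib))
  expect_equal(as.character(monomers(back)), as.character(monomers(lib)))
  expect_equal(speciesTag(back), "Tst")
})

test_that("referenceSeqs obeys the dimer/concatemer rule per family", {
  lib <- SatLibrary(c(rand_dna(183), "TTAGGG"), speciesTag = "Tst")
  refs <- referenceSeqs(lib)
  expect_equal(unname(Biostrings::width(refs)), c(366L, 204L))
  expect_equal(names(refs), familyNames(lib))
})
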