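test_that("k2pDistance matches the closed form and its domain edges", {
  expect_equal(k2pDistance(0, 0), 0)
  expect_equal(k2pDistance(0.1, 0.05), 0.1701812, tolerance = 1e-6)
  expect_error(k2pDistance(0.5, 0.0), "saturated")
  expect_error(k2pDistance(0.2, 0.5), "saturated")
  expect_error(k2pDistance(-0.1, 0), ">= 0")
})

test_that("k2pDistance dominates the p-distance over its whole domain", {
  set.seed(2)
  for (i in 1:1000) {
    P <- runif(1, 0, 0.45); Q <- runif(1, 0, 0.45)
    if (1 - 2 * P - Q <= 0.01 || 1 - 2 * Q <= 0.01) next
    expect_gte(k2pDistance(P, Q), P + Q)
  }
  expect_equal(k2pDistance(0, 0), 0)  # equality only at zero
})

test_that("countSubstitutions classifies transitions/transversions and excludes gaps", {
  expect_equal(unname(countSubstitutions("ACGT", "ACGT")), c(0L, 0L, 4L, 0L))
  expect_equal(unname(countSubstitutions("AG", "GA")), c(2L, 0L, 2L, 0L))
  expect_equal(unname(countSubstitutions("A-CT", "AGCA")), c(0L, 1L, 3L, 1L))
  # ambiguity columns excluded
  expect_equal(unname(countSubstitutions("ANGT", "ACGT")), c(0L, 0L, 3L, 0L))
  expect_error(countSubstitutions("AC", "ACG"), "equal length")
})

test_that("localAlign finds exact substrings with full score", {
  ref <- rand_dna(200)
  read <- substr(ref, 51, 110)
  al <- localAlign(read, ref)
  expect_equal(al$score, 60)
  expect_equal(al$read_span, c(0L, 60L))
  expect_equal(al$ref_span, c(50L, 110L))
  expect_equal(al$aligned_read, al$aligned_ref)
})

test_that("localAlign equals the brute-force optimum on small random instances", {
  set.seed(19)
  for (i in 1:20) {
    a <- rand_dna(8); b <- rand_dna(8)
    expect_equal(localAlign(a, b)$score, brute_local_score(a, b),
                 info = paste(a, b))
  }
  # a couple of gapped cases at longer lengths
  for (i in 1:5) {
    a <- rand_dna(10)
    b <- paste0(substr(a, 1, 5), "G", substr(a, 6, 10))
    expect_equal(localAlign(a, b)$score, brute_local_score(a, b),
                 info = paste(a, b))
  }
})

make_mask_fixture <- function(divergence = 0, n_copies = 60, seed = 303,
                              mlen = 150, prop_reads = 200) {
  mono <- randomMonomer(mlen, 0.5, seed = seed)
  lib <- nameFamilies(mono, 0.01, "Tst")
  arr <- paste(vapply(seq_len(n_copies), function(i)
    mutateMonomer(mono, divergence, seed = seed + i), character(1)),
    collapse = "")
  reads <- shearReads(arr, 150, coverage = prop_reads * 150 / nchar(arr),
                      seed = seed + 999)
  list(lib = lib, reads = reads, mono = mono)
}

test_that("maskSample assigns pure satellite reads to their family", {
  fx <- make_mask_fixture(divergence = 0)
  m <- maskSample(fx$reads, fx$lib)
  rec <- records(m)
  expect_gt(nrow(rec), 0.95 * length(fx$reads))
  expect_true(all(rec$family == "TstSat1-150"))
  expect_true(all(rec$k2p == 0))
  expect_setequal(unique(rec$strand), c("+", "-"))
})

test_that("maskSample rejects pure background (false-positive rate < 0.1%)", {
  g <- generateBackground(3e5, 0.59, seed = 71)
  reads <- shearReads(g, 150, 1, seed = 72)  # 2000 reads
  lib <- nameFamilies(randomMonomer(183, 0.5, seed = 70), 0.01, "Tst")
  m <- maskSample(reads, lib)
  expect_lte(nrow(records(m)), 0.001 * length(reads))
})

test_that("mean record k2p tracks the simulated divergence within 1 point", {
  for (d in c(0.05, 0.15)) {
    fx <- make_mask_fixture(divergence = d, seed = 404)
    m <- maskSample(fx$reads, fx$lib)
    rec <- records(m)
    expect_gt(nrow(rec), 50)
    expect_lt(abs(mean(rec$k2p) - 100 * d), 1)
  }
})

test_that("maskSample is deterministic and order-equivariant", {
  fx <- make_mask_fixture(divergence = 0.08, prop_reads = 80)
  m1 <- maskSample(fx$reads, fx$lib)
  m2 <- maskSample(fx$reads, fx$lib)
  expect_identical(records(m1), records(m2))
  perm <- rev(seq_along(fx$reads))
  m3 <- maskSample(fx$reads[perm], fx$lib)
  a <- records(m1); b <- records(m3)
  a <- a[order(a$read, a$read_start), ]; rownames(a) <- NULL
  b <- b[order(b$read, b$read_start), ]; rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("per-read resolution keeps the best-scoring family once", {
  mono <- randomMonomer(150, 0.5, seed = 31)
  # two families: the true monomer and a diverged cousin that also matches
  cousin <- mutateMonomer(mono, 0.08, seed = 32)
  lib <- nameFamilies(c(mono, cousin), c(0.02, 0.01), "Tst")
  reads <- shearReads(strrep(mono, 40), 150, 2, seed = 33)
  m <- maskSample(reads, lib)
  rec <- records(m)
  # every read appears with non-overlapping spans only, best family wins
  expect_true(all(tapply(seq_len(nrow(rec)), rec$read, function(ii) {
    r <- rec[ii, ]; r <- r[order(r$read_start), ]
    nrow(r) < 2 || all(r$read_start[-1] >= r$read_end[-nrow(r)])
  })))
  expect_gt(mean(rec$family == familyNames(lib)[1]), 0.95)
})

test_that("mask TSV round-trips records and sample metadata", {
  fx <- make_mask_fixture(divergence = 0.05, prop_reads = 50)
  m <- maskSample(fx$reads, fx$lib)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMaskTsv(m, f)
  back <- readMaskTsv(f)
  expect_equal(sampleLabel(back), sampleLabel(m))
  expect_equal(totalBp(back), totalBp(m))
  expect_equal(back@nReads, m@nReads)
  expect_equal(records(back)$read, records(m)$read)
  expect_equal(records(back)$k2p, records(m)$k2p, tolerance = 1e-4)
  expect_equal(records(back)$read_start, records(m)$read_start)
  expect_equal(records(back)$strand, records(m)$strand)
})

test_that("maskAssembly recovers proportions from the genome itself", {
  mono <- randomMonomer(180, 0.5, seed = 51)
  spec <- simSpec(list(
    familySimSpec(mono, 0.02, 0.05, nArrays = 4L, name = "f1")),
    genomeLength = 4e5, seed = 52)
  b <- buildGenome(spec)
  lib <- nameFamilies(mono, 0.02, "Tst")
  m <- maskAssembly(b$genome, lib)
  got <- genomeProportion(m, familyNames(lib))
  truth <- 100 * truthPerFamily(b$truth)$true_proportion
  expect_lt(abs(got - truth) / truth, 0.10)
})

test_that("collapsed-assembly masking mimics the assembly underestimation", {
  mono <- randomMonomer(180, 0.5, seed = 61)
  spec <- simSpec(list(
    familySimSpec(mono, 0.02, 0.05, nArrays = 4L, name = "f1")),
    genomeLength = 4e5, seed = 62)
  b <- buildGenome(spec)
  g <- as.character(b$genome[[1]])
  iv <- truthIntervals(b$truth)
  iv <- iv[order(-iv$start), ]
  for (i in seq_len(nrow(iv)))  # collapse every array to 2 monomers
    g <- paste0(substr(g, 1, iv$start[i]),
                substr(g, iv$start[i] + 1, iv$start[i] + 360),
                substr(g, iv$end[i] + 1, nchar(g)))
  lib <- nameFamilies(mono, 0.02, "Tst")
  collapsed <- genomeProportion(maskAssembly(g, lib), familyNames(lib))
  full <- genomeProportion(maskAssembly(b$genome, lib), familyNames(lib))
  expect_lt(collapsed, 0.5 * full)
})

test_that("maskAssembly on an empty assembly returns an empty result", {
  lib <- nameFamilies(randomMonomer(100, 0.5, 1), 0.01, "Tst")
  m <- maskAssembly(character(), lib)
  expect_equal(nrow(records(m)), 0)
})

test_that("readRepeatMaskerAlign parses headers and Kimura annotations", {
  f <- withr::local_tempfile(fileext = ".align")
  # synthetic .align excerpt (two hits, one reverse strand)
  writeLines(c(
    "239 8.21 0.00 0.00 read_000001 1 140 (10) TstSat1-183#Satellite 12 151 (215) m_b1",
    "",
    "  read_000001    1 ACGTACGT 8",
    "                   ||||||||",
    "  TstSat1-183   12 ACGTACGT 19",
    "",
    "Kimura (with divCpGMod): 8.64",
    "",
    "101 12.50 0.00 0.00 read_000002 11 150 (0) C TstSat2-60#Satellite (0) 120 1 m_b1",
    "",
    "Kimura (with divCpGMod): 13.20"), f)
  m <- readRepeatMaskerAlign(f, total_bp = 3e4, read_length = 150)
  rec <- records(m)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$strand, c("+", "-"))
  expect_equal(rec$family, c("TstSat1-183#Satellite", "TstSat2-60#Satellite"))
  expect_equal(rec$k2p, c(8.64, 13.20))
  expect_equal(rec$read_start, c(0L, 10L))
  expect_equal(rec$read_end, c(140L, 150L))
})
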