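test_that("generateBackground hits the target base composition and is seed-reproducible", {
  expect_equal(generateBackground(0, 0.59, 1), "")
  x <- generateBackground(1e6, 0.59, seed = 5)
  expect_equal(nchar(x), 1e6)
  expect_lt(abs(atContent(x) - 0.59), 0.002)  # ~4 sd of Binomial(1e6, .59)
  expect_identical(x, generateBackground(1e6, 0.59, seed = 5))
  expect_false(identical(substr(x, 1, 1000),
                         substr(generateBackground(1e6, 0.59, 6), 1, 1000)))
  expect_error(generateBackground(10, 1.2, 1), "at_fraction")
})

test_that("satsim calls do not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(generateBackground(100, 0.5, seed = 3))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("mutateMonomer round-trips the K2P divergence it was asked for", {
  m <- rand_dna(1e5)
  expect_identical(mutateMonomer(m, 0), m)
  out <- mutateMonomer(m, divergence = 0.05, kappa = 2, seed = 17)
  cnt <- countSubstitutions(out, m)
  est <- k2pDistance(cnt[["transitions"]] / cnt[["aligned_cols"]],
                     cnt[["transversions"]] / cnt[["aligned_cols"]])
  expect_lt(abs(est - 0.05), 0.005)
  # observed ts/tv approaches kappa/2 at small divergence (the two
  # transversion classes together run at rate 2*beta)
  out4 <- mutateMonomer(m, divergence = 0.05, kappa = 4, seed = 18)
  c4 <- countSubstitutions(out4, m)
  expect_lt(abs(c4[["transitions"]] / c4[["transversions"]] - 2), 0.3)
})

test_that("very large kappa gives (almost) pure transitions", {
  m <- rand_dna(2e4)
  out <- mutateMonomer(m, 0.1, kappa = 1e6, seed = 3)
  cnt <- countSubstitutions(out, m)
  expect_gt(cnt[["transitions"]], 100)
  expect_lte(cnt[["transversions"]], 1)
})

test_that("buildGenome: targeted bp within 1%, truth verified by string scan", {
  mono <- randomMonomer(200, 0.5, seed = 21)
  spec <- simSpec(list(
    familySimSpec(mono, 0.01, 0.0, nArrays = 4L, name = "fam")),
    genomeLength = 2e6, seed = 31)
  b <- buildGenome(spec)
  pf <- truthPerFamily(b$truth)
  expect_gte(pf$true_bp, 19800)
  expect_lte(pf$true_bp, 20200)
  g <- as.character(b$genome[[1]])
  iv <- truthIntervals(b$truth)
  # independent scan: at zero divergence every interval is exact copies
  expect_equal(sum(iv$end - iv$start), pf$true_bp)
  for (i in seq_len(nrow(iv))) {
    arr <- substr(g, iv$start[i] + 1, iv$end[i])
    expect_equal(substr(arr, 1, 200), mono)
    expect_equal(nchar(arr) %% 200, 0)
  }
  # arrays separated by at least 2 read lengths
  iv <- iv[order(iv$start), ]
  if (nrow(iv) > 1)
    expect_true(all(iv$start[-1] - iv$end[-nrow(iv)] >= 300))
  expect_equal(pf$true_proportion, pf$true_bp / nchar(g))
})

test_that("buildGenome with no families returns pure background", {
  spec <- simSpec(list(), genomeLength = 5e4, backgroundAT = 0.59, seed = 3)
  b <- buildGenome(spec)
  expect_equal(nchar(as.character(b$genome[[1]])), 5e4)
  expect_equal(nrow(truthPerFamily(b$truth)), 0)
  expect_lt(abs(atContent(as.character(b$genome[[1]])) - 0.59), 0.01)
})

test_that("truth intervals re-align to the consensus near the requested divergence", {
  mono <- randomMonomer(150, 0.5, seed = 8)
  spec <- simSpec(list(
    familySimSpec(mono, 0.02, 0.10, nArrays = 3L, name = "fam")),
    genomeLength = 5e5, seed = 41)
  b <- buildGenome(spec)
  g <- as.character(b$genome[[1]])
  iv <- truthIntervals(b$truth)
  ests <- c()
  for (i in seq_len(nrow(iv))) {
    arr <- substr(g, iv$start[i] + 1, iv$end[i])
    ncopy <- nchar(arr) %/% 150
    for (j in seq_len(ncopy)) {
      cnt <- countSubstitutions(substr(arr, (j - 1) * 150 + 1, j * 150), mono)
      ests <- c(ests, k2pDistance(cnt[["transitions"]] / 150,
                                  cnt[["transversions"]] / 150))
    }
  }
  expect_lt(abs(mean(ests) - 0.10), 0.01)
  expect_lt(abs(100 * mean(ests) -
                truthPerFamily(b$truth)$realized_divergence), 1e-6)
})

test_that("infeasible packing is rejected with advice", {
  spec <- simSpec(list(
    familySimSpec(rand_dna(100), 0.95, 0, nArrays = 2L, name = "big")),
    genomeLength = 1e4, seed = 1)
  expect_error(buildGenome(spec), "infeasible")
})

test_that("shearReads draws the formula read count, both strands, deterministically", {
  g <- generateBackground(1e6, 0.5, seed = 2)
  reads <- shearReads(g, 150, 2, seed = 9)
  expect_length(reads, 13333)
  expect_true(all(Biostrings::width(reads) == 150))
  st <- S4Vectors::mcols(reads)$strand
  expect_gt(mean(st == "-"), 0.45)
  expect_lt(mean(st == "-"), 0.55)
  again <- shearReads(g, 150, 2, seed = 9)
  expect_identical(as.character(reads), as.character(again))
  expect_error(shearReads("ACGT", 10, 1), "exceeds")
})

test_that("high-coverage shearing covers nearly the whole genome", {
  g <- generateBackground(2e4, 0.5, seed = 4)
  reads <- shearReads(g, 100, 20, seed = 5)
  cov <- integer(2e4)
  st <- S4Vectors::mcols(reads)$start
  for (s in st) cov[(s + 1):(s + 100)] <- 1L
  expect_gt(mean(cov), 0.99)
})

test_that("simulateSpeciesSet applies multipliers to the shared library", {
  mono <- list(randomMonomer(150, 0.5, 1), randomMonomer(90, 0.5, 2))
  base <- simSpec(list(
    familySimSpec(mono[[1]], 0.01, 0.03, nArrays = 3L, name = "f1"),
    familySimSpec(mono[[2]], 0.01, 0.03, nArrays = 3L, name = "f2")),
    genomeLength = 3e5, seed = 11)
  sps <- simulateSpeciesSet(base,
    list(A = list(multipliers = c(1, 1)),
         B = list(multipliers = c(2, 0))), seed = 12)
  tA <- truthPerFamily(sps$A$truth)
  tB <- truthPerFamily(sps$B$truth)
  expect_equal(tB$true_bp[tB$family == "f2"], 0)
  ratio <- tB$true_proportion[tB$family == "f1"] /
    tA$true_proportion[tA$family == "f1"]
  expect_lt(abs(log2(ratio) - 1), 0.1)
  expect_setequal(tB$family, c("f1", "f2"))
})
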