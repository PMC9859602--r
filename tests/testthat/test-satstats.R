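test_that("genomeProportion is aligned bp over sampled bp, as a percentage", {
  rec <- mk_records(c("r1", "r2", "r3"), "famA", c(150, 100, 50))
  m <- mk_mask(rec, total_bp = 30000)
  expect_equal(genomeProportion(m, "famA"), 100 * 300 / 30000)
  expect_equal(genomeProportion(m, "famB"), 0)
  expect_error(genomeProportion(mk_mask(rec, 0)), "totalBp")
})

test_that("landscape bins by floor(k2p) and conserves the family proportion", {
  rec <- mk_records(paste0("r", 1:4), "famA", rep(100, 4),
                    k2p = c(0.2, 0.9, 5.4, 5.9))
  m <- mk_mask(rec, total_bp = 40000)
  ls <- landscape(m, "famA")
  expect_equal(names(landscapeBins(ls)), c("0", "5"))
  expect_equal(unname(landscapeBins(ls)), c(0.5, 0.5))
  expect_equal(totalAbundance(ls), genomeProportion(m, "famA"))
  # all records at zero divergence: a single bin holding everything
  m0 <- mk_mask(mk_records("r1", "famA", 150, k2p = 0), 1500)
  expect_equal(landscapeBins(landscape(m0, "famA")),
               c("0" = 10))
})

test_that("tsi counts reads (not records) internal at >= 89% of read length", {
  # 3 of 5 aligned reads internal
  rec <- mk_records(paste0("r", 1:5), "famA",
                    span = c(150, 140, 134, 100, 60))
  m <- mk_mask(rec, 1e5)
  expect_equal(tsi(m, "famA"), 3 / 5)  # 134 >= 133.5 counts as internal
  # a read with two partial hits counts once, as external
  r6b <- mk_records("r6", "famA", 60)
  r6b$read_start <- 80L; r6b$read_end <- 140L
  rec2 <- rbind(rec, mk_records("r6", "famA", 70), r6b)
  m2 <- mk_mask(rec2, 1e5)
  expect_equal(tsi(m2, "famA"), 3 / 6)
  expect_true(is.na(tsi(m, "absent")))
})

test_that("divPeak is the argmax bin with ties to the smaller bin", {
  expect_equal(divPeak(mk_landscape(c("0" = 5))), 0L)
  expect_equal(divPeak(mk_landscape(c("3" = 1, "7" = 2, "8" = 0.5))), 7L)
  expect_equal(divPeak(mk_landscape(c("2" = 1, "9" = 1))), 2L)
  expect_error(divPeak(mk_landscape(setNames(numeric(), character()))),
               "empty")
})

test_that("rsp sums a 5-bin window truncated at zero", {
  expect_equal(rsp(mk_landscape(c("4" = 2))), 1.0)
  ls <- mk_landscape(setNames(rep(1, 6), as.character(0:5)))
  expect_equal(rsp(ls, 0L), 3 / 6)
  ls2 <- mk_landscape(c("5" = 2, "6" = 1, "9" = 1))
  expect_equal(rsp(ls2, 5L), 3 / 4)
  expect_error(rsp(mk_landscape(c("1" = 0))), "zero abundance")
})

test_that("summarizeTable computes mean, sample SD and median per column", {
  df <- data.frame(a = c(1, 2, 3, 4), b = c(10, 10, 10, 50))
  s <- summarizeTable(df)
  expect_equal(s$a, c(2.5, sd(1:4), 2.5))
  expect_equal(s$b[1], 20)
  expect_equal(s$b[3], 10)
  one <- summarizeTable(data.frame(a = 7))
  expect_equal(one$a, c(7, 0, 7))  # single row: SD 0 by convention
})

test_that("classifyLandscape separates recent, intermediate and degenerate shapes", {
  tab <- taquTable1()
  cls <- mapply(function(p, r) classifyLandscape(peak = p, rsp_value = r),
                tab$divpeak, tab$rsp)
  expect_equal(unname(cls[tab$name == "TaquSat5-3102"]), "leptokurtic")
  expect_equal(unname(cls[tab$name == "TaquSat13-54"]), "platykurtic")
  expect_equal(unname(cls[tab$name == "TaquSat1-183"]), "mesokurtic")
  expect_equal(unname(cls[tab$name == "TaquSat11-71"]), "leptokurtic")
  expect_equal(unname(cls[tab$name == "TaquSat3-6"]), "platykurtic")
})

test_that("familyStats conserves abundance: landscape sums equal proportions", {
  mono <- randomMonomer(160, 0.5, seed = 88)
  spec <- simSpec(list(
    familySimSpec(mono, 0.015, 0.06, nArrays = 4L, name = "f1")),
    genomeLength = 3e5, seed = 89)
  b <- buildGenome(spec)
  reads <- shearReads(b$genome, 150, 2, seed = 90)
  lib <- nameFamilies(mono, 0.015, "Tst")
  m <- maskSample(reads, lib)
  fam <- familyNames(lib)
  ls <- landscape(m, fam)
  expect_equal(sum(landscapeBins(ls)), genomeProportion(m, fam),
               tolerance = 1e-9)
  fs <- familyStats(m, lib)
  expect_equal(fs$genome_proportion, genomeProportion(m, fam))
  expect_equal(fs$divpeak, divPeak(ls))
  expect_equal(fs$rsp, rsp(ls))
  tab <- satellitomeTable(m, lib)
  expect_equal(tab$total, sum(fs$genome_proportion))
})

test_that("two-epoch families produce bimodal landscapes with diluted peaks", {
  mono <- randomMonomer(160, 0.5, seed = 91)
  spec <- simSpec(list(
    familySimSpec(mono, 0.01, 0.02, nArrays = 3L, name = "young"),
    familySimSpec(mono, 0.01, 0.20, nArrays = 3L, name = "old")),
    genomeLength = 4e5, seed = 92)
  b <- buildGenome(spec)
  reads <- shearReads(b$genome, 150, 2, seed = 93)
  lib <- nameFamilies(mono, 0.02, "Tst")  # one family catching both epochs
  m <- maskSample(reads, lib)
  ls <- landscape(m, familyNames(lib))
  expect_lt(rsp(ls), 0.6)
  # homogeneous young family alone scores high RSP
  bins <- landscapeBins(ls)
  low <- sum(bins[as.integer(names(bins)) <= 5])
  high <- sum(bins[as.integer(names(bins)) >= 12])
  expect_gt(low, 0.3 * sum(bins))
  expect_gt(high, 0.2 * sum(bins))
})
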