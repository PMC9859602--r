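## Canonical simulation scenarios.
##
## These fix the study conditions used throughout the package's validation
## suite and worked examples, so that tests, scripts and documentation all
## exercise the same data-generating processes. Monomers are drawn
## reproducibly from the scenario seed; everything else is fixed.

.scenario_monomer <- function(len, at, seed, k)
  randomMonomer(len, at, seed = as.integer((seed * 131 + k) %% 2^30))

#' Four-family parameter-recovery scenario
#'
#' A 2 Mb genome at 59% background A+T carrying four satDNA families with
#' proportions 1%, 0.5%, 0.3% and 0.1% and divergences 1%, 5%, 12% and
#' 20% (monomers of 183, 107, 172 and 120 bp), sheared into 150 bp reads
#' at 2x coverage. Used to check that the pipeline recovers abundances,
#' divergence peaks and peak shapes.
#'
#' @param seed Integer seed.
#' @return A [SimSpec-class].
#' @export
scenarioRecovery <- function(seed = 1L) {
  lens <- c(183L, 107L, 172L, 120L)
  ats <- c(0.55, 0.50, 0.50, 0.45)
  props <- c(0.01, 0.005, 0.003, 0.001)
  divs <- c(0.01, 0.05, 0.12, 0.20)
  arrs <- c(6L, 5L, 4L, 3L)
  fams <- lapply(1:4, function(i)
    familySimSpec(.scenario_monomer(lens[i], ats[i], seed, i),
                  props[i], divs[i], nArrays = arrs[i],
                  name = sprintf("fam_d%02d", round(100 * divs[i]))))
  simSpec(fams, genomeLength = 2e6, backgroundAT = 0.59,
          readLength = 150L, coverage = 2, seed = as.integer(seed))
}

#' Ten-family divergence-ladder scenario
#'
#' Ten equally abundant families (0.4% each) whose divergences step
#' evenly from 1% to 25%: the setting in which the DivPeak/RSP
#' anticorrelation of satellite landscapes (young families peak sharply
#' at low divergence; degenerate ones flatly at high divergence) must
#' emerge.
#'
#' @param seed Integer seed.
#' @return A [SimSpec-class].
#' @export
scenarioLadder <- function(seed = 1L) {
  lens <- seq(120L, 300L, by = 20L)
  divs <- seq(0.01, 0.25, length.out = 10)
  fams <- lapply(1:10, function(i)
    familySimSpec(.scenario_monomer(lens[i], 0.5, seed, 100 + i),
                  0.004, divs[i], nArrays = 4L,
                  name = sprintf("lad_d%04.1f", 100 * divs[i])))
  simSpec(fams, genomeLength = 2e6, backgroundAT = 0.59,
          readLength = 150L, coverage = 2, seed = as.integer(seed))
}

#' Array-length / TSI scenario
#'
#' Three families with identical abundance (0.4%), divergence (2%) and
#' monomer length (200 bp) but mean array lengths of about 1, 3 and 20
#' monomers (40, 13 and 2 arrays). TSI must increase with array length:
#' reads from long arrays lie wholly inside satellite sequence.
#'
#' @param seed Integer seed.
#' @return A [SimSpec-class].
#' @export
scenarioTsi <- function(seed = 1L) {
  arrs <- c(40L, 13L, 2L)
  fams <- lapply(1:3, function(i)
    familySimSpec(.scenario_monomer(200L, 0.5, seed, 200 + i),
                  0.004, 0.02, nArrays = arrs[i], arrayLengthCV = 0.3,
                  name = sprintf("tsi_a%02d", arrs[i])))
  simSpec(fams, genomeLength = 2e6, backgroundAT = 0.59,
          readLength = 150L, coverage = 2, seed = as.integer(seed))
}

#' Two-species library-hypothesis scenario
#'
#' A base satellitome of four families (0.8%, 0.4%, 0.6%, 0.5%; 5%
#' divergence) shared by two species: species A carries it unchanged,
#' species B with abundance multipliers 1, 2, 0.5 and 0 (the last family
#' absent), mirroring per-lineage expansion and loss from a shared
#' satDNA pool.
#'
#' @param seed Integer seed.
#' @return List: `base` (the [SimSpec-class]) and `perturbations`
#'   (suitable for [simulateSpeciesSet()]).
#' @export
scenarioComparative <- function(seed = 1L) {
  lens <- c(180L, 150L, 220L, 140L)
  props <- c(0.008, 0.004, 0.006, 0.005)
  fams <- lapply(1:4, function(i)
    familySimSpec(.scenario_monomer(lens[i], 0.5, seed, 300 + i),
                  props[i], 0.05, nArrays = 4L,
                  name = sprintf("cmp_f%d", i)))
  base <- simSpec(fams, genomeLength = 2e6, backgroundAT = 0.59,
                  readLength = 150L, coverage = 2, seed = as.integer(seed))
  list(base = base,
       perturbations = list(
         A = list(multipliers = c(1, 1, 1, 1)),
         B = list(multipliers = c(1, 2, 0.5, 0))))
}
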