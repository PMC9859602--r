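## Tandem periodicity detection and family naming: a quantitative
## replacement for visual dotplot inspection of repetitive contigs.

#' Detect the tandem period of a repetitive contig
#'
#' Computes the mean base identity between the contig and itself shifted
#' by p (the diagonal signal of a dotplot made quantitative) for every
#' candidate period, and reports the fundamental period: the smallest p
#' whose identity is within 0.01 of the maximum. This resolves the
#' multiple-of-period ambiguity that dotplot diagonals share. When the
#' best identity is below `min_identity` the contig is called
#' non-tandem (`period` = NA).
#'
#' @param contig DNA string (character or Biostrings object).
#' @param min_period,max_period Period search range in bp; `max_period`
#'   defaults to a third of the contig length (the contig should span at
#'   least three monomers).
#' @param min_identity Identity below which no tandem structure is called.
#' @param id Contig identifier stored in the result.
#' @return A [PeriodCall-class].
#' @export
detectPeriod <- function(contig, min_period = 2L, max_period = NULL,
                         min_identity = 0.6, id = "contig") {
  contig <- .as_char_seq(contig)
  L <- nchar(contig)
  if (is.null(max_period)) max_period <- max(min_period, L %/% 3L)
  if (L < 3L * min_period)
    stop("detectPeriod: contig shorter than 3x min_period")
  max_period <- min(max_period, L - 1L)
  x <- charToRaw(contig)
  ident <- vapply(min_period:max_period, function(p) {
    mean(x[seq_len(L - p)] == x[(p + 1L):L])
  }, numeric(1))
  # homopolymers: allow period 1 to win when even shift-1 identity is high
  p1 <- mean(x[seq_len(L - 1L)] == x[2:L])
  periods <- min_period:max_period
  if (p1 >= min_identity && min_period > 1L) {
    periods <- c(1L, periods); ident <- c(p1, ident)
  }
  best <- max(ident)
  if (best < min_identity)
    return(new("PeriodCall", contig = id, period = NA_integer_,
               identity = best, phase = 0L))
  p <- periods[which(ident >= best - 0.01)[1]]
  new("PeriodCall", contig = id, period = as.integer(p),
      identity = ident[match(p, periods)], phase = 0L)
}

#' Cut a contig into stacked monomer-length windows
#'
#' Consecutive period-length windows starting at `phase`; the trailing
#' partial window is dropped. The stack feeds [majorityConsensus()].
#'
#' @param contig DNA string.
#' @param period Monomer period in bp.
#' @param phase Offset in `[0, period)` at which to start cutting.
#' @return Character vector of period-length strings.
#' @export
extractAndStack <- function(contig, period, phase = 0L) {
  contig <- .as_char_seq(contig)
  L <- nchar(contig)
  period <- as.integer(period)
  stopifnot(period >= 1L, phase >= 0L, phase < period)
  n <- (L - phase) %/% period
  if (n < 1) return(character())
  starts <- phase + period * (seq_len(n) - 1L) + 1L
  substring(contig, starts, starts + period - 1L)
}

#' Canonical rotation of a monomer
#'
#' The start point of a monomer inside a tandem array is arbitrary;
#' comparing families therefore uses the lexicographically smallest
#' rotation, which is invariant under any rotation of the input.
#'
#' @param monomer Non-empty DNA string.
#' @return The canonical rotation (character).
#' @examples
#' canonicalRotation("GGA")     # "AGG"
#' canonicalRotation("TTAGGG")  # "AGGGTT"
#' @export
canonicalRotation <- function(monomer) {
  monomer <- .as_char_seq(monomer)
  m <- nchar(monomer)
  if (m < 1) stop("canonicalRotation: empty monomer")
  dd <- paste0(monomer, monomer)
  rots <- substring(dd, seq_len(m), seq_len(m) + m - 1L)
  min(rots)
}

#' Rank and name satDNA families by abundance
#'
#' Names follow the convention `<tag>Sat<rank>-<monomerLength>` with rank
#' 1 the most abundant family. Ties in proportion are broken by the
#' longer monomer first, then lexicographically by monomer sequence.
#'
#' @param monomers Character vector (or [Biostrings::DNAStringSet]) of
#'   consensus monomers.
#' @param proportions Measured genome proportions, one per monomer.
#' @param species_tag Species abbreviation used in the names.
#' @return A [SatLibrary-class] with families in rank order.
#' @examples
#' lib <- nameFamilies(c(strrep("AC", 50), "TTAGGG"), c(0.02, 0.3), "Sim")
#' familyNames(lib)  # "SimSat1-6" "SimSat2-100"
#' @export
nameFamilies <- function(monomers, proportions, species_tag) {
  monomers <- as.character(monomers)
  monomers <- vapply(monomers, .as_char_seq, character(1), USE.NAMES = FALSE)
  if (length(monomers) != length(proportions))
    stop("nameFamilies: need one proportion per monomer")
  ord <- order(-proportions, -nchar(monomers), monomers)
  monomers <- monomers[ord]
  nms <- sprintf("%sSat%d-%d", species_tag, seq_along(monomers),
                 nchar(monomers))
  if (anyDuplicated(nms))
    stop("nameFamilies: duplicate family names: ",
         paste(nms[duplicated(nms)], collapse = ", "))
  names(monomers) <- nms
  SatLibrary(monomers, speciesTag = species_tag)
}

#' Derive a consensus monomer from a tandem-repetitive contig
#'
#' Convenience wrapper: [detectPeriod()], [extractAndStack()],
#' [majorityConsensus()].
#'
#' @inheritParams detectPeriod
#' @return A list: `call` (the [PeriodCall-class]) and `consensus`
#'   (character, `NA` when no tandem structure was found or fewer than 2
#'   complete monomers fit).
#' @export
contigConsensus <- function(contig, min_period = 2L, max_period = NULL,
                            min_identity = 0.6, id = "contig") {
  call <- detectPeriod(contig, min_period, max_period, min_identity, id)
  if (is.na(call@period))
    return(list(call = call, consensus = NA_character_))
  stack <- extractAndStack(contig, call@period, call@phase)
  if (length(stack) < 2)
    return(list(call = call, consensus = NA_character_))
  list(call = call, consensus = majorityConsensus(stack))
}
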