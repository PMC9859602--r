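#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString readDNAStringSet writeXStringSet
#'   reverseComplement pairwiseAlignment nucleotideSubstitutionMatrix PDict
#'   vwhichPDict alignedPattern alignedSubject width pattern subject score
#' @importFrom IRanges IRanges start end
#' @importFrom GenomicRanges GRanges reduce findOverlaps
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom stats median pt rgamma runif sd setNames cor
#' @importFrom utils read.delim write.table
NULL

#' SatLibrary: a named collection of satellite DNA consensus monomers
#'
#' Holds the consensus monomer of each satDNA family together with its
#' library metadata: rank (1 = most abundant), monomer length and A+T
#' fraction. Family names follow the field convention
#' \code{<speciesTag>Sat<rank>-<monomerLength>}, e.g. \code{TaquSat1-183}.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of consensus monomers, named by
#'   family.
#' @slot info data.frame with columns \code{name}, \code{rank},
#'   \code{monomer_length}, \code{at_fraction}, one row per family, ordered
#'   by rank.
#' @slot speciesTag Short species abbreviation used in family names.
#' @export
setClass("SatLibrary",
  slots = c(seqs = "DNAStringSet", info = "data.frame", speciesTag = "character"))

setValidity("SatLibrary", function(object) {
  info <- object@info
  msgs <- character()
  need <- c("name", "rank", "monomer_length", "at_fraction")
  if (!all(need %in% names(info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (length(object@seqs) != nrow(info))
    msgs <- c(msgs, "seqs and info disagree on the number of families")
  if (nrow(info) > 0) {
    if (!identical(sort(info$rank), seq_len(nrow(info))))
      msgs <- c(msgs, "ranks must be 1..N without gaps")
    if (!identical(names(object@seqs), info$name))
      msgs <- c(msgs, "names(seqs) must equal info$name (same order)")
    if (!all(Biostrings::width(object@seqs) == info$monomer_length))
      msgs <- c(msgs, "monomer_length must equal the monomer widths")
    if (any(info$at_fraction < 0 | info$at_fraction > 1))
      msgs <- c(msgs, "at_fraction must lie in [0, 1]")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' FamilySimSpec: generative parameters for one simulated satDNA family
#'
#' @slot name Family label (filled in by [simSpec()] when empty).
#' @slot monomer Consensus monomer (character, A/C/G/T only).
#' @slot targetProportion Target fraction of the genome occupied by the family.
#' @slot divergence Expected per-site K2P divergence of copies from the
#'   consensus (fraction, 0-0.35).
#' @slot kappa Transition/transversion rate ratio (alpha/beta) of the K2P
#'   substitution process used to mutate copies.
#' @slot nArrays Number of tandem arrays the family is split into.
#' @slot arrayLengthCV Coefficient of variation of array lengths (gamma model).
#' @slot indelRate Per-site insertion/deletion rate applied to copies.
#' @export
setClass("FamilySimSpec",
  slots = c(name = "character", monomer = "character",
            targetProportion = "numeric", divergence = "numeric",
            kappa = "numeric", nArrays = "integer",
            arrayLengthCV = "numeric", indelRate = "numeric"))

setValidity("FamilySimSpec", function(object) {
  msgs <- character()
  if (nchar(object@monomer) < 1) msgs <- c(msgs, "monomer must be non-empty")
  if (grepl("[^ACGT]", object@monomer))
    msgs <- c(msgs, "monomer must contain only A/C/G/T")
  if (object@targetProportion < 0 || object@targetProportion >= 1)
    msgs <- c(msgs, "targetProportion must lie in [0, 1)")
  if (object@divergence < 0 || object@divergence > 0.35)
    msgs <- c(msgs, "divergence must lie in [0, 0.35]")
  if (object@kappa < 0) msgs <- c(msgs, "kappa must be >= 0")
  if (object@nArrays < 1L) msgs <- c(msgs, "nArrays must be >= 1")
  if (object@arrayLengthCV < 0) msgs <- c(msgs, "arrayLengthCV must be >= 0")
  if (object@indelRate < 0 || object@indelRate > 0.1)
    msgs <- c(msgs, "indelRate must lie in [0, 0.1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SimSpec: parameters of one simulated genome + read set
#'
#' The defaults mirror the study conditions this package targets: a
#' low-coverage Illumina survey of a mammalian genome (AT-rich background,
#' 150 bp reads at about 2x coverage), scaled down to a 2 Mb genome so a
#' full simulation runs at the desk.
#'
#' @slot genomeLength Genome length in bp.
#' @slot backgroundAT A+T fraction of the non-repetitive background.
#' @slot families list of [FamilySimSpec-class] objects.
#' @slot readLength Read length in bp (single-end shearing).
#' @slot coverage Fold sequencing coverage.
#' @slot errorRate Flat per-base sequencing substitution error (0 = none).
#' @slot seed Integer seed from which all randomness flows.
#' @export
setClass("SimSpec",
  slots = c(genomeLength = "numeric", backgroundAT = "numeric",
            families = "list", readLength = "integer", coverage = "numeric",
            errorRate = "numeric", seed = "integer"))

setValidity("SimSpec", function(object) {
  msgs <- character()
  if (object@genomeLength <= 0) msgs <- c(msgs, "genomeLength must be > 0")
  if (object@backgroundAT < 0 || object@backgroundAT > 1)
    msgs <- c(msgs, "backgroundAT must lie in [0, 1]")
  if (object@coverage <= 0) msgs <- c(msgs, "coverage must be > 0")
  if (object@readLength > object@genomeLength)
    msgs <- c(msgs, "readLength must not exceed genomeLength")
  if (!all(vapply(object@families, is, logical(1), "FamilySimSpec")))
    msgs <- c(msgs, "families must all be FamilySimSpec objects")
  props <- vapply(object@families, slot, numeric(1), "targetProportion")
  if (length(props) && sum(props) >= 1)
    msgs <- c(msgs, "family proportions must sum to < 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' TruthTable: ground truth emitted alongside a simulated genome
#'
#' @slot perFamily data.frame with one row per family: \code{family},
#'   \code{true_bp}, \code{true_proportion}, \code{n_arrays},
#'   \code{n_copies}, \code{realized_divergence} (mean per-copy K2P vs the
#'   consensus, percent).
#' @slot intervals data.frame of array placements: \code{contig},
#'   \code{family}, \code{start}, \code{end} (0-based half-open).
#' @slot genomeLength Realized genome length in bp.
#' @export
setClass("TruthTable",
  slots = c(perFamily = "data.frame", intervals = "data.frame",
            genomeLength = "numeric"))

setValidity("TruthTable", function(object) {
  iv <- object@intervals
  msgs <- character()
  if (nrow(iv)) {
    if (any(iv$end <= iv$start)) msgs <- c(msgs, "intervals must be non-empty")
    bycontig <- split(iv[order(iv$start), ], iv[order(iv$start), "contig"])
    for (d in bycontig)
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
        msgs <- c(msgs, "intervals must be non-overlapping")
  }
  pf <- object@perFamily
  if (nrow(pf) && any(abs(pf$true_proportion -
                          pf$true_bp / object@genomeLength) > 1e-9))
    msgs <- c(msgs, "true_proportion must equal true_bp / genomeLength")
  if (length(msgs)) paste(unique(msgs), collapse = "; ") else TRUE
})

#' MaskResult: alignments of one sample against a satDNA library
#'
#' The product of [maskSample()] / [maskAssembly()]: one row per retained
#' local alignment, after per-read best-hit resolution, together with the
#' total sampled bp that normalizes all abundances.
#'
#' @slot sample Sample label.
#' @slot totalBp Total sampled bp (sum of read lengths, or assembly length).
#' @slot nReads Number of reads (or windows) in the sample.
#' @slot records data.frame with columns \code{read}, \code{family},
#'   \code{strand}, \code{read_start}, \code{read_end} (0-based half-open),
#'   \code{ref_start}, \code{ref_end}, \code{aligned_cols},
#'   \code{transitions}, \code{transversions}, \code{gap_cols}, \code{k2p}
#'   (percent, NA when saturated), \code{score}, \code{read_length}.
#' @export
setClass("MaskResult",
  slots = c(sample = "character", totalBp = "numeric", nReads = "integer",
            records = "data.frame"))

setValidity("MaskResult", function(object) {
  r <- object@records
  need <- c("read", "family", "strand", "read_start", "read_end",
            "ref_start", "ref_end", "aligned_cols", "transitions",
            "transversions", "gap_cols", "k2p", "score", "read_length")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  msgs <- character()
  if (object@totalBp < 0) msgs <- c(msgs, "totalBp must be >= 0")
  if (nrow(r)) {
    if (isTRUE(any(r$transitions + r$transversions > r$aligned_cols)))
      msgs <- c(msgs, "transitions + transversions must be <= aligned_cols")
    if (isTRUE(any(r$read_end - r$read_start > r$read_length)))
      msgs <- c(msgs, "read span must not exceed read length")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Landscape: a family's abundance binned by integer K2P divergence
#'
#' @slot family Family name.
#' @slot bins Named numeric vector; names are integer divergence bins
#'   (floor of the K2P percentage), values are abundance as percent of the
#'   total sampled bp.
#' @slot totalAbundance Sum of the bins (the family's genome proportion, %).
#' @export
setClass("Landscape",
  slots = c(family = "character", bins = "numeric", totalAbundance = "numeric"))

setValidity("Landscape", function(object) {
  b <- object@bins
  msgs <- character()
  if (any(b < 0)) msgs <- c(msgs, "bin values must be >= 0")
  if (length(b)) {
    k <- suppressWarnings(as.integer(names(b)))
    if (anyNA(k) || any(k < 0) || any(k >= 100))
      msgs <- c(msgs, "bin names must be integers in [0, 100)")
    rel <- abs(sum(b) - object@totalAbundance) /
      max(object@totalAbundance, .Machine$double.eps)
    if (rel > 1e-9)
      msgs <- c(msgs, "bins must sum to totalAbundance")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' PeriodCall: detected tandem periodicity of a contig
#'
#' @slot contig Contig identifier.
#' @slot period Detected fundamental period in bp (NA when no tandem
#'   structure was found).
#' @slot identity Mean base identity at the detected period.
#' @slot phase Offset in `[0, period)` at which monomer windows start.
#' @export
setClass("PeriodCall",
  slots = c(contig = "character", period = "integer", identity = "numeric",
            phase = "integer"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "SatLibrary", function(object) {
  cat(sprintf("SatLibrary '%s' with %d famil%s\n", object@speciesTag,
              nrow(object@info), if (nrow(object@info) == 1) "y" else "ies"))
  if (nrow(object@info)) {
    df <- object@info
    df$at_pct <- round(100 * df$at_fraction, 1)
    print(df[, c("name", "rank", "monomer_length", "at_pct")],
          row.names = FALSE)
  }
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf(
    "SimSpec: %.3g bp genome, background A+T %.1f%%, %d famil%s,\n         %d bp reads at %.2gx coverage (seed %d)\n",
    object@genomeLength, 100 * object@backgroundAT, length(object@families),
    if (length(object@families) == 1) "y" else "ies",
    object@readLength, object@coverage, object@seed))
  for (f in object@families)
    cat(sprintf("  %s: %d bp monomer, %.3g%% of genome, %.3g%% divergence, %d array(s)\n",
                f@name, nchar(f@monomer), 100 * f@targetProportion,
                100 * f@divergence, f@nArrays))
})

setMethod("show", "TruthTable", function(object) {
  cat(sprintf("TruthTable: %d famil%s over a %.4g bp genome\n",
              nrow(object@perFamily),
              if (nrow(object@perFamily) == 1) "y" else "ies",
              object@genomeLength))
  if (nrow(object@perFamily)) print(object@perFamily, row.names = FALSE)
})

setMethod("show", "MaskResult", function(object) {
  cat(sprintf("MaskResult '%s': %d alignment record(s), %d reads, %.4g bp sampled\n",
              object@sample, nrow(object@records), object@nReads,
              object@totalBp))
  if (nrow(object@records)) {
    tab <- sort(table(object@records$family), decreasing = TRUE)
    cat("  records per family:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "Landscape", function(object) {
  cat(sprintf("Landscape of %s: %d bin(s), total abundance %.5f%%\n",
              object@family, length(object@bins), object@totalAbundance))
})

setMethod("show", "PeriodCall", function(object) {
  if (is.na(object@period))
    cat(sprintf("PeriodCall '%s': no tandem structure (best identity %.3f)\n",
                object@contig, object@identity))
  else
    cat(sprintf("PeriodCall '%s': period %d bp, identity %.3f, phase %d\n",
                object@contig, object@period, object@identity, object@phase))
})

## ---- accessors -------------------------------------------------------------

#' Accessors for satkit classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x A satkit object.
#' @return The slot value (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("familyNames", function(x) standardGeneric("familyNames"))
#' @rdname accessors
#' @export
setMethod("familyNames", "SatLibrary", function(x) x@info$name)

#' @rdname accessors
#' @export
setGeneric("monomers", function(x) standardGeneric("monomers"))
#' @rdname accessors
#' @export
setMethod("monomers", "SatLibrary", function(x) x@seqs)

#' @rdname accessors
#' @export
setGeneric("speciesTag", function(x) standardGeneric("speciesTag"))
#' @rdname accessors
#' @export
setMethod("speciesTag", "SatLibrary", function(x) x@speciesTag)

#' @rdname accessors
#' @export
setGeneric("libraryInfo", function(x) standardGeneric("libraryInfo"))
#' @rdname accessors
#' @export
setMethod("libraryInfo", "SatLibrary", function(x) x@info)

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setMethod("records", "MaskResult", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("totalBp", function(x) standardGeneric("totalBp"))
#' @rdname accessors
#' @export
setMethod("totalBp", "MaskResult", function(x) x@totalBp)

#' @rdname accessors
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))
#' @rdname accessors
#' @export
setMethod("sampleLabel", "MaskResult", function(x) x@sample)

#' @rdname accessors
#' @export
setGeneric("landscapeBins", function(x) standardGeneric("landscapeBins"))
#' @rdname accessors
#' @export
setMethod("landscapeBins", "Landscape", function(x) x@bins)

#' @rdname accessors
#' @export
setGeneric("totalAbundance", function(x) standardGeneric("totalAbundance"))
#' @rdname accessors
#' @export
setMethod("totalAbundance", "Landscape", function(x) x@totalAbundance)

#' @rdname accessors
#' @export
setGeneric("truthPerFamily", function(x) standardGeneric("truthPerFamily"))
#' @rdname accessors
#' @export
setMethod("truthPerFamily", "TruthTable", function(x) x@perFamily)

#' @rdname accessors
#' @export
setGeneric("truthIntervals", function(x) standardGeneric("truthIntervals"))
#' @rdname accessors
#' @export
setMethod("truthIntervals", "TruthTable", function(x) x@intervals)

#' @rdname accessors
#' @export
setGeneric("detectedPeriod", function(x) standardGeneric("detectedPeriod"))
#' @rdname accessors
#' @export
setMethod("detectedPeriod", "PeriodCall", function(x) x@period)
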