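## Sequence primitives, FASTA I/O and reference construction.

#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that uppercases
#' sequences, preserves record order and IUPAC ambiguity codes, and reports
#' the offending line for the common malformations (content before the
#' first header, empty header line).
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id (first word of
#'   the header). Empty files yield an empty set.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(Biostrings::DNAStringSet())
  first <- nonblank[1]
  if (!startsWith(lines[first], ">"))
    stop("malformed FASTA at line ", first, ": expected '>' header, got '",
         substr(lines[first], 1, 20), "'")
  empty <- which(trimws(lines) == ">")
  if (length(empty))
    stop("malformed FASTA at line ", empty[1], ": empty header")
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences as FASTA (60-column wrapping)
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

.as_char_seq <- function(seq) {
  if (is(seq, "XStringSet") || is(seq, "XString")) seq <- as.character(seq)
  toupper(seq)
}

#' A+T content of a DNA sequence
#'
#' Computed as (A+T) / (A+C+G+T); IUPAC ambiguity codes are excluded from
#' both numerator and denominator.
#'
#' @param seq A DNA string (character or Biostrings object). Vectorized.
#' @return Fraction in `[0, 1]`.
#' @examples
#' atContent("ACGT")   # 0.5
#' atContent("AANTT")  # 1 (N ignored)
#' @export
atContent <- function(seq) {
  seq <- .as_char_seq(seq)
  vapply(seq, function(s) {
    if (!nzchar(s)) stop("atContent: empty sequence")
    cnt <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                        levels = c("A", "C", "G", "T")))
    tot <- sum(cnt)
    if (tot == 0)
      stop("atContent: no unambiguous bases in sequence")
    unname((cnt[["A"]] + cnt[["T"]]) / tot)
  }, numeric(1), USE.NAMES = !is.null(names(seq)))
}

#' Reverse complement
#'
#' @param seq A DNA string (character, possibly vectorized) using IUPAC codes.
#' @return Character of the same length.
#' @export
revComp <- function(seq) {
  seq <- .as_char_seq(seq)
  bad <- grepl("[^ACGTRYSWKMBDHVN-]", seq)
  if (any(bad)) stop("revComp: non-IUPAC character in sequence")
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(gsub("-", "", seq))))
  unname(out)
}

#' Build the alignment reference for a monomer (dimer / ~200 bp concatemer)
#'
#' Families with monomers of at least half the target length get a dimer
#' (two concatenated copies); small monomers are tiled to the smallest
#' whole-number concatemer reaching the target length. A dimer (or longer
#' concatemer) is used so that reads spanning a monomer junction still
#' align contiguously.
#'
#' @param monomer Consensus monomer (character).
#' @param target_len Target reference length in bp (default 200).
#' @return Character string: the reference sequence.
#' @examples
#' nchar(buildReference(strrep("A", 183)))  # 366 (dimer)
#' nchar(buildReference("TTAGGG"))          # 204 (34 copies)
#' @export
buildReference <- function(monomer, target_len = 200L) {
  monomer <- .as_char_seq(monomer)
  m <- nchar(monomer)
  if (m < 1) stop("buildReference: monomer must be non-empty")
  n <- if (m >= target_len / 2) 2L else as.integer(ceiling(target_len / m))
  strrep(monomer, n)
}

#' The (TTAGGG)50 telomeric reference
#'
#' Fifty tandem copies of the vertebrate telomeric motif (300 bp), the
#' conventional probe for quantifying telomeric repeat abundance alongside
#' a satDNA library.
#'
#' @return A 300 bp character string.
#' @export
telomericReference <- function() strrep("TTAGGG", 50L)

#' Majority-rule consensus of pre-stacked monomers
#'
#' Per-column most frequent symbol over equal-length rows (gap symbol
#' `"-"` allowed). Columns whose majority symbol is the gap are dropped.
#' Ties are broken deterministically in the fixed base order A < C < G < T;
#' a gap never wins a tie against a base.
#'
#' @param aligned_monomers Character vector (>= 2 rows) of equal-length
#'   strings over \{A,C,G,T,-\}.
#' @return Consensus string.
#' @examples
#' majorityConsensus(c("A-GT", "AC-T", "ACGT"))  # "ACGT"
#' majorityConsensus(c("AT", "TA"))              # "AA"
#' @export
majorityConsensus <- function(aligned_monomers) {
  if (length(aligned_monomers) < 2)
    stop("majorityConsensus: need at least 2 rows")
  w <- unique(nchar(aligned_monomers))
  if (length(w) != 1) stop("majorityConsensus: rows must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aligned_monomers), "", fixed = TRUE))
  lev <- c("A", "C", "G", "T", "-")
  cols <- apply(mat, 2, function(col) {
    cnt <- table(factor(col, levels = lev))
    lev[which.max(cnt)]  # which.max takes the first max: A<C<G<T, gap last
  })
  paste(cols[cols != "-"], collapse = "")
}

## ---- SatLibrary construction and I/O --------------------------------------

#' Construct a SatLibrary
#'
#' @param monomers Named character vector or [Biostrings::DNAStringSet] of
#'   consensus monomers, ordered by decreasing abundance (rank 1 first).
#'   When unnamed, names are generated as
#'   \code{<speciesTag>Sat<rank>-<length>}.
#' @param speciesTag Short species abbreviation (e.g. `"Taqu"`).
#' @return A [SatLibrary-class] object.
#' @seealso [nameFamilies()] to rank and name families from measured
#'   proportions.
#' @export
SatLibrary <- function(monomers, speciesTag = "Sim") {
  if (is.character(monomers)) {
    nm <- names(monomers)
    monomers <- Biostrings::DNAStringSet(toupper(monomers))
    names(monomers) <- nm
  }
  n <- length(monomers)
  lens <- Biostrings::width(monomers)
  if (is.null(names(monomers)))
    names(monomers) <- sprintf("%sSat%d-%d", speciesTag, seq_len(n), lens)
  info <- data.frame(
    name = names(monomers),
    rank = seq_len(n),
    monomer_length = lens,
    at_fraction = if (n) unname(atContent(as.character(monomers))) else numeric(),
    stringsAsFactors = FALSE)
  new("SatLibrary", seqs = monomers, info = info, speciesTag = speciesTag)
}

#' Dimer/concatemer reference sequences of a library
#'
#' @param x A [SatLibrary-class].
#' @param target_len Target reference length passed to [buildReference()].
#' @return A [Biostrings::DNAStringSet] named by family.
#' @export
referenceSeqs <- function(x, target_len = 200L) {
  stopifnot(is(x, "SatLibrary"))
  refs <- vapply(as.character(x@seqs), buildReference, character(1),
                 target_len = target_len)
  out <- Biostrings::DNAStringSet(refs)
  names(out) <- familyNames(x)
  out
}

#' Read / write library metadata as TSV
#'
#' Columns: name, rank, monomer_length, at_fraction, monomer.
#'
#' @param x A [SatLibrary-class].
#' @param path TSV path.
#' @return `writeLibraryTsv`: `path` invisibly; `readLibraryTsv`: a
#'   [SatLibrary-class].
#' @export
writeLibraryTsv <- function(x, path) {
  stopifnot(is(x, "SatLibrary"))
  df <- x@info
  df$monomer <- as.character(x@seqs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLibraryTsv
#' @param speciesTag Species tag for the reconstructed library; when `NULL`
#'   it is inferred from the first family name.
#' @export
readLibraryTsv <- function(path, speciesTag = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- df[order(df$rank), , drop = FALSE]
  if (is.null(speciesTag))
    speciesTag <- sub("Sat.*$", "", df$name[1])
  seqs <- Biostrings::DNAStringSet(toupper(df$monomer))
  names(seqs) <- df$name
  new("SatLibrary", seqs = seqs,
      info = df[, c("name", "rank", "monomer_length", "at_fraction")],
      speciesTag = speciesTag)
}
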