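## Read-vs-library alignment and Kimura 2-parameter divergence.
##
## Stands in for a RepeatMasker "-a" run: reads (or assembly windows) are
## aligned to dimer/concatemer references by seed-and-extend local
## alignment, substitutions are classified into transitions and
## transversions, and each record gets a K2P divergence.

#' Kimura 2-parameter distance
#'
#' \eqn{K = -\frac{1}{2}\ln\left[(1-2P-Q)\sqrt{1-2Q}\right]} where P and Q
#' are the observed transition and transversion proportions. Always at
#' least the p-distance P+Q, with equality only at zero.
#'
#' @param P Transition proportion (A<->G, C<->T), in `[0, 1)`.
#' @param Q Transversion proportion, in `[0, 1)`. Vectorized.
#' @return Distance as a fraction (callers scale to percent).
#' @examples
#' k2pDistance(0.1, 0.05)  # 0.17018
#' @export
k2pDistance <- function(P, Q) {
  if (any(P < 0) || any(Q < 0)) stop("k2pDistance: P and Q must be >= 0")
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0) || any(w2 <= 0))
    stop("k2pDistance: saturated divergence (1-2P-Q and 1-2Q must be > 0)")
  -0.5 * log(w1 * sqrt(w2))
}

.TS_PAIRS <- c("AG", "GA", "CT", "TC")

#' Count transitions and transversions in a gapped alignment
#'
#' Gap columns and columns containing ambiguity codes are excluded from
#' `aligned_cols`. Transitions are A<->G and C<->T; every other mismatch
#' is a transversion.
#'
#' @param aligned_read,aligned_ref Equal-length gapped strings (gap `"-"`).
#' @return Named integer vector: `transitions`, `transversions`,
#'   `aligned_cols`, `gap_cols`.
#' @examples
#' countSubstitutions("AG", "GA")      # 2 transitions
#' countSubstitutions("A-CT", "AGCA")  # 1 transversion, 1 gap column
#' @export
countSubstitutions <- function(aligned_read, aligned_ref) {
  a <- strsplit(toupper(aligned_read), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(aligned_ref), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("countSubstitutions: aligned strings must have equal length")
  gap <- a == "-" | b == "-"
  ok <- !gap & a %in% .BASES & b %in% .BASES
  mism <- ok & a != b
  ts <- sum(paste0(a[mism], b[mism]) %in% .TS_PAIRS)
  c(transitions = as.integer(ts),
    transversions = as.integer(sum(mism) - ts),
    aligned_cols = as.integer(sum(ok)),
    gap_cols = as.integer(sum(gap)))
}

.SUBMAT <- NULL
.submat <- function(match = 1, mismatch = -1) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)
}

#' Optimal local alignment of a read against a reference
#'
#' Smith-Waterman local alignment under the default scoring
#' match +1 / mismatch -1, with affine gaps costing 4 for the first gap
#' base and 1 for each additional base. Backed by
#' [Biostrings::pairwiseAlignment()].
#'
#' @param read,reference DNA strings (character or Biostrings objects).
#' @param match,mismatch Match/mismatch scores.
#' @param gap_open Cost of a length-1 gap.
#' @param gap_extend Additional cost per extra gap base.
#' @return A list: `score`, `aligned_read`, `aligned_ref` (gapped
#'   strings), `read_span` and `ref_span` (0-based half-open integer
#'   pairs).
#' @export
localAlign <- function(read, reference, match = 1, mismatch = -1,
                       gap_open = 4, gap_extend = 1) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(.as_char_seq(read)),
    Biostrings::DNAString(.as_char_seq(reference)),
    type = "local", substitutionMatrix = .submat(match, mismatch),
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  list(score = Biostrings::score(aln),
       aligned_read = as.character(Biostrings::alignedPattern(aln)),
       aligned_ref = as.character(Biostrings::alignedSubject(aln)),
       read_span = c(start(pr) - 1L, end(pr)),
       ref_span = c(start(sr) - 1L, end(sr)))
}

# Shared alignment core: align each candidate read index against one
# subject, returning a records data.frame (possibly empty).
.align_batch <- function(reads, idx, subject, family, strand,
                         min_score, min_aligned) {
  if (!length(idx)) return(NULL)
  aln <- Biostrings::pairwiseAlignment(
    reads[idx], subject, type = "local",
    substitutionMatrix = .submat(), gapOpening = 3, gapExtension = 1)
  sc <- Biostrings::score(aln)
  keep <- sc >= min_score
  if (!any(keep)) return(NULL)
  aln <- aln[keep]; idx <- idx[keep]; sc <- sc[keep]
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  n <- length(idx)
  ts <- tv <- ac <- gc <- integer(n)
  for (i in seq_len(n)) {
    cnt <- countSubstitutions(pa[i], sa[i])
    ts[i] <- cnt[["transitions"]]; tv[i] <- cnt[["transversions"]]
    ac[i] <- cnt[["aligned_cols"]]; gc[i] <- cnt[["gap_cols"]]
  }
  ok <- ac >= min_aligned
  if (!any(ok)) return(NULL)
  data.frame(
    read = names(reads)[idx][ok], family = family, strand = strand,
    read_start = start(pr)[ok] - 1L, read_end = end(pr)[ok],
    ref_start = start(sr)[ok] - 1L, ref_end = end(sr)[ok],
    aligned_cols = ac[ok], transitions = ts[ok], transversions = tv[ok],
    gap_cols = gc[ok], k2p = NA_real_, score = sc[ok],
    read_length = Biostrings::width(reads)[idx][ok],
    stringsAsFactors = FALSE)
}

.k2p_percent <- function(ts, tv, cols) {
  P <- ts / cols; Q <- tv / cols
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  out <- rep(NA_real_, length(P))
  ok <- w1 > 0 & w2 > 0
  out[ok] <- 100 * (-0.5 * log(w1[ok] * sqrt(w2[ok])))
  out
}

# Greedy per-read best-hit resolution: records sorted by descending score
# (ties: lower family rank), accepted when their read span does not
# overlap an already accepted span of the same read.
.resolve_overlaps <- function(rec, rank_of) {
  if (nrow(rec) < 2) return(rec)
  rec <- rec[order(rec$read, -rec$score, rank_of[rec$family]), , drop = FALSE]
  keep <- logical(nrow(rec))
  i <- 1
  while (i <= nrow(rec)) {
    j <- i
    while (j < nrow(rec) && rec$read[j + 1] == rec$read[i]) j <- j + 1
    acc_s <- numeric(0); acc_e <- numeric(0)
    for (k in i:j) {
      s <- rec$read_start[k]; e <- rec$read_end[k]
      if (!length(acc_s) || all(e <= acc_s | s >= acc_e)) {
        keep[k] <- TRUE
        acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
      }
    }
    i <- j + 1
  }
  rec[keep, , drop = FALSE]
}

# All k-length substrings of x (character) as a character vector.
.kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character())
  substring(x, seq_len(n - k + 1L), k:n)
}

#' Align a read sample against a satDNA library
#'
#' Seed-and-extend masking: a (read, family, strand) candidate is formed
#' whenever the read shares at least one exact k-mer with that strand of
#' the family's dimer/concatemer reference; candidates are aligned with
#' Smith-Waterman local alignment (match +1 / mismatch -1 / gap 4+1);
#' records below `min_score` or `min_aligned` are dropped; per read,
#' overlapping hits are resolved to the highest-scoring family (ties:
#' lower family rank).
#'
#' @param reads A [Biostrings::DNAStringSet] (or named character vector).
#' @param library A [SatLibrary-class].
#' @param k_seed Exact-match seed length for the k-mer prefilter.
#' @param min_score Minimum alignment score.
#' @param min_aligned Minimum aligned (ungapped, unambiguous) columns.
#' @param target_len Reference target length (see [buildReference()]).
#' @param sample Sample label stored in the result.
#' @return A [MaskResult-class].
#' @export
maskSample <- function(reads, library, k_seed = 12L, min_score = 18,
                       min_aligned = 30L, target_len = 200L,
                       sample = "sample") {
  stopifnot(is(library, "SatLibrary"))
  if (is.character(reads)) {
    nm <- names(reads)
    reads <- Biostrings::DNAStringSet(toupper(reads))
    names(reads) <- nm
  }
  if (is.null(names(reads)) && length(reads))
    names(reads) <- sprintf("read_%06d", seq_along(reads))
  S4Vectors::mcols(reads) <- NULL
  empty <- data.frame(
    read = character(), family = character(), strand = character(),
    read_start = integer(), read_end = integer(), ref_start = integer(),
    ref_end = integer(), aligned_cols = integer(), transitions = integer(),
    transversions = integer(), gap_cols = integer(), k2p = numeric(),
    score = numeric(), read_length = integer(), stringsAsFactors = FALSE)
  total_bp <- sum(Biostrings::width(reads))
  if (!length(reads) || !nrow(library@info))
    return(new("MaskResult", sample = sample, totalBp = as.numeric(total_bp),
               nReads = length(reads), records = empty))
  refs <- referenceSeqs(library, target_len)
  fams <- familyNames(library)
  # k-mer table over both strands of every reference
  kms <- list(); km_fam <- integer(); km_strand <- character()
  for (i in seq_along(refs)) {
    fwd <- unique(.kmers(as.character(refs[[i]]), k_seed))
    rev <- unique(.kmers(revComp(as.character(refs[[i]])), k_seed))
    fwd <- fwd[!grepl("[^ACGT]", fwd)]
    rev <- rev[!grepl("[^ACGT]", rev)]
    kms <- c(kms, list(fwd), list(rev))
    km_fam <- c(km_fam, rep(i, 2))
    km_strand <- c(km_strand, "+", "-")
  }
  all_kmers <- unlist(kms)
  group <- rep(seq_along(kms), lengths(kms))  # pattern -> (family, strand)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(all_kmers))
  hits <- Biostrings::vwhichPDict(pd, reads)
  rec_list <- list()
  for (g in seq_along(kms)) {
    fam_i <- km_fam[g]; strand <- km_strand[g]
    gset <- which(group == g)
    idx <- which(vapply(hits, function(h) any(h %in% gset), logical(1)))
    subject <- if (strand == "+") refs[[fam_i]] else
      Biostrings::reverseComplement(refs[[fam_i]])
    rec_list[[length(rec_list) + 1L]] <-
      .align_batch(reads, idx, subject, fams[fam_i], strand,
                   min_score, min_aligned)
  }
  rec <- do.call(rbind, rec_list)
  if (is.null(rec) || !nrow(rec)) rec <- empty
  else {
    rank_of <- setNames(library@info$rank, library@info$name)
    rec <- .resolve_overlaps(rec, rank_of)
    rec$k2p <- .k2p_percent(rec$transitions, rec$transversions,
                            rec$aligned_cols)
    rownames(rec) <- NULL
  }
  new("MaskResult", sample = sample, totalBp = as.numeric(total_bp),
      nReads = length(reads), records = rec)
}

#' Mask an assembly by overlapping windows
#'
#' The assembly is cut into overlapping windows treated as reads; hits are
#' mapped back to assembly coordinates and, per family, deduplicated to a
#' non-overlapping set (greedy by score) so that window overlap does not
#' double-count abundance. `totalBp` is the assembly length, so
#' [genomeProportion()] measures the assembly fraction occupied by each
#' family.
#'
#' @param assembly A [Biostrings::DNAStringSet] (or named character) of
#'   contigs/scaffolds.
#' @param library A [SatLibrary-class].
#' @param window,overlap Window size and overlap in bp.
#' @param ... Passed to [maskSample()] (`k_seed`, `min_score`, ...).
#' @param sample Sample label.
#' @return A [MaskResult-class]; records carry extra columns `contig` and
#'   `genome_start`/`genome_end` (0-based half-open assembly coordinates).
#' @export
maskAssembly <- function(assembly, library, window = 1000L, overlap = 150L,
                         ..., sample = "assembly") {
  if (is.character(assembly)) {
    nm <- names(assembly)
    assembly <- Biostrings::DNAStringSet(toupper(assembly))
    names(assembly) <- if (is.null(nm))
      sprintf("contig_%d", seq_along(assembly)) else nm
  }
  if (is.null(names(assembly)))
    names(assembly) <- sprintf("contig_%d", seq_along(assembly))
  step <- window - overlap
  stopifnot(step > 0)
  wseq <- character(); wcontig <- character(); wstart <- integer()
  for (i in seq_along(assembly)) {
    L <- Biostrings::width(assembly)[i]
    if (L < 1) next
    starts <- seq(1L, max(1L, L - overlap), by = step)
    ends <- pmin(starts + window - 1L, L)
    keep <- ends - starts + 1L >= min(window, L)  # drop runt tail windows
    keep[1] <- TRUE
    s <- as.character(Biostrings::DNAStringSet(assembly[[i]],
                                               start = starts[keep],
                                               end = ends[keep]))
    wseq <- c(wseq, s)
    wcontig <- c(wcontig, rep(names(assembly)[i], sum(keep)))
    wstart <- c(wstart, starts[keep] - 1L)
  }
  if (!length(wseq)) {
    mr <- maskSample(character(), library, ..., sample = sample)
    mr@totalBp <- as.numeric(sum(Biostrings::width(assembly)))
    return(mr)
  }
  n_windows <- length(wseq)
  # iterative masking: windows can be much longer than the reference, so
  # after each round the unaligned flanks of hit windows are re-masked
  # (multiple local hits per window, BLAST-HSP style)
  frag_seq <- wseq; frag_contig <- wcontig; frag_off <- wstart
  rec_rounds <- list()
  for (round in 1:10) {
    if (!length(frag_seq)) break
    names(frag_seq) <- sprintf("frag%d_%06d", round, seq_along(frag_seq))
    mrr <- maskSample(frag_seq, library, ..., sample = sample)
    rr <- mrr@records
    if (!nrow(rr)) break
    fidx <- match(rr$read, names(frag_seq))
    rr$contig <- frag_contig[fidx]
    rr$genome_start <- frag_off[fidx] + rr$read_start
    rr$genome_end <- frag_off[fidx] + rr$read_end
    rec_rounds[[round]] <- rr
    new_seq <- character(); new_contig <- character(); new_off <- integer()
    for (i in unique(fidx)) {
      spans <- rr[fidx == i, c("read_start", "read_end"), drop = FALSE]
      spans <- spans[order(spans$read_start), , drop = FALSE]
      L <- nchar(frag_seq[[i]])
      gaps_s <- c(0L, spans$read_end)
      gaps_e <- c(spans$read_start, L)
      for (g in seq_along(gaps_s)) {
        if (gaps_e[g] - gaps_s[g] >= 30L) {
          new_seq <- c(new_seq, substr(frag_seq[[i]], gaps_s[g] + 1L,
                                       gaps_e[g]))
          new_contig <- c(new_contig, frag_contig[i])
          new_off <- c(new_off, frag_off[i] + gaps_s[g])
        }
      }
    }
    frag_seq <- new_seq; frag_contig <- new_contig; frag_off <- new_off
  }
  rec <- do.call(rbind, rec_rounds)
  if (!is.null(rec) && nrow(rec)) {
    # per-family genomic dedup: greedy by score over overlapping hits
    keep <- logical(nrow(rec))
    for (f in unique(rec$family)) {
      ii <- which(rec$family == f)
      ii <- ii[order(-rec$score[ii])]
      gr <- GenomicRanges::GRanges()
      for (k in ii) {
        cand <- GenomicRanges::GRanges(rec$contig[k],
          IRanges::IRanges(rec$genome_start[k] + 1L, rec$genome_end[k]))
        if (!length(GenomicRanges::findOverlaps(cand, gr))) {
          keep[k] <- TRUE
          gr <- c(gr, cand)
        }
      }
    }
    rec <- rec[keep, , drop = FALSE]
    rownames(rec) <- NULL
  } else {
    rec <- maskSample(character(), library)@records
    rec$contig <- character(); rec$genome_start <- integer()
    rec$genome_end <- integer()
  }
  new("MaskResult", sample = sample,
      totalBp = as.numeric(sum(Biostrings::width(assembly))),
      nReads = n_windows, records = rec)
}

## ---- TSV and RepeatMasker-align I/O ---------------------------------------

#' Write / read mask records as TSV
#'
#' RepeatMasker-`.out`-flavoured table: 1-based inclusive coordinates and
#' strand coded `+`/`C`, plus the K2P column. Header comment lines carry
#' the sample label, total sampled bp and read count so a
#' [MaskResult-class] round-trips.
#'
#' @param mask A [MaskResult-class].
#' @param path TSV path.
#' @return `writeMaskTsv`: `path` invisibly; `readMaskTsv`: a
#'   [MaskResult-class].
#' @export
writeMaskTsv <- function(mask, path) {
  stopifnot(is(mask, "MaskResult"))
  rec <- mask@records
  out <- data.frame(
    score = rec$score, k2p = round(rec$k2p, 4), read = rec$read,
    read_begin = rec$read_start + 1L, read_end = rec$read_end,
    strand = ifelse(rec$strand == "-", "C", "+"), family = rec$family,
    ref_begin = rec$ref_start + 1L, ref_end = rec$ref_end,
    aligned_cols = rec$aligned_cols, transitions = rec$transitions,
    transversions = rec$transversions, gap_cols = rec$gap_cols,
    read_length = rec$read_length, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sample=%s", mask@sample),
               sprintf("# total_sampled_bp=%.0f", mask@totalBp),
               sprintf("# n_reads=%d", mask@nReads)), con)
  suppressWarnings(utils::write.table(out, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' @rdname writeMaskTsv
#' @export
readMaskTsv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  getv <- function(key, default) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, "="), "", m[1]) else default
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  rec <- data.frame(
    read = as.character(df$read), family = df$family,
    strand = ifelse(df$strand == "C", "-", "+"),
    read_start = df$read_begin - 1L, read_end = df$read_end,
    ref_start = df$ref_begin - 1L, ref_end = df$ref_end,
    aligned_cols = df$aligned_cols, transitions = df$transitions,
    transversions = df$transversions, gap_cols = df$gap_cols,
    k2p = df$k2p, score = df$score, read_length = df$read_length,
    stringsAsFactors = FALSE)
  new("MaskResult", sample = getv("sample", "sample"),
      totalBp = as.numeric(getv("total_sampled_bp", NA)),
      nReads = as.integer(getv("n_reads", nrow(rec))), records = rec)
}

#' Read a RepeatMasker `.align` file into a MaskResult
#'
#' Tolerant parser for the alignment dump produced by RepeatMasker's `-a`
#' option (optionally annotated with `Kimura=` lines by its divergence
#' script), so genuine RepeatMasker output can feed the statistics layer.
#' Only header lines and Kimura annotations are used; per-block gapped
#' sequences are skipped. Substitution counts are not recoverable from
#' headers, so `transitions`/`transversions` are NA and `k2p` comes from
#' the `Kimura=` annotation (falling back to the header's divergence
#' percentage).
#'
#' @param path Path to a `.align` file.
#' @param total_bp Total sampled bp of the masked sample (required for
#'   abundance; when NA, proportions are not meaningful).
#' @param read_length Read length used, when uniform; per-read lengths are
#'   taken as `read_end + left_over` from the header when available.
#' @param sample Sample label.
#' @return A [MaskResult-class].
#' @export
readRepeatMaskerAlign <- function(path, total_bp = NA_real_,
                                  read_length = NA_integer_,
                                  sample = "rmalign") {
  lines <- readLines(path, warn = FALSE)
  # header: score div del ins query qbegin qend (qleft) strand/C repeat ...
  hdr_re <- paste0("^\\s*\\d+\\s+[0-9.]+\\s+[0-9.]+\\s+[0-9.]+\\s+\\S+",
                   "\\s+\\d+\\s+\\d+\\s+\\(\\d+\\)")
  hi <- grep(hdr_re, lines)
  recs <- list()
  for (j in seq_along(hi)) {
    tok <- strsplit(trimws(lines[hi[j]]), "\\s+")[[1]]
    # token 9 is 'C' for reverse hits, else already the repeat name
    strand <- if (tok[9] %in% c("C", "c")) "-" else "+"
    fam <- if (strand == "-") tok[10] else tok[9]
    qleft <- as.integer(gsub("[()]", "", tok[8]))
    block_end <- if (j < length(hi)) hi[j + 1] - 1 else length(lines)
    kim <- grep("Kimura", lines[hi[j]:block_end], value = TRUE)
    k2p <- if (length(kim))
      suppressWarnings(as.numeric(sub(".*[:=]\\s*", "", kim[1])))
    else as.numeric(tok[2])
    qb <- as.integer(tok[6]); qe <- as.integer(tok[7])
    recs[[j]] <- data.frame(
      read = tok[5], family = fam, strand = strand,
      read_start = qb - 1L, read_end = qe,
      ref_start = NA_integer_, ref_end = NA_integer_,
      aligned_cols = qe - qb + 1L,
      transitions = NA_integer_, transversions = NA_integer_,
      gap_cols = NA_integer_, k2p = k2p, score = as.numeric(tok[1]),
      read_length = if (!is.na(read_length)) as.integer(read_length)
                    else qe + qleft,
      stringsAsFactors = FALSE)
  }
  rec <- if (length(recs)) do.call(rbind, recs) else
    maskSample(character(), SatLibrary(character()))@records
  new("MaskResult", sample = sample, totalBp = as.numeric(total_bp),
      nReads = length(unique(rec$read)), records = rec)
}
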