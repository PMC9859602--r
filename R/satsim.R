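## Synthetic-data generator: genomes with tandem satDNA arrays of
## controlled abundance/divergence, sheared reads, and ground truth.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All satsim randomness flows through this.
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Random i.i.d. DNA background
#'
#' Bases are drawn independently with P(A) = P(T) = `at_fraction`/2 and
#' P(C) = P(G) = (1 - `at_fraction`)/2, emulating the base composition of
#' a non-repetitive genomic background.
#'
#' @param length Sequence length in bp (0 allowed).
#' @param at_fraction Target A+T fraction in `[0, 1]`.
#' @param seed Integer seed (same seed, same string).
#' @return Character string of the requested length.
#' @export
generateBackground <- function(length, at_fraction, seed = 1L) {
  if (length < 0) stop("generateBackground: length must be >= 0")
  if (at_fraction < 0 || at_fraction > 1)
    stop("generateBackground: at_fraction must lie in [0, 1]")
  if (length == 0) return("")
  withSeed(seed, {
    p <- c(at_fraction / 2, (1 - at_fraction) / 2,
           (1 - at_fraction) / 2, at_fraction / 2)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
          collapse = "")
  })
}

#' Random monomer sequence
#'
#' Convenience generator for library monomers with a given A+T content.
#'
#' @inheritParams generateBackground
#' @export
randomMonomer <- function(length, at_fraction = 0.5, seed = 1L)
  generateBackground(length, at_fraction, seed)

# Solve the K2P forward model: transition/transversion substitution
# probabilities (P, Q) whose estimated K2P distance has expectation
# `divergence`, for transition/transversion rate ratio kappa = alpha/beta.
# With s = beta * t: Q = (1 - exp(-8s))/2, P = (1 - 2 exp(-4s(kappa+1)) +
# exp(-8s))/4 and K = 2 s (kappa + 2).
k2pForwardPQ <- function(divergence, kappa) {
  if (divergence < 0 || divergence >= 0.75)
    stop("k2pForwardPQ: divergence must lie in [0, 0.75)")
  if (kappa < 0) stop("k2pForwardPQ: kappa must be >= 0")
  s <- divergence / (2 * (kappa + 2))
  Q <- 0.5 * (1 - exp(-8 * s))
  P <- 0.25 * (1 - 2 * exp(-4 * s * (kappa + 1)) + exp(-8 * s))
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop("k2pForwardPQ: no valid (P, Q) for divergence ", divergence,
         " at kappa ", kappa)
  c(P = P, Q = Q)
}

# Core mutator: returns the mutated integer-coded sequence plus realized
# substitution counts. code: 1=A 2=C 3=G 4=T.
.mutate_codes <- function(code, P, Q, indel_rate) {
  n <- length(code)
  ts_partner <- c(3L, 4L, 1L, 2L)   # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)          # A->C, C->A, G->C, T->A
  tv2 <- c(4L, 3L, 4L, 3L)          # A->T, C->G, G->T, T->G
  u <- runif(n)
  out <- code
  i1 <- u < P
  i2 <- !i1 & u < P + Q / 2
  i3 <- !i1 & !i2 & u < P + Q
  out[i1] <- ts_partner[code[i1]]
  out[i2] <- tv1[code[i2]]
  out[i3] <- tv2[code[i3]]
  ts <- sum(i1); tv <- sum(i2) + sum(i3)
  if (indel_rate > 0) {
    v <- runif(length(out))
    del <- v < indel_rate / 2
    ins <- v >= indel_rate / 2 & v < indel_rate
    if (any(ins)) {
      pieces <- as.list(out)
      ins_at <- which(ins)
      newb <- sample.int(4L, length(ins_at), replace = TRUE)
      for (k in seq_along(ins_at))
        pieces[[ins_at[k]]] <- c(out[ins_at[k]], newb[k])
      out <- unlist(pieces)
      del <- rep(FALSE, length(out))  # deletions drawn before expansion only
      del[which(v < indel_rate / 2)] <- TRUE
    }
    out <- out[!del[seq_along(out)]]
  }
  list(codes = out, transitions = ts, transversions = tv,
       sites = n)
}

.BASES <- c("A", "C", "G", "T")

#' Mutate a monomer under the Kimura 2-parameter model
#'
#' Each site is substituted independently with transition probability P and
#' transversion probability Q solving the K2P forward model, so that the
#' K2P distance estimated between input and output has expectation
#' `divergence`. Optionally applies simple indels.
#'
#' @param monomer Character string over A/C/G/T.
#' @param divergence Expected K2P divergence (fraction, < 0.75).
#' @param kappa Transition/transversion rate ratio (alpha/beta).
#' @param indel_rate Per-site indel probability (half insertions, half
#'   deletions).
#' @param seed Integer seed.
#' @return Mutated character string.
#' @examples
#' mutateMonomer("ACGTACGT", divergence = 0)  # unchanged
#' @export
mutateMonomer <- function(monomer, divergence, kappa = 2, indel_rate = 0,
                          seed = 1L) {
  monomer <- .as_char_seq(monomer)
  if (grepl("[^ACGT]", monomer))
    stop("mutateMonomer: monomer must contain only A/C/G/T")
  if (divergence == 0 && indel_rate == 0) return(monomer)
  pq <- k2pForwardPQ(divergence, kappa)
  withSeed(seed, {
    code <- match(strsplit(monomer, "", fixed = TRUE)[[1]], .BASES)
    m <- .mutate_codes(code, pq[["P"]], pq[["Q"]], indel_rate)
    paste(.BASES[m$codes], collapse = "")
  })
}

#' Construct a FamilySimSpec
#'
#' @param monomer Consensus monomer (character over A/C/G/T).
#' @param targetProportion Target genome fraction (e.g. 0.01 for 1%).
#' @param divergence Expected K2P divergence of copies from the consensus
#'   (fraction in `[0, 0.35]`).
#' @param kappa Transition/transversion rate ratio; 2 is a typical
#'   mammalian value.
#' @param nArrays Number of tandem arrays.
#' @param arrayLengthCV Coefficient of variation of array lengths.
#' @param indelRate Per-site indel rate for copies.
#' @param name Optional family label.
#' @return A [FamilySimSpec-class].
#' @export
familySimSpec <- function(monomer, targetProportion, divergence,
                          kappa = 2, nArrays = 1L, arrayLengthCV = 0.5,
                          indelRate = 0, name = NA_character_) {
  new("FamilySimSpec", name = as.character(name),
      monomer = .as_char_seq(monomer),
      targetProportion = targetProportion, divergence = divergence,
      kappa = kappa, nArrays = as.integer(nArrays),
      arrayLengthCV = arrayLengthCV, indelRate = indelRate)
}

#' Construct a SimSpec
#'
#' Defaults mirror a scaled-down low-coverage mammalian survey: a 2 Mb
#' genome with 59% A+T background, 150 bp single-end reads at 2x coverage.
#'
#' @param families List of [FamilySimSpec-class] objects.
#' @param genomeLength Genome length in bp.
#' @param backgroundAT Background A+T fraction.
#' @param readLength Read length in bp.
#' @param coverage Fold coverage.
#' @param errorRate Flat per-base sequencing substitution error.
#' @param seed Integer master seed.
#' @return A [SimSpec-class].
#' @export
simSpec <- function(families, genomeLength = 2e6, backgroundAT = 0.59,
                    readLength = 150L, coverage = 2, errorRate = 0,
                    seed = 1L) {
  families <- lapply(seq_along(families), function(i) {
    f <- families[[i]]
    if (is.na(f@name))
      f@name <- sprintf("SimSat%d-%d", i, nchar(f@monomer))
    f
  })
  new("SimSpec", genomeLength = genomeLength, backgroundAT = backgroundAT,
      families = families, readLength = as.integer(readLength),
      coverage = coverage, errorRate = errorRate, seed = as.integer(seed))
}

#' Build a genome carrying tandem satDNA arrays, with ground truth
#'
#' For each family, the target bp (proportion x genome length) is split
#' into `nArrays` arrays whose lengths follow a gamma law with the given
#' CV (minimum one monomer). Every monomer copy is mutated independently
#' from the consensus (star phylogeny). Arrays are placed in random order
#' at random positions, separated from each other and from the genome ends
#' by at least 2 read lengths of background.
#'
#' @param spec A [SimSpec-class].
#' @return A list with elements `genome` (a single-record
#'   [Biostrings::DNAStringSet] named `"genome"`) and `truth`
#'   (a [TruthTable-class]).
#' @export
buildGenome <- function(spec) {
  stopifnot(is(spec, "SimSpec"))
  withSeed(spec@seed, {
    G <- spec@genomeLength
    minGap <- 2L * spec@readLength
    arrays <- list(); arr_fam <- character()
    pf <- data.frame(family = character(), true_bp = numeric(),
                     true_proportion = numeric(), n_arrays = integer(),
                     n_copies = integer(), realized_divergence = numeric(),
                     stringsAsFactors = FALSE)
    for (f in spec@families) {
      mlen <- nchar(f@monomer)
      target_bp <- f@targetProportion * G
      copies_total <- max(f@nArrays, round(target_bp / mlen))
      if (f@arrayLengthCV > 0 && f@nArrays > 1) {
        w <- rgamma(f@nArrays, shape = 1 / f@arrayLengthCV^2)
        w <- w / sum(w)
      } else w <- rep(1 / f@nArrays, f@nArrays)
      copies <- pmax(1L, round(w * copies_total))
      # fix rounding so the copy total (hence bp) hits the target
      resid <- copies_total - sum(copies)
      while (resid != 0) {
        j <- if (resid > 0) which.max(copies) else which(copies > 1)[
          which.max(copies[copies > 1])]
        step <- sign(resid)
        copies[j] <- copies[j] + step
        resid <- resid - step
      }
      code0 <- match(strsplit(f@monomer, "", fixed = TRUE)[[1]], .BASES)
      pq <- k2pForwardPQ(f@divergence, f@kappa)
      fam_bp <- 0; ksum <- 0; kn <- 0
      for (ci in copies) {
        chunks <- character(ci)
        for (j in seq_len(ci)) {
          m <- .mutate_codes(code0, pq[["P"]], pq[["Q"]], f@indelRate)
          chunks[j] <- paste(.BASES[m$codes], collapse = "")
          p_hat <- m$transitions / m$sites
          q_hat <- m$transversions / m$sites
          k <- tryCatch(k2pDistance(p_hat, q_hat), error = function(e) NA_real_)
          if (!is.na(k)) { ksum <- ksum + k; kn <- kn + 1 }
        }
        a <- paste(chunks, collapse = "")
        arrays[[length(arrays) + 1L]] <- a
        arr_fam <- c(arr_fam, f@name)
        fam_bp <- fam_bp + nchar(a)
      }
      pf <- rbind(pf, data.frame(
        family = f@name, true_bp = fam_bp, true_proportion = NA_real_,
        n_arrays = f@nArrays, n_copies = copies_total,
        realized_divergence = if (kn) 100 * ksum / kn else NA_real_,
        stringsAsFactors = FALSE))
    }
    arr_len <- if (length(arrays)) nchar(unlist(arrays)) else integer()
    nA <- length(arrays)
    B <- G - sum(arr_len)
    if (B < (nA + 1) * minGap)
      stop("buildGenome: infeasible packing; reduce family proportions, ",
           "the number of arrays, or increase genomeLength")
    ord <- if (nA > 1) sample.int(nA) else seq_len(nA)
    extra <- B - (nA + 1) * minGap
    gaps <- rep(minGap, nA + 1)
    if (nA > 0 && extra > 0) {
      cuts <- sort(runif(nA))
      add <- floor(diff(c(0, cuts, 1)) * extra)
      add[nA + 1] <- add[nA + 1] + (extra - sum(add))
      gaps <- gaps + add
    } else if (nA == 0) gaps <- B
    bg <- generateBackground(B, spec@backgroundAT,
                             seed = sample.int(.Machine$integer.max, 1))
    pieces <- character(2 * nA + 1)
    iv <- data.frame(contig = character(), family = character(),
                     start = numeric(), end = numeric(),
                     stringsAsFactors = FALSE)
    bgpos <- 1; gpos <- 0
    for (i in seq_len(nA)) {
      pieces[2 * i - 1] <- substr(bg, bgpos, bgpos + gaps[i] - 1)
      bgpos <- bgpos + gaps[i]; gpos <- gpos + gaps[i]
      a <- arrays[[ord[i]]]
      pieces[2 * i] <- a
      iv <- rbind(iv, data.frame(contig = "genome", family = arr_fam[ord[i]],
                                 start = gpos, end = gpos + nchar(a),
                                 stringsAsFactors = FALSE))
      gpos <- gpos + nchar(a)
    }
    pieces[2 * nA + 1] <- substr(bg, bgpos, nchar(bg))
    genome <- paste(pieces, collapse = "")
    pf$true_proportion <- pf$true_bp / nchar(genome)
    gset <- Biostrings::DNAStringSet(genome)
    names(gset) <- "genome"
    list(genome = gset,
         truth = new("TruthTable", perFamily = pf, intervals = iv,
                     genomeLength = nchar(genome)))
  })
}

#' Shear a genome into uniform single-end reads
#'
#' Draws `round(coverage * genomeLength / readLength)` reads with uniform
#' start positions, each strand equiprobable. Optionally applies a flat
#' per-base substitution error.
#'
#' @param genome Character string or single-record
#'   [Biostrings::DNAStringSet].
#' @param read_length Read length in bp.
#' @param coverage Fold coverage.
#' @param seed Integer seed.
#' @param error_rate Flat per-base substitution error (0 = none).
#' @return A [Biostrings::DNAStringSet] of reads named `read_000001` ...;
#'   metadata columns `start` (0-based genome offset) and `strand`.
#' @export
shearReads <- function(genome, read_length = 150L, coverage = 2,
                       seed = 1L, error_rate = 0) {
  if (!is.character(genome)) genome <- as.character(genome)[1]
  L <- nchar(genome)
  read_length <- as.integer(read_length)
  if (read_length > L) stop("shearReads: read_length exceeds genome length")
  N <- round(coverage * L / read_length)
  withSeed(seed, {
    starts <- sample.int(L - read_length + 1L, N, replace = TRUE)
    minus <- runif(N) < 0.5
    seqs <- substring(genome, starts, starts + read_length - 1L)
    out <- Biostrings::DNAStringSet(seqs)
    if (any(minus))
      out[minus] <- Biostrings::reverseComplement(out[minus])
    if (error_rate > 0) {
      chars <- strsplit(as.character(out), "", fixed = TRUE)
      chars <- lapply(chars, function(v) {
        hit <- runif(length(v)) < error_rate
        if (any(hit)) {
          cur <- match(v[hit], .BASES)
          v[hit] <- .BASES[(cur - 1L + sample.int(3L, sum(hit),
                                                  replace = TRUE)) %% 4L + 1L]
        }
        v
      })
      out <- Biostrings::DNAStringSet(vapply(chars, paste, character(1),
                                             collapse = ""))
    }
    names(out) <- sprintf("read_%06d", seq_len(N))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      start = starts - 1L, strand = ifelse(minus, "-", "+"))
    out
  })
}

#' Simulate a set of species sharing one satDNA library
#'
#' Implements the library-hypothesis scenario: every species' genome is
#' built from the same monomer pool, with per-species abundance
#' multipliers (0 = family absent in that species) and optional divergence
#' offsets.
#'
#' @param base_spec A [SimSpec-class] describing the reference species.
#' @param perturbations Named list (one element per species). Each element
#'   is a list with `multipliers` (numeric, one per family) and optionally
#'   `div_offset` (numeric, added to each family's divergence, clamped at
#'   0).
#' @param seed Integer seed; per-species seeds are derived from it.
#' @return Named list (per species) of lists with elements `label`,
#'   `reads` ([Biostrings::DNAStringSet]) and `truth`
#'   ([TruthTable-class]). Families dropped by a zero multiplier appear in
#'   the truth table with `true_bp = 0`.
#' @export
simulateSpeciesSet <- function(base_spec, perturbations, seed = 1L) {
  stopifnot(is(base_spec, "SimSpec"))
  labels <- names(perturbations)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("simulateSpeciesSet: perturbations must be a named list")
  out <- vector("list", length(labels))
  names(out) <- labels
  for (i in seq_along(labels)) {
    p <- perturbations[[i]]
    mult <- p$multipliers
    if (length(mult) != length(base_spec@families))
      stop("simulateSpeciesSet: need one multiplier per family")
    if (any(mult < 0)) stop("simulateSpeciesSet: multipliers must be >= 0")
    offs <- if (is.null(p$div_offset)) 0 else p$div_offset
    offs <- rep_len(offs, length(mult))
    fams <- list(); dropped <- list()
    for (j in seq_along(base_spec@families)) {
      f <- base_spec@families[[j]]
      if (mult[j] == 0) { dropped[[length(dropped) + 1L]] <- f; next }
      f@targetProportion <- f@targetProportion * mult[j]
      f@divergence <- min(0.35, max(0, f@divergence + offs[j]))
      fams[[length(fams) + 1L]] <- f
    }
    sp <- base_spec
    sp@families <- fams
    sp@seed <- as.integer((seed + 7919 * i) %% .Machine$integer.max)
    built <- buildGenome(sp)
    reads <- shearReads(built$genome, sp@readLength, sp@coverage,
                        seed = sp@seed + 1L, error_rate = sp@errorRate)
    truth <- built$truth
    if (length(dropped)) {
      add <- data.frame(
        family = vapply(dropped, slot, character(1), "name"),
        true_bp = 0, true_proportion = 0,
        n_arrays = 0L, n_copies = 0L, realized_divergence = NA_real_,
        stringsAsFactors = FALSE)
      pf <- rbind(truth@perFamily, add)
      ordnm <- vapply(base_spec@families, slot, character(1), "name")
      pf <- pf[match(ordnm, pf$family), , drop = FALSE]
      truth@perFamily <- pf
    }
    out[[i]] <- list(label = labels[i], reads = reads, truth = truth)
  }
  out
}

#' Write the truth table as TSV
#'
#' @param truth A [TruthTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTruthTsv <- function(truth, path) {
  stopifnot(is(truth, "TruthTable"))
  utils::write.table(truth@perFamily, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
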