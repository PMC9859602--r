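## Cross-sample satellitome comparison: log2 abundance ratios, presence
## calls, Spearman rank correlation and the exact Wilcoxon signed-rank
## test.

#' log2 abundance ratio between two samples
#'
#' `log2(sample / reference)`, the conventional fold-change scale for
#' comparing a family's abundance across samples.
#'
#' @param sample_abundance,reference_abundance Abundances (both > 0).
#'   Vectorized.
#' @return Numeric.
#' @export
log2Ratio <- function(sample_abundance, reference_abundance) {
  if (any(sample_abundance <= 0) || any(reference_abundance <= 0))
    stop("log2Ratio: abundances must be > 0 (absent families have no ",
         "numeric ratio; see presenceCall)")
  log2(sample_abundance / reference_abundance)
}

#' Classify an abundance change from its log2 ratio
#'
#' `"lower"` when the ratio is strictly below `-threshold`, `"higher"`
#' when strictly above `+threshold`, `"similar"` otherwise (the
#' boundaries themselves count as similar).
#'
#' @param log2_ratio Numeric (vectorized).
#' @param threshold Fold-change threshold on the log2 scale (default 0.6,
#'   i.e. about 1.5-fold).
#' @return Character vector over \{"lower", "similar", "higher"\}.
#' @export
classifyAbundanceChange <- function(log2_ratio, threshold = 0.6) {
  ifelse(log2_ratio < -threshold, "lower",
         ifelse(log2_ratio > threshold, "higher", "similar"))
}

#' Presence call for a family in a sample
#'
#' A family is called present when its abundance and supporting read
#' count both clear (configurable) floors. "Presence" has no standard
#' quantitative definition in satellitome surveys; these defaults are
#' deliberately permissive and reported alongside results.
#'
#' @param abundance Genome proportion (percent). Vectorized.
#' @param n_reads Number of reads aligned to the family.
#' @param min_abundance,min_reads Floors for a present call.
#' @return Logical.
#' @export
presenceCall <- function(abundance, n_reads, min_abundance = 1e-4,
                         min_reads = 10L) {
  abundance >= min_abundance & n_reads >= min_reads
}

#' Spearman rank correlation (t approximation)
#'
#' Pearson correlation of average ranks (ties receive their mean rank),
#' with a two-sided p-value from the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 4).
#' @return List with `rho`, `p_value` and `n`.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("spearmanRho: lengths differ")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearmanRho: need at least 4 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("spearmanRho: correlation undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

# Exact distribution of twice the positive-rank sum, as counts over
# 0..sum(r2), via the generating function prod_i (1 + z^{r2_i}).
.signed_rank_counts <- function(r2) {
  S <- sum(r2)
  counts <- numeric(S + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(S + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test (two-sided)
#'
#' Enumerates the full permutation distribution of the positive-rank sum
#' over all 2^n sign assignments of the |difference| ranks, with average
#' ranks for tied magnitudes (which the classical exact tables cannot
#' handle). The two-sided p-value is the probability, under that
#' symmetric distribution, of a rank sum at least as far from its mean as
#' observed. Zero differences are dropped; when all differences are zero
#' the p-value is 1 by convention.
#'
#' @param x,y Paired numeric vectors.
#' @param max_n Maximum number of non-zero pairs for exact enumeration.
#' @return List with `statistic` (positive-rank sum W+), `p_value` and
#'   `n` (non-zero pairs).
#' @export
wilcoxonSignedRankExact <- function(x, y, max_n = 25L) {
  if (length(x) != length(y))
    stop("wilcoxonSignedRankExact: lengths differ")
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1, n = 0L))
  if (n > max_n)
    stop("wilcoxonSignedRankExact: n = ", n, " exceeds max_n = ", max_n,
         " for exact enumeration")
  r <- rank(abs(d))          # average ranks for ties
  r2 <- as.integer(round(2 * r))  # doubled ranks are integers
  W2 <- sum(r2[d > 0])
  counts <- .signed_rank_counts(r2)
  S <- sum(r2)               # distribution is symmetric about S/2
  k <- seq(0, S)
  dev <- abs(2 * k - S)      # |W2 - S/2| doubled to stay integral
  p <- sum(counts[dev >= abs(2 * W2 - S)]) / 2^n
  list(statistic = W2 / 2, p_value = min(1, p), n = n)
}

#' Compare masked samples against a reference sample
#'
#' Assembles the per-(family, sample) comparative table: abundance, mean
#' K2P divergence, read count, presence call, and log2 ratio versus the
#' reference sample (NA unless the family is present in both). Families
#' are ordered by their rank in the shared library.
#'
#' @param masks Named list of [MaskResult-class] objects, all masked with
#'   the same library.
#' @param reference Name (in `masks`) of the reference sample.
#' @param library The shared [SatLibrary-class].
#' @param min_abundance,min_reads Presence thresholds (see
#'   [presenceCall()]).
#' @return data.frame with columns `family`, `sample`, `abundance`,
#'   `mean_k2p`, `n_reads`, `presence`, `log2_ratio`, plus a per-sample
#'   summary in `attr(, "sample_summary")` (families present, total
#'   satellitome %).
#' @export
compareSamples <- function(masks, reference, library,
                           min_abundance = 1e-4, min_reads = 10L) {
  stopifnot(is(library, "SatLibrary"))
  if (is.null(names(masks)))
    names(masks) <- vapply(masks, sampleLabel, character(1))
  if (!reference %in% names(masks))
    stop("compareSamples: reference sample '", reference, "' not found")
  fams <- familyNames(library)
  per_sample <- lapply(masks, function(m) {
    fs <- familyStats(m, library)
    fs$presence <- presenceCall(fs$genome_proportion, fs$n_reads,
                                min_abundance, min_reads)
    fs
  })
  ref <- per_sample[[reference]]
  out <- do.call(rbind, lapply(names(masks), function(s) {
    fs <- per_sample[[s]]
    lr <- rep(NA_real_, nrow(fs))
    both <- fs$presence & ref$presence
    lr[both] <- log2(fs$genome_proportion[both] /
                     ref$genome_proportion[both])
    data.frame(family = fs$name, sample = s,
               abundance = fs$genome_proportion,
               mean_k2p = fs$kimura_divergence, n_reads = fs$n_reads,
               presence = fs$presence, log2_ratio = lr,
               stringsAsFactors = FALSE)
  }))
  out$family <- factor(out$family, levels = fams)
  out <- out[order(out$sample != reference, out$sample, out$family), ]
  out$family <- as.character(out$family)
  rownames(out) <- NULL
  summ <- do.call(rbind, lapply(names(masks), function(s) {
    fs <- per_sample[[s]]
    data.frame(sample = s, n_present = sum(fs$presence),
               total_pct = sum(fs$genome_proportion),
               stringsAsFactors = FALSE)
  }))
  attr(out, "sample_summary") <- summ
  out
}
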