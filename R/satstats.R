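## Per-family satellitome statistics: genome proportion, divergence
## landscape, TSI, DivPeak, RSP, and summary tables.

.fam_records <- function(mask, family) {
  rec <- mask@records
  rec[rec$family == family, , drop = FALSE]
}

#' Genome proportion of a family (read percentages)
#'
#' 100 x (aligned read bp assigned to the family) / (total sampled bp).
#' Aligned bp is the read-span width of each retained alignment record.
#'
#' @param mask A [MaskResult-class].
#' @param family Family name; when `NULL`, a named vector over all
#'   families present in the records.
#' @return Percent (numeric).
#' @export
genomeProportion <- function(mask, family = NULL) {
  stopifnot(is(mask, "MaskResult"))
  if (mask@totalBp <= 0) stop("genomeProportion: totalBp must be > 0")
  rec <- mask@records
  bp <- rec$read_end - rec$read_start
  if (is.null(family)) {
    out <- tapply(bp, rec$family, sum)
    return(100 * unlist(as.list(out)) / mask@totalBp)
  }
  100 * sum(bp[rec$family == family]) / mask@totalBp
}

#' Divergence landscape of a family
#'
#' Each alignment record contributes its aligned read bp (as a percentage
#' of the total sampled bp) to the integer bin `floor(k2p %)` - the
#' binning convention of RepeatMasker-style repeat landscapes. Records
#' with saturated (NA) divergence are excluded.
#'
#' @param mask A [MaskResult-class].
#' @param family Family name.
#' @return A [Landscape-class].
#' @export
landscape <- function(mask, family) {
  stopifnot(is(mask, "MaskResult"))
  rec <- .fam_records(mask, family)
  rec <- rec[!is.na(rec$k2p), , drop = FALSE]
  if (!nrow(rec))
    return(new("Landscape", family = family, bins = setNames(numeric(), character()),
               totalAbundance = 0))
  bin <- floor(rec$k2p)
  w <- 100 * (rec$read_end - rec$read_start) / mask@totalBp
  agg <- tapply(w, bin, sum)
  bins <- setNames(as.numeric(agg), names(agg))
  bins <- bins[order(as.integer(names(bins)))]
  new("Landscape", family = family, bins = bins,
      totalAbundance = sum(bins))
}

#' Tandem structure index (TSI)
#'
#' The fraction of reads aligned to the family whose aligned span covers
#' at least 89% of the read's length ("internal/pure" satDNA reads) among
#' all reads aligned to the family ("internal + external/mixed"). Reads,
#' not alignment records, are counted: a read with several partial hits
#' to the family counts once, as external (its best single span decides).
#' High TSI indicates long, clustered arrays.
#'
#' @param mask A [MaskResult-class].
#' @param family Family name.
#' @param min_cover Internal-read threshold (fraction of read length).
#' @return Fraction in `[0, 1]`; `NA` when no read aligns to the family.
#' @export
tsi <- function(mask, family, min_cover = 0.89) {
  rec <- .fam_records(mask, family)
  if (!nrow(rec)) return(NA_real_)
  span <- rec$read_end - rec$read_start
  best <- tapply(span / rec$read_length, rec$read, max)
  sum(best >= min_cover) / length(best)
}

#' Divergence peak (DivPeak)
#'
#' The integer divergence bin where the landscape is maximal; ties go to
#' the smallest bin. A proxy for the time since the family's last
#' expansion/homogenization.
#'
#' @param ls A [Landscape-class].
#' @return Integer bin.
#' @export
divPeak <- function(ls) {
  stopifnot(is(ls, "Landscape"))
  if (!length(ls@bins)) stop("divPeak: empty landscape")
  as.integer(names(ls@bins)[which.max(ls@bins)])  # bins sorted by bin
}

#' Relative peak size (RSP)
#'
#' The family abundance within +/-2 divergence bins of the peak
#' (a 5-bin window, truncated at bin 0) divided by the family's total
#' abundance. A proxy for homogenization: 1 means the whole family sits
#' in the peak.
#'
#' @param ls A [Landscape-class].
#' @param peak Peak bin; defaults to [divPeak()] of the same landscape.
#' @return Fraction in (0, 1].
#' @export
rsp <- function(ls, peak = divPeak(ls)) {
  stopifnot(is(ls, "Landscape"))
  if (ls@totalAbundance == 0) stop("rsp: landscape has zero abundance")
  k <- as.integer(names(ls@bins))
  win <- k >= max(0L, peak - 2L) & k <= peak + 2L
  sum(ls@bins[win]) / ls@totalAbundance
}

#' Classify a landscape shape
#'
#' Operationalization of the qualitative lepto/meso/platykurtic labels
#' used for satellite landscapes: leptokurtic (recent expansion) when the
#' peak is sharp and at low divergence, platykurtic (degenerated) when the
#' peak is flat and at high divergence, mesokurtic otherwise. Thresholds
#' are tunable.
#'
#' @param ls A [Landscape-class], or `NULL` when `peak`/`rsp_value` are
#'   given directly.
#' @param peak,rsp_value DivPeak and RSP; computed from `ls` by default.
#' @param rsp_lepto,divp_lepto Leptokurtic thresholds: RSP >= 0.8 and
#'   DivPeak <= 5.
#' @param rsp_platy,divp_platy Platykurtic thresholds: RSP <= 0.3 and
#'   DivPeak >= 15.
#' @return One of `"leptokurtic"`, `"mesokurtic"`, `"platykurtic"`.
#' @export
classifyLandscape <- function(ls = NULL, peak = divPeak(ls),
                              rsp_value = rsp(ls, peak),
                              rsp_lepto = 0.8, divp_lepto = 5,
                              rsp_platy = 0.3, divp_platy = 15) {
  if (rsp_value >= rsp_lepto && peak <= divp_lepto) "leptokurtic"
  else if (rsp_value <= rsp_platy && peak >= divp_platy) "platykurtic"
  else "mesokurtic"
}

#' Per-family statistics table (Table-1 shaped)
#'
#' Assembles the per-family row statistics from a masked sample: genome
#' proportion, monomer length, A+T percentage, mean K2P divergence
#' (aligned-bp weighted), TSI, DivPeak and RSP.
#'
#' @param mask A [MaskResult-class].
#' @param library A [SatLibrary-class]; rows appear in rank order.
#' @param min_cover TSI internal-read threshold.
#' @return data.frame with one row per family (families with no aligned
#'   reads get zero proportion and NA divergence statistics).
#' @export
familyStats <- function(mask, library, min_cover = 0.89) {
  stopifnot(is(mask, "MaskResult"), is(library, "SatLibrary"))
  info <- library@info
  rows <- lapply(seq_len(nrow(info)), function(i) {
    fam <- info$name[i]
    rec <- .fam_records(mask, fam)
    prop <- genomeProportion(mask, fam)
    if (nrow(rec)) {
      bp <- rec$read_end - rec$read_start
      ok <- !is.na(rec$k2p)
      mean_k2p <- if (any(ok)) sum(rec$k2p[ok] * bp[ok]) / sum(bp[ok])
                  else NA_real_
      ls <- landscape(mask, fam)
      dp <- if (length(ls@bins)) divPeak(ls) else NA_integer_
      rv <- if (length(ls@bins)) rsp(ls, dp) else NA_real_
    } else {
      mean_k2p <- NA_real_; dp <- NA_integer_; rv <- NA_real_
    }
    data.frame(
      name = fam, genome_proportion = prop,
      monomer_length = info$monomer_length[i],
      at_percent = 100 * info$at_fraction[i],
      kimura_divergence = mean_k2p,
      tsi = tsi(mask, fam, min_cover),
      divpeak = dp, rsp = rv,
      n_reads = length(unique(rec$read)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary statistics of a per-family table
#'
#' Arithmetic mean, sample SD (n-1; 0 by convention for a single row) and
#' median (midpoint of the two middle order statistics for even n) of
#' each numeric column. Rounding is left to the report layer.
#'
#' @param rows data.frame of per-family statistics (>= 1 row).
#' @param columns Columns to summarize; defaults to all numeric columns.
#' @return data.frame with rows `Mean`, `SD`, `Median`.
#' @export
summarizeTable <- function(rows, columns = NULL) {
  if (!nrow(rows)) stop("summarizeTable: need at least one row")
  if (is.null(columns))
    columns <- names(rows)[vapply(rows, is.numeric, logical(1))]
  stat <- function(f0) vapply(columns, function(cn) {
    x <- rows[[cn]]; x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else f0(x)
  }, numeric(1))
  out <- rbind(
    Mean = stat(mean),
    SD = stat(function(x) if (length(x) < 2) 0 else sd(x)),
    Median = stat(median))
  data.frame(statistic = rownames(out), out, row.names = NULL,
             check.names = FALSE)
}

#' Full satellitome table: per-family rows + summary + total
#'
#' @inheritParams familyStats
#' @return A list of class `"SatellitomeTable"` with elements `rows`
#'   (per-family data.frame), `summary` (Mean/SD/Median over monomer
#'   length, A+T, divergence, TSI, DivPeak, RSP) and `total` (summed
#'   genome proportion, %).
#' @export
satellitomeTable <- function(mask, library, min_cover = 0.89) {
  rows <- familyStats(mask, library, min_cover)
  summ <- summarizeTable(rows, c("monomer_length", "at_percent",
                                 "kimura_divergence", "tsi", "divpeak",
                                 "rsp"))
  structure(list(rows = rows, summary = summ,
                 total = sum(rows$genome_proportion)),
            class = "SatellitomeTable")
}

#' @export
print.SatellitomeTable <- function(x, ...) {
  cat(sprintf("SatellitomeTable: %d families, total %.5f%% of the genome\n",
              nrow(x$rows), x$total))
  print(x$rows, row.names = FALSE, digits = 4)
  cat("--\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
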