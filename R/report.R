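## Report layer: packaged reference table, table rendering, and the
## end-to-end pipeline driver.

#' The Talpa aquitania satellitome summary table
#'
#' The published per-family summary of the *Talpa aquitania* satellitome
#' shipped with the package as a 17-entry TSV: 15 named satDNA families
#' with the TaquSat4 family split into its 437 bp and 466 bp monomer
#' variants, plus the telomeric (TTAGGG)n repeat. Columns: family name,
#' genome proportion (%), monomer length (bp), A+T percentage, mean K2P
#' divergence (%), TSI, DivPeak and RSP. Summary statistics over this
#' table treat all 17 entries as ordinary rows.
#'
#' @return data.frame with 17 rows.
#' @export
taquTable1 <- function() {
  path <- system.file("extdata", "taqu_table1.tsv", package = "satkit",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.round_cols <- function(df, digits) {
  for (cn in names(digits))
    if (cn %in% names(df) && is.numeric(df[[cn]]))
      df[[cn]] <- round(df[[cn]], digits[[cn]])
  df
}

#' Render a satellitome table as TSV (and optionally markdown)
#'
#' Columns in the conventional order (proportion, monomer length, A+T,
#' divergence, TSI, DivPeak, RSP), proportions at 5 decimals, the other
#' statistics at 2, with Mean/SD/Median footer rows and a Total line for
#' the genome proportion.
#'
#' @param x A `SatellitomeTable` (from [satellitomeTable()]) or a plain
#'   per-family data.frame shaped like [familyStats()] output.
#' @param path Output TSV path, or `NULL` to return lines invisibly.
#' @param markdown Also return a markdown rendering.
#' @return Character vector of TSV lines, invisibly.
#' @export
renderTable <- function(x, path = NULL, markdown = FALSE) {
  if (inherits(x, "SatellitomeTable")) {
    rows <- x$rows; summ <- x$summary; total <- x$total
  } else {
    rows <- x
    summ <- if (nrow(rows)) summarizeTable(rows, intersect(
      c("monomer_length", "at_percent", "kimura_divergence", "tsi",
        "divpeak", "rsp"), names(rows))) else NULL
    total <- sum(rows$genome_proportion)
  }
  cols <- c("name", "genome_proportion", "monomer_length", "at_percent",
            "kimura_divergence", "tsi", "divpeak", "rsp")
  cols <- intersect(cols, names(rows))
  digits <- list(genome_proportion = 5, at_percent = 2,
                 kimura_divergence = 2, tsi = 2, divpeak = 2, rsp = 2,
                 monomer_length = 2)
  body <- .round_cols(rows[, cols, drop = FALSE], digits)
  lines <- paste(cols, collapse = "\t")
  fmt_row <- function(v) paste(vapply(v, function(z)
    if (is.na(z)) "" else as.character(z), character(1)), collapse = "\t")
  for (i in seq_len(nrow(body))) lines <- c(lines, fmt_row(body[i, ]))
  if (nrow(rows)) {
    lines <- c(lines, fmt_row(c("Total", format(round(total, 5)),
                                rep("", length(cols) - 2))))
    for (i in seq_len(nrow(summ))) {
      sr <- summ[i, , drop = FALSE]
      vals <- vapply(cols, function(cn) {
        if (cn == "name") sr$statistic
        else if (cn %in% names(sr)) as.character(round(sr[[cn]], 2))
        else ""
      }, character(1))
      lines <- c(lines, paste(vals, collapse = "\t"))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  if (markdown) {
    md <- vapply(lines, function(l)
      paste0("| ", gsub("\t", " | ", l), " |"), character(1))
    md <- append(md, paste0("|", paste(rep("---|", length(cols)),
                                       collapse = "")), after = 1)
    attr(lines, "markdown") <- unname(md)
  }
  invisible(lines)
}

#' Read back a rendered satellitome table
#'
#' @param path TSV written by [renderTable()].
#' @return List: `rows` (per-family data.frame), `summary`, `total`.
#' @export
readRenderedTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  is_footer <- df$name %in% c("Total", "Mean", "SD", "Median")
  rows <- df[!is_footer, , drop = FALSE]
  rownames(rows) <- NULL
  total <- if (any(df$name == "Total"))
    as.numeric(df$genome_proportion[df$name == "Total"]) else NA_real_
  summ <- df[df$name %in% c("Mean", "SD", "Median"), , drop = FALSE]
  rownames(summ) <- NULL
  list(rows = rows, summary = summ, total = total)
}

#' Run the simulate -> mask -> stats pipeline
#'
#' Builds a genome from `spec`, shears reads, masks them against the
#' library of the spec's own consensus monomers (named by true abundance
#' rank), computes the satellitome table and writes all deliverables to
#' `out_dir`: `genome.fasta`, `reads.fasta`, `truth.tsv`, `mask.tsv`,
#' `table.tsv` and one `landscapes/<family>.csv` per family. Outputs are
#' byte-deterministic for a fixed spec (all randomness flows from
#' `spec@seed`).
#'
#' @param spec A [SimSpec-class].
#' @param out_dir Output directory (created if needed).
#' @param species_tag Tag used to name families.
#' @param ... Masking parameters passed to [maskSample()].
#' @param write_reads Write the (possibly large) reads FASTA.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list: `library`, `truth`, `mask`, `table`.
#' @export
runPipeline <- function(spec, out_dir, species_tag = "Sim", ...,
                        write_reads = TRUE, quiet = FALSE) {
  stopifnot(is(spec, "SimSpec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  say("satkit: simulating genome (seed ", spec@seed, ", ",
      spec@genomeLength, " bp)")
  built <- buildGenome(spec)
  writeFasta(built$genome, file.path(out_dir, "genome.fasta"))
  writeTruthTsv(built$truth, file.path(out_dir, "truth.tsv"))
  reads <- shearReads(built$genome, spec@readLength, spec@coverage,
                      seed = spec@seed + 1L, error_rate = spec@errorRate)
  if (write_reads) writeFasta(reads, file.path(out_dir, "reads.fasta"))
  mono <- vapply(spec@families, slot, character(1), "monomer")
  prop <- vapply(spec@families, slot, numeric(1), "targetProportion")
  lib <- nameFamilies(mono, prop, species_tag)
  writeLibraryTsv(lib, file.path(out_dir, "library.tsv"))
  say("satkit: masking ", length(reads), " reads against ",
      nrow(libraryInfo(lib)), " families")
  mask <- maskSample(reads, lib, ..., sample = species_tag)
  writeMaskTsv(mask, file.path(out_dir, "mask.tsv"))
  tab <- satellitomeTable(mask, lib)
  renderTable(tab, file.path(out_dir, "table.tsv"))
  ldir <- file.path(out_dir, "landscapes")
  dir.create(ldir, showWarnings = FALSE)
  for (fam in familyNames(lib)) {
    ls <- landscape(mask, fam)
    df <- data.frame(bin = as.integer(names(landscapeBins(ls))),
                     abundance = unname(landscapeBins(ls)))
    utils::write.table(df, file.path(ldir, paste0(fam, ".csv")),
                       sep = ",", quote = FALSE, row.names = FALSE)
  }
  say("satkit: wrote ", out_dir)
  invisible(list(library = lib, truth = built$truth, mask = mask,
                 table = tab))
}
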