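# Hand-built MaskResult for direct-formula tests of the statistics layer.
mk_records <- function(read, family, span, read_length = 150L,
                       k2p = 0, score = NULL) {
  n <- length(read)
  data.frame(
    read = read, family = family, strand = rep("+", n),
    read_start = rep(0L, n), read_end = as.integer(span),
    ref_start = rep(0L, n), ref_end = as.integer(span),
    aligned_cols = as.integer(span), transitions = rep(0L, n),
    transversions = rep(0L, n), gap_cols = rep(0L, n),
    k2p = rep_len(k2p, n),
    score = if (is.null(score)) as.numeric(span) else rep_len(score, n),
    read_length = rep_len(as.integer(read_length), n),
    stringsAsFactors = FALSE)
}

mk_mask <- function(records, total_bp, n_reads = length(unique(records$read)),
                    sample = "test") {
  methods::new("MaskResult", sample = sample, totalBp = as.numeric(total_bp),
               nReads = as.integer(n_reads), records = records)
}

mk_landscape <- function(bins, family = "fam") {
  methods::new("Landscape", family = family,
               bins = setNames(as.numeric(bins), names(bins)),
               totalAbundance = sum(bins))
}
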