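# Read quality control. Reproduces the raw -> norm -> adapter -> enzyme ->
# range -> clean accounting ladder used to summarize MethylRAD libraries:
#   raw     sequenced reads
#   norm    after depth-equalizing subsampling across libraries
#   adapter after adapter trimming (reads reduced to nothing are dropped)
#   enzyme  reads containing a recognition motif on either strand
#   range   reads within the size-selected fragment length range (13-17)
#   clean   reads additionally passing the N and base-quality filters
# percent = clean / norm * 100, rounded half-up to two decimals.

#' Subsample reads to a target depth
#'
#' Uniform sampling without replacement when the input exceeds the
#' target; identity (with a warning) when it does not. Used to equalize
#' library depth across samples before filtering.
#'
#' @param reads read data.frame (`id`, `seq`, `qual`).
#' @param target_depth non-negative target read count.
#' @param seed RNG seed for reproducibility (optional).
#' @return subsampled read data.frame.
#' @export
subsample_to_norm <- function(reads, target_depth, seed = NULL) {
  if (target_depth < 0) stop("target_depth must be non-negative")
  n <- nrow(reads)
  if (n <= target_depth) {
    if (n < target_depth) {
      warning(sprintf("only %d reads available for target depth %d",
                      n, target_depth))
    }
    return(reads)
  }
  idx <- if (is.null(seed)) {
    sample.int(n, target_depth)
  } else {
    local_seed(seed, sample.int(n, target_depth))
  }
  reads[sort(idx), , drop = FALSE]
}

#' Trim 3' adapter sequence from reads
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter, requiring a minimum overlap of `min_overlap` bases and zero
#' mismatches. Quality strings are trimmed in step. Reads without a
#' qualifying overlap are returned unchanged.
#'
#' @param reads read data.frame.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum suffix/prefix overlap in bases.
#' @return read data.frame with trimmed `seq`/`qual`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L) {
  if (!nzchar(adapter)) stop("adapter_seq must be non-empty")
  alen <- nchar(adapter)
  n <- nchar(reads$seq)
  cut <- integer(nrow(reads))  # bases to remove from the 3' end
  for (i in seq_len(nrow(reads))) {
    for (L in seq(min(alen, n[i]), min_overlap)) {
      if (L < min_overlap) break
      if (substr(reads$seq[i], n[i] - L + 1L, n[i]) ==
          substr(adapter, 1L, L)) {
        cut[i] <- L
        break
      }
    }
  }
  keep_len <- n - cut
  reads$seq <- substr(reads$seq, 1L, keep_len)
  reads$qual <- substr(reads$qual, 1L, keep_len)
  reads
}

# TRUE for reads containing any expanded motif in the read or its
# reverse complement. The FspEI motif set {CCGG, CCAGG, CCTGG} is closed
# under reverse complement, so a forward regex over the set suffices.
has_enzyme_site <- function(seq, classes = c("CCGG", "CCWGG")) {
  motifs <- unlist(motif_classes(classes), use.names = FALSE)
  motifs <- unique(c(motifs, revcomp(motifs)))
  grepl(paste(motifs, collapse = "|"), seq)
}

#' Filter reads and build the QC accounting ladder
#'
#' A read survives to the clean set iff it contains a recognition motif
#' (either orientation), its length lies in `len_range`, its fraction of
#' ambiguous bases is <= `max_n_frac` (strictly more is discarded), and
#' the fraction of bases with Phred quality below `min_q` is strictly
#' less than `max_lowq_frac` (at or above is discarded). The three
#' per-read predicates are independent, so the clean set does not depend
#' on filter order; the ladder records losses in the stated stage order.
#'
#' @param reads trimmed read data.frame.
#' @param classes motif classes defining "enzyme reads".
#' @param len_range inclusive fragment length range, default `c(13, 17)`.
#' @param max_n_frac maximum tolerated N fraction (exclusive bound 0.08).
#' @param min_q Phred threshold defining a low-quality base (30).
#' @param max_lowq_frac low-quality base fraction at which a read is
#'   discarded (inclusive bound 0.15).
#' @return list with `reads` (clean set) and `counts`, a named vector
#'   with elements `input`, `enzyme`, `range`, `clean`.
#' @export
filter_reads <- function(reads, classes = c("CCGG", "CCWGG"),
                         len_range = c(13L, 17L),
                         max_n_frac = 0.08, min_q = 30L,
                         max_lowq_frac = 0.15) {
  if (nrow(reads) == 0L) {
    return(list(reads = reads,
                counts = c(input = 0L, enzyme = 0L, range = 0L, clean = 0L)))
  }
  enzyme_ok <- has_enzyme_site(reads$seq, classes)
  r1 <- reads[enzyme_ok, , drop = FALSE]
  len <- nchar(r1$seq)
  range_ok <- len >= len_range[1] & len <= len_range[2]
  r2 <- r1[range_ok, , drop = FALSE]
  clean_ok <- frac_n(r2$seq) <= max_n_frac &
    frac_below_q(r2$qual, min_q) < max_lowq_frac
  r3 <- r2[clean_ok, , drop = FALSE]
  list(reads = r3,
       counts = c(input = nrow(reads), enzyme = nrow(r1),
                  range = nrow(r2), clean = nrow(r3)))
}

#' Assemble a QC ledger row
#'
#' Validates the monotone ladder and computes the percent column
#' (clean / norm x 100, rounded half-up to two decimals).
#'
#' @param raw,norm,adapter,enzyme,range,clean stage read counts.
#' @param sample sample identifier.
#' @return one-row data.frame of class `qc_ledger`.
#' @export
qc_ledger <- function(sample, raw, norm, adapter, enzyme, range, clean) {
  counts <- c(raw, norm, adapter, enzyme, range, clean)
  if (any(diff(counts) > 0) || any(counts < 0)) {
    stop("QC ladder must be non-increasing and non-negative")
  }
  structure(
    data.frame(sample = sample, raw = raw, norm = norm, adapter = adapter,
               enzyme = enzyme, range = range, clean = clean,
               percent = if (norm > 0) round_half_up(clean / norm * 100, 2)
                         else NA_real_,
               stringsAsFactors = FALSE),
    class = c("qc_ledger", "data.frame"))
}

#' Run the full QC stage on one library
#'
#' Subsamples to the normalization depth, trims adapters (dropping reads
#' reduced to nothing), applies the enzyme/range/clean filters, and
#' returns the clean reads together with the ledger row.
#'
#' @param reads raw read data.frame.
#' @param sample sample identifier for the ledger.
#' @param adapter adapter sequence, or `NULL` to skip trimming.
#' @param norm_depth normalization depth, or `NULL` to skip subsampling.
#' @param seed RNG seed for the subsampling step.
#' @param ... passed to [filter_reads()].
#' @return list with `reads` (clean) and `ledger` (one-row data.frame).
#' @export
qc_pipeline <- function(reads, sample = "sample", adapter = NULL,
                        norm_depth = NULL, seed = NULL, ...) {
  raw <- nrow(reads)
  normed <- if (is.null(norm_depth)) reads else
    subsample_to_norm(reads, norm_depth, seed = seed)
  norm <- nrow(normed)
  trimmed <- if (is.null(adapter)) normed else trim_adapter(normed, adapter)
  trimmed <- trimmed[nchar(trimmed$seq) > 0L, , drop = FALSE]
  adapter_n <- nrow(trimmed)
  flt <- filter_reads(trimmed, ...)
  list(reads = flt$reads,
       ledger = qc_ledger(sample, raw, norm, adapter_n,
                          flt$counts[["enzyme"]], flt$counts[["range"]],
                          flt$counts[["clean"]]))
}
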