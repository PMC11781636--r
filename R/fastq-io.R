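# FASTQ I/O (Sanger Phred+33), backed by Biostrings. Reads are carried
# through the pipeline as a plain data.frame (id, seq, qual) so per-read
# predicates stay cheap and transparent.

#' Read a FASTQ file
#'
#' @param path FASTQ file (Sanger Phred+33 qualities).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
               con)
  }
  invisible(path)
}

#' Per-base Phred scores of a quality string
#'
#' @param qual character vector of Phred+33 quality strings.
#' @return list of integer vectors of Phred scores.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

# Fraction of bases with Phred score < cutoff, vectorized over reads.
frac_below_q <- function(qual, cutoff = 30L) {
  thr <- as.raw(33L + cutoff)
  vapply(qual, function(q) {
    r <- charToRaw(q)
    if (length(r) == 0L) return(0)
    sum(r < thr) / length(r)
  }, numeric(1), USE.NAMES = FALSE)
}

# Fraction of ambiguous (N) bases per read.
frac_n <- function(seq) {
  n <- nchar(seq)
  ifelse(n == 0L, 0, (n - nchar(gsub("N", "", seq, fixed = TRUE))) / n)
}
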