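# Small shared helpers.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.005 -> 0.01),
#' the convention used for the clean-read percentage column of the QC
#' ledger. Base `round()` rounds half to even, which gives different
#' second decimals on some ledger rows.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Reverse complement of character sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Coerce genome input (path, character vector, DNAStringSet) to an
# uppercase named DNAStringSet, validating the alphabet.
as_genome <- function(genome) {
  if (length(genome) == 0L) stop("empty genome")
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) {
      names(genome) <- paste0("chr", seq_along(genome))
    }
    bad <- regexpr("[^ACGTNacgtn]", genome)
    if (any(bad > 0)) {
      i <- which(bad > 0)[1]
      stop(sprintf(
        "invalid character '%s' at position %d of sequence '%s'",
        substr(genome[i], bad[i], bad[i]), bad[i], names(genome)[i]))
    }
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop("genome must be a FASTA path, named character vector or DNAStringSet")
  }
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L) {
    stop("empty genome")
  }
  freq <- Biostrings::alphabetFrequency(genome)
  extra <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                        drop = FALSE])
  if (any(extra > 0)) {
    i <- which(extra > 0)[1]
    chars <- strsplit(as.character(genome[[i]]), "")[[1]]
    pos <- which(!chars %in% c("A", "C", "G", "T", "N"))[1]
    stop(sprintf("invalid character '%s' at position %d of sequence '%s'",
                 chars[pos], pos, names(genome)[i]))
  }
  genome
}

# Write a data.frame as TSV without quoting or row names.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
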