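# Electronic digestion: enumerate FspEI-recognizable methylation sites on a
# reference genome and derive the reference tag for each site.
#
# FspEI is a methylation-dependent endonuclease. Two site classes are
# profiled: CCGG (methylated-CG context) and CCWGG (methylated-CHG context
# with W = A or T, i.e. the literal motifs CCAGG and CCTGG). The modified
# cytosine is the second C of the motif; its genome coordinate anchors the
# site for annotation. All coordinates are 0-based, half-open.

#' Motif classes recognized by FspEI
#'
#' Expands the two site-class names into their literal motifs: `CCGG`
#' expands to itself, `CCWGG` to `CCAGG` and `CCTGG` (W = A or T).
#'
#' @param classes character vector of class names, subset of
#'   `c("CCGG", "CCWGG")`.
#' @return named list mapping each class to its literal motifs.
#' @examples
#' motif_classes()
#' @export
motif_classes <- function(classes = c("CCGG", "CCWGG")) {
  all <- list(CCGG = "CCGG", CCWGG = c("CCAGG", "CCTGG"))
  classes <- match.arg(classes, names(all), several.ok = TRUE)
  if (length(classes) == 0L) stop("classes must be non-empty")
  all[classes]
}

#' Enumerate FspEI recognition sites in a genome
#'
#' Scans every sequence on both strands for all literal motifs of the
#' requested site classes. Each motif occurrence on each strand is one
#' stranded site; a CCGG locus therefore always yields a +/- pair (the
#' motif is its own reverse complement), and a CCAGG occurrence on the
#' plus strand is accompanied by a CCTGG site on the minus strand at the
#' same locus. `N` bases never match.
#'
#' @param genome FASTA path, named character vector, or
#'   [Biostrings::DNAStringSet].
#' @param classes site classes to enumerate (see [motif_classes()]).
#' @param genome_id identifier stored with the catalog.
#' @return A `site_catalog`: a data.frame with columns `chrom`, `pos`
#'   (0-based motif start), `strand`, `motif` (as read 5'->3' on the
#'   site's strand), `motif_class`, `mod_c_pos` (genome coordinate of the
#'   modified second cytosine) and `site_id`, sorted by (chrom, pos,
#'   strand), with attributes `genome_id` and `per_chrom_counts`.
#' @examples
#' enumerate_sites(c(chrA = "ACCGGT"))
#' @export
enumerate_sites <- function(genome, classes = c("CCGG", "CCWGG"),
                            genome_id = "genome") {
  genome <- as_genome(genome)
  cls <- motif_classes(classes)
  rows <- list()
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    for (class_name in names(cls)) {
      for (motif in cls[[class_name]]) {
        mlen <- nchar(motif)
        # plus strand: motif read directly on the reference
        p <- Biostrings::start(Biostrings::matchPattern(motif, subject)) - 1L
        if (length(p)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, pos = p, strand = "+", motif = motif,
            motif_class = class_name, mod_c_pos = p + 1L,
            stringsAsFactors = FALSE)
        }
        # minus strand: the motif occupies loci where its reverse
        # complement appears on the reference
        m <- Biostrings::start(
          Biostrings::matchPattern(revcomp(motif), subject)) - 1L
        if (length(m)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, pos = m, strand = "-", motif = motif,
            motif_class = class_name, mod_c_pos = m + mlen - 2L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  sites <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(chrom = character(), pos = integer(), strand = character(),
               motif = character(), motif_class = character(),
               mod_c_pos = integer(), stringsAsFactors = FALSE)
  }
  ord <- order(match(sites$chrom, names(genome)), sites$pos,
               match(sites$strand, c("+", "-")))
  sites <- sites[ord, , drop = FALSE]
  sites$site_id <- sprintf("%s:%d:%s:%s", sites$chrom, sites$pos,
                           sites$strand, sites$motif)
  stopifnot(!anyDuplicated(sites$site_id))
  rownames(sites) <- NULL

  counts <- data.frame(
    chrom = names(genome),
    n_CCGG = vapply(names(genome), function(ch)
      sum(sites$chrom == ch & sites$motif_class == "CCGG"), integer(1)),
    n_CCWGG = vapply(names(genome), function(ch)
      sum(sites$chrom == ch & sites$motif_class == "CCWGG"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(sites, class = c("site_catalog", "data.frame"),
            genome_id = genome_id, per_chrom_counts = counts)
}

#' Per-chromosome site class counts
#'
#' @param catalog a `site_catalog` from [enumerate_sites()].
#' @return data.frame with columns `chrom`, `n_CCGG`, `n_CCWGG`; rows sum
#'   to the class totals of the catalog. Chromosomes with no sites are
#'   omitted only if the catalog is empty of them entirely, never padded.
#' @export
per_chromosome_report <- function(catalog) {
  counts <- attr(catalog, "per_chrom_counts")
  if (is.null(counts)) stop("not a site_catalog")
  if (nrow(catalog) == 0L) {
    return(counts[counts$n_CCGG + counts$n_CCWGG > 0, , drop = FALSE])
  }
  counts
}

#' Extract reference tags for catalog sites
#'
#' The sequenced tag of a site is modeled as a fixed-length window
#' starting at the motif start, read on the site's strand (default 15 nt,
#' within the 13-17 bp fragment range the protocol size-selects). Sites
#' whose window runs off the chromosome end are dropped and counted as
#' clipped. Identical tags arising from identical sequence contexts are
#' flagged ambiguous but kept.
#'
#' @param genome genome the catalog was built from.
#' @param catalog a `site_catalog`.
#' @param tag_len tag window length in bases (>= 1).
#' @return A `tag_library`: data.frame with columns `tag`, `site_ids`
#'   (comma-joined), `n_sites`, `ambiguous`; attributes `tag_len_range`
#'   and `clipped_site_ids`.
#' @export
extract_tags <- function(genome, catalog, tag_len = 15L) {
  tag_len <- as.integer(tag_len)
  if (is.na(tag_len) || tag_len < 1L) {
    stop("tag_len must produce tags of length >= 1")
  }
  genome <- as_genome(genome)
  seqs <- as.character(genome)
  chrom_len <- nchar(seqs)[match(catalog$chrom, names(genome))]
  mlen <- nchar(catalog$motif)

  plus <- catalog$strand == "+"
  start0 <- ifelse(plus, catalog$pos, catalog$pos + mlen - tag_len)
  end0 <- start0 + tag_len
  clipped <- start0 < 0L | end0 > chrom_len

  raw <- substr(seqs[match(catalog$chrom, names(genome))],
                start0 + 1L, end0)
  tags <- ifelse(plus, raw, NA_character_)
  if (any(!plus & !clipped)) {
    idx <- which(!plus & !clipped)
    tags[idx] <- revcomp(raw[idx])
  }

  keep <- which(!clipped)
  tab <- split(catalog$site_id[keep], tags[keep])
  lib <- data.frame(
    tag = names(tab),
    site_ids = vapply(tab, paste, "", collapse = ","),
    n_sites = lengths(tab),
    row.names = NULL, stringsAsFactors = FALSE)
  lib$ambiguous <- lib$n_sites > 1L
  lib <- lib[order(lib$tag), , drop = FALSE]
  rownames(lib) <- NULL

  structure(lib, class = c("tag_library", "data.frame"),
            tag_len_range = c(tag_len, tag_len),
            clipped_site_ids = catalog$site_id[clipped])
}

#' Write a site catalog as BED6
#'
#' Intervals cover the motif (0-based, half-open); score is 0.
#'
#' @param catalog a `site_catalog`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_catalog_bed <- function(catalog, path) {
  bed <- data.frame(chrom = catalog$chrom, start = catalog$pos,
                    end = catalog$pos + nchar(catalog$motif),
                    name = catalog$site_id, score = 0L,
                    strand = catalog$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
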