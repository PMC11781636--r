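# Tag-to-site quantification: unique exact tag matching, per-sample depth
# columns, RPM normalization, and the depth-3 validity mask. Exact lookup
# of short reference tags replaces read alignment at this fragment size;
# the unique-mapping contract is preserved by discarding reads that match
# an ambiguous tag (one shared by several sites).

#' Match clean reads to reference tags for one sample
#'
#' A read increments exactly one site's depth iff its sequence (or, for
#' reads longer than the tag window, one of its tag-length subsequences)
#' matches exactly one unambiguous tag. Reads matching an ambiguous tag
#' or tags of more than one site are discarded as multi-mapping; reads
#' matching nothing are counted as unmatched.
#'
#' @param reads clean read data.frame.
#' @param tag_library a `tag_library` from [extract_tags()].
#' @return list with `depth` (named integer vector over all site ids in
#'   the library) and `stats` (`matched`, `multi`, `unmatched`; the three
#'   sum to the input read count).
#' @export
match_tags <- function(reads, tag_library) {
  if (nrow(tag_library) == 0L) stop("empty tag_library")
  site_ids <- unlist(strsplit(tag_library$site_ids, ",", fixed = TRUE))
  depth <- stats::setNames(integer(length(site_ids)), site_ids)
  stats <- c(matched = 0L, multi = 0L, unmatched = 0L)
  if (nrow(reads) == 0L) return(list(depth = depth, stats = stats))

  tag_len <- attr(tag_library, "tag_len_range")[1]
  # candidate tag hit per read: exact full-length match first, then the
  # tag-length subsequences of longer reads
  hit <- match(reads$seq, tag_library$tag)
  long <- which(is.na(hit) & nchar(reads$seq) > tag_len)
  multi_extra <- logical(nrow(reads))
  for (i in long) {
    n <- nchar(reads$seq[i])
    subs <- substring(reads$seq[i], 1:(n - tag_len + 1),
                      tag_len:(n))
    h <- unique(match(subs, tag_library$tag))
    h <- h[!is.na(h)]
    if (length(h) == 1L) hit[i] <- h
    else if (length(h) > 1L) multi_extra[i] <- TRUE
  }

  unmatched <- is.na(hit) & !multi_extra
  ambiguous <- !is.na(hit) & tag_library$ambiguous[hit]
  unique_hit <- !is.na(hit) & !ambiguous
  stats[["unmatched"]] <- sum(unmatched)
  stats[["multi"]] <- sum(ambiguous) + sum(multi_extra)
  stats[["matched"]] <- sum(unique_hit)
  if (any(unique_hit)) {
    counted <- table(tag_library$site_ids[hit[unique_hit]])
    depth[names(counted)] <- as.integer(counted)
  }
  list(depth = depth, stats = stats)
}

#' Build a site-by-sample count container
#'
#' @param depth integer matrix, sites in rows, samples in columns.
#' @param library_size per-sample high-quality (clean) read counts used
#'   as the RPM denominator; defaults to column sums of `depth`.
#' @return list of class `site_counts` with elements `depth`, `rpm`,
#'   `library_size`.
#' @export
site_count_matrix <- function(depth, library_size = colSums(depth)) {
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  if (any(depth < 0)) stop("depth must be non-negative")
  structure(list(depth = depth,
                 rpm = compute_rpm(depth, library_size),
                 library_size = library_size),
            class = "site_counts")
}

#' Reads-per-million normalization
#'
#' `RPM = depth / library_size * 1e6`, elementwise per sample, with no
#' pseudocount. Tag depth at a site, so normalized, is the relative
#' methylation signal of that site.
#'
#' @param depth site-by-sample integer matrix (or vector for one sample).
#' @param library_size per-sample library sizes (> 0).
#' @return numeric matrix of RPM values.
#' @export
compute_rpm <- function(depth, library_size) {
  depth <- as.matrix(depth)
  if (length(library_size) != ncol(depth)) {
    stop("library_size must have one entry per sample")
  }
  if (any(library_size <= 0)) stop("library_size must be positive")
  sweep(depth, 2, library_size, "/") * 1e6
}

#' Validity mask at a minimum sequencing depth
#'
#' A site is validly methylated in a sample iff its depth is at least
#' `min_depth` (default 3, the three-fold coverage rule).
#'
#' @param depth site-by-sample matrix.
#' @param min_depth minimum depth (>= 1).
#' @return logical matrix of the same shape.
#' @export
apply_validity <- function(depth, min_depth = 3L) {
  if (min_depth < 1L) stop("min_depth must be >= 1")
  as.matrix(depth) >= min_depth
}

#' Drop sites invalid in every sample
#'
#' Sites failing the validity rule in all samples carry no usable signal
#' and are removed before differential testing; sites valid in at least
#' one sample are retained.
#'
#' @param counts a `site_counts` object.
#' @param min_depth minimum valid depth.
#' @return filtered `site_counts`.
#' @export
filter_valid_sites <- function(counts, min_depth = 3L) {
  keep <- rowSums(apply_validity(counts$depth, min_depth)) > 0
  site_count_matrix(counts$depth[keep, , drop = FALSE],
                    counts$library_size)
}
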