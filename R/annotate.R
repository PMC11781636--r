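# Gene-model handling and site annotation: assignment of sites to genomic
# features (5'UTR, 3'UTR, exon, intron, upstream, intergenic), promoter
# mapping, and TSS / gene-body / TTS metagene profiles. Gene models are
# held as plain 0-based half-open interval tables; GFF3 import and export
# go through rtracklayer.

#' Construct a gene-model table
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based, half-open).
#' @param exons data.frame with columns `gene_id`, `start`, `end`.
#' @param cds optional data.frame like `exons`; used to derive UTRs.
#' @return list of class `gene_models` with elements `genes` (plus
#'   derived `tss`/`tts`, the 0-based coordinates of the first and last
#'   transcribed base), `exons`, `cds`.
#' @export
gene_models <- function(genes, exons, cds = NULL) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)),
            all(genes$end > genes$start),
            all(genes$strand %in% c("+", "-")))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tts <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_models")
}

#' Read gene models from GFF3
#'
#' Expects `gene`, `mRNA`, `exon` and optionally `CDS` records with
#' `ID`/`Parent` attributes; exons are lifted to their gene through the
#' mRNA parent. 1-based GFF coordinates are converted to the package's
#' 0-based half-open convention on read.
#'
#' @param path GFF3 file.
#' @return a `gene_models` object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))

  is_gene <- type == "gene"
  gene_of <- stats::setNames(ids[is_gene], ids[is_gene])
  is_rna <- type %in% c("mRNA", "transcript")
  gene_of <- c(gene_of, stats::setNames(parent[is_rna], ids[is_rna]))

  genes <- data.frame(
    gene_id = ids[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    stringsAsFactors = FALSE)

  part <- function(what) {
    sel <- type == what
    if (!any(sel)) return(NULL)
    data.frame(gene_id = unname(gene_of[parent[sel]]),
               start = GenomicRanges::start(gr)[sel] - 1L,
               end = GenomicRanges::end(gr)[sel],
               stringsAsFactors = FALSE)
  }
  exons <- part("exon")
  if (is.null(exons)) {  # exonless annotations: whole gene is one exon
    exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                        end = genes$end, stringsAsFactors = FALSE)
  }
  gene_models(genes, exons, part("CDS"))
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS records (one transcript per gene),
#' converting back to 1-based closed coordinates.
#'
#' @param models a `gene_models` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  g <- models$genes
  feat <- function(df, type, id, parent) {
    GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start + 1L, df$end),
      strand = df$strand, type = type, ID = id, Parent = parent)
  }
  rows <- list(
    feat(g, "gene", g$gene_id, NA_character_),
    feat(g, "mRNA", paste0(g$gene_id, ".t1"), g$gene_id))
  lift <- function(df, type, suffix) {
    gi <- match(df$gene_id, g$gene_id)
    d <- data.frame(chrom = g$chrom[gi], strand = g$strand[gi],
                    start = df$start, end = df$end)
    feat(d, type,
         paste0(df$gene_id, ".", suffix, seq_len(nrow(df))),
         paste0(df$gene_id, ".t1"))
  }
  rows[[3]] <- lift(models$exons, "exon", "e")
  if (!is.null(models$cds) && nrow(models$cds)) {
    cds_gr <- lift(models$cds, "CDS", "c")
    # reading-frame phase per piece, accumulated in transcription order
    phase <- integer(length(cds_gr))
    for (gid in unique(models$cds$gene_id)) {
      idx <- which(models$cds$gene_id == gid)
      strand <- g$strand[match(gid, g$gene_id)]
      ord <- order(models$cds$start[idx],
                   decreasing = (strand == "-"))
      len <- (models$cds$end - models$cds$start)[idx][ord]
      phase[idx[ord]] <- (3L - cumsum(c(0L, len))[seq_along(len)] %% 3L) %% 3L
    }
    cds_gr$phase <- phase
    rows[[4]] <- cds_gr
  }
  gr <- suppressWarnings(do.call(c, rows))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Derive UTR intervals: exonic sequence outside the CDS span, split into
# 5' and 3' by transcription direction. Returns data.frames like exons.
derive_utrs <- function(models) {
  empty <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (is.null(models$cds) || nrow(models$cds) == 0L) {
    return(list(utr5 = empty, utr3 = empty))
  }
  u5 <- list(); u3 <- list()
  for (gid in unique(models$cds$gene_id)) {
    ex <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
    cd <- models$cds[models$cds$gene_id == gid, , drop = FALSE]
    strand <- models$genes$strand[models$genes$gene_id == gid]
    exr <- IRanges::IRanges(ex$start + 1L, ex$end)
    cds_span <- IRanges::IRanges(min(cd$start) + 1L, max(cd$end))
    out <- IRanges::setdiff(exr, cds_span)
    if (length(out) == 0L) next
    before <- IRanges::end(out) < IRanges::start(cds_span)
    mk <- function(sel) {
      if (!any(sel)) return(NULL)
      data.frame(gene_id = gid, start = IRanges::start(out)[sel] - 1L,
                 end = IRanges::end(out)[sel], stringsAsFactors = FALSE)
    }
    if (strand == "+") {
      u5[[gid]] <- mk(before); u3[[gid]] <- mk(!before)
    } else {
      u5[[gid]] <- mk(!before); u3[[gid]] <- mk(before)
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else empty
  list(utr5 = bind(u5), utr3 = bind(u3))
}

# GRanges of 1-width anchors at each site's modified cytosine.
site_anchors <- function(catalog) {
  GenomicRanges::GRanges(catalog$chrom,
                         IRanges::IRanges(catalog$mod_c_pos + 1L, width = 1L))
}

#' Assign each site to a single genomic feature
#'
#' Sites are anchored at the modified cytosine and assigned one feature
#' with precedence 5'UTR > 3'UTR > exon > intron > upstream > intergenic
#' (UTRs outrank exon as sub-exonic annotations; genic context outranks
#' the upstream flank). The gene's strand governs the upstream direction.
#' Sites on chromosomes without gene models fall through to intergenic.
#'
#' @param catalog a `site_catalog`.
#' @param models a `gene_models` object.
#' @param upstream_span upstream flank width in bases (default 2000).
#' @return data.frame with `site_id`, `feature`, `gene_id` (`NA` for
#'   intergenic); exactly one row per catalog site.
#' @export
assign_feature <- function(catalog, models, upstream_span = 2000L) {
  anchors <- site_anchors(catalog)
  feature <- rep("intergenic", nrow(catalog))
  gene <- rep(NA_character_, nrow(catalog))
  g <- models$genes
  unknown <- setdiff(unique(catalog$chrom), unique(g$chrom))
  if (length(unknown)) {
    warning(sprintf(
      "no gene models on %s; sites there assigned intergenic",
      paste(unknown, collapse = ", ")))
  }
  utrs <- derive_utrs(models)

  up <- data.frame(
    gene_id = g$gene_id,
    start = ifelse(g$strand == "+", pmax(0L, g$start - upstream_span),
                   g$end),
    end = ifelse(g$strand == "+", g$start, g$end + upstream_span),
    stringsAsFactors = FALSE)
  gene_body <- data.frame(gene_id = g$gene_id, start = g$start, end = g$end,
                          stringsAsFactors = FALSE)

  layer <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    gi <- match(df$gene_id, g$gene_id)
    GenomicRanges::GRanges(g$chrom[gi],
                           IRanges::IRanges(df$start + 1L, df$end),
                           gene_id = df$gene_id)
  }
  layers <- list(utr5 = layer(utrs$utr5), utr3 = layer(utrs$utr3),
                 exon = layer(models$exons), intron = layer(gene_body),
                 upstream = layer(up))
  for (name in names(layers)) {
    lr <- layers[[name]]
    if (is.null(lr)) next
    hits <- suppressWarnings(GenomicRanges::findOverlaps(anchors, lr))
    first <- !duplicated(S4Vectors::queryHits(hits))
    qi <- S4Vectors::queryHits(hits)[first]
    si <- S4Vectors::subjectHits(hits)[first]
    open <- feature[qi] == "intergenic"
    feature[qi[open]] <- name
    gene[qi[open]] <- lr$gene_id[si[open]]
  }
  # the intron layer used whole gene bodies; demote nothing: exonic hits
  # were already claimed by earlier layers, so remaining body hits are
  # intronic by construction
  data.frame(site_id = catalog$site_id, feature = feature, gene_id = gene,
             stringsAsFactors = FALSE)
}

#' Map promoters to the sites they contain
#'
#' The promoter is the `span` bases immediately upstream of the TSS in
#' transcription direction, half-open at the TSS (a site exactly at the
#' TSS is excluded). A site may serve several genes; no arbitration is
#' applied.
#'
#' @param catalog a `site_catalog`.
#' @param models a `gene_models` object.
#' @param span promoter width in bases (default 2000).
#' @return data.frame with `gene_id`, `site_id`.
#' @export
promoter_map <- function(catalog, models, span = 2000L) {
  g <- models$genes
  proms <- GenomicRanges::GRanges(
    g$chrom,
    IRanges::IRanges(
      start = ifelse(g$strand == "+", pmax(0L, g$tss - span), g$tss + 1L) + 1L,
      end = ifelse(g$strand == "+", g$tss, g$tss + span + 1L)),
    gene_id = g$gene_id)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(site_anchors(catalog), proms))
  data.frame(gene_id = proms$gene_id[S4Vectors::subjectHits(hits)],
             site_id = catalog$site_id[S4Vectors::queryHits(hits)],
             stringsAsFactors = FALSE)
}

#' Metagene profile over upstream flank, gene body and downstream flank
#'
#' Signed distance from the TSS in transcription direction places each
#' site in a fixed-width upstream bin (2 kb flank by default), a
#' length-normalized gene-body bin, or a fixed-width downstream bin past
#' the TTS; minus-strand genes are reflected so bins always run 5'->3'.
#' The per-gene, per-bin signal is the mean site signal in the bin; the
#' profile averages over genes contributing to the bin. Genes with fewer
#' body bases than body bins are dropped with a warning.
#'
#' @param signal named numeric vector of per-site signal (e.g. mean RPM
#'   of a group), names are site ids.
#' @param catalog a `site_catalog`.
#' @param models a `gene_models` object.
#' @param n_bins bins per segment, `c(upstream, body, downstream)`.
#' @param flank flank span in bases (default 2000).
#' @return data.frame with `segment`, `bin` (1-based within segment),
#'   `signal` (`NA` where no site falls in a bin).
#' @export
metagene_profile <- function(signal, catalog, models,
                             n_bins = c(20L, 40L, 20L), flank = 2000L) {
  stopifnot(length(n_bins) == 3L)
  g <- models$genes
  too_short <- (g$end - g$start) < n_bins[2]
  if (any(too_short)) {
    warning(sprintf("%d gene(s) shorter than %d body bins dropped",
                    sum(too_short), n_bins[2]))
    g <- g[!too_short, , drop = FALSE]
  }
  if (nrow(g) == 0L) stop("no usable genes for metagene profile")
  nb <- sum(n_bins)
  sums <- numeric(nb)
  ngene <- numeric(nb)
  sig <- signal[catalog$site_id]
  for (i in seq_len(nrow(g))) {
    on_chrom <- catalog$chrom == g$chrom[i]
    if (!any(on_chrom)) next
    p <- catalog$mod_c_pos[on_chrom]
    s <- sig[on_chrom]
    glen <- g$end[i] - g$start[i]
    t_rel <- if (g$strand[i] == "+") p - g$tss[i] else g$tss[i] - p
    s_rel <- if (g$strand[i] == "+") p - g$tts[i] else g$tts[i] - p
    bin <- rep(NA_integer_, length(p))
    in_up <- t_rel >= -flank & t_rel <= -1L
    bin[in_up] <- floor((t_rel[in_up] + flank) / (flank / n_bins[1])) + 1L
    in_body <- t_rel >= 0L & t_rel < glen
    bin[in_body] <- n_bins[1] +
      pmin(n_bins[2], floor(t_rel[in_body] / glen * n_bins[2]) + 1L)
    in_dn <- s_rel >= 1L & s_rel <= flank
    bin[in_dn] <- n_bins[1] + n_bins[2] +
      floor((s_rel[in_dn] - 1L) / (flank / n_bins[3])) + 1L
    ok <- !is.na(bin) & !is.na(s)
    if (!any(ok)) next
    per_bin <- tapply(s[ok], bin[ok], mean)
    idx <- as.integer(names(per_bin))
    sums[idx] <- sums[idx] + per_bin
    ngene[idx] <- ngene[idx] + 1L
  }
  data.frame(
    segment = rep(c("upstream", "body", "downstream"), n_bins),
    bin = c(seq_len(n_bins[1]), seq_len(n_bins[2]), seq_len(n_bins[3])),
    signal = ifelse(ngene > 0, sums / pmax(ngene, 1), NA_real_),
    stringsAsFactors = FALSE)
}
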