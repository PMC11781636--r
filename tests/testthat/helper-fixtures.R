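# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; no stored binary data.

# build a read data.frame; qual defaults to uniform Q40 ("I")
mk_reads <- function(seqs, quals = strrep("I", nchar(seqs)),
                     ids = sprintf("r%03d", seq_along(seqs))) {
  data.frame(id = ids, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

# independent brute-force site scan: slides a window over the forward
# sequence for plus-strand motifs and over the reverse complement for
# minus-strand motifs, mapping the latter back through coordinate
# reflection (never reusing the package's matchPattern path)
naive_scan <- function(seqs, classes = c("CCGG", "CCWGG")) {
  motifs <- motif_classes(classes)
  rows <- list()
  for (chrom in names(seqs)) {
    s <- seqs[[chrom]]
    n <- nchar(s)
    rc <- revcomp(s)
    for (cls in names(motifs)) {
      for (m in motifs[[cls]]) {
        L <- nchar(m)
        if (n < L) next
        for (i in seq_len(n - L + 1L)) {
          if (substr(s, i, i + L - 1L) == m) {
            rows[[length(rows) + 1L]] <-
              data.frame(chrom = chrom, pos = i - 1L, strand = "+",
                         motif = m, stringsAsFactors = FALSE)
          }
          if (substr(rc, i, i + L - 1L) == m) {
            rows[[length(rows) + 1L]] <-
              data.frame(chrom = chrom, pos = n - (i - 1L) - L,
                         strand = "-", motif = m, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), motif = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos, match(out$strand, c("+", "-")),
            out$motif), ]
}

random_genome <- function(n_chrom = 2L, len = 2000L, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_chrom), function(i)
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  seqs
}

# minimal two-gene models on one chromosome, opposite strands
toy_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
    start = c(3000L, 12000L), end = c(6000L, 15000L),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB"),
    start = c(3000L, 5000L, 12000L, 14000L),
    end = c(3800L, 6000L, 12800L, 15000L), stringsAsFactors = FALSE)
  cds <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB"),
    start = c(3300L, 5000L, 12200L, 14000L),
    end = c(3800L, 5700L, 12800L, 14700L), stringsAsFactors = FALSE)
  gene_models(genes, exons, cds)
}

# catalog-shaped table from explicit anchors (for annotation tests)
toy_catalog <- function(chrom, mod_c_pos, strand = "+") {
  n <- length(mod_c_pos)
  structure(
    data.frame(chrom = chrom, pos = mod_c_pos - 1L,
               strand = rep_len(strand, n),
               motif = "CCGG", motif_class = "CCGG",
               mod_c_pos = mod_c_pos,
               site_id = sprintf("%s:%d:%s:CCGG", chrom, mod_c_pos - 1L,
                                 rep_len(strand, n)),
               stringsAsFactors = FALSE),
    class = c("site_catalog", "data.frame"))
}

# run QC + quantification over simulated per-sample reads
quantify_dataset <- function(ds) {
  qc <- lapply(names(ds$reads), function(s)
    qc_pipeline(ds$reads[[s]], sample = s, adapter = ds$config$adapter))
  names(qc) <- names(ds$reads)
  depth <- do.call(cbind, lapply(qc, function(q)
    match_tags(q$reads, ds$tags)$depth))
  colnames(depth) <- names(qc)
  list(qc = qc,
       counts = site_count_matrix(
         depth, vapply(qc, function(q) nrow(q$reads), integer(1))))
}
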