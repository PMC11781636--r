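test_that("gene models derive TSS/TTS by strand", {
  gm <- toy_models()
  g <- gm$genes
  expect_equal(g$tss, c(3000L, 14999L))
  expect_equal(g$tts, c(5999L, 12000L))
})

test_that("feature assignment follows containment and precedence", {
  gm <- toy_models()
  # exon interior (inside CDS span) of gA; intron of gA; upstream of gA;
  # 5'UTR of gA (exonic, before CDS); intergenic far away
  cat <- toy_catalog("chr1", c(3500L, 4500L, 2500L, 3100L, 9000L))
  out <- assign_feature(cat, gm)
  expect_equal(out$feature,
               c("exon", "intron", "upstream", "utr5", "intergenic"))
  expect_equal(out$gene_id[1:4], rep("gA", 4))
  expect_true(is.na(out$gene_id[5]))
})

test_that("minus-strand genes govern upstream direction and UTR sides", {
  gm <- toy_models()
  # 500 bases 5' of gB's TSS (TSS at 14999, upstream is higher coords)
  cat <- toy_catalog("chr1", c(15500L, 14800L, 12100L))
  out <- assign_feature(cat, gm)
  expect_equal(out$feature, c("upstream", "utr5", "utr3"))
  expect_equal(out$gene_id, rep("gB", 3))
})

test_that("sites on chromosomes without genes fall through to intergenic", {
  gm <- toy_models()
  cat <- toy_catalog("chrUn", 100L)
  expect_warning(out <- assign_feature(cat, gm), "chrUn")
  expect_equal(out$feature, "intergenic")
})

test_that("every site gets exactly one feature and counts sum", {
  cfg <- sim_config(seed = 3, n_chrom = 1L, chrom_len = 25000L,
                    n_genes = 8L)
  gg <- make_genome_and_genes(cfg)
  cat <- enumerate_sites(gg$genome)
  out <- assign_feature(cat, gg$models)
  expect_equal(nrow(out), nrow(cat))
  expect_false(anyNA(out$feature))
  expect_equal(sum(table(out$feature)), nrow(cat))
  expect_true(all(out$feature %in% c("utr5", "utr3", "exon", "intron",
                                     "upstream", "intergenic")))
})

test_that("promoter map is half-open at the TSS with a 2 kb span", {
  gm <- toy_models()
  # gA: + strand, TSS 3000. In: [1000, 2999]; out: 3000 and 999.
  cat <- toy_catalog("chr1", c(2900L, 3000L, 500L, 1000L))
  pm <- promoter_map(cat, gm)
  hits <- pm$site_id[pm$gene_id == "gA"]
  expect_setequal(hits, cat$site_id[c(1, 4)])
  # gB: - strand, TSS 14999. In: [15000, 16999]; out: 14999, 17000.
  cat2 <- toy_catalog("chr1", c(15099L, 14999L, 16999L, 17000L))
  pm2 <- promoter_map(cat2, gm)
  expect_setequal(pm2$site_id[pm2$gene_id == "gB"],
                  cat2$site_id[c(1, 3)])
})

test_that("a site may serve the promoters of several genes", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "-"),
                      start = c(5000L, 1000L), end = c(6000L, 3500L))
  gm <- gene_models(genes, data.frame(gene_id = genes$gene_id,
                                      start = genes$start,
                                      end = genes$end))
  cat <- toy_catalog("chr1", 4000L)  # between the genes, upstream of both
  pm <- promoter_map(cat, gm)
  expect_setequal(pm$gene_id, c("g1", "g2"))
})

test_that("metagene profile is flat for constant signal", {
  cfg <- sim_config(seed = 4, n_chrom = 1L, chrom_len = 20000L,
                    n_genes = 6L)
  gg <- make_genome_and_genes(cfg)
  cat <- enumerate_sites(gg$genome)
  sig <- setNames(rep(2.5, nrow(cat)), cat$site_id)
  prof <- metagene_profile(sig, cat, gg$models)
  expect_equal(nrow(prof), 80L)
  filled <- prof$signal[!is.na(prof$signal)]
  expect_true(length(filled) > 0)
  expect_true(all(abs(filled - 2.5) < 1e-12))
})

test_that("a site exactly at a plus-strand TSS lands in body bin 1", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 5000L, end = 9000L)
  gm <- gene_models(genes, data.frame(gene_id = "g1", start = 5000L,
                                      end = 9000L))
  cat <- toy_catalog("chr1", 5000L)
  sig <- setNames(3, cat$site_id)
  prof <- metagene_profile(sig, cat, gm)
  hit <- prof[!is.na(prof$signal), ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$segment, "body")
  expect_equal(hit$bin, 1L)
})

test_that("minus-strand profile equals the reflected plus-strand twin", {
  len <- 20000L
  plus <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                     start = 8000L, end = 12000L)
  minus <- plus; minus$strand <- "-"
  gm_p <- gene_models(plus, data.frame(gene_id = "g", start = 8000L,
                                       end = 12000L))
  gm_m <- gene_models(minus, data.frame(gene_id = "g", start = 8000L,
                                        end = 12000L))
  pos <- c(6500L, 8000L, 9000L, 11999L, 13000L)
  cat_p <- toy_catalog("chr1", pos)
  cat_m <- toy_catalog("chr1", len - pos - 1L)  # reflected anchors
  sig_p <- setNames(seq_along(pos), cat_p$site_id)
  sig_m <- setNames(seq_along(pos), cat_m$site_id)
  # reflecting the genome maps the minus-strand gene to the plus twin
  minus_refl <- data.frame(gene_id = "g", chrom = "chr1", strand = "-",
                           start = len - 12000L, end = len - 8000L)
  gm_mr <- gene_models(minus_refl,
                       data.frame(gene_id = "g", start = len - 12000L,
                                  end = len - 8000L))
  prof_p <- metagene_profile(sig_p, cat_p, gm_p)
  prof_m <- metagene_profile(sig_m, cat_m, gm_mr)
  expect_equal(prof_p$signal, prof_m$signal)
})

test_that("GFF3 round-trip preserves gene models", {
  gm <- toy_models()
  tmp <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(gm, tmp)
  back <- read_gene_models(tmp)
  expect_equal(back$genes[, c("gene_id", "chrom", "strand", "start",
                              "end", "tss", "tts")],
               gm$genes[, c("gene_id", "chrom", "strand", "start",
                            "end", "tss", "tts")])
  expect_equal(back$exons[order(back$exons$gene_id, back$exons$start), ],
               gm$exons[order(gm$exons$gene_id, gm$exons$start), ],
               ignore_attr = TRUE)
  expect_equal(nrow(back$cds), nrow(gm$cds))
})

test_that("genes shorter than the body bin count are dropped loudly", {
  genes <- data.frame(gene_id = c("tiny", "ok"), chrom = "chr1",
                      strand = "+", start = c(100L, 5000L),
                      end = c(120L, 9000L))
  gm <- gene_models(genes, data.frame(gene_id = genes$gene_id,
                                      start = genes$start,
                                      end = genes$end))
  cat <- toy_catalog("chr1", 6000L)
  sig <- setNames(1, cat$site_id)
  expect_warning(metagene_profile(sig, cat, gm), "dropped")
})
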