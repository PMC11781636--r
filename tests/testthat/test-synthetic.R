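test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11, n_chrom = 1L, chrom_len = 8000L,
                    n_genes = 4L)
  d1 <- tempfile(); d2 <- tempfile()
  for (d in c(d1, d2)) {
    dir.create(d)
    gg <- make_genome_and_genes(cfg)
    Biostrings::writeXStringSet(gg$genome, file.path(d, "genome.fa"))
    write_gene_models_gff3(gg$models, file.path(d, "genes.gff3"))
  }
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  expect_identical(readLines(file.path(d1, "genes.gff3")),
                   readLines(file.path(d2, "genes.gff3")))
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$reads, ds2$reads)
  expect_identical(ds1$expression$counts, ds2$expression$counts)
})

test_that("genome GC content lands near the configured value", {
  cfg <- sim_config(seed = 6, n_chrom = 2L, chrom_len = 50000L,
                    gc = 0.5, n_genes = 10L)
  gg <- make_genome_and_genes(cfg)
  freq <- Biostrings::alphabetFrequency(gg$genome, collapse = TRUE)
  gc <- sum(freq[c("C", "G")]) / sum(freq[c("A", "C", "G", "T")])
  expect_gt(gc, 0.47)
  expect_lt(gc, 0.53)
})

test_that("both site classes are guaranteed throughout the genome", {
  cfg <- sim_config(seed = 8, n_chrom = 1L, chrom_len = 10000L,
                    gc = 0.3, n_genes = 4L)
  gg <- make_genome_and_genes(cfg)
  cat <- enumerate_sites(gg$genome)
  expect_gt(sum(cat$motif_class == "CCGG"), 0)
  expect_gt(sum(cat$motif_class == "CCWGG"), 0)
})

test_that("zero genes still yields a valid genome and empty models", {
  cfg <- sim_config(seed = 2, n_chrom = 1L, chrom_len = 5000L,
                    n_genes = 0L, frac_coupled = 0, deg_frac = 0)
  gg <- make_genome_and_genes(cfg)
  expect_equal(sum(Biostrings::width(gg$genome)), 5000L)
  expect_equal(nrow(gg$models$genes), 0L)
})

test_that("no planted shift means identical group truth", {
  cfg <- sim_config(seed = 9, n_chrom = 1L, chrom_len = 8000L,
                    n_genes = 4L, frac_dms = 0, frac_coupled = 0)
  gg <- make_genome_and_genes(cfg)
  cat <- enumerate_sites(gg$genome)
  truth <- plant_methylation(cat, gg$models, cfg)
  expect_equal(truth$level[, truth$groups$young[1]],
               truth$level[, truth$groups$aged[1]])
  expect_equal(nrow(truth$dms), 0L)
})

test_that("a fold of one plants no effective shift", {
  cfg <- sim_config(seed = 9, n_chrom = 1L, chrom_len = 8000L,
                    n_genes = 4L, frac_dms = 0.2, dms_fold = 1,
                    frac_coupled = 0)
  gg <- make_genome_and_genes(cfg)
  truth <- plant_methylation(enumerate_sites(gg$genome), gg$models, cfg)
  expect_true(all(abs(truth$dms$true_l2fc) < 1e-12))
})

test_that("the planted DMS count matches the configured fraction", {
  cfg <- sim_config(seed = 10, n_chrom = 1L, chrom_len = 30000L,
                    n_genes = 10L, frac_dms = 0.1, frac_coupled = 0)
  gg <- make_genome_and_genes(cfg)
  cat <- enumerate_sites(gg$genome)
  truth <- plant_methylation(cat, gg$models, cfg)
  expect_equal(nrow(truth$dms), round(0.1 * nrow(cat)))
  expect_true(all(truth$dms$site_id %in% cat$site_id))
})

test_that("without planted failures every simulated read is clean", {
  cfg <- sim_config(seed = 13, n_chrom = 1L, chrom_len = 10000L,
                    n_genes = 4L, adapter_frac = 0,
                    qc_fail_fracs = c(n_rich = 0, low_qual = 0,
                                      motifless = 0))
  ds <- simulate_dataset(cfg)
  res <- qc_pipeline(ds$reads[[1]])
  expect_equal(res$ledger$clean, res$ledger$raw)
})

test_that("tag depth scales with the planted level", {
  cfg <- sim_config(seed = 15, n_chrom = 1L, chrom_len = 40000L,
                    n_genes = 4L, frac_dms = 0, frac_coupled = 0,
                    mean_depth = 60, dispersion = 0.1,
                    qc_fail_fracs = c(n_rich = 0, low_qual = 0,
                                      motifless = 0), adapter_frac = 0)
  gg <- make_genome_and_genes(cfg)
  cat <- enumerate_sites(gg$genome)
  tags <- extract_tags(gg$genome, cat, tag_len = cfg$tag_len)
  truth <- plant_methylation(cat, gg$models, cfg)
  # force two level tiers and compare realized mean depths
  truth$level[] <- rep(c(1, 0.5), length.out = length(truth$level))
  reads <- simulate_reads(truth, tags, cfg)
  depth <- match_tags(reads[[1]], tags)$depth
  lv <- truth$level[names(depth), 1]
  ratio <- mean(depth[lv == 1]) / mean(depth[lv == 0.5])
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("coupled genes realize strongly negative correlations at n = 20", {
  cfg <- sim_config(seed = 19, n_young = 10, n_aged = 10)
  gg <- make_genome_and_genes(cfg)
  cat <- enumerate_sites(gg$genome)
  truth <- plant_methylation(cat, gg$models, cfg)
  expr <- simulate_expression(truth, gg$models, cfg)
  rs <- vapply(truth$coupled_genes$gene_id, function(g) {
    s <- truth$prom_map$site_id[truth$prom_map$gene_id == g]
    meth <- colMeans(truth$level[s, , drop = FALSE])
    cor(log2(meth + 1e-3), log2(expr$cpm[g, ] + 1))
  }, numeric(1))
  expect_gte(mean(rs < -0.8), 0.8)
})

test_that("planted expression shifts are recovered by the NB test", {
  cfg <- sim_config(seed = 23, n_chrom = 1L, chrom_len = 30000L,
                    n_genes = 40L, frac_coupled = 0, deg_frac = 0.25,
                    deg_fold = 4)
  gg <- make_genome_and_genes(cfg)
  truth <- plant_methylation(enumerate_sites(gg$genome), gg$models, cfg)
  expr <- simulate_expression(truth, gg$models, cfg)
  deg <- diff_test(expr$counts, truth$groups$young, truth$groups$aged,
                   use_fdr = TRUE, labels = c("up", "down"))
  called <- deg$feature_id[deg$direction != "ns"]
  planted <- truth$deg_genes$gene_id
  expect_gte(length(intersect(called, planted)) / length(planted), 0.8)
})
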