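test_that("subsampling is identity at or under target and seeded above", {
  reads <- mk_reads(rep("ACGTACGTACGTACG", 100))
  expect_identical(subsample_to_norm(reads, 100), reads)
  s1 <- subsample_to_norm(reads, 40, seed = 9)
  s2 <- subsample_to_norm(reads, 40, seed = 9)
  expect_equal(nrow(s1), 40L)
  expect_identical(s1, s2)
  small <- mk_reads(rep("ACGT", 10))
  expect_warning(out <- subsample_to_norm(small, 40), "10 reads")
  expect_equal(nrow(out), 10L)
  expect_error(subsample_to_norm(reads, -1), "non-negative")
})

test_that("adapter trimming removes the longest matching suffix", {
  adapter <- "AGATCGGA"
  r <- mk_reads(paste0("ACGTACGT", adapter))
  out <- trim_adapter(r, adapter)
  expect_equal(out$seq, "ACGTACGT")
  expect_equal(nchar(out$qual), 8L)

  partial <- mk_reads(paste0("ACGTACGT", substr(adapter, 1, 6)))
  expect_equal(trim_adapter(partial, adapter)$seq, "ACGTACGT")

  none <- mk_reads("ACGTACGTTTTT")
  expect_identical(trim_adapter(none, adapter)$seq, none$seq)

  tiny <- mk_reads("ACG")
  expect_identical(trim_adapter(tiny, adapter)$seq, "ACG")
  expect_error(trim_adapter(r, ""), "non-empty")
})

test_that("N, quality and motif filters apply the documented thresholds", {
  # 20 bases with 2 Ns: 10% > 8% -> discarded even though motif present
  n_rich <- mk_reads(paste0("CCGG", strrep("T", 12), "NN", "TT"))
  expect_equal(filter_reads(n_rich, len_range = c(13, 25))$counts[["clean"]],
               0L)
  # exactly 15% of bases below Q30 is discarded (inclusive bound)
  lowq <- mk_reads("CCGGTTTTTTTTTTTTTTTT",
                   quals = paste0(strrep("=", 3), strrep("I", 17)))
  expect_equal(filter_reads(lowq, len_range = c(13, 25))$counts[["clean"]],
               0L)
  # 14.9%-equivalent (2 of 20) survives
  lowq2 <- mk_reads("CCGGTTTTTTTTTTTTTTTT",
                    quals = paste0(strrep("=", 2), strrep("I", 18)))
  expect_equal(filter_reads(lowq2, len_range = c(13, 25))$counts[["clean"]],
               1L)
  # clean 15-mer with a motif passes every stage
  good <- mk_reads("CCGGTTTTTTTTTTT")
  out <- filter_reads(good)
  expect_equal(unname(out$counts),
               c(1L, 1L, 1L, 1L))
  # motif on the reverse strand counts as an enzyme read
  rc <- mk_reads(revcomp("CCAGGTTTTTTTTTT"))
  expect_equal(filter_reads(rc)$counts[["enzyme"]], 1L)
  # no motif in either orientation -> removed at the enzyme stage
  bare <- mk_reads("ATATATATATATATA")
  expect_equal(filter_reads(bare)$counts[["enzyme"]], 0L)
  # empty input gives a zero ladder
  empty <- filter_reads(mk_reads(character(0)))
  expect_equal(unname(empty$counts), c(0L, 0L, 0L, 0L))
})

test_that("length gate bounds the range stage at 13-17", {
  reads <- mk_reads(c(strrep("CCGGT", 4),          # 20 nt: out of range
                      "CCGGTTTTTTTTT",             # 13 nt: in range
                      "CCGGTTTTTTTTTTTTT"))        # 17 nt: in range
  out <- filter_reads(reads)
  expect_equal(out$counts[["enzyme"]], 3L)
  expect_equal(out$counts[["range"]], 2L)
  expect_equal(out$counts[["clean"]], 2L)
})

test_that("ledger is monotone and percent reproduces published rows", {
  expect_error(qc_ledger("s", 10, 12, 9, 8, 7, 6), "non-increasing")
  tab <- lens_qc_summary()
  recomputed <- vapply(seq_len(nrow(tab)), function(i)
    qc_ledger(tab$sample[i], tab$raw[i], tab$norm[i], tab$adapter[i],
              tab$enzyme[i], tab$range[i], tab$clean[i])$percent,
    numeric(1))
  expect_equal(recomputed, tab$percent)
})

test_that("ladder counts never increase on arbitrary read sets", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 60
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T", "N"), sample(8:22, 1),
                   replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
            collapse = ""), character(1))
    quals <- vapply(nchar(seqs), function(L)
      paste(sample(c("I", "=", "5"), L, replace = TRUE,
                   prob = c(.8, .1, .1)), collapse = ""), character(1))
    res <- qc_pipeline(mk_reads(seqs, quals), adapter = "AGATCGGAAGAGC",
                       norm_depth = 50, seed = rep)
    led <- res$ledger
    counts <- unlist(led[c("raw", "norm", "adapter", "enzyme", "range",
                           "clean")])
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("clean set equals the intersection of the per-read predicates", {
  set.seed(88)
  seqs <- c("CCGGTTTTTTTTTTT", "ATATATATATATATA",
            paste0("CCGG", strrep("N", 4), "TTTTTTT"),
            "CCAGGTTTTTTTTTT")
  quals <- c(strrep("I", 15), strrep("I", 15),
             strrep("I", 15), paste0(strrep("5", 3), strrep("I", 12)))
  reads <- mk_reads(seqs, quals)
  out <- filter_reads(reads)
  keep <- has_enzyme_site(seqs) &
    nchar(seqs) >= 13 & nchar(seqs) <= 17 &
    methylrad:::frac_n(seqs) <= 0.08 &
    methylrad:::frac_below_q(quals) < 0.15
  expect_identical(out$reads$seq, seqs[keep])
})

test_that("planted failure modes are lost at the expected stages", {
  cfg <- sim_config(seed = 5, n_chrom = 1L, chrom_len = 20000L,
                    n_genes = 10L)
  ds <- simulate_dataset(cfg)
  reads <- ds$reads[[1]]
  res <- qc_pipeline(reads, adapter = cfg$adapter)
  led <- res$ledger
  # good + adapter-carrying reads all clean; planted failures per class
  n_fail <- led$norm - led$clean
  n_motifless <- led$norm - led$enzyme
  n_clean_stage <- led$range - led$clean
  # back out the planted counts from the generator's rounding rule
  n_good <- led$norm / (1 + sum(cfg$qc_fail_fracs))
  expect_equal(n_motifless, round(cfg$qc_fail_fracs[["motifless"]] * n_good),
               tolerance = 0.01)
  expect_equal(n_clean_stage,
               round((cfg$qc_fail_fracs[["n_rich"]] +
                        cfg$qc_fail_fracs[["low_qual"]]) * n_good),
               tolerance = 0.01)
  expect_equal(led$range, led$enzyme)  # all enzyme reads in 13-17 range
  expect_equal(n_fail, n_motifless + n_clean_stage)
})
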