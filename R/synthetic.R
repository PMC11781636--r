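# Synthetic-data generator: random genome with guaranteed recognition
# sites, non-overlapping gene models, planted per-site methylation levels
# with differential sites and promoter-coupled expression, tag reads with
# planted QC failures, and negative-binomial expression counts. Every
# stage of the pipeline can be exercised end to end from these outputs
# with known ground truth, fully deterministically under one seed.

#' Simulation configuration
#'
#' Defaults emulate the profiled study design: two groups (young
#' reference samples `SQ_*`, aged comparison samples `SL_*`) of three
#' replicates each, site methylation levels drawn from Beta(2, 5), and a
#' mean tag depth scaled so the average realized site depth is about 21
#' (the observed mean CCGG site coverage). Differential sites receive a
#' 4-fold shift (the >2-fold calling rule with headroom), split evenly
#' between hyper- and hypomethylation.
#'
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param n_chrom,chrom_len chromosome count and length (bases).
#' @param gc genome GC content.
#' @param n_genes total gene count, spread across chromosomes.
#' @param n_young,n_aged replicates per group.
#' @param meth_alpha,meth_beta Beta parameters of baseline site levels.
#' @param frac_dms fraction of sites with a planted group shift.
#' @param dms_fold multiplicative methylation shift of planted sites.
#' @param mean_depth expected tag depth at methylation level 1.
#' @param dispersion NB dispersion of tag counts.
#' @param frac_coupled fraction of promoter-bearing genes whose
#'   expression is negatively coupled to promoter methylation.
#' @param coupling_sd per-sample lognormal sd of coupled promoter
#'   methylation (creates within-group variation the correlation needs).
#' @param coupling_slope strength of the negative methylation-expression
#'   link on the log scale.
#' @param expr_noise_sd residual log2 expression noise of coupled genes.
#' @param deg_frac fraction of genes with a planted expression-only
#'   group shift (DEG decoys for the integration analysis).
#' @param deg_fold expression fold shift of planted DEGs.
#' @param expr_dispersion NB dispersion of expression counts.
#' @param expr_base_log2 mean baseline log2 expression.
#' @param qc_fail_fracs named fractions (`n_rich`, `low_qual`,
#'   `motifless`) of planted QC-failing reads, relative to good reads.
#' @param adapter adapter sequence appended to a fraction of reads.
#' @param adapter_frac fraction of good reads carrying the adapter.
#' @param tag_len reference tag window length.
#' @param promoter_span promoter width upstream of the TSS.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_len = 50000L,
                       gc = 0.45, n_genes = 60L, n_young = 3L,
                       n_aged = 3L, meth_alpha = 2, meth_beta = 5,
                       frac_dms = 0.10, dms_fold = 4, mean_depth = 75,
                       dispersion = 0.2, frac_coupled = 0.15,
                       coupling_sd = 0.3, coupling_slope = 1,
                       expr_noise_sd = 0.15, deg_frac = 0.10,
                       deg_fold = 4, expr_dispersion = 0.05,
                       expr_base_log2 = 7,
                       qc_fail_fracs = c(n_rich = 0.04, low_qual = 0.04,
                                         motifless = 0.04),
                       adapter = "AGATCGGAAGAGC", adapter_frac = 0.2,
                       tag_len = 15L, promoter_span = 2000L) {
  cfg <- as.list(environment())
  stopifnot(cfg$chrom_len >= 1000L, cfg$mean_depth >= 1,
            all(unlist(cfg[c("frac_dms", "frac_coupled", "deg_frac",
                             "adapter_frac")]) >= 0),
            all(unlist(cfg[c("frac_dms", "frac_coupled", "deg_frac",
                             "adapter_frac")]) <= 1),
            all(qc_fail_fracs >= 0 & qc_fail_fracs <= 1))
  structure(cfg, class = "sim_config")
}

sample_ids <- function(config) {
  list(young = paste0("SQ_", seq_len(config$n_young)),
       aged = paste0("SL_", seq_len(config$n_aged)))
}

#' Generate a random genome and gene models
#'
#' Bases are drawn at the configured GC content; one CCGG and one CCWGG
#' locus are planted per 2 kb block so both site classes are guaranteed
#' throughout. Genes are packed without overlap into per-chromosome
#' slots, strands alternating, each with three exons and a CDS that
#' leaves terminal UTRs.
#'
#' @param config a `sim_config`.
#' @return list with `genome` ([Biostrings::DNAStringSet]) and `models`
#'   (a `gene_models` object).
#' @export
make_genome_and_genes <- function(config) {
  local_seed(config$seed + 1L, {
    probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
               G = config$gc / 2, T = (1 - config$gc) / 2)
    seqs <- character(config$n_chrom)
    for (ci in seq_len(config$n_chrom)) {
      bases <- sample(names(probs), config$chrom_len, replace = TRUE,
                      prob = probs)
      # plant one locus of each class per 2 kb block
      for (bs in seq(1L, config$chrom_len - 2000L, by = 2000L)) {
        p1 <- bs + sample.int(900L, 1)
        bases[p1:(p1 + 3L)] <- c("C", "C", "G", "G")
        p2 <- bs + 1000L + sample.int(900L, 1)
        bases[p2:(p2 + 4L)] <-
          c("C", "C", sample(c("A", "T"), 1), "G", "G")
      }
      seqs[ci] <- paste(bases, collapse = "")
    }
    names(seqs) <- paste0("chr", seq_len(config$n_chrom))
    genome <- Biostrings::DNAStringSet(seqs)

    per_chrom <- diff(floor(seq(0, config$n_genes,
                                length.out = config$n_chrom + 1L)))
    grow <- list(); erow <- list(); crow <- list()
    gidx <- 0L
    for (ci in seq_len(config$n_chrom)) {
      ng <- per_chrom[ci]
      if (ng == 0L) next
      slot <- floor(config$chrom_len / ng)
      if (slot < 400L) stop("infeasible gene packing: too many genes")
      for (si in seq_len(ng)) {
        gidx <- gidx + 1L
        gid <- sprintf("gene%03d", gidx)
        slot_start <- (si - 1L) * slot
        glen <- floor(slot * stats::runif(1, 0.30, 0.42))
        gstart <- slot_start + floor(slot * stats::runif(1, 0.25, 0.35))
        gend <- gstart + glen
        strand <- sample(c("+", "-"), 1)
        grow[[gidx]] <- data.frame(
          gene_id = gid, chrom = names(seqs)[ci], strand = strand,
          start = gstart, end = gend, stringsAsFactors = FALSE)
        # three exons at fixed relative coordinates
        ef <- rbind(c(0, 0.30), c(0.45, 0.70), c(0.85, 1.0))
        erow[[gidx]] <- data.frame(
          gene_id = gid,
          start = gstart + floor(ef[, 1] * glen),
          end = gstart + ceiling(ef[, 2] * glen),
          stringsAsFactors = FALSE)
        # CDS spans the middle, leaving UTRs on the terminal exons
        cs <- gstart + floor(0.12 * glen)
        ce <- gstart + ceiling(0.93 * glen)
        ex <- erow[[gidx]]
        keep <- ex$end > cs & ex$start < ce
        crow[[gidx]] <- data.frame(
          gene_id = gid, start = pmax(ex$start[keep], cs),
          end = pmin(ex$end[keep], ce), stringsAsFactors = FALSE)
      }
    }
    empty <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
    genes_df <- if (length(grow)) do.call(rbind, grow) else
      cbind(empty[, "gene_id", drop = FALSE],
            data.frame(chrom = character(), strand = character(),
                       start = integer(), end = integer()))
    list(genome = genome,
         models = gene_models(
           genes_df,
           if (length(erow)) do.call(rbind, erow) else empty,
           if (length(crow)) do.call(rbind, crow) else NULL))
  })
}

#' Plant per-site methylation levels and ground truth
#'
#' Baseline levels are Beta(alpha, beta), shared across groups. A
#' `frac_dms` subset of sites gets a `dms_fold` shift in the aged group
#' (up or down, split evenly, clipped to (0, 1]). A `frac_coupled`
#' subset of promoter-bearing genes has all promoter sites shifted as a
#' block (making them differential) plus per-sample lognormal variation
#' shared within the gene, which the coupled expression tracks
#' negatively. A disjoint `deg_frac` subset of genes is marked for an
#' expression-only shift.
#'
#' @param catalog a `site_catalog` (non-empty).
#' @param models a `gene_models` object.
#' @param config a `sim_config`.
#' @return list of class `ground_truth`: `level` (site-by-sample true
#'   methylation levels), `groups`, `dms` (site_id, direction),
#'   `coupled_genes` (gene_id, meth_direction), `deg_genes` (gene_id,
#'   direction), `prom_map`.
#' @export
plant_methylation <- function(catalog, models, config) {
  if (nrow(catalog) == 0L) {
    if (config$frac_dms > 0) stop("cannot plant DMSs in an empty catalog")
  }
  local_seed(config$seed + 2L, {
    ids <- sample_ids(config)
    samples <- c(ids$young, ids$aged)
    n <- nrow(catalog)
    base <- pmin(0.98, pmax(0.02,
      stats::rbeta(n, config$meth_alpha, config$meth_beta)))
    names(base) <- catalog$site_id

    prom_map <- promoter_map(catalog, models, span = config$promoter_span)
    prom_genes <- unique(prom_map$gene_id)
    n_coupled <- round(config$frac_coupled * length(prom_genes))
    # greedy pick avoiding genes whose promoters share sites with an
    # already-chosen coupled gene, so planted shifts never collide
    coupled <- character(0)
    taken_sites <- character(0)
    for (gid in sample(prom_genes)) {
      if (length(coupled) >= n_coupled) break
      s <- prom_map$site_id[prom_map$gene_id == gid]
      if (!any(s %in% taken_sites)) {
        coupled <- c(coupled, gid)
        taken_sites <- c(taken_sites, s)
      }
    }
    coupled_dir <- sample(c("hyper", "hypo"), length(coupled),
                          replace = TRUE)
    coupled_site_list <- lapply(coupled, function(gid)
      unique(prom_map$site_id[prom_map$gene_id == gid]))
    coupled_sites <- unlist(coupled_site_list)

    free <- setdiff(catalog$site_id, coupled_sites)
    n_dms <- round(config$frac_dms * n)
    dms_free <- sample(free, min(n_dms, length(free)))
    dms_dir <- sample(c("hyper", "hypo"), length(dms_free), replace = TRUE)

    aged_level <- base
    shift <- function(level, dir) {
      ifelse(rep_len(dir == "hyper", length(level)),
             pmin(1, level * config$dms_fold),
             level / config$dms_fold)
    }
    aged_level[dms_free] <- shift(base[dms_free], dms_dir)
    for (i in seq_along(coupled)) {
      s <- coupled_site_list[[i]]
      if (coupled_dir[i] == "hyper") {
        # keep the planted fold realizable on the (0, 1] level scale: a
        # promoter that hypermethylates k-fold must start below 1/k
        base[s] <- pmin(base[s], 0.8 / config$dms_fold)
      }
      aged_level[s] <- shift(base[s], coupled_dir[i])
    }

    level <- matrix(base, n, length(samples),
                    dimnames = list(catalog$site_id, samples))
    level[, ids$aged] <- aged_level

    # per-sample lognormal variation on coupled promoter sites, shared
    # within a gene so aggregate methylation varies smoothly
    coupling_z <- matrix(0, length(coupled), length(samples),
                         dimnames = list(coupled, samples))
    if (length(coupled)) {
      coupling_z[] <- stats::rnorm(length(coupling_z), 0, 1)
      for (i in seq_along(coupled)) {
        s <- coupled_site_list[[i]]
        jitter <- exp(config$coupling_sd * coupling_z[i, ] -
                        config$coupling_sd^2 / 2)
        level[s, ] <- pmin(1, sweep(level[s, , drop = FALSE], 2, jitter,
                                    "*"))
      }
    }

    dms <- data.frame(
      site_id = c(dms_free, coupled_sites),
      direction = c(dms_dir,
                    rep(coupled_dir, lengths(coupled_site_list))),
      stringsAsFactors = FALSE)
    # realized group-level shift; clipping at level 1 attenuates
    # hypermethylation of high-baseline sites below the nominal fold
    dms$true_l2fc <- log2(aged_level[dms$site_id] / base[dms$site_id])

    decoy_pool <- setdiff(models$genes$gene_id, coupled)
    n_deg <- round(config$deg_frac * nrow(models$genes))
    deg <- if (n_deg > 0) sample(decoy_pool, min(n_deg, length(decoy_pool)))
           else character(0)

    structure(list(
      level = level, groups = ids,
      dms = dms,
      coupled_genes = data.frame(gene_id = coupled,
                                 meth_direction = coupled_dir,
                                 stringsAsFactors = FALSE),
      deg_genes = data.frame(
        gene_id = deg,
        direction = sample(c("up", "down"), length(deg), replace = TRUE),
        stringsAsFactors = FALSE),
      prom_map = prom_map), class = "ground_truth")
  })
}

# random sequences of the given length containing no recognition motif
motifless_seqs <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n - length(out) + 4L), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
    out <- c(out, cand[!has_enzyme_site(cand)])
  }
  out[seq_len(n)]
}

#' Simulate per-sample tag reads with planted QC failures
#'
#' For each site with a reference tag, per-sample tag copies are drawn
#' from a negative binomial with mean `mean_depth x level`. A fraction
#' of good reads carries the adapter on the 3' end. Planted failures are
#' appended at the configured fractions: N-rich reads (2 of `tag_len`
#' bases set to N, > 8%), low-quality reads (3 bases at Phred 20, >= 15%
#' below Q30) and motif-less random reads. Reads are shuffled.
#'
#' @param truth a `ground_truth` from [plant_methylation()].
#' @param tag_library a `tag_library` (non-empty).
#' @param config a `sim_config`.
#' @return named list (one per sample) of read data.frames.
#' @export
simulate_reads <- function(truth, tag_library, config) {
  if (nrow(tag_library) == 0L) stop("empty tag_library")
  samples <- colnames(truth$level)
  tag_len <- attr(tag_library, "tag_len_range")[1]
  # site -> tag (first covering tag; every non-clipped site has one)
  site_ids <- strsplit(tag_library$site_ids, ",", fixed = TRUE)
  site_tag <- stats::setNames(
    rep(tag_library$tag, lengths(site_ids)), unlist(site_ids))
  sites <- intersect(rownames(truth$level), names(site_tag))

  out <- vector("list", length(samples))
  names(out) <- samples
  for (si in seq_along(samples)) {
    out[[si]] <- local_seed(config$seed + 100L + si, {
      mu <- config$mean_depth * truth$level[sites, samples[si]]
      depth <- if (config$dispersion > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
      } else {
        stats::rpois(length(mu), mu)
      }
      seqs <- rep(unname(site_tag[sites]), depth)
      quals <- strrep("I", nchar(seqs))
      n_good <- length(seqs)
      if (config$adapter_frac > 0 && n_good > 0) {
        w <- sample.int(n_good, round(config$adapter_frac * n_good))
        seqs[w] <- paste0(seqs[w], config$adapter)
        quals[w] <- strrep("I", nchar(seqs[w]))
      }
      ff <- config$qc_fail_fracs
      n_nr <- round(ff[["n_rich"]] * n_good)
      n_lq <- round(ff[["low_qual"]] * n_good)
      n_ml <- round(ff[["motifless"]] * n_good)
      if (n_nr > 0) {
        nr <- sample(unname(site_tag[sites]), n_nr, replace = TRUE)
        substr(nr, 8L, 9L) <- "NN"
        seqs <- c(seqs, nr)
        quals <- c(quals, strrep("I", nchar(nr)))
      }
      if (n_lq > 0) {
        lq <- sample(unname(site_tag[sites]), n_lq, replace = TRUE)
        seqs <- c(seqs, lq)
        quals <- c(quals, paste0(strrep("5", 3L),
                                 strrep("I", nchar(lq) - 3L)))
      }
      if (n_ml > 0) {
        ml <- motifless_seqs(n_ml, tag_len)
        seqs <- c(seqs, ml)
        quals <- c(quals, strrep("I", nchar(ml)))
      }
      ord <- sample.int(length(seqs))
      data.frame(
        id = sprintf("%s_r%06d", samples[si], seq_along(ord)),
        seq = seqs[ord], qual = quals[ord],
        row.names = NULL, stringsAsFactors = FALSE)
    })
  }
  out
}

#' Simulate expression counts coupled to promoter methylation
#'
#' Uncoupled genes get a flat NB baseline. Coupled genes' log mean
#' follows the gene's per-sample promoter methylation with a negative
#' slope plus Gaussian noise, so their realized methylation-expression
#' Pearson correlation is strongly negative (measured, not assumed).
#' Planted DEGs get a `deg_fold` group shift.
#'
#' @param truth a `ground_truth`.
#' @param models a `gene_models` object.
#' @param config a `sim_config`.
#' @return list with `counts` (gene-by-sample integer matrix) and `cpm`
#'   (counts per million).
#' @export
simulate_expression <- function(truth, models, config) {
  local_seed(config$seed + 3L, {
    samples <- colnames(truth$level)
    genes <- models$genes$gene_id
    base_l2 <- stats::rnorm(length(genes), config$expr_base_log2, 1.2)
    names(base_l2) <- genes
    l2mu <- matrix(rep(base_l2, length(samples)), length(genes),
                   length(samples), dimnames = list(genes, samples))

    for (gid in truth$coupled_genes$gene_id) {
      s <- truth$prom_map$site_id[truth$prom_map$gene_id == gid]
      meth <- colMeans(truth$level[s, , drop = FALSE])
      x <- log2(meth) - mean(log2(meth))
      l2mu[gid, ] <- base_l2[gid] - config$coupling_slope * x +
        stats::rnorm(length(samples), 0, config$expr_noise_sd)
    }
    aged <- truth$groups$aged
    for (i in seq_len(nrow(truth$deg_genes))) {
      gid <- truth$deg_genes$gene_id[i]
      sgn <- if (truth$deg_genes$direction[i] == "up") 1 else -1
      l2mu[gid, aged] <- l2mu[gid, aged] + sgn * log2(config$deg_fold)
    }
    mu <- 2^l2mu
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$expr_dispersion),
      nrow(mu), ncol(mu), dimnames = dimnames(mu))
    list(counts = counts,
         cpm = sweep(counts, 2, colSums(counts), "/") * 1e6)
  })
}

#' Random gene-set collections for enrichment demonstrations
#'
#' Draws terms of varying size from the gene universe for each of the
#' BP/CC/MF namespaces and a pathway collection; purely structural (no
#' planted biology), used to exercise the enrichment stage.
#'
#' @param gene_ids gene universe.
#' @param n_terms terms per namespace.
#' @param size_range term size range.
#' @param seed RNG seed.
#' @return list with `go` (list of three collections) and `kegg`.
#' @export
simulate_gene_sets <- function(gene_ids, n_terms = 12L,
                               size_range = c(4L, 15L), seed = 1L) {
  local_seed(seed + 4L, {
    draw <- function(ns) {
      sets <- lapply(seq_len(n_terms), function(i)
        sample(gene_ids, min(length(gene_ids),
                             sample(size_range[1]:size_range[2], 1))))
      names(sets) <- sprintf("%s_term%02d", ns, seq_len(n_terms))
      gene_set_collection(sets, ns)
    }
    list(go = list(draw("BP"), draw("CC"), draw("MF")),
         kegg = draw("pathway"))
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs genome/gene generation, digestion, truth planting, read
#' simulation and expression simulation under one configuration.
#'
#' @param config a `sim_config`.
#' @return list with `genome`, `models`, `catalog`, `tags`, `truth`,
#'   `reads` (per-sample list), `expression` (counts + cpm), `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  gg <- make_genome_and_genes(config)
  catalog <- enumerate_sites(gg$genome)
  tags <- extract_tags(gg$genome, catalog, tag_len = config$tag_len)
  truth <- plant_methylation(catalog, gg$models, config)
  reads <- simulate_reads(truth, tags, config)
  expr <- simulate_expression(truth, gg$models, config)
  list(genome = gg$genome, models = gg$models, catalog = catalog,
       tags = tags, truth = truth, reads = reads, expression = expr,
       config = config)
}
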