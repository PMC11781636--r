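# End-to-end orchestration: run every stage in dependency order against a
# synthetic dataset (or user-supplied inputs written in the same formats),
# emit the tabular outputs each figure-equivalent analysis needs, and
# record a manifest of parameters, outputs and input checksums.

write_stage <- function(manifest, stage, files) {
  manifest$stages[[stage]] <- basename(unlist(files))
  manifest
}

#' Run the full methylation analysis pipeline
#'
#' Stages: simulate (or load) inputs, electronic digestion, read QC,
#' tag quantification, differential methylation, feature/metagene
#' annotation, methylation-expression integration, and (when gene sets
#' are available) enrichment of the selected genes. Each stage writes
#' its tables under `out_dir`; a `manifest.json` records package
#' version, parameters, per-stage outputs and input checksums. A stage
#' failure aborts with the failing stage named; outputs of completed
#' stages are retained. Reruns with the same config are byte-identical.
#'
#' @param config a [sim_config()]; drives both the synthetic inputs and
#'   the stage parameters.
#' @param out_dir output directory (created if needed).
#' @param gene_sets `"auto"` to generate demonstration gene sets,
#'   `NULL` to skip enrichment (logged, not an error), or a list with
#'   elements `go` (list of collections) and `kegg`.
#' @param min_depth site validity depth threshold (default 3).
#' @param min_abs_log2fc fold-change gate for calling (default 1).
#' @param alpha significance level (default 0.05).
#' @param r_cut integration correlation cutoff (default -0.8).
#' @return invisibly, a list with the main in-memory results
#'   (`dms`, `deg`, `integration`, `selected`, `enrichment`, `ledger`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         gene_sets = "auto", min_depth = 3L,
                         min_abs_log2fc = 1, alpha = 0.05, r_cut = -0.8) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  manifest <- list(
    package = "methylrad",
    version = as.character(utils::packageVersion("methylrad")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = c(unclass(config),
                   list(min_depth = min_depth,
                        min_abs_log2fc = min_abs_log2fc, alpha = alpha,
                        r_cut = r_cut)),
    stages = list())
  stage <- "simulate"
  result <- tryCatch({
    ## simulate ---------------------------------------------------------
    ds <- simulate_dataset(config)
    Biostrings::writeXStringSet(ds$genome, pth("genome.fa"))
    write_gene_models_gff3(ds$models, pth("genes.gff3"))
    fq <- vapply(names(ds$reads), function(s) {
      write_fastq(ds$reads[[s]], pth(paste0("reads_", s, ".fastq")))
    }, character(1))
    cnt <- data.frame(gene_id = rownames(ds$expression$counts),
                      ds$expression$counts, check.names = FALSE)
    write_tsv(cnt, pth("expression_counts.tsv"))
    write_tsv(ds$truth$dms, pth("truth_dms.tsv"))
    write_tsv(ds$truth$coupled_genes, pth("truth_coupled_genes.tsv"))
    manifest <- write_stage(manifest, "simulate",
                            c("genome.fa", "genes.gff3", fq,
                              "expression_counts.tsv", "truth_dms.tsv",
                              "truth_coupled_genes.tsv"))
    manifest$input_checksums <- as.list(
      tools::md5sum(c(pth("genome.fa"), pth("genes.gff3"))))
    names(manifest$input_checksums) <-
      basename(names(manifest$input_checksums))

    ## digest -----------------------------------------------------------
    stage <- "digest"
    write_catalog_bed(ds$catalog, pth("sites.bed"))
    write_tsv(per_chromosome_report(ds$catalog), pth("site_report.tsv"))
    write_tsv(as.data.frame(ds$tags), pth("tags.tsv"))
    manifest <- write_stage(manifest, "digest",
                            c("sites.bed", "site_report.tsv", "tags.tsv"))

    ## qc ---------------------------------------------------------------
    stage <- "qc"
    samples <- names(ds$reads)
    qc <- lapply(samples, function(s) {
      qc_pipeline(ds$reads[[s]], sample = s, adapter = config$adapter,
                  seed = config$seed + 200L)
    })
    names(qc) <- samples
    ledger <- do.call(rbind, lapply(qc, `[[`, "ledger"))
    write_tsv(ledger, pth("qc_ledger.tsv"))
    manifest <- write_stage(manifest, "qc", "qc_ledger.tsv")

    ## quantify ---------------------------------------------------------
    stage <- "quantify"
    matched <- lapply(samples, function(s) match_tags(qc[[s]]$reads,
                                                      ds$tags))
    depth <- do.call(cbind, lapply(matched, `[[`, "depth"))
    colnames(depth) <- samples
    lib <- vapply(samples, function(s) nrow(qc[[s]]$reads), integer(1))
    counts <- site_count_matrix(depth, lib)
    stats_tab <- data.frame(
      sample = samples,
      t(vapply(matched, `[[`, integer(3), "stats")))
    write_tsv(data.frame(site_id = rownames(depth), depth,
                         check.names = FALSE), pth("depth.tsv"))
    write_tsv(data.frame(site_id = rownames(depth),
                         round(counts$rpm, 4), check.names = FALSE),
              pth("rpm.tsv"))
    write_tsv(stats_tab, pth("match_stats.tsv"))
    manifest <- write_stage(manifest, "quantify",
                            c("depth.tsv", "rpm.tsv", "match_stats.tsv"))

    ## differential methylation -----------------------------------------
    stage <- "diffmeth"
    valid_counts <- filter_valid_sites(counts, min_depth)
    dms <- diff_test(valid_counts$depth, ds$truth$groups$young,
                     ds$truth$groups$aged,
                     min_abs_log2fc = min_abs_log2fc, alpha = alpha,
                     use_fdr = FALSE, labels = c("hyper", "hypo"))
    write_tsv(dms, pth("dms_records.tsv"))
    volcano <- data.frame(feature_id = dms$feature_id,
                          log2fc = dms$log2fc,
                          neglog10p = -log10(pmax(dms$pvalue, 1e-300)),
                          direction = dms$direction)
    write_tsv(volcano, pth("volcano.tsv"))
    manifest <- write_stage(manifest, "diffmeth",
                            c("dms_records.tsv", "volcano.tsv"))

    ## annotate ---------------------------------------------------------
    stage <- "annotate"
    feats <- assign_feature(ds$catalog, ds$models)
    write_tsv(feats, pth("site_features.tsv"))
    prom <- promoter_map(ds$catalog, ds$models,
                         span = config$promoter_span)
    write_tsv(prom, pth("promoter_map.tsv"))
    groups <- ds$truth$groups
    prof <- do.call(rbind, lapply(names(groups), function(gname) {
      sig <- rowMeans(counts$rpm[, groups[[gname]], drop = FALSE])
      cbind(group = gname,
            metagene_profile(sig, ds$catalog, ds$models))
    }))
    write_tsv(prof, pth("metagene.tsv"))
    manifest <- write_stage(manifest, "annotate",
                            c("site_features.tsv", "promoter_map.tsv",
                              "metagene.tsv"))

    ## integrate --------------------------------------------------------
    stage <- "integrate"
    deg <- diff_test(ds$expression$counts, groups$young, groups$aged,
                     min_abs_log2fc = min_abs_log2fc, alpha = alpha,
                     use_fdr = TRUE, labels = c("up", "down"))
    deg_set <- deg$feature_id[deg$direction != "ns"]
    dms_sites <- dms$feature_id[dms$direction != "ns"]
    dms_genes <- unique(prom$gene_id[prom$site_id %in% dms_sites])
    agg <- aggregate_promoter_methylation(
      prom, counts$rpm, valid = apply_validity(counts$depth, min_depth))
    rec <- integration_records(agg$meth, ds$expression$cpm,
                               groups$young, groups$aged)
    sel <- select_negative_pairs(rec, deg_set, dms_genes,
                                 r_cut = r_cut, alpha = alpha)
    write_tsv(rec, pth("integration_records.tsv"))
    write_tsv(sel, pth("selected_genes.tsv"))
    quad <- as.data.frame(table(quadrant = factor(rec$quadrant, 1:4)))
    write_tsv(quad, pth("quadrant_counts.tsv"))
    manifest <- write_stage(manifest, "integrate",
                            c("integration_records.tsv",
                              "selected_genes.tsv",
                              "quadrant_counts.tsv"))

    ## enrich (optional) -------------------------------------------------
    stage <- "enrich"
    enr <- NULL
    if (is.null(gene_sets)) {
      message("no gene sets supplied; enrichment stage skipped")
    } else {
      if (identical(gene_sets, "auto")) {
        gene_sets <- simulate_gene_sets(ds$models$genes$gene_id,
                                        seed = config$seed)
      }
      study <- if (nrow(sel)) sel$gene_id else deg_set
      enr <- enrich_pipeline(study, gene_sets$go, gene_sets$kegg,
                             background = ds$models$genes$gene_id)
      write_tsv(enr$go, pth("go_full.tsv"))
      write_tsv(enr$go_top30, pth("go_top30.tsv"))
      write_tsv(enr$kegg, pth("kegg_full.tsv"))
      write_tsv(enr$kegg_top20, pth("kegg_top20.tsv"))
      manifest <- write_stage(manifest, "enrich",
                              c("go_full.tsv", "go_top30.tsv",
                                "kegg_full.tsv", "kegg_top20.tsv"))
    }

    jsonlite::write_json(manifest, pth("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(dataset = ds, ledger = ledger, counts = counts, dms = dms,
         deg = deg, integration = rec, selected = sel, enrichment = enr,
         manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
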