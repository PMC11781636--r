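# Hypergeometric over-representation analysis against GMT gene sets, with
# the display-selection rules used for GO (top 10 per namespace among
# terms hitting more than 2 study genes) and KEGG (top 20 overall).

#' Read a GMT gene-set file
#'
#' @param path GMT file (term, description, member genes per line).
#' @param namespace label attached to every term (`"BP"`, `"CC"`,
#'   `"MF"`, `"pathway"`).
#' @return data.frame-backed collection of class `gene_set_collection`
#'   with columns `term_id`, `namespace` and a list column `genes`.
#' @export
read_gmt <- function(path, namespace = "pathway") {
  sets <- fgsea::gmtPathways(path)
  gene_set_collection(sets, namespace)
}

#' Build a gene-set collection from a named list
#'
#' @param sets named list of character vectors (term id -> member genes).
#' @param namespace namespace label for all terms.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, namespace = "pathway") {
  structure(
    data.frame(term_id = names(sets), namespace = namespace,
               genes = I(unname(lapply(sets, unique))),
               stringsAsFactors = FALSE),
    class = c("gene_set_collection", "data.frame"))
}

#' Write a collection as GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$term_id[i], collection$namespace[i],
            collection$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test for one term
#'
#' Upper-tail inclusive: `p = P[X >= k]` for
#' `X ~ Hypergeometric(N, K, n)` with `N` the background size, `K` the
#' term size within the background, `n` the study-set size and `k` the
#' observed hits. `k = 0` gives p = 1.
#'
#' @param study_set character vector of study genes (subset of the
#'   background after intersection).
#' @param term_genes character vector of term member genes.
#' @param background character vector, the gene universe.
#' @return one-row data.frame with `k`, `K`, `n`, `N`, `pvalue`.
#' @export
hypergeom_test <- function(study_set, term_genes, background) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  study <- intersect(unique(study_set), background)
  term <- intersect(unique(term_genes), background)
  k <- length(intersect(study, term))
  K <- length(term); n <- length(study); N <- length(background)
  p <- if (k == 0L) 1 else
    stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(k = k, K = K, n = n, N = N, pvalue = p)
}

#' Enrichment of a study set against a collection
#'
#' @param study_set character vector of study genes.
#' @param collection a `gene_set_collection`.
#' @param background gene universe.
#' @return `enrichment_result` data.frame with per-term `term_id`,
#'   `namespace`, `k`, `K`, `n`, `N`, `pvalue`, `fdr`, `neglog10p`,
#'   `enrichment_score` ((k/n) / (K/N)) and `gene_list` (comma-joined
#'   hits), ordered by p-value then term id.
#' @export
enrich_test <- function(study_set, collection, background) {
  background <- unique(background)
  study <- intersect(unique(study_set), background)
  rows <- lapply(seq_len(nrow(collection)), function(i) {
    res <- hypergeom_test(study, collection$genes[[i]], background)
    res$term_id <- collection$term_id[i]
    res$namespace <- collection$namespace[i]
    res$gene_list <- paste(
      intersect(study, collection$genes[[i]]), collapse = ",")
    res
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(term_id = character(), namespace = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), pvalue = numeric(), fdr = numeric(),
                      neglog10p = numeric(), enrichment_score = numeric(),
                      gene_list = character(), stringsAsFactors = FALSE))
  }
  out$fdr <- bh_adjust(out$pvalue)
  out$neglog10p <- -log10(out$pvalue)
  out$enrichment_score <- ifelse(out$K > 0 & out$n > 0,
                                 (out$k / out$n) / (out$K / out$N), 0)
  out <- out[order(out$pvalue, out$term_id),
             c("term_id", "namespace", "k", "K", "n", "N", "pvalue",
               "fdr", "neglog10p", "enrichment_score", "gene_list")]
  rownames(out) <- NULL
  out
}

#' Display-selection rules for enrichment tables
#'
#' `go_top30`: keep terms with more than 2 study hits, sort by
#' -log10 p descending within each of BP/CC/MF, take 10 per namespace
#' (fewer if fewer qualify). `kegg_top20`: same filter and sort, take 20
#' overall. Ties break by term id ascending.
#'
#' @param results an enrichment result data.frame from [enrich_test()].
#' @param mode `"go_top30"` or `"kegg_top20"`.
#' @return ordered subset of `results`.
#' @export
select_top_terms <- function(results, mode = c("go_top30", "kegg_top20")) {
  mode <- match.arg(mode)
  qual <- results[results$k > 2, , drop = FALSE]
  qual <- qual[order(-qual$neglog10p, qual$term_id), , drop = FALSE]
  out <- if (mode == "kegg_top20") {
    utils::head(qual, 20L)
  } else {
    do.call(rbind, lapply(c("BP", "CC", "MF"), function(ns) {
      utils::head(qual[qual$namespace == ns, , drop = FALSE], 10L)
    }))
  }
  rownames(out) <- NULL
  out
}

#' Full enrichment pipeline over GO and KEGG collections
#'
#' Deduplicates the study set, intersects it with the background
#' (unknown ids are reported, not fatal), tests every collection, and
#' returns full tables plus the display subsets and bubble-chart data.
#'
#' @param gene_list study genes (duplicates allowed, deduplicated).
#' @param go_collections list of `gene_set_collection`s with namespaces
#'   BP/CC/MF, or `NULL`.
#' @param kegg_collection a `gene_set_collection` (namespace `pathway`),
#'   or `NULL`.
#' @param background gene universe.
#' @return list with `go` (full table), `go_top30`, `kegg`,
#'   `kegg_top20`, `unknown_genes`.
#' @export
enrich_pipeline <- function(gene_list, go_collections = NULL,
                            kegg_collection = NULL, background) {
  genes <- unique(gene_list)
  unknown <- setdiff(genes, background)
  if (length(unknown)) {
    message(sprintf("%d study gene(s) not in background ignored",
                    length(unknown)))
  }
  go <- NULL; go_top <- NULL
  if (!is.null(go_collections) && length(go_collections)) {
    go <- do.call(rbind, lapply(go_collections, function(col)
      enrich_test(genes, col, background)))
    rownames(go) <- NULL
    go_top <- select_top_terms(go, "go_top30")
  }
  kegg <- NULL; kegg_top <- NULL
  if (!is.null(kegg_collection)) {
    kegg <- enrich_test(genes, kegg_collection, background)
    kegg_top <- select_top_terms(kegg, "kegg_top20")
  }
  list(go = go, go_top30 = go_top, kegg = kegg, kegg_top20 = kegg_top,
       unknown_genes = unknown)
}
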