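# Joint methylation-expression analysis: aggregate promoter methylation
# per gene, correlate it with expression across samples (both groups
# pooled), select negatively correlated DEG / promoter-DMS pairs at the
# strict r < -0.8 and p < 0.05 cutoffs, and classify genes into the four
# quadrants of joint methylation/expression change.

#' Aggregate promoter methylation per gene
#'
#' Per-sample aggregate of the RPM rows of a gene's promoter sites
#' (mean by default, max optionally). Genes with no promoter site, or
#' none passing the validity mask in any sample, are excluded with a
#' reason code.
#'
#' @param prom_map data.frame from [promoter_map()].
#' @param rpm site-by-sample RPM matrix (rownames are site ids).
#' @param method `"mean"` or `"max"`.
#' @param valid optional logical site-by-sample validity mask; a gene is
#'   kept only if at least one of its promoter sites is valid in at
#'   least one sample.
#' @return list with `meth` (gene-by-sample matrix) and `excluded`
#'   (data.frame `gene_id`, `reason`).
#' @export
aggregate_promoter_methylation <- function(prom_map, rpm,
                                           method = c("mean", "max"),
                                           valid = NULL) {
  method <- match.arg(method)
  agg <- if (method == "mean") colMeans else function(m) apply(m, 2, max)
  genes <- unique(prom_map$gene_id)
  rows <- list(); excluded <- list()
  for (gid in genes) {
    sids <- prom_map$site_id[prom_map$gene_id == gid]
    sids <- intersect(sids, rownames(rpm))
    if (length(sids) == 0L) {
      excluded[[gid]] <- "no_promoter_site_quantified"
      next
    }
    if (!is.null(valid) && !any(valid[sids, , drop = FALSE])) {
      excluded[[gid]] <- "no_valid_promoter_site"
      next
    }
    rows[[gid]] <- agg(rpm[sids, , drop = FALSE])
  }
  meth <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(), 0, ncol(rpm), dimnames = list(NULL, colnames(rpm)))
  list(meth = meth,
       excluded = data.frame(gene_id = names(excluded),
                             reason = unlist(excluded, use.names = FALSE),
                             stringsAsFactors = FALSE))
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson coefficient with the two-sided p-value from the
#' t-transform on n - 2 degrees of freedom (via [stats::cor.test()]).
#' Constant vectors make the correlation undefined and raise an error
#' rather than returning r = 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with elements `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need paired vectors of length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Classify a gene into a four-quadrant category
#'
#' Quadrants follow the joint direction of expression and methylation
#' change: 1 = expression up, methylation up; 2 = expression down,
#' methylation up; 3 = both down; 4 = expression up, methylation down.
#' Negatively coupled genes fall in quadrants 2 and 4.
#'
#' @param meth_direction,expr_direction character vectors with values
#'   `"up"`/`"down"` (or `"hyper"`/`"hypo"` for methylation).
#' @return integer vector of quadrants 1-4; `NA` where a direction is
#'   missing or not called.
#' @export
quadrant_classify <- function(meth_direction, expr_direction) {
  meth_up <- meth_direction %in% c("up", "hyper")
  meth_dn <- meth_direction %in% c("down", "hypo")
  expr_up <- expr_direction == "up"
  expr_dn <- expr_direction == "down"
  q <- rep(NA_integer_, length(meth_direction))
  q[expr_up & meth_up] <- 1L
  q[expr_dn & meth_up] <- 2L
  q[expr_dn & meth_dn] <- 3L
  q[expr_up & meth_dn] <- 4L
  q
}

#' Correlate promoter methylation with expression for every gene
#'
#' Computes the pooled-sample Pearson correlation between a gene's
#' aggregate promoter methylation and its expression, plus group-wise
#' direction calls (comparison over reference on means, with a
#' pseudocount), and the quadrant.
#'
#' @param meth gene-by-sample promoter methylation matrix.
#' @param expr gene-by-sample expression matrix (same samples, same
#'   order).
#' @param group_a,group_b column names of the reference (young) and
#'   comparison (aged) groups.
#' @param log_scale correlate `log2(x + 1)`-transformed values (the
#'   default): normalized abundances are log-scaled before correlation,
#'   the usual choice for right-skewed RPM/CPM values. Direction calls
#'   are unaffected (the transform is monotone).
#' @return data.frame with `gene_id`, `r`, `p`, `meth_direction`,
#'   `expr_direction`, `quadrant`. Genes absent from either matrix or
#'   with constant vectors are skipped.
#' @export
integration_records <- function(meth, expr, group_a, group_b,
                                log_scale = TRUE) {
  stopifnot(identical(colnames(meth), colnames(expr)))
  if (log_scale) {
    meth <- log2(meth + 1)
    expr <- log2(expr + 1)
  }
  genes <- intersect(rownames(meth), rownames(expr))
  rows <- lapply(genes, function(gid) {
    m <- meth[gid, ]; e <- expr[gid, ]
    if (stats::sd(m) == 0 || stats::sd(e) == 0) return(NULL)
    ct <- pearson_cor(m, e)
    mdir <- if (mean(m[group_b]) > mean(m[group_a])) "up" else "down"
    edir <- if (mean(e[group_b]) > mean(e[group_a])) "up" else "down"
    data.frame(gene_id = gid, r = ct$r, p = ct$p,
               meth_direction = mdir, expr_direction = edir,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  if (is.null(rec)) {
    rec <- data.frame(gene_id = character(), r = numeric(), p = numeric(),
                      meth_direction = character(),
                      expr_direction = character(), stringsAsFactors = FALSE)
  }
  rec$quadrant <- quadrant_classify(rec$meth_direction, rec$expr_direction)
  rownames(rec) <- NULL
  rec
}

#' Select negatively coupled DEG / promoter-DMS genes
#'
#' A gene is selected iff r < `r_cut` (strictly), p < `alpha` (strictly),
#' it is a differentially expressed gene, and its promoter holds at
#' least one differentially methylated site. Output is ordered by r
#' ascending with gene id as tiebreak.
#'
#' @param records data.frame from [integration_records()].
#' @param deg_set character vector of DEG gene ids.
#' @param dms_promoter_genes character vector of genes with >= 1 DMS in
#'   their promoter.
#' @param r_cut correlation cutoff (default -0.8).
#' @param alpha p-value cutoff (default 0.05).
#' @return `records` restricted to selected genes, with a `selected`
#'   column set to `TRUE`, ordered deterministically.
#' @export
select_negative_pairs <- function(records, deg_set, dms_promoter_genes,
                                  r_cut = -0.8, alpha = 0.05) {
  sel <- records$r < r_cut & records$p < alpha &
    records$gene_id %in% deg_set &
    records$gene_id %in% dms_promoter_genes
  out <- records[sel, , drop = FALSE]
  out <- out[order(out$r, out$gene_id), , drop = FALSE]
  out$selected <- TRUE
  rownames(out) <- NULL
  out
}
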