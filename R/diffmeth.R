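# Two-group negative-binomial differential testing, shared by methylation
# sites (tag depth) and expression genes (read counts). The model follows
# the classic count-based recipe: median-of-ratios size factors, a
# per-feature method-of-moments dispersion on normalized counts (floored
# at zero, i.e. Poisson), and an exact-style two-sided test of the
# group-sum split conditional on the feature's total count.

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over features of the ratio
#' of the sample's count to the feature's geometric mean across samples,
#' computed over features with strictly positive counts in every sample.
#'
#' @param counts feature-by-sample count matrix.
#' @return positive numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no feature has positive counts in all samples; ",
         "consider adding a pseudocount before size-factor estimation")
  }
  logc <- log(counts[all_pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  apply(logc, 2, function(x) exp(stats::median(x - loggeo)))
}

# Method-of-moments dispersion per feature: alpha = max(0, (v - m) / m^2)
# with m the mean of normalized counts over all samples and v the
# within-group pooled variance of normalized counts.
mom_dispersion <- function(norm, idxA, idxB) {
  m <- rowMeans(norm)
  vA <- apply(norm[, idxA, drop = FALSE], 1, stats::var)
  vB <- apply(norm[, idxB, drop = FALSE], 1, stats::var)
  nA <- length(idxA); nB <- length(idxB)
  v <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
}

# Exact-style NB p-value for one feature: condition on the total count T
# and sum the probabilities of all splits (a, T - a) no more likely than
# the observed one. Group sums are modeled as NB with moments matched to
# the summed per-sample means and dispersions.
nb_exact_p <- function(kA, kB, muA, muB, varA, varB) {
  total <- kA + kB
  if (total == 0L) return(1)
  a <- 0:total
  pA <- if (varA > muA) {
    stats::dnbinom(a, mu = muA, size = muA^2 / (varA - muA))
  } else {
    stats::dpois(a, muA)
  }
  pB <- if (varB > muB) {
    stats::dnbinom(total - a, mu = muB, size = muB^2 / (varB - muB))
  } else {
    stats::dpois(total - a, muB)
  }
  joint <- pA * pB
  denom <- sum(joint)
  if (denom <= 0) return(1)
  pobs <- joint[kA + 1L]
  min(1, sum(joint[joint <= pobs * (1 + 1e-8)]) / denom)
}

#' Negative-binomial differential test between two groups
#'
#' For each feature, estimates a method-of-moments dispersion from the
#' normalized counts (pooled within groups, floored at zero), then tests
#' whether the observed split of the feature's total raw count between
#' the groups is compatible with equal normalized means, summing the
#' probabilities of all splits at most as likely as the observed one
#' (two-sided). The log2 fold change is computed on normalized group
#' means with a pseudocount applied to the fold change only, never to
#' the test.
#'
#' @param counts feature-by-sample raw count matrix (non-negative
#'   integers), rownames are feature ids.
#' @param group_a,group_b column names or indices of the reference
#'   (young) and comparison (aged) groups; each needs >= 2 replicates.
#' @param size_factors per-sample size factors; estimated from `counts`
#'   by default.
#' @param pseudocount added to normalized group means for the fold
#'   change.
#' @return data.frame with `feature_id`, `base_mean`, `log2fc`
#'   (comparison over reference), `pvalue`.
#' @export
nb_test <- function(counts, group_a, group_b,
                    size_factors = estimate_size_factors(counts),
                    pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  idxA <- if (is.character(group_a)) match(group_a, colnames(counts))
          else as.integer(group_a)
  idxB <- if (is.character(group_b)) match(group_b, colnames(counts))
          else as.integer(group_b)
  if (anyNA(idxA) || anyNA(idxB)) stop("unknown sample names in groups")
  if (length(idxA) < 2L || length(idxB) < 2L) {
    stop("each group needs at least 2 replicates for dispersion estimation")
  }
  sf <- size_factors
  if (any(sf <= 0)) stop("size factors must be positive")

  norm <- sweep(counts, 2, sf, "/")
  disp <- mom_dispersion(norm, idxA, idxB)
  mA <- rowMeans(norm[, idxA, drop = FALSE])
  mB <- rowMeans(norm[, idxB, drop = FALSE])
  base_mean <- rowMeans(norm)

  sfA <- sf[idxA]; sfB <- sf[idxB]
  kA <- as.integer(round(rowSums(counts[, idxA, drop = FALSE])))
  kB <- as.integer(round(rowSums(counts[, idxB, drop = FALSE])))
  # common normalized mean under the null, conditional on the total
  q0 <- (kA + kB) / (sum(sfA) + sum(sfB))
  muA <- q0 * sum(sfA)
  muB <- q0 * sum(sfB)
  varA <- muA + disp * q0^2 * sum(sfA^2)
  varB <- muB + disp * q0^2 * sum(sfB^2)

  pval <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_p(kA[i], kB[i], muA[i], muB[i], varA[i], varB[i])
  }, numeric(1))

  data.frame(feature_id = rownames(counts) %||%
               paste0("f", seq_len(nrow(counts))),
             base_mean = base_mean,
             log2fc = log2((mB + pseudocount) / (mA + pseudocount)),
             pvalue = pval,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()]); input is validated to lie in \[0, 1\].
#'
#' @param pvalues numeric vector of p-values.
#' @return adjusted p-values, elementwise >= the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differential features at fold-change and significance thresholds
#'
#' A feature is called iff `|log2fc| > min_abs_log2fc` and its p-value
#' (FDR-adjusted if `use_fdr`) is below `alpha`; the direction label is
#' `hyper` (or `up`) for positive and `hypo` (`down`) for negative fold
#' change, `ns` otherwise. Hyper plus hypo always equals the number of
#' called features.
#'
#' @param records data.frame from [nb_test()].
#' @param min_abs_log2fc fold-change gate, default 1 (i.e. 2-fold).
#' @param alpha significance level, default 0.05.
#' @param use_fdr gate on BH-adjusted p-values instead of raw p-values.
#' @param labels direction labels, `c("hyper", "hypo")` for methylation
#'   or `c("up", "down")` for expression.
#' @return `records` with added `fdr` and `direction` columns and a
#'   `summary` attribute (named counts `called`, first label, second
#'   label).
#' @export
call_differential <- function(records, min_abs_log2fc = 1, alpha = 0.05,
                              use_fdr = FALSE,
                              labels = c("hyper", "hypo")) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  records$fdr <- bh_adjust(records$pvalue)
  crit <- if (use_fdr) records$fdr else records$pvalue
  called <- abs(records$log2fc) > min_abs_log2fc & crit < alpha
  records$direction <- ifelse(!called, "ns",
                              ifelse(records$log2fc > 0,
                                     labels[1], labels[2]))
  counts <- c(sum(called), sum(records$direction == labels[1]),
              sum(records$direction == labels[2]))
  names(counts) <- c("called", labels)
  stopifnot(counts[2] + counts[3] == counts[1])
  attr(records, "summary") <- counts
  records
}

#' Two-group differential methylation/expression in one call
#'
#' Convenience wrapper: size factors, NB test, BH adjustment and
#' threshold calling.
#'
#' @inheritParams nb_test
#' @inheritParams call_differential
#' @return the annotated record data.frame from [call_differential()].
#' @export
diff_test <- function(counts, group_a, group_b, min_abs_log2fc = 1,
                      alpha = 0.05, use_fdr = FALSE,
                      labels = c("hyper", "hypo"), pseudocount = 1,
                      size_factors = estimate_size_factors(counts)) {
  res <- nb_test(counts, group_a, group_b, size_factors = size_factors,
                 pseudocount = pseudocount)
  call_differential(res, min_abs_log2fc = min_abs_log2fc, alpha = alpha,
                    use_fdr = use_fdr, labels = labels)
}
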