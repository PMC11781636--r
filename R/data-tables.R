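# Published per-library summaries of the profiled mouse lens study,
# shipped as plain TSVs. They carry the printed sequencing accounting
# (read-count ladder per library) and per-class site coverage, and are
# used to check the package's ledger arithmetic against the study's own
# numbers.

#' Published sequencing QC summary of the six lens libraries
#'
#' Read-count accounting ladder (raw, norm, adapter, enzyme, range,
#' clean, percent) for the three young (`SQ_*`) and three aged (`SL_*`)
#' mouse lens libraries of the profiled study.
#'
#' @return data.frame, one row per library.
#' @export
lens_qc_summary <- function() {
  utils::read.delim(system.file("extdata", "lens_qc_summary.tsv",
                                package = "methylrad"))
}

#' Published differential-site counts of the lens study
#'
#' Hyper- and hypomethylated differentially methylated site counts per
#' site class, with the published totals.
#'
#' @return data.frame, one row per site class.
#' @export
lens_dms_counts <- function() {
  utils::read.delim(system.file("extdata", "lens_dms_counts.tsv",
                                package = "methylrad"))
}

#' Published site-coverage summary of the six lens libraries
#'
#' Per-library counts of covered CCGG and CCWGG sites and their mean
#' sequencing depths.
#'
#' @return data.frame, one row per library.
#' @export
lens_site_depth <- function() {
  utils::read.delim(system.file("extdata", "lens_site_depth.tsv",
                                package = "methylrad"))
}
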