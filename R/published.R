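#' Published lead-SNP statistics bundled with the package
#'
#' Four loci reported with genome-wide significant differential effects
#' between schizophrenia and PTSD in European-ancestry PGC GWAS:
#' per-trait betas/SEs/p-values plus the differential z-score and p-value
#' (`published_lead_snps()`), and the corresponding trans-ancestry
#' quantitative-PTSD meta-analysis z-scores and p-values used for
#' replication triage (`published_replication()`).
#'
#' @return `data.table` of the bundled table.
#' @export
published_lead_snps <- function() {
  data.table::fread(system.file("extdata", "published_lead_snps.tsv",
                                package = "diffgwas"))
}

#' @rdname published_lead_snps
#' @export
published_replication <- function() {
  data.table::fread(system.file("extdata",
                                "published_transancestry_ptsd.tsv",
                                package = "diffgwas"))
}
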