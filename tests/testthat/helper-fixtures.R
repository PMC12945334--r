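# toy summary-statistics builders shared across test files

make_sumstats <- function(chrom, pos, a1 = "A", a2 = "G", beta = 0.1,
                          se = 0.01, p = NULL, eaf = 0.3, rsid = NULL) {
  k <- length(pos)
  if (is.null(rsid)) rsid <- sprintf("rs%03d", seq_len(k))
  tab <- data.table::data.table(
    chrom = as.character(rep_len(chrom, k)), pos = as.integer(pos),
    rsid = rsid, a1 = rep_len(a1, k), a2 = rep_len(a2, k),
    eaf = rep_len(eaf, k), beta = rep_len(beta, k), se = rep_len(se, k),
    p = 0, n = NA_integer_)
  tab$p <- if (is.null(p)) p_two_sided(tab$beta / tab$se) else rep_len(p, k)
  tab
}

# write a table out in a PGC-like dialect (CHR/POS/SNP/A1/A2/FRQ/BETA/SE/P)
write_toy_file <- function(tab, path = tempfile(fileext = ".tsv")) {
  out <- data.table::data.table(
    CHR = tab$chrom, POS = tab$pos, SNP = tab$rsid, A1 = tab$a1,
    A2 = tab$a2, FRQ = tab$eaf, BETA = tab$beta, SE = tab$se, P = tab$p)
  data.table::fwrite(out, path, sep = "\t")
  path
}
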