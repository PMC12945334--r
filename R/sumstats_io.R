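#' Default column dialect for summary-statistics files
#'
#' A dialect maps the semantic fields the pipeline needs to the column
#' names of a particular file format. Required fields: `chrom`, `pos`,
#' `rsid`, `a1` (effect allele), `a2` (other allele), `beta`, `se`, `p`.
#' Optional: `eaf` (effect-allele frequency), `n` (sample size).
#'
#' @param ... named overrides, e.g. `beta = "Effect"`.
#' @return named list mapping semantic field -> source column name.
#' @export
#' @examples
#' sumstats_dialect(p = "PVAL", eaf = "FREQ1")
sumstats_dialect <- function(...) {
  d <- list(chrom = "CHR", pos = "POS", rsid = "SNP", a1 = "A1",
            a2 = "A2", eaf = "FRQ", beta = "BETA", se = "SE", p = "P",
            n = "N")
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad))
      stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    d[names(ov)] <- ov
  }
  d
}

#' Read a column dialect from a YAML file
#'
#' The file holds `semantic: source-column` pairs, e.g. `beta: Effect`.
#'
#' @param path YAML file.
#' @return dialect list as from [sumstats_dialect()].
#' @export
read_dialect <- function(path) {
  do.call(sumstats_dialect, yaml::read_yaml(path))
}

.required_fields <- c("chrom", "pos", "rsid", "a1", "a2", "beta", "se", "p")

# fread, decompressing .gz through a base connection
.fread_any <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    data.table::fread(text = readLines(con), header = TRUE)
  } else {
    data.table::fread(path, header = TRUE)
  }
}

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a tab- or whitespace-separated file (optionally gzipped), maps
#' columns through `dialect`, and validates each row. Chromosome labels
#' are normalized by stripping any "chr" prefix; only autosomes 1..22 are
#' retained. Rows failing validation (non-positive SE, p outside (0,1],
#' non-nucleotide or indel alleles unless `allow_indels`, bad positions or
#' frequencies) are dropped and itemized in the `drop_log` attribute.
#'
#' @param path input file.
#' @param dialect column mapping, see [sumstats_dialect()].
#' @param allow_indels keep multi-character alleles? Default `FALSE`: the
#'   downstream analysis is SNP-focused.
#' @param verbose message the drop counts.
#' @return `data.table` with columns chrom, pos, rsid, a1, a2, eaf (may be
#'   NA), beta, se, p, n (may be NA), and attribute `drop_log` (named
#'   integer vector of dropped-row counts by reason).
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          allow_indels = FALSE, verbose = TRUE) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  raw <- .fread_any(path)
  missing_cols <- vapply(.required_fields, function(f)
    !(dialect[[f]] %in% names(raw)), logical(1))
  if (any(missing_cols))
    stop("configuration error: required column(s) missing from ", path,
         ": ", paste(unlist(dialect[.required_fields][missing_cols]),
                     collapse = ", "))

  tab <- data.table::data.table(
    chrom = as.character(raw[[dialect$chrom]]),
    pos   = suppressWarnings(as.integer(raw[[dialect$pos]])),
    rsid  = as.character(raw[[dialect$rsid]]),
    a1    = toupper(as.character(raw[[dialect$a1]])),
    a2    = toupper(as.character(raw[[dialect$a2]])),
    eaf   = if (dialect$eaf %in% names(raw))
      suppressWarnings(as.numeric(raw[[dialect$eaf]])) else NA_real_,
    beta  = suppressWarnings(as.numeric(raw[[dialect$beta]])),
    se    = suppressWarnings(as.numeric(raw[[dialect$se]])),
    p     = suppressWarnings(as.numeric(raw[[dialect$p]])),
    n     = if (dialect$n %in% names(raw))
      suppressWarnings(as.integer(raw[[dialect$n]])) else NA_integer_
  )
  tab[, chrom := sub("^chr", "", chrom, ignore.case = TRUE)]

  log <- c(non_autosome = 0L, bad_position = 0L, bad_allele = 0L,
           bad_se = 0L, bad_p = 0L, bad_beta = 0L, bad_eaf = 0L)
  keep_step <- function(ok, reason) {
    log[reason] <<- log[reason] + sum(!ok)
    tab <<- tab[ok]
  }
  nuc <- if (allow_indels) "^[ACGT]+$" else "^[ACGT]$"
  keep_step(tab$chrom %in% as.character(1:22), "non_autosome")
  keep_step(!is.na(tab$pos) & tab$pos >= 1L, "bad_position")
  keep_step(grepl(nuc, tab$a1) & grepl(nuc, tab$a2) & tab$a1 != tab$a2,
            "bad_allele")
  keep_step(is.finite(tab$se) & tab$se > 0, "bad_se")
  keep_step(is.finite(tab$p) & tab$p > 0 & tab$p <= 1, "bad_p")
  keep_step(is.finite(tab$beta), "bad_beta")
  keep_step(is.na(tab$eaf) | (tab$eaf >= 0 & tab$eaf <= 1), "bad_eaf")

  if (nrow(tab) == 0L)
    stop("input error: no valid rows in ", path)
  if (verbose && sum(log) > 0L)
    message("read_sumstats: dropped ", sum(log), " row(s) [",
            paste(names(log)[log > 0], log[log > 0], sep = "=",
                  collapse = ", "), "]")
  data.table::setattr(tab, "drop_log", log)
  tab[]
}

#' Filter SNPs by minor-allele frequency
#'
#' Retains rows with `min(eaf, 1 - eaf) >= threshold`. If the table has no
#' usable frequency column the filter is a no-op with a warning.
#'
#' @param table summary records from [read_sumstats()].
#' @param threshold MAF cutoff in `[0, 0.5)`. Default 0.05.
#' @return filtered `data.table`.
#' @export
filter_maf <- function(table, threshold = 0.05) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold >= 0.5)
    stop("parameter error: MAF threshold must lie in [0, 0.5)")
  if (!("eaf" %in% names(table)) || all(is.na(table$eaf))) {
    warning("filter_maf: no allele frequencies available; filter skipped")
    return(table)
  }
  table[pmin(eaf, 1 - eaf) >= threshold]
}

#' Harmonization policy
#'
#' @param ambiguous handling of strand-ambiguous (palindromic A/T, C/G)
#'   SNPs: `"exclude"` (default; strand flips and allele swaps cannot be
#'   distinguished from alleles alone) or `"freq"` (resolve orientation by
#'   comparing allele frequencies; pairs with frequency near 0.5 in either
#'   study are still excluded).
#' @param freq_margin with `ambiguous = "freq"`, exclude palindromic SNPs
#'   whose frequency is within `freq_margin` of 0.5 in either study.
#' @return policy list.
#' @export
harmonization_policy <- function(ambiguous = c("exclude", "freq"),
                                 freq_margin = 0.10) {
  list(ambiguous = match.arg(ambiguous), freq_margin = freq_margin)
}

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize two summary-statistics tables onto a shared effect allele
#'
#' Inner-joins the two tables on (chrom, pos) and aligns trait-1 records
#' to trait-2's effect-allele orientation: same-orientation pairs merge
#' as-is; swapped-allele pairs merge with the trait-1 beta negated (and
#' frequency complemented) and `flipped = TRUE`; allele-incompatible
#' pairs are excluded. rsid display identifiers are taken from trait 1.
#'
#' @param t1,t2 validated tables from [read_sumstats()].
#' @param policy see [harmonization_policy()].
#' @param verbose message merge/flip/exclusion counts.
#' @return `data.table` with columns chrom, pos, rsid, a1, a2, beta1, se1,
#'   p1, beta2, se2, p2, flipped, maf (minor-allele frequency from trait 2
#'   where available, else trait 1), with attribute `log` (named counts:
#'   merged, flipped, excluded_incompatible, excluded_ambiguous,
#'   unmatched_t1, unmatched_t2).
#' @export
harmonize <- function(t1, t2, policy = harmonization_policy(),
                      verbose = TRUE) {
  for (nm in c("t1", "t2")) {
    tt <- get(nm)
    if (!all(.required_fields %in% names(tt)))
      stop("input error: ", nm, " lacks required summary-statistic columns")
    dup <- tt[duplicated(tt, by = c("chrom", "pos"))]
    if (nrow(dup))
      stop("input error: duplicate position key in ", nm, " at ",
           dup$chrom[1], ":", dup$pos[1])
  }
  m <- merge(
    t1[, .(chrom, pos, rsid, a1, a2, eaf1 = eaf, beta1 = beta, se1 = se,
           p1 = p)],
    t2[, .(chrom, pos, rsid2 = rsid, a1_2 = a1, a2_2 = a2, eaf2 = eaf,
           beta2 = beta, se2 = se, p2 = p)],
    by = c("chrom", "pos"))

  same <- m$a1 == m$a1_2 & m$a2 == m$a2_2
  swap <- m$a1 == m$a2_2 & m$a2 == m$a1_2
  pal  <- .is_palindromic(m$a1, m$a2) | .is_palindromic(m$a1_2, m$a2_2)

  drop_ambig <- pal & (same | swap)
  if (policy$ambiguous == "freq") {
    resolvable <- drop_ambig & !is.na(m$eaf1) & !is.na(m$eaf2) &
      abs(m$eaf1 - 0.5) > policy$freq_margin &
      abs(m$eaf2 - 0.5) > policy$freq_margin
    # palindromic alleles always "match" both ways; orientation is read
    # off the frequencies instead: same side of 0.5 = same orientation
    eaf1_for_cmp <- ifelse(swap & resolvable, 1 - m$eaf1, m$eaf1)
    agree <- sign(eaf1_for_cmp - 0.5) == sign(m$eaf2 - 0.5)
    drop_ambig <- drop_ambig & !(resolvable & agree)
  }

  take_same <- same & !drop_ambig
  take_swap <- swap & !same & !drop_ambig
  incompat  <- !same & !swap

  log <- c(merged = sum(take_same | take_swap),
           flipped = sum(take_swap),
           excluded_incompatible = sum(incompat),
           excluded_ambiguous = sum(drop_ambig & !incompat),
           unmatched_t1 = nrow(t1) - nrow(m),
           unmatched_t2 = nrow(t2) - nrow(m))

  out <- m[take_same | take_swap]
  flip <- take_swap[take_same | take_swap]
  out[, `:=`(
    a1 = a1_2, a2 = a2_2,
    beta1 = ifelse(flip, -beta1, beta1),
    eaf1 = ifelse(flip, 1 - eaf1, eaf1),
    flipped = flip)]
  out[, maf := ifelse(is.na(eaf2), pmin(eaf1, 1 - eaf1),
                      pmin(eaf2, 1 - eaf2))]
  out <- out[, .(chrom, pos, rsid, a1, a2, beta1, se1, p1, beta2, se2,
                 p2, flipped, maf)]
  if (nrow(out) == 0L)
    stop("input error: no harmonizable SNPs shared between the two tables")
  data.table::setkeyv(out, c("chrom", "pos"))
  if (verbose)
    message("harmonize: ", log[["merged"]], " merged (",
            log[["flipped"]], " allele-flipped), ",
            log[["excluded_incompatible"]], " allele-incompatible and ",
            log[["excluded_ambiguous"]], " strand-ambiguous excluded")
  data.table::setattr(out, "log", log)
  out[]
}

#' Write a table as tab-separated text
#'
#' Fixed header = the table's column names; `NA` written as "NA".
#'
#' @param table a `data.table`/data.frame.
#' @param path output path (".gz" suffix compresses).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(table, path) {
  data.table::fwrite(table, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a tab-separated table (plain or gzipped)
#'
#' Companion to [write_tsv()]; no validation or column mapping — for
#' validated GWAS input use [read_sumstats()].
#'
#' @param path input path.
#' @return `data.table`.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  .fread_any(path)
}
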