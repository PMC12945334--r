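#' Assemble an end-to-end run configuration
#'
#' @param t1_path,t2_path trait-1 / trait-2 summary-statistics files.
#' @param rep_path optional replication GWAS file.
#' @param t1_dialect,t2_dialect,rep_dialect column mappings; see
#'   [sumstats_dialect()]. The replication dialect maps `beta` and `se` to
#'   z-score-bearing columns only if present; a `z` entry may be given
#'   instead.
#' @param maf_threshold minor-allele-frequency cutoff applied to the
#'   trait-2 table (default 0.05); `maf_both = TRUE` extends it to trait 1.
#' @param maf_both apply the MAF filter to both tables.
#' @param policy harmonization policy, see [harmonization_policy()].
#' @param pruning a [pruning_config()].
#' @param selection a [selection_config()].
#' @param p_replicate,p_attenuate replication triage cutoffs.
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output.
#' @param robust robust genome-wide standardization.
#' @return a `run_config` list.
#' @export
run_config <- function(t1_path, t2_path, rep_path = NULL,
                       t1_dialect = sumstats_dialect(),
                       t2_dialect = sumstats_dialect(),
                       rep_dialect = sumstats_dialect(),
                       maf_threshold = 0.05, maf_both = FALSE,
                       policy = harmonization_policy(),
                       pruning = pruning_config(),
                       selection = selection_config(),
                       p_replicate = 5e-8, p_attenuate = 1e-3,
                       out_dir = NULL, robust = FALSE) {
  for (pp in c(t1_path, t2_path, rep_path))
    if (!file.exists(pp)) stop("configuration error: path not found: ", pp)
  structure(list(t1_path = t1_path, t2_path = t2_path,
                 rep_path = rep_path, t1_dialect = t1_dialect,
                 t2_dialect = t2_dialect, rep_dialect = rep_dialect,
                 maf_threshold = maf_threshold, maf_both = maf_both,
                 policy = policy, pruning = pruning,
                 selection = selection, p_replicate = p_replicate,
                 p_attenuate = p_attenuate, out_dir = out_dir,
                 robust = robust),
            class = "run_config")
}

#' Run the full differential-GWAS pipeline
#'
#' read -> MAF filter -> harmonize -> prune -> estimate rho -> differential
#' test -> candidate selection -> clumping -> (optional) replication
#' alignment and triage. Writes, when `cfg$out_dir` is set: the per-SNP
#' differential results (`diff_results.tsv`), the candidate-locus table
#' (`candidate_loci.tsv`), the replication triage (`replication.tsv`) and
#' a run report (`run_report.tsv`) with rho, its CI, all thresholds and
#' per-stage SNP counts.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list: `harmonized`, `rho` (overlap_estimate),
#'   `diff`, `candidates`, `loci`, `replication` (or NULL), `report`
#'   (data.table of stage counts and parameters).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  t1 <- stage("read_t1", read_sumstats(cfg$t1_path, cfg$t1_dialect))
  t2 <- stage("read_t2", read_sumstats(cfg$t2_path, cfg$t2_dialect))
  n_read <- c(t1 = nrow(t1), t2 = nrow(t2))
  t2 <- stage("maf_filter", filter_maf(t2, cfg$maf_threshold))
  if (cfg$maf_both)
    t1 <- stage("maf_filter", filter_maf(t1, cfg$maf_threshold))
  harm <- stage("harmonize", harmonize(t1, t2, cfg$policy))
  pruned <- stage("prune", prune(harm, cfg$pruning))
  rho <- stage("estimate_rho",
               estimate_rho(pruned, null_zmax = cfg$pruning$null_zmax))
  diff <- stage("diff_test",
                run_diff_gwas(harm, rho$rho, robust = cfg$robust))
  cand <- stage("select", select_candidates(diff, cfg$selection))
  loci <- stage("clump", clump(cand, cfg$selection$clump_window_bp))

  repl <- NULL
  if (!is.null(cfg$rep_path)) {
    leads <- merge(loci[, .(chrom, rsid = lead_rsid, pos = lead_pos)],
                   diff[, .(chrom, pos, rsid, a1, a2, beta2)],
                   by = c("chrom", "pos", "rsid"))
    rep_tab <- stage("read_replication",
                     .read_replication(cfg$rep_path, cfg$rep_dialect))
    repl <- stage("replication", prioritize(
      align_to_replication(leads, rep_tab),
      p_replicate = cfg$p_replicate, p_attenuate = cfg$p_attenuate))
  }

  report <- data.table::data.table(
    metric = c("n_read_t1", "n_read_t2", "n_after_maf_t2", "n_harmonized",
            "n_pruned", "rho", "rho_ci_lo", "rho_ci_hi", "rho_n_snps",
            "n_tested", "n_candidates", "n_loci",
            "maf_threshold", "p_diff_threshold", "p_nominal_threshold",
            "clump_window_bp", "p_replicate", "p_attenuate"),
    value = c(n_read[["t1"]], n_read[["t2"]], nrow(t2), nrow(harm),
              nrow(pruned), rho$rho, rho$ci95[1], rho$ci95[2],
              rho$n_snps, nrow(diff), nrow(cand), nrow(loci),
              cfg$maf_threshold, cfg$selection$p_diff_threshold,
              cfg$selection$p_nominal_threshold,
              cfg$selection$clump_window_bp, cfg$p_replicate,
              cfg$p_attenuate))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(diff, file.path(cfg$out_dir, "diff_results.tsv"))
    write_tsv(loci[, !"members"],
              file.path(cfg$out_dir, "candidate_loci.tsv"))
    if (!is.null(repl))
      write_tsv(repl, file.path(cfg$out_dir, "replication.tsv"))
    write_tsv(report, file.path(cfg$out_dir, "run_report.tsv"))
  }
  invisible(list(harmonized = harm, rho = rho, diff = diff,
                 candidates = cand, loci = loci, replication = repl,
                 report = report))
}

# replication file: needs rsid/a1/a2 plus either a z column or beta/se
.read_replication <- function(path, dialect) {
  raw <- .fread_any(path)
  need <- c(dialect$rsid, dialect$a1, dialect$a2, dialect$p)
  if (!all(need %in% names(raw)))
    stop("configuration error: replication file lacks column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  z <- if ("Z" %in% names(raw)) as.numeric(raw$Z)
       else if ("z" %in% names(raw)) as.numeric(raw$z)
       else as.numeric(raw[[dialect$beta]]) / as.numeric(raw[[dialect$se]])
  out <- data.table::data.table(
    rsid = as.character(raw[[dialect$rsid]]),
    a1 = toupper(as.character(raw[[dialect$a1]])),
    a2 = toupper(as.character(raw[[dialect$a2]])),
    z = z, p = as.numeric(raw[[dialect$p]]))
  if (dialect$chrom %in% names(raw)) {
    out[, chrom := sub("^chr", "", as.character(raw[[dialect$chrom]]),
                       ignore.case = TRUE)]
    out[, pos := suppressWarnings(as.integer(raw[[dialect$pos]]))]
  }
  out[]
}

#' Export Manhattan-plot-ready differential results
#'
#' Computes a cumulative genomic x-coordinate across chromosomes and the
#' -log10 differential p-value truncated at `cap` (default 30, keeping
#' extreme peaks from dwarfing the rest of the genome), plus the sign of
#' the standardized z-score.
#'
#' @param diff output of [run_diff_gwas()].
#' @param cap ceiling on -log10(p); `Inf` disables truncation.
#' @return `data.table`: chrom, pos, coord (cumulative bp), neglog10p,
#'   sign (of z_std).
#' @export
manhattan_export <- function(diff, cap = 30) {
  if (nrow(diff) == 0L) stop("input error: empty results table")
  out <- data.table::as.data.table(diff)[
    , .(chrom, pos, p_diff, z_std)]
  out[, chrom_n := as.integer(chrom)]
  data.table::setorderv(out, c("chrom_n", "pos"))
  sizes <- out[, .(len = max(pos)), by = chrom_n]
  sizes[, offset := data.table::shift(cumsum(as.numeric(len)), fill = 0)]
  out <- merge(out, sizes[, .(chrom_n, offset)], by = "chrom_n")
  out[, coord := pos + offset]
  out[, neglog10p := pmin(-log10(p_diff), cap)]
  out[, sign := sign(z_std)]
  out[, .(chrom, pos, coord, neglog10p, sign)]
}
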