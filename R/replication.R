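#' Align candidate loci to a replication GWAS
#'
#' Matches each candidate lead SNP to a replication-study record — by rsid
#' first, falling back to (chrom, pos) — and orients the replication
#' z-score to the candidate's effect allele: if the replication alleles
#' are swapped relative to the candidate's orientation the z-score is
#' negated; allele-incompatible or missing matches get status `"absent"`.
#' Direction consistency compares the sign of the aligned z with the sign
#' of the candidate's trait-2 effect (replication tables often carry z and
#' p only, no betas).
#'
#' @param candidates one row per candidate with columns rsid, chrom, pos,
#'   a1, a2 and beta2 (trait-2 effect on the shared allele) — e.g. the
#'   lead rows of [select_candidates()] output.
#' @param rep replication table with columns rsid, a1, a2, z, p (chrom/pos
#'   optional, used for the positional fallback).
#' @return `data.table`: rsid, a1, a2, z_rep, p_rep, direction_consistent,
#'   status (`"pending"` until [prioritize()], or `"absent"`).
#' @export
align_to_replication <- function(candidates, rep) {
  candidates <- data.table::as.data.table(candidates)
  rep <- data.table::as.data.table(rep)
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i]
    hit <- rep[rsid == cd$rsid]
    if (nrow(hit) == 0L && all(c("chrom", "pos") %in% names(rep)))
      hit <- rep[chrom == cd$chrom & pos == cd$pos]
    rec <- data.table::data.table(
      rsid = cd$rsid, a1 = cd$a1, a2 = cd$a2, z_rep = NA_real_,
      p_rep = NA_real_, direction_consistent = NA, status = "absent")
    if (nrow(hit) >= 1L) {
      hit <- hit[1L]
      if (hit$a1 == cd$a1 && hit$a2 == cd$a2) {
        rec$z_rep <- hit$z
      } else if (hit$a1 == cd$a2 && hit$a2 == cd$a1) {
        rec$z_rep <- -hit$z
      } else {
        warning("align_to_replication: allele-incompatible replication ",
                "match for ", cd$rsid, "; treated as absent")
      }
      if (!is.na(rec$z_rep)) {
        rec$p_rep <- hit$p
        rec$direction_consistent <-
          if ("beta2" %in% names(cd) && is.finite(cd$beta2))
            sign(rec$z_rep) == sign(cd$beta2) else NA
        rec$status <- "pending"
      }
    }
    out[[i]] <- rec
  }
  data.table::rbindlist(out)
}

#' Triage candidates by replication significance
#'
#' Three-way partition on the replication p-value: `replicated` below
#' `p_replicate` (genome-wide significance by default), `attenuated` at or
#' above `p_attenuate`, otherwise `intermediate` (retained, flagged for
#' follow-up). Records without a usable match stay `absent`.
#'
#' @param records output of [align_to_replication()], or any table with
#'   p_rep and status columns.
#' @param p_replicate replication cutoff, default 5e-8.
#' @param p_attenuate attenuation cutoff, default 1e-3.
#' @return `records` with status filled in.
#' @export
prioritize <- function(records, p_replicate = 5e-8, p_attenuate = 1e-3) {
  if (!(p_replicate < p_attenuate))
    stop("configuration error: p_replicate must be < p_attenuate")
  records <- data.table::as.data.table(records)
  records[status != "absent" & !is.na(p_rep),
          status := data.table::fifelse(
            p_rep < p_replicate, "replicated",
            data.table::fifelse(p_rep >= p_attenuate, "attenuated",
                                "intermediate"))]
  records[]
}
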