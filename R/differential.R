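#' Overlap-adjusted variance of an effect-size difference
#'
#' `Var(beta1 - beta2) = se1^2 + se2^2 - 2 * rho * se1 * se2`, where `rho`
#' is the cross-study correlation of effect-estimate errors induced by
#' sample overlap. With `rho = 0` this is the classical two-sample
#' variance.
#'
#' @param se1,se2 positive standard errors (vectorized).
#' @param rho correlation in `[-1, 1]`.
#' @return variance(s).
#' @export
#' @examples
#' delta_variance(0.011, 0.006, rho = 0)    # 1.57e-4
#' delta_variance(0.011, 0.006, rho = 0.3)  # 1.174e-4
delta_variance <- function(se1, se2, rho) {
  if (any(!is.finite(se1) | se1 <= 0) || any(!is.finite(se2) | se2 <= 0))
    stop("parameter error: standard errors must be positive")
  if (any(!is.finite(rho) | abs(rho) > 1))
    stop("parameter error: rho must lie in [-1, 1]")
  v <- se1^2 + se2^2 - 2 * rho * se1 * se2
  if (any(v <= 0))
    stop("degenerate-variance error: se1^2 + se2^2 - 2*rho*se1*se2 <= 0")
  v
}

#' Raw overlap-adjusted differential z-score
#'
#' `(beta1 - beta2) / sqrt(delta_variance(se1, se2, rho))`.
#'
#' @param beta1,beta2 effect sizes on the shared effect allele.
#' @inheritParams delta_variance
#' @return z-score(s).
#' @export
delta_z_raw <- function(beta1, beta2, se1, se2, rho) {
  (beta1 - beta2) / sqrt(delta_variance(se1, se2, rho))
}

#' Standardize z-scores genome-wide to mean 0, variance 1
#'
#' Affine transform `(z - m) / s`. Default `m`/`s` are the sample mean and
#' sample standard deviation; `robust = TRUE` uses median and MAD (scaled
#' to the normal), which resists inflation of the scale by heavy polygenic
#' tails.
#'
#' @param z numeric vector, length >= 2, non-constant.
#' @param robust use median/MAD location and scale.
#' @return standardized vector.
#' @export
standardize <- function(z, robust = FALSE) {
  if (length(z) < 2L)
    stop("standardization error: need at least 2 z-scores")
  if (robust) {
    m <- median(z); s <- mad(z)
  } else {
    m <- mean(z); s <- sd(z)
  }
  if (!is.finite(s) || s == 0)
    stop("standardization error: constant z-score vector")
  (z - m) / s
}

#' Two-sided normal p-value from a z-score
#'
#' `2 * P(Z > |z|)` computed through the upper-tail survival function, so
#' extreme scores keep full relative accuracy (no `1 - CDF` cancellation)
#' down to the smallest representable doubles.
#'
#' @param z finite z-score(s).
#' @return p-value(s) in `(0, 1]` (0 only below ~1e-308 by underflow).
#' @export
#' @examples
#' p_two_sided(5.631)  # 1.79e-8
p_two_sided <- function(z) {
  if (any(!is.finite(z))) stop("parameter error: z must be finite")
  pmin(1, 2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Run the differential test genome-wide
#'
#' For each harmonized SNP computes the effect difference, the
#' overlap-adjusted variance, the raw differential z-score, the
#' genome-wide standardized z-score (mean 0, SD 1 over all retained SNPs)
#' and its two-sided p-value. Rows with non-positive adjusted variance are
#' dropped with a logged count. The unstandardized p-value is kept as
#' `p_raw` for diagnostics (e.g. calibration checks against the classical
#' two-sample test).
#'
#' A post-hoc check flags any row where standardization flipped the sign
#' relative to the raw z-score (possible only under a large genome-wide
#' mean shift); such rows get `sign_consistent = FALSE` and a logged
#' count.
#'
#' @param table harmonized table from [harmonize()].
#' @param rho cross-study correlation, typically `estimate_rho(...)$rho`.
#' @param robust use robust standardization, see [standardize()].
#' @return input table with added columns delta_beta, var_adj, z_raw,
#'   z_std, p_raw, p_diff, sign_consistent; attribute
#'   `n_degenerate_dropped`.
#' @export
run_diff_gwas <- function(table, rho, robust = FALSE) {
  if (nrow(table) == 0L) stop("input error: empty harmonized table")
  if (length(rho) != 1L || !is.finite(rho) || abs(rho) > 1)
    stop("parameter error: rho must be a single value in [-1, 1]")
  out <- data.table::as.data.table(table)
  out[, delta_beta := beta1 - beta2]
  out[, var_adj := se1^2 + se2^2 - 2 * rho * se1 * se2]
  n_bad <- out[, sum(!is.finite(var_adj) | var_adj <= 0)]
  if (n_bad > 0L) {
    message("run_diff_gwas: dropped ", n_bad,
            " SNP(s) with degenerate adjusted variance")
    out <- out[is.finite(var_adj) & var_adj > 0]
  }
  out[, z_raw := delta_beta / sqrt(var_adj)]
  out[, z_std := standardize(z_raw, robust = robust)]
  out[, p_raw := p_two_sided(z_raw)]
  out[, p_diff := p_two_sided(z_std)]
  out[, sign_consistent := delta_beta == 0 | sign(z_std) == sign(z_raw)]
  if (any(!out$sign_consistent))
    message("run_diff_gwas: ", sum(!out$sign_consistent),
            " SNP(s) changed sign under standardization; flagged in ",
            "'sign_consistent'")
  data.table::setattr(out, "n_degenerate_dropped", n_bad)
  out[]
}

#' Candidate selection thresholds
#'
#' @param p_diff_threshold genome-wide significance cutoff for the
#'   differential p-value; default 5e-8.
#' @param p_nominal_threshold per-trait nominal cutoff; default 0.05.
#' @param require_opposite require opposite effect directions
#'   (`beta1 * beta2 < 0`); default TRUE.
#' @param clump_window_bp locus-merging window; default 1e6.
#' @return a `selection_config` list.
#' @export
selection_config <- function(p_diff_threshold = 5e-8,
                             p_nominal_threshold = 0.05,
                             require_opposite = TRUE,
                             clump_window_bp = 1e6) {
  if (!(p_diff_threshold > 0 && p_diff_threshold < p_nominal_threshold &&
        p_nominal_threshold < 1))
    stop("configuration error: need 0 < p_diff_threshold < ",
         "p_nominal_threshold < 1")
  if (clump_window_bp <= 0)
    stop("configuration error: clump_window_bp must be positive")
  structure(list(p_diff_threshold = p_diff_threshold,
                 p_nominal_threshold = p_nominal_threshold,
                 require_opposite = isTRUE(require_opposite),
                 clump_window_bp = clump_window_bp),
            class = "selection_config")
}

#' Apply the composite candidate-selection rule
#'
#' Retains SNPs that (i) pass genome-wide significance for the
#' differential test, (ii) are nominally significant in both traits, and
#' (iii) have opposite effect directions (when `require_opposite`) —
#' flagging antagonistic effects while screening out SNPs significant in
#' only one study.
#'
#' @param diff output of [run_diff_gwas()] (carries p1, p2, beta1, beta2).
#' @param cfg a [selection_config()].
#' @return subset of `diff`.
#' @export
select_candidates <- function(diff, cfg = selection_config()) {
  keep <- diff$p_diff < cfg$p_diff_threshold &
    diff$p1 < cfg$p_nominal_threshold &
    diff$p2 < cfg$p_nominal_threshold
  if (cfg$require_opposite) keep <- keep & diff$beta1 * diff$beta2 < 0
  diff[keep]
}

#' Clump selected SNPs into independent loci
#'
#' Greedy: the remaining SNP with the smallest differential p-value (ties
#' broken by chrom, pos ascending) becomes a lead; all remaining SNPs on
#' its chromosome within `window_bp` are absorbed as members; repeat.
#'
#' @param rows selected SNPs (need chrom, pos, rsid, p_diff).
#' @param window_bp absorption window around the lead; default 1e6.
#' @return `data.table`, one row per locus: chrom, lead_rsid, lead_pos,
#'   lead_p_diff, n_members, start, end, members (list of member rsids),
#'   ordered by lead_p_diff.
#' @export
clump <- function(rows, window_bp = 1e6) {
  rows <- data.table::as.data.table(rows)
  if (nrow(rows) == 0L) {
    return(data.table::data.table(
      chrom = character(), lead_rsid = character(), lead_pos = integer(),
      lead_p_diff = numeric(), n_members = integer(), start = integer(),
      end = integer(), members = list()))
  }
  ord <- order(rows$p_diff, rows$chrom, rows$pos)
  rows <- rows[ord]
  loci <- list()
  while (nrow(rows) > 0L) {
    lead <- rows[1L]
    in_locus <- rows$chrom == lead$chrom &
      abs(rows$pos - lead$pos) <= window_bp
    mem <- rows[in_locus]
    loci[[length(loci) + 1L]] <- data.table::data.table(
      chrom = lead$chrom, lead_rsid = lead$rsid, lead_pos = lead$pos,
      lead_p_diff = lead$p_diff, n_members = nrow(mem),
      start = min(mem$pos), end = max(mem$pos),
      members = list(mem$rsid))
    rows <- rows[!in_locus]
  }
  data.table::rbindlist(loci)
}
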