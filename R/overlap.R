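#' Pruning configuration
#'
#' Controls how a quasi-independent SNP subset is chosen before the
#' cross-study correlation is estimated. Two methods:
#' \describe{
#'   \item{distance_thin}{keep the lowest-position SNP in each
#'     non-overlapping `window_bp` window per chromosome. A deterministic,
#'     data-independent LD proxy requiring no reference panel.}
#'   \item{ld_file}{greedy removal of SNPs in LD (pairwise R-squared at or
#'     above `r2_threshold`) with any already-retained SNP, scanning by
#'     position, using a precomputed pairwise-LD table.}
#' }
#'
#' @param method `"distance_thin"` (default) or `"ld_file"`.
#' @param r2_threshold LD R-squared cutoff, default 0.1.
#' @param window_bp thinning window in bp, default 250000.
#' @param ld_path path to whitespace-separated table with columns
#'   SNP_A, SNP_B, R2 (extra columns ignored); required for `ld_file`.
#' @param null_zmax optional |z| ceiling restricting which SNPs enter the
#'   correlation estimate; see [estimate_rho()]. Default 2.
#' @return a `pruning_config` list.
#' @export
pruning_config <- function(method = c("distance_thin", "ld_file"),
                           r2_threshold = 0.1, window_bp = 250000L,
                           ld_path = NULL, null_zmax = 2.0) {
  method <- match.arg(method)
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold >= 1)
    stop("parameter error: r2_threshold must lie in (0, 1)")
  if (!is.numeric(window_bp) || window_bp <= 0)
    stop("parameter error: window_bp must be positive")
  if (method == "ld_file" && is.null(ld_path))
    stop("configuration error: ld_file method requires ld_path")
  structure(list(method = method, r2_threshold = r2_threshold,
                 window_bp = as.integer(window_bp), ld_path = ld_path,
                 null_zmax = null_zmax),
            class = "pruning_config")
}

#' Select a quasi-independent SNP subset
#'
#' @param table harmonized table (see [harmonize()]); any table with
#'   chrom/pos (and rsid for `ld_file`) columns works.
#' @param cfg a [pruning_config()].
#' @return subset of `table`, ordered by (chrom, pos).
#' @export
prune <- function(table, cfg = pruning_config()) {
  if (nrow(table) == 0L) stop("input error: empty table")
  tab <- data.table::as.data.table(table)
  data.table::setorderv(tab, c("chrom", "pos"))
  if (cfg$method == "distance_thin") {
    tab[, window := pos %/% cfg$window_bp]
    out <- tab[, .SD[1L], by = .(chrom, window)]
    out[, window := NULL]
    data.table::setorderv(out, c("chrom", "pos"))
    return(out[])
  }
  # ld_file: greedy scan by position
  if (!file.exists(cfg$ld_path))
    stop("input error: LD file not found: ", cfg$ld_path)
  ld <- data.table::fread(cfg$ld_path, header = TRUE)
  if (!all(c("SNP_A", "SNP_B", "R2") %in% names(ld)))
    stop("configuration error: LD file needs columns SNP_A, SNP_B, R2")
  unknown <- setdiff(unique(c(ld$SNP_A, ld$SNP_B)), tab$rsid)
  if (length(unknown))
    warning("prune: ", length(unknown),
            " LD-file SNP id(s) absent from the table; ignored")
  ld <- ld[R2 >= cfg$r2_threshold]
  # symmetric adjacency of high-LD pairs
  adj <- split(c(ld$SNP_B, ld$SNP_A), c(ld$SNP_A, ld$SNP_B))
  kept <- character(0)
  for (s in tab$rsid) {
    if (!length(intersect(adj[[s]], kept))) kept <- c(kept, s)
  }
  tab[rsid %in% kept][]
}

#' Estimate the cross-study z-score correlation
#'
#' Pearson correlation of per-SNP z-scores (`beta1/se1` vs `beta2/se2`)
#' over a quasi-independent SNP subset. Under sample overlap between the
#' two studies this correlation estimates the covariance term of the
#' effect-difference variance (on the z scale); theory predicts
#' `rho = n_overlap / sqrt(n1 * n2)` for null SNPs.
#'
#' Optionally restricts to SNPs with `max(|z1|, |z2|) < null_zmax` so that
#' strongly associated SNPs (true shared polygenic signal) do not inflate
#' the estimate. Note that on data with little true signal this truncation
#' biases the estimate toward zero; pass `null_zmax = NULL` when the input
#' is believed null.
#'
#' @param table harmonized (ideally pruned) table.
#' @param null_zmax optional |z| ceiling; `NULL` disables the restriction.
#' @return an `overlap_estimate` list: `rho`, `n_snps`, `ci95` (Fisher
#'   z-transform 95% interval), `method`.
#' @export
estimate_rho <- function(table, null_zmax = 2.0) {
  z1 <- table$beta1 / table$se1
  z2 <- table$beta2 / table$se2
  if (!is.null(null_zmax)) {
    keep <- pmax(abs(z1), abs(z2)) < null_zmax
    z1 <- z1[keep]; z2 <- z2[keep]
  }
  nn <- length(z1)
  if (nn < 2L)
    stop("estimation error: fewer than 2 usable SNPs for rho")
  if (sd(z1) == 0 || sd(z2) == 0)
    stop("estimation error: zero variance in a z-score vector")
  r <- cor(z1, z2)
  ci <- if (nn > 3L && abs(r) < 1) {
    fz <- atanh(r) + c(-1, 1) * qnorm(0.975) / sqrt(nn - 3)
    tanh(fz)
  } else c(-1, 1)
  structure(list(rho = r, n_snps = nn, ci95 = ci,
                 method = if (is.null(null_zmax)) "pearson"
                          else sprintf("pearson|z|<%g", null_zmax)),
            class = "overlap_estimate")
}

#' @export
print.overlap_estimate <- function(x, ...) {
  cat(sprintf(
    "Cross-study z-score correlation: rho = %.4f (95%% CI %.4f..%.4f), %d SNPs [%s]\n",
    x$rho, x$ci95[1], x$ci95[2], x$n_snps, x$method))
  invisible(x)
}
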