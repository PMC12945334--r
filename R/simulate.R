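#' Specification of a synthetic pair of overlapping GWAS cohorts
#'
#' Defines two association studies of `n1` and `n2` individuals sharing
#' `n_overlap` samples, genotyped at `n_snps` biallelic SNPs. Under the
#' standard summary-level overlap model, shared samples (with shared
#' phenotype noise) induce correlation
#' `rho_star = n_overlap / sqrt(n1 * n2)` between the two studies'
#' effect-estimate errors at null SNPs; the generator imposes exactly that
#' correlation analytically through a bivariate-normal noise model rather
#' than simulating genotypes.
#'
#' Causal SNPs come in two classes: `shared` (equal true effects in both
#' studies) and `opposite` (antagonistic: effects of equal standardized
#' magnitude, opposite signs). Standardized magnitudes |beta|/se are drawn
#' uniformly from `effect_scale`.
#'
#' @param n1,n2 study sample sizes.
#' @param n_overlap shared samples, `0 <= n_overlap <= min(n1, n2)`.
#' @param n_snps total SNP count.
#' @param n_shared,n_opposite causal SNP counts by class.
#' @param maf_range allele-frequency sampling interval; default
#'   `c(0.05, 0.5)`.
#' @param effect_scale range of |beta|/se for causal SNPs; default
#'   `c(4, 8)`.
#' @param flip_fraction fraction of trait-1 records emitted with swapped
#'   alleles (beta negated, frequency complemented), to exercise
#'   harmonization; default 0.
#' @param ambiguous_fraction fraction of SNPs given palindromic (A/T)
#'   alleles instead of A/G; default 0.
#' @param seed random seed used by [simulate_pair()].
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n1 = 10000, n2 = 10000, n_overlap = 0,
                        n_snps = 10000, n_shared = 0, n_opposite = 0,
                        maf_range = c(0.05, 0.5),
                        effect_scale = c(4, 8),
                        flip_fraction = 0, ambiguous_fraction = 0,
                        seed = 1L) {
  if (n_overlap < 0 || n_overlap > min(n1, n2))
    stop("parameter error: need 0 <= n_overlap <= min(n1, n2)")
  if (n_shared + n_opposite > n_snps)
    stop("parameter error: n_shared + n_opposite must not exceed n_snps")
  if (seed >= 2^31) stop("parameter error: seed must fit a 32-bit integer")
  structure(list(n1 = n1, n2 = n2, n_overlap = n_overlap,
                 n_snps = n_snps, n_shared = n_shared,
                 n_opposite = n_opposite, maf_range = maf_range,
                 effect_scale = effect_scale,
                 flip_fraction = flip_fraction,
                 ambiguous_fraction = ambiguous_fraction,
                 seed = as.integer(seed),
                 rho_star = n_overlap / sqrt(n1 * n2)),
            class = "cohort_spec")
}

# quantitative-trait large-sample SE of a per-allele regression beta
.gwas_se <- function(n, f) 1 / sqrt(2 * n * f * (1 - f))

#' Simulate a pair of GWAS summary-statistics tables with known truth
#'
#' For each SNP with frequency `f`, study k has
#' `se_k = 1 / sqrt(2 * n_k * f * (1 - f))` and the estimate pair
#' `(beta1_hat, beta2_hat)` is bivariate normal around the true effects
#' with those SDs and correlation `rho_star`. P-values are two-sided
#' normal on `beta_hat / se`. Positions are laid out uniformly over 22
#' autosomes of 130 Mb. Deterministic under the cohort specification's seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with `t1`, `t2` (summary tables in [read_sumstats()]
#'   layout) and `truth` (per-SNP class in {null, shared, opposite}, true
#'   betas, eaf, and `rho_star`).
#' @export
simulate_pair <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  m <- spec$n_snps
  chrom <- as.character(sample(1:22, m, replace = TRUE))
  pos <- sample.int(130e6, m, replace = TRUE)
  # unique (chrom,pos) keys: resample clashes
  key <- paste(chrom, pos)
  while (anyDuplicated(key)) {
    d <- duplicated(key)
    pos[d] <- sample.int(130e6, sum(d), replace = TRUE)
    key <- paste(chrom, pos)
  }
  ord <- order(as.integer(chrom), pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  rsid <- sprintf("rs%07d", seq_len(m))
  f <- runif(m, spec$maf_range[1], spec$maf_range[2])
  se1 <- .gwas_se(spec$n1, f)
  se2 <- .gwas_se(spec$n2, f)

  cls <- rep("null", m)
  causal <- sample.int(m, spec$n_shared + spec$n_opposite)
  cls[head(causal, spec$n_shared)] <- "shared"
  cls[utils::tail(causal, spec$n_opposite)] <- "opposite"
  lambda <- runif(m, spec$effect_scale[1], spec$effect_scale[2])
  sgn <- sample(c(-1, 1), m, replace = TRUE)
  beta1_true <- beta2_true <- numeric(m)
  sh <- cls == "shared"; op <- cls == "opposite"
  beta1_true[sh] <- beta2_true[sh] <-
    (sgn * lambda * (se1 + se2) / 2)[sh]
  beta1_true[op] <- (sgn * lambda * se1)[op]
  beta2_true[op] <- (-sgn * lambda * se2)[op]

  r <- spec$rho_star
  e1 <- rnorm(m)
  e2 <- r * e1 + sqrt(1 - r^2) * rnorm(m)
  beta1 <- beta1_true + se1 * e1
  beta2 <- beta2_true + se2 * e2

  a1 <- rep("A", m); a2 <- rep("G", m)
  if (spec$ambiguous_fraction > 0) {
    amb <- runif(m) < spec$ambiguous_fraction
    a2[amb] <- "T"
  }
  mk <- function(beta, se, eaf, n) data.table::data.table(
    chrom = chrom, pos = pos, rsid = rsid, a1 = a1, a2 = a2, eaf = eaf,
    beta = beta, se = se, p = p_two_sided(beta / se), n = as.integer(n))
  t1 <- mk(beta1, se1, f, spec$n1)
  t2 <- mk(beta2, se2, f, spec$n2)
  if (spec$flip_fraction > 0) {
    fl <- runif(m) < spec$flip_fraction
    t1[fl, `:=`(a1 = a2, a2 = a1, beta = -beta, eaf = 1 - eaf)]
  }
  truth <- data.table::data.table(
    chrom = chrom, pos = pos, rsid = rsid, eaf = f, class = cls,
    beta1_true = beta1_true, beta2_true = beta2_true,
    rho_star = r)
  list(t1 = t1[], t2 = t2[], truth = truth)
}

#' Simulate a replication GWAS from trait-2 true effects
#'
#' Emits z-scores and p-values per SNP at replication sample size `n_rep`:
#' `z = (beta2_true + se_rep * e) / se_rep` with independent standard
#' normal noise `e` and `se_rep = 1 / sqrt(2 * n_rep * f * (1 - f))`.
#' Causal trait-2 effects replicate in direction with probability
#' approaching 1 as `n_rep` grows; null SNPs give uniform p-values.
#'
#' @param truth truth table from [simulate_pair()].
#' @param n_rep replication sample size.
#' @param seed random seed.
#' @return `data.table`: chrom, pos, rsid, a1, a2, z, p.
#' @export
simulate_replication <- function(truth, n_rep, seed = 1L) {
  set.seed(seed)
  se_rep <- .gwas_se(n_rep, truth$eaf)
  z <- truth$beta2_true / se_rep + rnorm(nrow(truth))
  data.table::data.table(
    chrom = truth$chrom, pos = truth$pos, rsid = truth$rsid,
    a1 = "A", a2 = "G", z = z, p = p_two_sided(z))
}
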