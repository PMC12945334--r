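test_that("delta_variance follows se1^2 + se2^2 - 2*rho*se1*se2", {
  expect_equal(delta_variance(0.011, 0.006, 0), 1.57e-4)
  expect_equal(delta_variance(0.011, 0.006, 0.3),
               1.57e-4 - 0.6 * 0.011 * 0.006)
  expect_error(delta_variance(0.01, 0.01, 1), "degenerate-variance")
  expect_error(delta_variance(-0.01, 0.01, 0), "positive")
  expect_error(delta_variance(0.01, 0.01, 1.5), "rho")
})

test_that("delta_z_raw reproduces hand-computed differential z-scores", {
  expect_equal(delta_z_raw(0.1, 0.1, 0.01, 0.02, 0.2), 0)
  # lead-SNP betas/SEs: -0.091 / sqrt(1.57e-4) and with rho = 0.3
  expect_equal(delta_z_raw(-0.068, 0.023, 0.011, 0.006, 0), -7.263,
               tolerance = 1e-4)
  expect_equal(delta_z_raw(-0.068, 0.023, 0.011, 0.006, 0.3), -8.399,
               tolerance = 1e-4)
})

test_that("standardize maps to mean 0 / sd 1 and preserves order", {
  expect_equal(standardize(c(2, 4, 6)), c(-1, 0, 1))
  z <- rnorm(100, mean = 3, sd = 7)
  s <- standardize(z)
  expect_equal(mean(s), 0)
  expect_equal(sd(s), 1)
  expect_equal(order(s), order(z))
  expect_equal(standardize(s), s, tolerance = 1e-12)  # idempotent
  expect_error(standardize(rep(1, 10)), "constant")
  expect_error(standardize(1), "at least 2")
  # robust variant shrugs off a huge outlier in the scale
  z2 <- c(rnorm(500), 1000)
  expect_gt(max(abs(standardize(z2, robust = TRUE))), 100)
})

test_that("p_two_sided matches printed p-values and keeps tail accuracy", {
  expect_equal(p_two_sided(0), 1)
  expect_equal(p_two_sided(5.631), 1.79e-8, tolerance = 0.01)
  expect_equal(p_two_sided(-5.58), 2.40e-8, tolerance = 0.05)
  expect_equal(p_two_sided(1.96), 0.05, tolerance = 0.01)
  expect_gt(p_two_sided(37), 0)            # no 1 - CDF cancellation
  expect_lt(p_two_sided(37), 1e-290)
  expect_error(p_two_sided(NA), "finite")
})

test_that("run_diff_gwas surfaces the constant-vector degenerate case", {
  t1 <- make_sumstats("1", seq(1e5, 1e6, by = 1e5),
                      beta = rnorm(10, sd = 0.02))
  h <- harmonize(t1, t1, verbose = FALSE)
  expect_error(run_diff_gwas(h, rho = 0), "constant")
})

test_that("at rho = 0 the test reduces exactly to the two-sample z-test", {
  sim <- simulate_pair(cohort_spec(n_snps = 1000, seed = 5))
  h <- harmonize(sim$t1, sim$t2, verbose = FALSE)
  d <- run_diff_gwas(h, rho = 0)
  expect_identical(d$z_raw,
                   (h$beta1 - h$beta2) / sqrt(h$se1^2 + h$se2^2))
})

test_that("|z_raw| increases strictly with rho when effects differ", {
  zs <- vapply(c(0, 0.2, 0.5, 0.8),
               function(r) delta_z_raw(0.05, -0.02, 0.01, 0.012, r),
               numeric(1))
  expect_true(all(diff(abs(zs)) > 0))
})

test_that("swapping the two studies negates z and preserves p", {
  sim <- simulate_pair(cohort_spec(n_snps = 2000, n_overlap = 3000,
                                   n_opposite = 5, seed = 13))
  h <- harmonize(sim$t1, sim$t2, verbose = FALSE)
  swapped <- data.table::copy(h)[, `:=`(
    beta1 = beta2, se1 = se2, p1 = p2,
    beta2 = beta1, se2 = se1, p2 = p1)]
  a <- run_diff_gwas(h, rho = 0.3)
  b <- run_diff_gwas(swapped, rho = 0.3)
  expect_equal(b$z_raw, -a$z_raw)
  expect_equal(b$z_std, -a$z_std)
  expect_equal(b$p_diff, a$p_diff)
})

test_that("select_candidates applies the composite rule", {
  base <- data.table::data.table(
    chrom = "1", pos = 1:4 * 1000L, rsid = sprintf("rs%d", 1:4),
    p_diff = 1e-9, p1 = 1e-9, p2 = 0.01, beta1 = 0.1, beta2 = -0.1)
  base$p2[2] <- 0.2                      # fails trait-2 nominal
  base$beta2[3] <- 0.1                   # same direction
  base$p_diff[4] <- 1e-7                 # fails genome-wide cutoff
  got <- select_candidates(base, selection_config())
  expect_equal(got$rsid, "rs1")
  # without the opposite-direction requirement row 3 comes back
  got2 <- select_candidates(base,
                            selection_config(require_opposite = FALSE))
  expect_setequal(got2$rsid, c("rs1", "rs3"))
})

test_that("tightening any selection threshold never adds rows", {
  set.seed(21)
  sim <- simulate_pair(cohort_spec(n_snps = 5000, n_opposite = 10,
                                   effect_scale = c(4, 7), seed = 21))
  h <- harmonize(sim$t1, sim$t2, verbose = FALSE)
  d <- run_diff_gwas(h, rho = 0)
  loose <- select_candidates(d, selection_config(
    p_diff_threshold = 1e-4, p_nominal_threshold = 0.1))
  for (cfg in list(selection_config(p_diff_threshold = 1e-6,
                                    p_nominal_threshold = 0.1),
                   selection_config(p_diff_threshold = 1e-4,
                                    p_nominal_threshold = 0.01))) {
    tight <- select_candidates(d, cfg)
    expect_true(all(tight$rsid %in% loose$rsid))
  }
})

test_that("clump groups SNPs into leads greedily by p_diff", {
  two <- data.table::data.table(
    chrom = "1", pos = c(1e6L, 1.1e6L), rsid = c("a", "b"),
    p_diff = c(1e-9, 1e-12))
  loci <- clump(two, 1e6)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$lead_rsid, "b")
  expect_setequal(loci$members[[1]], c("a", "b"))

  split2 <- data.table::copy(two)[2, chrom := "2"]
  expect_equal(nrow(clump(split2, 1e6)), 2L)

  # greedy trace: best p at 1.8 Mb absorbs the middle SNP, first SNP
  # forms its own locus
  three <- data.table::data.table(
    chrom = "1", pos = c(1L, 900001L, 1800001L),
    rsid = c("s1", "s2", "s3"), p_diff = c(1e-8, 1e-9, 1e-10))
  loci3 <- clump(three, 1e6)
  expect_equal(loci3$lead_rsid, c("s3", "s1"))
  expect_setequal(loci3$members[[1]], c("s2", "s3"))
  expect_equal(clump(three[0], 1e6), clump(three, 1e6)[0])
})

test_that("selection_config validates its thresholds", {
  expect_error(selection_config(p_diff_threshold = 0.5,
                                p_nominal_threshold = 0.05),
               "configuration error")
  expect_error(selection_config(clump_window_bp = -1),
               "configuration error")
})
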