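test_that("read_sumstats parses a toy file and maps columns", {
  tab <- make_sumstats("1", c(100L, 200L, 300L), beta = c(0.1, -0.2, 0.3))
  path <- write_toy_file(tab)
  got <- read_sumstats(path, verbose = FALSE)
  expect_equal(nrow(got), 3L)
  expect_equal(got$beta, c(0.1, -0.2, 0.3))
  expect_equal(got$pos, c(100L, 200L, 300L))
  expect_equal(got$a1, rep("A", 3))

  # gzip round-trip through the same reader
  gz <- tempfile(fileext = ".tsv.gz")
  data.table::fwrite(data.table::fread(path), gz, sep = "\t")
  expect_equal(read_sumstats(gz, verbose = FALSE)$beta, got$beta)
})

test_that("read_sumstats drops and counts invalid rows", {
  tab <- make_sumstats("1", c(100L, 200L, 300L, 400L, 500L))
  tab$se[2] <- 0                      # violates se > 0
  tab$a1[3] <- "AT"                   # indel under reject policy
  tab$p[4] <- 0                       # violates p in (0,1]
  path <- write_toy_file(tab)
  got <- suppressMessages(read_sumstats(path))
  expect_equal(nrow(got), 2L)
  log <- attr(got, "drop_log")
  expect_equal(unname(log[c("bad_se", "bad_allele", "bad_p")]),
               c(1L, 1L, 1L))

  # indels kept when explicitly allowed
  got2 <- suppressMessages(read_sumstats(path, allow_indels = TRUE))
  expect_true("AT" %in% got2$a1)
})

test_that("read_sumstats errors name missing columns; rejects empty", {
  tab <- make_sumstats("1", 100L)
  path <- write_toy_file(tab)
  expect_error(read_sumstats(path, sumstats_dialect(beta = "EFFECT")),
               "EFFECT")
  tab$se <- 0
  expect_error(suppressMessages(read_sumstats(write_toy_file(tab))),
               "no valid rows")
})

test_that("chromosome labels are normalized and non-autosomes dropped", {
  tab <- make_sumstats(c("chr1", "2", "X"), c(100L, 200L, 300L))
  got <- suppressMessages(read_sumstats(write_toy_file(tab)))
  expect_equal(got$chrom, c("1", "2"))
})

test_that("filter_maf uses min(eaf, 1 - eaf)", {
  tab <- make_sumstats("1", c(1L, 2L, 3L, 4L),
                       eaf = c(0.02, 0.05, 0.95, 0.60))
  expect_equal(filter_maf(tab, 0.05)$eaf, c(0.05, 0.95, 0.60))
  expect_equal(filter_maf(tab, 0), tab)             # identity at 0
  expect_equal(nrow(filter_maf(make_sumstats("1", 1L, eaf = 0.97), 0.05)),
               0L)                                  # maf symmetry
  expect_error(filter_maf(tab, 0.5), "parameter error")
  expect_error(filter_maf(tab, -0.1), "parameter error")
  no_eaf <- data.table::copy(tab)[, eaf := NA_real_]
  expect_warning(out <- filter_maf(no_eaf, 0.05), "skipped")
  expect_equal(nrow(out), 4L)
})

test_that("harmonize merges, flips and excludes as dictated by alleles", {
  t2 <- make_sumstats("1", c(100L, 200L, 300L), a1 = "A", a2 = "G",
                      beta = c(0.20, -0.05, 0.07))
  t1 <- data.table::copy(t2)
  t1$beta <- c(0.10, 0.10, 0.10)
  # row 2: trait-1 alleles swapped; row 3: incompatible allele pair
  t1[2, `:=`(a1 = "G", a2 = "A", eaf = 1 - eaf)]
  t1[3, a2 := "C"]
  h <- harmonize(t1, t2, verbose = FALSE)
  expect_equal(nrow(h), 2L)
  expect_equal(h$flipped, c(FALSE, TRUE))
  expect_equal(h$beta1, c(0.10, -0.10))   # flip negates trait-1 beta
  expect_equal(h$a1, c("A", "A"))         # trait-2 orientation adopted
  log <- attr(h, "log")
  expect_equal(unname(log[c("merged", "flipped", "excluded_incompatible")]),
               c(2L, 1L, 1L))
})

test_that("harmonize self-join is the identity (round trip)", {
  t1 <- make_sumstats("2", seq(1e5, 9e5, by = 1e5),
                      beta = rnorm(9, sd = 0.02))
  h <- harmonize(t1, t1, verbose = FALSE)
  expect_false(any(h$flipped))
  expect_equal(h$beta1, h$beta2)
  expect_equal(nrow(h), nrow(t1))
})

test_that("harmonize is invariant to trait-1 allele representation", {
  set.seed(7)
  t2 <- make_sumstats("3", seq(1e5, 1e6, by = 1e5),
                      beta = rnorm(10, sd = 0.02))
  t1 <- data.table::copy(t2)
  t1$beta <- rnorm(10, sd = 0.02)
  h_ref <- harmonize(t1, t2, verbose = FALSE)
  # flip every trait-1 allele pair and negate every beta: beta1 unchanged
  t1_flip <- data.table::copy(t1)
  t1_flip[, `:=`(a1 = a2, a2 = a1, beta = -beta, eaf = 1 - eaf)]
  h_flip <- harmonize(t1_flip, t2, verbose = FALSE)
  expect_equal(h_flip$beta1, h_ref$beta1)
  expect_true(all(h_flip$flipped))
})

test_that("harmonize partitions input rows among merged/excluded/unmatched", {
  t2 <- make_sumstats("1", c(100L, 200L, 300L, 400L))
  t1 <- data.table::copy(t2)[1:3]
  t1[2, a2 := "C"]  # incompatible
  h <- harmonize(t1, t2, verbose = FALSE)
  log <- attr(h, "log")
  expect_equal(log[["merged"]] + log[["excluded_incompatible"]] +
               log[["excluded_ambiguous"]] + log[["unmatched_t1"]],
               nrow(t1))
  expect_equal(log[["merged"]] + log[["excluded_incompatible"]] +
               log[["excluded_ambiguous"]] + log[["unmatched_t2"]],
               nrow(t2))
})

test_that("harmonize rejects duplicate position keys, empty intersections", {
  t1 <- make_sumstats("1", c(100L, 100L), a2 = c("G", "C"),
                      rsid = c("rs1", "rs2"))
  t2 <- make_sumstats("1", c(100L, 200L))
  expect_error(harmonize(t1, t2, verbose = FALSE), "1:100")
  expect_error(harmonize(make_sumstats("1", 1L), make_sumstats("2", 1L),
                         verbose = FALSE),
               "no harmonizable")
})

test_that("strand-ambiguous SNPs are excluded unless frequency-resolved", {
  t2 <- make_sumstats("1", c(100L, 200L), a1 = c("A", "A"),
                      a2 = c("T", "G"), eaf = 0.2)
  t1 <- data.table::copy(t2)
  h <- harmonize(t1, t2, verbose = FALSE)
  expect_equal(nrow(h), 1L)           # palindromic A/T dropped
  expect_equal(attr(h, "log")[["excluded_ambiguous"]], 1L)

  hf <- harmonize(t1, t2, harmonization_policy("freq"), verbose = FALSE)
  expect_equal(nrow(hf), 2L)          # frequencies agree -> kept as-is
  expect_false(any(hf$flipped))

  # frequency near 0.5 stays unresolvable
  t1b <- data.table::copy(t1)[, eaf := 0.45]
  t2b <- data.table::copy(t2)[, eaf := 0.45]
  hb <- harmonize(t1b, t2b, harmonization_policy("freq"), verbose = FALSE)
  expect_equal(nrow(hb), 1L)
})
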