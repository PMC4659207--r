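test_that("call rates and allele frequencies count what they should", {
  g <- matrix(0L, 100, 3)
  g[1:3, 2] <- NA_integer_
  g[, 3] <- NA_integer_
  expect_equal(unname(snp_call_rate(g)), c(1, 0.97, 0))
  expect_equal(unname(sample_call_rate(g))[1], 1 / 3)

  expect_equal(minor_allele_frequency(matrix(c(0L, 1L, 2L, 2L), 4, 1))[1],
               0.375)  # p = 5/8
  expect_equal(minor_allele_frequency(matrix(0L, 4, 1))[1], 0)
  expect_equal(minor_allele_frequency(matrix(1L, 4, 1))[1], 0.5)
  expect_true(is.nan(minor_allele_frequency(matrix(NA_integer_, 4, 1))[1]))
})

test_that("exact HWE test agrees with the enumeration oracle (n <= 200)", {
  expect_equal(hwe_exact_test(1, 2, 1), 1)
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-15)
  expect_equal(hwe_exact_test(10, 0, 0), 1)  # monomorphic

  set.seed(42)
  for (rep in 1:60) {
    n <- sample(2:200, 1)
    counts <- as.vector(stats::rmultinom(1, n, prob = runif(3, 0.05, 1)))
    got <- hwe_exact_test(counts[1], counts[2], counts[3])
    want <- hwe_oracle(counts[1], counts[2], counts[3])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("heterozygosity outlier screen flags extreme SNPs only", {
  set.seed(7)
  g <- matrix(rbinom(1000 * 50, 2, 0.5), 50, 1000)
  expect_false(any(het_outlier_flags(cbind(g0 = rep(1L, 50),
                                           matrix(1L, 50, 3))[, 1:2])))
  g[, 1] <- 1L                      # Ho = 1 among SNPs with Ho ~ 0.5
  flags <- het_outlier_flags(g, 3)
  expect_true(flags[1])
  expect_lt(mean(flags[-1]), 0.02)
  expect_false(any(het_outlier_flags(g, Inf)))
})

test_that("QC cascade removes by first failing rule and keeps the counting
           identity", {
  set.seed(11)
  n <- 60
  g <- matrix(rbinom(n * 8, 2, 0.4), n, 8)
  g[, 2] <- c(rep(NA_integer_, 10), rep(0L, n - 10))      # call rate 5/6
  g[, 3] <- c(1L, rep(0L, n - 1))                          # MAF < 0.01
  g[, 4] <- rep(c(0L, 2L), n / 2)                          # HWE disaster
  pos <- as.integer(seq_len(8) * 1e5)
  map <- data.frame(snp_id = paste0("s", 1:8),
                    chrom = c("X", "1", "1", "1", "1", "1", "1", "1"),
                    pos_bp = c(pos[1:4], NA, pos[6:8]),
                    allele_a = "A", allele_b = "B")
  panel <- genopanel(g, map, rep("P1", n))
  qc <- apply_qc(panel, qc_config())
  rep_counts <- setNames(qc$report$n_snps, qc$report$reason)
  expect_equal(rep_counts[["non_autosomal"]], 1L)
  expect_equal(rep_counts[["unmapped"]], 1L)
  expect_equal(rep_counts[["low_call_rate"]], 1L)
  expect_equal(rep_counts[["low_maf"]], 1L)
  expect_equal(rep_counts[["hwe"]], 1L)
  expect_equal(sum(qc$report$n_snps), ncol(g))   # identity incl. survivors

  # idempotence: a second pass removes nothing
  qc2 <- apply_qc(qc$panel, qc_config())
  expect_equal(ncol(qc2$panel$geno), ncol(qc$panel$geno))
  expect_equal(qc2$report$n_snps[qc2$report$reason != "surviving"],
               rep(0L, 7))

  # fuzzed counting identity
  for (rep_i in 1:10) {
    gg <- matrix(rbinom(40 * 12, 2, runif(1, 0.02, 0.5)), 40, 12)
    gg[runif(length(gg)) < 0.1] <- NA_integer_
    pf <- make_panel(gg)
    qf <- apply_qc(pf, qc_config())
    expect_equal(sum(qf$report$n_snps), 12L)
    expect_equal(sum(qf$surviving),
                 qf$report$n_snps[qf$report$reason == "surviving"])
  }
})

test_that("a clean panel passes QC unchanged and GC scores are honoured", {
  set.seed(3)
  g <- matrix(rbinom(200 * 6, 2, 0.5), 200, 6)
  panel <- make_panel(g)
  qc <- apply_qc(panel, qc_config())
  expect_equal(qc$panel$geno, panel$geno)
  gc <- c(0.9, 0.5, 0.9, 0.9, 0.9, 0.9)
  qc_gc <- apply_qc(panel, qc_config(), gc_scores = gc)
  expect_equal(qc_gc$report$n_snps[qc_gc$report$reason == "low_gc"], 1L)
  expect_error(apply_qc(panel, qc_config(min_maf = 0.5)), "review")
})
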