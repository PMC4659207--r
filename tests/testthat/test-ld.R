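test_that("EM equals direct haplotype counting when phase is resolvable", {
  set.seed(21)
  for (rep_i in 1:25) {
    # build tables with no double heterozygotes
    repeat {
      x <- rbinom(40, 2, runif(1, 0.2, 0.8))
      y <- rbinom(40, 2, runif(1, 0.2, 0.8))
      y[x == 1L & y == 1L] <- sample(c(0L, 2L), sum(x == 1L & y == 1L),
                                     replace = TRUE)
      if (any(x == 1L) || any(y == 1L)) break
    }
    em <- em_haplotype_freqs(x, y)
    if (!em$valid) next
    oracle <- phased_count_freqs(x, y)
    expect_equal(em$f11, oracle$f11, tolerance = 1e-9)
    expect_equal(em$f10, oracle$f10, tolerance = 1e-9)
    expect_equal(em$f01, oracle$f01, tolerance = 1e-9)
    expect_equal(em$f00, oracle$f00, tolerance = 1e-9)
  }
})

test_that("EM fixed points: duplicated SNP and exact independence", {
  x <- c(rep(0L, 30), rep(1L, 40), rep(2L, 30))
  em <- em_haplotype_freqs(x, x)
  expect_equal(em$f11, 0.5, tolerance = 1e-9)
  expect_equal(em$f10, 0, tolerance = 1e-9)
  expect_equal(em$f01, 0, tolerance = 1e-9)
  st <- ld_stats(em)
  expect_equal(st$r2, 1, tolerance = 1e-9)
  expect_equal(st$dprime, 1, tolerance = 1e-9)

  # exact product-of-HWE-margins table (p = q = 0.5, n = 64)
  x2 <- rep(c(0L, 1L, 2L), c(16, 32, 16))
  y2 <- c(rep(c(0L, 1L, 2L), c(4, 8, 4)),     # within x=0
          rep(c(0L, 1L, 2L), c(8, 16, 8)),    # within x=1
          rep(c(0L, 1L, 2L), c(4, 8, 4)))     # within x=2
  em2 <- em_haplotype_freqs(x2, y2)
  expect_equal(em2$f11, 0.25, tolerance = 1e-9)
  st2 <- ld_stats(em2)
  expect_equal(st2$r2, 0, tolerance = 1e-9)
  expect_equal(st2$dprime, 0, tolerance = 1e-9)
})

test_that("EM never decreases the likelihood relative to its equilibrium
           start, and margins are preserved", {
  set.seed(33)
  for (rep_i in 1:20) {
    x <- rbinom(30, 2, runif(1, 0.15, 0.85))
    y <- rbinom(30, 2, runif(1, 0.15, 0.85))
    em <- em_haplotype_freqs(x, y)
    if (!em$valid) next
    # log-likelihood at the linkage-equilibrium start
    eq <- list(f11 = em$p1 * em$p2, f10 = em$p1 * (1 - em$p2),
               f01 = (1 - em$p1) * em$p2, f00 = (1 - em$p1) * (1 - em$p2))
    cc <- !is.na(x) & !is.na(y)
    cnt <- flockdiv:::pair_genotype_counts(cbind(x[cc], y[cc]), 1L, 2L)
    ll_eq <- flockdiv:::pair_loglik(eq$f11, eq$f10, eq$f01, eq$f00, cnt)
    expect_gte(em$loglik, ll_eq - 1e-9)
    # haplotype frequencies sum to 1 and match the allele-frequency margins
    expect_equal(em$f11 + em$f10 + em$f01 + em$f00, 1, tolerance = 1e-9)
    expect_equal(em$f11 + em$f10, em$p1, tolerance = 1e-6)
    expect_equal(em$f11 + em$f01, em$p2, tolerance = 1e-6)
  }
})

test_that("r2 and D-prime are invariant under allele relabeling", {
  set.seed(4)
  x <- rbinom(60, 2, 0.3); y <- rbinom(60, 2, 0.6)
  st <- ld_stats(em_haplotype_freqs(x, y))
  st_swap_x <- ld_stats(em_haplotype_freqs(2L - x, y))
  st_swap_both <- ld_stats(em_haplotype_freqs(2L - x, 2L - y))
  expect_equal(st_swap_x$r2, st$r2, tolerance = 1e-9)
  expect_equal(st_swap_x$dprime, st$dprime, tolerance = 1e-9)
  expect_equal(st_swap_both$r2, st$r2, tolerance = 1e-9)
  expect_equal(st_swap_both$dprime, st$dprime, tolerance = 1e-9)
})

test_that("D-prime bounds: concentration with evidence, width without", {
  x <- c(rep(0L, 100), rep(1L, 60), rep(2L, 40))
  ci <- dprime_confidence_bounds(x, x)      # perfect coupling, 200 ind.
  expect_gte(ci$ci_high, 0.98)
  expect_gt(ci$ci_low, 0.7)

  for (cfg in list(c(2L, 2L, 0L, 0L), c(2L, 1L, 1L, 0L))) {
    ci4 <- dprime_confidence_bounds(cfg, cfg)
    expect_gt(ci4$ci_high - ci4$ci_low, 0.5)   # 4 individuals: wide
  }

  # adding coupling-consistent individuals never lowers ci_low
  prev <- -1
  for (n in c(8, 16, 32, 64, 128)) {
    xx <- rep(c(0L, 2L), each = n / 2)
    ci_n <- dprime_confidence_bounds(xx, xx)
    expect_gte(ci_n$ci_low, prev)
    prev <- ci_n$ci_low
  }

  # degenerate: monomorphic locus -> uninformative (0, 1)
  cid <- dprime_confidence_bounds(c(0L, 0L, 0L, 0L), c(0L, 1L, 2L, 1L))
  expect_equal(cid$ci_low, 0)
  expect_equal(cid$ci_high, 1)
})

test_that("decay binning uses half-open bins and counts every pair once", {
  bins <- ld_bins()
  expect_equal(nrow(bins), 14L)
  expect_equal(bins$low_bp[-1], bins$high_bp[-14])   # partition of (0, Inf)

  set.seed(6)
  g <- matrix(rbinom(40 * 3, 2, 0.5), 40, 3)
  # SNPs at 1, 10001, 2000001: distances 10 kb (bin 2), 2 Mb - and 1999999
  panel <- make_panel(g, pos = c(1L, 10001L, 2000001L))
  dec <- ld_decay(panel, "P1")$decay
  expect_equal(sum(dec$n_pairs), 3L)
  expect_equal(dec$n_pairs[dec$bin == "10-20kb"], 1L)   # exactly 10 kb
  expect_equal(dec$n_pairs[dec$bin == "1-2Mb"], 1L)     # 1,999,999 bp
  expect_equal(dec$n_pairs[dec$bin == "2-5Mb"], 1L)     # 2,000,000 bp

  g2 <- matrix(rbinom(30 * 2, 2, 0.5), 30, 2)
  dec2 <- ld_decay(make_panel(g2), "P1")$decay
  expect_equal(sum(dec2$n_pairs), 1L)
})

test_that("adjacent LD averages consecutive pairs per chromosome", {
  set.seed(8)
  base <- rbinom(50, 2, 0.5)
  g <- cbind(base, base, base)            # duplicated columns -> r2 = 1
  panel <- make_panel(g)
  adj <- adjacent_ld(panel, "P1")
  expect_equal(adj$n_pairs, 2L)
  expect_equal(adj$mean_r2, 1, tolerance = 1e-9)

  g1 <- matrix(rbinom(30, 2, 0.5), ncol = 1)
  adj1 <- adjacent_ld(make_panel(g1), "P1")
  expect_true(is.na(adj1$mean_r2))
})

test_that("non-syntenic LD is seed-deterministic and enumerates cross
           pairs", {
  set.seed(10)
  g <- matrix(rbinom(50 * 4, 2, 0.5), 50, 4)
  panel <- make_panel(g, pos = c(1e5, 2e5, 1e5, 2e5),
                      chrom = c("1", "1", "2", "2"))
  ns1 <- nonsyntenic_ld(panel, "P1", fraction = 1, seed = 3)
  ns2 <- nonsyntenic_ld(panel, "P1", fraction = 1, seed = 3)
  expect_identical(ns1, ns2)
  expect_equal(ns1$n_pairs, 4L)   # 2 x 2 cross-chromosome pairs
  g_one <- make_panel(g, chrom = rep("1", 4))
  expect_error(nonsyntenic_ld(g_one, "P1"), "2 chromosomes")
})

test_that("LD decays with distance and is stronger in small populations", {
  sim_small <- simulate_panel(two_breed_scenario(77, n_sample = 40,
                                                 ne_a = 40, ne_b = 500))
  dec_small <- ld_decay(sim_small$panel, "A")$decay
  dec_large <- ld_decay(sim_small$panel, "B")$decay
  ok <- !is.na(dec_small$mean_r2) & !is.na(dec_large$mean_r2)
  # small-Ne population dominates in the short-range bins
  expect_gt(dec_small$mean_r2[1], dec_large$mean_r2[1])
  # decay: Spearman correlation of mean r2 with bin order is negative
  sp <- cor(seq_len(sum(ok)), dec_small$mean_r2[ok], method = "spearman")
  expect_lt(sp, 0)
})
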