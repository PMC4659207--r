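test_that("the minimum-SNP formula evaluates, rounds up, and guards its
           domain", {
  expect_equal(min_roh_snps(48599, 1273, 0.05, 0.35), 49L)
  expect_equal(min_roh_snps(100, 10, 0.05, 1 - 1e-9), 1L)  # het -> 1 limit
  expect_warning(l0 <- min_roh_snps(2, 2, 4, 0.3), "0")
  expect_error(min_roh_snps(100, 10, 0.05, 0), "het")
  # direct evaluation against the closed form
  expect_equal(min_roh_snps(1000, 50, 0.05, 0.3),
               as.integer(ceiling(log(0.05 / (1000 * 50)) / log(0.7))))
})

test_that("planted homozygous runs are recovered, short ones rejected, and
           long gaps split candidates", {
  params <- roh_params(window_span_kb = 300)
  fx <- roh_fixture(600)
  panel <- make_panel(fx$geno, pos = fx$pos)
  segs <- detect_roh(panel, params, l = 10L)
  expect_equal(nrow(segs), 1L)
  # boundaries within a few SNPs of the plant (hit-fraction smearing)
  expect_lt(abs(segs$start_bp - fx$run_range[1]), 4 * 40 * 1000)
  expect_lt(abs(segs$end_bp - fx$run_range[2]), 4 * 40 * 1000)

  fx4 <- roh_fixture(400, seed = 2)
  segs4 <- detect_roh(make_panel(fx4$geno, pos = fx4$pos), params, l = 5L)
  expect_equal(nrow(segs4), 0L)       # fails the 500 kb length filter

  # 1200 kb run with a 300 kb interior gap: two segments, tested separately
  fx_gap <- roh_fixture(1200, gap_at = 15, gap_kb = 300, seed = 3)
  panel_gap <- make_panel(fx_gap$geno, pos = fx_gap$pos)
  segs_gap <- detect_roh(panel_gap, params, l = 10L)
  expect_equal(nrow(segs_gap), 2L)
  gap_between <- segs_gap$start_bp[2] - segs_gap$end_bp[1]
  expect_gte(gap_between, 250 * 1000)
})

test_that("every emitted segment satisfies the three ROH filters", {
  params <- roh_params()
  for (seed in 1:5) {
    set.seed(seed)
    m <- 300
    g <- matrix(rbinom(4 * m, 2, runif(1, 0.2, 0.5)), 4, m)
    # make two individuals mostly homozygous so segments appear
    g[1:2, ] <- 2L * matrix(rbinom(2 * m, 1, 0.5), 2, m)
    g[matrix(runif(4 * m) < 0.01, 4, m)] <- NA_integer_
    panel <- make_panel(g, pos = as.integer(cumsum(rep(2e4, m))))
    segs <- detect_roh(panel, params, l = 25L)
    if (nrow(segs) == 0L) next
    expect_true(all(segs$n_snps >= 25L))
    expect_true(all(segs$length_bp >= params$min_length_kb * 1000))
    for (r in seq_len(nrow(segs))) {
      inside <- panel$map$pos_bp >= segs$start_bp[r] &
        panel$map$pos_bp <= segs$end_bp[r]
      expect_lte(max(diff(panel$map$pos_bp[inside])),
                 params$max_gap_kb * 1000)
    }
  }
})

test_that("fully heterozygous individuals have no ROH; fully homozygous ones
           tile the chromosome", {
  m <- 200
  pos <- as.integer(cumsum(rep(2e4, m)))
  het <- make_panel(matrix(1L, 1, m), pos = pos)
  expect_equal(nrow(detect_roh(het, roh_params(), l = 20L)), 0L)

  set.seed(5)
  hom <- make_panel(matrix(2L * rbinom(m, 1, 0.5), 1, m), pos = pos)
  segs <- detect_roh(hom, roh_params(), l = 20L)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[m])
})

test_that("length categories are half-open Mb bins with sub-1 Mb segments in
           totals only", {
  segs <- data.frame(
    individual = c("i1", "i1", "i1", "i2"), population = "P1",
    chrom = "1", start_bp = 0,
    end_bp = c(3e6, 4e6, 6e6, 5e6),
    n_snps = 50L, length_bp = c(3e6, 4e6, 6e6, 5e6))
  segs$end_bp <- segs$start_bp + segs$length_bp
  rc <- roh_length_categories(segs)
  i1 <- rc$per_individual[rc$per_individual$individual == "i1", ]
  expect_equal(i1[["1-5Mb"]], 7)      # 3 + 4 Mb
  expect_equal(i1[["5-10Mb"]], 6)
  i2 <- rc$per_individual[rc$per_individual$individual == "i2", ]
  expect_equal(i2[["5-10Mb"]], 5)     # boundary 5 Mb exactly -> upper bin
  expect_equal(i2[["1-5Mb"]], 0)

  short <- data.frame(individual = "i3", population = "P1", chrom = "1",
                      start_bp = 0, end_bp = 7e5, n_snps = 60L,
                      length_bp = 7e5)
  rc2 <- roh_length_categories(short)
  expect_equal(rc2$per_individual$total_mb, 0.7)
  expect_equal(sum(rc2$per_individual[, c("1-5Mb", "5-10Mb", "10-15Mb",
                                          "15-20Mb", "20-25Mb", ">25Mb")]),
               0)
})

test_that("incidence counts individuals covering each SNP", {
  map <- data.frame(snp_id = paste0("s", 1:30), chrom = "1",
                    pos_bp = as.integer(1:30 * 1e5),
                    allele_a = "A", allele_b = "B")
  expect_equal(roh_incidence(data.frame(individual = character(),
                                        chrom = character(),
                                        start_bp = integer(),
                                        end_bp = integer()), map),
               rep(0L, 30))
  segs <- data.frame(individual = c("i1", "i2"), chrom = "1",
                     start_bp = c(10e5, 15e5), end_bp = c(20e5, 25e5))
  inc <- roh_incidence(segs, map)
  expect_equal(inc[9], 0L)
  expect_equal(inc[10], 1L)
  expect_equal(inc[17], 2L)   # overlap of both segments
  expect_equal(inc[25], 1L)
})

test_that("per-chromosome summaries follow the two-step mean construction", {
  map <- data.frame(snp_id = c("a", "b"), chrom = c("1", "2"),
                    pos_bp = c(1e6, 1e6), allele_a = "A", allele_b = "B")
  segs <- data.frame(individual = c("i1", "i2"), population = "P1",
                     chrom = "1", start_bp = 0, end_bp = c(10e6, 20e6),
                     n_snps = 10L, length_bp = c(10e6, 20e6))
  s <- roh_chromosome_summary(segs, map,
                              chrom_lengths_bp = c("1" = 1e8, "2" = 1e8))
  r1 <- s[s$chrom == "1", ]
  expect_equal(r1$mean_mb, 15)        # (10 + 20) / 2 animals
  expect_equal(r1$pct_coverage, 15)
  r2 <- s[s$chrom == "2", ]
  expect_equal(r2$pct_coverage, 0)
  expect_true(r2$no_roh)

  one <- segs[1, ]
  s1 <- roh_chromosome_summary(one, map,
                               chrom_lengths_bp = c("1" = 1e8, "2" = 1e8))
  expect_equal(s1$pct_coverage[s1$chrom == "1"], 10)
})
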