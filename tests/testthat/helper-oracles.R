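# Shared fixtures and independent oracles used across the test files.

# quick panel builder: geno is individuals x SNPs; positions default 100 kb
# spacing on one chromosome
make_panel <- function(geno, pop = rep("P1", nrow(geno)),
                       pos = NULL, chrom = NULL) {
  m <- ncol(geno)
  if (is.null(pos)) pos <- as.integer(seq_len(m) * 1e5)
  if (is.null(chrom)) chrom <- rep("1", m)
  map <- data.frame(snp_id = paste0("s", seq_len(m)), chrom = chrom,
                    pos_bp = as.integer(pos), allele_a = "A", allele_b = "B",
                    stringsAsFactors = FALSE)
  genopanel(geno, map, pop)
}

# exact HWE enumeration oracle: direct combinatorial probability of every
# compatible heterozygote count (no recurrence, log-factorials only)
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  if (n_a == 0L || n_b == 0L) return(1)
  hets <- seq.int(min(n_a, n_b) %% 2L, min(n_a, n_b), by = 2L)
  logp <- vapply(hets, function(h) {
    naa <- (n_a - h) / 2
    nbb <- (n_b - h) / 2
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(n_a + 1) - lgamma(n_b + 1))
  }, numeric(1))
  pr <- exp(logp)
  obs <- pr[match(n_ab, hets)]
  min(sum(pr[pr <= obs * (1 + 1e-12)]), 1)
}

# haplotype frequencies by direct counting — valid only when no individual
# is a double heterozygote (phase fully resolved)
phased_count_freqs <- function(x, y) {
  cc <- !is.na(x) & !is.na(y)
  x <- x[cc]; y <- y[cc]
  stopifnot(!any(x == 1L & y == 1L))
  c11 <- c10 <- c01 <- c00 <- 0
  for (i in seq_along(x)) {
    h1 <- c(x[i] >= 1L, y[i] >= 1L)   # one haplotype
    h2 <- c(x[i] == 2L, y[i] == 2L)   # the other
    for (h in list(h1, h2)) {
      if (h[1] && h[2]) c11 <- c11 + 1
      else if (h[1]) c10 <- c10 + 1
      else if (h[2]) c01 <- c01 + 1
      else c00 <- c00 + 1
    }
  }
  tot <- 2 * length(x)
  list(f11 = c11 / tot, f10 = c10 / tot, f01 = c01 / tot, f00 = c00 / tot)
}

# a small diverged two-breed + F1 scenario reused by several files
two_breed_scenario <- function(seed, n_sample = 40, split_generations = 60,
                               ne_a = 50, ne_b = 400, with_cross = FALSE) {
  crosses <- if (with_cross)
    list(AB = list(parents = c("A", "B"), n_sample = n_sample)) else list()
  sim_scenario(
    chromosome_lengths_mb = c("1" = 40, "2" = 30),
    snps_per_mb = 10, founder_ne = 200,
    split_generations = split_generations,
    breeds = list(A = list(ne = ne_a, n_sample = n_sample),
                  B = list(ne = ne_b, n_sample = n_sample)),
    crosses = crosses, missing_rate = 0.02, genotype_error_rate = 0,
    seed = seed)
}
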