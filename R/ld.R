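# ---------------------------------------------------------------------------
# Pairwise LD from unphased genotypes.
#
# The workhorse is a vectorized engine: for a list of SNP index pairs it
# tabulates the 3x3 genotype table of every pair (complete-case), runs the
# EM haplotype-frequency iteration on all pairs simultaneously, and derives
# r2 / D' (and, on request, likelihood-profile D' confidence bounds). Only
# double heterozygotes are phase-ambiguous; every other genotype pair
# contributes known haplotypes.
# ---------------------------------------------------------------------------

# 3x3 genotype counts for index pairs (ii, jj); chunked to bound memory.
# Returns a list of 9 integer vectors n_gh, g/h = dosage at ii/jj.
pair_genotype_counts <- function(g, ii, jj, chunk = 20000L) {
  ind <- list(`0` = !is.na(g) & g == 0L,
              `1` = !is.na(g) & g == 1L,
              `2` = !is.na(g) & g == 2L)
  P <- length(ii)
  out <- stats::setNames(vector("list", 9L),
                         as.vector(outer(0:2, 0:2, paste0)))
  for (nm in names(out)) out[[nm]] <- integer(P)
  start <- 1L
  while (start <= P) {
    end <- min(start + chunk - 1L, P)
    sl <- start:end
    for (gg in 0:2) {
      A <- ind[[gg + 1L]][, ii[sl], drop = FALSE]
      for (hh in 0:2) {
        B <- ind[[hh + 1L]][, jj[sl], drop = FALSE]
        out[[paste0(gg, hh)]][sl] <- as.integer(colSums(A & B))
      }
    }
    start <- end + 1L
  }
  out
}

# EM over all pairs at once. cnt: list from pair_genotype_counts.
# Returns per-pair haplotype freqs (f11 carries the B allele at both loci),
# margins, complete-case S, iteration count and final log-likelihood.
em_haplotype_freqs_counts <- function(cnt, tol = 1e-10, max_iter = 1000L) {
  n00 <- cnt[["00"]]; n01 <- cnt[["01"]]; n02 <- cnt[["02"]]
  n10 <- cnt[["10"]]; n11 <- cnt[["11"]]; n12 <- cnt[["12"]]
  n20 <- cnt[["20"]]; n21 <- cnt[["21"]]; n22 <- cnt[["22"]]
  S <- n00 + n01 + n02 + n10 + n11 + n12 + n20 + n21 + n22
  p1 <- (2 * (n20 + n21 + n22) + n10 + n11 + n12) / (2 * S)
  p2 <- (2 * (n02 + n12 + n22) + n01 + n11 + n21) / (2 * S)
  valid <- S >= 2L & p1 > 0 & p1 < 1 & p2 > 0 & p2 < 1

  f11 <- p1 * p2; f10 <- p1 * (1 - p2)
  f01 <- (1 - p1) * p2; f00 <- (1 - p1) * (1 - p2)
  iters <- integer(length(S))
  if (any(valid)) {
    for (it in seq_len(max_iter)) {
      num <- f11 * f00
      den <- num + f10 * f01
      pi_c <- ifelse(den > 0, num / den, 0.5)   # coupling fraction of 1/1s
      c11 <- 2 * n22 + n21 + n12 + pi_c * n11
      c10 <- 2 * n20 + n21 + n10 + (1 - pi_c) * n11
      c01 <- 2 * n02 + n12 + n01 + (1 - pi_c) * n11
      c00 <- 2 * n00 + n10 + n01 + pi_c * n11
      t11 <- c11 / (2 * S); t10 <- c10 / (2 * S)
      t01 <- c01 / (2 * S); t00 <- c00 / (2 * S)
      delta <- pmax(abs(t11 - f11), abs(t10 - f10),
                    abs(t01 - f01), abs(t00 - f00))
      f11 <- t11; f10 <- t10; f01 <- t01; f00 <- t00
      moved <- valid & delta >= tol
      iters[valid & iters == 0L & !moved] <- it
      if (!any(moved)) break
    }
    iters[valid & iters == 0L] <- max_iter
  }
  ll <- pair_loglik(f11, f10, f01, f00, cnt)
  f11[!valid] <- NA_real_; f10[!valid] <- NA_real_
  f01[!valid] <- NA_real_; f00[!valid] <- NA_real_
  ll[!valid] <- NA_real_
  list(f11 = f11, f10 = f10, f01 = f01, f00 = f00,
       p1 = p1, p2 = p2, n = S, iterations = iters, loglik = ll,
       valid = valid, counts = cnt)
}

# multinomial log-likelihood of the 3x3 tables given haplotype freqs
pair_loglik <- function(f11, f10, f01, f00, cnt) {
  eps <- 1e-12
  lg <- function(x) log(pmax(x, eps))
  cnt[["22"]] * lg(f11^2) + cnt[["21"]] * lg(2 * f11 * f10) +
    cnt[["20"]] * lg(f10^2) + cnt[["12"]] * lg(2 * f11 * f01) +
    cnt[["11"]] * lg(2 * (f11 * f00 + f10 * f01)) +
    cnt[["10"]] * lg(2 * f10 * f00) + cnt[["02"]] * lg(f01^2) +
    cnt[["01"]] * lg(2 * f01 * f00) + cnt[["00"]] * lg(f00^2)
}

#' EM haplotype frequencies for one SNP pair
#'
#' Maximum-likelihood haplotype frequencies for two unphased biallelic SNPs.
#' Individuals missing either genotype are dropped (complete-case). The EM
#' iteration starts at linkage equilibrium and splits the phase-ambiguous
#' double heterozygotes each round in the ratio f11*f00 : f10*f01, stopping
#' when no frequency moves by 1e-10 (or after 1000 iterations).
#'
#' @param x,y dosage vectors (0/1/2/NA) at the two SNPs.
#' @return List with haplotype frequencies `f11`, `f10`, `f01`, `f00`
#'   (index 1 = the dosage-counted B allele), allele frequencies `p1`, `p2`,
#'   complete-case size `n`, `iterations`, `loglik`, and `valid` (FALSE when
#'   either locus is monomorphic in the complete cases, where LD is
#'   undefined).
#' @export
em_haplotype_freqs <- function(x, y) {
  stopifnot(length(x) == length(y))
  cc <- !is.na(x) & !is.na(y)
  g <- cbind(x[cc], y[cc])
  cnt <- pair_genotype_counts(g, 1L, 2L)
  res <- em_haplotype_freqs_counts(cnt)
  lapply(res[c("f11", "f10", "f01", "f00", "p1", "p2", "n",
               "iterations", "loglik", "valid")], `[`, 1L)
}

#' r-squared and D-prime from haplotype frequencies
#'
#' D = f11 - p1*p2; r2 = D^2 / (p1 q1 p2 q2); D' = |D| / Dmax with
#' Dmax = min(p1*q2, q1*p2) for D > 0 and min(p1*p2, q1*q2) for D < 0
#' (D = 0 gives D' = 0). Undefined (NA) when either margin is fixed.
#'
#' @param freqs output of [em_haplotype_freqs()] (or any list with `f11`,
#'   `p1`, `p2`; vectors allowed).
#' @return List with vectors `D`, `r2`, `dprime`.
#' @export
ld_stats <- function(freqs) {
  p1 <- freqs$p1; p2 <- freqs$p2
  q1 <- 1 - p1; q2 <- 1 - p2
  D <- freqs$f11 - p1 * p2
  denom <- p1 * q1 * p2 * q2
  r2 <- ifelse(denom > 0, D^2 / denom, NA_real_)
  dmax <- ifelse(D >= 0, pmin(p1 * q2, q1 * p2), pmin(p1 * p2, q1 * q2))
  dprime <- ifelse(denom > 0,
                   ifelse(D == 0 | dmax == 0, 0, abs(D) / dmax),
                   NA_real_)
  list(D = D, r2 = pmin(r2, 1), dprime = pmin(dprime, 1))
}

# Likelihood-profile D' bounds, vectorized over pairs.
# Allele frequencies are held at their MLEs; the data likelihood is evaluated
# on the grid D' = 0, 0.01, ..., 1 (oriented so the point estimate of D is
# non-negative), normalized to a discrete distribution; the bounds are the
# 5th and 95th percentiles of that distribution.
dprime_ci_counts <- function(em, grid_step = 0.01) {
  cnt <- em$counts
  P <- length(em$p1)
  # orient locus 2 so D >= 0
  D <- em$f11 - em$p1 * em$p2
  flip <- !is.na(D) & D < 0
  cnt_o <- cnt
  if (any(flip)) {
    for (gg in 0:2) {
      a <- paste0(gg, "0"); b <- paste0(gg, "2")
      tmp <- cnt_o[[a]][flip]
      cnt_o[[a]][flip] <- cnt_o[[b]][flip]
      cnt_o[[b]][flip] <- tmp
    }
  }
  p1 <- em$p1; p2 <- ifelse(flip, 1 - em$p2, em$p2)
  q1 <- 1 - p1; q2 <- 1 - p2
  dmax <- pmin(p1 * q2, q1 * p2)
  grid <- seq(0, 1, by = grid_step)
  ll <- matrix(NA_real_, P, length(grid))
  for (k in seq_along(grid)) {
    Dk <- grid[k] * dmax
    ll[, k] <- pair_loglik(p1 * p2 + Dk, p1 * q2 - Dk,
                           q1 * p2 - Dk, q1 * q2 + Dk, cnt_o)
  }
  mx <- apply(ll, 1L, max)
  w <- exp(ll - mx)
  w <- w / rowSums(w)
  cum <- matrix(t(apply(w, 1L, cumsum)), nrow = P)
  lo <- grid[apply(cum >= 0.05, 1L, which.max)]
  hi <- grid[apply(cum >= 0.95, 1L, which.max)]
  bad <- !em$valid
  lo[bad] <- 0; hi[bad] <- 1          # degenerate: uninformative bounds
  list(ci_low = lo, ci_high = hi)
}

#' One-sided 95\% confidence bounds on D-prime
#'
#' @inheritParams em_haplotype_freqs
#' @return List with `ci_low`, `ci_high` in [0, 1]. A degenerate table
#'   (either locus monomorphic) returns the uninformative bounds (0, 1).
#' @export
dprime_confidence_bounds <- function(x, y) {
  cc <- !is.na(x) & !is.na(y)
  cnt <- pair_genotype_counts(cbind(x[cc], y[cc]), 1L, 2L)
  em <- em_haplotype_freqs_counts(cnt)
  ci <- dprime_ci_counts(em)
  list(ci_low = ci$ci_low[1L], ci_high = ci$ci_high[1L])
}

#' Pairwise LD for an explicit list of SNP pairs
#'
#' @param geno dosage matrix or [genopanel].
#' @param ii,jj integer vectors of SNP column indices (paired).
#' @param ci also compute D-prime confidence bounds (slower).
#' @return data.frame with one row per pair: indices, complete-case `n`,
#'   allele frequencies, `D`, `r2`, `dprime` (NA for pairs where either SNP
#'   is monomorphic among complete cases) and, if `ci`, `ci_low`/`ci_high`.
#' @export
ld_pairs <- function(geno, ii, jj, ci = FALSE) {
  g <- if (inherits(geno, "genopanel")) geno$geno else geno
  stopifnot(length(ii) == length(jj))
  if (length(ii) == 0L)
    return(data.frame(i = integer(), j = integer(), n = integer(),
                      p_i = numeric(), p_j = numeric(), D = numeric(),
                      r2 = numeric(), dprime = numeric()))
  cnt <- pair_genotype_counts(g, ii, jj)
  em <- em_haplotype_freqs_counts(cnt)
  st <- ld_stats(em)
  out <- data.frame(i = ii, j = jj, n = em$n, p_i = em$p1, p_j = em$p2,
                    D = st$D, r2 = st$r2, dprime = st$dprime)
  if (ci) {
    bounds <- dprime_ci_counts(em)
    out$ci_low <- bounds$ci_low
    out$ci_high <- bounds$ci_high
  }
  out
}

#' The 14 standard LD decay distance bins
#'
#' Half-open intervals [low, high) in bp: <10 kb, 10-20, 20-40, 40-60,
#' 60-100, 100-200, 200-500 kb, 500 kb-1 Mb, 1-2, 2-5, 5-10, 10-20,
#' 20-50, >50 Mb.
#'
#' @return data.frame with `label`, `low_bp`, `high_bp`.
#' @export
ld_bins <- function() {
  breaks <- c(0, 1e4, 2e4, 4e4, 6e4, 1e5, 2e5, 5e5,
              1e6, 2e6, 5e6, 1e7, 2e7, 5e7, Inf)
  data.frame(
    label = c("<10kb", "10-20kb", "20-40kb", "40-60kb", "60-100kb",
              "100-200kb", "200-500kb", "500kb-1Mb", "1-2Mb", "2-5Mb",
              "5-10Mb", "10-20Mb", "20-50Mb", ">50Mb"),
    low_bp = breaks[-length(breaks)], high_bp = breaks[-1L])
}

# indices of all within-chromosome pairs, optionally capped by bp distance
syntenic_pairs <- function(map, max_distance_bp = Inf) {
  res_i <- list(); res_j <- list(); k <- 0L
  for (ch in unique(as.character(map$chrom))) {
    idx <- which(as.character(map$chrom) == ch)
    mc <- length(idx)
    if (mc < 2L) next
    pr <- utils::combn(mc, 2L)
    i <- idx[pr[1L, ]]; j <- idx[pr[2L, ]]
    if (is.finite(max_distance_bp)) {
      keep <- abs(map$pos_bp[j] - map$pos_bp[i]) <= max_distance_bp
      i <- i[keep]; j <- j[keep]
    }
    k <- k + 1L
    res_i[[k]] <- i; res_j[[k]] <- j
  }
  list(i = unlist(res_i), j = unlist(res_j))
}

# restrict a panel to one population and drop SNPs monomorphic within it
population_subpanel <- function(panel, population) {
  idx <- panel$pop == population
  if (!any(idx)) stop("population not found: ", population)
  sub <- panel[idx, ]
  p <- allele_frequency(sub)
  keep <- !is.nan(p) & p > 0 & p < 1
  out <- sub[, keep]
  attr(out, "n_monomorphic_dropped") <- sum(!keep)
  out
}

#' LD decay table for one population
#'
#' Evaluates r2 and D' for all syntenic (within-chromosome) SNP pairs of one
#' population (complete-case per pair; SNPs monomorphic within the population
#' are dropped first and their number logged as an attribute), bins pairs by
#' distance into the 14 standard categories, and also returns per-chromosome
#' all-pairs means.
#'
#' @param panel a [genopanel] (QC-passed).
#' @param population population label.
#' @param bins bin table as from [ld_bins()].
#' @param max_distance_bp optional cap on pair distance (default exact/all).
#' @return List with `decay` (one row per bin: mean r2, mean D', pair count),
#'   `by_chromosome` (per-chromosome all-pairs means), and attribute
#'   `n_monomorphic_dropped`.
#' @export
ld_decay <- function(panel, population, bins = ld_bins(),
                     max_distance_bp = Inf) {
  sub <- population_subpanel(panel, population)
  pr <- syntenic_pairs(sub$map, max_distance_bp)
  ld <- ld_pairs(sub, pr$i, pr$j)
  dist <- abs(sub$map$pos_bp[pr$j] - sub$map$pos_bp[pr$i])
  ok <- !is.na(ld$r2)
  bin_idx <- findInterval(dist, c(bins$low_bp, Inf),
                          rightmost.closed = FALSE)  # [low, high)
  decay <- data.frame(bin = bins$label, low_bp = bins$low_bp,
                      high_bp = bins$high_bp)
  decay$n_pairs <- vapply(seq_len(nrow(bins)),
                          function(b) sum(bin_idx == b & ok), integer(1))
  decay$mean_r2 <- vapply(seq_len(nrow(bins)), function(b) {
    sel <- bin_idx == b & ok
    if (!any(sel)) NA_real_ else mean(ld$r2[sel])
  }, numeric(1))
  decay$mean_dprime <- vapply(seq_len(nrow(bins)), function(b) {
    sel <- bin_idx == b & ok
    if (!any(sel)) NA_real_ else mean(ld$dprime[sel])
  }, numeric(1))

  chrom_i <- as.character(sub$map$chrom)[pr$i]
  by_chrom <- do.call(rbind, lapply(unique(chrom_i), function(ch) {
    sel <- chrom_i == ch & ok
    data.frame(chrom = ch, n_pairs = sum(sel),
               mean_r2 = if (any(sel)) mean(ld$r2[sel]) else NA_real_,
               mean_dprime = if (any(sel)) mean(ld$dprime[sel]) else NA_real_)
  }))
  out <- list(decay = decay, by_chromosome = by_chrom)
  attr(out, "n_monomorphic_dropped") <- attr(sub, "n_monomorphic_dropped")
  out
}

#' Mean LD between adjacent SNPs, per chromosome
#'
#' @inheritParams ld_decay
#' @return data.frame per chromosome: number of adjacent pairs and mean r2
#'   (NA for single-SNP chromosomes).
#' @export
adjacent_ld <- function(panel, population) {
  sub <- population_subpanel(panel, population)
  ord <- map_order(sub$map)
  sub <- sub[, ord]
  chrom <- as.character(sub$map$chrom)
  res <- lapply(unique(chrom), function(ch) {
    idx <- which(chrom == ch)
    if (length(idx) < 2L)
      return(data.frame(chrom = ch, n_pairs = 0L, mean_r2 = NA_real_))
    i <- idx[-length(idx)]; j <- idx[-1L]
    ld <- ld_pairs(sub, i, j)
    ok <- !is.na(ld$r2)
    data.frame(chrom = ch, n_pairs = sum(ok),
               mean_r2 = if (any(ok)) mean(ld$r2[ok]) else NA_real_)
  })
  do.call(rbind, res)
}

#' Baseline LD between non-syntenic SNPs
#'
#' Samples a seeded fraction of SNPs on each chromosome and evaluates r2 for
#' every cross-chromosome pair among the sampled SNPs. In the absence of
#' population structure this estimates the pure sampling floor of r2
#' (approximately 1/S + 3.19/S^2 for sample size S).
#'
#' @inheritParams ld_decay
#' @param fraction fraction of SNPs sampled per chromosome (ceiling).
#' @param seed RNG seed for the SNP sample.
#' @return List with `mean_r2`, `n_pairs`, and the sampled SNP ids.
#' @export
nonsyntenic_ld <- function(panel, population, fraction = 0.05, seed = 1L) {
  sub <- population_subpanel(panel, population)
  chrom <- as.character(sub$map$chrom)
  chroms <- unique(chrom)
  if (length(chroms) < 2L) stop("non-syntenic LD needs >= 2 chromosomes")
  sel <- with_seed(seed, {
    unlist(lapply(chroms, function(ch) {
      idx <- which(chrom == ch)
      sort(sample(idx, ceiling(fraction * length(idx))))
    }))
  })
  ch_sel <- chrom[sel]
  pr <- utils::combn(length(sel), 2L)
  cross <- ch_sel[pr[1L, ]] != ch_sel[pr[2L, ]]
  i <- sel[pr[1L, cross]]; j <- sel[pr[2L, cross]]
  ld <- ld_pairs(sub, i, j)
  ok <- !is.na(ld$r2)
  list(mean_r2 = if (any(ok)) mean(ld$r2[ok]) else NA_real_,
       n_pairs = sum(ok), snp_ids = sub$map$snp_id[sel])
}
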