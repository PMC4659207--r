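# Burrows composite LD and the LD method for contemporary Ne.
#
# The composite disequilibrium is estimable from unphased genotypes without
# assuming HWE: Delta = cov(x, y)/2 with the sample (S-1) covariance -- the
# scaling the downstream bias-corrected Ne formulas are calibrated to -- and
# the squared correlation uses Weir's composite denominator (pq + D_hom) per
# locus, where D_hom is the locus's homozygote excess relative to HWE. For a
# duplicated locus Delta(MLE) = pq + D_hom exactly, so the (S/(S-1))^2
# inflation is clipped at 1.

# per-pair Burrows r2 from the 9 genotype counts (vectorized)
burrows_r2_counts <- function(cnt) {
  n00 <- cnt[["00"]]; n01 <- cnt[["01"]]; n02 <- cnt[["02"]]
  n10 <- cnt[["10"]]; n11 <- cnt[["11"]]; n12 <- cnt[["12"]]
  n20 <- cnt[["20"]]; n21 <- cnt[["21"]]; n22 <- cnt[["22"]]
  S <- n00 + n01 + n02 + n10 + n11 + n12 + n20 + n21 + n22
  sxy <- 4 * n22 + 2 * n21 + 2 * n12 + n11
  px <- (2 * (n20 + n21 + n22) + n10 + n11 + n12) / (2 * S)
  py <- (2 * (n02 + n12 + n22) + n01 + n11 + n21) / (2 * S)
  Pxx <- (n20 + n21 + n22) / S          # homozygote (dosage 2) freq, locus x
  Pyy <- (n02 + n12 + n22) / S
  delta <- (sxy / 2 - 2 * S * px * py) / (S - 1)   # cov(x, y)/2, S-1 form
  dx <- Pxx - px^2                       # homozygote excess
  dy <- Pyy - py^2
  denom <- (px * (1 - px) + dx) * (py * (1 - py) + dy)
  r2 <- ifelse(S >= 2L & px > 0 & px < 1 & py > 0 & py < 1 & denom > 0,
               pmin(delta^2 / denom, 1), NA_real_)
  list(r2 = r2, n = S)
}

#' Burrows composite r-squared for one locus pair
#'
#' @param x,y dosage vectors (0/1/2/NA); individuals missing either locus
#'   are dropped.
#' @return r2 (NA when either locus is monomorphic among complete cases).
#' @export
burrows_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  cc <- !is.na(x) & !is.na(y)
  if (sum(cc) < 2L) return(NA_real_)
  cnt <- pair_genotype_counts(cbind(x[cc], y[cc]), 1L, 2L)
  burrows_r2_counts(cnt)$r2[1L]
}

# Waples sampling expectation and Ne solution, random-mating model.
# large sample (S >= 30): E[r2] = 1/S + 3.19/S^2,
#   Ne = (1/3 + sqrt(1/9 - 2.76 rd)) / (2 rd)
# small sample:           E[r2] = 0.0018 + 0.907/S + 4.44/S^2,
#   Ne = (0.308 + sqrt(0.308^2 - 2.08 rd)) / (2 rd)
r2_sampling_floor <- function(S, small_sample = FALSE) {
  if (small_sample) 0.0018 + 0.907 / S + 4.44 / S^2 else 1 / S + 3.19 / S^2
}

ne_from_r2drift <- function(rd, small_sample = FALSE) {
  if (rd <= 0) return(Inf)
  a <- if (small_sample) 0.308 else 1 / 3
  b <- if (small_sample) 2.08 else 2.76
  disc <- a^2 - b * rd
  if (disc < 0) disc <- 0
  (a + sqrt(disc)) / (2 * rd)
}

#' LD-based effective population size for one population
#'
#' Single-sample LD method under random mating: mean Burrows composite r2
#' across locus pairs (weighted by per-pair complete-case sample size), minus
#' the sampling expectation for unlinked loci at the harmonic mean sample
#' size, gives the drift component of LD; Ne follows from the bias-corrected
#' quadratic. Non-positive drift r2 yields an infinite estimate.
#'
#' Unlinked pairs are the method's assumption, so the default pair set is
#' non-syntenic (cross-chromosome) pairs among a seeded per-chromosome SNP
#' subsample; `pairs = "all"` uses every pair among the retained SNPs for
#' comparability with whole-panel runs, at the cost of a known downward bias
#' from physical linkage.
#'
#' @param panel a [genopanel].
#' @param population population label.
#' @param pcrit lowest allele frequency retained (SNPs with MAF < pcrit are
#'   excluded before pairing).
#' @param pairs `"nonsyntenic"` (default) or `"all"`.
#' @param fraction per-chromosome SNP sampling fraction for the non-syntenic
#'   set.
#' @param seed RNG seed for the SNP subsample.
#' @param small_sample use the small-sample (S < 30) correction constants.
#' @return List of class `ne_estimate`: `ne_hat` (possibly `Inf`),
#'   `mean_r2`, `r2_drift`, `expected_r2_floor`, `n_pairs`, `harmonic_s`,
#'   `pcrit`, `pairs`.
#' @export
estimate_ne <- function(panel, population, pcrit = 0.05,
                        pairs = c("nonsyntenic", "all"), fraction = 0.05,
                        seed = 1L, small_sample = FALSE) {
  pairs <- match.arg(pairs)
  idx <- panel$pop == population
  if (!any(idx)) stop("population not found: ", population)
  S_ind <- sum(idx)
  if (S_ind < 30L && !small_sample)
    stop("sample size < 30: use `small_sample = TRUE` ",
         "(small-sample correction constants)")
  sub <- panel[idx, ]
  maf <- minor_allele_frequency(sub)
  sub <- sub[, !is.nan(maf) & maf >= pcrit]
  chrom <- as.character(sub$map$chrom)
  if (pairs == "nonsyntenic") {
    chroms <- unique(chrom)
    if (length(chroms) < 2L)
      stop("non-syntenic pairing needs >= 2 chromosomes")
    sel <- with_seed(seed, {
      unlist(lapply(chroms, function(ch) {
        cidx <- which(chrom == ch)
        sort(sample(cidx, ceiling(fraction * length(cidx))))
      }))
    })
    pr <- utils::combn(length(sel), 2L)
    keep <- chrom[sel[pr[1L, ]]] != chrom[sel[pr[2L, ]]]
    ii <- sel[pr[1L, keep]]; jj <- sel[pr[2L, keep]]
  } else {
    pr <- utils::combn(ncol(sub$geno), 2L)
    ii <- pr[1L, ]; jj <- pr[2L, ]
  }
  cnt <- pair_genotype_counts(sub$geno, ii, jj)
  br <- burrows_r2_counts(cnt)
  ok <- !is.na(br$r2) & br$n >= 2L
  if (!any(ok)) stop("no informative locus pairs")
  w <- br$n[ok]
  mean_r2 <- sum(br$r2[ok] * w) / sum(w)
  harm_s <- length(w) / sum(1 / w)
  floor_r2 <- r2_sampling_floor(harm_s, small_sample)
  rd <- mean_r2 - floor_r2
  structure(list(ne_hat = ne_from_r2drift(rd, small_sample),
                 mean_r2 = mean_r2, r2_drift = rd,
                 expected_r2_floor = floor_r2, n_pairs = sum(ok),
                 harmonic_s = harm_s, pcrit = pcrit, pairs = pairs),
            class = "ne_estimate")
}

#' @method print ne_estimate
#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf(
    "LD-based Ne: %s  (mean r2 = %.5f, drift r2 = %.5f, %d pairs, S = %.1f)\n",
    if (is.infinite(x$ne_hat)) "infinite" else sprintf("%.1f", x$ne_hat),
    x$mean_r2, x$r2_drift, x$n_pairs, x$harmonic_s))
  invisible(x)
}
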