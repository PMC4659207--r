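#' Expected heterozygosity of a biallelic locus
#'
#' Gene diversity: one minus the sum of squared allele frequencies,
#' He = 2p(1-p) for a biallelic SNP.
#'
#' @param p allele frequency (vectorized), in [0, 1].
#' @return He in [0, 0.5].
#' @export
expected_het <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  2 * p * (1 - p)
}

#' Per-population heterozygosity and polymorphism summary
#'
#' For each population, expected heterozygosity He = 2p(1-p) and observed
#' heterozygosity Ho (fraction of heterozygous calls) are computed per SNP
#' from within-population frequencies (complete-case) and averaged over SNPs.
#' The percent of polymorphic SNPs counts SNPs at which both alleles are
#' observed in that population.
#'
#' @param panel a [genopanel].
#' @return data.frame with one row per population: `population`, `n`, `he`,
#'   `ho`, `pct_polymorphic`.
#' @export
population_diversity <- function(panel) {
  stopifnot(inherits(panel, "genopanel"))
  pops <- levels(panel$pop)
  rows <- lapply(pops, function(pp) {
    idx <- panel$pop == pp
    if (sum(idx) < 2L) stop("population ", pp, " has <2 individuals")
    g <- panel$geno[idx, , drop = FALSE]
    p <- colMeans(g, na.rm = TRUE) / 2
    ok <- !is.nan(p)
    he <- expected_het(p[ok])
    ho <- colMeans(g[, ok, drop = FALSE] == 1L, na.rm = TRUE)
    data.frame(population = pp, n = sum(idx),
               he = mean(he), ho = mean(ho, na.rm = TRUE),
               pct_polymorphic = 100 * mean(p[ok] > 0 & p[ok] < 1))
  })
  do.call(rbind, rows)
}

#' Pairwise FST between two populations
#'
#' Weighted Nei-style estimator: per SNP, the pooled frequency is the
#' sample-size weighted mean of the two population frequencies,
#' HT = 2*pbar*(1-pbar) and HS the weighted mean of the within-population
#' expected heterozygosities. HS and HT are averaged over loci first and
#' FST = (HT - HS) / HT ("ratio of averages"). SNPs monomorphic in the pooled
#' pair carry no information (0/0) and are excluded from both averages.
#'
#' @param panel a [genopanel].
#' @param pop_a,pop_b population labels.
#' @return FST in [0, 1]; 0 (with a warning) when both populations are fixed
#'   everywhere.
#' @export
pairwise_fst <- function(panel, pop_a, pop_b) {
  stopifnot(inherits(panel, "genopanel"))
  ia <- panel$pop == pop_a
  ib <- panel$pop == pop_b
  if (!any(ia)) stop("population not found: ", pop_a)
  if (!any(ib)) stop("population not found: ", pop_b)
  ga <- panel$geno[ia, , drop = FALSE]
  gb <- panel$geno[ib, , drop = FALSE]
  na <- colSums(!is.na(ga)); nb <- colSums(!is.na(gb))
  pa <- colMeans(ga, na.rm = TRUE) / 2
  pb <- colMeans(gb, na.rm = TRUE) / 2
  ok <- na > 0L & nb > 0L
  na <- na[ok]; nb <- nb[ok]; pa <- pa[ok]; pb <- pb[ok]
  pbar <- (na * pa + nb * pb) / (na + nb)
  ht <- expected_het(pbar)
  hs <- (na * expected_het(pa) + nb * expected_het(pb)) / (na + nb)
  poly <- ht > 0                       # pooled-monomorphic SNPs excluded
  if (!any(poly)) {
    warning("populations fixed and identical at every SNP; FST set to 0")
    return(0)
  }
  HT <- mean(ht[poly]); HS <- mean(hs[poly])
  (HT - HS) / HT
}

#' All pairwise FST values
#'
#' @param panel a [genopanel].
#' @return Symmetric population x population matrix, diagonal 0.
#' @export
fst_matrix <- function(panel) {
  pops <- levels(panel$pop)
  k <- length(pops)
  out <- matrix(0, k, k, dimnames = list(pops, pops))
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      out[i, j] <- out[j, i] <- pairwise_fst(panel, pops[i], pops[j])
    }
  }
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = ZZ' / (2 * sum p_k (1 - p_k)) with Z the dosage matrix centered at
#' twice the allele frequency. Frequencies default to the pooled cohort so
#' that all populations share one relationship space; missing dosages are
#' centered to zero (i.e. imputed at the mean 2p). Monomorphic SNPs
#' contribute nothing to Z and are dropped from the denominator.
#'
#' @param panel a [genopanel] (or plain dosage matrix).
#' @param freqs optional per-SNP allele frequencies to center/scale with.
#' @return n x n symmetric matrix with sample ids as dimnames.
#' @export
grm <- function(panel, freqs = NULL) {
  g <- if (inherits(panel, "genopanel")) panel$geno else panel
  stopifnot(nrow(g) >= 2L)
  p <- if (is.null(freqs)) colMeans(g, na.rm = TRUE) / 2 else freqs
  poly <- !is.nan(p) & p > 0 & p < 1
  if (!any(poly)) stop("all SNPs monomorphic: GRM denominator is zero")
  g <- g[, poly, drop = FALSE]; p <- p[poly]
  z <- sweep(g, 2L, 2 * p)
  z[is.na(z)] <- 0
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(z) / denom
  dimnames(G) <- list(rownames(g), rownames(g))
  G
}

#' Principal components of a genomic relationship matrix
#'
#' Eigendecomposition of the GRM; scores are eigenvectors scaled by the
#' square root of their eigenvalues, and variance-explained fractions use
#' eigenvalues floored at zero (small negative eigenvalues can arise
#' numerically).
#'
#' @param G a GRM from [grm()].
#' @param k number of components to return (truncated to n).
#' @return List with `scores` (n x k), `eigenvalues` (all n, non-increasing),
#'   `var_explained` (length k fractions).
#' @export
grm_pca <- function(G, k = 2L) {
  stopifnot(nrow(G) >= 3L, k >= 1L)
  k <- min(k, nrow(G))
  e <- eigen(G, symmetric = TRUE)
  lam <- e$values
  pos <- pmax(lam, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(k)]), k, k)
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, eigenvalues = lam,
       var_explained = pos[seq_len(k)] / sum(pos))
}
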