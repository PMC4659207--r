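#' QC thresholds
#'
#' Default thresholds reproduce a standard SNP-array cleaning recipe for
#' diversity studies: SNP call rate >= 0.95, GC score >= 0.6 (only when a
#' per-SNP GC column is available), MAF >= 0.01, exact Hardy-Weinberg
#' p >= 1e-15, and per-SNP heterozygosity within 3 SD of the panel mean. The
#' individual call-rate filter defaults to report-only (threshold 0).
#'
#' @param min_snp_call_rate minimum fraction of non-missing calls per SNP.
#' @param min_gc minimum Illumina GenCall score, applied only if GC scores
#'   are supplied.
#' @param min_maf minimum minor allele frequency (pooled cohort).
#' @param hwe_p_cutoff SNPs with exact HWE p-value below this are removed.
#' @param het_sd_limit per-SNP heterozygosity outlier limit, in SD units.
#' @param min_ind_call_rate minimum per-individual call rate; 0 = report only.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_snp_call_rate = 0.95, min_gc = 0.6,
                      min_maf = 0.01, hwe_p_cutoff = 1e-15,
                      het_sd_limit = 3, min_ind_call_rate = 0) {
  stopifnot(min_snp_call_rate >= 0, min_snp_call_rate <= 1,
            min_gc >= 0, min_gc <= 1, min_maf >= 0, min_maf <= 0.5,
            hwe_p_cutoff >= 0, hwe_p_cutoff <= 1, het_sd_limit > 0,
            min_ind_call_rate >= 0, min_ind_call_rate <= 1)
  structure(list(min_snp_call_rate = min_snp_call_rate, min_gc = min_gc,
                 min_maf = min_maf, hwe_p_cutoff = hwe_p_cutoff,
                 het_sd_limit = het_sd_limit,
                 min_ind_call_rate = min_ind_call_rate),
            class = "qc_config")
}

#' Per-SNP call rate
#'
#' @param geno dosage matrix (individuals x SNPs) or [genopanel].
#' @return Numeric vector, fraction of non-missing calls per SNP.
#' @export
snp_call_rate <- function(geno) {
  g <- if (inherits(geno, "genopanel")) geno$geno else geno
  colMeans(!is.na(g))
}

#' Per-individual call rate
#'
#' @inheritParams snp_call_rate
#' @return Numeric vector, fraction of non-missing calls per individual.
#' @export
sample_call_rate <- function(geno) {
  g <- if (inherits(geno, "genopanel")) geno$geno else geno
  rowMeans(!is.na(g))
}

#' B-allele frequency per SNP
#'
#' @inheritParams snp_call_rate
#' @param subset optional individual (row) subset.
#' @return Numeric vector p = mean dosage / 2 over non-missing calls; `NaN`
#'   for all-missing SNPs.
#' @export
allele_frequency <- function(geno, subset = NULL) {
  g <- if (inherits(geno, "genopanel")) geno$geno else geno
  if (!is.null(subset)) g <- g[subset, , drop = FALSE]
  colMeans(g, na.rm = TRUE) / 2
}

#' Minor allele frequency per SNP
#'
#' @inheritParams allele_frequency
#' @return Numeric vector min(p, 1-p) in [0, 0.5]; `NaN` where all calls are
#'   missing.
#' @export
minor_allele_frequency <- function(geno, subset = NULL) {
  p <- allele_frequency(geno, subset)
  pmin(p, 1 - p)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value sums the probabilities of all heterozygote counts (same parity,
#' fixed margins) whose conditional probability does not exceed that of the
#' observed count. Monomorphic SNPs return p = 1 by convention. A chi-square
#' approximation is useless at cutoffs like 1e-15, hence the exact
#' construction; probabilities are computed through a log-space recurrence so
#' the tails stay accurate at array scale.
#'
#' @param n_aa,n_ab,n_bb genotype counts (vectors recycle elementwise).
#' @return Numeric vector of p-values in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- max(length(n_aa), length(n_ab), length(n_bb))
  n_aa <- rep_len(as.integer(n_aa), n)
  n_ab <- rep_len(as.integer(n_ab), n)
  n_bb <- rep_len(as.integer(n_bb), n)
  stopifnot(all(n_aa >= 0), all(n_ab >= 0), all(n_bb >= 0),
            all(n_aa + n_ab + n_bb > 0))
  vapply(seq_len(n), function(i) hwe_exact_one(n_aa[i], n_ab[i], n_bb[i]),
         numeric(1))
}

hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2L * n_aa + n_ab          # rarer-or-not does not matter: symmetric
  n_b <- 2L * n_bb + n_ab
  if (n_a == 0L || n_b == 0L) return(1)
  n_min <- min(n_a, n_b)
  hets <- seq.int(n_min %% 2L, n_min, by = 2L)
  # log P(het = h | margins) up to a constant:
  #   P(h) ∝ n_a! n_b! / ((n_a-h)/2)! ((n_b-h)/2)! h!  * 2^h
  lp <- h_logprob(hets, n_a, n_b)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  p <- sum(pr[pr <= obs + 1e-12 * obs])
  min(p, 1)
}

h_logprob <- function(h, n_a, n_b) {
  h * log(2) - lgamma((n_a - h) / 2 + 1) - lgamma((n_b - h) / 2 + 1) -
    lgamma(h + 1)
}

#' Exact HWE p-values for every SNP in a panel
#'
#' @inheritParams snp_call_rate
#' @return Numeric vector of p-values (pooled genotype counts per SNP).
#' @export
hwe_pvalues <- function(geno) {
  g <- if (inherits(geno, "genopanel")) geno$geno else geno
  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  out <- rep(1, ncol(g))
  ok <- n0 + n1 + n2 > 0L
  out[ok] <- hwe_exact_test(n0[ok], n1[ok], n2[ok])
  out
}

#' Flag SNPs with outlying heterozygosity
#'
#' A SNP is flagged when its observed heterozygosity (fraction of het calls,
#' pooled across all samples) lies more than `het_sd_limit` standard
#' deviations from the panel mean. With zero dispersion no SNP is flagged.
#'
#' @inheritParams snp_call_rate
#' @param het_sd_limit SD multiple.
#' @return Logical vector per SNP.
#' @export
het_outlier_flags <- function(geno, het_sd_limit = 3) {
  g <- if (inherits(geno, "genopanel")) geno$geno else geno
  stopifnot(ncol(g) >= 2L)
  ho <- colMeans(g == 1L, na.rm = TRUE)
  mu <- mean(ho, na.rm = TRUE)
  s <- stats::sd(ho, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(FALSE, ncol(g)))
  out <- abs(ho - mu) > het_sd_limit * s
  out & !is.na(out)
}

#' Apply the SNP quality-control cascade
#'
#' Filters are applied in a fixed order and each removed SNP is attributed to
#' the first rule it fails, so the per-reason counts are mutually exclusive
#' and sum (with the survivors) to the input SNP count:
#' non-autosomal, unmapped, low GC score (if supplied), low call rate, low
#' MAF, HWE deviation, heterozygosity outlier. MAF and HWE are computed on
#' the pooled cohort by default — the analyses downstream share one SNP set
#' across populations.
#'
#' @param panel a [genopanel].
#' @param config a [qc_config()].
#' @param gc_scores optional numeric vector in [0,1], one per SNP.
#' @param autosomes chromosome labels treated as autosomes; defaults to
#'   "1".."26" (the sheep karyotype).
#' @return A list with `panel` (filtered), `report` (data.frame of removal
#'   counts by reason), `surviving` (logical per input SNP), and
#'   `ind_call_rate` (per-individual call rates, report-only unless
#'   `min_ind_call_rate` > 0, in which case failing individuals are dropped
#'   before SNP filters).
#' @export
apply_qc <- function(panel, config = qc_config(), gc_scores = NULL,
                     autosomes = as.character(1:26)) {
  stopifnot(inherits(panel, "genopanel"))
  g <- panel$geno
  map <- panel$map
  m <- ncol(g)
  icr <- sample_call_rate(g)
  if (config$min_ind_call_rate > 0) {
    keep_ind <- icr >= config$min_ind_call_rate
    g <- g[keep_ind, , drop = FALSE]
    panel <- genopanel(g, map, panel$pop[keep_ind])
  }

  reason <- rep(NA_character_, m)
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  flag(!(as.character(map$chrom) %in% autosomes), "non_autosomal")
  flag(is.na(map$pos_bp) | map$pos_bp < 1L, "unmapped")
  if (!is.null(gc_scores)) {
    stopifnot(length(gc_scores) == m)
    flag(!is.na(gc_scores) & gc_scores < config$min_gc, "low_gc")
  }
  flag(snp_call_rate(g) < config$min_snp_call_rate, "low_call_rate")
  maf <- minor_allele_frequency(g)
  flag(is.nan(maf) | maf < config$min_maf, "low_maf")
  hw <- hwe_pvalues(g)
  flag(hw < config$hwe_p_cutoff, "hwe")
  flag(het_outlier_flags(g, config$het_sd_limit), "het_outlier")

  surviving <- is.na(reason)
  if (!any(surviving))
    stop("all SNPs removed by QC; review thresholds")
  reasons <- c("non_autosomal", "unmapped", "low_gc", "low_call_rate",
               "low_maf", "hwe", "het_outlier")
  report <- data.frame(
    reason = c(reasons, "surviving"),
    n_snps = c(vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                      integer(1)),
               sum(surviving)))
  list(panel = panel[, surviving], report = report, surviving = surviving,
       ind_call_rate = icr)
}
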