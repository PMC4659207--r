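#' Marker-based inbreeding coefficients F1, F2, F3
#'
#' Three per-individual estimators averaged over SNPs, each zero in
#' expectation under Hardy-Weinberg equilibrium (x = B-allele dosage, p =
#' within-population B-allele frequency, q = 1 - p):
#' \itemize{
#'   \item F1, from the variance of the additive genotype:
#'     t1 = (x - 2p)^2 / (2pq) - 1;
#'   \item F2, from the excess of homozygotes:
#'     t2 = 1 - x(2 - x) / (2pq) (a fully homozygous individual has F2 = 1
#'     exactly, since x(2 - x) = 0);
#'   \item F3, the correlation between uniting gametes:
#'     t3 = (x^2 - (1 + 2p)x + 2p^2) / (2pq).
#' }
#' Frequencies are computed within each population: this is what makes F1
#' crosses of diverged parents come out negative (excess heterozygosity
#' relative to their own gene pool). SNPs monomorphic within a population
#' are skipped and counted.
#'
#' @param panel a [genopanel].
#' @param f2_form `"mean_of_ratios"` (default; per-SNP terms averaged with
#'   equal weight) or `"ratio_of_means"` (sum of numerators over sum of
#'   denominators) for F2 — tools differ in this convention.
#' @return data.frame per individual: `individual`, `population`, `f1`,
#'   `f2`, `f3`, `n_snps_used`; attribute `n_monomorphic` gives per-population
#'   skipped-SNP counts.
#' @export
f_coefficients <- function(panel,
                           f2_form = c("mean_of_ratios", "ratio_of_means")) {
  stopifnot(inherits(panel, "genopanel"))
  f2_form <- match.arg(f2_form)
  out <- list(); skipped <- integer(0)
  for (pp in levels(panel$pop)) {
    idx <- which(panel$pop == pp)
    if (length(idx) < 2L) stop("population ", pp, " has <2 individuals")
    g <- panel$geno[idx, , drop = FALSE]
    p <- colMeans(g, na.rm = TRUE) / 2
    poly <- !is.nan(p) & p > 0 & p < 1
    skipped[pp] <- sum(!poly)
    g <- g[, poly, drop = FALSE]
    p <- p[poly]
    tpq <- 2 * p * (1 - p)
    x <- g                                # n_idx x m, NA = missing
    t1 <- sweep(sweep(x, 2L, 2 * p)^2, 2L, tpq, "/") - 1
    t2 <- 1 - sweep(x * (2 - x), 2L, tpq, "/")
    t3 <- sweep(x^2 - x * matrix(1 + 2 * p, nrow(x), ncol(x), byrow = TRUE) +
                  matrix(2 * p^2, nrow(x), ncol(x), byrow = TRUE),
                2L, tpq, "/")
    f1 <- rowMeans(t1, na.rm = TRUE)
    f3 <- rowMeans(t3, na.rm = TRUE)
    f2 <- if (f2_form == "mean_of_ratios") {
      rowMeans(t2, na.rm = TRUE)
    } else {
      num <- rowSums(x * (2 - x), na.rm = TRUE)
      den <- (!is.na(x)) %*% tpq
      1 - num / as.vector(den)
    }
    out[[pp]] <- data.frame(individual = rownames(panel$geno)[idx],
                            population = pp, f1 = f1, f2 = f2, f3 = f3,
                            n_snps_used = rowSums(!is.na(x)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_monomorphic") <- skipped
  res
}

#' Percentage of individuals above an inbreeding threshold
#'
#' @param fc data.frame from [f_coefficients()].
#' @param threshold critical F value (default 0.065).
#' @return data.frame per population: mean F1/F2/F3 and the percentage of
#'   individuals with each F above the threshold.
#' @export
critical_percentage <- function(fc, threshold = 0.065) {
  rows <- lapply(split(fc, fc$population), function(d) {
    data.frame(population = d$population[1L], n = nrow(d),
               mean_f1 = mean(d$f1), mean_f2 = mean(d$f2),
               mean_f3 = mean(d$f3),
               crit_f1 = 100 * mean(d$f1 > threshold),
               crit_f2 = 100 * mean(d$f2 > threshold),
               crit_f3 = 100 * mean(d$f3 > threshold))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
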