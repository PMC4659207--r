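#' Classify a SNP pair from its D-prime confidence bounds
#'
#' Gabriel-style rule: "strong LD" when the upper one-sided 95\% bound on D'
#' reaches 0.98 and the lower bound 0.70; "strong evidence of historical
#' recombination" when the upper bound stays below 0.90; anything else is
#' uninformative.
#'
#' @param ci_low,ci_high D-prime bounds (vectors recycle).
#' @return Character vector: "STRONG_LD", "RECOMBINATION" or "UNINFORMATIVE".
#' @export
classify_pair <- function(ci_low, ci_high) {
  out <- rep("UNINFORMATIVE", max(length(ci_low), length(ci_high)))
  out[ci_high >= 0.98 & ci_low >= 0.70] <- "STRONG_LD"
  out[ci_high < 0.90] <- "RECOMBINATION"
  out
}

# classify all within-chromosome pairs up to max span; returns the ld_pairs
# data.frame with a `class` column
classified_pairs <- function(sub, max_span_bp) {
  pr <- syntenic_pairs(sub$map, max_span_bp)
  if (length(pr$i) == 0L) {
    out <- ld_pairs(sub, integer(0), integer(0))
    out$ci_low <- numeric(0); out$ci_high <- numeric(0)
    out$class <- character(0)
    return(out)
  }
  ld <- ld_pairs(sub, pr$i, pr$j, ci = TRUE)
  ld$class <- classify_pair(ld$ci_low, ld$ci_high)
  ld$class[is.na(ld$r2)] <- "UNINFORMATIVE"
  ld
}

#' Find Gabriel-style haplotype blocks in one population
#'
#' Candidate blocks are SNP intervals whose outermost pair is in strong LD,
#' that span at most `max_span_kb`, and in which at least 95\% of the
#' informative pairs (strong LD or recombination; uninformative pairs are
#' excluded from the denominator) are strong. Candidates are accepted
#' greedily by decreasing physical length, discarding any that overlap an
#' accepted block. A two-SNP candidate is its own outermost pair, so it is
#' accepted only when that single pair is strong.
#'
#' @param panel a [genopanel] (QC-passed).
#' @param population population label.
#' @param max_span_kb maximum block span in kb (default 500, the Haploview
#'   cap, which is why maximum block lengths in dense panels sit just under
#'   500 kb).
#' @param strong_ci_low,strong_ci_high,recomb_ci_high classification
#'   thresholds, see [classify_pair()].
#' @param informative_frac minimum fraction of informative pairs that must
#'   be strong (default 0.95).
#' @return data.frame of blocks: `chrom`, `first_snp`, `last_snp` (ids),
#'   `start_bp`, `end_bp`, `n_snps`, `length_bp`; zero rows when no blocks.
#' @export
find_blocks <- function(panel, population, max_span_kb = 500,
                        strong_ci_low = 0.70, strong_ci_high = 0.98,
                        recomb_ci_high = 0.90, informative_frac = 0.95) {
  sub <- population_subpanel(panel, population)
  ord <- map_order(sub$map)
  sub <- sub[, ord]
  cp <- classified_pairs(sub, max_span_bp = max_span_kb * 1000)
  if (!identical(c(strong_ci_low, strong_ci_high, recomb_ci_high),
                 c(0.70, 0.98, 0.90))) {
    cp$class <- rep("UNINFORMATIVE", nrow(cp))
    cp$class[cp$ci_high >= strong_ci_high &
               cp$ci_low >= strong_ci_low] <- "STRONG_LD"
    cp$class[cp$ci_high < recomb_ci_high] <- "RECOMBINATION"
    cp$class[is.na(cp$r2)] <- "UNINFORMATIVE"
  }
  empty <- data.frame(chrom = character(), first_snp = character(),
                      last_snp = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      length_bp = integer())
  if (nrow(cp) == 0L) return(empty)

  map <- sub$map
  pos <- map$pos_bp
  chrom <- as.character(map$chrom)
  # pair lookup per chromosome via a dense class matrix (within-span only)
  blocks <- list(); bk <- 0L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    mc <- length(idx)
    if (mc < 2L) next
    local_i <- match(cp$i, idx); local_j <- match(cp$j, idx)
    sel <- !is.na(local_i) & !is.na(local_j)
    cls <- matrix(NA_character_, mc, mc)
    cls[cbind(local_i[sel], local_j[sel])] <- cp$class[sel]

    # enumerate candidates: outer pair strong & span within cap
    cand <- which(cls == "STRONG_LD", arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    span <- pos[idx[cand[, 2L]]] - pos[idx[cand[, 1L]]]
    cand <- cand[span <= max_span_kb * 1000, , drop = FALSE]
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      a <- cand[k, 1L]; b <- cand[k, 2L]
      inner <- cls[a:b, a:b]
      inner <- inner[upper.tri(inner)]
      informative <- sum(inner %in% c("STRONG_LD", "RECOMBINATION"),
                         na.rm = TRUE)
      strong <- sum(inner == "STRONG_LD", na.rm = TRUE)
      keep[k] <- informative > 0L && strong / informative >= informative_frac
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) next
    len <- pos[idx[cand[, 2L]]] - pos[idx[cand[, 1L]]]
    ord_c <- order(-len, cand[, 1L])
    taken <- rep(FALSE, mc)
    for (k in ord_c) {
      a <- cand[k, 1L]; b <- cand[k, 2L]
      if (any(taken[a:b])) next
      taken[a:b] <- TRUE
      bk <- bk + 1L
      blocks[[bk]] <- data.frame(
        chrom = ch, first_snp = map$snp_id[idx[a]],
        last_snp = map$snp_id[idx[b]],
        start_bp = pos[idx[a]], end_bp = pos[idx[b]],
        n_snps = b - a + 1L, length_bp = pos[idx[b]] - pos[idx[a]])
    }
  }
  if (bk == 0L) return(empty)
  out <- do.call(rbind, blocks)
  out[order(chrom_rank(out$chrom), out$start_bp), , drop = FALSE]
}

#' Summarise haplotype blocks
#'
#' Aggregates a block set the way breed comparisons are usually tabled:
#' block count, total and percent genome length in blocks, mean / median /
#' min / max block length, total and percent SNPs inside blocks, and the
#' range of SNPs per block.
#'
#' @param blocks data.frame from [find_blocks()].
#' @param map the SNP map the blocks refer to.
#' @param chrom_lengths_bp named vector of chromosome lengths in bp;
#'   defaults to the largest mapped position per chromosome.
#' @return One-row data.frame of summary statistics.
#' @export
block_summary <- function(blocks, map, chrom_lengths_bp = NULL) {
  if (is.null(chrom_lengths_bp)) chrom_lengths_bp <- map_chrom_lengths(map)
  genome_bp <- sum(chrom_lengths_bp)
  n_snps_total <- nrow(map)
  if (nrow(blocks) == 0L)
    return(data.frame(n_blocks = 0L, total_length_mb = 0,
                      pct_genome = 0, mean_length_kb = NA_real_,
                      median_length_kb = NA_real_, min_length_kb = NA_real_,
                      max_length_kb = NA_real_, n_snps_in_blocks = 0L,
                      pct_snps_in_blocks = 0, min_snps_per_block = NA_integer_,
                      max_snps_per_block = NA_integer_))
  data.frame(
    n_blocks = nrow(blocks),
    total_length_mb = sum(blocks$length_bp) / 1e6,
    pct_genome = 100 * sum(blocks$length_bp) / genome_bp,
    mean_length_kb = mean(blocks$length_bp) / 1e3,
    median_length_kb = stats::median(blocks$length_bp) / 1e3,
    min_length_kb = min(blocks$length_bp) / 1e3,
    max_length_kb = max(blocks$length_bp) / 1e3,
    n_snps_in_blocks = sum(blocks$n_snps),
    pct_snps_in_blocks = 100 * sum(blocks$n_snps) / n_snps_total,
    min_snps_per_block = min(blocks$n_snps),
    max_snps_per_block = max(blocks$n_snps))
}
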