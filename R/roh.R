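#' ROH detection parameters
#'
#' Defaults follow a PLINK v1.07-style sliding-window screen parameterized in
#' kb: windows of consecutive SNPs spanning at most 1000 kb, at most two
#' missing and one heterozygous call per window, a per-SNP homozygous-window
#' hit threshold of 0.05, candidate runs split at inter-SNP gaps over 250 kb,
#' and segments shorter than 500 kb discarded. `alpha` is the genome-wide
#' false-positive allowance used by [min_roh_snps()].
#'
#' @param window_span_kb maximum physical span of a sliding window.
#' @param max_missing_per_window,max_het_per_window tolerated calls/window.
#' @param min_length_kb minimum segment length retained.
#' @param max_gap_kb maximum gap between consecutive SNPs inside a segment.
#' @param alpha false-positive allowance for the minimum-SNP rule.
#' @param window_hit_threshold minimum fraction of homozygous windows
#'   overlapping a SNP for it to be ROH-eligible.
#' @return List of class `roh_params`.
#' @export
roh_params <- function(window_span_kb = 1000, max_missing_per_window = 2,
                       max_het_per_window = 1, min_length_kb = 500,
                       max_gap_kb = 250, alpha = 0.05,
                       window_hit_threshold = 0.05) {
  stopifnot(window_span_kb > 0, max_missing_per_window >= 0,
            max_het_per_window >= 0, min_length_kb > 0, max_gap_kb > 0,
            alpha > 0, alpha < 1, window_hit_threshold > 0,
            window_hit_threshold <= 1)
  structure(as.list(environment()), class = "roh_params")
}

#' Minimum number of SNPs in a credible ROH
#'
#' False-positive bound on run length: with `n_s` SNPs per individual, `n_i`
#' individuals, mean per-SNP heterozygosity `het` and allowance `alpha`, the
#' minimum SNP count is
#' l = ceiling( ln(alpha / (n_s * n_i)) / ln(1 - het) ),
#' i.e. the run length at which a chance all-homozygous stretch is expected
#' fewer than `alpha` times in the whole dataset. The ceiling makes the
#' count integral.
#'
#' @param n_s number of genotyped SNPs per individual.
#' @param n_i number of individuals.
#' @param alpha false-positive allowance.
#' @param het mean observed per-SNP heterozygosity across all SNPs.
#' @return Integer `l` (0, with a warning, when alpha >= n_s * n_i).
#' @export
min_roh_snps <- function(n_s, n_i, alpha = 0.05, het) {
  stopifnot(n_s >= 1, n_i >= 1, alpha > 0, het >= 0, het < 1)
  if (het == 0) stop("het = 0: minimum-SNP formula undefined")
  if (alpha >= n_s * n_i) {
    warning("alpha >= n_s * n_i: minimum SNP count is 0")
    return(0L)
  }
  as.integer(ceiling(log(alpha / (n_s * n_i)) / log(1 - het)))
}

# per-chromosome eligibility + runs for one individual's dosage vector
detect_roh_chrom <- function(g, pos, params, l) {
  m <- length(g)
  if (m == 0L) return(NULL)
  span_bp <- params$window_span_kb * 1000
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  # window starting at s covers SNPs s..e(s), the largest run within span
  e <- findInterval(pos + span_bp, pos)
  ch <- cumsum(c(0L, het)); cm <- cumsum(c(0L, mis))
  n_het <- ch[e + 1L] - ch[seq_len(m)]
  n_mis <- cm[e + 1L] - cm[seq_len(m)]
  hom_win <- n_het <= params$max_het_per_window &
    n_mis <= params$max_missing_per_window
  # SNP k is covered by windows s with s <= k <= e(s): difference arrays
  # (+1 at s, -1 past e(s)) turned into running sums
  cover <- cumsum(rep(1L, m) - tabulate(e[e < m] + 1L, m))
  hits <- cumsum(as.integer(hom_win) -
                   tabulate(e[hom_win & e < m] + 1L, m))
  eligible <- hits / cover >= params$window_hit_threshold

  # maximal runs of eligible SNPs, split at long gaps
  if (!any(eligible)) return(NULL)
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list(); k <- 0L
  for (q in which(r$values)) {
    a <- starts[q]; b <- ends[q]
    if (b > a) {
      gaps <- diff(pos[a:b])
      cut_after <- which(gaps > params$max_gap_kb * 1000)
      bounds <- c(a - 1L, a - 1L + cut_after, b)
    } else bounds <- c(a - 1L, b)
    for (t in seq_len(length(bounds) - 1L)) {
      s1 <- bounds[t] + 1L; s2 <- bounds[t + 1L]
      n_snps <- s2 - s1 + 1L
      len <- pos[s2] - pos[s1]
      if (n_snps >= l && len >= params$min_length_kb * 1000) {
        k <- k + 1L
        segs[[k]] <- c(s1, s2, n_snps, len)
      }
    }
  }
  if (k == 0L) return(NULL)
  do.call(rbind, segs)
}

#' Detect runs of homozygosity
#'
#' Sliding-window ROH screen for every individual in the panel. Windows of
#' consecutive SNPs spanning at most the window span slide one SNP at a time;
#' a window is "homozygous" when it has at most the allowed heterozygous and
#' missing calls. Each SNP's hit fraction is the proportion of windows
#' containing it that are homozygous; SNPs at or above the hit threshold are
#' ROH-eligible. Maximal runs of eligible SNPs are split at gaps larger than
#' `max_gap_kb` and kept when they contain at least `l` SNPs and span at
#' least `min_length_kb`.
#'
#' @param panel a [genopanel] (map-sorted internally).
#' @param params a [roh_params()].
#' @param l minimum SNP count, usually from [min_roh_snps()]; if `NULL` it is
#'   computed from the panel (whole cohort: n_s = SNPs, n_i = individuals,
#'   het = mean observed per-SNP heterozygosity).
#' @return data.frame of segments: `individual`, `population`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `length_bp`; attribute `l` records the
#'   minimum SNP count used.
#' @export
detect_roh <- function(panel, params = roh_params(), l = NULL) {
  stopifnot(inherits(panel, "genopanel"))
  ord <- map_order(panel$map)
  panel <- panel[, ord]
  if (is.null(l)) {
    het <- mean(colMeans(panel$geno == 1L, na.rm = TRUE), na.rm = TRUE)
    l <- min_roh_snps(ncol(panel$geno), nrow(panel$geno),
                      params$alpha, het)
  }
  map <- panel$map
  chroms <- unique(as.character(map$chrom))
  out <- list(); k <- 0L
  for (ind in seq_len(nrow(panel$geno))) {
    for (ch in chroms) {
      idx <- which(as.character(map$chrom) == ch)
      segs <- detect_roh_chrom(panel$geno[ind, idx], map$pos_bp[idx],
                               params, l)
      if (is.null(segs)) next
      k <- k + 1L
      out[[k]] <- data.frame(
        individual = rownames(panel$geno)[ind],
        population = as.character(panel$pop[ind]),
        chrom = ch,
        start_bp = map$pos_bp[idx][segs[, 1L]],
        end_bp = map$pos_bp[idx][segs[, 2L]],
        n_snps = segs[, 3L], length_bp = segs[, 4L])
    }
  }
  res <- if (k == 0L)
    data.frame(individual = character(), population = character(),
               chrom = character(), start_bp = integer(),
               end_bp = integer(), n_snps = integer(), length_bp = integer())
  else do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "l") <- l
  res
}

#' Sum of ROH per individual by length category
#'
#' Length categories are half-open Mb intervals [1,5), [5,10), [10,15),
#' [15,20), [20,25) and >=25 Mb; segments of 0.5-1 Mb count toward the total
#' but not toward any category. Per-population means average over all
#' individuals present in the segment table's panel.
#'
#' @param segments data.frame from [detect_roh()].
#' @param individuals optional data.frame (`individual`, `population`)
#'   enumerating every animal (so zero-ROH animals enter the means); defaults
#'   to the individuals present in `segments`.
#' @return List with `per_individual` (Mb sums per category + total) and
#'   `population_means`.
#' @export
roh_length_categories <- function(segments, individuals = NULL) {
  cats <- data.frame(label = c("1-5Mb", "5-10Mb", "10-15Mb", "15-20Mb",
                               "20-25Mb", ">25Mb"),
                     low = c(1, 5, 10, 15, 20, 25) * 1e6,
                     high = c(5, 10, 15, 20, 25, Inf) * 1e6)
  if (is.null(individuals))
    individuals <- unique(segments[, c("individual", "population")])
  per <- individuals
  for (cl in cats$label) per[[cl]] <- 0
  per$total_mb <- 0
  if (nrow(segments) > 0L) {
    ci <- findInterval(segments$length_bp, c(cats$low, Inf))
    for (r in seq_len(nrow(segments))) {
      w <- match(segments$individual[r], per$individual)
      per$total_mb[w] <- per$total_mb[w] + segments$length_bp[r] / 1e6
      if (ci[r] >= 1L)
        per[[cats$label[ci[r]]]][w] <-
          per[[cats$label[ci[r]]]][w] + segments$length_bp[r] / 1e6
    }
  }
  num <- c(cats$label, "total_mb")
  means <- do.call(rbind, lapply(split(per[num], per$population), colMeans))
  means <- data.frame(population = rownames(means), means,
                      check.names = FALSE, row.names = NULL)
  list(per_individual = per, population_means = means)
}

#' Per-SNP ROH incidence
#'
#' For each SNP, the number of individuals whose ROH segments cover its
#' position.
#'
#' @param segments data.frame from [detect_roh()].
#' @param map SNP map.
#' @return Integer vector, one count per map row.
#' @export
roh_incidence <- function(segments, map) {
  counts <- integer(nrow(map))
  if (nrow(segments) == 0L) return(counts)
  chrom <- as.character(map$chrom)
  for (r in seq_len(nrow(segments))) {
    hit <- chrom == as.character(segments$chrom[r]) &
      map$pos_bp >= segments$start_bp[r] &
      map$pos_bp <= segments$end_bp[r]
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

#' Per-chromosome ROH counts and coverage
#'
#' Coverage follows a two-step construction: the mean ROH length per
#' chromosome is the summed ROH length (Mb) divided by the number of animals
#' that have at least one ROH on that chromosome; the percentage is that mean
#' divided by the chromosome length. Chromosomes without ROH report 0 with a
#' flag.
#'
#' @param segments data.frame from [detect_roh()].
#' @param map SNP map (for the chromosome list).
#' @param chrom_lengths_bp named chromosome lengths in bp; defaults to map
#'   extent.
#' @return data.frame per chromosome: `n_roh`, `n_animals`, `mean_mb`,
#'   `pct_coverage`, `no_roh` flag.
#' @export
roh_chromosome_summary <- function(segments, map, chrom_lengths_bp = NULL) {
  if (is.null(chrom_lengths_bp)) chrom_lengths_bp <- map_chrom_lengths(map)
  chroms <- unique(as.character(map$chrom))
  rows <- lapply(chroms, function(ch) {
    sel <- segments[as.character(segments$chrom) == ch, , drop = FALSE]
    n_an <- length(unique(sel$individual))
    if (nrow(sel) == 0L)
      return(data.frame(chrom = ch, n_roh = 0L, n_animals = 0L,
                        mean_mb = 0, pct_coverage = 0, no_roh = TRUE))
    mean_mb <- sum(sel$length_bp) / 1e6 / n_an
    data.frame(chrom = ch, n_roh = nrow(sel), n_animals = n_an,
               mean_mb = mean_mb,
               pct_coverage = 100 * mean_mb / (chrom_lengths_bp[[ch]] / 1e6),
               no_roh = FALSE)
  })
  do.call(rbind, rows)
}
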