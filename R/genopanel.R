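#' Genotype panel container
#'
#' Bundles an individuals x SNPs dosage matrix, its SNP map, and per-sample
#' population labels into a light S3 object consumed by every analysis stage.
#'
#' Dosages count copies of `allele_b` (the B/ALT allele), take values 0, 1, 2,
#' and use `NA` for missing calls. All statistics in the package are
#' orientation-invariant, so the arbitrary strand of array data is harmless;
#' the orientation is recorded in the map so frequencies can be reported for
#' both alleles.
#'
#' @param geno integer matrix, individuals x SNPs, values in \{0, 1, 2, NA\};
#'   rownames are sample ids.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos_bp`, `allele_a`,
#'   `allele_b`; one row per column of `geno`, same order.
#' @param pop character or factor of per-sample population labels, length
#'   `nrow(geno)`.
#' @return An object of class `genopanel`: a list with elements `geno`, `map`,
#'   `pop` (factor).
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 2L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), NULL))
#' m <- data.frame(snp_id = c("snp1", "snp2"), chrom = c(1L, 1L),
#'                 pos_bp = c(100L, 200L), allele_a = "A", allele_b = "G")
#' genopanel(g, m, c("P1", "P1"))
#' @export
genopanel <- function(geno, map, pop) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(ncol(geno) == nrow(map), nrow(geno) == length(pop))
  required <- c("snp_id", "chrom", "pos_bp", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols) > 0L)
    stop("map lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp_id in map")
  bad <- geno[!is.na(geno)]
  if (length(bad) > 0L && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  colnames(geno) <- map$snp_id
  structure(list(geno = geno, map = map, pop = factor(pop)),
            class = "genopanel")
}

#' @method print genopanel
#' @export
print.genopanel <- function(x, ...) {
  cat(sprintf("genopanel: %d individuals x %d SNPs, %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  tab <- table(x$pop)
  cat("populations:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                            collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("missing rate: %.3f\n", miss))
  invisible(x)
}

#' @method dim genopanel
#' @export
dim.genopanel <- function(x) dim(x$geno)

#' Subset a genotype panel
#'
#' @param x a `genopanel`.
#' @param i individual (row) index; missing keeps all.
#' @param j SNP (column) index; missing keeps all.
#' @param ... ignored.
#' @return A `genopanel` restricted to the selected individuals and SNPs.
#' @export
`[.genopanel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  genopanel(x$geno[i, j, drop = FALSE], x$map[j, , drop = FALSE],
            x$pop[i])
}

#' Sort a SNP map by chromosome and position
#'
#' @param map SNP map data.frame.
#' @return Integer permutation ordering the map by chromosome then bp.
#' @keywords internal
map_order <- function(map) {
  order(chrom_rank(map$chrom), map$pos_bp)
}

# numeric-aware chromosome ordering ("1" < "2" < "10" < "X")
chrom_rank <- function(chrom) {
  ch <- as.character(chrom)
  num <- suppressWarnings(as.numeric(ch))
  r <- ifelse(is.na(num), Inf, num)
  rank(r, ties.method = "min") + match(ch, sort(unique(ch))) * 1e-9
}

#' Approximate lengths (Mb) of the 26 sheep autosomes
#'
#' Physical lengths of the Ovis aries autosomes (Oar_v3.1 assembly, rounded),
#' used as the default chromosome sizes by the breed simulator and by
#' percentage-coverage summaries when no explicit lengths are supplied.
#'
#' @format Named numeric vector of length 26 (names "1".."26"), in Mb.
#' @export
ovine_autosome_mb <- c(
  "1" = 275.61, "2" = 248.97, "3" = 224.28, "4" = 119.22, "5" = 107.84,
  "6" = 116.89, "7" = 100.01, "8" = 90.62, "9" = 94.58, "10" = 86.38,
  "11" = 62.17, "12" = 79.03, "13" = 82.95, "14" = 62.72, "15" = 80.26,
  "16" = 71.69, "17" = 72.25, "18" = 68.49, "19" = 60.45, "20" = 51.05,
  "21" = 50.07, "22" = 50.78, "23" = 62.28, "24" = 42.03, "25" = 45.37,
  "26" = 44.05)

#' Chromosome lengths implied by a SNP map
#'
#' @param map SNP map data.frame.
#' @return Named numeric vector: per chromosome, the largest mapped position
#'   in bp (a lower bound on the physical length).
#' @export
map_chrom_lengths <- function(map) {
  vapply(split(map$pos_bp, as.character(map$chrom)), max, numeric(1))
}

# run expr with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}
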