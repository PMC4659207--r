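#' Demographic scenario for the breed-panel simulator
#'
#' Describes a multi-breed SNP-array study design: a common founder pool,
#' pure breeds drifting at their own effective sizes after the split
#' (optionally through a formation bottleneck), and F1-type crosses between
#' named populations (crosses may reference earlier crosses, e.g. a
#' three-way terminal cross). Sampled animals are an offspring cohort drawn
#' from the final generation, so samples can exceed Ne and naturally contain
#' half-sib families.
#'
#' @param chromosome_lengths_mb named numeric vector of chromosome lengths.
#' @param snps_per_mb average SNP density before ascertainment.
#' @param founder_ne diploid size of the founder pool.
#' @param split_generations generations from the split to the present.
#' @param breeds named list; each element a list with `ne` (post-split
#'   diploid size), optional `bottleneck_ne` and `bottleneck_gens` (applied
#'   at the start of the breed's history), and `n_sample`.
#' @param crosses named list; each element a list with `parents` (two
#'   population names, breeds or earlier crosses) and `n_sample`.
#' @param cm_per_mb genetic map scale (uniform).
#' @param maf_ascertainment pooled-MAF floor mimicking array design.
#' @param missing_rate per-call missing probability.
#' @param genotype_error_rate per-call probability of being replaced by one
#'   of the other two genotypes.
#' @param seed mandatory RNG seed; the whole panel is reproducible from it.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(chromosome_lengths_mb, snps_per_mb = 18,
                         founder_ne = 500, split_generations = 100,
                         breeds, crosses = list(), cm_per_mb = 1,
                         maf_ascertainment = 0.01, missing_rate = 0.02,
                         genotype_error_rate = 0.001, seed) {
  stopifnot(all(chromosome_lengths_mb > 0), snps_per_mb > 0,
            founder_ne >= 2, split_generations >= 1, length(breeds) >= 1,
            cm_per_mb >= 0, maf_ascertainment >= 0, missing_rate >= 0,
            missing_rate < 1, genotype_error_rate >= 0,
            genotype_error_rate < 1, !missing(seed))
  if (is.null(names(chromosome_lengths_mb)))
    names(chromosome_lengths_mb) <-
      as.character(seq_along(chromosome_lengths_mb))
  known <- names(breeds)
  for (cn in names(crosses)) {
    if (!all(crosses[[cn]]$parents %in% known))
      stop("cross ", cn, " references undefined population(s): ",
           paste(setdiff(crosses[[cn]]$parents, known), collapse = ", "))
    known <- c(known, cn)
  }
  structure(list(chromosome_lengths_mb = chromosome_lengths_mb,
                 snps_per_mb = snps_per_mb, founder_ne = founder_ne,
                 split_generations = split_generations, breeds = breeds,
                 crosses = crosses, cm_per_mb = cm_per_mb,
                 maf_ascertainment = maf_ascertainment,
                 missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate, seed = seed),
            class = "sim_scenario")
}

#' Five-population sheep-like scenario
#'
#' The study design the package's analyses were written around: three pure
#' breeds — one large and diverse (wool-type), two with breed-formation
#' bottlenecks (meat-type) — plus an F1 of the first two and a terminal
#' three-way cross. Defaults use the 26 sheep autosome lengths, ~55 kb SNP
#' spacing and the study's sample sizes; pass a subset of chromosomes and
#' smaller samples for desk-scale runs.
#'
#' @param chromosomes which autosomes to simulate (indices into
#'   [ovine_autosome_mb]).
#' @param snps_per_mb SNP density.
#' @param n_per_pop named or unnamed sample sizes for BL, PD, MER, MxB,
#'   MxBxP (recycled if length 1).
#' @param split_generations,founder_ne as in [sim_scenario()].
#' @param seed RNG seed.
#' @return A `sim_scenario`.
#' @export
sheep_scenario <- function(chromosomes = 1:26, snps_per_mb = 18,
                           n_per_pop = c(BL = 253, PD = 264, MER = 265,
                                         MxB = 260, MxBxP = 231),
                           split_generations = 100, founder_ne = 500,
                           seed = 17L) {
  n_per_pop <- rep_len(n_per_pop, 5L)
  if (is.null(names(n_per_pop)))
    names(n_per_pop) <- c("BL", "PD", "MER", "MxB", "MxBxP")
  sim_scenario(
    chromosome_lengths_mb = ovine_autosome_mb[chromosomes],
    snps_per_mb = snps_per_mb,
    founder_ne = founder_ne, split_generations = split_generations,
    breeds = list(
      BL = list(ne = 140, bottleneck_ne = 50, bottleneck_gens = 20,
                n_sample = n_per_pop[["BL"]]),
      PD = list(ne = 152, bottleneck_ne = 50, bottleneck_gens = 20,
                n_sample = n_per_pop[["PD"]]),
      MER = list(ne = 348, n_sample = n_per_pop[["MER"]])),
    crosses = list(
      MxB = list(parents = c("MER", "BL"), n_sample = n_per_pop[["MxB"]]),
      MxBxP = list(parents = c("MxB", "PD"),
                   n_sample = n_per_pop[["MxBxP"]])),
    seed = seed)
}

# one recombinant gamete per entry of `parents` for a single chromosome;
# hap: 2N x m (rows 2i-1, 2i belong to individual i)
make_gametes <- function(hap, parents, morgans, pos, len_bp) {
  n_g <- length(parents)
  m <- ncol(hap)
  gam <- matrix(0L, n_g, m)
  nx <- stats::rpois(n_g, morgans)
  phase <- sample.int(2L, n_g, replace = TRUE) - 1L   # 0 or 1
  simple <- nx == 0L
  if (any(simple))
    gam[simple, ] <- hap[2L * parents[simple] - 2L + 1L + phase[simple], ,
                         drop = FALSE]
  for (k in which(!simple)) {
    cx <- sort(stats::runif(nx[k], 0, len_bp))
    seg <- findInterval(pos, cx)
    use2 <- (seg + phase[k]) %% 2L == 1L
    h1 <- hap[2L * parents[k] - 1L, ]
    h2 <- hap[2L * parents[k], ]
    gam[k, ] <- ifelse(use2, h2, h1)
  }
  gam
}

# advance a whole-genome population state one generation (or produce an
# offspring cohort of arbitrary size)
next_generation <- function(state, n_offspring, geno_info) {
  n_par <- nrow(state[[1L]]) / 2L
  fathers <- sample.int(n_par, n_offspring, replace = TRUE)
  mothers <- sample.int(n_par, n_offspring, replace = TRUE)
  lapply(seq_along(state), function(ci) {
    gi <- geno_info[[ci]]
    gf <- make_gametes(state[[ci]], fathers, gi$morgans, gi$pos, gi$len_bp)
    gm <- make_gametes(state[[ci]], mothers, gi$morgans, gi$pos, gi$len_bp)
    out <- matrix(0L, 2L * n_offspring, ncol(gf))
    out[seq(1L, 2L * n_offspring, by = 2L), ] <- gf
    out[seq(2L, 2L * n_offspring, by = 2L), ] <- gm
    out
  })
}

haps_to_geno <- function(state) {
  do.call(cbind, lapply(state, function(h) {
    n <- nrow(h) / 2L
    h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  }))
}

#' Simulate a multi-breed SNP genotype panel
#'
#' Discrete-generation Wright-Fisher diploids with Poisson crossovers on a
#' uniform genetic map. Founder haplotypes are drawn at linkage equilibrium
#' from a neutral (1/p) site-frequency spectrum; LD then accrues through
#' drift along each breed's history (bottleneck, then post-split size).
#' Crosses sample one gamete from each named parent population. Sites are
#' ascertained on pooled MAF to mimic array design, then missingness and
#' genotype error are applied. Fully reproducible from the scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @return List with `panel` (a [genopanel]) and `truth` (nominal Ne per
#'   population, founder frequencies of the ascertained sites, SNP ids).
#' @export
simulate_panel <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed(scenario$seed, simulate_panel_impl(scenario))
}

simulate_panel_impl <- function(sc) {
  lens <- sc$chromosome_lengths_mb
  C <- length(lens)
  geno_info <- vector("list", C)
  founder_p <- vector("list", C)
  for (ci in seq_len(C)) {
    len_bp <- round(lens[ci] * 1e6)
    m <- max(2L, round(lens[ci] * sc$snps_per_mb))
    pos <- sort(sample.int(len_bp - 1L, m)) + 1L
    # neutral SFS: density proportional to 1/p on [0.01, 0.99]
    u <- stats::runif(m)
    p <- 0.01 * (0.99 / 0.01)^u
    founder_p[[ci]] <- p
    geno_info[[ci]] <- list(pos = pos, len_bp = len_bp,
                            morgans = lens[ci] * sc$cm_per_mb / 100)
  }
  founders <- lapply(seq_len(C), function(ci) {
    m <- length(founder_p[[ci]])
    matrix(stats::rbinom(2L * sc$founder_ne * m, 1L,
                         rep(founder_p[[ci]], each = 2L * sc$founder_ne)),
           nrow = 2L * sc$founder_ne, ncol = m)
  })

  pop_states <- list()   # final-generation states for gamete sampling
  samples <- list()      # sampled genotype matrices per population
  for (bn in names(sc$breeds)) {
    b <- sc$breeds[[bn]]
    bn_ne <- if (!is.null(b$bottleneck_ne)) b$bottleneck_ne else b$ne
    bn_gens <- if (!is.null(b$bottleneck_gens)) b$bottleneck_gens else 0L
    sizes <- c(rep(bn_ne, bn_gens),
               rep(b$ne, max(0L, sc$split_generations - bn_gens)))
    state <- founders
    for (g in sizes) state <- next_generation(state, g, geno_info)
    pop_states[[bn]] <- state
    cohort <- next_generation(state, b$n_sample, geno_info)
    samples[[bn]] <- haps_to_geno(cohort)
  }
  for (cn in names(sc$crosses)) {
    cr <- sc$crosses[[cn]]
    n <- cr$n_sample
    pa <- pop_states[[cr$parents[1L]]]
    pb <- pop_states[[cr$parents[2L]]]
    ia <- sample.int(nrow(pa[[1L]]) / 2L, n, replace = TRUE)
    ib <- sample.int(nrow(pb[[1L]]) / 2L, n, replace = TRUE)
    state <- lapply(seq_len(C), function(ci) {
      gi <- geno_info[[ci]]
      ga <- make_gametes(pa[[ci]], ia, gi$morgans, gi$pos, gi$len_bp)
      gb <- make_gametes(pb[[ci]], ib, gi$morgans, gi$pos, gi$len_bp)
      out <- matrix(0L, 2L * n, ncol(ga))
      out[seq(1L, 2L * n, by = 2L), ] <- ga
      out[seq(2L, 2L * n, by = 2L), ] <- gb
      out
    })
    pop_states[[cn]] <- state
    samples[[cn]] <- haps_to_geno(state)
  }

  geno <- do.call(rbind, samples)
  pop <- rep(names(samples), vapply(samples, nrow, integer(1)))
  rownames(geno) <- paste0(pop, "_", unlist(lapply(samples, function(s)
    seq_len(nrow(s)))))
  map <- do.call(rbind, lapply(seq_len(C), function(ci) {
    data.frame(snp_id = sprintf("snp%s_%d", names(lens)[ci],
                                seq_along(geno_info[[ci]]$pos)),
               chrom = names(lens)[ci], pos_bp = geno_info[[ci]]$pos,
               allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  }))

  # array-style ascertainment on pooled MAF
  pooled_p <- colMeans(geno) / 2
  keep <- pmin(pooled_p, 1 - pooled_p) >= sc$maf_ascertainment
  if (sum(keep) < 2L)
    stop("ascertainment left <2 SNPs; increase founder diversity, density, ",
         "or lower maf_ascertainment")
  geno <- geno[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]
  founder_keep <- unlist(founder_p)[keep]

  if (sc$genotype_error_rate > 0) {
    err <- which(stats::runif(length(geno)) < sc$genotype_error_rate)
    if (length(err) > 0L)
      geno[err] <- (geno[err] + sample.int(2L, length(err),
                                           replace = TRUE)) %% 3L
  }
  if (sc$missing_rate > 0)
    geno[stats::runif(length(geno)) < sc$missing_rate] <- NA_integer_

  truth <- list(
    ne = c(vapply(sc$breeds, function(b) b$ne, numeric(1)),
           stats::setNames(rep(NA_real_, length(sc$crosses)),
                           names(sc$crosses))),
    founder_freq = founder_keep,
    snp_id = map$snp_id,
    planted_regions = list())
  list(panel = genopanel(geno, map, pop), truth = truth)
}

#' Plant an autozygous segment in one individual
#'
#' Overwrites the genotypes of one individual inside a map region with
#' homozygous dosages consistent with a single haplotype drawn from the
#' individual's population allele frequencies; everything outside the region
#' is untouched. Useful as a positive control for ROH detection.
#'
#' @param panel a [genopanel].
#' @param individual sample id or row index.
#' @param chrom,start_bp,end_bp target region (inclusive).
#' @param seed RNG seed for the haplotype draw.
#' @return The modified panel, with the region recorded in attribute
#'   `planted_regions`.
#' @export
plant_roh <- function(panel, individual, chrom, start_bp, end_bp,
                      seed = 1L) {
  stopifnot(inherits(panel, "genopanel"))
  row <- if (is.character(individual))
    match(individual, rownames(panel$geno)) else individual
  if (is.na(row)) stop("unknown individual: ", individual)
  in_region <- as.character(panel$map$chrom) == as.character(chrom) &
    panel$map$pos_bp >= start_bp & panel$map$pos_bp <= end_bp
  if (sum(in_region) < 2L)
    stop("planted region covers <2 SNPs")
  p <- allele_frequency(panel, subset = panel$pop == panel$pop[row])
  p <- ifelse(is.nan(p), 0.5, p)
  hap <- with_seed(seed,
                   stats::rbinom(sum(in_region), 1L,
                                 pmin(pmax(p[in_region], 0), 1)))
  panel$geno[row, in_region] <- 2L * hap
  attr(panel, "planted_regions") <-
    c(attr(panel, "planted_regions"),
      list(list(individual = rownames(panel$geno)[row], chrom = chrom,
                start_bp = start_bp, end_bp = end_bp)))
  panel
}
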