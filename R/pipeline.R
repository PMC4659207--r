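#' Configuration for a full pipeline run
#'
#' One config drives every stage: input (a panel, PED/MAP or VCF paths, or a
#' simulation scenario), per-module parameters, the output directory and the
#' run seed. The config is serialized verbatim into the output bundle's JSON
#' sidecar.
#'
#' @param panel a [genopanel] (alternative to file inputs).
#' @param ped,map,vcf,pop_map input file paths (PED/MAP or VCF + population
#'   map TSV).
#' @param scenario a [sim_scenario()] to simulate the input panel.
#' @param out_dir output directory.
#' @param seed run seed (per-stage seeds are derived from it).
#' @param populations which populations to analyse; default all.
#' @param qc a [qc_config()].
#' @param roh a [roh_params()].
#' @param max_block_span_kb Gabriel block span cap.
#' @param ld_max_distance_bp optional cap on LD pair distance.
#' @param nonsyntenic_fraction per-chromosome SNP fraction for the
#'   non-syntenic baseline and Ne.
#' @param ne_pcrit MAF screen for the Ne estimator.
#' @param ne_pairs `"nonsyntenic"` or `"all"` (see [estimate_ne()]).
#' @param f_threshold critical inbreeding threshold.
#' @return List of class `run_config`.
#' @export
run_config <- function(panel = NULL, ped = NULL, map = NULL, vcf = NULL,
                       pop_map = NULL, scenario = NULL,
                       out_dir = "flockdiv_out", seed = 17L,
                       populations = NULL, qc = qc_config(),
                       roh = roh_params(), max_block_span_kb = 500,
                       ld_max_distance_bp = Inf,
                       nonsyntenic_fraction = 0.05, ne_pcrit = 0.05,
                       ne_pairs = "nonsyntenic", f_threshold = 0.065) {
  n_inputs <- (!is.null(panel)) + (!is.null(ped)) + (!is.null(vcf)) +
    (!is.null(scenario))
  if (n_inputs != 1L)
    stop("exactly one of panel, ped(+map), vcf(+pop_map), scenario required")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full diversity pipeline
#'
#' QC, per-population diversity and pairwise FST, GRM-PCA, LD decay /
#' adjacent / non-syntenic LD, Gabriel haplotype blocks, ROH, LD-based Ne
#' and marker-based inbreeding, written as a TSV bundle with a JSON
#' parameter sidecar. Stages run in order on the QC-passing panel; any
#' failure aborts with the stage name, preserving the outputs already
#' written. Identical config and seed reproduce the bundle byte for byte.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the computed objects (`panel`, `qc`,
#'   `diversity`, `fst`, `pca`, `ld`, `blocks`, `roh`, `ne`, `inbreeding`)
#'   and `files` (paths written).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "input"
  res <- list()
  emit <- function(tables) {
    params <- config[c("seed", "max_block_span_kb", "nonsyntenic_fraction",
                       "ne_pcrit", "ne_pairs", "f_threshold")]
    params$qc <- unclass(config$qc)
    params$roh <- unclass(config$roh)
    write_reports(tables, out_dir, params = params)
  }
  tryCatch({
    panel <- if (!is.null(config$panel)) config$panel
    else if (!is.null(config$ped)) read_ped_map(config$ped, config$map)
    else if (!is.null(config$vcf)) read_vcf(config$vcf, config$pop_map)
    else simulate_panel(config$scenario)$panel
    pops <- config$populations
    if (is.null(pops)) pops <- levels(panel$pop)
    unknown <- setdiff(pops, levels(panel$pop))
    if (length(unknown) > 0L)
      stop("unknown population label(s): ", paste(unknown, collapse = ", "))
    res$panel <- panel

    stage <- "qc"
    qc <- apply_qc(panel, config$qc)
    panel <- qc$panel
    res$qc <- qc
    files <- emit(list(qc_report = qc$report))

    stage <- "diversity"
    div <- population_diversity(panel)
    fst <- fst_matrix(panel)
    G <- grm(panel)
    pca <- grm_pca(G, k = min(4L, nrow(G) - 1L))
    res$diversity <- div; res$fst <- fst; res$pca <- pca
    fst_df <- data.frame(population = rownames(fst), fst,
                         check.names = FALSE)
    pca_df <- data.frame(individual = rownames(pca$scores),
                         population = as.character(panel$pop),
                         pca$scores, check.names = FALSE)
    files <- c(files, emit(list(
      diversity = div, fst_matrix = fst_df, pca_scores = pca_df,
      pca_variance = data.frame(component = seq_along(pca$var_explained),
                                var_explained = pca$var_explained))))

    stage <- "ld"
    ld_tabs <- lapply(pops, function(pp) {
      dec <- ld_decay(panel, pp, max_distance_bp = config$ld_max_distance_bp)
      adj <- adjacent_ld(panel, pp)
      ns <- nonsyntenic_ld(panel, pp,
                           fraction = config$nonsyntenic_fraction,
                           seed = config$seed)
      list(decay = cbind(population = pp, dec$decay),
           by_chrom = cbind(population = pp, dec$by_chromosome),
           adj = cbind(population = pp, adj),
           ns = data.frame(population = pp, mean_r2 = ns$mean_r2,
                           n_pairs = ns$n_pairs))
    })
    res$ld <- ld_tabs
    files <- c(files, emit(list(
      ld_decay = do.call(rbind, lapply(ld_tabs, `[[`, "decay")),
      ld_by_chromosome = do.call(rbind, lapply(ld_tabs, `[[`, "by_chrom")),
      ld_adjacent = do.call(rbind, lapply(ld_tabs, `[[`, "adj")),
      ld_nonsyntenic = do.call(rbind, lapply(ld_tabs, `[[`, "ns")))))

    stage <- "blocks"
    blk <- lapply(pops, function(pp)
      find_blocks(panel, pp, max_span_kb = config$max_block_span_kb))
    names(blk) <- pops
    blk_all <- do.call(rbind, lapply(pops, function(pp)
      if (nrow(blk[[pp]]) > 0L) cbind(population = pp, blk[[pp]]) else NULL))
    if (is.null(blk_all))
      blk_all <- data.frame(population = character(), chrom = character(),
                            first_snp = character(), last_snp = character(),
                            start_bp = integer(), end_bp = integer(),
                            n_snps = integer(), length_bp = integer())
    blk_sum <- do.call(rbind, lapply(pops, function(pp)
      cbind(population = pp, block_summary(blk[[pp]], panel$map))))
    res$blocks <- blk
    files <- c(files, emit(list(blocks = blk_all,
                                block_summary = blk_sum)))

    stage <- "roh"
    segs <- detect_roh(panel, config$roh)
    inds <- data.frame(individual = rownames(panel$geno),
                       population = as.character(panel$pop))
    cats <- roh_length_categories(segs, individuals = inds)
    chrom_sum <- roh_chromosome_summary(segs, panel$map)
    inc <- data.frame(snp_id = panel$map$snp_id, chrom = panel$map$chrom,
                      pos_bp = panel$map$pos_bp,
                      n_roh = roh_incidence(segs, panel$map))
    res$roh <- list(segments = segs, categories = cats,
                    by_chromosome = chrom_sum, incidence = inc, l = attr(segs, "l"))
    files <- c(files, emit(list(
      roh_segments = segs, roh_category_means = cats$population_means,
      roh_by_chromosome = chrom_sum, roh_incidence = inc)))

    stage <- "ne"
    ne_rows <- lapply(pops, function(pp) {
      est <- tryCatch(
        estimate_ne(panel, pp, pcrit = config$ne_pcrit,
                    pairs = config$ne_pairs,
                    fraction = config$nonsyntenic_fraction,
                    seed = config$seed,
                    small_sample = sum(panel$pop == pp) < 30L),
        error = function(e) NULL)
      if (is.null(est))
        return(data.frame(population = pp, ne_hat = NA_real_,
                          mean_r2 = NA_real_, r2_drift = NA_real_,
                          n_pairs = NA_integer_, harmonic_s = NA_real_))
      data.frame(population = pp, ne_hat = est$ne_hat,
                 mean_r2 = est$mean_r2, r2_drift = est$r2_drift,
                 n_pairs = est$n_pairs, harmonic_s = est$harmonic_s)
    })
    ne_tab <- do.call(rbind, ne_rows)
    res$ne <- ne_tab
    files <- c(files, emit(list(ne = ne_tab)))

    stage <- "inbreeding"
    fc <- f_coefficients(panel)
    fsum <- critical_percentage(fc, config$f_threshold)
    res$inbreeding <- list(per_individual = fc, summary = fsum)
    files <- c(files, emit(list(inbreeding_individual = fc,
                                inbreeding_summary = fsum)))

    res$files <- unique(files)
    invisible(res)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}
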