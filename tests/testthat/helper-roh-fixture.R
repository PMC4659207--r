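# Build one individual's chromosome: regular SNP grid, heterozygous flanking
# tracts, and a planted homozygous run. The window span used with these
# fixtures must be smaller than the run: a window can only be called
# homozygous when it fits (nearly) inside the run, so a span larger than the
# run leaves every window straddling the het flanks.
roh_fixture <- function(run_span_kb, spacing_kb = 40, flank_snps = 60,
                        flank_het = 1, gap_at = NULL, gap_kb = 300,
                        seed = 1) {
  set.seed(seed)
  run_snps <- as.integer(run_span_kb / spacing_kb) + 1L
  m <- flank_snps * 2L + run_snps
  pos <- cumsum(rep(spacing_kb * 1000, m))
  if (!is.null(gap_at)) {
    k <- flank_snps + gap_at
    pos[(k + 1L):m] <- pos[(k + 1L):m] + gap_kb * 1000
  }
  run_idx <- (flank_snps + 1L):(flank_snps + run_snps)
  g <- integer(m)
  flank <- setdiff(seq_len(m), run_idx)
  g[flank] <- ifelse(rbinom(length(flank), 1, flank_het) == 1L, 1L,
                     2L * rbinom(length(flank), 1, 0.5))
  g[run_idx] <- 2L * rbinom(run_snps, 1, 0.5)
  list(geno = matrix(as.integer(g), 1, m), pos = as.integer(pos),
       run_range = range(pos[run_idx]))
}

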