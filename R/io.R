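#' Read PLINK text PED/MAP files
#'
#' Parses the PLINK 6-column PED dialect (FID, IID, PAT, MAT, SEX, PHENO,
#' then two allele columns per SNP) together with a 4-column MAP
#' (chrom, snp_id, cM, bp). The population label of each sample is taken from
#' the family-ID column, the PLINK convention for cohort files without an
#' external population map.
#'
#' For each SNP, allele orientation is taken from the first heterozygous
#' genotype (its two alleles are written in `allele_a allele_b` order, which
#' is what [write_ped_map()] emits, making write/read a bit-exact round
#' trip); if a SNP has no heterozygote, `allele_a` is the first allele
#' observed in file order. Dosage counts copies of `allele_b`, so a
#' monomorphic SNP reads as all zeros. "0 0" is a missing call. Every
#' statistic in the package is invariant to the orientation.
#'
#' @param ped_path path to the .ped file.
#' @param map_path path to the .map file.
#' @return A [genopanel].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_tok)
  if (any(nf != 4L))
    stop(sprintf("MAP parse error at line %d: expected 4 fields, found %d",
                 which(nf != 4L)[1L], nf[nf != 4L][1L]))
  map <- data.frame(
    snp_id = vapply(map_tok, `[`, "", 2L),
    chrom = vapply(map_tok, `[`, "", 1L),
    pos_bp = as.integer(vapply(map_tok, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  m <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  ped_tok <- strsplit(trimws(ped_lines), "[ \t]+")
  nf <- lengths(ped_tok)
  want <- 6L + 2L * m
  if (any(nf != want))
    stop(sprintf("PED parse error at line %d: expected %d fields, found %d",
                 which(nf != want)[1L], want, nf[nf != want][1L]))

  tok <- matrix(unlist(ped_tok), nrow = n, byrow = TRUE)
  fid <- tok[, 1L]
  iid <- tok[, 2L]
  a1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]

  geno <- matrix(NA_integer_, n, m)
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    seen <- unique(c(rbind(x1[!miss], x2[!miss])))
    if (length(seen) > 2L)
      stop(sprintf("SNP %s has >2 alleles: %s", map$snp_id[j],
                   paste(seen, collapse = ",")))
    het <- which(!miss & x1 != x2)
    if (length(het) > 0L) {            # orientation from the first het call
      allele_a[j] <- x1[het[1L]]
      allele_b[j] <- x2[het[1L]]
    } else {
      allele_a[j] <- if (length(seen) >= 1L) seen[1L] else "0"
      allele_b[j] <- if (length(seen) == 2L) seen[2L] else "0"
    }
    d <- (x1 == allele_b[j]) + (x2 == allele_b[j])
    d[miss] <- NA_integer_
    geno[, j] <- as.integer(d)
  }
  map$allele_a <- allele_a
  map$allele_b <- allele_b
  map <- map[, c("snp_id", "chrom", "pos_bp", "allele_a", "allele_b")]
  ids <- if (anyDuplicated(iid)) paste(fid, iid, sep = "_") else iid
  rownames(geno) <- ids
  genopanel(geno, map, fid)
}

#' Write a panel as PLINK text PED/MAP
#'
#' Inverse of [read_ped_map()]: family ID is the population label, missing
#' dosages become "0 0". A round trip through [read_ped_map()] reproduces the
#' panel exactly.
#'
#' @param panel a [genopanel].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(panel, ped_path, map_path) {
  map <- panel$map
  map_out <- sprintf("%s %s 0 %d", map$chrom, map$snp_id, map$pos_bp)
  writeLines(map_out, map_path)

  g <- panel$geno
  n <- nrow(g); m <- ncol(g)
  aa <- matrix(rep(map$allele_a, each = n), n, m)
  bb <- matrix(rep(map$allele_b, each = n), n, m)
  x1 <- ifelse(is.na(g), "0", ifelse(g == 2L, bb, aa))   # het = "a b" order
  x2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, bb, aa))
  gt <- matrix(paste(x1, x2), n, m)
  lead <- sprintf("%s %s 0 0 0 -9", as.character(panel$pop), rownames(g))
  body <- apply(gt, 1L, paste, collapse = " ")
  writeLines(paste(lead, body), ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read biallelic SNPs from a VCF
#'
#' Loads GT fields from a VCF v4.x file, counting ALT-allele copies (phase is
#' ignored; `./.` is missing). Records that are multiallelic or not simple
#' SNPs are skipped; the number skipped is attached as attribute
#' `skipped_records`.
#'
#' @param vcf_path path to a VCF file (plain or bgzipped).
#' @param pop_map either a path to a two-column TSV (sample, population) or a
#'   data.frame with those columns. VCF carries no population field, so
#'   explicit labels are required.
#' @return A [genopanel] with attribute `skipped_records`.
#' @export
read_vcf <- function(vcf_path, pop_map) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!"GT" %in% rownames(v@gt) && !grepl("GT", v@gt[1L, "FORMAT"]))
    stop("VCF has no GT field")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  skipped <- sum(!keep)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # count ALT alleles irrespective of phasing separator
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  geno <- t(dose)
  rownames(geno) <- colnames(gt)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  map <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                    pos_bp = as.integer(fix[, "POS"]),
                    allele_a = fix[, "REF"], allele_b = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  if (is.character(pop_map) && length(pop_map) == 1L)
    pop_map <- utils::read.table(pop_map, header = FALSE, sep = "\t",
                                 col.names = c("sample", "population"),
                                 stringsAsFactors = FALSE)
  idx <- match(rownames(geno), pop_map[[1L]])
  if (anyNA(idx))
    stop("pop_map lacks label(s) for sample(s): ",
         paste(rownames(geno)[is.na(idx)], collapse = ", "))
  panel <- genopanel(geno, map, pop_map[[2L]][idx])
  attr(panel, "skipped_records") <- skipped
  panel
}

#' Write result tables with a reproducibility sidecar
#'
#' Writes each element of `results` as a TSV (header line, no quoting, "\n"
#' line endings, NA as "NA") plus one `run_params.json` sidecar recording the
#' parameters that produced them, so a run can be reproduced byte-for-byte.
#'
#' @param results named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @param params named list of run parameters (seed, thresholds, ...).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(results, out_dir, params = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  stopifnot(is.list(results), !is.null(names(results)),
            all(nzchar(names(results))))
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    df <- as.data.frame(results[[nm]])
    con <- file(p, open = "wb")
    utils::write.table(format_numeric_cols(df), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, eol = "\n")
    close(con)
    paths <- c(paths, p)
  }
  jp <- file.path(out_dir, "run_params.json")
  jsonlite::write_json(params, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, jp))
}

# fixed 15-significant-digit formatting => byte-stable TSVs across runs
format_numeric_cols <- function(df) {
  for (k in seq_along(df)) {
    if (is.double(df[[k]]))
      df[[k]] <- formatC(df[[k]], digits = 15, format = "g")
  }
  df
}
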