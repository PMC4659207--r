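test_that("PED genotypes map to B-allele dosages with 0 0 as missing", {
  ped <- c("FAM1 id1 0 0 0 -9 A A G G",
           "FAM1 id2 0 0 0 -9 A G 0 0",
           "FAM2 id3 0 0 0 -9 G G G T")
  map <- c("1 snp1 0 1000", "1 snp2 0 2000")
  pd <- tempfile(fileext = ".ped"); mp <- tempfile(fileext = ".map")
  writeLines(ped, pd); writeLines(map, mp)
  panel <- read_ped_map(pd, mp)

  # allele_a = first seen (A at snp1), allele_b = G; "A A" with allele_b=G -> 0
  expect_equal(panel$map$allele_a, c("A", "G"))
  expect_equal(panel$map$allele_b, c("G", "T"))
  expect_equal(unname(panel$geno[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(panel$geno[, 2]), c(0L, NA_integer_, 1L))
  expect_equal(as.character(panel$pop), c("FAM1", "FAM1", "FAM2"))
})

test_that("PED/MAP round trip is the identity on panel, map and labels", {
  g <- matrix(c(0L, 1L, 2L, NA_integer_, 2L, 1L), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  panel <- make_panel(g, pop = c("X", "X", "Y"))
  pd <- tempfile(fileext = ".ped"); mp <- tempfile(fileext = ".map")
  write_ped_map(panel, pd, mp)
  back <- read_ped_map(pd, mp)
  expect_identical(unname(back$geno), unname(panel$geno))
  expect_equal(back$map$pos_bp, panel$map$pos_bp)
  expect_equal(as.character(back$pop), as.character(panel$pop))
})

test_that("malformed PED/MAP inputs fail with located errors", {
  pd <- tempfile(fileext = ".ped"); mp <- tempfile(fileext = ".map")
  writeLines(c("1 snp1 0 1000", "1 snp2 0 2000"), mp)
  writeLines(c("F a 0 0 0 -9 A A G G", "F b 0 0 0 -9 A A G"), pd)
  expect_error(read_ped_map(pd, mp), "line 2")
  writeLines(c("F a 0 0 0 -9 A T G G", "F b 0 0 0 -9 C A G G"), pd)
  expect_error(read_ped_map(pd, mp), "snp1")
})

test_that("VCF reading counts ALT alleles, skips non-biallelic records, and
           matches the PED/MAP reading of the same cohort", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
           "1\t1000\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1|1",
           "1\t2000\tsnp2\tT\tC\t.\tPASS\t.\tGT\t./.\t1/1\t0/1",
           "1\t3000\tbad1\tA\tC,T\t.\tPASS\t.\tGT\t0/1\t0/2\t1/1",
           "1\t4000\tbad2\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0")
  vp <- tempfile(fileext = ".vcf")
  writeLines(vcf, vp)
  pops <- data.frame(sample = c("s1", "s2", "s3"), population = "P1")
  panel <- read_vcf(vp, pops)
  expect_equal(attr(panel, "skipped_records"), 2L)
  expect_equal(ncol(panel$geno), 2L)
  expect_equal(unname(panel$geno[, "snp1"]), c(0L, 1L, 2L))  # 1|1 phased -> 2
  expect_equal(unname(panel$geno[, "snp2"]), c(NA_integer_, 2L, 1L))

  # same cohort through the PED/MAP dialect gives the identical matrix
  pd <- tempfile(fileext = ".ped"); mp <- tempfile(fileext = ".map")
  writeLines(c("P1 s1 0 0 0 -9 A A 0 0",
               "P1 s2 0 0 0 -9 A G C C",
               "P1 s3 0 0 0 -9 G G T C"), pd)
  writeLines(c("1 snp1 0 1000", "1 snp2 0 2000"), mp)
  ped_panel <- read_ped_map(pd, mp)
  expect_identical(unname(ped_panel$geno), unname(panel$geno))
})

test_that("report writing is deterministic and keeps headers on empty tables", {
  d1 <- tempfile(); d2 <- tempfile()
  empty_roh <- data.frame(individual = character(), chrom = character(),
                          start_bp = integer(), end_bp = integer())
  res <- list(decay = data.frame(bin = ld_bins()$label, mean_r2 = runif(14)),
              roh = empty_roh)
  write_reports(res, d1, params = list(seed = 7))
  write_reports(res, d2, params = list(seed = 7))
  for (f in c("decay.tsv", "roh.tsv", "run_params.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  roh_lines <- readLines(file.path(d1, "roh.tsv"))
  expect_length(roh_lines, 1L)  # header only
  expect_match(roh_lines, "individual\tchrom")
  expect_equal(length(readLines(file.path(d1, "decay.tsv"))), 15L)
})
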