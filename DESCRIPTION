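Package: flockdiv
Title: Genome-Wide Linkage Disequilibrium and Genetic Diversity Analysis for SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for population-level analysis of dense unphased SNP genotype
    panels in structured livestock populations: quality control (call rate, minor
    allele frequency, exact Hardy-Weinberg test, heterozygosity outliers),
    per-population heterozygosity and pairwise FST, genomic relationship matrix
    and principal components, pairwise linkage disequilibrium (r-squared and
    D-prime) from unphased genotypes via an EM haplotype-frequency estimator with
    likelihood-profile D-prime confidence bounds, Gabriel-style haplotype block
    partitioning, PLINK-style runs-of-homozygosity detection with a false-positive
    bound on the minimum SNP count, linkage-disequilibrium based effective
    population size with small-sample bias correction, and three marker-based
    inbreeding coefficients. A seeded forward-in-time Wright-Fisher breed
    simulator generates multi-breed panels (bottlenecks, crosses, planted
    autozygous segments) so the whole pipeline can be exercised and validated
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
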