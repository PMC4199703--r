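Package: tetramap
Title: Autotetraploid GBS Linkage Mapping via Single-Dose Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Construction of haplotype-resolved genetic linkage maps for
    autotetraploid F1 populations from genotyping-by-sequencing (GBS)
    allele read depths. Implements binomial read-depth genotype calling
    for tetrasomic biallelic SNPs (11-read homozygote rule, two-read /
    10% minor-allele-frequency heterozygote rule), single-dose-allele
    screening by presence:absence segregation ratio, two-way
    pseudo-testcross map construction (LOD grouping, SARF seriation
    ordering, Kosambi distances, homolog naming), chi-square segregation
    distortion scanning with LOESS smoothing, and synteny comparison
    against a reference genome from BLAST tabular hits. Includes a
    tetrasomic-meiosis simulator with negative-binomial GBS read depths
    and optional viability selection, which provides ground truth for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
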