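# tetramap

Haplotype-resolved genetic linkage maps for autotetraploid F1 populations
from genotyping-by-sequencing (GBS) allele read depths.

Autotetraploids such as cultivated alfalfa carry four homologous copies of
each chromosome that segregate tetrasomically, so a biallelic SNP has a
dosage of 0–4 and ordinary diploid mapping software cannot be applied
directly. The established workaround is the **two-way pseudo-testcross**:
keep only *single-dose alleles* (SDA, simplex — present on exactly one
homolog of exactly one parent), which segregate 1:1 presence:absence in the
F1 like a backcross marker, and build a separate map per parent in which
each linkage group corresponds to a single homolog. `tetramap` implements
that entire chain for GBS data, plus the simulator needed to validate it:

1. **Genotype calling** — binomial read-depth model
   `P(X_A | G; N, α)` with success probabilities `1−α, 3/4, 1/2, 1/4, α`
   for `G = AAAA, AAAB, AABB, ABBB, BBBB`; deterministic rules: a
   homozygote needs ≥ 11 reads of a single allele (the smallest `N` with
   `(3/4)^N < 0.05`, the triplex-miscall bound), a heterozygote needs ≥ 2
   reads per allele and minor-allele fraction > 0.10.
2. **SDA screen** — parental configuration (AB×AA / AA×AB), presence:absence
   ratio < 2:1 (the simplex/duplex equal-evidence point is
   `√5 ≈ 2.24`), missingness < 50%, and a 1-df χ² test against 1:1.
3. **Map construction** — pairwise recombination fractions
   `r̂ = min(R/n, 0.5)` with LOD
   `R log₁₀ r̂ + (n−R) log₁₀(1−r̂) + n log₁₀ 2`; grouping at LOD ≥ 14
   (connected components); SARF seriation ordering with 2-opt polish under
   LOD ≥ 1.0 / r ≤ 0.35 filters; Kosambi distances
   `d = 25 ln((1+2r)/(1−2r))`; homologs lettered A–D by marker count.
4. **Segregation-distortion scan** — LOESS-smoothed `−log₁₀(p)` along each
   group; a region needs the curve above 3 and ≥ 3 consecutive markers
   skewed the same way at `p < 0.001`.
5. **Synteny** — best-hit filtering of BLAST tabular output (e-value
   < 1e-5 or 1e-20), chromosome assignment by majority vote, dotplot
   tables with Spearman |ρ| collinearity per group.
6. **Simulation** — tetrasomic meiosis (random bivalent pairing, Haldane
   crossovers, no double reduction), negative-binomial GBS depths,
   sequencing errors, optional viability selection, with full latent truth.

See `vignettes/tetramap-methods.Rmd` for the model details, design
decisions, and what the validation experiments do and do not show.

## Worked example

Simulate a two-chromosome slice of an F1 population (384 progeny, mean
depth 30), call genotypes, screen for single-dose alleles and build the
maternal map:

```r
library(tetramap)

cfg <- sim_config(n_progeny = 384, n_chromosomes = 2,
                  markers_per_homolog = 25, depth_mean = 30,
                  duplex_per_chromosome = 5, seed = 42)
sim   <- simulate_cross(cfg)
calls <- call_matrix(merge_parent_replicates(sim$reads))
sda   <- sda_screen(calls)
table(sda$configuration)
#> maternal_only paternal_only      unusable
#>            82            89           239

pres <- presence_matrix(calls, sda, "mother")
gm   <- build_linkage_map(pres, map_config(), parent = "mother")
gm
#> genetic map: 76 markers in 9 linkage groups (1 unplaced)
#>   total length: 476.0 cM; group sizes 2-12 markers
summary(gm)
#>   linkage_group lg_name n_markers length_cM
#> 1             1      NA        12  65.92614
#> 2             2      NA        11  78.22022
#> ...
```

Reading the output: the two simulated chromosomes have 2 × 4 = 8 homologs,
each a true 70 cM. Eight of the nine recovered groups are those homologs
(estimated lengths 40–78 cM, 7–12 markers each); one homolog split into
two fragments (groups 8 and 9) because marker attrition opened a gap that
LOD-14 linkage cannot bridge. The attrition is dominated by parent-call
dropout: 239/410 markers are "unusable" since a deeply pooled homozygous
parent usually shows at least one error read and the calling rules then
return a missing genotype — a property of the published rule set that the
package reproduces faithfully (see the vignette's validation notes).

Downstream, `scan_distortion(gm, sda)` scans each group for
segregation-distortion regions, and `filter_best_hits()` /
`assign_chromosomes()` / `dotplot_table()` compare a map against a
reference genome from a BLAST tabular file (for simulated maps,
`simulate_hit_table()` fabricates a truth-linked one).

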