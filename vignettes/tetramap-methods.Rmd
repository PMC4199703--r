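---
title: "Methods: autotetraploid GBS linkage mapping with tetramap"
author: "tetramap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autotetraploid GBS linkage mapping with tetramap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetramap)
```

## The problem

Cultivated alfalfa is a tetrasomic autotetraploid: each locus sits on four
homologous chromosomes that pair and segregate randomly among themselves at
meiosis, so an individual carries a biallelic SNP at dosage 0–4.
Genotyping-by-sequencing (GBS) yields, for every SNP and individual, a pair
of allele read counts rather than a genotype, with depth varying wildly
across loci and samples. `tetramap` implements the full analysis chain that
turns such read counts into haplotype-resolved genetic linkage maps of the
two parents of an F1 population, plus a segregation-distortion scan and a
synteny comparison against a reference genome. A tetrasomic-meiosis
simulator with full latent truth underpins all validation.

## Genotype calling from read depth

For a SNP with alleles A/B, total depth $N$ and true dosage class
$G$, the A-allele count follows a binomial distribution with success
probability

$$p_G = 1-\alpha,\; 3/4,\; 1/2,\; 1/4,\; \alpha
\quad\text{for}\quad G = \mathrm{AAAA}, \mathrm{AAAB}, \mathrm{AABB},
\mathrm{ABBB}, \mathrm{BBBB},$$

where $\alpha$ is the symmetric allele-switch (sequencing error) rate. Only
the homozygote classes involve $\alpha$; the heterozygote classes use exact
allele fractions. `genotype_likelihood()` evaluates these probabilities;
they justify the deterministic calling rules but are not themselves used by
the caller, and heterozygote dosage classes are never emitted (separating
the three heterozygotes would need depth ≥ 60).

The rules, implemented in `call_genotype()`:

* single allele observed — homozygote if $N \ge 11$, else missing. Eleven
  is the smallest depth at which a triplex heterozygote (AAAB) yields only
  its major allele with probability $(3/4)^N < 0.05$
  (`min_homozygote_depth(0.05)` returns 11, $(3/4)^{11} \approx 0.042$);
* both alleles observed — heterozygote if each allele has ≥ 2 reads *and*
  the minor-allele fraction strictly exceeds 0.10, else missing;
* zero depth — missing.

Boundary conventions are literal: a minor-allele fraction of exactly 0.10
is missing, and a homozygote needs $N \ge 11$ exactly. Parent replicate
libraries are pooled by summing depths (`merge_parent_replicates()`)
before calling.

A consequence worth knowing: at high depth with $\alpha > 0$, a true
homozygote almost always shows at least one error read of the other allele,
falls into the "both alleles observed" branch, fails the heterozygote
thresholds, and is assigned *missing*. Deeply sequenced (pooled) parents
therefore lose a substantial fraction of their homozygous calls — at a
pooled depth of ~200 reads and $\alpha = 0.005$, only
$0.995^{200} \approx 37\%$ of homozygous parent genotypes are callable.
This is a property of the printed rule set, not of the implementation, and
it propagates: a marker whose homozygous parent is uncalled has an
unusable parental configuration and drops out of mapping.

## Single-dose-allele screening

Mapping uses the two-way pseudo-testcross: markers heterozygous in exactly
one parent (AB×AA or AB×BB) behave like backcross markers. A single-dose
(simplex) allele segregates 1:1 presence:absence among F1 progeny; a
double-dose (duplex) allele segregates 5:1 under random chromosome
segregation. The presence:absence ratio at which a marker is equally
consistent with both — defined by equality of the 1-df $\chi^2$
goodness-of-fit statistics against the two expectations — is
$\sqrt{5} \approx 2.24$ (`equal_evidence_ratio()`; the statistic equality
is scale-free, so the value is sample-size independent). A plain
binomial-likelihood equality would instead give ≈ 2.15; the $\chi^2$
definition is used because it reproduces the conventional 2.24:1 screen
point. `sda_screen()` accepts markers with ratio strictly below 2:1 and
missingness strictly below 50%, with no lower ratio bound: presence
deficits stay eligible and are picked up by the distortion test.
`distortion_test()` is the 1-df $\chi^2$ against 1:1 without continuity
correction — immaterial at n ≈ 384, flagged for small simulations.

## Map construction

For one parent's SDA presence/absence matrix, `pairwise_linkage()`
estimates each pair's recombination fraction as the mismatch fraction over
pairwise-complete progeny (the ML estimator for a backcross;
pairwise-complete analysis is unbiased under missingness that is
independent of genotype) and the base-10 LOD of linkage against
independence evaluated at the estimate. Mismatch fractions above 0.5 are
capped at $r = 0.5$ with LOD 0: repulsion-phase linkage is deliberately
ignored, because in an autotetraploid pseudo-testcross repulsion signal is
weak, and ignoring it is precisely what makes each linkage group a single
homolog.

Grouping (`group_markers()`) takes connected components at LOD ≥ 14
(single linkage — the simplest reading of grouping by a minimum LOD).
Ordering (`order_group()`) replaces the proprietary regression algorithm
of desktop mapping software with a documented seriation: only pairs with
LOD ≥ 1.0 and $r \le 0.35$ inform the objective (others cost the maximum
0.5), the farthest qualifying pair seeds the order, remaining markers are
inserted nearest-first at the position of least increase in the sum of
adjacent recombination fractions (SARF), and a 2-opt segment-reversal pass
polishes to a local optimum. Output is canonical: input order never
matters, and orientation puts the lexicographically smaller end marker
first. Validation is order *recovery* on simulated truth, not equality
with any external program.

Distances are Kosambi, $d = 25\ln\frac{1+2r}{1-2r}$ cM, accumulated over
adjacent pairs (`map_positions()`). An adjacent pair with no shared typed
progeny falls back to the nearest typed pair spanning the gap, its Kosambi
length split evenly over the spanned gaps; an adjacent estimate at the 0.5
cap is truncated to 0.49 (≈ 57 cM) to keep distances finite — in practice
unreachable inside a LOD-14 group. Homologs within a chromosome are
lettered A–D by descending marker count (`name_homologs()`), ties broken
by smallest marker id; published tables are not always strictly sorted
this way, so the descending-count rule is a documented convention, not a
reproduction.

## Segregation-distortion scan

`scan_distortion()` plots $-\log_{10}(p)$ of the per-marker 1:1 test along
each linkage group, smooths it with LOESS (degree 1, tricube weights over
the span-fraction nearest neighbours, single pass, default span 0.3 —
matching common plotting defaults; the span is exposed and results should
be robust over 0.25–0.5), and calls a distortion region wherever the
smoothed curve exceeds 3 (the $p = 10^{-3}$ line) *and* at least three
consecutive markers are individually distorted at $p < 0.001$ in the same
direction. Direction constancy is required of the marker-level signs, not
of the curve. Smoothing is per linkage group; groups with fewer than three
markers are passed through unsmoothed, and spans are widened on very small
groups so each local fit keeps at least three points.

## Synteny comparison

`read_blast_table()` parses standard 12-column tabular alignment output
(malformed rows reported with line numbers); the subject position is
`min(sstart, send)`, strand-agnostic. "Best hit" is defined as maximum
bitscore among hits with e-value strictly below the cutoff (1e-5 default,
1e-20 stringent), ties broken by lowest e-value then lowest subject
position — alignment tools do not define "best hit" for this purpose, so
the convention is stated. `assign_chromosomes()` assigns each linkage
group by majority vote of its markers' hit chromosomes (ambiguous on a tie
or top fraction < 0.5; unassigned below 3 votes), and `dotplot_table()`
reports per-group Spearman $|\rho|$ between genetic and physical position
as a collinearity score — the sign is arbitrary because group orientation
is arbitrary. Inversion- and translocation-like patterns are displayed
(rank-discordant runs, cross-chromosome dots), not modelled.

## The simulator

`simulate_cross()` generates the study conditions end to end:

* **Parents.** Four homologs per chromosome; every homolog of every parent
  carries `markers_per_homolog` simplex markers at evenly spaced positions
  (default 25 per homolog over 70 cM, against a backdrop of eight
  chromosomes — per-homolog genetic lengths in published tetraploid
  alfalfa maps run roughly 42–81 cM), plus duplex "decoy" markers on two
  homologs of one parent (default 5 per chromosome) that the 2:1 screen
  should reject.
* **Meiosis** (`meiosis()`). The four homologs pair uniformly at random
  into two bivalents (three equally likely pairings); crossovers are a
  Poisson process at 1 event / 100 cM with no interference (Haldane — no
  interference model is implied by 1:1/5:1 expectations, so the simplest
  is used); one recombinant product per bivalent enters the gamete. Double
  reduction is absent by default (random chromosome segregation — the
  1:1 and 5:1 expectations presuppose it); a coarse hook
  (`double_reduction`) duplicates one bivalent product with the given
  probability. Exact gamete dosage distributions from enumerating the
  pairings (`gamete_dosage_probs()`): simplex transmits its allele with
  probability 1/2; duplex gives dosage (0, 1, 2) with probability
  (1/6, 2/3, 1/6), hence 5:1 presence:absence.
* **Viability selection.** Conceived progeny carrying a selected allele
  survive with the configured probability and are redrawn otherwise —
  rejection sampling at conception, matching the interpretation of
  distortion regions as viability loci.
* **Reads.** Total depth is negative-binomial (`mu = depth_mean`,
  `size = depth_dispersion`), zeros allowed; $X_A$ is binomial with
  $p = (d/4)(1-\alpha) + (1-d/4)\alpha$ for dosage $d$. Parent replicate
  columns (defaults 5 maternal, 7 paternal, echoing a multi-library
  design) are re-drawn from the parental dosages.

**Depth calibration.** The default `depth_dispersion = 0.7` was fixed once
from the caller's missingness profile. Under the calling rules the
missingness floor at `depth_mean = 4` is ≈ 84% *for every* dispersion
value (the 11-read homozygote rule dominates); 0.7 sits in the flat
minimum of that curve and produces missingness ≈ 0.94 / 0.84 / 0.64 /
0.40 at mean depth 2 / 4 / 10 / 30, reproducing the qualitative structure
of real GBS missingness tiers. No empirical per-locus depth distribution
was available to calibrate against, so the calibration is qualitative
only.

**What the simulator does not emulate.** No sequence-level effects
(restriction sites, barcodes, tag collisions), no depth correlation
between nearby markers or within individuals beyond the shared
negative-binomial, no genotyping batch effects, and no double reduction by
default. Passing recovery tests on this generator therefore show the
estimators are correct *under the stated meiosis and depth model*, not
that real data meet that model.

## Validation findings worth stating

Two end-to-end recovery experiments on the simulator fail at the full
study conditions (depth_mean = 30, α = 0.005, 25 markers per homolog,
n = 384), and the mechanism is informative in both cases:

* **Homolog-group recovery.** With parents pooled to ~150–210 reads,
  ~53–65% of simplex markers lose their homozygous parent call to error
  reads (see the calling section), so only ~9–12 markers per homolog
  survive to mapping and LOD-14 single linkage can no longer bridge every
  thinned gap (~19 cM is the largest bridgeable gap at the observed
  pairwise-complete sample sizes): homologs fragment into ~33–40 groups
  instead of 32. The machinery itself is correct: with ≥ 20 markers per
  homolog entering grouping, or denser simulated marker sets, recovery is
  a clean 32/32 with the true homolog partition (unit-tested). The
  attrition also mirrors the asymmetry seen in real data, where the more
  deeply replicated parent yields fewer usable single-dose markers.
* **Distortion-region recovery.** The calling rules drop homozygous
  (presence-absent) progeny more often than heterozygous ones (call rates
  ≈ 0.50 vs ≈ 0.70 at mean depth 30), biasing presence:absence among
  typed progeny to ≈ 0.58 genome-wide. About 17% of *null* markers then
  reach $p < 0.001$ (excess presence) — strikingly close to the 16–18%
  distorted markers reported in real tetraploid GBS maps — while a
  genuine viability locus (excess absence) is partially cancelled by the
  opposing bias. On error-free reads (α = 0) the scan recovers an
  implanted survival-0.5 locus reliably (unit-tested); under the full
  error model the 1:1 test measures calling bias as much as biology.
  Distortion scans of GBS pseudo-testcross data should be read with this
  in mind — which is consistent with published cautions that markers with
  many missing calls can be misclassified as distorted.

The distortion-recovery experiments scan markers at their true simulated
positions rather than a re-estimated map; this isolates the scan from
map-building noise, which the grouping experiments cover separately.

## Numerical choices and degenerate inputs

* Likelihood normalisation is exact to 1e-12 for depths ≤ 50.
* `0 log 0` terms in the LOD are defined as 0; pairs with no shared typed
  progeny are NA and excluded from grouping and ordering.
* The equal-evidence ratio is found by `uniroot` on the scale-free
  statistic difference to tolerance 1e-12; identical hypotheses return 1
  by convention.
* 2-opt accepts a reversal only if it lowers SARF by more than 1e-12, so
  polishing terminates and never worsens the objective.
* Groups with no qualifying ordering pairs fall back to marker-id order
  with a warning; ties throughout (seeding, insertion, naming) break
  lexicographically so all outputs are deterministic.
* Problem sizes in the shipped tests — population 384, eight chromosomes,
  10,000-gamete segregation checks, 20-replicate recovery experiments —
  are the package's validation conditions; smaller toy cases cover exact
  closed forms.

## Known limitations

* The caller is the literal printed rule set; no posterior or EM dosage
  estimation, no use of the likelihoods in calling, and the
  high-depth-homozygote dropout described above is reproduced, not
  corrected.
* Only single-dose markers of one parent per map: no duplex or
  double-simplex mapping, no integrated consensus map, no QTL machinery.
* Repulsion linkage is discarded by design; homolog assignment of groups
  relies on synteny votes, not repulsion phase.
* The distortion scan has no model of the distortion mechanism (no
  selection-coefficient estimate) and, under the full error model,
  inherits the calling bias discussed above.
* Synteny consumes precomputed tabular hits; alignment itself is out of
  scope.
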