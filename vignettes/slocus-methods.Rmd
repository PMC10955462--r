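---
title: "Models and methods behind slocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slocus)
```

This vignette documents the models implemented in slocus, the choices made
where the underlying biology or published description left the design
open, and what the synthetic-data generators do and do not emulate.

## The genotype-frequency recursion

Distyly in *Primula* is controlled by a hemizygous supergene, the S-locus:
thrums carry it in one copy (`S/0`), pins lack it (`0/0`). Homostyles
arise when the S-locus gene *CYP^T* is disrupted (haplotype `S*`), and can
be hemizygous (`S*/0`) or homozygous (`S*/S*`). The recursion tracks the
four frequencies (p, q, r, s) of (`0/0`, `S/0`, `S*/0`, `S*/S*`) through
non-overlapping generations.

The historical description of the model defers the full cross table to
supplementary material, so the mating table here is stated explicitly as
this package's own concrete design:

* **Pollen is non-limiting** and anther height structures the pollen
  pools. Thrums and homostyles have high anthers; their pollen export is
  proportional to genotype frequency, and each genotype contributes
  alleles by Mendelian segregation of the hemizygous locus (`S/0` → ½ S,
  ½ 0; `S*/0` → ½ S*, ½ 0; `S*/S*` → S*).
* **Pin mothers** self with probability `sigma_pin` (default 0.10, the
  model's classical assumption — removing it does not change the
  qualitative outcomes); otherwise they are fertilized from the
  high-anther pool. Pin ovules always transmit `0`.
* **Thrum mothers** are self- and intra-morph-incompatible and receive
  pin pollen only (allele `0`); their offspring are ½ `S/0`, ½ `0/0`.
  When pins are absent thrums leave no offspring.
* **Homostyle mothers** self with probability `sigma_hom` (default 1:
  homostyles are self-compatible with anthers and stigma at the same
  height); any outcrossed remainder is fertilized from the high-anther
  pool.

`S*/S*` offspring are weighted by the viability `v` — the proportion of
germinated seeds that reach reproduction, relative to the other three
genotypes — and the offspring vector is renormalized. There are no
fecundity differences: all mothers produce equal seed numbers.

Two bookkeeping decisions follow from the four-genotype state space.
First, `S/S` and `S/S*` genotypes (observed rarely in nature) are not part
of the recursion. Second, when `sigma_hom < 1` and thrum pollen reaches a
homostyle ovule, the `S/S*` product falls outside the state space; it is
dropped before renormalization and the dropped mass is reported in the
`"untracked_mass"` attribute of `crosby_step()`. With the default
`sigma_hom = 1` no mass is ever dropped, which is why 1 is the default.

The two equilibrium regimes are structural, not tuned: with `v = 1`
selfing `S*/S*` plants breed true and fix; with `v = 0.65` the penalty on
`S*/S*` balances the segregation of `S*/0` selfing (¼ `0/0` : ½ `S*/0` :
¼ `S*/S*`), leaving both homostyle genotypes at roughly equal frequency,
pins low but positive, and thrums extinct. Convergence is declared when
the L∞ change between consecutive states falls below `tol = 1e-10`
(capped at `max_gens = 1e5`); both regimes converge in ~110 generations.

Trajectory tables do not depend on a canonical starting state being
published; `crosby_state()` is a required argument and the documented
convention (p = q = 0.495, r = 0.01, s = 0) is only a convention, which is
why the equilibrium-based assertions in the tests are
initialization-independent.

## Copy number from relative depth

`Rel = depth(S-locus coding) / depth(genome-wide coding)` normalizes away
per-individual sequencing depth. The classification bands are 0.5 ± 0.25
(haploid) and 1 ± 0.25 (diploid). The two bands share the point 0.75; the
tie goes to haploid (closed upper bound) so the rule is deterministic.
No published threshold defines "absent", but pins produce no S-locus
reads at all, so `rel_depth < 0.05` is called absent; values in
[0.05, 0.25) or above 1.25 are `unclassifiable` rather than forced into a
band. Means are taken over the full width of the target intervals, with
positions missing from the depth track counted as depth 0 — an explicit,
testable convention. Depth can come from samtools-depth-style TSV tracks
(the default here) or from VCF DP fields; no GC or mappability correction
is attempted.

At a genome mean of ~19× and ≥50 kb of coding sites per region, the
sampling noise of `Rel` is of order 0.01, so the three classes are
separated by dozens of standard errors; the ≥99% recovery seen in the
calibration tests reflects that geometry rather than a tuned threshold.

## Variant filtering and consequence annotation

Hard filters follow the standard GATK recipe (QD > 2, MQ > 40, FS < 60,
MQRankSum > −12.5, ReadPosRankSum > −8, InbreedingCoeff ≥ −0.99). The
printed depth rule "(DP > ½X) || (DP < 3X)" is tautological as a
disjunction — it removes nothing — so it is applied as the conjunction
½·mean < DP < 3·mean, the standard depth mask. `X` is read as the mean
site depth, cohort-wide by default. Missing annotations pass their
sub-filter (rank-sum statistics are undefined at sites without
heterozygotes), and filtering at a fixed mean is idempotent.

Consequence calls translate codons under the standard nuclear code: SNVs
are synonymous, missense, or stop-gain; indels are frameshift exactly when
their exonic length is not divisible by 3. The 8-bp exon-1 deletion is
therefore handled by the consequence path, while the depth-based deletion
screen requires runs of ≥50 bp of zero depth — short indels never reach
the structural path, and the paths cannot double-count.

The allele catalogue ships the four alleles whose defining lesions are
operational (`CYP^T-1` functional, `-2` exon-2 stop, `-6` exon-1
frameshift, `-8` exon-1 + promoter deletion); `-3`, `-4`, `-5`, `-7` are
placeholders defined in prior work. Conflicting signatures yield
`"novel"`, never a forced catalogue label. Promoter and motif intervals
are inputs: motif discovery is out of scope.

## Nucleotide diversity

π is computed as pixy computes it: per site, with `c_ref` and `c_alt`
alleles among non-missing genotypes, differences are `c_ref · c_alt` and
comparisons `C(c_ref + c_alt, 2)`; the estimate is the ratio of the sums,
so invariant-but-callable sites add comparisons and missing genotypes
shrink a site's weight instead of biasing it. Sites with fewer than two
called alleles are excluded from both sums, and π_N/π_S is `NA` when
π_S = 0. Only 0-fold and 4-fold degenerate positions enter π_N and π_S;
2- and 3-fold positions are excluded from both.

Hemizygous S-locus carriers appear in a diploid call set as homozygous
diploid genotypes. By default they are consumed as written — matching how
a joint-called VCF is actually analyzed — with an optional `haploid`
argument that counts one allele per hemizygote; the two modes differ
because the diploid reading duplicates each hemizygous allele into a
within-individual comparison pair that is never polymorphic.

## Goodness of fit

Observed genotype tables are built from surveyed phenotype counts, with
homostyles split between `S*/0` and `S*/S*` by the classified proportions
of a genotyped subsample (fractional counts rounded, residual to the
larger class, so totals are preserved). Pearson chi-squared statistics are
assembled by hand because of the zero-cell rules: cells expected and
observed zero are dropped (df reduced); an observed count where the
expectation is exactly zero is incompatibility (p = 0) rather than a
division by zero. `stats::pchisq` supplies the upper tail, and
`stats::chisq.test` serves as the independent oracle in the tests. The
Bonferroni family defaults to all (v × generation) cells tested per
population — the published analysis does not state its family size, so
both raw and adjusted p-values are reported and the family is
configurable.

## What the synthetic data emulate — and what they do not

The generators reproduce the *structure* of the study system: a CYP^T
model with exons of 286 and 227 bp, a 3-kb promoter with motif intervals
placed 15–1361 bp upstream, four further S-genes and four autosomal
paralogs (intron/intergenic lengths and base composition are free
parameters with fixed defaults); cohorts with the surveyed composition
(37 thrums, 37 pins, 31 homostyles; homostyles 40%/60%/0% haploid in the
three focal populations; alleles 8 × `-6` + 2 × `-2`, 10 × `-2`, and
11 × `-8`); Poisson depth at a genome mean of 18.9 (19 in calibration
runs), halved over the S-locus for hemizygotes, zeroed for pins and
inside structural deletions, with a negative-binomial option because real
resequencing is overdispersed; and genotype matrices whose per-site
expected heterozygosity is θ by construction (a site is polymorphic with
probability 2θ at allele frequency ½), with excess homozygosity
(F = 0.9) in selfing groups.

They do **not** emulate linkage (sites are independent — adequate because
every downstream statistic is a per-site sum, stated as a limitation),
read-level errors, mapping bias, GC or mappability structure, or
coalescent genealogies. Passing tests therefore demonstrate that the
estimators and screens are correct on data satisfying their stated
assumptions, not that those assumptions hold in any particular real
dataset; the published real-data values (e.g. the per-gene diversity
table) require the deposited resequencing data and are deliberately not
asserted by the test suite.

Problem sizes in the tests and the acceptance script — 10-kb genotype
matrices, 50-kb depth regions, 500-individual calibration cohorts — were
chosen as the smallest sizes at which Monte-Carlo error is negligible
relative to the tested contrasts.

## Known limitations

* The mating table is this package's reconstruction; implementers with
  access to the original full cross table should reconcile and note
  deviations.
* The recursion is deterministic and infinite-population: no drift, no
  inbreeding depression, no pollen limitation, no spatial structure.
* The structural screen flags cross-contig mate pairs but does not
  resolve translocation insertion sites, and no split-read or assembly
  evidence is used.
* Surveyed-count tables in the source material contain two internal
  inconsistencies (a thrum-split rounding oddity and collected-count
  totals that disagree with the text); the package follows the text's
  totals and documents the choice rather than reproducing the anomalies.
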