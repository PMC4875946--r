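---
title: "Methods: contrasting selection on protein domains and unassigned regions"
author: "domseln"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrasting selection on protein domains and unassigned regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domseln)
```

## The question and the design

Most proteins are mosaics of conserved Pfam domains and the "unassigned"
sequence between them.  `domseln` asks whether population variation and
recent fixed differences behave differently in the two region classes:
whether purifying selection is stronger inside domains, whether synonymous
variation is itself unevenly constrained, and whether the set of domain
families that carry no SNP at all is larger than chance.

The pipeline mirrors a five-step design: map SNPs onto spliced coding
sequences; classify each as synonymous or non-synonymous; annotate
proteins with precomputed domain hits (E ≤ 10⁻³ by default); split SNPs
into domain (doSNP) and unassigned (unSNP) groups, stratified by minor
allele frequency — rare (MAF < 0.5%), low (0.5% ≤ MAF ≤ 5%, boundaries
inclusive), common (MAF > 5%); and call fixed human–ancestor differences
at sites that are monomorphic in the sample and have a high-confidence
(upper-case) ancestral call.

## Statistics

**Density contrast.** For each effect class the *density* is SNPs per
Nei–Gojobori fractional site.  Sites are counted unweighted: at each codon
position, the fraction of its three possible changes that are synonymous
accrues to the synonymous site count, so every codon contributes exactly 3
sites.  Mutations to stop codons count as non-synonymous (nonsense SNPs
are pooled with non-synonymous throughout; the alternative is recomputable
because alt codons are emitted).  The contrast is the 2×2 table
`[SNPs, sites − SNPs]` for the two regions; we report the sample odds
ratio (a·d)/(b·c) as the density ratio together with the two-sided Fisher
exact p-value, and also expose the conditional-MLE odds ratio printed by
`fisher.test()` — the two differ in the third decimal on large tables.
Real-valued site totals are rounded half-up to integers for the exact
test, an error of at most half a site.

**Direction of Selection.** `DoS = Dn/(Dn+Ds) − Pn/(Pn+Ps)`; negative
values mean non-synonymous variants are over-represented among
polymorphisms relative to fixed differences, the footprint of segregating
deleterious mutations.

**Gamma DFE from paired spectra.** Following the Poisson Random Field
treatment with per-class demographic nuisances, the expected number of
neutral variants at derived count *i* (sample size *n* chromosomes) is
`θ_neu · r_i / i`; for selected variants it is `θ_sel · r_i · E_i`, with

E_i(S) = ∫₀¹ C(n,i) xⁱ (1−x)ⁿ⁻ⁱ · (e^{−Sx} − e^{−S}) / ((1 − e^{−S}) x(1−x)) dx,

the sojourn expectation for a derived allele opposed with scaled strength
S = 4Nₑs ≥ 0 (E_i → 1/i as S → 0; the implementation switches to the
analytic limit below S = 10⁻⁸ and splits the integral near the origin for
S > 20, where the integrand concentrates — stable beyond S = 10⁶).  The
DFE mixes E_i(S) over a gamma distribution with shape β and mean S̄ by
64-node Gauss–Legendre quadrature on log S over [10⁻⁴, 10⁶] (configurable);
gamma mass outside the bounds is assigned the neutral and boundary values
respectively.  The r_i (r₁ ≡ 1) are shared by both spectra, absorbing
demography and ascertainment.  The likelihood is a product of Poisson
terms; `fit_dfe()` maximizes it by bounded quasi-Newton on log-transformed
parameters from eight deterministic starts.  Folded spectra sum
complementary class means before the per-observed-class distortions apply.
Reported alongside the estimates: the gamma mass in |S| ∈ [0,1), [1,10),
[10,100), [100,∞), with parametric-bootstrap standard errors when
`dfe_config(n_boot = )` is positive (disabled by default: 200 refits per
fit is expensive, and the point estimates do not need it).

Two practical notes.  First, samples of thousands of chromosomes are
projected down (default 32) by hypergeometric projection before fitting —
the standard SFS reduction; variants monomorphic in the subsample are
lost, which mostly removes singletons.  Second, with shape < 1 the DFE
mean S̄ is dominated by the far upper tail where frequency data carry
almost no information: the profile likelihood over S̄ is nearly flat
(well under one log-unit between S̄ = 50 and 400 at the simulation
settings below), so S̄ point estimates scatter by factors of ~2–3 while β
and the category proportions are stable.  Interval statements about S̄
should come from the bootstrap, not the point estimate.

**Confounder controls.** Amino-acid composition: Pearson chi-square
(no continuity correction, no simulation p-values; expected counts < 5
trigger a logged warning only) on the 2×20 region-by-residue table,
columns absent from both regions dropped; genes with p < 0.05 are set
aside and the density analysis repeated on the remainder.  Codon usage:
Wright's effective number of codons, ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ +
3/F̄₆ over the synonymous-family partition {2-fold: 9, 3-fold: Ile,
4-fold: 5, 6-fold: Leu/Ser/Arg}, with F̂ = (nΣp² − 1)/(n − 1) per family,
families with n ≤ 1 (or F̂ ≤ 0) excluded, a missing 3-fold class imputed
as (F̄₂ + F̄₄)/2, values capped at 61, and stop codons excluded.  Genes
with ENC ≤ 50 are excluded in the codon-bias control.  Because F̂ carries
a small-sample correction, ENC is *not* exactly invariant under
duplicating a gene's codon multiset — the shift is O(61/length) and the
tests assert invariance only asymptotically.

**Zero-SNP domain survey.** A domain accession is SNP-free iff no variant
falls in any instance across all transcripts.  The null: each replicate
re-throws the N observed SNPs uniformly over all protein residues
(a per-protein-total-preserving variant is available), and the empirical
p-values are the fraction of replicates with (a) at least as many SNP-free
accessions and (b) at least as high a mean occurrence of the SNP-free set,
using the plain ≥ convention; +1/(n+1)-corrected versions are reported
alongside.  Domain lengths with/without SNPs are compared by a two-sided
Mann–Whitney test, and protein length vs per-class SNP counts by Spearman
rank correlation with average-rank ties.

## What the synthetic data emulate — and what they do not

`generate_proteome()` lays stop-free ORFs (ATG … stop) on one chromosome
with 1–3 exons, random strands and random intergenic spacers, and assigns
disjoint domain intervals whose coverage is jittered uniformly (±0.15)
around the target fraction (default 0.44, the residue share of domains in
the real human annotation).  `simulate_variants()` drops candidate
mutations uniformly on coding sites at per-site intensity θ (default
0.015, the observed coding SNP frequency), computes each candidate's
effect from its codon, thins non-synonymous candidates by region-specific
acceptance probabilities (default 0.9 in domains vs 1.0 outside —
selection acts by thinning, not by frequency shifts), and draws allele
counts from a 1/i-weighted distribution over 1..n−1 (default n = 2184
chromosomes), which populates all three MAF classes without a coalescent.
`simulate_ancestor()` plants Poisson(rate × length) substitutions in the
ancestral copy, never at polymorphic sites, never creating an ancestral
stop, with stronger thinning for non-synonymous fixations (default: the
squares of the polymorphism acceptances), and lower-cases a configurable
fraction of positions as low-confidence.  Every emitted record carries a
ground-truth row, and every generator is a pure function of (inputs, seed).

Deliberately absent: linkage, recombination, demography (it enters only
through the r_i of the SFS simulator), haplotypes, transition/transversion
bias, CpG effects, overlapping genes and alternative isoforms.  A green
test on this world therefore establishes that the bookkeeping —
coordinates, strand handling, codon arithmetic, counting, and the
estimators — is correct, not that the biological defaults are realistic
beyond the few anchors above.

For the DFE machinery the generator is `simulate_sfs_pair()`: Poisson
class counts at exactly the model expectations.  The recovery experiment
(β = 0.3, S̄ = 50, n = 20, L = 10⁶ sites, r ≡ 1) uses per-site
θ = 0.002, implied by the observed coding SNP frequency (0.015 per site
at 2184 chromosomes ≈ θ·Σ1/i with θ ≈ 0.0018).  It is run on *unfolded*
spectra with the distortions held at their generating value: with folded
n = 20 spectra and nine free folded-class nuisances estimated from twenty
Poisson cells, (β, S̄) sit on a likelihood ridge and no optimizer choice
changes that — conditioning on the known nuisances is what makes the
experiment a test of the DFE code rather than of nuisance identifiability.
Distortion recovery is exercised separately (a shared doubleton excess is
recovered to ±0.25).  Real-data fits default to folded spectra with
distortions estimated, the robust choice when ancestral polarization is
uncertain.

## Numerical and policy choices

* Coordinates are 1-based inclusive everywhere a file format is touched
  (GFF/VCF convention); residue r spans CDS nucleotides 3(r−1)+1..3r.
* The terminal stop codon is retained in the CDS but excluded from site
  counting, variant classification and divergence calling (domain
  coordinates never cover it).
* Codons carrying two polymorphic sites are classified one SNP at a time
  against the reference codon (phase is unavailable); codons with two
  divergent sites are classified one at a time, left to right, against
  the ancestral codon.  Variants in codons split across splice junctions
  are classified through the spliced CDS map.
* Variants whose VCF reference base disagrees with the extracted CDS base
  (after strand correction) are skipped and counted in a QC report, as
  are monomorphic and non-coding records.
* Multi-allelic VCF records are split into one variant per alt allele;
  downstream "polymorphic site" logic uses the position set.
* Divergence calling requires only that the ancestral base be a concrete
  A/C/G/T (outgroup present), not that an additional outgroup agree.
* `density_test()` errors on empty site totals; `dos()` names the zero
  denominator; `fit_dfe()` flags non-convergence instead of throwing;
  `enc()` flags genes with no usable synonymous family (`NA`).
* Randomization p-values have resolution 1/n_reps and use the ≥
  convention; with an empty SNP-free set the mean occurrence is defined
  as 0, so such replicates never exceed a positive observed mean.

## Known limitations

The DFE model is deleterious-only (no positive mass, no adaptive-fraction
estimate); divergence counts enter DoS but not the DFE likelihood.  The
density contrast is genome-aggregate, not per gene.  ENC is the only
codon-bias index.  GO annotation of SNP-free domains, liftover, isoform
selection and running the domain scanner itself are out of scope: domain
hits arrive precomputed.  S̄ point estimates are tail-driven and should be
read with their flat profile in mind.
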