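# domseln

Do Pfam domains and the unassigned remainder of protein-coding sequences
evolve differently?  `domseln` is an R package for population-genetic
contrasts between the two region classes of a proteome: it maps
population SNPs and human–ancestor fixed differences onto spliced coding
sequences, classifies every change as synonymous or non-synonymous,
stratifies by minor allele frequency (rare < 0.5%, low 0.5–5%, common
> 5%), and then compares the regions with

* **density odds ratios** — SNPs per Nei–Gojobori fractional site,
  domain vs unassigned, with Fisher exact tests
  (ρ = (a·d)/(b·c) on the `[SNPs, sites − SNPs]` 2×2 table);
* **Direction of Selection** — DoS = Dn/(Dn+Ds) − Pn/(Pn+Ps), negative
  when deleterious non-synonymous variants segregate;
* **a gamma distribution of fitness effects** fitted by Poisson Random
  Field likelihood to paired (synonymous, non-synonymous)
  site-frequency spectra, with per-frequency-class nuisance multipliers
  r_i absorbing demography and mass reported in |S| ∈ [0,1), [1,10),
  [10,100), [100,∞), S = 4Nₑs;
* **confounder controls** — per-protein amino-acid-composition
  chi-square filtering and Wright's effective number of codons
  (ENC ∈ [20, 61]; genes kept when ENC > 50);
* **a randomization null** for the number of domain families devoid of
  SNPs (N observed SNPs re-thrown uniformly over all residues, 1000×),
  plus domain-length (Mann–Whitney) and length–SNP-count (Spearman)
  comparisons.

It reads the standard formats (FASTA, GFF3/GTF CDS features, VCF with
AC/AN or genotypes, pfam_scan-style TSV) and ships a synthetic-data
module that generates genomes, annotations, variants and ancestral
sequences with known ground truth, so the whole pipeline is testable
without genome-scale inputs.  Audience: population geneticists and
methods developers who want a small, fully tested, reproducible
implementation of this analysis pattern.

## Worked example

Simulate a 60-gene proteome with the default "human-shaped" settings
(44% of residues in domains, 2184 sampled chromosomes, a mild
non-synonymous acceptance deficit inside domains) and run everything:

```r
library(domseln)
cfg <- sim_config(n_genes = 60, aa_len_range = c(100, 300), theta = 0.03,
                  divergence_rate = 0.01, seed = 42)
dir <- file.path(tempdir(), "demo"); dir.create(dir)
prot <- generate_proteome(cfg, dir = dir)
sim  <- simulate_variants(prot, cfg, vcf = file.path(dir, "variants.vcf"))
anc  <- simulate_ancestor(prot, cfg, polymorphic = sim$variants,
                          fasta = file.path(dir, "ancestral.fa"))
res <- run_pipeline(run_config(
  genome = file.path(dir, "genome.fa"), gff = file.path(dir, "genes.gff3"),
  vcf = file.path(dir, "variants.vcf"), domains = file.path(dir, "domains.tsv"),
  ancestral = file.path(dir, "ancestral.fa"),
  out_dir = file.path(dir, "out"), seed = 42))

res$dos
#>      region  Dn Ds  Pn  Ps         dos
#>      domain  83 37 331 117 -0.04717262
#>  unassigned 139 43 477 161  0.01608736
res$density[res$density$class == "all",
            c("kind", "effect", "odds_ratio", "p_value")]
#>          kind        effect odds_ratio    p_value
#>  polymorphism nonsynonymous  0.8951344 0.13074271
#>  polymorphism    synonymous  0.9304563 0.58093683
#>    divergence nonsynonymous  0.7711386 0.06647818
#>    divergence    synonymous  1.1051008 0.65294624
res$survey$randomization
#> randomization_result: N = 1086, observed zero-SNP domains = 0 (mean occurrence 0.00)
#>   p_count = 1, p_occurrence = 1 (1000 reps)
```

Reading it: the generator thinned non-synonymous candidates inside
domains (acceptance 0.9 vs 1.0), and the recovered non-synonymous
density ratio is 0.90 — domains carry ~10% fewer non-synonymous SNPs per
non-synonymous site.  The fixed-difference ratio is lower still (0.77,
the default fixation thinning is the square of the polymorphism
thinning), so DoS is more negative in domains (−0.047 vs +0.016): the
classic footprint of stronger purifying selection on domains.  At this
simulated SNP density every domain family contains a SNP, so the
zero-SNP survey's empirical p-values are 1.  Per-stage tables
(`counts_table.tsv`, `density.tsv`, `dos.tsv`, `dfe_fits.json`,
`enc.tsv`, `domain_occurrence.tsv`, …) and a `manifest.json` with the
seed and record counts at every filter land in `out/`.

A worked single statistic, from the published count table this package's
checks are anchored to: `dos(10153, 18988, 104956, 81593)` returns
`-0.214…` → −0.21 for domain regions, and
`dos(21810, 23626, 153022, 96960)` → −0.13 for unassigned regions.

There is also a thin CLI (`inst/cli/domseln`):

```sh
Rscript inst/cli/domseln simulate --out sim/ --seed 2 --n-genes 50
Rscript inst/cli/domseln run-all --genome sim/genome.fa --gff sim/genes.gff3 \
    --vcf sim/variants.vcf --domains sim/domains.tsv \
    --ancestral sim/ancestral.fa --out out/ --seed 17
Rscript inst/cli/domseln dos --dn 10153 --ds 18988 --pn 104956 --ps 81593
```

## Layout

`R/` — I/O and domain types (`data_model_io.R`), generators
(`synthetic_data.R`), classification (`variant_classify.R`), site
counting and density (`sites_density.R`), DoS/DFE (`selection_dfe.R`),
composition/ENC controls (`composition_codon.R`), zero-SNP survey
(`domain_survey.R`), pipeline and CLI (`cli_report.R`).
`vignettes/domseln-methods.Rmd` — the model, its assumptions, parameter
choices and limitations.  `tests/testthat/` — unit, property and
acceptance tests against independent oracles (brute-force enumeration,
closed forms, exact tail sums, high-resolution quadrature).
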