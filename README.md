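# synthcorr

**How often do rare-variant genotypes predict common-variant genotypes
within a gene?**

Synthetic association — a common marker SNP showing phenotype association
because its genotypes happen to be correlated with rare causal variants in
the same gene — requires that such rare-to-common genotype correlation
occurs reasonably often, independent of any phenotype.  `synthcorr`
quantifies that precondition.  It is aimed at statistical geneticists who
want to measure, in their own cohorts or in simulated ones, the rate of
nominally significant prediction of common-variant genotypes by
rare-variant burden scores, in unrelated and in pedigree samples.

## The statistic

For each gene with 10–50 variants and at least one common variant
(MAF > 0.10), one common variant is drawn at random and its genotype score
(CVGS, the 0/1/2 minor-allele count) is regressed on the unweighted sum of
the individual's minor-allele counts over the gene's rare variants
(MAF < 0.01, positive, with no minor-allele homozygote) — the SRVGS burden
score:

- unrelated samples: Gaussian ML regression
  `CVGS ~ 1 + covariates + SRVGS`, likelihood-ratio test of the burden
  term against chi-square(1);
- family samples: kinship variance-component model
  `y = a + Xg + b*SRVGS + g + e`, `cov(g) = 2 Phi sigma2_g`,
  `cov(e) = I sigma2_e`, fitted by ML via eigendecomposition of the
  relationship matrix `2 Phi` and a profiled heritability ratio;
- optional stratification correction with principal-component scores
  computed from synonymous variants only.

The fraction of tests with P < 0.05, cross-classified by the functional
type (synonymous / nonsynonymous) of the common variant and of the rare
set, is the quantity of interest, alongside within-gene LD summaries
(mean |rho| of genotype scores) and paired unrelated-vs-family
comparisons on identical rare sets.

Because the motivating exome dataset is access-restricted, the package
includes a first-class synthetic-data generator: Balding–Nichols
structured-population founder haplotypes with an optional rare–common
coupling knob, pedigree templates, and gene dropping of whole gene
haplotypes (no within-gene recombination).  See the vignette
(`vignettes/rare-common-genotype-correlation.Rmd`) for the model,
parameter choices, and what the generator does and does not emulate.

## Worked example

```r
library(synthcorr)

bundle <- run_pipeline(list(
  seed = 101,
  simulate = list(
    n_genes = 600, n_unrelated = 697,
    model = list(n_populations = 2, divergence = 0.1),
    families = list(n_families = 100, template = "nuclear", n_children = 5)
  ),
  ld = FALSE
))

attr(bundle$unrelated$tally, "overall")$pct_significant
#> [1] 8.708415
attr(bundle$family$tally, "overall")$pct_significant
#> [1] 20.65344
colMeans(bundle$comparison[, c("n_rare_unrelated", "n_rare_family")])
#> n_rare_unrelated    n_rare_family
#>         2.237815         1.398319
```

One structured founder pool (two populations, F = 0.1) feeds both
cohorts: 697 unrelated individuals, and 100 nuclear families (700
members) gene-dropped from 200 founders.  The unrelated sample shows an
8.7% nominally significant rate (inflation above 5% reflects the
uncorrected population structure); the family sample more than doubles it
(20.7%) because whole-haplotype segregation induces gametic phase
disequilibrium between rare and common variants — the kinship random
effect in the family model accounts for relatedness of the response, not
for this genotypic coupling, which is the phenomenon under study.  The
mean number of rare variants per test drops from 2.24 to 1.40 in the
families as founder effects silence rare alleles.

`run_pipeline(cfg, out_dir = "...")` additionally writes every table
(classification, gene selection, per-test results, tallies, LD, paired
comparison, pedigree, and a YAML manifest) as plain TSV.

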