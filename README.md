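# mpsscore

Multiparametric severity scoring of missense mutations in
N-sulfoglucosamine sulfohydrolase (SGSH), the lysosomal sulfatase
deficient in mucopolysaccharidosis type IIIA (MPS-IIIA, Sanfilippo
syndrome type A).

Most MPS-IIIA alleles are single amino-acid substitutions that impair
enzyme *biogenesis* — folding, maturation, trafficking — rather than
catalysis, which makes them candidates for pharmacological-chaperone
therapy.  `mpsscore` is for researchers and variant curators who need a
standardised, evidence-explicit severity estimate for such mutations: it
scores each substitution on ten biogenesis-related parameters and
characterises the resulting score distribution and its genotype–phenotype
correlations.

## The score

For a substitution at residue *i*, ten binary evidence parameters are
evaluated (stability is 0–2, double weight), and the total

&nbsp;&nbsp;&nbsp;&nbsp;*S* = p₁ + p₂ + … + p₁₀ ∈ [0, 11]

accumulates: codon/tRNA-abundance drop (p₁), aggregation hot-spot gain on
the sliding-window propensity profile (p₂), external stability-predictor
call (p₃, 0–2), secondary-structure element breakage by Chou–Fasman
propensity (p₄), heavy-atom proximity ≤ 8 Å to the catalytic site (p₅),
N-X-[S/T] sequon loss/gain or proximity to a glycosylated Asn (p₆),
proline/glycine/cysteine involvement (p₇), surface polarity or formal
charge-class change (p₈), alignment-column conservation ≥ 60 % (p₉), and
calcium-ligand / dimer-interface involvement (p₁₀).

Genotypes: a homozygote scores its allele total; a compound heterozygote
scores the **product** of its two allele totals (the sum is kept for
comparison — the product is the better severity predictor).

Bands against the catalogue mean ± 1 SD classify mutations as low
(< 3), moderate (3–6) or high (> 6) expected impact.

## Worked example

```r
library(mpsscore)

cat86 <- table1_dataset()           # bundled reference catalogue
cat86
#> <mutation catalogue> 86 mutations at 72 positions (totals 0..7)
#> provenance: bundled SGSH missense catalogue (86 mutations)

s <- describe_distribution(cat86$total)
s
#> n = 86, mean 4.4419, sd 1.5986
#> skewness G1 -0.4757 (SES 0.2597); kurtosis G2 -0.2833 (SEK 0.5139)
#> D'Agostino-Pearson K2 = 3.5512, p = 0.1694

table(score_band(cat86$total, s$mean, s$sd))
#>      low moderate     high
#>       10       70        6

h <- score_histogram(cat86$total, 0, 11)
fit_gaussian(h$count, h$center)
#> Gaussian fit: A 20.7381, mean 4.6861, sd 1.6819 (df 9)
#> R2 0.9355, SS_res 45.8976, sy.x 2.2583

compound_score(5, 3, "product")     # e.g. Arg245His x Ser298Pro
#> <genotype score> product = 15
```

The mean score of 4.44 sits far from zero — every catalogued mutation is
predicted to perturb biogenesis to some degree — and ~81 % of mutations
fall within one SD of the mean (the 10/70/6 partition above).  The
Gaussian fitted to the 12-bin score histogram (mean 4.69, SD 1.68,
R² = 0.94) summarises that near-normal shape.

De-novo scoring runs against an explicit evidence bundle; the packaged
synthetic bundle demonstrates the mechanics end to end:

```r
tb <- make_toy_bundle()             # synthetic 60-residue protein + evidence
score_all(parse_mutation_label("Cys26Ser", mut_codon = "AGC"), tb$bundle)
#> <parameter scores> Cys26Ser: [0 0 0 0 1 0 1 0 0 1] total 3
```

Cohort analysis with the synthetic patient generator:

```r
coh <- synth_cohort(seed = 1, n_patients = 200, link = "multiplicative")
r <- run_cohort(coh, table1_dataset())
r$spearman$product$rho              # 0.682 (sum mode: 0.683 on this seed)
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/mpsscore.R`
(`Rscript mpsscore.R score|stats|cohort|fixtures --config run.yaml --out DIR`).

## Package layout

* `R/` — catalogue I/O, evidence-bundle readers and validation, the ten
  parameter scorers, score aggregation and banding, distribution
  statistics, cohort analysis, fixtures, reporting.
* `inst/extdata/` — bundled scored catalogue (TSV), raw pre-selection
  list, human codon-usage table.
* `vignettes/multiparametric-scoring.Rmd` — the methods vignette: model,
  conventions, design decisions, generator calibration, limitations.
* `tests/testthat/` — unit, property and acceptance tests (brute-force
  oracles for hot-spot detection and tied-rank correlation, frozen
  cross-implementation checks for the omnibus normality statistic).
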