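# carbotrait

Genotype-to-phenotype analysis of carbohydrate utilization in
*Oenococcus oeni*, the lactic acid bacterium that drives malolactic
fermentation in wine.

Strains of *O. oeni* differ widely in which wine sugars they can grow on,
but the genetic basis is hard to read off the genomes: most carbohydrate
genes are in the core genome, phenotype loss usually comes from
pseudogenization (truncating point mutations) rather than gene loss, and
isoforms frequently complement one another. `carbotrait` provides the
analysis layer for exactly this situation, over two simple data objects —
a binary strain × sugar `PhenotypeMatrix` and a strain × gene
`GeneStateMatrix` with four functionality states
(`ABSENT` / `PSEUDOGENE` / `SINGULAR` / `INTACT`):

* **Phenotyping** — assay-threshold growth calls (colour change plus
  > 10 mM lactate = positive, < 5 mM = negative), per-sugar usage counts and
  half-up-rounded percentages, per-strain totals, bins, branch means and
  preference order.
* **Gene-trait association** — 2×2 functionality × phenotype tables,
  two-sided Fisher exact p (point-probability rule), Benjamini–Hochberg FDR
  within sugar, perfect-separation flags, and a lineage-aware permutation
  test (|log OR| with Haldane correction, phenotypes shuffled only within
  phylogenomic branches) guarding against the species' strong lineage
  confounding.
* **Pathway logic** — monotone OR-of-AND `PathwayModel` rules (phenotype
  positive ⇔ some route has every isoform group containing ≥ 1 functional
  gene), concordance reports with named discordant strains, complementation
  (rescue) detection, and exhaustive inference of all minimal
  maximal-concordance rules within user-set bounds.
* **Stoichiometry** — carbon-balanced yield vectors for homolactic EMP
  (2 lactate/hexose), phosphoketolase (1 lactate + 1 ethanol + 1 CO2) and the
  mannitol-sink dismutation (1/3 lactate + 1/3 acetate + 2/3 mannitol +
  1/3 CO2); convex-combination yield prediction and simplex grid-search flux
  fitting with masked and upper-bounded axes.
* **Synthetic data** — fully seeded Yule trees, three-state gene
  gain/loss/pseudogenization histories with replayable event logs,
  rule-driven phenotypes with recorded flip noise, and recovery benchmarks.

A transcription of the published 41-strain × 18-sugar growth table ships as
the `table1` fixture, together with prose-derived gene-state fixtures and
per-sugar pathway rules (`loadFixture()`, `fixtureNames()`,
`fixtureEvidence()`).

## Worked example

```r
library(carbotrait)

tab <- loadFixture("table1")
head(substrateUsage(tab), 8)
#>         sugar count percent
#> 1     glucose    41     100
#> 2   trehalose    40      98
#> 3  cellobiose    39      95
#> 4      ribose    37      90
#> 5     mannose    36      88
#> 6   melibiose    32      78
#> 7 L-arabinose    23      56
#> 8    fructose    19      46

binStrainTotals(tab)
#>  <=4  5-9 >=10
#>    5   30    6

groupMeanUsage(tab)
#>   branch  n  mean_raw mean_rounded
#> 1      A 29  6.103448            6
#> 2      B 11  9.545455           10
#> 3      C  1 11.000000           11
```

Every strain in the table grows on glucose; trehalose is used by 98% of
strains; the five never-used sugars sit at 0%. Branch A strains (the
"domesticated" lineage) use about 6 sugars on average, branch B about 10.

Pathway rules evaluate gene functionality with complementation. In the
arabinose rule, a truncated `araD` can be rescued by the accessory isomerase
`araD1`, but a truncated `araA` cannot:

```r
pred <- predictPhenotypes(loadFixture("arabinose_states"),
                          loadFixture("rules/arabinose"))
subset(pred, strain %in% c("AWRI_B429", "IOEB_0607", "AWRI_B419"))[, 1:3]
#>       strain predicted n_active_routes
#> 4  AWRI_B429  NEGATIVE               0
#> 9  AWRI_B419  POSITIVE               1
#> 27 IOEB_0607  NEGATIVE               0
```

Fermentation yields: an equal flux split between the homolactic EMP route
and the phosphoketolase route predicts 1.5 mol lactate per mol fructose, and
fitting the observed lactate/acetate/mannitol profile of the
homolactic-leaning strain recovers that split:

```r
predictYields(c(EMP_homolactic = 0.5, PK_ethanol = 0.5))
#>  lactate  acetate  ethanol mannitol      CO2
#>      1.5      0.0      0.5      0.0      0.5

s19 <- fermentationProfile("S19",
  c(lactate = 1.5, acetate = 0.2, mannitol = 0.1),
  bounds = c(mannitol = "le"))
fitFluxSplit(s19, builtinRoutes()[c("EMP_homolactic", "PK_ethanol")])
#> FluxSplit: EMP_homolactic=0.500, PK_ethanol=0.500 (residual 0.2)
classifyFermentationMode(s19)
#> [1] "homolactic-dominant"
```

`runReferenceAnalysis("out/")` regenerates the full packaged analysis —
summary statistics plus the concordance of all seven per-sugar rules —
writing `summary.json` and `concordance.tsv`.

## The methods vignette

`vignettes/carbohydrate-genotype-phenotype.Rmd` documents the models and
their assumptions, the functionality policy, the rule-inference search and
its minimality criterion, the stoichiometric conventions, what the synthetic
generator does and does not emulate, and the numerical choices (rounding,
tie-breaking, degenerate inputs).
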