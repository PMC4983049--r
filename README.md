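# pmca

Cytological deconvolution of bulk transcriptomes by permutation-based
maximum covariance analysis.

## What problem this solves

Bulk RNA-seq of a heterogeneous tissue averages over cell states. When the
*same* samples are also scored cytologically — so that each sample carries a
compositional vector of cell-substage frequencies — the covariance between
the two blocks can be decomposed to assign genes to the substages whose
frequencies their expression tracks. The motivating design is the first
wave of mouse spermatogenesis: germ cells sampled across juvenile
development, immunolabeled for SYCP3 / γH2AX / STRA8 / H1T to classify
each cell into spermatogonia or one of seven meiotic prophase substages,
with RNA-seq on the same samples. The package is for computational
biologists who have such paired composition + expression data (or want to
study the method itself) and need gene-to-substage assignments with a
controlled false positive rate.

## The method

With $X$ the substage × sample frequency matrix (columns sum to 1) and $Y$
the gene × sample log-expression matrix, both row-centered:

$$C = \tfrac{1}{n}\tilde X\tilde Y^{\mathsf T} = U\Sigma V^{\mathsf T},
\qquad P_x = U^{\mathsf T}\tilde X,\qquad
Z_x = \tilde X P_x^{\mathsf T},\; Z_y = \tilde Y P_x^{\mathsf T},$$

with every row of $Z_x$ (cyto-patterns) and $Z_y$ (gene patterns) divided
by its root mean square (divisor $p-1$ for $p$ substages). A compositional
$X$ loses one degree of freedom, so 6 substages give exactly 5 usable
components. A gene is **concordant** with a substage if its pattern lies
within a window $w$ of the substage's cyto-pattern on every component up to
the chosen depth, and **negatively concordant** if it lies within $w$ of
the negated cyto-pattern. The width $w$ is calibrated by permuting
expression sample labels, re-running the entire pipeline, and choosing the
largest width whose estimated false positive rate at the third component is
≤ 0.05. See `vignettes/pmca-methods.Rmd` for the full account.

## Worked example

Everything below runs from the package's own synthetic generator — no
downloads. The generator plants 30 concordant and 30 negatively concordant
genes per substage (8-fold programs, 10 % multiplicative noise) in a
2,000-gene, 6-substage × 28-sample first-wave-like design.

```r
library(pmca)

cfg  <- simulationConfig(seed = 1)
cyto <- simulateCytology(cfg)
sim  <- simulateExpression(cfg, cyto)
expr <- logTransform(sim$expression)

rep <- selectWidth(cyto, expr, nPermutations = 100, seed = 2)
rep
#> WidthSelectionReport: 20 candidate widths, 100 permutations
#>   chosen width 0.0895214 (FPR <= 0.05 at component 3); seed 2

round(fprGrid(rep)[match(chosenWidth(rep), rep@candidateWidths), ], 4)
#> depth1 depth2 depth3 depth4 depth5
#> 0.6085 0.1485 0.0350 0.0090 0.0035

fit <- pmcaFit(cyto, expr, width = chosenWidth(rep))
fit$assignment
#> AssignmentResult: width 0.08952 , depth 5
#>   concordant genes: 49 | negatively concordant: 23 | excluded: 0

rec <- scoreRecovery(fit$assignment, sim$truth)
subset(rec, polarity == "concordant")[,
    c("substage", "nPlanted", "nRecovered", "sensitivity", "precision")]
#>                 substage nPlanted nRecovered sensitivity precision
#>            Spermatogonia       30          5   0.1666667 0.6250000
#>             Preleptonema       30          0   0.0000000       NaN
#>           EarlyLeptonema       30          0   0.0000000       NaN
#>   LateLeptonema/Zygonema       30          0   0.0000000       NaN
#>           EarlyPachynema       30         25   0.8333333 1.0000000
#>  LatePachynema/Diplonema       30         15   0.5000000 0.9375000
#>                  overall      180        45   0.2500000 0.9183673

pcaConcordance(cyto, expr)$pc1Correlation
#> [1] 0.9818
```

Reading the numbers: the permutation calibration picks a window of ~0.09 on
the normalized pattern scale; at that width only 3.5 % of genes would be
assigned at depth 3 if expression were independent of the composition, and
0.35 % at full depth. On the real (here: planted) data the assignments are
highly precise, and sensitivity is high exactly for the substages whose
frequencies actually vary over the time course (early/late pachynema);
substages with near-constant composition — the generator mimics that too —
are intrinsically refractory, because their proportion carries almost no
signal into the mixture. The PC1 concordance of 0.98 between independent
PCAs of the two blocks is the feasibility check for combining them at all.

End-to-end runs with declared outputs and a manifest:

```r
res <- runPmca(runConfig(cytology = cyto, expression = sim$expression,
                         outDir = "pmca_out", width = NULL,
                         nPermutations = 100, seed = 1))
```

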