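# methcart

Clone-level CpG methylation calling and decision-tree classification for
targeted bisulfite amplicon sequencing.

## The problem

Epigenetic silencing of the mismatch-repair gene *MLH1* in normal human
hematopoietic stem and progenitor cells is studied by sequencing two
bisulfite PCR amplicons of the *MLH1* promoter (Fragment 1, −938..−483,
38 CpG sites; Fragment 2, −596..−337, 16 CpG sites; coordinates relative
to the transcription start site at 0) from single colony-forming-cell
(CFC) clones, each tagged with a 9-bp barcode. The analytical question:
given per-clone, per-CpG methylation frequencies, can the binary *MLH1*
expression status of a clone be predicted from its promoter methylation
pattern?

`methcart` implements the full analysis as a tidy, testable R pipeline:

1. **Demultiplex** multiplexed reads by exact 9-bp barcode.
2. **Trim and orient** reads by primer match; **align** to the theoretical
   bisulfite-converted reference (assay on the minus strand: a methylated
   CpG reads `CG` in plus sense, an unmethylated one `CA`; every non-CpG
   minus-strand C reads `A`); filter at > 70% identity.
3. **Score** CpG sites per read (`CG` → 1, `CA` → 0, else `NA`) and
   estimate bisulfite conversion efficiency from non-CpG positions.
4. **Correct PCR amplification bias** with the two-template hyperbola
   `o = m / (m + b(1 − m))`, calibrating `b` from 1:0, 1:1, 0:1
   methylated:unmethylated control mixtures (`b = (1 − o_half)/o_half`)
   and inverting `m = ob / (1 − o + ob)`, clamped to [0, 1].
5. **Compare groups** per site (two-tailed pooled-variance t-tests, with
   BH q-values alongside) and by univariate logistic regression.
6. **Classify** clones with a from-scratch CART over site frequencies:
   node deviance `D_i = −2 Σ_k n_k ln(n_k/n)`, exhaustive deviance-minimal
   splits, stopping at `n < 10` cases or node deviance below 1% of the
   root, and cost-complexity pruning minimizing `D(T) + k·size(T)` with
   `k = 2` (AIC).

A synthetic read generator (pattern and two-template modes, conversion
failures, substitution/indel noise, amplification bias) stands in for the
sequencing run, so every stage is testable offline. The packaged
reference sequence is synthetic (CG dinucleotides exactly at the assay
coordinates); the published 30-clone cohort table ships in
`inst/extdata/`.

## Worked example

```r
library(methcart)

ref <- mlh1_promoter()
res <- run_pipeline(pipeline_config(
  out_dir = "run1", seed = 1,
  simulate = list(n_expressing = 10, n_nonexpressing = 20,
                  depth = c(600, 1500)),
  controls = list(bias_b = 1.5, n = 5000)), ref)

res$aggregate
#> # A tibble: 2 × 6
#>   fragment  mean_expressing mean_nonexpressing t_statistic  p_value    df
#>   <chr>               <dbl>              <dbl>       <dbl>    <dbl> <dbl>
#> 1 Fragment1           0.223              0.505       -29.6 8.33e-43    74
#> 2 Fragment2           0.245              0.504       -20.2 5.17e-19    30

glance(res$tree)
#> # A tibble: 1 × 8
#>    size deviance root_deviance     k cost_complexity misclassified misclass_rate
#>   <int>    <dbl>         <dbl> <dbl>           <dbl>         <int>         <dbl>
#> 1     3        0          38.2     2               6             0             0

print(res$tree)
#> <meth_cart> size 3, deviance 0.000 (pruned, k = 2)
#> A(branch n=30 D=38.191 mis=10/30)
#>   f1.-608 < 0.188836: P(leaf n=9 D=0.000 mis=0/9)
#>   f1.-608 >= 0.188836: A(branch n=21 D=8.041 mis=1/21)
#>     f1.-896 < 0.172616: P(leaf n=1 D=0.000 mis=0/1)
#>     f1.-896 >= 0.172616: A(leaf n=20 D=0.000 mis=0/20)
```

Reading the output: the simulated cohort draws expressing clones from a
low-methylation regime and non-expressing clones from a higher,
heterogeneous one, so the aggregate per-site comparison is strongly
significant (p = 8.3e-43 for Fragment 1: group mean frequencies 0.22 vs
0.51). The root deviance 38.19 is the 10/20 class mix; the pruned tree
(size 3, cost-complexity 0 + 2·3 = 6) first sends clones with corrected
methylation below 0.189 at site −608 to an expressing (P) leaf, then
separates the rest at site −896, classifying all 30 training clones
correctly. The run's conversion-efficiency QC (here 99.95%, reflecting
the simulated conversion-failure and substitution noise) is in
`res$conversion_efficiency`. With real demultiplexed FASTQ data, point
`pipeline_config(reads_path =, sample_sheet_path =)` at your files
instead.

Useful entry points: `demultiplex()`, `trim_reads()`,
`align_to_reference()`, `score_reads()`, `build_matrix()`,
`fit_hyperbolic()` / `correct_matrix()`, `compare_sites()`,
`meth_cart()` / `prune_tree()` / `predict()` / `tidy()` / `glance()`,
`autoplot()` (methylation heat map, tree diagram), `cart_to_json()`.

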