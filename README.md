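# lmindex

Quantifying the differentiation state of a transcriptome, and screening
drug-response compendia for treatments that push malignant cells toward
maturity.

Differentiation therapy — ATRA in acute promyelocytic leukemia is the
classical case — induces leukemic blasts to mature instead of killing them.
Finding new drugs with that activity in public expression compendia
requires a scalar readout of *where along a lineage* a profile sits.
`lmindex` provides that readout, the **Lineage Maturation Index (LMI)**,
for anyone analyzing bulk or single-cell log2 expression matrices of
hematopoietic (or other staged) lineages, plus the batch-controlled
screening machinery to rank candidate differentiation-inducing drugs.

## The score

Fix an immature endpoint profile **a** (e.g. hematopoietic stem cells) and
a mature endpoint **b** (e.g. granulocytes), both replicate-averaged, and
keep only the *N* genes with at least a 4-fold endpoint difference
(|b<sub>i</sub> − a<sub>i</sub>| ≥ 2 log2 units, inclusive). The LMI of a
sample **c** is the scalar projection of **c** − **a** onto the lineage
vector **b** − **a**:

```
LMI(c) = (b − a)·(c − a) / ‖b − a‖
       = Σᵢ (bᵢ − aᵢ)(cᵢ − aᵢ) / sqrt(Σᵢ (bᵢ − aᵢ)²)
```

0 at the immature endpoint, ‖b − a‖ at the mature one, linear in between;
larger = more differentiated. In a screen, each treated array's
**ΔLMI** is its LMI minus the mean LMI of the vehicle (DMSO) controls in
its experimental batch; treatments are ranked by mean ΔLMI and tested
against controls with a two-sided (Welch by default) t-test.

## Worked example

Simulate an 8-stage myeloid-like lineage, build the reference vector from
its endpoints, score the stages, then screen a simulated 50-drug batched
compendium with 5 planted differentiation inducers:

```r
library(lmindex)

sim <- simulate_lineage(lineage_sim_config(seed = 2))
vec <- build_lineage_vector(sim$truth$a_star, sim$truth$b_star)
vec
#> LineageVector: 200 genes, |b - a| = 43.02 (threshold 2 log2)

lmis <- compute_lmi_table(vec, sim$matrix)
transform(lmis, relative = round(relative_maturity(vec, lmi), 3))
#>     sample         lmi relative
#> 1 stage_01 -0.06196903   -0.001
#> 2 stage_02  6.25141938    0.145
#> 3 stage_03 12.16130434    0.283
#> 4 stage_04 18.10210716    0.421
#> 5 stage_05 24.50470069    0.570
#> 6 stage_06 30.51897035    0.709
#> 7 stage_07 37.22609340    0.865
#> 8 stage_08 43.20945587    1.004
```

The 200-gene filter recovered the planted signature, and despite 0.2 log2
units of per-value noise the eight developmental stages score in perfect
order, from ≈ 0 (immature endpoint) to ≈ ‖b − a‖ = 43.02 (mature
endpoint). Now the screen:

```r
scr <- simulate_screen(screen_sim_config(seed = 2), vec)
dl  <- compute_delta_lmi(compute_lmi_table(vec, scr$matrix), scr$annotation)
res <- screen(dl, scr$annotation)
top_k(res, 6)
#>  rank treatment n_treated mean_delta_lmi t_statistic  p_value significant
#>     1  drug_048         3         12.985       220.4 5.94e-14        TRUE
#>     2  drug_021         3         12.980       159.7 5.87e-09        TRUE
#>     3  drug_006         3         12.821       241.6 1.49e-08        TRUE
#>     4  drug_015         3         12.814       162.2 1.27e-13        TRUE
#>     5  drug_032         3         12.757       116.2 9.59e-06        TRUE
#>     6  drug_041         3          0.112         1.9 1.01e-01       FALSE

scr$truth$positives
#> [1] "drug_006" "drug_015" "drug_021" "drug_032" "drug_048"
```

The five planted positives occupy exactly the top five ranks: their mean
ΔLMI of ≈ 12.9 log2-units is 0.3 × ‖b − a‖, the planted 30 %-of-lineage
maturation shift, and all five are flagged at p < 0.05 while the first
null drug is not.

The same pipeline from the shell:

```sh
lmi simulate lineage --seed 2 --out-dir sim
lmi build-vector --matrix sim/matrix.tsv --annotation sim/annotation.tsv \
    --immature stage_01 --mature stage_08 --out-dir vec
lmi screen --vector vec/lineage_vector.tsv --matrix scr/matrix.tsv \
    --annotation scr/annotation.tsv --out-dir out
lmi report --screen out/screen_result.tsv --top-k 20
```

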