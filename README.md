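# droughtnet

Cross-variety hormone co-expression network analysis for long-term drought
time courses.

## The problem

Long-term drought reshapes hormone signaling in plants, and different
varieties of the same species respond with different genes. A way to find
the regulation they *share* is: call differentially expressed genes (DEGs)
per treatment stage in each variety, correlate the abundances of
hormone-pathway DEGs with each other and with measured hormone levels,
keep only edges that are significant under both Pearson and Spearman
correlation, and intersect the drought networks of the two varieties at
the protein-family level. The node with the most neighbours in that common
network is the pivotal hub of the shared drought response — in the study
this package re-implements, the clade-A protein phosphatase 2C (*PP2C*)
family of the ABA pathway.

droughtnet is that analysis as a reusable, tested R pipeline, for anyone
with a two-condition, multi-stage, replicated expression + hormone design:

- **DEG calling**: per stage, Welch's t on log2(FPKM + 1), BH-adjusted;
  a DEG has fold change ≥ 2 *and* FDR < 0.01. Stage-overlap (Venn) and
  cross-variety common-DEG accounting via a homolog map.
- **Consensus networks**: per variety × condition, an edge needs
  |coefficient| > 0.7 and p < 0.05 under **both** Pearson and Spearman.
- **Differential + common network**: gained/lost/stable edges between
  conditions; drought edges collapsed to protein families (mean signed
  coefficient; both signs ⇒ a *mixed* edge, minority-sign variety
  labelled) and intersected across varieties.
- **Hub identification**: degree = distinct neighbours; maximal-degree
  node(s) are pivotal.
- **Duncan's multiple range test** with compact letter displays for
  hormone/phenotype group comparisons.
- **Synthetic data**: a generator that emulates the 2-variety × 2-condition
  × 5-day × 3-replicate design with planted DEGs, a planted hub module and
  drought-responsive ABA/IAA profiles, plus a deterministic fixture that
  reproduces the published network topology end-to-end. The whole package
  validates with no external data.

Formally, for samples of one variety × condition, an edge between nodes
u, v (gene abundances on log2(FPKM+1), hormones in ng/g) requires

    |r_P(u,v)| > 0.7, p_P < 0.05   and   |r_S(u,v)| > 0.7, p_S < 0.05

with p-values from t = r·√((n−2)/(1−r²)) on n−2 df. Duncan's test uses
critical ranges R_p = q(1−α_p, p, df_err)·√(MSE/n_h), α_p = 1−(1−α)^(p−1).

## Worked example

The bundled deterministic fixture runs the full pipeline and reproduces
the published topology:

```r
library(droughtnet)
fx  <- fig4_fixture()
res <- run_pipeline(fx$expr, fx$design, fx$hormones, fx$pathways,
                    fx$homologs)
res$common
#> Common network (K326 & BX; drought-present): 6 family-level edges
#>  family_a  sign family_b mean_pos mean_neg variety_labels
#>     A-ARR     -     PP2C       NA  -0.8118
#>       ABF     +     PP2C   0.8118       NA
#>       BZR     -     PP2C       NA  -0.8118
#>       GID     +     PP2C   0.8118       NA
#>       IAA mixed     PP2C   0.8118  -0.8118             BX
#>      PP2C     +    SnRK2   0.8118       NA
head(res$hub_report, 3)
#>    node degree rank is_pivotal
#> 1  PP2C      6    1       TRUE
#> 2 A-ARR      1    2      FALSE
#> 3   ABF      1    2      FALSE
```

Read: every common edge involves PP2C (positive with ABF/SnRK2/GID,
negative with A-ARR/BZR); the PP2C–IAA edge is mixed because variety BX
contributes an additional negative gene-level correlation (hence the "BX"
label); PP2C has strictly maximal degree — it is the pivotal hub.

On a synthetic study, hormone group comparisons look like:

```r
st  <- simulate_study(sim_config(seed = 1))
sel <- st$design$variety == "K326" & st$design$day == 2
duncan_mrt(split(st$hormones["ABA", st$design$sample_id[sel]],
                 st$design$condition[sel]))
#> Duncan's multiple range test (alpha = 0.05, df = 4, MSE = 301.6)
#>    group      mean n letters
#>  drought 176.33383 3       a
#>  control  63.36388 3       b
```

Distinct letters: drought ABA at day 2 (planted 3× elevation) is
significantly higher than control.

## Command line

```sh
Rscript inst/cli/droughtnet.R simulate --out data/ --seed 42
Rscript inst/cli/droughtnet.R run-all \
    --expression data/expression.tsv --samples data/samples.tsv \
    --hormones data/hormones.tsv --pathways data/pathways.tsv \
    --homologs data/homologs.tsv --out results/
```

Subcommands: `simulate`, `deg`, `network`, `diffnet`, `common`, `hubs`,
`duncan`, `run-all`. Flags override a `--config` YAML/JSON file; outputs
carry a provenance header; networks export as TSV, SIF and GraphML
(Cytoscape-ingestible).

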