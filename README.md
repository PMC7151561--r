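# netpharm

Network-pharmacology inference for multi-herb formulas.

Traditional multi-herb prescriptions act through dozens of compounds
hitting dozens of protein targets, so their pharmacology is analyzed as a
set of coupled networks rather than as single drug–target pairs. `netpharm`
implements that full inference chain for R users — pharmacologists and
systems biologists studying formula mechanisms — with the eight-herb Xia Qi
Decoction (XQD) against lung cancer as the shipped worked example:

* **ADME screening** of candidate ingredients on oral bioavailability (OB,
  percent) and drug-likeness (DL ∈ [0,1]) with per-herb OB overrides
  (reference policy: OB ≥ 30%, DL ≥ 0.18, Licorice tightened to OB ≥ 50%);
* **typed herb–ingredient–target networks** with degree, unnormalized
  Brandes **betweenness**, Wasserman–Faust component-scaled **closeness**,
  and strict-threshold key-node rules (`degree > 2×mean`, or fixed
  thresholds to consume published values verbatim);
* **PPI subnetworks** at strict confidence > 0.9 with excluded-seed
  auditing and `degree > 2×median` hub detection;
* **disease-target classification** by PPI hop distance — *direct* = set
  overlap (hop 0), *indirect* = within 1–2 interactions, computed by BFS
  with deterministic lexicographic witness paths;
* **hypergeometric pathway enrichment**,
  $p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$ for $k$
  of $n$ query genes in a pathway of $K$ of $N$ universe genes, with the
  p ≤ 0.05, k ≥ 4 filter and BH q-values;
* a per-gene **chi-square screen** for immune-tissue-specific expression
  (gene profile vs pooled background, 2×K contingency, df = K−1) and the
  bipartite gene–tissue network;
* **seeded synthetic-data generators** that plant known ground truth
  (hop distances, an enriched pathway, tissue-dominant genes) so every
  stage is testable offline, plus `run_pipeline()` to orchestrate the
  whole chain deterministically.

## Worked example

```r
library(netpharm)

# 1. ADME screen on the shipped 112-ingredient XQD table
t1 <- load_fixture("table1_ingredients")
screened <- apply_screen(t1, screen_policy(30, 0.18, c(LO = 50)))
nrow(screened)
#> [1] 112                     # the curated table is closed under its policy
per_herb_counts(screened)
#> LO AC PC AT FR PR SC CR
#> 42 19 15 13 13 13  8  5    # shared ingredients count once per herb

# 2. a planted PPI scenario: 5 direct, 7 one-hop, 6 two-hop, 10 unlinked
sc  <- simulate_ppi_scenario(c(d = 5, i1 = 7, i2 = 6, u = 10), seed = 1)
ppi <- build_ppi(sc$interactions, min_confidence = 0.9)
ppi$network
#> pharm_network: 112 nodes ( target 112 ), 251 edges

cls <- classify_disease_targets(sc$formula_targets, ppi$network,
                                sc$disease_genes)
head(cls[cls$category == "indirect", ], 3)
#>    gene category hop     witness
#> 6 P0015 indirect   1 P0047|P0015
#> 7 P0028 indirect   1 P0047|P0028
#> 8 P0056 indirect   1 P0103|P0056
unlist(summarize_classification(cls))
#>       n_direct     n_indirect n_total_linked
#>              5             13             18   # planted truth recovered

# 3. chi-square immune screen on the shipped 8-gene x 14-tissue panel
mat <- load_fixture("table7_expression")
head(chi_square_screen(mat)[, c("gene", "statistic", "df", "p",
                                "significant")], 4)
#>    gene statistic df            p significant
#> 1  LEF1 218.43899 13 2.188920e-39        TRUE
#> 2 ACTA2  80.94912 13 7.311444e-12        TRUE
#> 3 HLA-B  78.60623 13 2.016119e-11        TRUE
#> 4 ADRB2  73.54266 13 1.776590e-10        TRUE
```

The statistic is the Pearson sum over the 2×14 table of a gene's profile
against the pooled profile of the other genes: LEF1's thymus/T-cell spike
deviates most strongly from the HLA-B-dominated background. The indirect
classifications above carry a witness path (`target|…|gene`) of length
equal to the hop count.

See `vignettes/network-pharmacology-methods.Rmd` for the model
conventions, the generator design, numerical choices, and known
limitations.

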