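# glknet

Cross-tissue co-expression network analysis of SLC/ABC transporter and
drug-metabolizing-enzyme (DME) genes, centered on the gut-liver-kidney
(GLK) axis.

## What it is for

Transporters and DMEs are usually studied as drug-handling machinery, but
the same genes move and modify endogenous metabolites between organs. If
two genes are expressed in similar *sets of tissues*, they are candidates
for acting in the same inter-organ pathway. `glknet` turns that idea into
a tested pipeline for systems biologists:

* average a genes × samples expression matrix per tissue and compute
  Pearson correlation **across tissues**, so r measures similarity of
  tissue expression patterns;
* keep the top-*k* correlated pairs among SLC, ABC and Phase 1/2 DME
  genes (default *k* = 10,000, equivalent to r > 0.59 on the 37-tissue
  reference atlas) as an undirected network, and label every gene and
  edge with its tissue of highest (pair-mean) expression;
* count edges per tissue pair into a proximity matrix, order tissues by
  average-linkage clustering on 1 − r between proximity rows, and
  quantify GLK enrichment of the focal classes against size-matched
  random gene sets and a GPCR-like control class (10 replicates,
  mean ± sd);
* rank outside genes by single- and paired-tissue connectivity — the
  paired score is min(count in tissue 1, count in tissue 2), rewarding
  genes wired to *both* organs — and expand the GLK network with the top
  20 per tissue pair;
* filter edges by protein-protein interactions (PCNet-style edge list)
  and prioritize genes by normalized betweenness centrality;
* score gene-family wiring with a hypergeometric tail:
  score = −log10 P(X ≥ x) for x observed inter-family edges given E
  network edges among N = C(n, 2) pairs (display threshold 2 ⇔
  p < 0.01);
* assemble the ADME-centered **remote sensing and signaling (RSS)
  network**: curated core/extended/related ADME genes in the network
  plus their first neighbors, with every edge both co-expressed and
  PPI-supported; and
* compute the percent-overlap statistic used to validate predicted
  transcription-factor targets against knockout/ChIP-seq evidence.

A synthetic-data module (`simulate_glk_default()`) generates expression,
catalog and PPI inputs with planted tissue-specific modules, so the whole
pipeline runs and is testable without any download. See the methods
vignette (`vignettes/glknet-methods.Rmd`) for the model and every default.

## Worked example

```r
library(glknet)

sim <- simulate_glk_default(seed = 1)   # ~1,200 genes, 12 tissues, 48 samples
cfg <- pipeline_config(edge_mode = "top_k", edge_value = 2000, seed = 1)
res <- run_pipeline(sim$expr, sim$design, sim$catalog, sim$ppi, cfg)
#> 335 gene(s) retained after class subsetting
#> PPI filter: 4430 -> 592 edges
#> ADME status counts: core=3, extended=17, related=8, none=227

fr <- res$fractions
sprintf("GLK edge fraction: focal %.3f | random %.4f +/- %.4f | GPCR-like %.4f",
        fr$focal$fraction, fr$random$mean, fr$random$sd, fr$control$mean)
#> "GLK edge fraction: focal 0.825 | random 0.0002 +/- 0.0005 | GPCR-like 0.0000"

res$ordering$order        # gut, liver, kidney cluster together
#> [1] "gut"    "kidney" "liver"  "brain"  "testis"

head(res$pair_rank[["kidney-liver"]], 3)   # planted liver+kidney hubs lead
#>         gene score count_kidney count_liver
#> 1 NR_HUB_006    60           69          60
#> 2 NR_HUB_001    44           70          44
#> 3 NR_HUB_004    16           75          16

head(res$rss_centrality, 5)                # RSS betweenness table
#>             gene betweenness degree
#> 1 KIDNEY_UGT_019   0.1809001      9
#> 2     NR_HUB_003   0.1728506      4
#> 3     NR_HUB_005   0.1595540      5
#> 4  LIVER_CYP_016   0.1387911      5
#> 5     NR_HUB_007   0.1280387      5

validation_overlap(108, 85)$percent        # TF-target validation statistic
#> [1] 78.7
```

Reading the numbers: 82.5% of the top co-expression edges among the
simulated transporter/DME genes map to gut, liver or kidney, versus
essentially zero for random or GPCR-like control sets — the planted GLK
axis is recovered, and those three tissues form the tightest block of the
proximity dendrogram. The planted cross-tissue regulator module
(`NR_HUB_*`) tops the kidney-liver paired-connectivity ranking and ranks
among the most central genes of the RSS network, exactly the behavior
that flags hub transcription factors on real data. The percent overlap
reproduces the published validation arithmetic (85 of 108 associated
genes supported, 78.7%).

`run_pipeline(..., out_dir = "run")` additionally writes every network
(edge-list TSV + GraphML + node table), the proximity CSV, ranking and
centrality TSVs, and a JSON manifest recording the configuration, seed
and all logged counts. A thin command-line wrapper with `simulate`,
`run` and `overlap` subcommands is installed at
`inst/scripts/xtissue.R`.

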