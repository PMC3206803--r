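# taxolit

Quantifying taxonomic bias in ecological research effort by text-mining
bibliographic records.

Most ecological knowledge concentrates on a few taxa — fishes, corals,
kelps, mangroves, seagrasses — while many speciose groups are nearly
absent from the literature. `taxolit` measures that bias. It matches all
unique one- and two-word sequences from titles, author keywords and
abstracts against a WoRMS-style taxonomy registry (resolving synonyms to
valid names, flagging cross-kingdom homonyms), filters records into
ecosystems by exact multi-word phrases ("coral reef(s)", "kelp
forest(s)", "mangrove forest(s)", "seagrass bed(s)/meadow(s)"), and
aggregates the matches into taxon×ecosystem occurrence matrices in which
*papers play the role of individuals*.

On those matrices it computes the standard community-ecology battery:

- **Shannon evenness** `J = -Σ p_i ln p_i / ln S` of paper counts across
  taxa;
- **Chao1 richness** `S_obs + f1²/(2 f2)` (bias-corrected fallback when
  `f2 = 0`), with classic standard errors;
- **average taxonomic distinctness** `Δ⁺` — the mean taxonomic path
  length over all species pairs on a fixed 7-rank ladder, scaled to
  `[0, 100]` — with randomization **funnels** (simulated mean ± 2 sd of
  random subsets of a master pool) as the null envelope;
- **individual-based rarefaction** with exact hypergeometric expectations
  and analytic confidence clouds;
- **effort-versus-richness models**: per-class occurrence probabilities
  (binomial MLE with logit-scale Wald intervals), and a
  `log10(papers) ~ spline(log10(named species))` fit with phylum-level
  random intercepts, whose **residuals** rank classes from over- to
  under-studied relative to their globally named richness.

A seeded synthetic-data generator (`synth_config()`, `make_registry()`,
`make_corpus()`) emits registries, RIS corpora and a plant log of exact
ground truth, so the entire pipeline is testable without external data.

## Worked example

```r
library(taxolit)

cfg  <- synth_config(seed = 42)        # 1,000 records, 200 species, 20 classes
reg  <- make_registry(cfg)
corp <- make_corpus(cfg, reg)
recs <- read_ris(corp$path)
res  <- run_pipeline(recs, reg$registry)
res$summary
#>         ecosystem papers classes species
#> 1      coral_reef    397      20     110
#> 2     kelp_forest     38      16      31
#> 3 mangrove_forest     96      18      55
#> 4    seagrass_bed    108      20      63
```

397 of the 1,000 records carry a coral-reef phrase *and* at least one
taxon name resolvable to phylum level or better; those papers mention 110
species from all 20 classes. The diversity battery for that ecosystem:

```r
av <- abundance_vector(res$species_matrix, "coral_reef")
shannon_evenness(av)                      # 0.797
chao1(av)$estimate                        # 139.6  (se 12.2)
delta_plus(names(av), reg$registry)$delta_plus   # 94.13
```

Evenness of 0.80 means coral-reef papers are spread fairly evenly across
the species they mention; Chao1 estimates ~140 species would appear with
unlimited sampling (110 observed); Δ⁺ near 94 reflects a species set
spanning all three kingdoms. Ranking classes by effort residual:

```r
fit <- fit_effort_richness(effort_table(res$class_matrix, reg$registry))
rank_classes(fit, k = 3)$top[, c("class", "n_papers",
                                 "n_species_worms", "residual")]
#>         class n_papers n_species_worms  residual
#> 1 Plochabraex      225               2 0.7168012
#> 2    Deceluus      137              13 0.7057906
#> 3 Cecrubraeex       58              41 0.4024330
```

The most over-studied class drew 225 papers despite holding only 2 named
species — about 5× (10^0.72) more papers than its richness predicts.

Thin command-line wrappers live in `inst/cli/`: `filter.R` (phrase
filtering to CSV) and `synth.R` (fixture generation from a YAML config).

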