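---
title: "Mining taxonomic bias in ecological literature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining taxonomic bias in ecological literature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxolit)
```

## The problem

Ecological knowledge accumulates unevenly across taxa: a handful of
commercially or ecologically prominent groups (fishes, habitat-forming
corals, kelps, mangroves, seagrasses) attract most research, while many
speciose groups are barely represented in the literature. `taxolit`
quantifies that bias by mining bibliographic records: it recognizes
scientific names in titles, author keywords and abstracts, aggregates them
into taxon-by-ecosystem paper counts, and summarizes the result with
community-ecology statistics in which *papers play the role of
individuals* and taxa the role of species in a community sample.

The pipeline has five stages, each an independent module:

1. **Taxonomy registry** — a WoRMS-style table of valid names and synonyms
   over a fixed seven-rank ladder (kingdom … species).
2. **Corpus** — an RIS-style reader, an exact ecosystem phrase filter, and
   publication-period binning.
3. **Name matching** — all unique one- and two-word sequences per record,
   matched against the registry with synonym resolution.
4. **Community aggregation** — species- and class-level occurrence
   matrices.
5. **Diversity and effort statistics** — evenness, Chao1, taxonomic
   distinctness with randomization funnels, rarefaction, and
   effort-versus-richness residual rankings.

A sixth module generates ground-truthed synthetic registries and corpora
so that every stage is testable exactly, with no external data.

## Name matching

Each record's title, author keywords and abstract are tokenized
(lowercased, hyphens split, punctuation stripped at token edges) and all
unique unigrams and adjacent bigrams are collected; bigrams never span
sentence-final punctuation or keyword boundaries. An n-gram that equals a
registry name (after the same normalization) is a match; matches to
synonyms are credited to the accepted valid name. Three rules shape the
assignment:

* **Phylum-or-better.** A record is retained only if some match resolves
  to phylum rank or below. A kingdom name alone says too little about
  what was studied.
* **Species supersedes genus.** `Velara prima` in a text also produces the
  unigram `velara`; the binomial match supersedes the embedded genus
  match, so the mention is counted once, at species rank.
* **Homonyms.** One normalized name can denote valid taxa in different
  kingdoms. By default such matches are flagged ambiguous and excluded
  (protecting precision); `policy = "all"` assigns them to every
  candidate instead. Genus names that are also common English words are a
  real failure mode of dictionary matching, and the ambiguity flag is the
  hook for dealing with them.

Counting is presence/absence per record: ten mentions of one species in
an abstract count once, but one record may contribute to several taxa and
several ecosystems. Class-level counts therefore satisfy
`class count >= max(member species counts)`, not the sum.

## The ecosystem filter

Records are assigned to ecosystems by exact multi-word phrases (e.g.
"coral reef(s)", "seagrass bed(s)/meadow(s)") in title, author keywords or
abstract — never by single words like "coral", which would sweep in any
study of the organism rather than the ecosystem. Database-generated
keywords (the `ID` tag; "KeyWords Plus"-style fields) are ignored both in
filtering and matching, because they are not chosen by the authors.
Matching is case-insensitive on word boundaries, and hyphens split tokens
so "coral-reef fish" matches.

Period binning defaults to three bins: before 2000, 2000–2006, and
2007–2009. The upper boundaries are inclusive and configurable; 2006
belongs to the middle bin.

## Diversity battery

All statistics operate on a vector of per-taxon paper counts for one
ecosystem (`abundance_vector()`).

**Shannon evenness** is $J = -\sum_i p_i \ln p_i / \ln S$ with
$p_i$ the proportion of papers on taxon $i$ and $S$ the number of taxa
observed. Natural logs throughout; undefined for $S < 2$.

**Chao1 richness** is the classic abundance-based estimator
$\hat S = S_{obs} + f_1^2 / (2 f_2)$, with the bias-corrected fallback
$S_{obs} + f_1(f_1 - 1)/2$ when no doubletons exist, and the matching
classic variance formulas for the standard error. The variant used is
recorded in the result (`$variant`). Note that some software reports the
bias-corrected estimator for *all* inputs; the classic form is the one
used here, and the reported `±` is a standard error, not a confidence
half-width.

**Average taxonomic distinctness** ($\Delta^+$) is the mean taxonomic
path length over all unordered species pairs, presence/absence only.
Path lengths use equal step weights on the seven-rank ladder: congeners
are 2 steps apart (up to the genus and back down), species sharing only
their kingdom 12. Distances are rescaled so that maximum equals 100.
Registries here span several kingdoms, so cross-kingdom pairs exist; they
are joined at a zero-length root above kingdom and take the same maximum
distance of 100. This clamping keeps $\Delta^+$ in $[0, 100]$ and
preserves the ultrametric property; it is equivalent to computing
equal-step distances from the classification *without* the kingdom
column, letting the root sit at kingdom height.

**The distinctness funnel** draws `n_sim` random subsets (without
replacement) of each size $m$ from a master species pool and reports the
simulated mean of $\Delta^+$ and mean ± 2 standard deviations. Observed
ecosystem or period points below the funnel indicate significantly
narrower taxonomic breadth than a random draw of the same size. The
master pool is the union of species observed across all ecosystems and
periods being compared; this is a genuine modelling choice (a
per-ecosystem pool asks a different question) and the pool is therefore
an explicit argument.

**Individual-based rarefaction** uses the exact hypergeometric
expectation
$E[S_n] = \sum_i \left(1 - \binom{N - N_i}{n} \big/ \binom{N}{n}\right)$
with the standard analytic variance (Heck et al. 1975) — the same form
vegan's `rarefy(se = TRUE)` implements — and a normal 95% interval,
truncated below at 1 because any subsample of one paper contains one
taxon. The analytic form was chosen over resampling for determinism.
Binomial coefficients are evaluated through `lchoose()` so large paper
counts do not overflow.

## Effort versus known richness

For each class, research effort (cross-ecosystem paper total) is modelled
against its globally named species richness (valid species in the
registry):

$$\log_{10}(\text{papers}_c) = f(\log_{10}(\text{species}_c)) + b_{p(c)}
  + \varepsilon_c$$

where $f$ is a natural cubic spline with fixed degrees of freedom
(default `spline_df = 3`) and $b_p$ a phylum-level random intercept
absorbing taxonomic non-independence among classes of one phylum. Both
log10 transforms remove the "trumpeting" of variances visible on raw
counts. The random intercept is estimated by iterative shrinkage: fit the
smooth on intercept-adjusted responses, take phylum means of the
residuals, shrink them toward zero by the moment-estimated variance ratio
$\sigma_b^2 / (\sigma_b^2 + \sigma_e^2 / n_p)$, and refit to a $10^{-8}$
convergence tolerance. With fewer than three phyla the random effect is
dropped with a warning. This deliberately stops short of full REML mixed
model machinery: it is deterministic, transparent, and recovers planted
phylum intercepts exactly on noiseless data (a property the test suite
asserts).

The **residual** $\log_{10}(\text{papers}) - \text{fitted}$ is the
effort-corrected study index: positive means over-studied relative to
named richness, negative under-studied. Classes with zero papers cannot
enter the regression (log of zero) and are reported separately as
"unstudied" rather than being silently dropped. Rankings break ties
lexicographically by class name, so they are reproducible.

**Occurrence probability** per class and ecosystem is the intercept-only
binomial MLE (the observed proportion) with a 95% Wald interval on the
log-odds scale; degenerate counts (0 or all) receive a one-sided interval
via a 0.5 continuity adjustment and are flagged.

## The synthetic generator

`synth_config()` defaults define the reference simulation conditions:
three kingdoms, 6 phyla, 20 classes, 200 species, a 15% synonym rate, and
a 1,000-record corpus over 1957–2009. Ecosystem plant rates
(0.50/0.05/0.12/0.17 for coral reef / kelp forest / mangrove forest /
seagrass bed) follow the relative sizes of the four literatures; per-class
mention rates are drawn log-normally so class paper counts show the heavy
right tail real class tables have. Registry names come from a syllable
grammar with a reserved filler lexicon, so prose words and taxon names
can only collide where a homonym is deliberately planted; the plant log
records every planted phrase and mention with its surface form.

What the generator emulates: multi-field records, synonym surface forms,
cross-kingdom homonyms, phrases hidden in database-generated keyword
fields, malformed entries. What it does not: real English prose (so
matching precision against natural-language homonymy — "Conus" the genus
versus "conus" in prose — is exercised only through planted homonyms),
abbreviated binomials ("A. millepora", excluded by design), OCR noise,
and non-English titles. Passing the exact ground-truth tests therefore
demonstrates correctness of the machinery, not field precision/recall on
real abstracts.

The parameter-recovery experiment for the effort model
(`simulate_effort_classes()`) generates 60 classes in 6 phyla from a
known concave effort curve plus phylum intercepts (sd 0.3 in log10 units)
and class noise (sd 0.1), with two classes planted ±1.2 — roughly a
16-fold excess/deficit of papers. Counts stay continuous so planted
deviations are exact in log10 units. The residual–truth correlation is a
stochastic quantity; the test suite measures it over ten replicate
simulations and asserts its median exceeds 0.9, alongside exact recovery
of the planted extremes in every replicate.

## Numerical and design choices

* Period boundaries: inclusive upper bounds, third bin 2007–2009.
* Name normalization: lowercase, hyphen-split, edge punctuation stripped,
  whitespace collapsed; applied identically to registry names and text.
* Registry rows with lineage gaps are rejected (with row numbers), never
  imputed: $\Delta^+$ needs a uniform tree depth.
* Synonym chains must resolve in one hop; anything else is a data error.
* Funnel and generator draws are seeded explicitly; identical seeds give
  byte-identical outputs.
* Problem sizes in the test suite (1,000-record corpora, 50-species
  funnel pools with 2,000-draw envelopes and 10,000 calibration trials,
  ten effort-model replicates) were chosen to estimate each stochastic
  quantity well while keeping the whole suite fast to run routinely.

## Known limitations

* Matching is exact (no fuzzy or abbreviation matching) and confined to
  title/keywords/abstract, mirroring the substantive choice that these
  fields define a *relative* index of research effort — not a complete
  retrieval of every paper about a taxon.
* The homonym flag handles names duplicated *within the registry*; a
  registry name that is also an ordinary English word will still match
  prose. On real corpora that calls for a stop-list, which is out of
  scope here.
* The effort model's shrinkage estimator uses phylum means, which extreme
  classes contaminate slightly; with few classes per phylum the random
  intercepts are noisy. The spline has fixed degrees of freedom — there
  is no automatic smoothness selection.
* Chao1 and rarefaction inherit the "papers as individuals" reading:
  they describe the sampled literature, not the underlying fauna.
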