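---
title: "Methods: from knockout phenotyping tables to regulatory networks"
author: "phenomore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from knockout phenotyping tables to regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomore)
```

## Overview

`phenomore` implements a discovery pipeline for multi-center knockout-mouse
metabolic phenotyping. Starting from a per-mouse measurement table it

1. reduces each gene to a single strain (homozygote preferred, then the
   genotype measured in both sexes),
2. residual-adjusts the two body-mass-dominated readouts (VO2, metabolic
   rate),
3. computes mutant/wild-type mean ratios per gene, parameter, sex and
   phenotyping center,
4. calls percentile outliers into per-(parameter, sex, tail) gene lists
   whose union is the strong-phenotype gene set,
5. tests candidate gene sets for enrichment in those tails by permutation,
6. scores cross-phenotype GWAS association of SNPs with the CPMA
   likelihood-ratio statistic,
7. mines ordered multi-element promoter cassettes (MORE cassettes) shared
   by promoter sets, merges them into MORE sets, and scores genome-wide
   over-representation, and
8. builds regulatory networks from shared MORE sets and validates
   cassette-based phenotype prediction with Fisher's exact test.

Every input can be produced by the synthetic-data generators, so the full
pipeline runs and is testable without any external download.

## Ratio pipeline

**Ratios.** For every (gene, center, sex) cohort and each of the seven
parameters — fasting glucose T0 (mg/dl), glucose-tolerance AUC
((mg/dl)·min, relative), triglycerides TG (mg/dl), body mass BM (g), VO2
(ml/h), metabolic rate MR (energy/h) and RER (dimensionless) — the ratio is
the mutant mean divided by the wild-type mean of the same center and sex.
Cohorts with fewer than 7 mutants per sex are dropped (`min_group_size`,
configurable); this is the cohort size high-throughput screens use as the
power/throughput trade-off. Controls are all wild types of the same center
and sex; no time-windowing is applied because the upstream data do not
carry batch structure the generator could emulate.

**Mass adjustment.** Absolute VO2 and MR scale with body mass, which would
swamp genotype effects. Within each (center, sex) stratum a linear model
`value ~ mean_body_mass` is fitted over mutants and wild types jointly and
the adjusted value is the residual plus the prediction at the stratum mean
mass. This keeps the readout's scale and stratum mean while making the
adjusted values exactly uncorrelated with mass (the tests assert
|r| < 1e-10); the operation is idempotent. Strata with fewer than three
animals cannot support a regression and are skipped with a warning.

**Outlier calling.** Ratios are pooled per (parameter, sex) across centers
— a gene phenotyped in several centers keeps one row per center, because a
center-merge rule would have to be invented. Empirical quantiles use the
linear-interpolation definition (R type 7); a gene is flagged when its
ratio is *strictly* below the 5% quantile or strictly above the 95%
quantile. Strict inequalities mean heavy ties at the cutoff can only shrink
the flagged fraction, so the combined two-tail flag rate never exceeds 10%.
Distributions with fewer than 20 ratios are skipped. With seven parameters
and two sexes this yields 28 (parameter, sex, tail) lists. The equivalent
parametric thresholds are mean ± 1.645 s.d. (`sd_thresholds()`), 1.645
being the standard normal 0.95 quantile.

**Permutation enrichment.** The statistic for a candidate gene set is the
fraction of its genes flagged in at least one list at the chosen band
(5/95 primary, 20/80 secondary). The null permutes the gene-to-ratio
assignment *within* each (parameter, sex) stratum — strata-wise rather than
global shuffling, so each distribution's shape and flag count are
preserved. The one-sided p-value uses the add-one estimator
(#null ≥ observed + 1)/(N + 1), which cannot return 0. On a single stratum
the null is exactly hypergeometric, which the tests exploit as an
independent oracle.

**Novelty annotation.** Strong-phenotype genes are stratified by prior
knowledge with a sequential filter: a metabolic mammalian-phenotype
annotation (screen-derived rows removed first, to avoid circular
discovery), then metabolic GO biological-process or KEGG Metabolism
membership, classify a gene as known-metabolic; any other annotation (e.g.
GO molecular function only) makes it known-nonmetabolic; otherwise it is
unannotated. Annotation tables are plain inputs; no live database queries
are performed.

## CPMA

For one SNP with p-values $p_1,\dots,p_n$ across $n$ traits (default 16),
let $x_i = -\ln p_i$. Under the null the $x_i$ are unit exponential; the
alternative is exponential with decay rate $\lambda$. The MLE is
$\hat\lambda = n / \sum x_i$ and the likelihood-ratio statistic

$$ T = 2\left(n \ln \hat\lambda - n + \sum_i x_i\right) $$

is referred to a $\chi^2_1$ distribution; the reported score is
$-\log_{10}$ of its upper tail, with scores above 3.1 flagged significant.
The statistic is two-sided: $\hat\lambda$ on either side of 1 gives a
positive value, and the flag uses the score regardless of direction.
P-values are clamped to $[10^{-300}, 1 - 10^{-16}]$ for numerical safety.
Rows with missing trait values are dropped rather than imputed. At
$n = 16$ the $\chi^2_1$ reference is adequate in the calibration range the
package checks: on 50,000 simulated null SNPs the fraction of scores above
$t \in \{1, 2\}$ matches $10^{-t}$ within three binomial standard errors.

SNP QC retains common (MAF ≥ 0.05), bi-allelic, well-called (call rate
≥ 0.75, both inclusive) SNPs and prunes linkage greedily in input order at
r < 0.8; the pruning order is a design choice since no algorithm is
prescribed by the upstream screen. The Bonferroni helper returns the
generic `alpha/n_tests`. Minimum p-values per SNP are binned into reporting
classes with inclusive bounds on the significant side: ≤ 5e-8 genome-wide,
≤ 2.59e-6 lookup-corrected, ≤ 1e-3 suggestive, ≤ 0.05 nominal, weak
otherwise.

## PWM scanning and MORE mining

**Scanner.** Matches are scored by probability-weighted matrix similarity:
the sum over positions of the probability of the observed base, divided by
the maximal attainable sum, giving a score in [0, 1] where 1 is the
per-position consensus everywhere. This MatInspector-style similarity (not
log-odds) was chosen because detection thresholds in the mined cassettes
are expressed on that scale; the default threshold is 0.85, configurable
per matrix. Both strands are scanned (the reverse strand via the
reverse-complemented matrix), windows containing N are skipped, overlaps
are allowed. Coordinates are 1-based inclusive in memory; BED-like writers
emit 0-based half-open.

**Mining.** A MORE cassette is an ordered, strand-oriented tuple of 3–6
TFBS elements with a distance range per adjacent pair. Distances are
measured start-to-start on the forward strand — the original tooling's
convention is not published, so one convention is fixed and applied
consistently by miner and matcher. The miner grows candidates level-wise
(a-priori style): supported ordered pairs with distance windows at most
`dist_var` wide (20 bp, falling back to 30 when nothing is found) and at
least `min_dist` (10 bp) apart are extended one element at a time;
support is recomputed at each extension by a forward-reachability chain
test per promoter, and a cassette is kept when at least `quorum` promoters
(adapted top-down from the set size, floored at 3) contain a valid chain.
Final ranges are tightened to the gaps realised on actual chains
(positions both forward- and backward-reachable). Cassettes whose element
list is a contiguous sub-list of another reported cassette with identical
support are suppressed as non-maximal, and output is canonically sorted so
mining is invariant to input order. Exactness at desk scale was preferred
over heuristics; the search is exponential in the worst case but the
quorum and distance constraints prune it hard at realistic scan densities.

**Sets.** Cassettes identical in elements and order form one MORE set;
cassettes of ≥ 4 elements differing in exactly one position additionally
merge when their support overlap `|A ∩ B| / min(|A|, |B|)` exceeds 0.8
(the overlap denominator is a design choice; only "exceeds 80%" is
prescribed). Grouping is transitive via union-find.

**Matching and enrichment.** A promoter hits a cassette when a valid chain
exists; the mirrored reading (the cassette on the promoter's other strand)
is also tested, which recovers matches missed at mining time. A MORE set
hits when any member cassette hits — detection always uses the individual
cassettes, never a merged consensus. Over-representation of a set in a
test promoter set is observed/expected with expected = |test| × background
rate; a ratio ≥ 2 declares association, and the opposite-direction
phenotype set can be evaluated alongside as a control.

## Networks and prediction

Genes sharing at least one enriched MORE set under the same sub-phenotype
(parameter-sex-direction, e.g. "AUC-mh") are connected; cross-phenotype
sharing is deliberately not an edge, matching the separation of phenotype
areas in the source analysis. Pathway networks connect genes mapping to a
common pathway (optionally restricted to the Metabolism class), and the
overlay labels each union edge `more`, `pathway` or `both`. Prediction
validation bins genes into 0 vs ≥ 1 cassette matches (the observed "1–11"
range in the motivating cohort is a range, not a rule), crosses that with
the has-metabolic-phenotype flag and applies the conventional two-sided
Fisher's exact test (sum of hypergeometric probabilities not exceeding the
observed table's).

## Synthetic data

The generators exist to give every stage inputs with exactly the
statistical structure the methods assume:

- **Phenotypes** (`simulate_phenotypes()`): per center and sex, wild-type
  cohorts around fixed physiological baselines with lognormal
  multiplicative noise (keeps values positive and allows the right-skew
  seen in ratio distributions; coefficient of variation 0.1 by default);
  mutants are the same baselines scaled by configured effects, 7 mutants
  per sex by default, one center per gene. VO2 and MR are linear in body
  mass so that mass explains most of their variance, which is what the
  residual adjustment assumes. RER is generated directly in a
  physiological band around 0.85. Wild-type cohort size is exposed
  (`n_wt_per_sex`, default 50) because the upstream screen does not fix
  it. With all effects 1 and cv 0 every downstream ratio is exactly 1.
- **Promoters** (`simulate_promoters()`): i.i.d. background bases at
  configurable GC (the simplest null for scanner false-positive control),
  601 bp by default, with planted cassettes written as PWM consensi at
  sampled gaps inside the stated ranges; a truth table records exact
  coordinates. Planted sites can in principle be overwritten when several
  cassettes share a carrier — the fixtures avoid this.
- **GWAS p-values** (`simulate_gwas_pvalues()`): null SNPs uniform per
  trait; signal SNPs with −ln p exponential of mean λ > 1.

What the generators do *not* emulate: litter/pedigree structure, batch
and seasonal effects, realistic promoter composition (CpG islands, repeat
content) or linkage structure between SNPs. Passing tests therefore show
the algorithms are correct under their stated assumptions, not that the
biological conclusions transfer to any particular real dataset.

## Numerical choices and problem sizes

- Quantiles: R type 7; strict inequalities at cutoffs.
- Permutation p: add-one estimator; default 10^6 permutations, tests and
  the bundled checks use 10^4, at which Monte-Carlo error is ~0.005.
- CPMA: statistics clamped at 0 against floating-point cancellation.
- Mining: scores at threshold 0.9 on the bundled near-deterministic
  matrices admit only exact consensus matches, which keeps the planted
  fixtures unambiguous.
- Standard test problem sizes, chosen to exercise the asymptotics the
  methods rely on while keeping the default suite fast: 10,000 genes for
  the null flag-rate check, 50,000 SNPs for CPMA calibration, 200-gene /
  30-candidate permutation oracle at 10,000 permutations, 12-promoter
  mining fixtures with 3 carriers.

## Known limitations

- The miner's distance anchoring (start-to-start) and the set-merge
  overlap denominator are fixed conventions where the source methods are
  silent; both are applied consistently and documented here.
- `dedupe_strains()` resolves zygosity/sex preference but does not model
  allele series beyond hom/het.
- The pipeline demo couples planted cassette carriers to a sub-phenotype
  list only illustratively; enrichment significance on real promoter sets
  requires genome-scale backgrounds the demo does not pretend to provide.
- Networks are undirected and unweighted; edge multiplicity is carried as
  annotation, not as parallel edges.
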