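---
title: "Effect masking in pooled association studies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect masking in pooled association studies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratamask)
library(dplyr)
```

## The problem

Case-control association studies usually pool all subjects and ask whether a
genotype is more common among cases than controls. When the genotype's effect
runs in opposite directions in different environments — protective here, risk
promoting there — the pooled odds ratio can sit exactly at 1 while each
environment carries a large, genuine effect. Worse, a causal agent that is
present for *every* subject produces no exposed/unexposed contrast at all, so
no case-control comparison can implicate it, however many deaths it causes.

`stratamask` makes this masking mechanism concrete and measurable. It
provides (i) a generative gene-by-environment-by-cause simulation with fully
explicit penetrance tables, (ii) the stratified and pooled 2x2 machinery used
to analyse such cohorts, and (iii) replicate-based power comparisons between
pooled and partitioned designs. A companion module implements short-peptide
homology scanning and antigenicity-segment calling for molecular-mimicry
style analyses; it shares the package's emphasis on small, exactly testable
primitives.

## The generative model

A *scenario* is a complete description of a simulated population experiment:

* **strata** ("islands"): named subpopulations of fixed size, each with named
  exposures at prevalence 0, 1, or anything between;
* **loci**: biallelic markers with an allele frequency and a sampling mode —
  `binomial` (per-individual draws) or `exact_count` (each stratum receives
  exactly `round(freq * size)` copies of the first allele, in seeded random
  order);
* **a penetrance table**: death probabilities keyed by (genotype, stratum,
  exposure pattern), with a global background mortality as fallback;
* **null loci**: markers drawn independently of everything, for calibration;
* **a master seed**.

The canonical `two_island_fox` scenario places 1,000 rabbits on a snowy
island and 1,000 on an ash-covered island, exactly 500 black and 500 white on
each, with a fox everywhere. Its penetrance table is deterministic: the fox
takes every colour-matched rabbit (black on snow, white on ash) and nothing
else; without the fox nothing dies. `three_island` adds an island with no fox
and an old-age mortality of 0.1 applied equally to both colours — the
reference population that makes the cause estimable. The stratum size of
1,000 is a deliberate default: large enough that odds ratios are stable and
the pooled null is sharp, small enough that a full report runs in about a
second.

Two modelling simplifications are intentional. Genotypes are haploid (one
"colour gene" with two states); diploid genetics, mating and selection
dynamics over generations are out of scope. And cohorts are analysed in
full — every rabbit is observed — rather than case-control sampled;
case-control sampling would only add noise around the same odds ratios and
is left as an extension.

### What the simulation does and does not emulate

The generator produces discrete genotypes, categorical strata, binary
exposures and Bernoulli outcomes under an explicit penetrance table. It does
**not** emulate linkage disequilibrium between loci, population structure,
genotyping error, covariate confounding, or longitudinal follow-up. Passing
tests therefore demonstrate properties of the *analysis machinery* under a
known truth, not robustness to the full messiness of real GWAS data.

## The statistics

All effect measures are odds ratios from 2x2 tables with cells `a` (factor+
cases), `b` (factor+ controls), `c` (factor- cases), `d` (factor- controls):

* **Odds ratio** `OR = (a d)/(b c)`. The deterministic scenarios force zero
  cells, so the default zero-cell policy is Haldane-Anscombe: add 0.5 to
  every cell (before all computations) if and only if some cell is zero. The
  uncorrected ratio is always recorded alongside (`or_raw`), so a run where
  the raw OR is infinite stays visibly infinite while still yielding a
  finite, CI-bearing estimate. A `report_infinite` policy returns the bare
  infinity instead.
* **Tests**: Fisher's exact test (two-sided, summing tables with probability
  at most that observed) whenever any raw cell is below 5, otherwise the
  Pearson chi-square without continuity correction. The continuity
  correction is omitted deliberately: sparse tables are already routed to
  the exact test, and the uncorrected statistic matches its nominal
  chi-square reference better at the moderate counts where it is used. The
  choice made is recorded in each estimate's `method` field. P-values are
  always computed on the raw (uncorrected) counts; the zero-cell policy
  affects only the estimate and its Wald interval
  `exp(log OR ± z * sqrt(1/a + 1/b + 1/c + 1/d))`.
* **Mantel-Haenszel pooling** `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i /
  n_i)` with the Robins-Breslow-Greenland variance for the log estimate and
  the Mantel-Haenszel chi-square for the p-value. A continuity correction is
  applied per stratum *only* when every summand on one side vanishes —
  otherwise the estimator is left exact, which is what makes the two-island
  pooled null an integer identity (`sum(a_i d_i / n_i) = 250 = sum(b_i c_i /
  n_i)`).
* **Woolf heterogeneity** `X^2 = sum w_i (log OR_i - log OR_bar)^2` with
  inverse-variance weights on Haldane-corrected counts, chi-square with
  `strata - 1` degrees of freedom. This quantifies "risk here, protective
  there" directly.
* **Multiplicity**: Benjamini-Hochberg step-up within each analysis mode,
  across all loci and partition cells of that mode. "Detection" means
  BH-adjusted p below `alpha`, default 0.05; the parable itself fixes no
  significance convention, so the conventional one is used and is a
  parameter everywhere.

## Partitioned analysis and power

`stratified_scan()` crosses the levels of the chosen stratification
variables into partition cells, builds every (locus, cell) table, and flags
detections per mode. Cells smaller than `min_cell_size` (default 10) are
skipped with a warning rather than contributing unstable estimates; a locus
monomorphic within a cell yields a degenerate row that is excluded from
adjustment rather than an error.

`power_comparison()` repeats generation + outcomes + scan `n_replicates`
times and reports, per analysis mode, the fraction of replicates in which
the true risk locus was detected, with Monte Carlo standard error
`sqrt(p(1-p)/n)`. On the deterministic two-island scenario the stratified
analysis detects the colour gene in every replicate while the pooled
analysis sits at its false-positive floor — the masking is structural, not
a sample-size problem, so "more power" cannot fix it.

The `interaction_demo` scenario makes the same point with noise. Its
parameters are a design choice of this package: an uninfected stratum
(n = 700, baseline mortality 0.30) where carrying the variant *halves* the
odds of death, and an infected stratum (n = 300, baseline 0.10) where it
multiplies them eightfold. The two effects nearly cancel in the pooled
table (pooled OR about 1.1), so stratified power exceeds pooled power for
structural reasons. A quantitative interaction with both odds ratios above 1
would illustrate the weaker "effect size depends on stratum" phenomenon;
the qualitative version was chosen because it shows the masking mechanism
sharply. The parameters were fixed when the scenario was written and are not
tuned to any external estimate.

Replicate counts used by the shipped tests and the acceptance script are
1,000 replicates for null calibration (one stratum of 500, 100 null loci,
BH at 0.05) and 200 replicates for the power comparison — enough that the
family-wise detection rate and the power difference are resolved to within
a few Monte Carlo standard errors while a full run stays comfortably fast.

## Determinism

Every stochastic stage derives its seed from the scenario's master seed via
a stable keyed hash (`derive_seed(master, key, index)`), so any stage can be
reproduced in isolation and a whole pipeline re-run with the same master
seed exports byte-identical tables. No stage touches the caller's RNG
state.

## The peptide scanner

`find_runs()` slides a query peptide along each subject protein at every
ungapped offset and reports *maximal* runs: both ends identical or
physicochemically similar, at most `max_mismatch_inside` internal
mismatches (default 1), and at least `min_len` residues. "Similar" follows
the convention behind BLAST's `+` marks: a strictly positive BLOSUM62 score
for a non-identical pair. Runs are rendered in a three-symbol mask — query
letter for identity, `+` for similarity, space for an internal mismatch.
Overlapping maximal runs that share a match block across different mismatch
spans are all reported; an exhaustive position-enumeration oracle in the
test suite pins this behaviour down exactly.

`propensity_profile()` averages a per-residue scale (Hopp-Woods and
Kyte-Doolittle ship as built-ins) over an odd sliding window truncated at
the sequence ends; `call_segments()` extracts maximal contiguous
above-threshold stretches of at least `min_len` residues.

The bundled fixture is the 42-residue amyloid-beta peptide together with
fixed per-residue B-cell and T-cell antigenicity indices from a
charge/hydrophobicity epitope predictor. Treating these printed values as
given input keeps segment calling exactly testable: at thresholds 0.35
(B cell) and 0.5 (T cell), inclusive, with the pentapeptide minimum, the
B-cell track yields residues 1-12 and 24-28 and the T-cell track exactly
16-20, which spells KLVFF. Two edge conventions deserve a note:

* the threshold comparison defaults to **inclusive** (`>=`): two residues
  score exactly 0.35, and the inclusive reading gives the more conservative
  (longer) B-cell segments; strict comparison is available via
  `inclusive = FALSE`;
* the default `min_len` differs between matching (4) and segment calling
  (5): tetrapeptide alignments are common and informative in mimicry scans,
  while antigenic regions are conventionally required to reach pentapeptide
  length.

Reproducing any specific epitope server's scores, or BLAST's E-value
statistics, is explicitly not attempted: the scanner is generic and takes
scores and subject sets as inputs. The bundled subject FASTA contains
synthetic sequences built to carry the KLVFF/VGSNK/VGGVV motifs, and is
labelled as such.

## A worked pass through the parable

```{r demo}
report <- fox_rabbit_report(builtin_scenario("two_island_fox"))
tidy(report)
```

```{r three-island}
co3 <- generate_cohort(builtin_scenario("three_island")) |> apply_outcomes()
glance(cause_detectability(co3, "fox"))
```

The first block shows the four two-island claims (per-island detection,
pooled null, meta-analytic null, undetectable cause); the second shows the
cause becoming estimable once an unexposed reference island exists.

## Known limitations

* Haploid genotypes only; no diploid models, no allelic dosage.
* Full-cohort analysis; no case-control sampling designs.
* No covariate adjustment or regression models — the package's statistics
  are deliberately the classical stratified 2x2 toolkit.
* The peptide scanner is ungapped; insertions/deletions between query and
  subject are outside its run model.
* Exact reproduction of external epitope predictors and of BLAST statistics
  is out of scope by design.
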