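---
title: "Simulating misdiagnosis and undiagnosis in pattern differentiation"
author: "patternsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating misdiagnosis and undiagnosis in pattern differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patternsim)
```

## The diagnostic problem

In Chinese medicine, a diagnosis is a *pattern* — for example one of the 73
Zangfu single patterns — identified from the signs and symptoms
(*manifestations*) a patient presents. Manifestations are collected through
the Four Examinations, applied cumulatively in a canonical order:
inspection (Ip), auscultation and olfaction (AO), inquiry (Iq), and
palpation (P). Because patterns share manifestations, a patient's profile
may be compatible with several patterns, and the differentiation process can
fail in two distinct ways: *misdiagnosis* (a wrong pattern is identified)
and *undiagnosis* (no unique pattern can be identified). `patternsim`
implements a full stochastic simulation study of how pattern similarity
drives these two error types, and how the cumulative use of the Four
Examinations mitigates them.

The pipeline has five stages, each an independently usable module:

1. a validated **pattern dataset** model (patterns × examination methods ×
   manifestation term sets);
2. a seedable **synthetic dataset generator**, because the study's real
   dataset is not public;
3. Monte-Carlo simulation of **manifestation profiles** — true-positive
   cases and true-negative controls;
4. a rule-based **pattern differentiation algorithm** (PDA) with a
   calibrated decision cutoff;
5. **similarity and ordinal statistics** — Jaccard-type similarity
   coefficients, their ordinal categorization, and Goodman–Kruskal gamma on
   the resulting cross-tables.

## The differentiation model

A simulated patient presents $N_P$ distinct terms. For each candidate
pattern $K$ (any pattern explaining at least one term, found by exact
matching of normalized terms), two criteria are computed:

* explained information
  $F_{\%,K} = \dfrac{N_{E,K}}{N_P} \times 100\%$, the share of the
  patient's manifestations that pattern $K$ accounts for, with $N_{E,K}$
  the number of matched terms;
* available information
  $N_{\%,K} - \text{cutoff} = \dfrac{N_{E,K}}{N_{T,K}} \times 100\% -
  \text{cutoff}$, the share of the pattern's own manifestations present in
  the profile, shifted by a calibration cutoff, with $N_{T,K}$ the
  pattern's size under the chosen examination combination.

Candidates are ranked by descending $F_\%$, then ascending
$N_\% - \text{cutoff}$. The profile is *identified* only when a single
candidate holds the top-ranked pair; a tie on that exact pair, or an empty
hypothesis list, is an undiagnosis. For a case simulated from pattern $K$,
identifying $K$ is a correct diagnosis and identifying anything else a
misdiagnosis; for a control (a profile actually drawn from a donor pattern
$J \ne K$ but evaluated against $K$), identifying anything other than $K$
is correct and identifying $K$ is a misdiagnosis.

### The role of the cutoff: an interpretation choice

Subtracting a constant from every candidate's $N_\%$ cannot change an
ascending ordering, so a rule written purely as "rank ascending by
$N_\% - \text{cutoff}$" would make the calibrated cutoff inert — yet the
cutoff is explicitly estimated by simulation to maximize accuracy. The
design resolves this with two explicit modes on `rank_and_identify()` and
everything above it:

* **`literal`** (default): candidates whose available information falls
  below the cutoff ($N_\% - \text{cutoff} < 0$) are removed from the
  hypothesis list before ranking. The cutoff then acts as a floor on how
  much of a pattern must be observed before it may compete, which is what
  makes large, vague patterns lose to specific ones.
* **`absdev`**: no candidate is removed; the secondary sort key is
  $|N_\% - \text{cutoff}|$, i.e. prefer the candidate whose available
  information is closest to the calibrated value.

Neither mode is claimed to replicate the original implementation, which is
not public; `literal` is the default because it is the reading under which
calibration demonstrably changes accuracy. `estimate_cutoff()` performs the
calibration: a dedicated simulation run (default 100 cases + 100 controls
per pattern, its own seed, so no leakage into evaluation runs) scored over
a grid of cutoffs (default 0–100% in steps of 0.5), returning the
accuracy-maximizing value with ties broken toward the smallest cutoff.
Accuracy is correct diagnoses over non-missing profiles, cases and controls
jointly.

## Similarity measures

Two patterns $K_i, K_j$ with $F_i, F_j$ manifestations of which $F_{ij}$
are shared have dual-pattern similarity
$S = F_{ij} / (F_i + F_j - F_{ij})$, the Jaccard coefficient of their term
sets. A pattern's similarity to the rest of the dataset is
$S^{*} = F_{id} / (2 F_i - F_{id})$, where $F_{id}$ counts the pattern's
manifestations that occur anywhere else; $S^{*} = 1$ when every
manifestation is shared, $0$ for a pathognomonic pattern.

Both coefficients are categorized on the ordinal scale 0.00 (no
similarity), 0.01–0.20 (negligible), 0.21–0.40 (weak), 0.41–0.70
(moderate), 0.71–0.99 (strong), 1.00 (perfect). The printed bin edges are
two-decimal values, leaving gaps such as $(0.20, 0.21)$ undefined for a
continuous coefficient; `similarity_category()` therefore rounds half-up to
two decimals before binning, which makes the bins exhaustive and the
categorization deterministic. Pairs whose similarity is undefined under a
combination (a pattern with no manifestations there) are recorded as `NA`
and excluded from category counts rather than coded as zero, mirroring the
exclusion of missing cases.

## Ordinal association

Associations between ordinal variables — similarity category, examination
combination (ordered by information content), and differentiation outcome
(correct < misdiagnosis < undiagnosis, ordered by clinical consequence) —
are measured with Goodman–Kruskal
$\gamma = (C - D)/(C + D)$ over concordant and discordant record pairs,
computed exactly from the cell counts. The standard error uses the ASE1
cell-pair formula, the confidence interval is the normal interval
$\gamma \pm z \cdot \text{ASE}$, and the p-value the two-sided normal test;
the published study reports intervals without naming a method, so interval
estimates here are a documented package choice rather than a reproduction.
The squared PRE companion statistic reported alongside $\gamma$ in the
study is based on a variant whose formula the study does not give;
`gamma_pre_measure()` ships plain $\gamma^2$, explicitly labeled an
approximation, with a plug-in argument for a faithful replacement.

`printed_tables()` bundles the study's three published cross-tables, and
`reproduce_printed_tables()` recomputes every gamma from those counts. The
misdiagnosis row of the `Ip+AO` section of the outcome-by-$S^{*}$ table
sums to 1,652 while the study's outcome table prints 1,052 for the same
quantity; that section is internally inconsistent as printed, its
recomputed gamma does not match the reported one, and the discrepancy is
reported rather than hidden.

## What the synthetic generator emulates — and what it does not

The real dataset is available only on request and in Portuguese, so
`generate_dataset()` creates datasets with the *printed structure*: 73
patterns; 539 distinct manifestations split Ip = 112, AO = 42, Iq = 359,
P = 26; per-pattern per-method counts drawn uniformly on the printed
min–max ranges (Ip 0–16, AO 0–6, Iq 2–29, P 0–5). Terms are opaque
synthetic tokens in per-method namespaces, which gives intra-pattern
consistency by construction; inter-pattern duplicate profiles are resolved
by resampling, and a final sweep guarantees every vocabulary term is used
at least once. The study reports per-pattern summaries of the form
"4 [0–16]", read here as median [min–max]; only the range is enforced —
uniform draws do not reproduce the printed medians, and no attempt is made
to match them.

Design choices a user should know:

* **`sharing` (default 0.3).** The probability that a term slot reuses an
  already-assigned vocabulary term rather than introducing a fresh one —
  the single dial for inter-pattern overlap. The default was chosen so
  that, as in the study's dataset, the dual-similarity histogram under the
  full combination is dominated by the "no similarity" and "negligible"
  bins with sparse mass above. `tune_similarity()` grid-searches this
  parameter against any target category histogram; a target of all-perfect
  similarity is unreachable by design, since perfectly similar patterns
  would share a complete profile, which inter-pattern consistency forbids.
* **`force_one_empty_Ip_AO` (default `TRUE`).** The study's dataset had
  exactly one pattern with no inspection and no auscultation-olfaction
  manifestations, producing 100 missing cases (1.4%) in each of the Ip and
  Ip+AO runs. To emulate that single-missing-pattern condition the
  generator forces one pattern empty on both methods *and* redraws every
  other pattern to hold at least one inspection term — under uniform
  counts on 0–16, roughly four other patterns would otherwise be
  Ip-empty, which would misstate the printed missing rate.
* **Determinism.** A dataset is a pure function of (configuration, seed);
  simulation runs derive one RNG stream per (seed, combination, pattern
  index), so per-pattern results do not depend on iteration order, and
  every report records its seeds.

What the generator does **not** emulate: clinically meaningful term
content, non-uniform manifestation prevalence, graded severity relations
between terms, or the co-occurrence structure of real patients. Passing
tests on synthetic data therefore validate the *pipeline* — its
algorithms, accounting and statistics — not any clinical claim about real
pattern datasets. In particular, the dataset-specific quantities of the
published study (its calibrated cutoffs of 51.5/51.5/26.5/24.5 and its
94.7% peak accuracy) depend on the unpublished dataset and are not
reproducible; synthetic datasets yield their own calibrated cutoffs.

## Simulation design and numerical choices

The default study design follows the published one: for each of the four
cumulative combinations, 100 true-positive cases and 100 true-negative
controls per pattern — 14,600 profiles per run, 58,400 per study. A case
for pattern $K$ draws its size $N_R$ uniformly on the *inclusive* integer
range $[1, N_{T,K}]$ (an exclusive reading would forbid full-profile cases,
contradicting the study's complete dataset-recovery result) and samples
that many distinct terms without replacement. A control draws its donor
uniformly among the other patterns with at least one manifestation under
the combination, and its size from the *donor's* range — the study reuses
one symbol for both counts, and drawing from the donor is the reading that
is always feasible. One donor per control; no mixing.

A pattern empty under a combination yields missing profiles, which are
excluded before differentiation and reported in a dedicated column.
`reverse_engineer_check()` implements the study's quality check: rebuilding
the restricted dataset from the union of simulated case profiles and
classifying each pattern as completely simulated, partially simulated, or
not used. At the default 100 cases per pattern, complete recovery is the
expected outcome and is verified in the test suite.

Degenerate inputs are handled explicitly: empty profiles cannot be scored
(`score_F`, `find_candidates` raise errors); a dataset entirely empty under
a combination cannot calibrate; both-empty term sets have undefined
Jaccard similarity; an all-ties cross-table has undefined gamma. Validation
functions, by contrast, report violations rather than throwing.

The test suite exercises the full published design — the complete
58,400-profile study, with per-combination cutoff calibration at 100+100
profiles per pattern over the default 201-point grid — which completes in
about a minute on a single CPU; unit tests use small purpose-built
datasets. The chi-square uniformity checks of the sampler use 10,000 draws.

## Known limitations

* The PDA ranking semantics around the cutoff are an interpretation (two
  modes shipped); neither is guaranteed to match the original unpublished
  implementation.
* $\gamma^{*2}$ is approximated by $\gamma^2$ until a faithful variant is
  plugged in; published $\gamma^{*2}$ values are not reproduced.
* Confidence intervals use ASE1 with a normal approximation; the study's
  interval method is unknown, so only point estimates of gamma are treated
  as reproducible.
* Synthetic datasets reproduce printed marginal structure, not clinical
  content; all full-scale results on them characterize the method, not
  Chinese-medicine practice.
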