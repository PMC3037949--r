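# patternsim

Stochastic simulation of diagnostic errors in Chinese-medicine pattern
differentiation.

In Chinese medicine a diagnosis is a *pattern* (such as one of the 73
Zangfu single patterns), identified from the manifestations a patient
presents under the Four Examinations — inspection (Ip), auscultation and
olfaction (AO), inquiry (Iq) and palpation (P), applied cumulatively in
that order. Patterns share manifestations, so differentiation can fail by
**misdiagnosis** (a wrong pattern is identified) or **undiagnosis** (no
unique pattern can be identified). `patternsim` is for methodologists who
want to quantify how pattern similarity drives these two error types, and
how much each added examination method suppresses them, using a fully
seeded Monte-Carlo pipeline.

## The model

For a profile of `N_P` distinct terms, every pattern `K` explaining at
least one term (exact matching of normalized terms) is scored on two
criteria:

- explained information `F%_K = N_E,K / N_P × 100%` — the share of the
  profile the pattern accounts for;
- available information `N%_K − cutoff = N_E,K / N_T,K × 100% − cutoff` —
  the share of the pattern's own manifestations present in the profile,
  shifted by a cutoff calibrated by simulation.

Candidates are ranked by descending `F%`, then ascending `N% − cutoff`
(candidates below the cutoff are removed first, in the default `literal`
mode); the profile is identified only if a single candidate holds the
top-ranked pair, otherwise it is undiagnosed. Similarity is measured by
the Jaccard coefficient `S = F_ij / (F_i + F_j − F_ij)` for pattern pairs
and the variant `S* = F_id / (2 F_i − F_id)` against the rest of the
dataset, categorized on the ordinal scale none / negligible / weak /
moderate / strong / perfect. Associations between similarity, examination
combination and outcome are measured with Goodman–Kruskal
`γ = (C − D) / (C + D)`.

The study's real dataset is unpublished, so a seeded generator builds
datasets with its printed structure (73 patterns; 539 manifestations split
112/42/359/26 across Ip/AO/Iq/P; per-pattern counts in the printed ranges;
controllable term sharing; one pattern empty under Ip and AO). See the
methods vignette (`vignettes/pattern-differentiation-errors.Rmd`) for every
modelling choice.

## Worked example

```r
library(patternsim)

d <- generate_dataset(generator_config(seed = 1))
d
#> <pattern_dataset> 73 patterns, 539 distinct manifestations
#>   N_T per pattern: median 28 [6-49]

summarize_dataset(d)
#>   method n_terms   pct median min max
#> 1     Ip     112  20.8      8   0  16
#> 2     AO      42   7.8      3   0   6
#> 3     Iq     359  66.6     14   2  29
#> 4      P      26   4.8      3   0   5
#> 5  Total     539 100.0     28   6  49

set.seed(43)
profile <- simulate_case(d, "pattern 07", "Ip+AO+Iq")   # a 4-term case
differentiate(profile$terms[[1]], d, "Ip+AO+Iq", cutoff = 3.5)
#> <differentiation_result> status: identified (pattern 07)
#>      pattern n_e n_t f_pct n_pct_cutoff
#> 1 pattern 07   4  35   100     7.928571
#> 2 pattern 03   1  22    25     1.045455
#> ...
```

The true pattern explains all four terms (`F% = 100`) and is the unique
top-ranked candidate, so the case is correctly diagnosed; four other
patterns each explain one shared term. A full study — four cumulative
examination combinations × 73 patterns × (100 cases + 100 controls), with
per-combination cutoff calibration — is one call:

```r
report <- run_study(study_config(seed = 1))   # 58,400 profiles, ~1 min
report$outcomes_cases      # outcome × combination counts, Missing column included
report$gammas$outcome_vs_combo_cases$gamma   # negative: more exams, fewer errors
```

The published study's own contingency tables are bundled, and their gamma
statistics recompute from the raw counts:

```r
reproduce_printed_tables()
#>                  table      gamma  reported         delta
#> 1       Table 1 (full)  0.1921491     0.192  0.0001491326
#> 2 Table 1 (S > 0 only) -0.6458472    -0.646  0.0001527595
#> 3           Table 2 TP -0.6184792    -0.618 -0.0004792476
#> ...
```

(The `Ip+AO` section of Table 3 is internally inconsistent as printed and
is reported with its visible discrepancy; see the vignette.)

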