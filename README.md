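# apmix

Bait-normalized mixture-model scoring of affinity-purification
mass-spectrometry (AP-MS) pulldowns.

## The problem

An AP-MS experiment pulls down a tagged bait protein and identifies the
proteins that co-purify with it. Spectral or peptide counts give a
semi-quantitative abundance for each co-purifying protein, but the raw
counts mix three effects: protein length (longer proteins yield more
detectable peptides), pulldown efficiency (which varies between assays),
and genuine association with the bait. `apmix` separates these so that the
question "is this prey in complex with the bait?" becomes a posterior
probability.

The procedure, for each replicate pulldown:

1. sum peptide counts per protein,
2. divide by protein length (amino acids),
3. divide by the bait's own length-normalized value in the same assay,

which puts every prey on a *bait-relative* scale where the bait is 1 and a
value of 2⁻⁵ means "this protein was recovered at 1/32 of bait level once
length is accounted for". Values from all replicate assays are pooled as
separate observations on the log₂ scale and modelled as a two-component
Gaussian mixture

    f(x) = w₁ φ(x; μ₁, σ₁²) + w₂ φ(x; μ₂, σ₂²),   μ₁ < μ₂,

fitted by expectation-maximization: the low component is nonspecific
background, the high component is bait-bound preys. Each protein's score is
the mean of its log₂ observations, and its posterior under the high
component is the Bayes-rule membership probability. A prey is called
**in complex** when

    posterior > 0.5   AND   summed raw peptide counts ≥ 5,

with the posterior inequality strict and the count floor guarding against
calls driven by one or two stray spectra.

## Worked example

A synthetic pulldown study with known ground truth (three assays, a bait
plus 10 planted interactors at mean −2 log₂ units and 300 background
proteins at −7):

```r
library(apmix)

truth <- simulate_pulldown(sim_config(seed = 1))
#> Synthetic pulldown: 310 preys (10 true interactors) x 3 assays, seed 1

run <- run_pipeline(table = truth$table, output_dir = NULL)
run$fit
#> Gaussian mixture fit (k = 2, n = 624)
#> k: 2
#> weights: 0.96019187 0.039808132
#> means: -6.7021871 -1.4282048
#> variances: 1.5754528 0.86636463
#> log_likelihood: -1118.36114952
#> n_iter: 67
#> converged: true

head(run$calls[, 1:5], 6)
#>     protein_id total_raw_count mean_log2_score posterior is_interactor
#> 1         BAIT             765       0.0000000 1.0000000          TRUE
#> 311    INT_010             778      -0.3611870 0.9999009          TRUE
#> 302    INT_001             367      -0.5566193 0.9998273          TRUE
#> 305    INT_004             737      -0.6824494 0.9997504          TRUE
#> 307    INT_006             900      -0.9264379 0.9994783          TRUE
#> 304    INT_003             211      -1.9056962 0.9864249          TRUE
```

The fit has found the two populations: 96% of pooled observations in a
background component at −6.7 (close to the configured −7) and 4% in a
high component at −1.4 (the planted interactors sit at −2). The calls are
ranked by posterior; the bait heads the table with a sentinel posterior
of 1. Against the ground truth:

```r
unlist(evaluate_calls(truth, run$calls))[c("tp", "fp", "fn", "sensitivity", "specificity")]
#>          tp          fp          fn sensitivity specificity
#>   8.0000000   1.0000000   2.0000000   0.8000000   0.9966667
```

8 of 10 planted interactors are recovered with one false discovery among
300 background proteins. With `output_dir` set, `run_pipeline()` also
writes `calls.tsv`, an exclusion log, a fit summary, and a
`run_record.yaml` from which `replay_run()` reproduces the run exactly.

A companion filter for paired expression data, `phase_sort()`, retains
transcripts with |log₂ fold change| > 1.5 (and adjusted *P* ≤ 0.1) and
partitions them into G1, S/M/C, or noncyclical peak-expression groups.

A command-line front-end covering all of this lives in
`inst/scripts/apmix.R` (subcommands `score`, `simulate`, `phase-sort`,
`replay`).

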