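# pssmpp

Sequence-only prediction of **heme-binding residues** from protein chains,
built around an *integrative sequence profile* that couples evolutionary
information (PSI-BLAST position-specific scoring matrices, PSSMs) with
selected physicochemical amino-acid scales (AAindex1).

The package is for bioinformaticians who have protein sequences, PSI-BLAST
profiles and residue-level binding annotations, and want (a) a residue
classifier that works without structures, and (b) a principled way to pick
a small set of informative physicochemical scales.

## The method

Each residue is encoded over a sliding window of `w` positions (default
`w = 17`). Per window slot the available encoders emit:

| encoder | channels per slot | total size (w = 17, 4 scales) |
|---|---|---|
| `binary` | one-hot amino-acid identity (20) + terminal bit | 357 |
| `pssm` | logistic-scaled PSSM log-odds (20) + bit | 357 |
| `pp` | selected scale values of the slot's residue (P) + bit | 85 |
| `pssm_pp_concat` | pssm + pp channels, one shared bit | 425 |
| `pssmpp` | integrative profile (P) + bit | 85 |

The integrative profile condenses a position's 20 scaled PSSM entries
`M_ij` into one number per selected property `p`, using the scale's
normalized values `w_pj` (zero mean, unit population standard deviation
over the 20 amino acids):

```
F_ip = Σ_{j=1..20} w_pj · M_ij ,   M_ij = 1 / (1 + exp(-PSSM_ij))
```

Scales are selected in two stages: a classifier-free **AUC ranking** (each
scale's per-residue values scored against the labels by the Mann–Whitney
AUC, folded so either orientation counts), then a **greedy forward
selection** that accepts a candidate only if it improves the pooled
cross-validated AUC of the integrative-profile classifier, pruning
candidates correlated with an accepted scale at `|r| ≥ 0.8`.

The classifier is an RBF-kernel SVM (e1071/LibSVM, default
hyperparameters) trained with **balanced sampling** — all positive
residues plus an equal random draw of negatives — and evaluated on
held-out folds at their natural imbalance (chain-grouped 5-fold CV), with
the full metric suite: ACC, SN, SP, PR, MCC, F1 and ROC/AUC.

A planted-signal synthetic generator (`simulate_dataset()`) emulates all
four input artifacts — FASTA, ASCII PSSMs, an AAindex1 file, labels at a
13.5% positive rate — so the entire pipeline is testable offline.

## Worked example

```r
library(pssmpp)

ds <- simulate_dataset(fixture_config(seed = 1))   # 60 chains, ~2000 residues
ranking <- rank_scales(ds$samples, ds$scales, ds$profiles)
head(ranking, 3)
#> # A tibble: 3 × 4
#>   accession  description                              auc  rank
#>   <chr>      <chr>                                  <dbl> <int>
#> 1 SYNTH00002 Synthetic random scale 2 (informative) 0.740     1
#> 2 SYNTH00001 Synthetic random scale 1 (informative) 0.717     2
#> 3 SYNTH00009 Synthetic random scale 9               0.646     3

sel <- greedy_select(ds$samples, ds$scales, ds$profiles, ranking = ranking,
                     config = selection_config(seed = 1))
sel$selected   # accessions accepted by the greedy loop, in acceptance order
#> [1] "SYNTH00002" "SYNTH00001" "SYNTH00019"

cv <- cross_validate(ds$samples, ds$profiles,
                     scales = ds$scales[match(sel$selected, ds$scales$accession), ],
                     encoder = "pssmpp", window = 17, seed = 1)
glance(cv)
#> # A tibble: 1 × 15
#>   encoder window folds threshold    TP    FP    TN    FN   ACC    SN    SP    PR
#>   <chr>    <dbl> <int>     <dbl> <int> <int> <int> <int> <dbl> <dbl> <dbl> <dbl>
#> 1 pssmpp      17     5         0   214   346  1328    58 0.792 0.787 0.793 0.382
#> #   with MCC = 0.444, F1 = 0.514, AUC = 0.862 in the remaining columns
cv$auc
#> [1] 0.8623344
autoplot(cv)   # pooled ROC curve
```

The classifier-free ranking puts the two signal-carrying scales first
(per-residue AUC 0.74 and 0.72), and the greedy loop selects both plus one
weak extra before the remaining candidates stop improving the
cross-validated AUC. The pooled CV AUC of the integrative-profile
classifier built on the selected scales is 0.86, with the
sensitivity/precision pattern typical of balanced training on a
13.5%-positive dataset evaluated at natural imbalance (SN 79% at PR 38%).

A command-line interface wrapping the same functions ships at
`inst/cli/pssmpp` (subcommands `simulate`, `rank-properties`, `select`,
`encode`, `train`, `cross-validate`, `predict`, `evaluate`).

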