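# ddiscreen

Screening drug–drug interaction (DDI) signals in spontaneous-reporting-system
(SRS) data.

Pharmacovigilance databases such as JADER or FAERS collect post-marketing
adverse-event reports. Disproportionality statistics flag drug–event pairs
that are reported together more often than expected; extending this to drug
*pairs* is harder, and a popular shortcut — computing the reporting odds
ratio (ROR) of drug D2 inside the subset of reports that mention drug D1 —
over-fires badly: if D2 alone is risky, the subset signals whether or not D1
plays any role. `ddiscreen` implements the stricter **both-subsets
criterion** (a DDI signal requires the ROR to signal both for D2 within
D1-users *and* for D1 within D2-users), together with the comparators
needed to evaluate it, and a synthetic report generator so the whole
pipeline runs without a database download.

## What it computes

For each (drug1, drug2, event) triple, every case report falls into one
cell of the 4×2 table `n_ijk` (i = uses drug1, j = uses drug2, k = target
event vs other events). On that table:

- **Subset ROR**: within D1-users the 2×2 table is (N11, N10, N01, N00) =
  (n111, n110, n101, n100); `ROR = (N11/N10)/(N01/N00)` with 95% CI
  `exp(ln ROR ± 1.959964·√(ΣN⁻¹))`. A directional subset signals when the
  CI lower bound exceeds 1; the *either-subset* ("previous") criterion ORs
  the two directions, the *both-subsets* ("new") criterion ANDs them.
- **Ω shrinkage measure**: `Ω = log2((n111+0.5)/(E111+0.5))`, with
  `E111 = g11·n11+` built from the cell event proportions
  `f_ij = n_ij1/n_ij+` combined on the odds scale; signal when
  `Ω025 = Ω − 1.959964/(ln 2·√n111) > 0`.
- **Component interaction models** (additive risk difference,
  multiplicative ratio-of-ratios, Yates-corrected one-sided χ²), whose
  three-way signal intersection forms the surrogate ("hypothetical") truth
  set used for evaluation.
- **Evaluation**: confusion counts against a truth set; accuracy,
  precision (PPV), recall (sensitivity), specificity, Youden's index,
  F-measure, NPV; Cohen's κ with an asymptotic 95% CI plus positive /
  negative proportionate agreement between any two detectors.

## Worked example

```r
library(ddiscreen)

# 20,000 synthetic cases: 12 drugs in 6 disjoint pairs, one injected
# synergistic interaction (f11 = 0.30 vs nulls 0.09 / 0.25), 5 null pairs
scenario <- demo_scenario(seed = 42, n_cases = 20000)
rx <- recovery_experiment(scenario,
                          algorithms = c("subset-new", "subset-previous",
                                         "omega"))
rx$metrics[, c("algorithm", "tp", "fp", "tn", "fn",
               "precision", "recall", "f_measure")]
#>         algorithm tp fp tn fn precision recall f_measure
#> 1      subset-new  1  1 64  0    0.5000      1     0.667
#> 2 subset-previous  1 23 42  0    0.0417      1     0.080
#> 3           omega  1  0 65  0    1.0000      1     1.000
```

All three detectors recover the injected pair (tp = 1, recall = 1), but the
either-subset criterion drags in 23 false pairs — every triple that merely
shares a drug with a risky exposure — while the both-subsets criterion cuts
those to 1. That is the qualitative pattern the criterion was designed for:
equal true positives, far fewer false positives.

```r
agreement(rx$verdicts[["subset-new"]], rx$verdicts[["omega"]], rx$counts)
#> <ddi_agreement> kappa 0.660 (95% CI 0.038-1.282)  P+ 0.667  P- 0.992
```

The published evaluation tables are a pure function of confusion counts;
feeding the both-subsets row reproduces its metric row exactly:

```r
classification_metrics(542, 367, 2634, 381)
#> <ddi_metrics>
#>    accuracy   precision      recall specificity      youden   f_measure
#>       0.809       0.596       0.587       0.878       0.465       0.592
#>         npv
#>       0.874
```

Real data goes through the same steps explicitly: `read_cases()` on
DEMO/DRUG/REAC csv tables (use `jader_columns()` for the Japanese JADER
headers), `enumerate_triples()` for the universe of pairs co-reported with
the target event, `tabulate_triples()`, `detect_signals()`,
`hypothetical_truth()`, then `confusion()` / `classification_metrics()` /
`agreement()`.

## Command line

Every step is exposed as a subcommand of the `inst/cli/ddiscreen` script
(or `ddiscreen::ddi_main(argv)`):

```sh
ddiscreen simulate --out sim/ --scenario demo --n-cases 20000 --seed 42
ddiscreen tabulate --demo sim/DEMO.csv --drug sim/DRUG.csv --reac sim/REAC.csv \
          --event "stevens-johnson syndrome" --out counts.csv
ddiscreen detect   --counts counts.csv --algorithm subset-new --out new.csv
ddiscreen detect   --counts counts.csv --algorithm subset-previous --out prev.csv
ddiscreen evaluate --truth sim/ground_truth.csv --out metrics.csv new.csv prev.csv
ddiscreen compare  --a new.csv --b prev.csv --universe counts.csv --out agree.csv
```

Outputs are csv with a JSON provenance sidecar (tool version + config
digest); writes are atomic.

## Scope

Synergistic interaction screening only (no antagonism), report-level
counting, exact string matching of drug names and event preferred terms.
No MedDRA hierarchy expansion, no drug-dictionary mapping, no
single-drug Bayesian baselines.
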