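---
title: "Screening drug-drug interaction signals with subset disproportionality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening drug-drug interaction signals with subset disproportionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddiscreen)
```

## The problem

Spontaneous reporting systems (SRS) such as JADER collect voluntary
post-marketing adverse-event reports. Each report carries a set of suspect
drugs and a set of adverse-event preferred terms. Disproportionality
analysis asks whether a drug and an event co-occur in reports more often
than the rest of the database would predict. For drug *pairs* the
dedicated interaction statistics are considered hard to compute in routine
practice, so analysts often fall back on **subset analysis**: restrict the
database to reports using drug D1 and compute the ordinary reporting odds
ratio (ROR) of drug D2 against the target event inside that subset.

Used with the customary "either direction suffices" rule, subset analysis
has two failure modes. First, when D2 alone is strongly associated with
the event, the D1-restricted subset inherits that association whether or
not D1 modifies it: the "interaction" signal fires for every drug that
merely co-occurs with D2. Second, the two directions (D2 within D1-users,
D1 within D2-users) need not agree, and no rule said which value counts.
The criterion implemented here as `subset_signal(..., criterion = "new")`
resolves both: a pair is a DDI signal only when **both** directional
subsets signal. Since the both-subsets signal set is by construction a
subset of the either-subset set, the criterion can only remove signals —
and the removed ones are exactly the asymmetric, single-drug-driven kind.

## The model, cell by cell

For one (drug1, drug2, event) triple each report falls into one cell of
the 4×2 table $n_{ijk}$: $i$ = uses drug1, $j$ = uses drug2, $k = 1$ for
the target event, $k = 0$ for any other event. Marginals
($n_{ij+}$, $n_{++k}$, $n_{+++}$) are always derived from the eight
cells, never stored.

**Subset ROR.** Within D1-users, $(N_{11}, N_{10}, N_{01}, N_{00}) =
(n_{111}, n_{110}, n_{101}, n_{100})$; within D2-users the last two
become $(n_{011}, n_{010})$. Then

$$ROR = \frac{N_{11}/N_{10}}{N_{01}/N_{00}}, \qquad
  CI_{95} = \exp\!\left(\ln ROR \pm z_{0.975}
  \sqrt{\tfrac{1}{N_{11}}+\tfrac{1}{N_{10}}+\tfrac{1}{N_{01}}+\tfrac{1}{N_{00}}}\right).$$

A directional subset signals when the ROR is computable (no zero cell)
and the CI lower bound exceeds 1 — the standard ROR025 rule; the
threshold and an optional minimum $N_{11}$ floor are exposed as
parameters. The either-subset criterion ORs the two directions; the
both-subsets criterion ANDs them.

**Ω shrinkage measure.** With cell event proportions
$f_{ij} = n_{ij1}/n_{ij+}$ and odds $o(x) = x/(1-x)$, the expected
co-exposed proportion combines the background and single-drug risks on
the odds scale:
$$o(g_{11}) = \max\{o(f_{00}), o(f_{10})\} + \max\{o(f_{00}), o(f_{01})\}
  - o(f_{00}),$$
so that when one drug carries no excess risk the closed form collapses to
$g_{11} = \max(f_{00}, f_{01})$ (or symmetrically $\max(f_{00}, f_{10})$).
Then $E_{111} = g_{11} n_{11+}$,
$\Omega = \log_2\frac{n_{111}+0.5}{E_{111}+0.5}$, and the signal rule is
$\Omega_{025} = \Omega - z_{0.975}/(\ln 2\sqrt{n_{111}}) > 0$. The 0.5
shrinkage terms tame small counts; $n_{111} = 0$ gives
$\Omega_{025} = -\infty$, never a signal.

**Component models and surrogate truth.** No complete gold standard of
drug-interaction adverse events exists, so evaluation uses a surrogate
truth set: the intersection of the signals of three further models on the
same tables —

- *additive*: excess risk $\Delta = f_{11} - f_{10} - f_{01} + f_{00}$
  with normal variance $\sum_{ij} f_{ij}(1-f_{ij})/n_{ij+}$, signal when
  the 95% lower bound exceeds 0;
- *multiplicative*: ratio-of-ratios
  $R = f_{11}f_{00}/(f_{10}f_{01})$ with log-scale variance
  $\sum_{ij}(1-f_{ij})/(n_{ij+}f_{ij})$, signal when the lower bound of
  $R$ exceeds 1;
- *chi-square*: Yates-corrected
  $\chi^2 = (|n_{111}-e|-0.5)^2(1/e + 1/(n_{11+}-e))$ against the
  no-multiplicative-interaction expectation
  $e = n_{11+} f_{10}f_{01}/f_{00}$ (clamped to $[0, n_{11+}]$), signal
  when $\chi^2 > 3.841$ **and** $n_{111} > e$ (excesses only).

The source study cites but does not reprint these component formulations;
the versions above are standard textbook forms, and each is a plain
exported function so alternative published variants can be swapped in.
Because of this freedom, full-database truth counts are deliberately not
reproduction targets.

**Evaluation.** `confusion()` scores a signal set against a truth set
over a fixed triple universe; `classification_metrics()` yields accuracy,
precision (PPV), recall (sensitivity), specificity, Youden's index,
F-measure and NPV, with 0/0 cases reported as `NA` rather than coerced —
silently mapping undefined precision to 0 or 1 inflates or deflates
scores on degenerate strata. `agreement()` gives Cohen's κ with the
large-sample Fleiss–Cohen–Everitt standard error and the
chance-uncorrected positive/negative proportionate agreements
$P_{pos} = 2a/(2a+b+c)$, $P_{neg} = 2d/(2d+b+c)$.

## Numerical choices

- $z_{0.975}$ is fixed at 1.959964 (double precision) rather than
  calling a quantile function, making results bit-reproducible; printed
  tables round half-to-even at 3 decimals (metrics) / 4 (statistics),
  but all comparisons happen on unrounded values.
- Strict inequalities at every threshold: a CI lower bound of exactly 1,
  $\Omega_{025} = 0$, or $\chi^2 = 3.841$ is *not* a signal.
- Zero ROR cells give `computable = FALSE` and no signal; a
  Haldane–Anscombe +0.5 option exists for exploration but is off by
  default so the default matches the plain formula.
- The odds transform in $g_{11}$ is undefined at $f = 1$; proportions
  are clamped to $1 - 10^{-12}$ first (ordering preserved, flagged in
  the result).
- Drug and event identity is trimmed, case-folded exact string match.
  No MedDRA hierarchy, no ingredient mapping: both require licensed
  dictionaries and neither changes the statistics.
- The triple universe is every canonical drug pair co-reported with the
  target event at least once ($n_{111} \ge 1$); pairs never co-reported
  contribute nothing to screening. Duplicate case ids keep the
  last-seen record (quarterly SRS files ship revisions), with a warning.

## What the synthetic generator emulates — and what it does not

`ddi_scenario()` + `generate_reports()` draw, per case, independent
suspect-drug exposures with configured marginal probabilities, then one
Bernoulli target-event draw whose probability is the exposure cell of the
configured pairs: baseline $f_{00}$, single-exposure $f_{10}/f_{01}$,
co-exposure $f_{11}$ (first matching pair in canonical order wins), or a
per-drug multiplier for unpaired risky drugs. A pooled "other adverse
reaction" (default probability 0.9, roughly the ubiquity of non-target
events in real SRS data) keeps the other-AE column populated. Ground
truth is analytic: a pair is a true interaction iff its configured
$f_{11}$ strictly exceeds **both** the additive null
$f_{10}+f_{01}-f_{00}$ and the multiplicative null
$f_{10}f_{01}/f_{00}$. A pure-null scenario is obtained with
$f_{10}=f_{01}=f_{11}=f_{00}$, where both nulls coincide — the validator
annotates which null each pair sits on, since sitting on both with
distinct cells is impossible.

The packaged `demo_scenario()` states one world and keeps it: 50,000
cases, twelve drugs at exposure 0.15 in six disjoint pairs, baseline
event probability 0.01, one injected interaction with cells
(0.01, 0.05, 0.05, 0.30) — the synergy magnitude used throughout the
examples — and five null pairs. `null_scenario()` is its no-effect
counterpart at 2,000 cases for replicated false-positive-rate studies.

The generator does **not** emulate: reporting-odds confounders
(stimulated reporting, notoriety bias), correlated prescribing beyond an
optional shared-cell construction, duplicate or revised reports, MedDRA
term granularity, or report volumes drifting over time. A green
recovery test therefore establishes that the statistics behave as
designed on tables whose cells match their assumptions — not that real
SRS data satisfies those assumptions.

One calibration note: in replicated null studies the either-subset
criterion shows a false-signal rate near $1-(1-0.025)^2 \approx 0.049$,
twice the single-test 0.025. That is not a bug to tolerate but the
phenomenon itself — an OR of two one-sided tests gets two chances to
fire — and the tests compare each detector against its own nominal rate.

## Design choices where the design was open

- **Signal rule for the subset ROR**: the source material never defines
  "signal detected" for a subset; the conventional CI-lower-bound > 1
  rule is used, exposed as `threshold` with an optional `min_n11` floor.
- **Last-seen duplicate resolution** rather than first-seen or merge:
  deterministic, matches how quarterly revision files supersede records.
- **Component-model formulations** (above) are this package's defaults;
  they are deliberately plain functions rather than a framework.
- **Kappa CI variant**: the asymptotic Fleiss–Cohen–Everitt standard
  error; published interaction studies rarely state their variant, so
  printed κ CIs elsewhere are not reproduction targets.
- **CLI dialect**: csv in/out with JSON sidecar metadata and atomic
  writes; SRS distributions are csv-native, and sidecars keep the data
  files clean for downstream tools.

## Known limitations

- Only synergistic (risk-increasing) interactions are detectable; every
  signal rule is one-sided by construction.
- Exact-string drug identity will fragment signals across synonyms in
  real data; pre-normalisation is the user's responsibility.
- The surrogate truth set inherits the component models' biases; metrics
  against it measure agreement with those models, not clinical truth.
- Case-level RNG makes the generator exact in distribution but means
  realised cell counts fluctuate; property tests use 3-standard-error
  bands, so roughly one cell check in ~370 would fail under reseeding.
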