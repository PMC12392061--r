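---
title: "Methods and design choices in evmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in evmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmir)
```

`evmir` analyzes quantification-cycle (Cq) matrices from preconfigured
qPCR miRNA arrays run on paired intracellular (IN) and
extracellular-vesicle (EV) samples of several cell populations. This
vignette explains the statistical model behind each stage, the parameters
a user may want to move, the numerical conventions, and what the bundled
synthetic-data generator can and cannot tell you about real data.

## The measurement model

Cq is the PCR cycle at which an assay's fluorescence crosses threshold;
it is linear in log2 template abundance (one cycle ≈ one two-fold
dilution), with *lower* Cq meaning *more* template. Three properties of
array Cq data shape the whole design:

* values above ~30 cycles are dominated by stochastic amplification and
  are not quantitative;
* non-amplification ("Undetermined") is categorical, not a censored
  number — imputing a ceiling such as Cq 40 would drag group means;
* per-sample offsets (input amount, plate effects) shift all assays of a
  sample equally on the Cq scale.

Accordingly the package stores non-detection as an explicit sentinel
(`NA`), works on the Cq/log2 scale throughout, and removes sample offsets
by global-mean normalization rather than by reference-gene division.

## Detection and completeness

`detection_call()` flags a reaction detected iff
`lower_cq ≤ Cq ≤ upper_cq`, defaults 15 and 30 cycles, both inclusive.
The inclusive upper bound is a deliberate tie-break: with "Cq = 30 is the
detection cut-off" and "Cq > 30 is non-expressed" as the two operative
rules, only the inclusive reading makes them consistent. The lower bound
guards against threshold artifacts in the first cycles.

`group_complete()` requires *every* replicate of a group detected before
the assay gets a group mean; a single failed read discards the assay from
that group's statistics. With n = 3 biological replicates per group, a
mean over two detected replicates would silently mix abundance with
detectability, so completeness is strict.

## Global-mean normalization

The normalizer set is the assays detected in all samples of the dataset,
computed once on the full design — not per comparison — so that all
samples share one scale. Relative expression is

```
expr(g, j) = mean_{n in normalizer set} Cq(n, j) − Cq(g, j)
```

The arithmetic mean of Cq is used because Cq is already a log-scale
quantity (it is the geometric mean of linear abundances). The sign
convention makes larger expr mean higher abundance, so a contrast's
log2 fold change is simply `mean(expr_A) − mean(expr_B)`. Two exact
invariants follow and are property-tested: the per-sample mean of expr
over the normalizer set is 0, and adding a constant to all Cq of one
sample leaves its expr unchanged.

## Moderated differential expression

With three replicates per group, per-assay variance estimates are
unstable; the package shrinks them with the standard empirical-Bayes
hierarchy: pooled two-group variances are modeled as
`s² ~ s0²·F(d_g, d0)` and the prior `(d0, s0²)` is estimated by moment
matching on the log scale — `E[log s²]` and `Var[log s²]` have closed
forms in digamma/trigamma functions, and the trigamma equation is solved
with a Newton inverse iterated on a nearly linear transform. When the
observed spread of `log s²` is no larger than sampling alone predicts,
`d0 = ∞` and all moderated variances collapse to `s0²`. The moderated
statistic is

```
s̃² = (d0·s0² + d_g·s²) / (d0 + d_g)
t  = log2FC / sqrt(s̃²·(1/n_A + 1/n_B)),   df = d0 + d_g
```

Setting `d0 = 0` (`moderation_params_manual(0, 1)`) recovers the
classical pooled t-test exactly; the test suite asserts this equivalence
at 1e-10 and cross-checks the hyperparameter fit against the independent
`limma` implementation.

Two design choices deserve notice:

* **Per-contrast moderation, not a global linear model.** Each of the
  nine comparisons estimates `(d0, s0²)` from its own pooled variances
  rather than fitting one six-group design matrix. With balanced n = 3
  groups the pairwise results are the same quantity the global fit would
  test, the assay sets differ per comparison anyway (the completeness
  rule is applied per comparison), and the per-contrast form keeps every
  comparison self-contained.
* **Unblocked contrasts.** Donor is carried in the metadata but not used
  as a blocking factor; with three donors the gain from blocking is
  small and the unpaired analysis is the more conservative default.

Significance requires both adjusted `p ≤ alpha` (Benjamini–Hochberg,
default 0.05) and `|log2FC| ≥ log2(fc_threshold)` (default 1.5): the
fold-change rule is applied on the log2 scale on which the test runs,
and reported `FC_linear` is signed (`−2` = halved).

## Exclusivity calls

Assays can be biologically decisive yet statistically untestable: present
in every replicate of one group and absent from the other. The rule is
`Cq < expressed_cq` (default 28) in *every* replicate of one group and
non-detected (`Cq > upper_cq` or sentinel) in *every* replicate of the
other. The per-replicate evaluation is the default because it is the
stricter, fully reproducible reading; a group-mean variant
(`method = "group_mean"`) is available and every result records which was
used. The 28–30 cycle gap between "expressed" and "non-detected" is
intentional: an assay detected at 29 cycles in one group is evidence of
presence, not absence, and such patterns are deliberately `neither`.
Exclusivity overrides the statistical status in `call_de()`, and
exclusive assays carry no t/p — they never reach the test, because the
absent group is by definition incomplete.

## EV signature classification

From the within-population EV-vs-IN contrasts (EV listed first), each
population gets an EV-enriched set (statistical `up_A`) and an
EV-exclusive set (categorical). An assay counts as *EV-loaded* if it is
in either; the universal EV signature is the assays EV-loaded in all
three populations. Counting both evidence kinds is necessary, not
generous: the most strongly loaded cargo tends to fall below
intracellular detection and is then only reachable through the
exclusivity rule. Population-specific sets are assays EV-loaded in
exactly one population.

The neural-shared set has two defensible definitions and the package
implements both behind `neural_shared_def`:

* `"ev_vs_in"` (default): EV-loaded in both neural populations (NSC and
  FPP) but not in PSC — consistent with how the other signature sets are
  built, so the partition property (universal ⊆ each population;
  specific sets disjoint) holds by construction;
* `"vs_psc_ev"`: up in both NSC-EV and FPP-EV relative to PSC-EV — a
  cross-population contrast on the EV axis.

The chosen definition is recorded as an attribute of the result.

## ΔΔCt validation

`delta_delta_ct()` aggregates the two reference genes by the arithmetic
mean of their Ct values (again: geometric mean of linear quantities),
anchors ΔΔCt at the calibrator group's mean ΔCt, and reports
`FC = 2^(−ΔΔCt)`. The calibrator is the second-listed group of the
contrast of interest so that reported fold changes read in the direction
of the first group. Group tests are Welch t-tests on log2 fold changes —
each gene individually, no common-SD assumption — with Holm-Šídák
step-down correction (`adj_(i) = max_{j≤i} [1 − (1 − p_(j))^(m−j+1)]`),
which base R's `p.adjust` does not provide in the Šídák form.

## Over-representation

`hypergeometric_ora()` is the standard one-sided hypergeometric upper
tail over user-supplied gene→pathway tables, BH-adjusted across
pathways. No target or pathway database is bundled: prediction databases
are version-volatile, so the package takes plain TSV mapping tables and
ships only tiny fixtures. The universe defaults to all genes in the
pathway table and is overridable; an optional `score` column supports
interaction-confidence filtering of target tables.

## The synthetic generator

`generate_cq_dataset()` emulates the full design: 754 assays, 3 donors ×
3 cell populations × 2 compartments. Its defaults are chosen once to
match the structure of real cards of this kind:

| parameter | default | rationale |
|---|---|---|
| `p_expressed` | 0.31 | only a minority of card assays amplify in any one cell type; yields ≈24% detected reactions per compartment |
| `baseline_mean`, `baseline_sd` | 26.5, 3 cycles | expressed assays centered mid-window |
| `ev_baseline_offset` | 0.6 cycles | vesicle preps recover less template, so EV detection runs slightly below intracellular |
| `noise_sd` | 0.35 cycles | replicate-to-replicate technical + biological noise |
| `donor_sd` | 0.2 cycles | per-(assay, donor) intercepts reproduce donor clustering |
| `plate_sd` | 0.3 cycles | per-sample offsets, removed by normalization |
| `dropout_mid`, `dropout_scale` | 29, 0.8 | non-detection probability `plogis((Cq−29)/0.8)`: dropout concentrates just below the 30-cycle boundary |
| `frac_de`, `de_min`, `de_max` | 0.25, 0.6, 2.5 | planted cell-type effects spanning sub-threshold to strong |
| `frac_ev_enriched`, shifts | 0.10, 1–3 cycles | selective EV loading |
| `frac_ev_exclusive` | 0.02, EV Cq 24.5 ± 0.8 | intracellularly silent cargo; the EV level sits within the range of published exemplar candidates (Cq means 23–27) and far enough below the dropout zone that the per-replicate exclusivity rule can see it consistently |

What the generator does *not* emulate: pre-amplification bias,
plate-position effects, cross-hybridization, rRNA-fragment contamination
of EV RNA, or donor-paired correlation structure beyond random
intercepts. Passing tests on synthetic data therefore demonstrate that
the *algorithms* implement their definitions and recover planted truth
under realistic noise — not that any particular biological conclusion
transfers to a given real dataset.

`generate_validation_ct()` similarly plants a known linear fold change in
one group with stable references (ACTB at Ct 20, GUSB at 22, sd 0.15
cycles); with zero noise the ΔΔCt pipeline returns the planted fold
change exactly, which the suite asserts.

## Numerical conventions and degenerate inputs

* Non-detection is `NA` everywhere; parsing never coerces a sentinel to
  a number or vice versa, and write→read round trips are lossless.
* Ties at the detection bounds are inclusive (`Cq = 30` detected,
  `30.01` not).
* `log2FC = 0` is reported with `t = 0, p = 1`; zero moderated variance
  makes an assay `not_evaluable` rather than producing infinities.
* Degenerate ΔΔCt comparisons (zero variance in both groups, equal
  means) return `p = 1`.
* The trigamma inverse runs Newton until the relative step falls below
  1e-10 (at most 50 iterations), with asymptotic closed forms at the
  extremes.
* An empty normalizer set, a missing reference gene, unknown group
  labels, duplicate assay ids, and ragged or non-numeric matrix cells
  are hard errors that name the offender; pipeline stages prefix errors
  with the stage name.

## Test problem sizes

The suite exercises: oracle equivalence of the moderated t at d0 = 0
(1e-10); hyperparameter recovery at 5000 assays (d0 within 25%, s0²
within 10%); realized false-discovery proportion on 2000-assay null data
over 200 Monte-Carlo replicates; ≥80% power on 2000 assays with 10%
planted 1.5-log2FC effects at n = 3 and noise sd 0.35; universal-EV
recovery across 50 simulated cards; and hand-computed BH, Holm-Šídák and
hypergeometric oracles. These sizes give stable Monte-Carlo estimates
while keeping the full suite under a minute on one core.

## Limitations

* Two-group contrasts only: no multi-factor or donor-paired models, no
  ANOVA path for the validation genes.
* No amplification-efficiency (Pfaffl) correction and no reference-gene
  stability ranking; the design assumes efficiency near 1 and stable
  references.
* Assay identifiers are taken verbatim; no miRBase version remapping.
* The normalizer set is data-dependent; datasets with very few
  consistently detected assays will normalize on a small, noisier set
  (its size and membership are always reported).
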