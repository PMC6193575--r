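---
title: "Predicting lysine succinylation sites: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine succinylation sites: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsuc)
```

## The problem

Lysine succinylation is a post-translational modification in which a
succinyl group is attached to a lysine side chain, changing the residue's
charge and often the protein's function. Experimentally mapping these sites
is expensive, so sequence-based predictors are used to prioritise candidate
lysines. `gpsuc` implements a five-channel predictor: each candidate lysine
is represented by a 41-residue window (the site plus 20 flanking residues on
each side, terminal overhangs padded with `-`), the window is encoded five
ways, each encoding is scored by its own random forest, and the five scores
are fused into a single probability by logistic regression.

## The five encodings

For a window $w$ with an aligned $41 \times 20$ sequence profile $P$
(PSI-BLAST log-odds, or the packaged pseudo-profile):

* **AAC** (20 features): occurrence frequencies of the 20 residues among the
  observed flank positions. The central lysine is not counted, and neither
  are pad (`-`) or unknown (`X`) symbols, so the vector is a true
  composition of what was seen.
* **BE** (820): one-hot encoding, a 20-bit block per position; pads and
  `X` give all-zero blocks.
* **AAindex** (492): twelve physicochemical scales (volume,
  secondary-structure propensities, membrane-protein compositions,
  hydrophobicity and contact-energy scales) looked up per position.
  `NA` values in a scale are replaced by 0.
* **PSSM** (820): the profile window flattened row-major.
* **pCKSAAP** (2000): for each gap $k \in \{0..4\}$ and ordered residue pair
  $(a, b)$,
  $$S_{ab}(k) = \frac{1}{L-k-1} \sum_{r=1}^{L-k-1}
    \max\{\min(P_{r,a},\, P_{r+k+1,b}),\, 0\}, \qquad L = 41,$$
  i.e. a positive contribution wherever both profile scores of a $k$-spaced
  pair are positive. All 2000 values are non-negative and bounded by the
  largest positive profile entry.

The concatenated vector has $20+820+492+820+2000 = 4152$ named features.
Feature names carry block, window offset and descriptor
(`pCKSAAP:k2:AC`, `BE:pos-7:R`, `AAindex:pos+3:TSAJ990101`), so selected
subsets remain self-describing.

The sum over *all* positions $r$ in the pCKSAAP formula deserves a note:
the formula is sometimes written as a sum over the $T$ occurrences of the
pair, but only position pairs where both profile scores are positive
contribute, which is exactly the floored sum above; this reading reproduces
the published width of $5 \times 400$ features. The ordering of pairs
within each $k$ (first residue major, alphabet `ACDEFGHIKLMNPQRSTVWY`) is
our fixed convention.

## Profiles and the pseudo-profile fallback

Real profiles come from `psiblast -out_ascii_pssm` (typically 3 iterations,
e-value $10^{-4}$, against Swiss-Prot); `read_psiblast_pssm()` parses the
20 log-odds columns and remaps them to the package's canonical alphabet
order. Running PSI-BLAST is out of scope. When no profile file exists,
`pseudo_profile()` substitutes a deterministic profile whose row $r$ is the
BLOSUM62 substitution row of the residue at $r$ — it carries residue
identity and coarse exchangeability, not true evolutionary conservation,
and is what all synthetic tests use. Profile rows at terminal padding and
at `X` residues are zero-filled; this is our documented choice, the source
method does not state one.

## Feature selection

Each feature is screened with a two-sample Wilcoxon rank-sum test (positive
vs negative windows). The statistic is the positive-group rank-sum $W$ with
mid-ranks for ties. The exact null distribution is computed by dynamic
programming over all $\binom{r+s}{r}$ rank assignments whenever that count
is at most $2 \times 10^5$ (and on demand at any size); otherwise a normal
approximation with tie and continuity corrections is used. Screening must
catch depletion as well as enrichment, so the two-sided p-value
$\min(1, 2\min(P_{\le}, P_{\ge}))$ is used, and "best" features are those
with the smallest p (ties broken by original column index) — this is how we
read "ordered by rank-sum score", since a raw $W$ ordering would be
direction-dependent.

Only the two widest blocks are reduced: the generic preset keeps the top
390 pCKSAAP and top 250 AAindex features; nine species presets
(`top_n_preset()`) carry the published per-species pairs. AAC, BE and PSSM
are kept in full — the source description of how those three blocks were
"adopted" is ambiguous, and keeping them whole is the conservative reading.
Selection is recomputed inside every training fold during cross-validation,
so held-out labels never influence the plan; published results may not have
done this, which is a possible source of divergence from printed AUC
values.

## Channels and fusion

Each encoding block trains one probability random forest (default 500
trees, $\sqrt{p}$ candidate features per split, single-threaded with a
fixed seed for bitwise reproducibility); a channel's score is the fraction
of trees voting "positive". The five channel scores $S_n$ are fused by
logistic regression,
$$\log \frac{P}{1-P} = \sum_{n=1}^{5} \beta_n S_n + \alpha,$$
with $\alpha$ fixed at 0 by default, matching the published per-species
coefficient sets (shipped as `fusion_preset()`; the H. sapiens set is
0.142, 1.566, 0.665, 0.342, 0.667 over AAC, AAindex, BE, PSSM, pCKSAAP).
No complete set was ever printed for *M. musculus* — only four of five
values — so that preset intentionally errors rather than guess the missing
channel.

Two design points are worth making explicit:

* **What the fusion is fitted on.** Fitting $\beta$ on resubstitution
  channel scores would be optimistic, so `train_model()` fits on
  out-of-fold channel scores (default, 10 folds with selection rebuilt per
  fold) or on the forests' out-of-bag votes (`fusion_scores = "oob"`).
  Inside `cross_validated_report()` the OOB variant is the default: a
  nested out-of-fold loop within every outer fold would multiply the number
  of forest fits by the inner fold count for little statistical gain.
* **Degenerate fits.** The five channel scores are strongly collinear (all
  channels are trained on the same windows toward the same labels) and on
  well-separated data the likelihood diverges. When the ML fit shows
  separation or coefficients outside $|\beta| \le 25$ (scores live in
  $[0,1]$, so larger magnitudes are not interpretable), the fit falls back
  to a mildly ridge-penalised logistic regression with non-negative
  coefficients, the standard stacking constraint; a warning is emitted.
  Every published coefficient set is positive, consistent with this
  constraint.

The decision cutoff defaults to the smallest value achieving specificity
$\ge 0.90$ on the validation-style fused scores ("confident cutoff"). With
$\alpha = 0$ every non-negative score combination gives $P \ge 0.5$, so a
fixed 0.5 cutoff would systematically overcall positives; the
specificity-targeted cutoff is the coherent companion of the zero
intercept. A fixed cutoff remains available.

## Evaluation

`metrics()` implements accuracy, specificity, sensitivity and Matthews
correlation from confusion counts, with any zero denominator mapping the
metric to 0; score ties at the cutoff count as positive calls. Note that
the verbal definitions of false positives/negatives that sometimes
accompany these formulas are internally inconsistent with the specificity
and sensitivity equations themselves; the standard definitions are used.
`roc_auc()` sweeps thresholds over the distinct scores (tied scores step
simultaneously) and integrates by trapezoid, which equals the Mann-Whitney
concordance probability — the test suite asserts that identity to 1e-12 and
cross-checks against pROC. `cross_validated_report()` repeats the entire
training workflow (selection, channels, fusion, cutoff) inside each of 10
stratified folds.

## Compositional analyses

`positional_aaf()`, `mean_profile_value()` (MPV) and
`mean_property_value()` (MPP, default scale NAKH920108, the amino-acid
composition of multi-spanning membrane proteins) summarise positive and
negative windows per position. `positional_test()` compares the groups:
Kruskal-Wallis per position for value matrices (with two groups this *is*
the rank-sum test, and is computed by the same code), or per-(position,
residue) chi-square tests of occurrence counts over window offsets -5..+5.
All p-values are Bonferroni-corrected by the number of tests actually
performed, which is reported in the output — published supplementary tables
do not state their family size, ours is always explicit. The central
position is constant (always K), so its chi-square tables have an empty
margin; these are reported with p = 1 under a single summary warning.
`enrichment_depletion()` returns the signed per-position frequency
differences that a two-sample logo would render (image rendering is out of
scope).

## The synthetic generator

`generate_synthetic()` produces proteins, labelled sites and matching
pseudo-profiles with no external inputs. Background sequences are uniform
over the 20 residues (a Swiss-Prot-like composition is available); each
lysine becomes a positive site with probability 0.30 (leaving enough
negatives for the 1:2 positive:negative training assembly to subsample);
around every positive site, flank residues at offsets ±1..±5 are rewritten
to a charged residue (E/R/D, uniform) with probability `effect_size`.
`effect_size = 0` is an exact null: labels are independent of sequence.

Lysine is deliberately excluded from the planted motif alphabet even though
charged-residue enrichment around real sites includes K: a planted K is
itself a new candidate site, so its window would near-duplicate the
adjacent positive's window while carrying a negative label. In an early
design that included K, roughly half the negatives were such twins and
out-of-bag channel scores dropped below chance while resubstitution scores
stayed near perfect — label noise the generative model does not intend.
This also means the generator does **not** emulate several properties of
real data: K enrichment around sites, homology between proteins (real
datasets are pre-filtered at 30% identity with CD-HIT, which this package
documents but does not re-implement), realistic residue composition
(unless the Swiss-Prot preset is chosen) and true evolutionary profiles.
Passing tests on synthetic data therefore demonstrate the machinery and
its calibration, not performance on real proteomes.

## Problem sizes and numerical choices

The end-to-end checks use the generator's defaults — 100 proteins of
150–250 residues, about 900 candidate sites, 10-fold cross-validation with
500-tree channels — and the null-calibration check uses 100 generator runs
of 30 proteins each. The exact rank-sum enumeration bound
($\binom{r+s}{r} \le 2 \times 10^5$), the ridge fallback strength
($\lambda = 10^{-2}$), the coefficient plausibility bound
($|\beta| \le 25$) and the specificity target (0.90) are the package's
fixed numerical conventions, documented where they act.

## Known limitations

* Pseudo-profiles are not evolutionary profiles; PSSM-derived channels are
  weaker informatively than with real PSI-BLAST output.
* The published datasets for the nine species are not redistributable
  here, so printed AUC/MCC tables are not reproduced; the package verifies
  structure, oracle equivalence and recovery on synthetic data instead.
* With two groups the Kruskal-Wallis positional test is the rank-sum test;
  no multi-group interface is exposed.
* The fusion's non-negativity fallback is a modelling choice; users who
  want the raw ML fit regardless of conditioning can fit their own `glm`
  on `out_of_fold_scores()` output.

```{r example, eval = FALSE}
# A complete synthetic round-trip:
dir <- tempfile()
run_simulate(file.path(dir, "data"), n_proteins = 30, effect_size = 1,
             seed = 1)
run_train(file.path(dir, "data", "proteins.fasta"),
          file.path(dir, "data", "sites.tsv"),
          file.path(dir, "model"),
          pssm_dir = file.path(dir, "data", "pssm"),
          top_n = c(pCKSAAP = 80, AAindex = 50), num_trees = 100, seed = 1)
run_predict(file.path(dir, "data", "proteins.fasta"),
            file.path(dir, "model"), file.path(dir, "pred.tsv"),
            pssm_dir = file.path(dir, "data", "pssm"))
run_evaluate(file.path(dir, "pred.tsv"),
             file.path(dir, "data", "sites.tsv"),
             file.path(dir, "metrics.json"))
```
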