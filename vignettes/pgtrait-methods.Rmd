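---
title: "Models and methods behind pgtrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pgtrait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pgtrait` predicts peptidoglycan (PG) metabolic capacity from gene-family
content and analyses how that capacity evolved. This vignette explains each
model, the parameters that matter, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The classifier and its truth model

A genome's capacity for PG metabolism is read off its CAZy family counts: it
must be able to synthesize the polymer (one GT28 gene for the
GlcNAc–MurNAc dimer, one GT51 gene for strand polymerization) and to
remodel or lyse it (at least one gene among GH23, GH73, GH102, GH103,
GH104). Presence means a count of at least one: CAZy reports per-genome
gene counts, and a single copy suffices for the enzymatic capacity the
rule encodes, so no higher threshold is defensible. GH25 also lyses PG-like
substrates but acts more broadly, so the default rule leaves it out; the
six-family variant is one argument away
(`geneset_rule(required_any = c(pg_focal_gh(), "GH25"))`).

Ground truth for PG presence comes from literature curation and is
genuinely three-valued: present, absent, or unknown. The package handles
this by exclusion, never imputation — unknown-status genomes are removed
from every confusion table and their number is carried in the output, so a
reader can always see how much evidence was discarded. Metrics with empty
denominators are `NA` ("undefined"), never 0 or 1: a marker that was never
negative has no negative predictive value, rather than a perfect one. The
orientation of "positive" is an explicit argument because both directions
are scientifically useful: the 3-gene set predicts PG *presence*, while the
absence of the single marker GT51 predicts PG *absence*.

## Association statistics

Domain associations use Pearson's chi-squared on 2×2 tables without the
Yates correction by default (the correction is available by flag; on
tables with cell counts in the hundreds it is immaterial). Correlation
between absence indicators uses the phi coefficient, computed in closed
form; because "Pearson correlation of two binary vectors" is exactly phi,
the package tests that identity explicitly rather than leaving the
equivalence implicit. PCA runs on the centered indicator matrix without
variance scaling by default — absence indicators already share a scale,
and scaling would inflate the influence of nearly-constant families — with
a `scale.` flag for the alternative reading. No multiple-testing
correction is applied anywhere; the analyses are descriptive screens, and
consumers who need familywise control can apply `p.adjust` to the reported
p-values.

The covariate regression is a binomial GLM of PG absence on three
binarized predictors: GC content below 50%, genome size below 1.5 Mb, and
obligate intracellular lifestyle (the cut-offs are arguments with these
defaults). The predictors enter jointly by default; a univariate mode
exists because published odds ratios of this kind are sometimes
per-predictor fits. Confidence intervals are Wald intervals on the log-odds
scale; complete separation (a predictor that perfectly splits the outcome)
is detected by runaway coefficients and reported as an infinite-odds-ratio
marker with a flag rather than an error or a silently huge number.
Goodness of fit uses a hand-rolled Hosmer–Lemeshow test on deciles of
fitted risk; with three binary predictors the fitted values tie heavily, so
the test bins by distinct risk levels and adjusts its degrees of freedom to
the realized number of bins.

## Gain-penalizing parsimony

Ancestral reconstruction uses Sankoff dynamic programming over the rooted
topology with asymmetric transition costs, defaulting to gain = 2,
loss = 1. The asymmetry encodes a biological prior: for these gene
families, regaining a lost gene requires horizontal transfer while losing
one requires nothing, so reconstructions should prefer losses. The 2:1
ratio is the smallest integer asymmetry that changes the optimum away from
classical parsimony — a gain is inferred only where it saves at least two
losses — and with equal costs the method reduces exactly to Fitch/Sankoff,
which the tests verify against phangorn.

Branch lengths are deliberately ignored (parsimony is a topology method),
and polytomies are handled natively by the DP rather than being resolved
arbitrarily. Ties are broken deterministically: at the root toward
presence (consistent with reading ancestral genomes as gene-bearing when
the evidence is balanced), and below the root toward the parent's state,
which pushes unavoidable changes toward the tips; tied nodes carry an
`ambiguous` flag. An event is a branch whose endpoint states differ, and a
branch — the "date" used by the clustering step — is identified by its
child node, so the root can host no event.

## The correlated-evolution test

Two binary characters are modelled jointly on the four states
{00, 01, 10, 11} of a continuous-time Markov chain in which simultaneous
double transitions have rate zero. The independent model gives each
character its own gain and loss rate (4 parameters); the dependent model
lets each character's rates depend on the other's current state
(8 parameters). Likelihoods come from Felsenstein pruning with per-branch
transition probabilities `expm(Qt)`; the root is weighted by a uniform
prior over the four states — implementations differ here, and the flat
prior keeps the likelihood a pure function of the rate parameters. Trees
without branch lengths get unit lengths: the comparative analyses this
package targets consume cladogram-like rRNA trees, and unit branches make
rates per-edge quantities.

The score is the likelihood-ratio statistic `2 (lnL_dep − lnL_indep)`,
clamped at zero since the models are nested and any negative difference is
optimizer noise. Because the asymptotic chi-squared(4) reference is
unreliable on trees of realistic size, significance comes from a
parametric bootstrap: characters are re-simulated under the *fitted
independent* model on the same tree, refitted under both models with the
identical procedure, and the error percentage is
`100 × (1 + #{simulated ≥ observed}) / (n_sim + 1)` — the add-one
correction keeps it strictly positive, and the resolution is
`100/(n_sim + 1)`, which is why `n_sim < 19` is rejected. Exchangeability
between the observed and simulated fits is what makes this calibrated, so
both run through exactly the same optimizer configuration.

Fitting maximizes over log-rates bounded in [1e-6, 1e3] by multi-start
Nelder–Mead (5 starts by default: one data-informed, the rest seeded
perturbations), followed by restart polishing — Nelder–Mead restarted at
its own optimum regains a full-size simplex and escapes premature
contraction. The independent model factorizes into two 2-state fits, which
is faster and more robust than a joint 4-parameter search; the dependent
fit starts from the independent optimum mapped into the 8-rate space, so
on null-like data the search begins near its optimum. The 4-state pruning
kernel is compiled (one eigendecomposition of the generator per likelihood
evaluation, two complex 4-vectors per edge) and the 2-state kernel uses the
binary chain's closed-form transition probabilities. The dependent-model
optimum was cross-checked against phytools' independent implementation.

## Event clustering

Date clustering asks which (character, event-type) pairs recur together on
the same branches. The implementation reports the *closed* co-occurring
sets: a set of events is a cluster when all members share at least two
branches and no strictly larger set shares exactly the same branches —
branch-exact co-occurrence is the strictest reading of events framed by
the same two speciation events, and a radius-1 neighborhood option was
considered and rejected as a default because it blurs precisely the
signal the date concept is meant to capture. Feature clustering groups
characters whose event-branch profiles match (Jaccard similarity 1 by
default, i.e. identical profiles; lowering the threshold merges by single
linkage), and may legitimately mix gains of one family with losses of
another. Clusters of two or more characters are verified by pairwise
Pagel tests and flagged supported when every pairwise error percentage is
at most 5 — one resolution step of a 19-simulation bootstrap, i.e. a
Monte-Carlo p-value of 0.05. Every input event either lands in a cluster
or is returned in the unclustered remainder, so nothing is silently
dropped.

## Synthetic data: what it emulates, and what it does not

The generators exist so that every stage of the pipeline can be exercised,
calibrated and regression-tested without any external data.

`simulate_tree` grows pure-birth (Yule) trees: epochs with *k* lineages
last Exp(k·birth_rate), a uniformly chosen lineage splits, and one final
epoch follows the last split, giving the textbook expected depth
Σ 1/(k·birth_rate). A death rate was left out deliberately: extinct
lineages change nothing about the methods under test and would complicate
the closed-form check.

`simulate_characters` evolves the joint 2-character chain by exact
waiting-time simulation, recording every node state and every change —
including multiple hits on a branch. Parsimony will undercount multiple
hits; that is a property of parsimony, not a bug, and the event-recovery
experiments therefore condition on histories with few changes (at most 10
on a 200-tip tree), where the identifiable regime lives. Replaying the
recorded events from the root must reproduce the tip states exactly; this
internal-consistency contract is asserted for every generated history the
tests touch.

`generate_cohort` draws annotation cohorts with a configurable confusion
design. Its defaults are the published screen's structure: 1,398 genomes,
90.1% set prevalence, PG present in every set-positive genome (which makes
PPV exactly 1 by construction, a deterministic component), PG absent in
84/108 of known-status set-negatives, 30/138 of set-negatives unknown, and
114/138 of set-negatives lacking GT51. Family counts are drawn consistently
with the set label (set-positives always satisfy the rule; set-negatives
never do). What the generator does *not* emulate: phylogenetic
autocorrelation between related genomes (rows are exchangeable),
annotation error in CAZy itself, and the taxonomic clustering of PG loss
in real phyla — so passing tests demonstrate the correctness and
calibration of the machinery, not the biological conclusions, which
require the real annotation tables and trees.

`simulate_covariate_cohort` is the regression companion: binary latent
predictors with known odds ratios generate PG absence through a logistic
model, and continuous covariates are drawn on the matching side of the
regression cut-offs, giving a parameter-recovery oracle.

## Problem sizes and reproducibility

The test-suite experiments use sizes chosen to make their statistical
assertions meaningful at interactive cost: parsimony is checked against
exhaustive enumeration on 500 trees of up to 8 tips (where enumeration is
exact), pruning against brute-force state summation on trees of up to 6
tips at tolerance 1e-8, bootstrap calibration on 200 replicates of
200-tip Yule trees with 19 bootstrap simulations each (the coarsest
resolution the error percentage allows, and the calibration property is
resolution-free), run with 2 optimizer starts per fit — calibration
depends only on observed and simulated data being fitted identically, not
on the number of starts — and event recovery on 200-tip trees conditioned
to at most 10 true changes. Every stochastic step flows from an explicit
integer seed; `pagel_test` and the generators restore the caller's RNG
state, and rerunning the pipeline with the same seed reproduces its
reports byte for byte.

## Known limitations

Parsimony reconstructions are point estimates with deterministic
tie-breaks; no uncertainty is attached to ancestral states. The
parametric bootstrap assumes the independent model class is adequate under
the null. The clustering step treats branch identity as exact, so events
separated by a single unresolved node never co-occur. And the classifier
is only as good as the annotations behind the counts: a family missed by
annotation is a false absence the package cannot detect.
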