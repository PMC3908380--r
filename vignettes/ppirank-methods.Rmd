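---
title: "Scoring bait-prey interactions from TAP/MS spectral counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring bait-prey interactions from TAP/MS spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppirank)
```

## The problem

Tandem affinity purification followed by mass spectrometry (TAP/MS)
pulls down a tagged bait protein together with everything bound to it —
its genuine interaction partners, but also sticky proteins that bind any
bead, and abundant cellular machinery (heat-shock chaperones, ribosomal
proteins) that contaminates most purifications. The spectral count (SC)
of a prey — the number of spectra mapped uniquely to it in a run — is a
label-free proxy for its abundance in the pulled-down complex. The
analysis task is to rank candidate bait–prey pairs so that true
interactions sit at the top, using only the SC tables of the bait
purifications and of negative-control purifications (untagged or
GFP-tagged cells processed identically).

This package scores each (bait group, prey) pair, where a *bait group*
is the set of biological replicates of one bait under one condition
(e.g. a stimulation time point). Conditions are scored independently:
an interaction may be present at 10 minutes of stimulation and absent
at 0. Control runs are shared globally across all bait groups — one
pool of negative controls serves the whole study (configurable at the
data-model level by declaring different tables, but the shipped
convention is global, matching the common design of six control
replicates against three bait replicates).

## The score

For prey $j$ in a purification run, the normalized spectral abundance
factor is

$$\mathrm{NSAF}_j = \frac{SC_j / L_j}{\sum_k SC_k / L_k},$$

the length-normalized count over the run total (long proteins yield
more peptides, so raw SCs overstate them). NSAF values within a run sum
to 1. Across the $T$ replicates of a bait group the per-replicate NSAFs
are averaged, counting 0 for replicates without a detection.

Three multiplicative terms turn abundance into an interaction score for
pair $(i, j)$:

$$\mathrm{PPIRank}_{i,j} = \overline{\mathrm{NSAF}}_{i,j}
  \times (1 - \mathrm{FDR}_{i,j})^{T}
  \times W_j \times \left(\frac{K}{\sum_i f_{i,j}}\right)^{R}.$$

**The control penalty.** $\mathrm{FDR}_{i,j}$ calibrates a one-sided
Wilcoxon–Mann–Whitney p-value — the prey's SCs in the group's
replicates versus its SCs in all control runs, both zero-filled — into
a lower bound on the posterior probability of a null interaction, via
the $-e\,p\,\ln p$ bound:
$\mathrm{FDR} = \left(1 + (-e\,p\ln p)^{-1}\right)^{-1}$ for
$p < 1/e$ and $0.5$ otherwise. The bound is only valid for $p < 1/e$
and approaches $0.5$ there, so clamping at $0.5$ keeps the calibration
continuous and monotone on $(0, 1]$. Raising $(1-\mathrm{FDR})$ to the
$T$-th power makes the penalty compound with the number of replicates:
a pair indistinguishable from control keeps at most $0.5^T$ of its
abundance score.

**The frequency penalty.** $K$ is the number of bait groups,
$\sum_i f_{i,j}$ the number of them detecting prey $j$; their ratio is
1 for promiscuous preys and $K$ for preys unique to one bait. $W_j$ is
the coefficient of variation of the prey's replicate-mean SC across all
$K$ bait groups (population standard deviation over mean; 1 when the
mean or the CV is 0): preys whose abundance varies strongly across
baits are more likely specific.

**The reproducibility exponent.** $R = N/T$ is the fraction of the
group's replicates detecting the pair. Rather than requiring detection
in every replicate, $R$ tempers the frequency reward: a pair seen in 1
of 3 replicates of an otherwise unique prey still earns $K^{1/3}$. This
is what lets the method *rescue* statistically strong but imperfectly
reproducible pairs — the motivating example is a pair with replicate
SCs 3/21/0 against six clean controls, whose exact rank-sum p-value is
$1/12$, FDR $\approx 0.36$, and score strictly positive — while a
binary reproducibility rule would drop it.

Two readings of the printed formula are possible for the placement of
$W_j$ relative to the exponent; the default applies $R$ to the
frequency ratio only, with `ppirank_config(exponent_includes_w = TRUE)`
giving the alternative $\left((K/\sum f)\,W_j\right)^R$. Similarly the
baseline CompPASS weighted-D score keeps its original square-root form
$\sqrt{s\,((K/\sum f)\,W_j)^N}$; neither switch is silent, both are
config fields.

## Baselines, filters, decision points

`score_all()` also reports NSAF-only, the CompPASS-style $Z$ score
(the pair's replicate-mean SC standardized against the prey's mean and
SD across all bait groups), and the weighted-D score, so method
comparisons run on one table.

Two filters flag rows (never delete them; ranks are recomputed over
survivors):

* **Singleton filter** — every replicate SC $\le 1$. A lone spectrum
  per replicate is the signature of identification noise even when it
  recurs. The literal stricter rule (every SC exactly 1) is
  `singleton_strict = TRUE`; the default generalizes it so that e.g.
  SCs (0, 1, 0) with $T = 3$ are also flagged, which is the sensible
  extension for designs with $T \ne 3$.
* **Exclusion filter** — glob patterns over prey/bait identifiers with
  category tags (heat-shock, ribosomal, user), shipped as an editable
  text file (`inst/extdata/contaminants.txt`) because contaminant
  *classes*, not fixed gene lists, are the stable notion.

Deliberate conventions, chosen where the method's description leaves
latitude:

* **Replicate collapse for cross-purification statistics** ($W_j$,
  $Z$): the replicate-mean SC per bait group, zeros included — the mean
  is the collapse used everywhere else in the scoring.
* **Standard deviation**: population ($\div K$), so $Z$ is defined at
  $K = 2$; `sd_type = "sample"` switches both $W$ and $Z$.
* **Sidedness**: one-sided (bait greater than control). The test exists
  to find enrichment over control; a two-sided test would also reward
  control-enriched contaminants.
* **Exact versus approximate rank-sum**: exact enumeration of all
  $\binom{n_1+n_2}{n_1}$ label assignments up to pooled size 12 —
  covering the canonical $3+6$ design with $\binom{9}{3} = 84$
  assignments and handling ties exactly, which base R's exact path
  refuses — then the tie- and continuity-corrected normal
  approximation.
* **Numerical floors**: p-values are clamped to $[10^{-16}, 1]$ before
  $\ln p$, preventing a $0 \cdot \infty$ at underflow; all-equal
  samples give $p = 1$ directly.
* **Ties and determinism**: ranks break ties lexicographically by
  (bait group, prey), so output is a pure function of input. Top-$k$
  cuts in the evaluation module are taken after tie-breaking and are
  always exactly $k$ pairs.
* **Self-detections** (prey = bait protein) are scored and flagged
  `is_self`, since the bait always purifies itself; they are excluded
  from evaluation rankings and benchmarks.
* **Control-only preys** are never scored: with $\sum_i f_{i,j} = 0$
  there is no pair to score, which is itself the correct call.

## What the simulator emulates — and what it does not

`simulate_apms()` generates the design the statistics assume: several
baits $\times$ several conditions $\times$ $T \ge 3$ biological
replicates, plus $\ge 6$ shared negative controls. Prey classes:

* **true interactors** (10 per bait by default, carried across
  conditions): $SC \sim \mathrm{Poisson}(\lambda_{true} = 10)$ per
  replicate, thinned by Bernoulli dropout (0.2) — the "detected in 2 of
  3 replicates" phenomenon; absent from controls;
* **sticky binders** (10% of preys): $\mathrm{Poisson}(\lambda_{bg} =
  2)$ in a random ~70% of bait groups, carried into each control run
  with probability 0.3;
* **contaminants** (5%, named `Hsp..`/`RpL..` to exercise the
  exclusion patterns): like sticky preys but abundant
  ($\lambda = 8$, present in ~80% of groups) — the realistic failure
  mode of abundance-only scoring;
* **background**: sparse noise, each (prey, run) detected with
  probability 0.05 at $\mathrm{Poisson}(2)$, controls included;
* **bait self-rows** at $\mathrm{Poisson}(60)$.

Counts are Poisson (negative-binomial via `dispersion > 0` if
overdispersion is wanted); lengths are uniform on 100–1000 residues.
The default problem size — 18 bait groups, 60 runs, 300 preys, roughly
1200 detected pairs — keeps a full simulate–score–benchmark cycle
under a few seconds, and the benchmark in the acceptance script
averages five such replicate experiments.

The generator is deliberately idealized: counts are independent across
preys (no compositional competition for the MS instrument beyond the
NSAF normalization itself), there is no peptide-level identification
ambiguity, no batch structure among runs, no correlation between a
prey's length and its abundance, and true edges are equally strong in
every condition. Passing benchmarks on this generator therefore shows
that the scoring separates the *statistical signatures* it targets —
reproducible enrichment over clean controls versus promiscuous or
sporadic binding — not that it will achieve the same AUROC on any real
dataset.

On these defaults the composite score recovers planted edges with mean
AUROC above 0.9 and above the NSAF-only and $Z$ baselines (the
weighted-D baseline is also strong on this generator, where its
unbounded frequency reward is never punished by related baits sharing
true partners — the regime where it is known to fail is many baits of
one pathway, which the generator's independent-bait design does not
create). In the noise-free limit (no dropout, no background, no
carryover) every scored non-self pair is a planted edge and every
planted edge is scored positive — perfect separation; the AUROC
statistic itself is then degenerate (its negative class is empty) and
`benchmark_methods()` reports `NA` with a warning rather than
inventing a value.

## Choosing a cutoff

The ranking is continuous; significance calls need a threshold.
`cutoff_from_reference()` sweeps every rank cutoff against a
known-interaction reference (e.g. BioGRID physical interactions, loaded
with `read_biogrid_tab(..., physical_only = TRUE)` since genetic
interactions are indirect) and returns the score maximizing F1 of
known-pair recovery over the scored list (or precision at a recall
floor). Known pairs are compared as unordered gene-symbol pairs —
reciprocal detections of the same interaction from either bait count
once — with identifier-to-symbol mapping applied only at evaluation
time so that scoring stays identifier-stable.

## Known limitations

* The per-pair FDR is a calibration of a single p-value, not a
  set-level error rate across all reported pairs; no multiplicity
  correction is applied, by design.
* With fewer than three replicates the reproducibility term loses
  resolution ($R \in \{0.5, 1\}$ at $T = 2$); `score_all()` warns.
* $K$ counts bait groups within the table being scored; scoring
  conditions jointly versus separately changes $K$ and hence the
  frequency reward. The shipped convention scores per condition.
* The exact rank-sum enumeration grows combinatorially; above pooled
  size 12 the normal approximation is used, which for very sparse
  counts at small $n$ is conservative near $p = 1$.
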