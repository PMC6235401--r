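---
title: "Reconstructing Y-chromosome gene-content evolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing Y-chromosome gene-content evolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ycontent)
```

## The problem

Drosophila Y chromosomes occasionally stop being Y chromosomes: a single
Y-linked gene can move to an autosome or the X ("Y chromosome gene
transfer"), a gene can be deleted outright ("genomic gene loss"), or — more
dramatically — the entire Y can be incorporated into another chromosome, so
that every formerly male-limited gene becomes present in females. Surveys of
these events use a cheap and scalable assay: degenerate PCR of known
Y-linked genes in males and females. Each species × gene cell then takes one
of four observation states:

* `M` — amplification in males only: the gene is Y-linked;
* `MF` — amplification in both sexes: the gene is autosomal or X-linked
  ("A/X");
* `F` — failure in both sexes: a candidate genomic loss;
* `NA` — not tested, or an uninterpretable assay.

Raw cells are not events. The same `MF` state shared by a whole clade traces
back to a single change in its stem lineage, so the observations must be
placed on a phylogeny and the minimal set of independent state changes
inferred. `ycontent` implements that inference, the exact statistics used to
summarise it, and a forward simulator of the underlying process that serves
as the package's synthetic-data generator.

## Parsimony model

Ancestral states live in `{Y, AX, absent}`. Tips map as `M → Y`,
`MF → AX`; `F` maps to `absent` only when corroborated (see below), and `NA`
tips are free variables, equivalent to pruning them. Reconstruction is
minimum-cost (Sankoff) dynamic programming under a 3×3 cost matrix with
three presets:

* **Dollo** (default for ancestrally Y-linked genes): `AX → Y` and any
  resurrection from `absent` are forbidden (infinite cost); losses cost 1.
  A gene known to be on the ancestral Y can leave it, but re-gains are
  implausible under the assay's own logic — on the eight-species ORY
  example, the ancestral-Y hypothesis needs 2 changes while the
  ancestral-A/X alternative needs 4 independent gains.
* **Fitch**: all changes cost 1; useful for sensitivity analysis.
* **Sankoff**: arbitrary user costs, including `Inf` to forbid transitions.

The root state can be constrained (`Y` for genes known to be on the
ancestral Y, `AX`, or free). Data that would require a forbidden change
under the chosen constraints are reported as infeasible, never silently
relaxed.

**Tie-breaking.** Minimum-cost assignments are often non-unique. We resolve
ties by delayed transformation: in the root-to-tip pass each node keeps its
parent's state whenever that state is among the co-optimal choices, pushing
changes toward the tips; remaining ties use the fixed order `Y`, `AX`,
`absent`. This makes reconstructions deterministic. It is a convention — on
NA-heavy regions an event could equally sit one branch rootward.

**Verification.** `brute_force_min_cost()` enumerates every internal-state
assignment (up to 14 tips) and is tested against the dynamic program on
hundreds of random trees, tip patterns and cost models; Fitch-mode minima
are additionally cross-checked against `phangorn::parsimony()`.

## From changes to independent events

Changes on the same branch are merged by `classify_events()`:

* if the `Y → AX` changes on a branch cover at least `inc_fraction` of the
  genes reconstructed `Y` in the parent node *and* at least `min_genes`
  genes, they form one **incorporation** event. Defaults are
  `min_genes = 3`, `inc_fraction = 1.0` ("all genes"); `0.9` is a useful
  "nearly all" sensitivity setting, since real incorporations can be
  followed by losses that erode the signal.
* genes declared physically adjacent (a user-supplied `groups` list backed
  by synteny evidence — e.g. *PRY* and *JY-alpha*, side by side on the
  *obscura*-group X) that change on the same branch merge into one
  **transfer**; adjacency is never inferred from the data.
* remaining `Y → AX` changes are single-gene **transfers**; `Y → absent`
  changes are **genomic losses**; `AX → Y` changes (possible only outside
  Dollo mode) are **gains**.

Every change belongs to exactly one event, so event gene-counts per branch
sum to the raw change count — a tested invariant.

**The `F → absent` rule.** PCR failure is ambiguous: primer mismatch or a
true deletion. We map `F` to `absent` only when the gene shows `F` in at
least two species (`f_min_species = 2`) or when it is listed in
`confirmed_absent`. The published surveys confirm failures by repeated,
multi-strain PCR; a corroboration count is the closest operational proxy
that needs no wet-lab metadata. Isolated `F` cells become `NA`.

## Exact statistics

**Rates.** Exposure is the time a gene spent at risk: the sum of branch
lengths (Myr) over branches whose parent node is reconstructed `Y`,
summed over genes (gene-Myr). The branch on which a loss is inferred counts
in full — the event time within the branch is unknown and the gene was at
risk until it happened; `event_branch = "half"` is provided as a
sensitivity setting. Rates are `n/T` with the exact Garwood interval
(`qchisq(α/2, 2n)/2T`, `qchisq(1−α/2, 2n+2)/2T`), which reproduces the
published per-gene loss-rate bounds:

```{r garwood}
tidy(poisson_rate_ci(13, 13198))
```

Whole-Y incorporations are lineage-level events, so their exposure is tree
time (total branch length, Myr), not gene-Myr. One published incorporation
rate is computed from supplementary accounting that is not reconstructable
from the main text; the package therefore fixes the denominator convention
(total tree Myr) and documents it rather than matching that figure.

**Tests.** Two rate estimates are compared by the exact conditional test
for the ratio of two Poisson means: given `n1 + n2`, `n1` is binomial with
probability `T1/(T1+T2)` under equal rates. Re-acquisition tables are
tested by the two-tailed Fisher exact test. Both two-sided p-values use the
minimum-likelihood convention (sum of outcomes no more likely than the
observed one), which reproduces the published `P = 0.011` on the (9,2;0,4)
table; tail-doubling is available behind a flag for the ratio test. Both
tests are verified against full enumeration and against the independent
`stats::fisher.test` / `stats::binom.test` implementations.

## The duplicated-Y simulator

`simulate_gene_content()` runs a continuous-time forward model down a tree:

* per-gene Poisson processes: transfer (`λ_transfer`, per Y-only gene per
  Myr), genomic loss (`λ_genomic_loss`), gain (`λ_gain`, default 0 because
  gains are not unbiasedly detectable by the male/female PCR design);
* a lineage-level incorporation process (`μ_incorporation`) that fires only
  while at least one gene is Y-only and duplicates every Y-only gene: the
  free Y survives alongside the new A/X copy;
* per-redundant-gene resolution (`ρ_resolution`), keeping the Y copy with
  probability `π_keep_Y`.

The observation layer then maps truth to the assay: `M` iff only the Y copy
remains, `MF` whenever an A/X copy exists (a surviving Y copy is invisible
behind it), `F` when no copy remains, plus independent `NA` masking with
`pcr_fail_prob`. This reproduces the central asymmetry of the duplicated-Y
model: genes appear to "re-acquire" Y-linkage only after the A/X copy is
lost, and only ancestrally Y-linked genes can ever do so — control genes
that start A/X can never show `M` (a tested structural property).

Defaults are chosen to resemble the published survey's regime: transfer
rates of order 10⁻³ per gene per Myr (the published point estimate is
0.000985), genomic losses an order of magnitude rarer (1 of 17 single-gene
events in the survey), gains off. No resolution rate is published; `ρ` and
`π_keep_Y` defaults (0, 0.5) are illustrative and must be set by the user
for duplicated-Y scenarios. The *D. nikananu* persistence argument (copies
retained from the incorporation ≥ ~19 Myr ago until a ~5.9 Myr-old split)
only bounds `ρ` loosely from above and is treated as an anecdote, not a
calibration.

Reproducibility: a seed is mandatory; random numbers are consumed in a
fixed order (pre-order branches, genes in input order), so identical
configurations give identical truth matrices and event logs. Deterministic
scenarios (e.g. "one incorporation on this clade stem at this time") are
expressed with `forced_events`, which the tests use for limit-behaviour
checks.

**What the generator does not emulate.** Real surveys have phylogenetic
uncertainty, non-independent PCR failure (primer families fail together),
lineage-specific rates, and detection biases near the root; the simulator
assumes the tree known, cells independent, and rates homogeneous. Passing
recovery tests therefore validate the inference machinery under the model's
own assumptions, not the robustness of the published conclusions to
violations of them.

## Parameter recovery and problem sizes

`recovery_experiment()` closes the loop: simulate → observe → infer →
compare to the truth log. At the package's reference scale (500 replicates
of 100-tip Yule trees, birth rate 0.1/Myr — giving total tree lengths near
1,000 Myr, comparable per-gene to the published survey's 6,529 Myr over
400 species — 9 genes, λ = 0.001/gene/Myr) the Garwood 95% CI covers the
true rate in ≈97% of replicates and the mean signed rate error is ≈ −1%
of λ. Exact intervals are conservative by construction, so coverage sits
above — not at — the nominal level.

A replicate is *parsimony-identifiable* when, for every gene, the Dollo
minimum cost on the true tip states equals the number of true events: with
~1 expected event per gene per tree, two parallel transfers of the same
gene occasionally land on sister branches and collapse into one inferred
event. That is the correct parsimony answer to the data, so exact-match
recovery (count and branch placement) is asserted on identifiable
replicates (~97% of all) and the identifiable fraction is reported
alongside. The tie-break convention guarantees that a single true transfer
is recovered on exactly its true branch.

Yule trees use an explicit stopping convention — the tree is extended past
the n-th speciation by an `Exp(n·λ_birth)` overhang — chosen because it
gives the closed-form expected crown age `Σ_{k=2..n} 1/(k·λ_birth)` used as
the test oracle.

## Numerical and design choices

* Species matching is exact after whitespace trimming; no fuzzy matching —
  a silently mis-matched tip corrupts the parsimony, so mismatches are
  errors.
* Linkage matrices are TSV by default, CSV by flag; state tokens are
  case-insensitive with a synonym map (`male`, `male+female`, `fail`, `-`).
* Branch lengths are Myr throughout. Trees without lengths support event
  counting only: exposure, and hence every rate, is refused rather than
  silently computed on unit branches.
* Cost-model ties in the dynamic program are compared with a 10⁻⁹ absolute
  tolerance, adequate for user costs of order 1; `Inf` encodes forbidden
  transitions exactly.
* p-values use a `(1 + 10⁻⁷)` relative tolerance when collecting outcomes
  "as extreme as observed", matching the convention of R's own exact tests.
* The package's in-built worked examples encode only facts stated in the
  source figures, captions and text; the full 400-species matrix lives in
  supplementary material and is not reproduced. The *montium* fixture
  therefore carries `NA` for unstated cells plus a separate one-row
  clade-summary matrix (which genes are Y-linked in ≥ 1 species) from
  which the published 9/2/0/4 table is computed.

## Known limitations

* Parsimony undercounts events in high-rate regimes (homoplasy); the
  recovery experiment quantifies this through the identifiable fraction,
  but no correction is applied.
* The `F → absent` corroboration rule is a proxy; with very sparse
  matrices it can both over- and under-call genomic losses.
* Event placement on NA-heavy paths is conventional (delayed
  transformation); the alternative accelerated placement can shift an
  event one branch rootward and thereby change exposure slightly.
* Incorporation calling with `inc_fraction = 1` is strict: an
  incorporation followed by a same-branch genomic loss of one gene is
  classified as transfers plus a loss unless the threshold is relaxed.
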