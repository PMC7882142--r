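---
title: "Quantitative quarry analyses: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative quarry analyses: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`quarrypal` bundles the four quantitative analyses that typically accompany
the description of a partial plesiosaurian (or comparable marine-reptile)
skeleton: proportional body-length estimation, gastrolith shape statistics,
circular statistics on element orientations, and morphological
maximum-parsimony phylogenetics. This vignette documents the models behind
each stage, the conventions and tunable parameters, the design choices made
where the methods literature leaves latitude, and what the synthetic-data
generators do and do not emulate.

## Proportional body-length estimation

**Model.** The specimen preserves a pectoral-to-sacral vertebral column
("trunk", length $T$ mm) plus an incomplete caudal series and has an
estimated skull length $S$ mm. Complete relatives supply two kinds of
fractions: the caudal series as a fraction $f$ of the post-cervical column
(trunk + caudal), and the neck as a fraction $g$ of the postcranial skeleton.
Assuming isometry,

$$\text{caudal} = \frac{f\,T}{1-f}, \qquad
  \text{postcranial} = \frac{T + \text{caudal}}{1-g}, \qquad
  \text{total} = \text{postcranial} + S.$$

Ranges come from the extreme fractions in the comparative table; averages are
midpoints. A final isometric step scales the average by the linear ratio of
the largest referred specimen.

**Rounding convention.** All rounding is half-up (half away from zero,
`round_half_up()`), applied only where a quantity is reported: caudal lengths
to integer mm, metre values to one decimal, fractions to three decimals.
Intermediate values stay unrounded, with two deliberate exceptions that
mirror how such chains are conventionally reported: the caudal average is the
midpoint of the *reported* (integer-mm) caudal range, and the total average is
the midpoint of the *reported* (one-decimal) total range. Base R's
round-half-to-even would print the midpoint of a 4.0–6.3 m range as 5.1 m;
half-up gives the conventional 5.2 m.

**The reference table.** `reference_proportions()` carries the standard
elasmosaurid comparative set: caudal/post-cervical fractions for
*Thalassomedon* (1,216/4,299 mm = 0.283), *Albertonectes* (1,860/4,180 mm =
0.445) and *Morenosaurus* (1,632/3,627 mm = 0.450), and neck/postcranial
fractions for *Nakonanectes* (39.3%) and *Albertonectes* (62.5%). The
*Nakonanectes* neck length is stored as 2,083 mm, back-computed from the
printed percentage of its 5,300 mm postcranium: the frequently quoted
"2.2 m" neck is itself a rounded figure and would give 41.5%, not the 39.3%
the downstream chain requires. Likewise the post-cervical length entering the
postcranial step is kept at full mm precision (e.g. 2,246 mm) rather than a
rounded "2.2 m": the unrounded value is what reproduces a 3.7–6.0 m
postcranial range.

**Degenerate inputs.** A single proportion per part kind collapses the range
to a point; fractions at or outside (0, 1) are rejected (the caudal formula
has a pole at $f = 1$).

## Gastrolith (clast) shape statistics

Each clast is measured on three orthogonal axes $a \ge b \ge c$ (mm); the
constructor sorts whatever order the field sheet used. Two indices are
computed per clast:

* **Maximum Projection Sphericity** $\psi = (c^2/(ab))^{1/3}$. The compact
  in-line notation "(c^2/b × a)^1/3" sometimes seen in print is read this
  way — the literal left-to-right parse would not be dimensionless, and only
  this reading matches the index's definition in the sedimentological
  literature.
* **Oblate–Prolate index** $OP = \dfrac{10}{c/a}\left(\dfrac{a-b}{a-c} -
  0.5\right)$, negative for disk-tending, positive for rod-tending clasts.
  $OP$ is undefined for equant clasts ($a = c$); these are excluded from OP
  aggregation, counted, and reported.

**Shape classes.** The four-class disk/sphere/blade/roller assignment is
realized, by default, as the Zingg partition of the $(b/a,\, c/b)$ plane at
the classical 2/3 threshold. Because published four-class schemes are also
drawn on the Sneed–Folk form triangle, a second scheme
(`scheme = "form_triangle"`, on $c/a$ and $(a-b)/(a-c)$ with thirds) is
available behind a switch so a deposited measurement sheet can arbitrate
between the two; both are exhaustive and exclusive.

**Population summaries.** Means and sample standard deviations ($n-1$) of
$\psi$ and $OP$, class percentages (summing to 100), and mass statistics over
clasts with recorded mass. The mass histogram uses fixed-width bins from 0;
the default width of 2 g matches the granularity customary in gastrolith
figures and is a parameter. The (mean $\psi$, mean $OP$) pair is exported as
plot coordinates for visual comparison with published beach/river discriminant
fields; no depositional-environment label is assigned automatically, because
that assignment is a visual judgement against a published field diagram, not
a computation.

## Orientation (circular) statistics

Angles are compass bearings in degrees, clockwise from north, stored in
$[0, 360)$; all trigonometry converts to radians internally. Elongate-bone
orientations are **axial** (defined only up to 180°), so tests and summaries
operate on doubled angles $2\theta \bmod 360$ and mean directions are halved
back and reported as a $\theta/\theta{+}180$ pair. A flag
(`use_axial_doubling = FALSE`) allows running on raw bearings for comparison
with software that treats the data as directed.

The battery comprises the mean resultant length $R$ (circular variance
$1 - R$), a dispersion-based large-sample 95% confidence arc for the mean
direction (flagged undefined when the arcsine argument exceeds 1), and four
uniformity tests:

* **Rayleigh** $Z = nR^2$, asymptotic $p$ by the standard fourth-order series
  in $Z$ and $n$; powerful against unimodal concentration.
* **Rao's Spacing** $U = \tfrac12 \sum_i |T_i - \lambda|$ over circular
  spacings $T_i$ with $\lambda = 360/n$; sensitive to multimodal departure.
* **Watson's $U^2$**, the rotation-invariant Cramér–von Mises statistic, with
  the usual small-sample modification before the asymptotic series.
* **Kuiper's $V = D^+ + D^-$**, reported on both the raw scale and the
  stabilized scale $V(\sqrt n + 0.155 + 0.24/\sqrt n)$, so either convention
  found in circular-statistics software can be matched; the asymptotic series
  is applied to the stabilized value.

**p-value methods.** Every test offers a seeded Monte-Carlo $p$ (default
10,000 simulations, default seed 20210211). Rao's Spacing additionally offers
`method = "table"`, which returns a bracketing range between conventional
significance levels (the familiar "0.50 > p > 0.10" style). The bracket grid
is a set of null quantiles frozen from a one-time simulation of 200,000
uniform samples per tabulated $n$ — a simulated stand-in documented as such,
not a copy of published tables — and values are interpolated linearly in $n$.
Tests under the uniform null show the grid's 5% critical value rejecting at
the nominal rate.

**Known accuracy limits.** The stabilized Kuiper series is an asymptotic tail
approximation: at $n = 50$ it tracks Monte-Carlo $p$-values to well within
0.02 in the rejection-relevant region ($p \lesssim 0.35$) but can deviate by
up to about 0.03 in mid-distribution ($p$ around 0.5–0.9), where no decision
rides on it. The Monte-Carlo method is authoritative when the two disagree.

## Maximum-parsimony phylogenetics

Characters are unordered and equally weighted. Missing (`?`) and gap (`-`)
scorings both contribute the full state alphabet to the Fitch state set — the
default treatment for standard (morphological) data — and polymorphic
scorings contribute their state set as-is. Fitch optimization is implemented
on bitmask state sets; length is invariant to root placement, and polytomies
other than the basal trifurcation of an unrooted tree are refused rather than
silently resolved.

**Step bounds and ensemble indices.** Per character, the minimum steps equal
the number of distinct unambiguously observed states minus one, and the
maximum (over binary trees) equals the number of unambiguously scored taxa
minus the modal-state count. The ensemble consistency index
$CI = \sum m_i / L$ and retention index
$RI = (\sum M_i - L) / (\sum M_i - \sum m_i)$ are reported to two decimals.
The headline $CI$ conventionally includes parsimony-uninformative characters;
`exclude_uninformative = TRUE` computes the variant that drops them (and
their fixed contribution to $L$), since published values do not always state
which convention was used.

**Search.** Each replicate draws a random addition sequence, builds a
starting tree by greedy stepwise addition, and then hill-climbs with full
tree-bisection-reconnection (TBR) swapping, keeping up to a configured number
of equally short trees per replicate (plateau collection). The global result
is the deduplicated union — tree identity is the unrooted bipartition set —
of the shortest trees across replicates, capped with a warning at
`max_trees_total`. Ties (equal-length candidates) are broken by a seeded
draw, so the whole search is reproducible from `search_config(seed = )`.

**Consensus and wildcards.** The strict consensus keeps exactly the
bipartitions common to all trees. The Adams consensus is the classic
nesting-based construction: the partition product of the root partitions,
recursing inside each block on the restricted trees; unrooted inputs must
designate an outgroup. Wildcard (rogue) detection is operationalized as a
greedy pruning rule — score each leaf by the gain in strict-consensus
resolution (internal-edge count) after pruning it from every tree, select
while the gain is positive — with the classical strict-vs-Adams placement
disagreement reported as supporting evidence for each selection rather than
being the selector itself. The reduced strict consensus re-deduplicates the
pruned trees (pruning can merge topologies) and can recompute lengths on the
pruned leaf set when the matrix is supplied.

**Bootstrap.** Characters are resampled with replacement; each replicate runs
a reduced-budget search (default 10 addition-sequence replicates — a full
search per pseudo-matrix would be wasteful since support values are
aggregates), and support is the percentage of replicates whose strict
consensus contains the bipartition. Deterministic given the seed.

**Rooting.** No outgroup is hard-wired; rooting affects neither lengths nor
strict-consensus bipartitions, only Adams consensus and displayed trees.

## Synthetic data

The generators produce inputs with the statistical structure each stage
assumes, at sizes where independent oracles are affordable:

* `gen_clasts()` draws the $a$ axis from a log-normal (default
  $\ln a \sim N(\ln 18, 0.45^2)$, spanning the few-mm-to-few-cm range typical
  of plesiosaurian gastroliths) and the $b/a$, $c/b$ ratios from scaled
  Beta(2,2) distributions supported strictly inside the drawn class's Zingg
  region, so the intended class mix is honoured by construction. The default
  mix (65.8% disk, 13.2% sphere, remainder split evenly between blade and
  roller) mirrors a beach-dominated gastrolith population; masses are a
  density × ellipsoid-volume proxy at 2.65 g/cm³.
* `gen_orientations()` is uniform at $\kappa = 0$ and otherwise von Mises on
  the doubled circle (Best–Fisher sampler), halved back to axial bearings
  with random end assignment.
* `gen_matrix_on_tree()` evolves unordered characters root-to-tip under a
  symmetric $k$-state model with a per-edge change probability, plus optional
  per-cell missingness; it returns the generating topology as the recovery
  target.
* `gen_specimen_proportions()` decomposes a true skeleton by fractions drawn
  on a 0.001 grid (so the three-decimal proportion table is lossless at zero
  noise) and perturbs emitted fractions by multiplicative log-normal noise.

Every generator takes an explicit seed and derives a private substream, so
adding a generator never changes another's output. `write_default_fixtures()`
regenerates the committed example set (76 clasts, 50 near-uniform axial
angles, a 12-taxon × 60-character matrix with its true tree, and the
reference proportion table) from one seed.

**What the generators do not emulate** — and hence what passing tests do not
establish about real data: correlated characters and clade-specific rate
variation in matrices (characters are i.i.d. given the tree); taphonomic
mixtures of aligned and jumbled elements (angle samples are single-population
uniform or unimodal); lithology-dependent shape and mass covariance in
clasts; and measurement error on skeletal lengths (only the comparative
fractions carry noise). They are statistical stand-ins, not forgeries of any
particular quarry's unpublished measurements.

## Problem sizes used by the test suite

The suite favours sizes where exhaustive oracles exist: search optimality is
checked against full topology enumeration on 200 seeded matrices of 5–7 taxa;
Fitch lengths against brute-force internal labelings on trees of up to 6
leaves and 3 states; Adams consensus against an independent nesting-set
oracle on all 5,565 unordered pairs of rooted 5-leaf binary trees; test
calibration on 2,000 simulated null datasets of $n = 50$; and estimator
recovery on hundreds of synthetic skeletons. The topology-recovery suite uses
a per-edge change probability of 0.05 on 6-taxon, 200-character binary
matrices — about one expected change per character across the tree, this
package's realization of a "low-rate" regime. Note that recovery of the
generating tree *as the unique most-parsimonious tree* is a property of the
data as much as of the method: at finite character counts a simulated matrix
can have tied optima, or an optimum that differs from the generating tree,
and no exact search can undo that. These sizes are the package's chosen
trade-off between oracle coverage and runtime.

## Limitations

* The heuristic search is exact only in expectation: like any
  random-addition + TBR scheme it can miss the optimum on adversarial
  instances, and its pure-R tree surgery targets matrices of tens of taxa,
  not the hundreds that compiled programs handle.
* Rao's Spacing table brackets rest on simulated quantiles (see above).
* The Adams consensus requires rooted trees or an explicit outgroup.
* No ordered or weighted characters, step matrices, implied weighting, Bremer
  support, likelihood or Bayesian inference; no body-mass or allometric
  models; no two-sample circular tests.
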