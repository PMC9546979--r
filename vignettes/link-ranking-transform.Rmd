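---
title: "Comparing network groups through link-weight rankings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing network groups through link-weight rankings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankdelta)
```

## The problem and the representation

Deciding whether two populations of weighted networks — say, functional
brain connectivity matrices from patients and matched controls — differ is
usually attacked link by link, or through global topological indices. Both
approaches tie the answer to link *identity* (which electrode pair, which
ROI pair). `rankdelta` implements a deliberately topography-free
alternative: each network's off-diagonal link weights are ranked in
decreasing order, and the two groups are compared *position by position in
the ranking*. The question becomes "do the strongest (second-strongest, ...,
weakest) connections behave differently across conditions?", regardless of
where in the network they sit.

For each ranking position $r$ and each group $g$, the package computes the
median $M_g(r)$ and the sample standard deviation $Std_g(r)$ of the $r$-th
ranked weight across the group's networks, and reports their contrasts

$$\Delta M(r) = \log_2 \frac{M_{g2}(r)}{M_{g1}(r)}, \qquad
  \Delta Std(r) = \log_2 \frac{Std_{g2}(r)}{Std_{g1}(r)}.$$

Positive $\Delta M$ means the second group has the stronger links at that
position; positive $\Delta Std$, the larger between-subject variability. A
$\Delta$ of 3 is an eight-fold ratio (`fold_change(3)` = 8). The profile is
drawn in the $\Delta Std$–$\Delta M$ plane, one point per ranking position,
coloured from red (rank 1, strongest) to blue (weakest); group differences
show up as characteristic curve geometries readable at a glance.

A note on orientation: descriptions of this representation sometimes write
the ratio with the groups the other way up while simultaneously reading
positive values as "the second group is larger". The package fixes the
convention to the reading above — $\Delta = \log_2(\text{group 2}/\text{group
1})$ — because it is the one every downstream interpretation in the plane
relies on, and documents it here once.

## Statistics of order statistics, and their uncertainty

Per-rank medians are statistics of order statistics: the $r$-th ranked
weight of a network is an extreme-value quantity, so its across-network
distribution is *not* the weight distribution of any one link. Medians are
used instead of means for robustness at the extreme ranks. Standard
deviations use the $n-1$ (sample) denominator; group sizes may differ and
each group is summarised with its own size.

Ranks where a median or standard deviation is non-positive in either group
have no defined log-ratio. Such ranks are flagged (`defined = FALSE`),
excluded from plots, and *no epsilon is added*: connectivity weights such as
$-\log_{10} p$ can be exactly zero, and nudging them would silently bias the
weakest ranks, exactly where the method claims sensitivity. Each of
$\Delta M$ and $\Delta Std$ is still reported wherever its own ratio is
defined.

Uncertainty is quantified by subsampling: `floor(n/2)` networks are drawn
without replacement from each group (independently per group — the two
cohorts are independent samples, so coupling the halvings would fake
correlation), the transform is recomputed, and per rank the 16th–84th
percentiles across `n_resamples = 200` such draws form a box around the
point — the spread the point would have if only half the data were
available. Percentiles use the linear-interpolation convention
(`quantile(type = 7)`). For small groups `exhaustive = TRUE` replaces
sampling by complete enumeration of half-subset pairs, which is also how
the box computation is validated in the test suite (group size 4, all
$\binom{4}{2}^2 = 36$ pairs).

## The synthetic validation models

Six seeded generators produce the benchmark conditions under which the
representation's geometries are known by construction. All use 20-node
undirected networks; the study-scale group size is 10,000 networks
(`n_networks` default), with 1,000–2,000 used in the test suite and
acceptance script so that each check runs in seconds to a couple of minutes.

**Static models** assign link $l$ (in a fixed canonical link order; the
choice is immaterial because draws are independent across links) the weight
$\mathcal N(l, 1)$ in group 1 and, by variant, $\mathcal N(l^2, 1)$,
$\mathcal N(l, l)$ or $\mathcal N(l^2, l)$ in group 2. The second parameter
is a **variance**. This reading is a deliberate design decision: with
standard deviation $l$ instead, selection effects among the strongly
overlapping draws inflate the top order statistics of group 2 so much that
model 2's defining property — median structure unchanged
($|\Delta M| < 0.2$ on the top quartile) while variability grows into a
left-to-right curve — is destroyed (simulation gives $|\Delta M|$ up to
$\approx 1.5$ there). With variance $l$ all three panels show their
intended geometry: model 1 a bottom-to-top curve (supralinear medians),
model 2 left-to-right (variability only), model 3 diagonal.

**Dynamic models** derive weights from node time series, the typical
neuroscience situation. Each network draws a pattern $\pi$ of $\tau = 8$
uniform$(0,1)$ values; node $i$'s series is $\pi_t + a_i\,\mathcal
U(-1,1)$ per sample, and link weights are absolute Pearson correlations.
Group 1 uses $a_i = \alpha_i \sim \mathcal U(0,1)$; group 2 uses, by
variant, $\beta_i \sim \mathcal U(0,8)$ (globally noisier),
$\beta_i \sim \mathcal U(0,0.2)$ for $i \le 10$ and exponential with mean 4
otherwise (ten synchronised nodes), or $\beta_i \sim \mathcal U(0, 0.3i)$
(node-indexed heterogeneity). Two scope decisions were genuinely open:

* **$\pi$ is redrawn per network** (shared by that network's nodes). A
  single global $\pi$ would couple all networks through one realisation,
  making the groups non-exchangeable; simulations show the top-rank
  $\Delta Std$ then swings by a factor of three across seeds (0.39–1.34),
  whereas per-network $\pi$ is stable (0.52–0.58 at 2,000 networks/group).
* **Amplitudes are redrawn per network** as well, for the same
  exchangeability reason.

The generators emulate the *order-statistic structure* of connectivity
cohorts — what the transform consumes — not the spectral or spatial
structure of real recordings (no autocorrelated signals, no volume
conduction, no parcellation effects). Passing the synthetic suite therefore
validates the transform and its uncertainty machinery, not any claim about
a particular imaging modality.

Under the literal construction, two qualitative behaviours these models are
often described as producing do not reproduce, and the package keeps the
honest results rather than bending the generators:

* Dynamic model 1's weakest five ranks give $\Delta M \approx -1.5$ and
  $\Delta Std \approx -3.1$ at 2,000 networks/group (stable across seeds),
  more extreme than the "$\approx -1$ / $\approx -2$" sometimes associated
  with this panel; the strongest ranks ($\Delta M \approx -0.2$,
  $\Delta Std \approx 0.6$) do land on the "$\approx 0$ / $\approx 1$"
  description. The weakest rank is the minimum of 190 near-independent
  $|r|$ values at $\tau = 8$, and its group-2 dispersion is genuinely tiny.
* Dynamic model 3's "$\Delta Std < 0$ for the five strongest links" does
  not emerge: group 1's top ranks are maxima over 190 pairs with a ceiling
  at $|r| = 1$, and extreme-value selection makes them *more* stable across
  networks than group 2's forced-synchronised pairs, whose $\beta \le 0.3$
  noise is comparable to the pattern's own scale ($\mathrm{sd}(\pi) \approx
  0.29$). Measured top-5 $\Delta Std$ is $+0.5$ to $+0.8$.

The corresponding acceptance checks are kept at the stated readings and
allowed to fail, so the discrepancy stays visible.

## Functional network reconstruction

`reconstruct_networks()` turns a multichannel recording into a group of
windowed connectivity matrices: optional zero-phase band-pass (4th-order
Butterworth, forward–backward, so no phase distortion enters lagged
estimators; band edges default to the conventional EEG bands, delta 0.5–4
through gamma 30–45 Hz, all configurable), optional literal stride
decimation (no anti-alias filter — the point is to *emulate* a slow
modality, aliasing included), then non-overlapping windows of $\tau = 128$
samples, each yielding one matrix treated as an independent group member.

Four estimators are provided. Absolute Pearson correlation (undirected, in
$[0,1]$). Granger causality (directed), weighted as $-\log_{10} p$ of the
F-test comparing the target's AR(`order`, default 1) model with and without
the source's lags; under no coupling the p-value is exactly uniform, which
the suite verifies by Kolmogorov–Smirnov at 10,000 null replicates. Mutual
information (undirected) and transfer entropy (directed) use
nearest-neighbour estimators — Kraskov–Stögbauer–Grassberger algorithm 1
and its Frenzel–Pompe conditional variant, $k = 3$, max-norm, strict-
inequality counts, in nats, clipped below at zero; exact duplicate samples
are separated by a deterministic rank-based offset about $10^{10}$ times
smaller than the data range. Gaussian closed forms
($-\tfrac12\ln(1-\rho^2)$; the residual-variance identity
$\tfrac12\ln(\sigma^2_{restr}/\sigma^2_{full})$) serve as independent test
oracles only, at $n = 4096$ and tolerance 0.1 nats, which comfortably
covers the estimators' small-sample bias at that size.

## Topological metric rankings

The same per-rank machinery applies to any per-link or per-node metric:
`metric_delta_transform()` ranks, per network, edge betweenness (with link
weights raised to an exponent $\alpha$), the Onnela geometric-mean weighted
clustering coefficient, node betweenness, or closeness vitality (the change
in the all-pairs distance sum upon node removal), and runs the identical
median/std/log-ratio pipeline; with the raw-weight "metric" it reduces to
`delta_transform()` bit for bit. Path-based metrics use the universal
strength-to-distance convention $d = 1/w^\alpha$. Exact zero weights follow
the adjacency convention — absent link, not a zero-length link — which is
what makes textbook fixtures (paths, stars) expressible; negative weights
are a domain error. Graphs disconnected by a node's removal give that node
an undefined (flagged) vitality rather than an arbitrary large value.
igraph performs the shortest-path computations; clustering and vitality are
implemented directly and all four metrics are validated against literal
brute-force enumeration (all simple paths; Floyd–Warshall plus
remove-and-recompute) on every test graph of up to 6 nodes.

`smooth_profile()` averages profiles over non-overlapping blocks of 4
consecutive ranks (trailing partial blocks over their actual size;
undefined ranks excluded from their block's mean), the standard de-noising
step for high-dimensional parcellations. `ranking_stability()` computes
Spearman correlations between members' weight vectors *in canonical link
order* — correlating the sorted vectors would be trivially 1 — as a
diagnostic of how reliable a cohort's ranking is.

## Numerical and interface choices

Ties in ranking are broken by stable sort (equal values, so no statistic is
affected). Degenerate correlations from zero-variance synthetic series map
to weight 0. All generators and every resampling path are bit-reproducible
given an integer seed, and the two groups of a generator pair use
decorrelated streams derived from the same user seed, so a single `--seed`
controls a whole pipeline run. Profiles serialize to delimited text with a
fixed column contract (`rank, delta_m, delta_std, delta_m_low,
delta_m_high, delta_std_low, delta_std_high, defined`) at full 17-digit
precision, so save/load round-trips are exact; undefined ranks have empty
value cells. The command-line interface (`exec/rankdelta`) exposes
`simulate`, `reconstruct`, `transform`, `plot` and `stability` subcommands
over these functions and returns conventional exit codes (0 success, 1
runtime error, 2 usage).

## Worked example

```{r toy}
toy <- generate_toy_example(seed = 1)
p <- delta_transform(toy$g1, toy$g2)
as.data.frame(p)[, c("rank", "delta_m", "delta_std", "defined")]
```

At study scale the same call on dynamic model 1 (2,000 networks per group)
reproduces the benchmark numbers discussed above; see
`scripts/acceptance.R` in the source repository, which recomputes them from
scratch.

## Known limitations

The transform discards link identity by design: it can show *that* and
*where in the hierarchy* groups differ, not *which* connections drive the
difference. No significance test accompanies $\Delta M$/$\Delta Std$ — the
representation is exploratory, and the uncertainty boxes are descriptive
(half-sample spread), not confidence intervals. The information-theoretic
estimators are $O(n^2)$ per pair and meant for windowed segments, not
hour-long recordings. Real-data idiosyncrasies (artefacts, re-referencing,
parcellation choices) are upstream of this package and out of its scope.
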