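---
title: "Models and methods in cnphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cnphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnphylo)
```

# The problem

Multi-region and longitudinal tumour samples profiled by shallow
whole-genome sequencing yield integer copy-number profiles (CNPs): one
integer per genomic site (a fixed-size bin or a variable-size segment) per
sample, either total copy numbers or haplotype-specific pairs
$(c_A, c_B)$. `cnphylo` reconstructs the phylogeny of the samples of a
single patient from these profiles by maximum likelihood, and — when the
samples were taken at two or more time points — jointly estimates node
ages in calendar years and the per-year duplication and deletion rates.
A companion simulator generates realistic test data under the same or
deliberately violated assumptions.

# The Markov model of copy-number change

Each site evolves independently along the tree under a continuous-time
Markov chain on haplotype-specific states $(c_A, c_B)$ with
$c_A + c_B \le c_{max}$. States are ordered by increasing total, ties by
increasing $c_A$, so that for any $c_{max}$ the normal diploid state
$(1,1)$ is state 4 (0-based) and there are
$(c_{max}+1)(c_{max}+2)/2$ states. A haplotype with at least one copy
duplicates at rate $u$ and loses one copy at rate $e$ (per haplotype per
site per year); $(0,0)$ is absorbing — a lost site cannot be regained.
Duplications that would push the total past $c_{max}$ are disallowed
rather than redirected, the only reading consistent with a finite state
space.

Two conventions were possible for how the rate scales with copy number:
attached to the haplotype (a haplotype mutates at rate $u$ regardless of
how many copies it holds) or attached to the copy (rate $u\,c_h$). We use
the per-haplotype convention as the default because the rate is defined
"per haplotype per site per year"; `build_rate_matrix(per_copy = TRUE)`
switches to the alternative.

Transition probabilities $P(t) = e^{Qt}$ are computed from a cached
eigendecomposition of $Q$ (each branch then costs two matrix products)
and memoized per distinct branch length; when the eigendecomposition
fails a numerical soundness check (reconstruction error above $10^{-9}$
relative) the code falls back to Padé scaling-and-squaring, and — for
stiff generators (very asymmetric rates over long branches, where the
Padé result's row sums drift) — to uniformization, the Poisson mixture
$e^{Qt} = \sum_k \mathrm{Pois}(k;\Lambda t)\,(I + Q/\Lambda)^k$, which is
row-stochastic by construction. Computed probabilities are clipped to
$[0,1]$ and rows are validated to sum to 1 within $10^{-6}$ (typical
error on the primary path is far below $10^{-10}$).

# Likelihood

The tree is rooted at the last unaltered common ancestor (LUCA), which
carries the normal state at every site and is joined to the samples'
MRCA by a branch of length $t_m$; a zero-length branch to a normal tip
makes the tree binary. Because $P(0) = I$, that tip contributes an
identity factor, so the implementation equivalently places a point-mass
root prior on $(1,1)$.

The likelihood is the product over sites of the probability of the
observed column, computed by Felsenstein pruning over the
haplotype-specific state space. Haplotype-specific observations give
indicator tip partials; total copy numbers are ambiguous observations
whose partials put 1 on every compatible state $(0,c), \ldots, (c,0)$ —
the likelihood then automatically sums over all haplotype-specific
matrices compatible with the data. At the root the MRCA state is summed
over against the LUCA-to-MRCA transition row. (The pruning completion at
the root sums over the MRCA state; fixing it instead would discard valid
histories and break the equality between the total-input likelihood and
the explicit sum over compatible haplotype matrices, which the test
suite verifies by enumeration.)

Identical site-pattern columns are collapsed and computed once. Partial
likelihoods are rescaled per pattern column (accumulating the log scale)
whenever a column sum falls below $10^{-280}$.

# Time calibration and optimization

With all samples at one time point, rates and times are confounded: only
branch lengths in expected CNAs per site, $l_i = (u_0+e_0)\,t_i$, are
identifiable. `fit_same_time()` therefore fixes $(u_0, e_0)$ and
optimizes branch lengths (in years at those rates) on a log scale with
L-BFGS-B, bounded below by the minimal branch length
$l_m = 10^{-3}$ years.

With at least three samples at two or more time points,
`fit_time_calibrated()` jointly optimizes node ages and rates under a
global clock. Ages (in years since patient birth, with tips pinned at
the patient age plus sampling offsets) are mapped to a box of optimizer
variables:

* $x_1$ is the tree height from the LUCA to the last-sampled tip,
  bounded in $[d + n\,l_m,\; A_0 + d]$, where $A_0$ is the patient age
  at the first sample and $d$ the largest sampling offset. The upper
  bound pins the LUCA no earlier than the patient's birth.
* every other internal node (MRCA included) gets the fractional position
  of its age between its parent's age $+\,l_m$ and the largest age that
  leaves each descendant room for $l_m$ per branch, clipped to
  $[0.01, 0.99]$.

This transform is a numerically stable bijection between the box and the
set of valid age configurations (round-trip error below $10^{-9}$ in the
tests); any bijection respecting the same box would do. Rates are
optimized as $\log_{10} u$, $\log_{10} e$ within $[10^{-6}, 1]$;
the bounds bracket the range over which simulation studies find the
model informative. Convergence uses L-BFGS-B defaults with a cap of 500
iterations; gradients are finite differences with step $10^{-5}$ on the
transformed scale. Small initial rates ($5 \times 10^{-4}$ by default)
are recommended when the plausible range is unknown, because high starts
can strand the optimizer on a local peak when the true rate is low.

# Topology search

Up to seven samples, all $(2n-3)!!$ rooted topologies are enumerated.
Every topology is first fitted with a capped optimization (10 iterations
by default) to rank candidates cheaply; the top `refine_k` (10 by
default) are refitted to convergence and the best is returned. The
capped-fit ranking is the package's definition of the "approximate
likelihood" used for screening; it is deterministic and in our testing
the refined set always contained the final optimum well inside its
margin.

For larger trees, `heuristic_search()` builds up to `n_initial` (100)
random-addition-order parsimony start trees (Fitch parsimony on the
copy-number characters, haplotype B characters appended after haplotype
A for haplotype input, rooted via an added normal genome), deduplicates
them, ranks them by capped-fit likelihood, hill-climbs the top `n1` (20)
by nearest-neighbour interchange (each internal edge of the sample
subtree contributes two rearrangements; a move is accepted only when the
capped-fit likelihood improves), and fully optimizes the top `n2` (5)
unique results. The LUCA-MRCA edge and the normal tip are excluded from
rearrangement.

# Ancestral reconstruction

Given a fitted tree and rates, `marginal_mrca()` returns the posterior
over MRCA states per unique variant site (a variant site whose pattern
occurs exactly once), proportional to the LUCA-to-MRCA transition row
times the MRCA partial likelihood. `joint_reconstruct()` returns the
jointly most probable assignment of states to all internal nodes,
conditional on the root being normal, by max-product dynamic programming
with back-pointers. Ties break to the lowest state index, which makes
runs reproducible; optimality of the returned assignments is checked
against brute-force enumeration on small trees in the test suite. We read "unique variant sites" as multiplicity-one variant
columns: under that reading each scored site has an unambiguous
simulated truth, whereas distinct-pattern scoring would collide patterns
with different true histories.

With total input the reconstruction lives in the latent
haplotype-specific space; `states_to_cn()` projects to totals for
reporting. Note that total data cannot distinguish $(c_A,c_B)$ from
$(c_B,c_A)$, so exact-state accuracy against a simulated truth is
intrinsically capped under total input — phase-ambiguous internal states
are recovered only up to the deterministic tie-break. Accuracy claims
for joint reconstruction are therefore evaluated on haplotype-specific
input, where the assignment is identifiable.

# Uncertainty

`bootstrap_trees()` resamples sites (columns) with replacement — at
segment level by recommendation, since segments are less correlated than
bins — and re-runs the full search per pseudo-sample. Branch support is
the percentage of bootstrap trees containing each clade of the
reference tree. `ci_from_bootstrap()` holds the topology fixed, refits
each pseudo-sample (initial rates at the point estimates), and reports
2.5th/97.5th percentiles for rates and node ages.

Tree accuracy metrics follow the field's definitions: normalized
Robinson–Foulds distance over clades (divided by $2n-4$ for rooted
binary trees) and the branch score distance (root-sum-square of
branch-length differences matched by clade, absent branches at length
zero, lengths in years).

# The simulator

`sample_tree()` draws a coalescent tree of the samples (exponential
growth at rate $\beta$, or the basic coalescent at $\beta = 0$),
rescales it so the MRCA sits `mrca_height` years before the
first-sampled tips, and prepends the LUCA with an
exponentially-distributed LUCA-to-MRCA branch (rate $\beta$, or a
$U(0,1)$-drawn rate when $\beta = 0$). Staggered sampling lengthens
terminal branches by $k_i\,dt$ with $k_i$ uniform on $\{1..n\}$ (the
first sample is the reference at offset 0). Internal branches shrink if
the height would exceed the patient age at the last sample. Defaults —
five samples, $\beta = 1$/yr, MRCA 20 years before the first sample,
patient aged 60, $m = 1000$ segment sites over 22 autosomes (sites
allocated by a Dirichlet draw concentrated around chromosome bin-count
proportions), $u = e = 0.001$, $c_{max} = 6$ — are the package's study
conditions and are deliberately not tuned per analysis. Under these
conditions a typical replicate carries roughly 150–290 variant sites of
1000; the coalescent shape parameters trade off against this count, and
$\beta$ was fixed once at 1/yr.

Two generation modes exist. Direct mode draws each site's child state
from the row of $P(l)$ — exactly the inference model, so
inference-on-direct-simulations is a pure consistency check. Waiting-time
mode is a Gillespie simulation on 4401 fixed 500-Kbp bins (the default
per-autosome bin counts sum to 4401) with five event types: segment
duplication/deletion (exponential sizes with a configured mean, at least
one bin, truncated at the chromosome end; duplications tandem or
interspersed with equal probability), chromosome gain/loss, and
whole-genome doubling. Chromosome gains and WGD are suppressed when any
bin would exceed $c_{max}$, and duplications skip bins already at
$c_{max}$; overlapping events violate the independent-sites assumption
on purpose.

Post-processing utilities emulate real-data pathologies: `inject_errors()`
resamples exactly `round(m * f_e)` sites per sample from a Poisson
centred on the true value (clamped to $[0, c_{max}]$);
`mix_subclones()` makes each sample a Dirichlet-weighted mixture of its
own clone (fraction $f_d$) with other clones and a normal clone, rounding
the weighted mean to the nearest integer — the rounding mirrors how
callers report a dominant integer signal, as the discretization of mixed
profiles is otherwise unspecified; `make_relative()` divides by a
per-sample baseline (half the rounded mean total, per-haplotype rounded
means, or $2^{N_{WGD}}$), rounds nearest or randomly up/down, subtracts
the normal ploidy and clamps to $[-2, 2]$, matching the output range of
sWGS callers.

What the simulator does not emulate: read-level noise (coverage, GC
bias), sex chromosomes, CNA calling itself, and clonal deconvolution.
Passing tests on simulated data therefore demonstrate correctness of the
inference machinery and robustness to the modelled violations (errors,
mixtures, overlapping events, relative scaling) — not robustness to
calling artefacts upstream of the copy-number matrix.

# Problem sizes in the validation scripts

The acceptance script reproduces the package's headline simulation
results at reduced replicate counts chosen as the package's desk-scale
defaults: 30 replicates for same-time topology recovery and ancestral
accuracy, 5 replicates per error fraction $f_e \in \{0.1,0.3,0.5,0.7\}$,
10 per subclonal-mixing condition (both rates crossed with dominant
fractions 0.6 and 0.8, four clones), and 4 per condition for the
time-calibrated mixed-clone study. Recovery fractions are pooled over
the conditions of each study. The test suite runs the same checks at
smaller replicate counts.

# Known limitations

* No rate heterogeneity across sites and no error model inside the
  likelihood; errors are handled only in the simulator.
* A strict global clock; no relaxed or lineage-specific rates.
* Chromosome-level gains/losses and WGD exist in the simulator but not
  in the inference chain's rate matrix.
* Exhaustive search is practical only to seven samples; the heuristic's
  candidate schedule (rank, NNI, refine) is a deliberate simplification
  of full candidate-set maintenance in modern ML tree searchers.
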