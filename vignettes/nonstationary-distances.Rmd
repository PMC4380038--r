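---
title: "Measuring genetic distance under nonstationary substitution processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genetic distance under nonstationary substitution processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdist)
```

## The problem

The genetic distance between two homologous sequences is usually defined as
the expected number of substitutions per site separating them under a
continuous-time Markov model of sequence change. Almost all distance
formulae in routine use assume the substitution process is *stationary*:
the nucleotide composition of the sequence is at equilibrium and does not
change along the tree. Real alignments frequently violate this — the
composition of the two sequences simply differs — and applying a
stationary formula to nonstationary data biases the distance, and with it
downstream inferences such as relative-rate tests of the molecular clock.

`ensdist` implements a distance that drops the stationarity and
reversibility assumptions while keeping time homogeneity along each edge.

## The expected number of substitutions (ENS)

Consider a Markov process on $\{A,C,G,T\}$ with generator $Q$ (rows sum to
zero, off-diagonals nonnegative) and initial state distribution $f(0)$, a
row vector. The state distribution at time $s$ is $f(s) = f(0)e^{Qs}$, and
the expected number of substitutions accumulated on $[0, t]$ is

$$ n(t) \;=\; -\int_0^t f(s)\,\mathrm{d}s \;\mathrm{diag}(Q), $$

where $\mathrm{diag}(Q)$ is the column vector of diagonal entries. When
$f(0)$ equals the stationary distribution $\pi$ (the probability vector
with $\pi Q = 0$), $f(s) = \pi$ for all $s$ and the integral collapses to
the familiar linear form $n(t) = -\sum_i \pi_i Q_{ii}\, t$. Away from
stationarity the integral genuinely differs from the linear formula: for a
Felsenstein-type process ($Q_{ij} = \alpha\pi_j$) with
$\pi = (0.5, 0.2, 0.1, 0.2)$, $\alpha = 1$ and $t = 1.5$ the stationary
value is $0.99$, but starting the process at $(0.1, 0.3, 0.2, 0.4)$ gives
$1.09$ and starting at $(0.6, 0.2, 0.1, 0.1)$ gives $0.97$:

```{r f81}
pi0 <- c(0.5, 0.2, 0.1, 0.2)
Q <- rate_matrix_f81(pi0, alpha = 1)
c(stationary = ens(pi0, Q, 1.5),
  skewed_up = ens(c(0.1, 0.3, 0.2, 0.4), Q, 1.5),
  skewed_down = ens(c(0.6, 0.2, 0.1, 0.1), Q, 1.5))
```

The closed form for this model is
$n(t) = \alpha t \sum_i \pi_i(1-\pi_i) +
(1 - e^{-\alpha t})\sum_i (1-\pi_i)(f_i(0)-\pi_i)$. The sign of the
correction term follows directly from the integral above; it is the only
sign consistent with the three values printed here, which the package
verifies by three independent routes (augmented matrix, quadrature,
closed form).

### Computing the integral

`ens()` evaluates $n(t)$ by exponentiating the $5\times 5$ augmented
matrix

$$ C = \begin{pmatrix} Q & -\mathrm{diag}(Q) \\ 0 & 0 \end{pmatrix},
\qquad n(t) = f(0)\, \big[e^{Ct}\big]_{1..4,\,5}, $$

which is exactly as robust as the matrix exponential itself. Matrix
exponentials use scaling-and-squaring with Padé approximants (Armadillo's
`expmat`); eigendecomposition is used only as an independent cross-check
in the test suite, because it degrades on defective or near-defective
generators. `ens_quadrature()` integrates $-f(s)\,\mathrm{diag}(Q)$
directly by composite Simpson's rule with stepwise propagation of $f$;
the two routes agree to better than $10^{-6}$ for $t \le 5$ at the
default $10^4$ steps, and the quadrature shares no code with the
augmented-matrix path, making it a genuine oracle.

### Calibration

A rate matrix is *calibrated* when its stationary substitution rate is
one, $-\sum_i \pi_i Q_{ii} = 1$, so that a stationary edge's duration is
its expected number of substitutions. `calibrate()` divides by the total
rate; it is idempotent and scale-equivariant. Calibration uses the
matrix's own stationary distribution unless explicit frequencies are
given. For nonstationary edges only the product $Qt$ is identifiable and
needs no calibration: the reported edge length is the ENS itself,
computed with the marginal distribution at the edge's ancestor as
$f(0)$.

## The triad model hierarchy

Inference is on three-taxon alignments (triads) with a declared ingroup
pair. The two edges emanating from the original root are not separately
identifiable, so they are merged into a single outgroup edge and the
fitted process is rooted at the ingroup ancestor: a three-edge star.
Likelihoods are multinomial over the 64 ordered site patterns,

$$ p(ijk) = \sum_{r} f_0(r)\, P_a(r,i)\, P_b(r,j)\, P_c(r,k), $$

with $P_e = e^{Q_e t_e}$, averaged over four equal-probability
discrete-gamma rate bins for the rate-heterogeneous family.

Three families are fitted, in order of increasing generality:

* **GTR** — one time-reversible calibrated rate matrix
  ($Q_{ij} = R_{ij}\pi_j$, $R$ symmetric) shared by all edges; root
  distribution equal to its stationary $\pi$. Free parameters: 5 relative
  exchangeabilities (GT fixed at 1), 3 frequencies, 3 edge lengths —
  11 degrees of freedom (10 under the clock).
* **GTR+Γ** — GTR plus gamma rate heterogeneity across sites in four
  equal-probability bins represented by their conditional means (the
  standard discrete-gamma construction); one extra shape parameter —
  12 degrees of freedom (11 under the clock). Note this family is not
  nested with respect to GTR at finite shape.
* **General** — an unconstrained generator per edge and a free root
  distribution, so the process may be nonstationary and nonreversible.
  The identifiable quantity per edge is the product $M_e = Q_e t_e$; its
  12 off-diagonal entries are optimised directly for each edge, plus 3
  free root probabilities — 39 degrees of freedom (38 under the clock).
  Any decomposition of $M_e$ into $(Q_e, t_e)$ is non-unique and purely
  for reporting.

The degrees of freedom above are derived from the parameterizations, not
transcribed from elsewhere.

### Sequential fitting

`sequential_fit()` fits GTR first, then seeds GTR+Γ and the General model
from it (a GTR point is an exact General point with
$M_e = Q t_e$ and root $\pi$). Because the bounded quasi-Newton optimiser
never moves uphill in its objective, seeding guarantees
$\ln L(\text{General}) \ge \ln L(\text{GTR})$ — the nesting
monotonicity is structural, not a numerical accident. When the clock
suite is requested, free fits are additionally guaranteed at least their
clock counterpart's likelihood: if an independently fitted free model
ever came out below the clock fit, it is re-optimised from the clock
solution (a feasible free-model point).

### Optimiser

All positive parameters are optimised on the log scale and probability
vectors through logits against a fixed baseline, with `L-BFGS-B`.
Bounds: calibrated relative rates in $[10^{-6}, 200]$, gamma shape in
$[0.01, 200]$, edge-product entries in $[10^{-8}, 50]$, logits in
$[-30, 30]$. The caps exceed biologically plausible values and exist to
stop flat-likelihood drift. Each fit runs one fully converged start from
the seed plus three randomly perturbed restarts; restarts are short,
loose-tolerance probes, and a probe that beats the seeded optimum is
polished to full tolerance. Convergence uses `factr = 1e7` (objective
tolerance of order $10^{-9}$ relative) with up to 1000 iterations.
Initial GTR edge lengths come from pairwise mismatch proportions with a
Jukes–Cantor correction decomposed onto the star; initial rates are
strictly positive (floor $10^{-6}$), which keeps every site pattern at
positive probability — a pattern with positive count and zero probability
is treated as an explicit failure state rather than silently scored
$-\infty$.

### The clock constraint

Clock-like models constrain the two ingroup edges to equal ENS. For the
GTR families this is a shared duration parameter. For the General model
the second ingroup edge's parameters give only the *shape* of $M_b$; its
scale is solved at every likelihood evaluation so that
$\mathrm{ENS}(f_0, s M_b) = \mathrm{ENS}(f_0, M_a)$. ENS is strictly
increasing in the scale (the integrand is nonnegative), so the scalar
equation has a unique root, found by bracketed bisection to a relative
tolerance of $10^{-12}$; the ENS function of the scale is evaluated in
closed form through the eigendecomposition of $M_b$, with an
augmented-matrix fallback when the eigenbasis is ill-conditioned. The
redundant overall scale of the $M_b$ parameters leaves one flat direction
in the 39-parameter space, which L-BFGS-B tolerates; the reported
degrees of freedom (38) count the constraint.

`clock_lrt()` refers $2(\ln L_\text{free} - \ln L_\text{clock})$, floored
at zero, to $\chi^2_1$. No boundary-mixture correction is applied: the
constraint is an interior equality, not a boundary.

## Distances from data and from fits

* `ens_path_distance()` — sum of per-edge ENS along the path between two
  nodes; on the star, leaf-to-leaf distances are sums of two edge ENS
  values, each computed with the fitted root distribution as $f(0)$.
* `paralinear_distance()` — $-\tfrac14 \ln\det\big(
  \mathrm{diag}(\pi_\mu)^{-1/2} J \,\mathrm{diag}(\pi_\nu)^{-1/2}\big)$
  from an empirical joint distribution $J$; marginals are taken from
  $J$'s row and column sums, not pooled compositions. Zero cells in $J$
  are tolerated; a zero marginal raises a singularity error and a
  nonpositive determinant a saturation error. An optional Laplace
  pseudocount exists behind an explicit argument and is off by default
  because raw frequencies are the intended estimator.
* `logdet_distance()` — $-\ln\det J$; documented as *not* an edge-length
  estimator, provided for comparison.
* `jsd()` / `shannon_entropy()` — equally weighted Jensen–Shannon
  divergence in nats; the package's measure of compositional departure.
  For Felsenstein-type processes the JSD between $f(0)$ and $f(t)$ is
  provably monotone in $t$ (compositions relax linearly toward $\pi$),
  and the test suite asserts exactly that; monotonicity for arbitrary
  nonstationary processes is plausible but not relied upon.

## Identifiability and goodness of fit

Two screens guard interpretation of General-model fits. A fitted
transition matrix must be **diagonal largest in column** (every diagonal
entry strictly the largest in its column; ties fail, since the condition
is sufficient only when strict), which rules out relabelling of internal
states. And the mapping from transition matrix back to a generator must
be **unique**: `unique_mapping_check()` passes only when all eigenvalues
are real, strictly positive, and distinct — then the principal logarithm
is the only real logarithm. The criterion is deliberately conservative in
the rejecting direction: a Jukes–Cantor transition matrix (triple
eigenvalue) fails it even though its generator is in fact recoverable,
and any nonpositive determinant fails immediately. Bootstrap replicates
are *not* filtered by these screens — the screens address
identifiability of estimates, not the null distribution of the fit
statistic.

Goodness of fit uses the G statistic
$G = 2\sum_{\text{patterns}} O \ln(O/E)$ against the unrestricted
multinomial, which equals twice the gap between the saturated and fitted
log likelihoods. Its null distribution is obtained by a parametric
bootstrap: simulate alignments of the original length under the fitted
model (100 by default, giving P-value resolution 0.01), refit the same
family seeded through GTR, and report the proportion of replicate G
values exceeding the observed one. Replicate fit failures are excluded
and counted. A fit with $P < 0.05$ is flagged by `gof_rejected()`.

## What the simulator emulates — and what it does not

`simulate_alignment()` draws i.i.d. sites: root state from the root
distribution (plus a rate bin under Γ), then end states along each edge
from transition probabilities. One random stream is derived per edge and
one for the root, so enlarging the alignment does not perturb unrelated
draws. `random_general_model()` generates nonstationary truths: a
Dirichlet(5) root composition and, per edge, a generator attracted to an
edge-specific concentrated composition (Dirichlet(0.8), floored at
$10^{-3}$) with lognormal rate noise (sd 0.5), rescaled so the edge ENS
lands uniformly in a requested range (0.05–0.5 substitutions/site by
default — the range where triad inference is informative but not
saturated). Departure from stationarity is controlled by
rejection-sampling each edge until the JSD between root and leaf
marginal falls in a requested band.

Synthetic data from this generator are i.i.d. across sites, free of
indels, alignment error, selection, and context dependence, and exactly
Markov on each edge. Passing recovery and calibration tests therefore
demonstrates correctness of the estimators under the model's own
assumptions — not robustness of the model to the ways real genomes
violate them.

## Problem sizes used by the test suite

The shipped tests run the full designs at sizes a single CPU handles in
minutes: likelihood-oracle equivalence on 20 random models and 50 random
ENS processes; General-model recovery on twenty 50,000-site simulations
(median ingroup-edge ENS error under 5%, root entries within 0.02);
clock-LRT size on 200 clock-true nonstationary replicates of 5,000 sites
(rejection at $\alpha = 0.05$ within $[0.02, 0.09]$) and power against a
doubled rate on 40 replicates; paralinear consistency at $10^5$ sites;
and a five-stratum synthetic corpus (50 alignments of 2,000 sites per
stratum) checking that the stationary-model excess
$d_\mathrm{GTR} - d_\mathrm{ENS}$ grows with the generating process's
JSD. Corpus-scale empirical percentages from real genome databases are
outside what synthetic desk-scale data can certify and are deliberately
not asserted.

## Known limitations

* Nucleotides only; no codon or amino-acid state spaces.
* Exactly three taxa with a declared ingroup; no topology search.
* Rate heterogeneity across sites is available only for the stationary
  families — combining Γ mixing with nonstationary edges is not
  implemented.
* The General model's per-edge $(Q, t)$ decomposition is non-unique by
  construction; report and compare only ENS values or the products
  $Qt$.
* The uniqueness screen is conservative: it rejects some transition
  matrices whose generator is actually unique (any repeated spectrum).
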