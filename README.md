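# ensdist

Genetic distances for **nonstationary** nucleotide substitution processes.

Most distance estimators assume the substitution process is stationary and
time-reversible: base composition is at equilibrium and identical in every
lineage. Real alignments often violate this, and a stationary formula
applied to nonstationary data systematically distorts distances — and with
them relative-rate tests of the molecular clock. `ensdist` is for
molecular evolutionists who want edge lengths that remain meaningful when
composition drifts.

## What it computes

For a continuous-time Markov process with generator $Q$ and initial
distribution $f(0)$, the expected number of substitutions (ENS) on
$[0, t]$ is

$$ n(t) = -\int_0^t f(s)\,\mathrm{d}s\; \mathrm{diag}(Q), \qquad
   f(s) = f(0)\,e^{Qs}, $$

which reduces to the classical $-\sum_i \pi_i Q_{ii}\,t$ when
$f(0) = \pi$. The integral is evaluated through a 5×5 augmented matrix
exponential. Around this core the package provides:

* maximum-likelihood fitting of a nested triad-model hierarchy — GTR,
  GTR+Γ (four discrete rate bins), and a General model with a free
  generator per edge and free root distribution — fitted sequentially so
  richer models never lose log likelihood, with clock-constrained
  variants (equal ingroup ENS) of each family;
* the ENS path distance on fitted models, plus paralinear and LogDet
  distances from empirical joint distributions, Jensen–Shannon
  divergence of compositions, entropy, and G+C content;
* goodness of fit by the G statistic with a parametric bootstrap,
  identifiability screens (diagonal-largest-in-column; conservative
  matrix-logarithm uniqueness), AIC, and a one-degree-of-freedom
  molecular-clock likelihood-ratio test;
* an exact triad simulator and generators of random stationary and
  nonstationary truths for recovery studies;
* FASTA input with gap/ambiguity-column filtering, a batch analysis
  pipeline returning a tidy report table, and a thin command-line
  interface (`inst/cli/ensdist.R`).

## Worked example

```r
library(ensdist)

## ENS: the stationary formula misses composition drift
pi0 <- c(0.5, 0.2, 0.1, 0.2)
Q <- rate_matrix_f81(pi0, alpha = 1)
c(stationary = ens(pi0, Q, 1.5),
  nonstationary = ens(c(0.1, 0.3, 0.2, 0.4), Q, 1.5))
#>    stationary nonstationary
#>         0.990         1.091

## fit the hierarchy to a simulated nonstationary triad
tree <- triad_tree(c("a", "b"), "c")
truth <- random_general_model(seed = 42, ens_range = c(0.1, 0.4),
                              jsd_floor = 0.02)
aln <- simulate_alignment(truth, 20000, seed = 42)
set.seed(42)
fits <- sequential_fit(aln, tree, clock_suite = TRUE)
fits$general
#> Triad fit: General
#>   taxa: ((a, b), c)
#>   log likelihood: -63062.23562  df: 39
#>   root distribution: A=0.4287 C=0.1800 G=0.2486 T=0.1427
#>   edge ENS: a=0.3938 b=0.3726 c=0.2761
truth$edge_ens
#> a=0.3767 b=0.3757 c=0.2789

## stationary models overestimate the same distance
ens_path_distance(fits$gtr, "a", "b")      # 1.0924  (dGTR)
ens_path_distance(fits$general, "a", "b")  # 0.7664  (dENS)
paralinear_distance(empirical_joint(aln[["a"]], aln[["b"]]))
#> 0.9032

clock_lrt(fits$general_clock, fits$general)$p.value
#> 0.04811
identifiability_checks(fits$general)$dlc_all
#> TRUE
```

The fitted General model recovers the generating edge lengths to a few
percent at 20,000 sites, while the GTR distance between the ingroup pair
(1.09) exceeds the nonstationary estimate (0.77) — the compositional
drift built into the truth is absorbed by the stationary model as extra
substitutions. The paralinear distance, designed for nonstationary data
but purely pairwise, lands between the two.

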