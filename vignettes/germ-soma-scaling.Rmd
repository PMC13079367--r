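---
title: "Size scaling of the cost of germ-soma specialization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size scaling of the cost of germ-soma specialization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germsoma)
```

## The model

Consider a multicellular organism that develops clonally: a single-celled
propagule divides synchronously until the adult contains $N$ cells, of which
a fraction $p_g$ are germ cells ($1/N \le p_g \le 1$; at least one germ cell)
and the rest are soma. At maturity the $N p_g$ germ cells disperse as new
propagules and the somatic cells are discarded. Development takes
$\tau = \log_2 N$ rounds of division, so with time measured in cellular
generations the population grows as $P(t) = P(0)\,(N p_g)^{t/\tau}$, giving
the intrinsic rate

$$ r = \frac{\ln(N p_g)}{\log_2 N}, \qquad r_{\max} = r\big|_{p_g = 1} = \ln 2 ,$$

independent of size. The proportional cost of somatic specialization is
therefore

$$ 1 - \frac{r}{r_{\max}} = -\frac{\ln p_g}{\ln N} .$$

The key consequence is that a fixed proportional investment in soma costs
less in larger organisms: with $p_g = 0.1$ the cost is 50% of the maximal
growth rate at $N = 10^2$, 25% at $N = 10^4$ and 16.7% at $N = 10^6$
(`specialization_cost()`), because development time grows like $\log N$ while
the reproductive loss is a fixed proportion of the final cell number. The
model is agnostic to *when* differentiation happens during development; only
the germ fraction at maturity enters. `fold_reduction()` reports the
equivalent factor $r_{\max}/r = \ln N / \ln(N p_g)$; for *Volvox aureus*
(about 2,040 somatic cells and 8 germ cells, so $N = 2048$, $p_g = 8/2048$)
it evaluates to $11/3 \approx 3.7$, matching the observed three- to four-fold
growth difference between *V. aureus* and its unicellular relatives.

```{r cost}
specialization_cost(c(1e2, 1e4, 1e6), 0.1)
fold_reduction(2048, 8 / 2048)
```

`cost_surface()` evaluates the fold reduction on an $(N, p_g)$ grid for
contour plots; $N$ is treated as real-valued so the surface is continuous,
and grid entries below the one-germ-cell line $p_g < 1/N$ are masked (flagged
`NA`, never silently dropped) rather than clamped, since that line is a hard
feasibility boundary.

## Survival benefit and the optimal allocation

Why invest in soma at all? The package's benefit model assumes recurrent
stress events every $t_s$ time units (same units as $\tau$), each survived
with probability linear in somatic investment,
$s(p_g) = s_s + (s_g - s_s) p_g$, where $s_g$ and $s_s$ are the survival of
all-germ and all-soma groups and $s_g < s_s$ when soma helps. The population
equation becomes $P(t) = P(0)(N p_g)^{t/\tau} s(p_g)^{t/t_s}$, with implied
net exponential rate `net_growth_rate()`:

$$ r_{net}(p_g) = \frac{\ln(N p_g)}{\log_2 N} + \frac{\ln s(p_g)}{t_s} .$$

This objective is strictly concave in $p_g$ (a sum of logs of linear
functions), so its interior stationary point is the unique maximum:

$$ p_g^* = \frac{s_s/(s_s - s_g)}{1 + \log_2(N)/t_s} ,$$

clamped to $[1/N, 1]$ by `optimal_allocation()`. The unclamped value is
reported too, because the critical stress interval
$t_s^* = (s_s/s_g - 1)\log_2 N$ (`critical_ts()`) is defined by where the
unclamped optimum crosses 1: soma is favored exactly when $t_s < t_s^*$, and
the tie $t_s = t_s^*$ is counted as *not* favored (strict inequality).
$t_s^*$ grows with $N$, so larger groups need less frequent stress to favor
specialization; and since $r$ increases with $N$ at any fixed $p_g < 1$
(`size_feedback_check()`), a positive feedback links size and somatic
investment: for large $N$, $p_g^* \sim t_s\,s_s/(s_s - s_g) / \log_2 N$.
Rather than assuming concavity silently, the test suite verifies the
closed-form optimum against a grid search and checks the first-order
condition by central finite differences.

```{r optimum}
optimal_allocation(1024, survival_params(sg = 0.5, ss = 1, ts = 5))
```

The degenerate case $s_g = s_s$ (benefit-free soma) is handled as an explicit
branch returning $p_g^* = 1$ instead of letting the closed form divide by
zero.

## The simulator

`simulate_population()` plays the life cycle out on a continuous timeline:
reproduction at multiples of $\tau$ (each organism replaced by its $N p_g$
propagules), stress at multiples of $t_s$ (population multiplied by
$s(p_g)$). When the two coincide, reproduction is applied first — the
product form makes the order immaterial at commensurate horizons, but a
fixed convention keeps trajectories byte-reproducible. Deterministic mode
propagates expected values and reproduces the closed forms to $10^{-9}$
relative whenever the horizon is a common multiple of $\tau$ and $t_s$;
`fit_rate()` recovers $r$ from the log-linear trajectory. Stochastic mode
draws offspring as Poisson with mean $N p_g$ (species data give
non-integral mean gonidia counts, so integer litters are not assumed) and
stress survivors as binomial; its expectation matches the deterministic
mode, and extinction truncates the trajectory with a flag rather than
erroring. The simulator doubles as the brute-force oracle for the rate laws
in the test suite.

## Comparative validation: contrasts and the scaling exponent

Across volvocine algae, the germ fraction falls with size approximately as a
power law $p_g \propto N^b$. `germ_scaling()` estimates $b$ two ways on
$\log_{10}$-transformed species data (the exponent is invariant to the log
base): ordinary least squares across species, and phylogenetic independent
contrasts, which whiten the shared-ancestry covariance under a
Brownian-motion model. The contrasts engine (`pic_contrasts()`) implements
Felsenstein's pruning pass directly: at each internal node the standardized
contrast $(x_1 - x_2)/\sqrt{v_1 + v_2}$ is recorded, the ancestral value is
the branch-length-weighted average, and the parent branch is lengthened by
$v_1 v_2/(v_1 + v_2)$. Contrast regression is through the origin, with the
no-intercept convention $r^2 = 1 - \mathrm{SSR}/\sum y^2$ (stated here
because published comparative $r^2$ values do not always say which
convention they use) and a two-sided $t$ test on $n - 1$ degrees of freedom.
Polytomies are resolved deterministically to binary with zero-length
branches, so repeated traits on one tree always see the same topology.
Species with $p_g = 1$ are excluded by default: the scaling law concerns
species with germ-soma differentiation. Species named in the table but
absent from the tree are a hard error, because silently dropping them would
silently change the comparative result. An exponent of $-1$ would mean a
strictly constant proportional cost across species;
`constant_cost_check()` reports the spread of per-species costs directly.

Correctness rests on two independent oracles in the test suite: the
through-origin contrast slope must equal the generalized-least-squares slope
under the Brownian covariance matrix built from shared path lengths (to
$10^{-8}$ over random trees), and the contrasts themselves must match an
independent reference implementation. On a star phylogeny the contrasts
regression collapses to OLS, and rescaling all branch lengths leaves the
slope unchanged; both are tested.

## Synthetic volvocine-like data

`generate_volvocine_data()` supplies datasets with known ground truth so the
comparative stage is testable without any downloads. Defaults describe the
study system: 18 differentiated species on a Yule (pure-birth) tree;
$\log_{10} N$ evolving by Brownian motion (SD 0.5 per unit branch length)
from a root at $\log_{10} 2000$, clamped to span roughly $10^2$ to
$5 \times 10^4$ cells; and
$\log_{10} p_g = a + b \log_{10} N + \varepsilon$ with $b = -1.2$,
$a = 1.57$ (which pins the line through the *V. aureus* point) and
lognormal noise. The noise SD defaults to 0.05 (log10 units), a calibration
chosen once so that the contrasts regression on a typical draw has
$r^2 \approx 0.95$, the magnitude seen in real volvocine data; it is a
calibration choice, not an empirical constant. Counts are rounded to
integers with at least one germ cell, as in real species records;
`integer_counts = FALSE` keeps continuous traits, under which a noise-free
draw identifies $b$ exactly and the gap to the rounded version quantifies
rounding bias (below 0.05 at default sizes, tested).

Because the trait model matches the contrasts assumption (Brownian motion on
the tree) exactly, parameter recovery is a clean test of the contrasts
engine rather than of model misspecification; conversely, passing it says
nothing about robustness to non-Brownian evolution, measurement error in
cell counts, or within-species variation, none of which the generator
emulates. The tree process (Yule rather than birth-death) is not critical
since the analysis conditions on the tree.

```{r synth}
ds <- generate_volvocine_data(volvocine_config(seed = 42))
fit <- germ_scaling(ds$species, ds$tree)
fit
```

## Numerical choices and problem sizes

- The one-germ-cell constraint is enforced with a small tolerance
  ($p_g N \ge 1 - 10^{-12}$) so values at the boundary survive float
  round-trips; below it, inputs are rejected, not clamped.
- Grid-search verification of $p_g^*$ uses a coarse-to-fine scheme reaching
  $10^{-6}$ absolute resolution, exact here because the objective is
  strictly concave.
- Monte-Carlo test sizes (500 optimizer draws, 200 recovery seeds, 1,000
  stochastic replicates, 100 random trees) keep the default suite around
  ten seconds while leaving standard errors far below the tolerances they
  check.
- Full precision is kept internally everywhere; rounding to two significant
  figures (the convention for quoted fold reductions) happens only in
  presentation, e.g. the CLI's `--paper-style` flag.

## Limitations

The growth model assumes synchronous division, exponential (resource-
unlimited) growth — deliberately the worst case for the cost of soma — and
clonal development from a unicellular propagule; aggregative or
size-structured life cycles are out of scope. The benefit model is linear in
$p_g$ with deterministic stress timing. The comparative stage implements
contrasts under Brownian motion only; phylogenetic signal tests, OU models
and measurement-error models are out of scope, and published-data
reproduction requires the user to supply the species table and tree files,
which are not bundled.
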