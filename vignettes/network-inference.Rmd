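---
title: "Inferring gene regulatory networks from time series and steady-state expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene regulatory networks from time series and steady-state expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grndyn)
```

## The model

A gene regulatory network (GRN) is a directed graph of transcriptional
influences: an edge $i \to j$ means that the expression of gene $i$
helps determine the transcription rate of gene $j$. grndyn infers a
*ranking* of all candidate edges from expression data; choosing a
cutoff on that ranking is deliberately left to the user.

The dynamical model behind the main method (`dyngenie3()`) describes
each gene's mRNA concentration $x_j(t)$ by a first-order ordinary
differential equation,

$$\frac{dx_j}{dt} = -\alpha_j\,x_j(t) + f_j(\mathbf{x}(t)),$$

where $\alpha_j > 0$ is the gene's mRNA decay rate (inverse time
units) and $f_j$ — the *transcription function* — maps the full
expression state to gene $j$'s production rate. Nothing parametric is
assumed about $f_j$: it is learned as a Random forest of regression
trees. The semi-parametric split is the point: the decay term carries
the known first-order chemistry, the forest carries everything we do
not want to assume.

A time series sampled at $t_1 < \dots < t_N$ turns into a regression
problem through the forward finite difference of the ODE: for each
consecutive pair of time points, one training case with input
$\mathbf{x}(t_k)$ and output

$$y_k \;=\; \frac{x_j(t_{k+1}) - x_j(t_k)}{t_{k+1}-t_k} + \alpha_j\,x_j(t_k),$$

which is exactly $f_j(\mathbf{x}(t_k))$ up to discretization and noise.
Steady-state conditions (where $dx_j/dt = 0$, so
$f_j(\mathbf{x}) = \alpha_j x_j$) contribute extra cases
$(\mathbf{x}(e_k),\, \alpha_j x_j(e_k))$; `dyngenie3()` pools both when
a steady-state matrix is supplied. No case ever spans two different
series, and a per-row origin tag is kept so out-of-bag diagnostics can
restrict themselves to time-series rows.

Edges are ranked by Mean Decrease Impurity (MDI) importance. At every
split node $\mathcal{N}$ the variance reduction

$$I(\mathcal{N}) = \#S\,\mathrm{Var}(S) - \#S_t\,\mathrm{Var}(S_t)
  - \#S_f\,\mathrm{Var}(S_f)$$

is credited to the split variable; a variable's importance is the sum
over its nodes, averaged over trees. For one fully grown tree these
importances sum exactly to the total output variation
$N_S\,\mathrm{Var}(S)$ — an accounting identity the test suite checks
to $10^{-9}$. Because of it, raw importances scale with how much each
target gene varies, so each target's scores are normalized to sum to
one (after zeroing the self-edge and any non-candidate regulator).
Columns with no importance at all stay zero: no evidence is not
uniform evidence.

Three companions round out the family:

* `genie3()` — the static variant: $x_j = f_j(\mathbf{x}_{-j})$ per
  condition, the target excluded from its own inputs. Given time
  series it naively stacks time points as independent conditions.
* `genie3_lagged()` — static learning on lagged pairs. With a uniform
  sampling interval $\Delta t$ and $\alpha_j = 1/\Delta t$ the
  dynamical variant reduces to it exactly: the regression targets
  differ by the positive factor $1/\Delta t$, which cannot change any
  variance-reduction split, so under a shared seed the two rankings
  are identical (asserted in the tests).
* `mcz_ranking()` — median-corrected z-scores from a systematic
  single-knockout panel, $w_{i,j} = |x^j_{i,\mathrm{ko}} -
  x^j_{\mathrm{wt}}| / \sigma_j$; `combine_rankings()` multiplies it
  elementwise with a forest-based ranking so only edges supported by
  both stay on top.

## Parameters that matter

* **`decay`** — by far the most influential setting. Options:
  experimentally measured per-gene rates (`read_decay_rates()`, with
  genes missing from the file filled with the median of the provided
  rates); a single uniform rate; or `"data_derived"` (the default),
  which assumes an exponential decay between each gene's highest and
  lowest observed values: $\alpha_j = \ln(x_{\max}/x_{\min}) /
  |t(x_{\min}) - t(x_{\max})|$. Minima are floored at
  $10^{-6}x_{\max}$; across several series the per-series maximum (the
  fastest decay actually observed) is kept — a conservative choice,
  since the aggregation rule is genuinely open. Data-derived rates are
  order-of-magnitude estimates, not kinetic measurements, but that is
  usually enough for ranking.
* **`n_trees`** (default 1000) and **`k`** (variables screened per
  split; default `"all"` = the number of candidate regulators).
  Rankings are insensitive to `n_trees` well below the default;
  lowering `k` trades a little accuracy for speed.
* **`seed`** — per-gene seeds are derived from the master seed and the
  *gene name*, so results are independent of gene order and of which
  subset of genes is fitted.

`tune_decay()` sweeps uniform decay values (plus labelled per-gene
candidates) and reports two refit-free criteria per setting: the
out-of-bag prediction score (Pearson correlation between out-of-bag
predicted and true next-step expression levels, averaged over genes)
and the tree-stability score (mean pairwise overlap of the per-tree
top-5 regulator sets). Both are diagnostics, not oracles: on real data
neither is guaranteed to co-vary with recovery of true edges, which is
why the sweep reports them next to AUPR when a gold standard exists
rather than optimizing anything automatically.

## Simulation and knockout prediction

Because the model is a proper ODE, a fitted `grn_fit` can be run
forward: `simulate_to_steady_state()` integrates
$x_j \leftarrow x_j + \Delta t(\hat f_j(\mathbf{x}) - \alpha_j x_j)$
by explicit Euler — deliberately the same scheme the models were
trained under, with the data's sampling interval as the default step.
Expression is floored at zero (forests cannot extrapolate below their
training range), convergence is a relative sup-norm change below
`tol` (default $10^{-4}$) in one step, and `max_steps` defaults to
1000. `predict_double_knockout()` starts from wild type with the two
deleted genes at zero and *clamps* them there — deletion semantics,
not just an initial condition, since a deleted gene cannot be
re-expressed; the conventional baseline (the $t=0$ levels themselves)
is returned alongside for comparison. When this experiment is run on
the synthetic benchmark, deletion pairs are drawn among genes with at
least one outgoing edge in the ground truth: knocking out a
non-regulator changes no other gene, so such experiments test nothing
beyond the baseline.

## Evaluation

`pr_curve()` scores a ranking against a gold standard over the
eligible pairs (candidate regulators × genes, minus self-pairs). Gold
edges outside that set are dropped with a warning; eligible pairs the
method never weighted are appended with weight zero in deterministic
lexicographic order so every method ranks the same pair set. The AUPR
convention is the trapezoid rule over the (recall, precision) points
of every rank prefix, with the polyline started at recall 0 at the
first prefix's precision; since recall only moves when a positive is
retrieved, each positive contributes one trapezoid between the
precision just before it and at it. A perfect ranking scores exactly
1; a random one averages close to the positive fraction — the pair of
properties that pins the convention down.
Ties are broken lexicographically rather than averaged over tie
orders — a documented simplification.

`aupr_significance()` estimates the probability that a random ranking
does as well, from 100,000 sampled rankings by default;
`aupr_score()` aggregates networks as $-\frac1n\sum\log_{10} p$. When
an observed AUPR beats every null sample the tail is extrapolated
from a log-normal fit to the null (flagged `extrapolated`); this only
matters for $p < 10^{-5}$ and is this package's own stand-in for an
unpublished convention. `topk_overlap()`/`topk_null()` count gold
edges among the top-$k$ (default 500) and calibrate the count against
random edge sets — a simulation kept distinct from the closed-form
hypergeometric tail precisely so the tests can check one against the
other.

## The synthetic benchmark generator

`sample_network()` + `simulate_dataset()` produce complete benchmark
datasets in the style of the in-silico challenge suites: per series, a
random perturbation (additive transcription input on roughly a third
of the genes) applied at $t=0$ and removed after 10 of the 21 sampled
points, 50 time units apart, after which the system relaxes back to
its resting state; a steady-state compendium (wild type, the complete
single-knockout panel, multifactorial conditions with jittered basal
rates); the knockout matrix for `mcz_ranking()`; the gold-standard
edge list; and the true decay rates. Observation noise is additive
Gaussian (sd 0.02 by default) truncated at zero.

Two generator choices deserve explanation:

* **The generating model is not the learned model.** Transcription is
  a saturating Hill-type sum, $f_j = \alpha_j\,(b_j + \sum_i s_{ij}
  H(x_i))$ with $H(x) = x^2/(x^2+K^2)$, integrated with an inner Euler
  step of `interval/50`. The mismatch is intentional: recovery results
  should not depend on the learner meeting its own model class.
* **Kinetics are slow relative to sampling.** Decay rates are drawn
  from $[0.005, 0.02]$ per time unit — half-lives of 0.7–2.8 sampling
  intervals — so perturbation responses and the return to rest are
  *visible across several sampled points*. Writing strengths as
  steady-state gains (the $\alpha_j$ prefactor above) keeps expression
  of order 1 regardless of kinetics. With fast kinetics every sample
  sits at quasi-equilibrium, the series degenerate into repeated
  steady states, and a time-series method has nothing to work with;
  that regime is a valid dataset but a vacuous benchmark for dynamics.

What passing on these fixtures does **not** show: real expression data
have far more genes than samples, heteroscedastic and non-Gaussian
noise, unmeasured regulators, and incomplete gold standards. The
generator probes correctness and qualitative behaviour, not field
performance.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the recovery benchmark
at 10 networks × 10 genes, 5 series × 21 points, with 150–250 trees
per ensemble — sizes chosen so the complete benchmark is a desk-scale
run; ranking quality is flat in the ensemble size well before that.
Other numerical choices, gathered in one place: population (biased)
variance inside the impurity computation (the choice cancels in the
normalized ranking but fixes the conservation identity); split
thresholds at midpoints of consecutive distinct values; split scores
compared with a $10^{-9}$ relative tolerance, with ties going to the
feature met first in the per-node shuffle of the gene-name-ordered
feature pool — exact cross-feature ties are structural at small nodes
(any feature separating a two-row node reduces the variance
identically), and this rule keeps tie credit randomized across nodes
and trees while making the fitted forests invariant to gene column
order and to positive rescaling of the regression targets, not merely
reproducible under one seed;
all-equal target nodes detected exactly (not via a floating-point
variance threshold) so constant genes get genuinely zero importance;
missing values rejected everywhere (the finite-difference construction
has no missing-data semantics); zero time intervals rejected; decay
estimation floors and median-fills as described above.

## Worked example

```{r example, eval = FALSE}
net <- sample_network(10, avg_degree = 1.5, seed = 1)
data <- simulate_dataset(net, seed = 1)

fit <- dyngenie3(data$series, ss = data$ss,
                 config = forest_config(n_trees = 250, seed = 1))
tidy(fit)                      # ranked edge tibble
pr <- pr_curve(fit, data$gold)
glance(pr)                     # aupr, positives, eligible pairs
autoplot(pr)

combined <- combine_rankings(fit$ranking,
                             mcz_ranking(data$ko$ko_values,
                                         data$ko$wild_type))
pr_curve(combined, data$gold)$aupr

res <- predict_double_knockout(fit, data$ko$wild_type, c("G1", "G2"))
autoplot(res$simulation)
```

## Known limitations

The finite-difference derivative misses regulation faster than the
sampling interval; smoothing-based derivative estimates are out of
scope here. Candidate regulator sets are global, not per-gene. The
explicit Euler integrator is not suited to stiff fitted dynamics
(lower `dt` if a simulation oscillates). Knockout clamping is a
modelling decision — the alternative (deletion as initial condition
only) is defensible and differs in systems where the deleted gene's
targets can re-activate it. MDI importance is biased toward variables
with many distinct values; with expression data all inputs are
continuous, so the bias is shared and the normalized ranking is
unaffected in practice.
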