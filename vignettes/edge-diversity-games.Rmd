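---
title: "Multiplayer games on regular graphs with edge diversity: models and methods"
author: "edgegames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplayer games on regular graphs with edge diversity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgegames)
```

## The model

A population of $N$ individuals occupies the nodes of a random regular graph
of degree $k$. Every edge carries one of $n$ *types* — a fixed label standing
for the nature of the tie (same versus different task role, strong versus
weak social tie, interaction rate, genetic or geographic proximity). Every
node has exactly $g_i$ neighbours along type-$i$ edges, with
$\sum_{i=1}^n g_i = k$; the pair $(k; g_1,\dots,g_n)$ is the *degree
profile*, shared by all nodes. Types are assigned when the graph is built
and never change.

Each individual plays one of two strategies, $A$ or $B$, and collects a
payoff from a single multiplayer interaction with its $k$ neighbours. The
payoff depends on the *typed* composition of the neighbourhood: if
$s_i$ of the $g_i$ type-$i$ neighbours play $A$, a focal $A$-player earns
$a_{s_1\cdots s_n}$ and a focal $B$-player earns $b_{s_1\cdots s_n}$. The
pair of maps $(a, b)$ over all $\prod_i (g_i + 1)$ configurations is a
*payoff tensor* (`payoff_tensor()`), and every game family in the package is
a tensor constructor. Payoff $\pi$ becomes fitness through
$F = 1 - \omega + \omega \pi$, with selection intensity $\omega \ll 1$
(weak selection). Evolution follows death-birth updating: a uniformly random
individual resets its strategy and copies neighbour $j$ with probability
$F_j / \sum_{l} F_l$ over its neighbours, an imitation reading under which
edge types are static.

## The sigma rule

Strategy $A$ is favoured over $B$ when a single $A$-mutant fixates more
readily than a single $B$-mutant, $\rho_A > \rho_B$. Under weak selection
this reduces to a linear inequality in the payoffs,

$$\sum_{s_1=0}^{g_1}\cdots\sum_{s_n=0}^{g_n} \sigma_{s_1\cdots s_n}
  \left(a_{s_1\cdots s_n} - b_{(g_1-s_1)\cdots(g_n-s_n)}\right) > 0,$$

whose weights $\sigma_{s_1\cdots s_n}$ — the structure coefficients — depend
only on the degree profile and the update rule, never on the payoffs. The
bracket is the *gain from flipping*: what a focal $A$ in configuration $s$
would lose if every individual switched strategy at once. For death-birth
updating on large random regular graphs, pair approximation yields the
closed form implemented in `sigma_coefficient()`:

$$\sigma_{s_1\cdots s_n} = \frac{(k-2)^{\,k-S}}{k^2 (k+1)(k+2)}\,
  \frac{\prod_j \binom{g_j}{s_j}}{\binom{k}{S}}
  \sum_{l=0}^{k} (k-l)\Big\{[2k + (k-2) l]\,\Psi(k,S,l)
  + [k^2 - (k-2) l]\,\Phi(k,S,l)\Big\},$$

with $S = \sum_j s_j$ and the kernels $\Psi, \Phi$ of `psi_kernel()` (two
binomial-over-power terms each, with the convention that out-of-range
binomials vanish; $\Phi(k,i,l) = \Psi$ reflected in $l$). Three structural
facts, each verified by the test suite, make the table easy to reason
about:

* **Normalisation.** The table sums to one, so $\sigma$ is a probability
  distribution over configurations and the rule says "the expected gain
  from flipping is positive". All entries are strictly positive.
* **Hypergeometric factorisation.** $\sigma_s$ is the degree-only
  coefficient $\sigma_S$ (the $n = 1$ table at the same $k$) times the
  multivariate hypergeometric probability of splitting $S$ A-neighbours as
  $(s_1,\dots,s_n)$ across types. Edge diversity therefore costs nothing
  beyond bookkeeping: `marginal_sigma(table, "total")` recovers the
  single-type table exactly.
* **Mean configuration.** $\sum_s \sigma_s\, s_i = g_i (k+1)/(2k)$, the
  identity that collapses all edge-dependent *pairwise* games to a single
  averaged game with the familiar structure coefficient $(k+1)/(k-1)$ and
  turns per-type donation games into the averaged-benefit rule
  $\bar B / \bar C > k$.

A note on provenance of the formula's prefactor: with $(k-2)^{k-S}$ the
table satisfies every identity above *exactly* (to double precision) for
all $k$ tested up to 40, and the replicator construction below reproduces
it independently; the package treats those identities as the defining
cross-checks of the implementation.

## Infinite populations

In the infinite-population limit the frequency $x$ of $A$-players follows

$$\dot x = \frac{\omega (k-2)}{k^2}\, x (1-x)\, f(x),$$

where $f$ mixes the drift terms $\Lambda_a(s) - \Lambda_b(s)$ over
binomially sampled configurations (`f_of_x()`). $\Lambda_a$ thins the
focal's $B$-neighbours with a $\mathrm{Binom}(g_j - s_j, z)$ kick,
$z = 1/(k-1)$, and weighs the payoff at the kicked configuration by
$(s_j + r_j)$ plus a shifted term with coefficient $z s_j + r_j/z$;
$\Lambda_b$ is the mirror image. The coefficient of the shifted term is the
one genuinely delicate reading in the model, and the package pins it down
by a validation protocol rather than by fiat: the implemented reading is
the one under which (i) the mean-configuration identity re-emerges from the
flow, (ii) the functional $\int_0^1 f(x)\,dx$ has the exact flip symmetry
of the sigma rule, and (iii) the two levels of description agree exactly,

$$\int_0^1 f(x)\,dx = \frac{k^2}{k-1}\,
  \sum_s \sigma_s (a_s - b_{g-s}),$$

an identity the suite checks on random tensors. So the finite-population
comparison $\rho_A$ vs $\rho_B$ and the average infinite-population flow
always point the same way.

`equilibria()` locates interior rest points by a sign-change scan
(grid $10^{-3}$) refined by bisection (tolerance $10^{-10}$; simple roots
only), `trajectory()` integrates the flow with `deSolve::ode`
(atol $10^{-9}$, rtol $10^{-8}$), clipped to $[0,1]$. A drift identically
below $10^{-12}$ on the scan grid is reported as degenerate (neutral game)
rather than as a root list.

## Game families

* **Edge-dependent pairwise games** (`pairwise_tensor()`): one $2\times 2$
  matrix $(\alpha_i, \beta_i, \gamma_i, \theta_i)$ per type, payoffs
  accumulated over the $k$ interactions. Donation games
  (`donation_tensor()`) give the $\bar B/\bar C > k$ rule.
* **Diverse multiplayer games** (`additive_tensor()`): one $(g_j+1)$-player
  game per type — volunteer's dilemmas (`volunteers_table()`: one
  cooperator provides $B_v$ to everyone at personal cost $C_v$) and linear
  public goods games (`pgg_table()`). For equal group sizes the rule
  reduces to $g+1$ marginal coefficients $\tilde\sigma_s$, and the diverse
  system is exactly $n$ times the single *averaged* game
  (`average_game()`); the critical volunteer's-dilemma ratio is
  $(B_v/C_v)^* = 1/\tilde\sigma_g$.
* **Weighted graphs** (`weighted_tables()`): per-type weights $\zeta_j$
  scale the per-type games (interaction rates). Critical ratios and
  interior equilibria are invariant in $\zeta$, while the speed of
  selection scales with the mean weight — strong ties accelerate evolution
  but do not redirect it.
* **Division of labour** (`dol_tensor()`, `ndol_table()`): a two-role
  threshold public goods game. Benefits require a cooperator of each role;
  type-1 edges join same-role, type-2 edges cross-role neighbours, so a
  focal cooperator needs only $s_2 \ge 1$ while a focal defector needs
  both $s_1 \ge 1$ and $s_2 \ge 1$. The accumulative variant pays
  $(s_1+s_2+1)B - C$ per provisioned cooperator; the flat variant pays $B$
  once the thresholds are met. The single-threshold comparison game uses
  threshold 2 at the same $k$. `critical_dol()` evaluates the closed-form
  critical ratios directly from the sigma table, and `dol_scan()` sweeps
  $g_1$ at fixed $k$: the critical ratio is monotone in $g_1$ and drops
  below the no-division value when the focal's own role group is small —
  specialisation lowers the barrier to cooperation by shrinking the group
  one can free-ride on. `dol_mean_payoffs()` implements the large-$k$
  closed forms for the flat variant and `payoff_ratio_compare()` the
  relative-advantage comparison.

## Finite-population simulator

`estimate_fixation()` and `estimate_delta_p()` drive a compiled
(C++) death-birth engine; `exact_fixation()` solves the full
$2^N$-state absorbing Markov chain and is the ground truth on tiny graphs
(the suite holds the sampler to within 3 standard errors of it, and to
$\rho = 1/N$ exactly at $\omega = 0$). Protocol choices:

* Fixation runs start one mutant at a uniformly random node and iterate to
  absorption, capped at $10^4$ generations of $N$ elementary events;
  $\rho_A$ and $\rho_B$ come from separate batches with paired seeds, and
  estimates carry binomial standard errors. A warning is attached if more
  than 1% of runs hit the cap.
* The drift estimate at frequency $p$ averages $p_{\text{after}} -
  p_{\text{before}}$ over independent Bernoulli($p$) initialisations run
  for exactly one generation ($N$ elementary events). This matches the
  replicator's instantaneous drift in both sign and, empirically, scale.
* Fitness positivity $1 - \omega + \omega \min(a, b) > 0$ is vetted against
  the tensor extrema before any run.

## Synthetic graphs

`generate_typed_graph()` overlays $n$ independent random $g_i$-regular
simple layers (igraph's configuration-model sampler) on one vertex set.
Because the expected number of pairs linked in two layers is about
$g_i g_j / 2$ regardless of $N$, colliding edges are repaired by
degree-preserving double-edge swaps inside their layer — each swap vetted
against self-loops, duplicate edges and cross-layer collisions — with a
full redraw as fallback (budget 1000). The result realises the profile
exactly at every node and is deterministic given a seed.

This generator emulates the *locally tree-like, degree-regular* population
the analytic theory assumes. It does not produce degree heterogeneity,
clustering, community structure or assortative type placement, and ties
never rewire. Agreement between simulation and the sigma rule on these
graphs therefore validates the pair approximation on its home turf; it
does not by itself certify predictions for empirical networks, where the
closed form should be treated as a first-order guide.

## Numerical choices and test design

* Structure coefficients use double precision throughout; every factor is
  a ratio of exact small integers and the relative error stays near
  machine epsilon up to $k = 40$ (the scan size used for the
  division-of-labour sweep). The test suite cross-checks all entries for
  $k \le 8$ against an independent exact-rational evaluation of the
  unsimplified formula.
* Verdicts treat $|\text{lhs}| < 10^{-12}$ as neutral (float noise near
  criticality). Critical ratios exploit that the rule is affine in the
  benefit: two evaluations give the root in closed form, which keeps the
  weight-invariance checks exact; a non-positive slope returns `Inf`
  ("cooperation never favoured") rather than an error so parameter scans
  can plot it.
* In the large-$k$ mean-payoff comparison the dol/ndol gap decays like
  $r^{g_2}(1-p)^{g_2}$ and falls below double resolution as $p \to 1$, and
  the two payoff ratios converge to $(B-C)/B$ within $\sim 10^{-5}$ of
  each other; comparisons near that boundary therefore use a $10^{-4}$
  equality band, with strict inequalities asserted where the gap is
  representable.
* Monte Carlo test sizes are chosen to finish in minutes while leaving
  3-standard-error margins: $10^5$ runs on $N \le 8$ oracle graphs;
  $N = 500$, $k = 8$, $2\times 10^4$ runs per point at three
  benefit-to-cost values straddling the critical ratio for the
  weak-selection law $\rho_A - \rho_B \approx \omega \times \text{lhs}$;
  $N = 1000$ with 2000 replicates per frequency for the drift curves.
  Stochastic sign checks are gated on the prediction being resolvable
  above $3$ standard errors of the estimate — at frequencies where the
  predicted drift is itself indistinguishable from zero, a sign test would
  only measure noise.
* The Gaussian-sampled game fixtures truncate draws at $10^{-6}$ to keep
  benefits and costs positive. The public goods game divides the produced
  benefit among all $g + 1$ participants (the focal plus its group), the
  natural reading of a $(g+1)$-player game.
* Graph files use 0-based node ids, one undirected edge per line with
  $u < v$; per-type weights are written per edge and validated for
  consistency on read.

## Limitations

The closed forms are pair-approximation, weak-selection, large-$N$
results for death-birth updating only; they are first-order in $\omega$,
and small populations show visible finite-size deviations (the exact
Markov oracle quantifies them on tiny graphs). Birth-death and
pairwise-comparison update rules, strong selection, mutation-selection
balance, per-individual asymmetric payoffs and coevolving edge types are
out of scope.
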