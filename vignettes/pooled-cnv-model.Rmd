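---
title: "The pooled-capture negative binomial model behind poolcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pooled-capture negative binomial model behind poolcnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolcnv)
```

## Why pooled capture changes the problem

Read-depth CNV detection from exome sequencing is limited less by
sequencing noise than by *capture* noise: each hybridization reaction
pulls down exons with slightly different efficiencies, so two libraries
captured separately differ at every exon for reasons that have nothing
to do with copy number. When the barcoded libraries of a whole pool are
mixed *before* a single capture reaction, every sample experiences the
same bait kinetics and the per-exon depth profile becomes strikingly
reproducible across the pool. `poolcnv` is built for exactly this
design: it treats the other members of the pool as the reference, so no
external panel of controls and no prior on variant size or prevalence
is needed. The cost of the comparative design is that variants common
to most of the pool are invisible — the model estimates the diploid
mean from the pool itself.

Two tools in the package quantify the variance reduction that motivates
the caller. `fit_dirichlet()` treats each subject's per-exon proportion
vector as a draw from a Dirichlet distribution; the fitted precision
$\alpha_0 = \sum_j \alpha_j$ is inversely related to the inter-sample
variance of the proportions, so better-balanced pools show larger
$\alpha_0$. `mean_variance_profile()` shows the same thing without a
parametric model: across-subject variance against mean per exon, with
the Poisson 1:1 line as the no-excess-variance reference.

## The count model

Let $c_{ij}$ be the number of molecules (deduplicated read pairs)
observed for subject $i$ at target $j$. The model is

$$C_{ij} \sim \mathrm{NB}\!\left(f_i\, s_{ij}\, \hat\mu_j,\;
  \tilde\phi_j / f_i\right),$$

in mean/dispersion parameterization (variance $m + \phi m^2$), where
$f_i$ is a per-subject size factor, $s_{ij}$ the copy-state multiplier
($1$ = diploid, $0.5$ = heterozygous deletion, $2$ = duplication to
four copies), $\hat\mu_j$ the diploid mean at target $j$, and
$\tilde\phi_j$ a *shrunken* per-target dispersion. Scaling the
dispersion by $1/f_i$ keeps the coefficient of variation of a target
consistent across subjects of different depth.

`cnv_call()` estimates the states by iterating, from an all-diploid
start:

1. **Adjust**: $c'_{ij} = c_{ij} / \hat s_{ij}$ puts every cell on the
   diploid scale (`adjusted_counts()`).
2. **Normalize**: $f_i = \mathrm{median}_j\, (c'_{ij} / g_j)$ over the
   cells with $c'_{ij} > 10$, where $g_j$ is the geometric mean of
   target $j$ across subjects (`size_factors()`). The median-of-ratios
   construction is robust to the (rare) true variants that remain
   mis-assigned at this point.
3. **Moments**: $\hat\mu_j$ and $\hat\phi_j = \max\!\big(0,
   (\hat\sigma_j^2 - \hat\mu_j)/\hat\mu_j^2\big)$ from the sample mean
   and variance of $c'_{ij}/f_i$ (`mom_dispersion()`).
4. **Shrink**: $\tilde\phi_j = (1-\delta)\hat\phi_j + \delta\hat\xi$
   with $\delta$ the ratio of the deviation sums scaled by $1/(J-1)$
   and $1/(J-2)$, clamped to $[0,1]$ (`shrink_dispersion()`). The
   shrinkage target $\hat\xi$ admits two defensible readings, both
   implemented. The default takes $\hat\xi = \overline{\hat\phi}$, the
   stationary point of the squared-distance criterion; $\delta$ then
   degenerates to $(J-2)/(J-1)$, i.e. near-complete shrinkage to one
   pool-wide dispersion — the right small-sample behavior when a
   16-subject method-of-moments $\hat\phi_j$ is noise dominated.
   `target = "min-derivative"` instead minimizes the *signed*
   derivative $\tfrac{d}{d\xi}\, 1/\sum_j(\hat\phi_j-\xi)^2$, with
   closed form $\hat\xi = \overline{\hat\phi} +
   \mathrm{sd}(\hat\phi)/\sqrt{3}$ (cross-checked by grid
   minimization in `poolcnv:::xi_grid()`); there $\delta \approx 3/4$
   and a quarter of the per-target signal survives, at a mildly
   conservative common value. In simulation the two trade a couple of
   points of duplication sensitivity (mean reading higher) against a
   modest reduction in false-positive duplications (min-derivative
   lower), and neither removes the mid-depth instability described
   under limitations; the mean reading is the default. The clamp keeps
   the update a convex combination in every case, and a pool where all
   $\hat\phi_j$ coincide takes $\delta = 1$ as a no-op.
5. **Assign**: $\hat s_{ij} = \arg\max_{s \in S}
   \mathcal{L}(s \mid c_{ij}, f_i, \hat\mu_j, \tilde\phi_j)$ over the
   grid $S = \{0.001, 0.5, 1, 1.5, 2\}$ (`update_states()`). The grid
   uses $0.001$, not $0$, for homozygous deletions so that step 1 stays
   defined; the *simulator's* state set uses a true $0$ — the two sets
   are deliberately different. Likelihood ties resolve toward the
   diploid state, then toward the state nearest $1$.

The loop stops when the number of changed states falls to
`change_threshold` (default 0) or after `max_iter` (default 40)
iterations; the defaults were chosen because state flips become
confined to a handful of borderline low-count cells after a few
iterations, and 40 rounds bounds the cost of the occasional two-cycle
oscillation among them. After convergence each cell receives a p-value
for the diploid state and the Benjamini–Hochberg adjustment is applied
once, jointly across all (subject, target) cells of the pool; calls are
cells with adjusted $p < \alpha$ (default 0.05) and a non-diploid
state.

### The diploid p-value

The model statement $\pi_{ij} = \Pr(s_{ij} = 1)$ admits two readings,
and both are implemented behind `p_method`:

* `"tail"` (default): a doubled-minimum-tail exact test under the
  diploid model, $\pi = \min\{1,\, 2\min(\Pr(C \le c), \Pr(C \ge c))\}$.
  This is a classical two-sided p-value and is what the BH step
  expects.
* `"posterior"`: the normalized likelihood of $s = 1$ across the grid
  (a uniform-prior posterior probability). It orders cells almost
  identically but is not uniformly distributed under the null, so the
  tail form is the default.

### Choices where the procedure is underdetermined

* The $1/n_j$ and $n_j - 2$ factors in the shrinkage weight are read as
  $1/J$ and $J - 2$ ($J$ = number of targets), the only reading under
  which the weight is a dimensionless ratio of two variance estimates
  of the same sum; `poolcnv:::xi_grid()` provides an independent
  numerical check that the stationary point of the criterion sits at
  the mean.
* The $c' > 10$ subset governs the size-factor median only; dispersion
  estimation uses all unmasked cells. Dropping low-count cells from a
  ratio median guards against zero geometric means, which is not a
  concern for the moment estimates.
* Targets with zero estimated mean, all-zero rows, and targets with
  fewer than two unmasked subjects are excluded from calling and
  reported with `NA` state rather than guessed at.
* BH is applied pooled across subjects, matching the single
  final call-set the procedure produces.
* Merged variant records (contiguous same-direction flagged exons of
  one subject) are reporting conveniences; every statistic in the
  package is computed at the (subject, exon) level, and breakpoints
  within an exon are out of scope by construction.

## What the simulator emulates

`simulate_pool()` models capture as a multinomial process: each
captured molecule is one trial whose outcome is a target. Per subject,
the shared baseline simplex $\mathbb{E}$ is multiplied elementwise by
the subject's copy states, renormalized, and counts are drawn
multinomially with the subject's total depth as the trial count — so
row sums equal realized depths *exactly*, and the conditional expected
count is $n_i\, e_j s_{ij} / \sum_k e_k s_{ik}$.

Defaults encode the study conditions the package is benchmarked under:

* **Pool size 16**, the typical multiplexed-capture batch.
* **Depth** drawn uniformly within ±30% of the nominal molecules per
  subject (a nominal 10 million gives 7–13 million), rounded to
  integers since molecules are discrete.
* **Variant prior 1/1000 per cell**, split equally over
  $\{0, 0.5, 1.5, 2\}$ — single-exon variants, injected independently
  per (subject, target). Multi-exon variants are not simulated by
  default (an explicit `state_matrix` can place them).
* **Baseline simplex** from `random_simplex(J, concentration = 1.5)` —
  normalized Gamma(1.5) weights. The concentration was fixed at 1.5
  because it reproduces the median-to-mean per-exon count ratio
  (≈ 0.78) observed in real multiplexed exome pools; smaller values
  give unrealistically many near-dead targets, larger ones an
  implausibly flat capture profile.

What the simulator does *not* reproduce: GC- and fragment-length
capture bias (deliberately absent from the model as well), correlated
variants spanning adjacent exons, reference artifacts such as
repetitive or low-complexity regions (an exclusion list can be passed
to the evaluator instead), and mosaicism. Passing simulation
benchmarks therefore demonstrates correctness of the estimator under
its own generative model, not freedom from real-data artifacts.

## Molecule counting

`count_molecules()` reduces alignments to the model's sufficient data:
per-target molecule counts. A molecule is counted when it is properly
paired, not a duplicate, both mates are primary non-supplementary
alignments, and both mapping qualities are ≥ 20. The fragment span runs
from the leftmost mate start to the rightmost mate end, and the
molecule increments every target its span overlaps by ≥ 1 bp — once per
target, since the model treats targets independently and splitting a
molecule across targets would require an arbitrary attribution rule.
Coordinates are BED-style 0-based half-open end to end.

## Dirichlet fitting notes

The maximum-likelihood fit runs Newton–Raphson on the Dirichlet
log-likelihood with digamma/trigamma derivatives, a moment-matching
start, and the diagonal-plus-rank-one Hessian structure for linear-time
steps; step halving enforces positivity and monotone likelihood.
Convergence is declared at a per-observation gradient max-norm below
1e-8 (cap 1000 iterations). Targets are pre-filtered so that every
subject has between 5 and 2000 counts — the per-subject reading of the
bound is the default because it is what guarantees strictly positive
proportions in the log-likelihood; a pool-sum reading is available via
`scope = "pool"`. Two genuinely degenerate regimes are reported as
provisional fits with a warning rather than silently: iteration-cap
exhaustion, and a diverging precision ($\alpha_0 > 10^8$), which is the
signature of (near-)identical proportion vectors whose MLE does not
exist.

## Problem sizes used in the shipped checks

The package's own test suite exercises the caller at desk scale chosen
to keep the full suite within a coffee break while leaving the
estimator in its intended operating regime: pools of 6–16 subjects,
400–20,000 targets, and depths of 25–225 mean molecules per target.
The headline simulation (10 pools of 16 × 20,000 at 225
molecules/target, ≈ 3.2 million evaluated cells) mirrors the
recommended sequencing practice of collecting about 225 filtered read
pairs per target; the depth sweep uses 2,000 targets with 5 replicates
per depth. Dirichlet recovery uses 16 subjects over 200 targets with
true $\alpha_0 \in \{50, 500, 5000\}$.

## Known limitations

* The comparative design cannot see variants shared by most of the
  pool, and a variant present in half the pool inflates $\hat\mu_j$
  enough to distort calls at that exon.
* The per-target model is scale degenerate: "every subject duplicated
  with diploid mean $\hat\mu_j$" fits the counts exactly as well as
  "every subject diploid with mean $2\hat\mu_j$". The all-diploid
  initialization is the only anchor breaking that symmetry, and at
  targets whose mean count sits near the diploid/1.5-state likelihood
  crossover (roughly 10–40 molecules) the iteration can cascade into
  the spurious all-duplicated solution, yielding clustered
  false-positive duplications at a handful of targets per pool. The
  effect peaks at intermediate depths — below, the flipped cells
  cannot reach significance; above, few targets sit in the vulnerable
  band — so the false discovery rate need not fall monotonically with
  depth even though sensitivity rises, as the package's own depth
  sweep shows. Neither shrinkage-target reading removes the
  instability.
* Sensitivity degrades smoothly at weakly captured exons; below
  roughly 25 molecules per target the five-state grid is barely
  identifiable and state flips among neighboring grid values are
  expected even for true diploids (calls remain controlled by the
  adjusted p-value, not the raw state).
* The doubled-tail p-value inherits the usual conservatism of discrete
  two-sided tests at low counts.
* No GC/fragment-length correction is applied anywhere; pools whose
  depth profile drifts with GC between subjects (e.g. independently
  captured libraries) violate the shared-simplex assumption and
  should be profiled with `fit_dirichlet()` before trusting calls.

```{r example, eval = FALSE}
# a minimal end-to-end run
pool <- simulate_pool(subjects = 16, targets = 2000, depth = 450e3,
                      variant_prob = 1/1000, seed = 1)
fit <- cnv_call(pool$counts, alpha = 0.05)
summary(fit)
cnv_confusion(fit, pool)
```
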