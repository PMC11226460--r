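---
title: "Context tree models for stimulus-driven response sequences: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context tree models for stimulus-driven response sequences: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlmcdrive)
```

This vignette is the package's own account of the statistics it
implements: the models and estimators, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the numerical and design choices made where more
than one reasonable option existed.

## 1. Context tree models

A *context tree model* (variable-length Markov chain) over a finite
alphabet $A$ is a pair $(\tau, p)$: a suffix-free set $\tau$ of *context*
strings and a transition distribution $p(\cdot \mid w)$ for each context
$w$. Contexts are written oldest-first with the most recent symbol last,
so the context `"21"` applies whenever the previous symbol was `1`
preceded by `2`. Suffix-freeness makes the context of any sufficiently
long past unique; `context_of()` implements the lookup, and
`context_tree()` enforces the invariant at construction. The empty string
is the root context (an order-0, i.i.d. model) and cannot coexist with
other contexts.

The package ships a registry of four three-symbol stimulus models
(`kicker_model(1:4)`) organized in two pairs that share a tree but differ
in their transition probabilities:

* models 1 and 2 on the tree $\{0, 2, 01, 11, 21\}$, with the transitions
  at `01` and `21` deterministic in model 1 and stochastic
  (return with 0.25 / move on with 0.75) in model 2;
* models 3 and 4 on the tree $\{2, 00, 10, 20, 01, 11, 21\}$; model 3
  concatenates blocks `211`, independently replacing each `1` by `0` with
  probability 0.25, which makes it a noisy *periodic* chain; model 4
  interchanges the distributions of `01` and `21` and moves the mode of
  context `2` from `1` to `0`, destroying the periodicity at almost the
  same entropy.

Only model 3 is fully determined by its published generative description.
For models 1, 2 and 4 the registry encodes reconstructions: the documented
transition changes fix part of each model, and the free entries were
chosen — once — so that the computed entropy rates reproduce the reference
values (0.65, 0.81, 0.54, 0.56 bits/symbol). The reconstruction of models
1 and 2 reproduces 0.65 and 0.81 exactly (0.6490 and 0.8113); for model 4
the closest structurally consistent variant gives 0.5664, which matches
the reference 0.56 only under truncation. These three models therefore
carry `verified = FALSE`, every analysis records a model fingerprint in
its metadata, and `read_model()` lets users substitute exact
probabilities if they have them.

## 2. Entropy rate, matching and maximizing scores

`markov_embedding()` rewrites a model of height $L$ as a first-order
Markov chain on the space of length-$L$ pasts with positive stationary
probability. Transitions shift the window by one symbol, with
probabilities taken from the context of the current past. Recurrent
support is found by a reachability closure: states in closed
communicating classes are kept, transient states (reachable only from
special starts) carry no stationary mass and are dropped; two or more
closed classes raise an error, since the stationary distribution is then
not unique. For model 3 this gives 8 recurrent length-2 pasts — all
pairs except `22`, which the block structure forbids.

The stationary distribution is the normalized left eigenvector of the
transition matrix for eigenvalue 1 (`eigen` on $M^\top$, with a
linear-solve fallback and a residual check at $10^{-8}$), and

$$H \;=\; \sum_i \mu_i \Big( -\sum_j M_{ij} \log_2 M_{ij} \Big)$$

is the entropy rate in bits per symbol. Base 2 matters: the 211-block
model evaluates to $2\,H_2(0.25)/3 = 0.5409$ bits, which reproduces the
reference 0.54, while natural logs would give 0.375. A height-0 (i.i.d.)
model is embedded at order 1 rather than as a single state — a one-state
embedding would report zero entropy for any i.i.d. source, which is the
entropy of the *embedding*, not of the chain.

Two scalar summaries describe a fully informed responder:
the *matching score* $\sum_w \mu(w) \sum_a p(a|w)^2$ (the probability
that an independent draw from the context distribution equals the next
symbol) and the *maximizing score* $\sum_w \mu(w) \max_a p(a|w)$. The
maximizing score dominates the matching score for every model (max vs
mean-square), which the test suite checks on a thousand random models.

## 3. The simulator and the responder agents

`simulate_chain()` starts from a uniformly drawn past of length equal to
the tree height and discards `burn_in = 100` warm-up symbols, so the
returned stretch is approximately stationary regardless of the start.
The last pre-output symbols are attached as `init_past`, so a responder
can condition on a well-defined context from trial 1. Internally the
simulator tracks pasts as integer indices (base-$|A|$ digits of the most
recent symbols), which lets `build_benchmark()` run thousands of chains
in parallel as vectorized operations.

`respond()` implements the agents:

* **matching** samples from $p(\cdot \mid \text{context})$ — it emulates
  the generator;
* **maximizing** answers $\arg\max_a p(a \mid \text{context})$, with ties
  broken toward the smallest symbol in alphabet order (a deterministic
  rule is required for reproducibility);
* **uniform** and **constant** are the reference suboptimal agents.

Responses at trials whose past has no defined context (possible only when
`init_past` is absent) fall back to uniform draws. All randomness flows
through explicit seeds; seeded calls restore the caller's RNG state.

What the generator emulates — and what it does not. Simulated responders
have *fixed* strategies and perfect model knowledge. Human participants
learn: their early windows mix exploration, misidentified contexts and
reliance on their own past. Passing tests on synthetic cohorts therefore
validates the *machinery* (estimators, benchmarks, tests), not any claim
about how human learning unfolds; in particular the slope-based exclusion
rule, applied to fully informed agents whose performance has no trend,
flags about half of them — on real data it is a compliance filter, on
informed agents it is noise.

## 4. The BIC context-tree estimator

Given a paired sample, `count_tables()` computes
$N(u, a)$ — how often stimulus past $u$ is followed by response $a$ —
for every observed $u$ up to length $L$, with trials before $t = l(u)$
contributing to no count. The estimator maximizes
$\log L_{(\tau,\hat q)} - c \cdot df(\tau) \log n$ over admissible trees
of height $\le L$ built on observed pasts, where the likelihood
factorizes over contexts, $\hat q(a|u) = N(u,a)/N(u)$, and
$df(u) = \#\{a : N(u,a) \ge 1\} - 1$ counts observed free parameters.

`bic_prune()` solves the maximization exactly by the bottom-up indicator
recursion: each node carries
$V_w = \max\{n^{-c\,df(w)} L_w,\ \prod_b V_{bw}\}$ and an indicator of
whether splitting won; the estimated contexts are the nodes with
indicator 0 whose ancestors all have indicator 1. Numerical choices:

* all $V$ values are held in the log domain ($n^{-c\,df} L_w$ underflows
  long before $n = 1000$);
* the penalty uses the natural log of $n$ (only the product
  $c \log n$ matters, since $c$ is tuned);
* ties in the strict comparison resolve to pruning, so degenerate splits
  (children reproducing the parent exactly) never survive;
* unobserved children contribute factor 1 (log 0); nodes with no
  occurrences as a past are never candidates.

`exhaustive_bic()` enumerates every admissible tree for $L \le 2$ and
$|A| \le 3$ and scores it with the *same nested summation order* as the
recursion, so oracle and recursion agree bit for bit, ties included; the
test suite checks equality on hundreds of random instances.

### Tuning the penalty

Small $c$ overfits, large $c$ underfits; `select_penalty()` scores each
$c$ on a default grid of 40 log-spaced points in $[0.05, 4]$ by an
estimate of the final prediction error of the fitted tree's plug-in
predictor (per-trial Brier score of $\hat q(\cdot \mid \text{context})$).
Two estimates are available:

* `risk = "cv"` (default): 2-fold chronological cross-validation — the
  tree and its probabilities are refitted on each half of the sequence
  and scored on the other half, with unseen contexts backing off to the
  longest past observed in training;
* `risk = "fpe"`: the in-sample Brier score times the classical
  correction $(N + df)/(N - df)$.

The in-sample estimate is kept only as a diagnostic: in-sample Brier
error is monotone non-increasing under tree refinement, so its raw
minimizer drifts to the smallest penalties, and the $(N+df)/(N-df)$
correction is too weak to repair this (tree-recovery experiments at
$n = 1000$ showed ~25% recovery under `"fpe"` versus 95–100% under
`"cv"`).

Ties go to the largest $c$ (the smaller tree), and by default the
**one-standard-error rule** is applied to the risk curve: the chosen $c$
is the largest one whose risk is within one standard error of the
minimum. The rule matters here for a structural reason: splitting a
context into children with *identical* response distributions (e.g. the
children of `20` in model 3) changes the prediction risk by essentially
zero, so the raw minimizer of a noisy risk curve picks the refinement
about half the time. With the one-SE rule, fits at the full session
length ($n = 1000$) recover the generating tree of model 3 in
effectively all seeds, and at the single-window length ($n = 250$) in
roughly half — individually noisy, but unbiased enough that a
25-participant consensus tree is already correct in the first window.

## 5. The mode (consensus) context tree

A cohort of estimated trees is summarized by majority-rule consensus:
starting at the root, a node $w$ is kept as a context when at least as
many trees identified $w$ itself as identified some deeper context inside
$w$'s branch; otherwise the node is split and the rule recurses into its
supported children. Ties keep the node (the shallower tree), and branches
never identified by any tree are dropped. Per-node vote proportions
(fraction of trees identifying each string as a context) are returned for
consensus-shading displays.

A seemingly natural alternative — choosing the admissible tree that
maximizes the *sum* of leaf votes — was rejected after it proved to
double-count disagreement: five trees that each split a branch
differently contribute five scattered leaf votes that together outvote a
node supported by a majority outright, so the "mode" tree over-refines
exactly where individual fits are noisiest. Majority rule reduces to the
obvious answers in the clean cases (identical trees; a majority of
identical trees against scattered alternatives) and summarizes noisy
cohorts without that artifact.

## 6. Scoring, benchmarks and strategy classification

The per-window score is the proportion of correct predictions
(`pcp`; `cpcp` is its running version). Windows are 250 trials sliding
by 150 — six windows for a 1000-trial session, the last covering trials
751–1000. For cross-model comparability scores are divided by the
model's theoretical maximizing score and logit-transformed, with the
ratio clipped to $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-3}$
(a lucky window can exceed the theoretical ceiling; clipping absorbs
the boundary). A per-participant least-squares slope of the logit scores
across windows flags participants with negative slopes for exclusion;
a zero slope is kept.

`build_benchmark()` simulates, per model, 10,000 stimulus sequences of
250 trials with fully informed matching and maximizing responders, and
forms Gaussian-kernel density estimates (Silverman bandwidth — no kernel
or bandwidth is prescribed by the protocol, and the defaults of
`stats::density` are the field's default too) of the two score samples.
`classify_strategy()` labels a score *suboptimal* below the benchmark's
cutoff — the 0.5% quantile of the matching sample, a quantile rather
than a density support bound because KDE tails are unstable — and
otherwise by whichever density is higher at the observed score, ties
going to *matching*, the more conservative label.

## 7. The own-past independence test

`lrt_independence()` tests whether the response at each trial is
conditionally independent of the responder's previous $k$ responses given
the previous $k'$ stimulus symbols. Both hypotheses are stratified
multinomials fitted by maximum likelihood, and
$-2\log R = 2(\ell_1 - \ell_0)$ is referred to a chi-squared
distribution. Defaults $k = k' = 1$ keep every stratum well-populated at
the window length of 250 trials.

The nominal degrees of freedom,
$(|A|-1)|A|^{k'}(|A|^k - 1)$ (= 12 for three symbols and $k = k' = 1$),
count parameters over the full product space. Data from low-entropy
models contain *structural zeros* — a matching responder facing model 3
never answers `2` after a stimulus `2`, and several (stimulus, response)
past combinations never occur — so the statistic genuinely lives on a
lower-dimensional space and the nominal reference makes the test
arbitrarily conservative (for model 3 with a matching agent the observed
dimension is 4, and rejection rates against $\chi^2_{12}$ fall to
$\sim 10^{-3}$). By default the p-value therefore uses degrees of freedom
counted from the observed support,
$\sum_{w_x,w_y}(k_{w_x,w_y}-1) - \sum_{w_x}(k_{w_x}-1)$; both counts are
reported, `df_method = "nominal"` restores the textbook formula, and the
output flags samples in which more than 10% of strata are empty. Strata
with zero counts contribute zero to the statistic. Under this default the
Monte-Carlo type-I error at $\alpha = 0.05$, $n = 1000$, sits inside the
99% binomial band over 500 replicates, and p-values are approximately
uniform.

Why the default $k' = 1$ is compatible with model 3 even though the model
has memory 2: all stochastic contexts of model 3 share the distribution
$(0.25, 0.75, 0)$, so a matching responder's previous answer carries no
information about the earlier stimulus beyond what the last stimulus
symbol already provides, and the conditional-independence null holds
exactly. For models where stochastic contexts differ, $k'$ should match
the model height.

## 8. The cohort driver

`run_cohort()` chains the full pipeline over a synthetic cohort —
simulate pairs, score windows, fit a tree and run the independence test
per participant and window, compute per-window mode trees, classify
scores against the benchmark, and flag exclusions — from a single seeded
configuration (defaults: 30 participants, 1000 trials, windows 250/150,
$L = 4$, tuned $c$, 10,000 benchmark sequences). Per-participant seeds
are derived deterministically from the master seed, the manifest records
them together with the model fingerprint, and reruns of the same
configuration are bit-identical.

## 9. Problem sizes and limitations

The test suite exercises the estimators at the study scales — sessions of
1000 trials, windows of 250, candidate height $L = 4$, cohorts of up to
25 agents, benchmarks of up to 10,000 × 250 trials, 100-seed recovery and
500-replicate calibration experiments — all within a default
`devtools::test()` run of about a minute.

Known limitations:

* Models 1, 2 and 4 of the registry are reconstructions (Section 1);
  conclusions that depend on their exact probabilities should use
  externally supplied model files.
* The exhaustive oracle is restricted to $L \le 2$, $|A| \le 3$; beyond
  that only the recursion (whose correctness is established at small
  sizes) is available.
* The estimator assumes the response depends on the stimulus past only;
  the independence test is the diagnostic for that assumption, not a
  repair.
* Agents do not learn within a session; modeling learning dynamics is
  out of scope.
* The chi-squared reference for the independence test is asymptotic;
  for short windows with many strata ($k, k' > 1$) an exact or
  permutation reference would be preferable and is not provided.
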