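---
title: "Graphical directed information: model, estimator, and design choices"
author: "gdinfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphical directed information: model, estimator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Given simultaneous recordings from $R$ nodes of a neural network — binned
spike trains or continuous voltage-like signals — we want a *directed,
signed* graph of functional connectivity in which an edge $j \to k$ means
that node $j$'s past carries information about node $k$'s present *that no
other node's past carries*. Pairwise measures cannot deliver the italicised
part: a chain $6 \to 1 \to 4$ produces an apparent pairwise link
$6 \to 4$, parallel paths produce spurious shortcuts, and a node driven by
several inputs ("sink") has each single input diluted by the others.

## Model

### Directed information

For processes $\mathbf{X}$ and $\mathbf{Y}$ with memory $M$ samples,
directed information (DI) is the conditional mutual information

$$ I(\mathbf{X} \to \mathbf{Y}) \;=\; I(X_{i-M..i-1};\, Y_i \mid Y_{i-M..i-1}), $$

the information the source's past carries about the target's present beyond
the target's own past. It is model-free: no linearity or Gaussianity is
assumed. *Graphical* directed information (GDI) additionally conditions on
the pasts of all remaining nodes,

$$ I_G(X^{(j)} \to X^{(k)}) \;=\; I\!\left(X^{(j)}_{past};\, X^{(k)}_i \mid
   X^{(k)}_{past},\, X^{(*)}_{past}\right), $$

so that edges express conditional dependence: proxy and extended-path links
vanish, and sink edges *grow* (removing co-inputs from the noise raises the
effective signal-to-noise ratio of each remaining input). The signed graph
carries weights $w^{(j,k)} = S^{(j,k)} \times I_G$, with the sign from the
partial-correlation method below.

### Classifier-based estimation

Every CMI above is a difference of two mutual informations, and each MI is
a KL divergence between the joint distribution $p$ of windowed samples and
the product surrogate $q$ obtained by permuting one block. We estimate the
KL via its Donsker–Varadhan representation: the optimal witness function is
the pointwise log-likelihood ratio, which a probabilistic binary classifier
estimates directly. Concretely, non-overlapping windows of length $M+1$
yield samples; a multi-layer perceptron is trained with binary
cross-entropy to separate joint samples (label 1) from block-permuted
samples (label 0); its predicted probabilities give
$L(x) = \hat P(\ell = 1 \mid x)/(1 - \hat P(\ell = 1 \mid x))$ and

$$ \widehat{D}_{KL}(p \| q) \;=\; \frac{1}{N_p}\sum_n \log L(x_{n,p})
   \;-\; \log \frac{1}{N_q}\sum_m L(x_{m,q}). $$

Each *bootstrap iteration* draws a fresh 2/3–1/3 train/test split and a
fresh permutation; iteration values are averaged. Both MI terms of a CMI
share the iteration seeds so correlated estimation bias cancels in the
difference.

### Which block to permute

The CMI $I(A; B \mid Z)$ can be written either as
$I(A; [B, Z]) - I(A; Z)$ or, by the chain rule on the other argument, as
$I(B; [A, Z]) - I(B; Z)$. Both are the same quantity, but they pose very
different estimation problems. In a densely connected network the source's
past $A$ can share more than a nat of information with the wide
conditioning block $Z$, putting both MI terms in a high-divergence regime
where the plug-in above is strongly downward-biased (the classifier cannot
represent a very large likelihood ratio from a few thousand samples, and
the bias grows with the magnitude of the term, so it does **not** cancel in
the difference). `estimate_cmi` therefore permutes the *lower-dimensional*
of the two blocks — for DI/GDI the one-sample target current value — which
bounds both terms by that variable's own information content (typically
well under one nat). In controlled experiments on the linear-Gaussian
benchmark network this reduced worst-case on-edge errors from roughly
−40..−60% to −5..−25% at $2\times 10^4$ samples, with no change at all to
the estimand.

### Classifier and training

The ratio model is a deliberately small MLP: one hidden layer of 16 ReLU
units by default, trained with mini-batch Adam (batch 512, learning rate
0.01, L2 penalty $10^{-4}$) on standardised features, with early stopping:
a fifth of the training rows are held out, and the weights of the
best-validation-loss epoch are kept (patience 10, at most 100 epochs).
Larger networks trained to convergence *look* better in-sample but
overfit the permuted class, which inflates the $\log \frac1{N_q}\sum L$
term and can collapse the DV estimate; the combination of a small
architecture, weight decay and validation-based stopping was the most
stable configuration across the continuous, discrete and high-dimensional
benchmark problems, and is roughly an order of magnitude faster than a
2×64 network. All widths and optimisation settings are exposed through
`classifier_spec()`. Predicted probabilities are clipped into
$[10^{-3}, 1 - 10^{-3}]$ so the plug-in stays finite on separable data;
with 1/3 of a few thousand windows as test points, ratios beyond $10^3$
cannot be resolved anyway, so the clip costs nothing in practice. We also
evaluated appending squared or bilinear interaction features to the
classifier input: squares help precisely one benchmark (detecting
zero-straddling quadratic couplings in the nonlinear network) but
measurably hurt the linear and low-dimensional cases, so the default input
is the raw embedding.

Negative MI/CMI estimates are reported as-is by the estimator layer —
they are informative about estimator noise — and floored at zero only in
graph weights (`floor_negative`, default on).

## Sign inference

Information measures are sign-blind, so edges are labelled excitatory or
inhibitory with time-lagged correlation machinery. The time-lagged
correlation (TLC) is the Pearson coefficient between $x_i$ and
$y_{i-\tau}$; a future-directed effect with delay $s$ appears at
$\tau = -s$. The time-lagged *partial* correlation (TLPC) first
residualises both series on the other channels at lag 0 and correlates the
residuals; this is algebraically identical to the classic
one-variable-at-a-time elimination recursion (both are implemented;
`tlpc()` uses least-squares residualisation, `tlpc_recursive()` is kept as
a cross-check and the two agree to machine precision on a common aligned
sample). The edge sign is the sign of the TLPC at the negative lag
maximising its absolute value (`infer_sign()`), with ties broken toward
lag 0 and the default scan window $[-5M, -1]$ samples.

The three-node demonstrations (`gen_three_node_demo()`) encode the case
that motivates the partial approach: $W$ excites $Y$ and $X$ inhibits $Y$
with equal 0.125 s delays, while $X$ is strongly correlated with $W$. The
inhibition is visible only through a brief per-cycle dip in $X$
(continuous) or intermittent dropout of $X$ (spiking); TLC labels
$X \to Y$ excitatory, TLPC recovers the inhibition. Removing the
dip/dropout (arguments `dip`, `dropout`) produces the documented degenerate
mode in which no method can identify the inhibition — the signal simply is
not in the data. Both TLC and TLPC are linear methods: on the nonlinear
benchmark network they misclassify one edge whose coupling is an even
function of a zero-straddling input, and this failure is expected and
asserted (at most one error) rather than patched.

## Spike data

Spike-time tables are binned into binary series (`bin_spike_trains()`):
half-open bins $[t, t + w)$, a spike exactly on an edge belongs to the
later bin, multiple spikes clip to 1. For binary data, DI/GDI values are
normalized by the target's plug-in conditional entropy
$H(Y_i \mid Y_{i-M..i-1})$ (estimated from all sliding positions), which
expresses incoming information relative to the target's own information
and maps values into $[0, 1]$. The exact normalization of the prior
literature is not reproduced in full anywhere we could verify, so this
conditional-entropy denominator is an interpretive choice: it is the
natural "information content of the target" and upper-bounds achievable
DI. Normalization is applied only in binary mode; continuous-mode values
are reported in nats.

With modest sample sizes the package can restrict each edge's conditioning
set to channels whose incoming normalized DI to the target reaches a
threshold $\theta$ (default 0.01, `conditioning_policy = "di-thresholded"`),
keeping the dimensionality of each conditional problem low; the threshold
is interpreted on incoming influence $r \to k$ because incoming links are
what can confound an edge into $k$. For bin-width robustness,
`average_over_bin_widths()` repeats the whole analysis over a sweep of
widths (e.g. 15–40 ms in 5 ms steps), thresholds each width's normalized
values at $\theta$, averages magnitudes across widths, and takes the sign
of the mean of per-width signs over widths with non-zero estimates; an
exactly tied vote leaves the sign undetermined (`NA`) and the weight
unsigned.

## Synthetic benchmarks and oracles

`default_network_spec()` ships the 11-node ground truth used throughout:
extended path $6 \to 1 \to 4 \to 11$, sink $\{6, 8, 9\} \to 2$, multipath
$6 \to \{3,5\} \to 10$, node 7 isolated; path/multipath couplings
$|\beta| = 0.45$, sink couplings $|\beta| = 0.25$, $\sum_j |\beta^{(j,k)}|
+ \alpha^{(k)} = 1$ per node, edges $6 \to 1$ and $5 \to 10$ inhibitory.
The linear-Gaussian simulator uses standard normal innovations; the
nonlinear variant draws source nodes from Uniform(0, 1), couples targets to
the *square* of parent past values, and uses noise variance 0.25 so the
noise does not swamp the small squared inputs.

For the linear network the analytic edge values are available in closed
form and are exact for this generator: source-driven edges
$\tfrac12\ln(1 + \beta^2/\alpha_k^2)$, pairwise DI into multi-input nodes
$\tfrac12\ln(1 + \beta^2/(\alpha_k^2 + \sum_l \beta_{l,k}^2))$, and
second-hop GDI $\tfrac12\ln(1 + \beta^2\alpha_j^2/\alpha_k^2)$ (the
conditioning explains all of the parent's past except its own innovation).
One caveat is documented in `analytic_network_di()`: the multi-input
pairwise form treats parent processes as independent unit-variance inputs,
which holds exactly for the sink (whose parents are white sources) but is
an approximation for node 10, whose parents share driver 6. The GDI
formulas carry no such caveat. An exact discrete enumeration oracle
(`discrete_mi()`/`discrete_cmi()`, plug-in over frequency tables) is the
independent reference for all binary benchmarks, and
`analytic_bsc_di()`/`analytic_pair_di()` cover the two-node scaling models.

The spiking surrogate (`gen_spiking_network()`) replaces conductance-based
simulation with logistic-Bernoulli dynamics: each unit's per-bin spike
probability is $\mathrm{logit}^{-1}(b_0 + \text{gain}\sum_j \beta^{(j,k)}
s_j(i - \text{lag}))$. Defaults ($b_0 = -1.4$, gain 12, 35 ms bins) give
baseline rates near 0.2 spikes/bin (≈ 6 Hz) and synapses strong enough
that a presynaptic spike moves the postsynaptic probability across most of
its range — an operating point at which inhibitory edges onto the sparse
baseline remain informative and chains genuinely propagate activity, so
indirect pairwise links exist for conditioning to remove. This surrogate
reproduces the *statistical* phenomena (indirect-link suppression,
sink enhancement, sign recovery); it does not emulate conductance dynamics,
bursting, or rheobase-calibrated synaptic strengths, so quantitative
agreement with biophysical simulators is out of scope.

## Problem sizes used by the test suite

The reproduction suite runs every benchmark at desk scale, chosen so the
full suite completes on a single CPU while leaving each effect clearly
resolvable: the two-node scaling models use $N = 2500$ windows with 10
bootstrap iterations and 10 replicate seeds; the network recoveries use
$N = 2\times10^4$ samples ($M = 3$, hence 5000 windows) with $B = 20$; the
spiking surrogate uses 300 s at 35 ms bins with $B = 5$ and thresholded
conditioning; the discrete-oracle equivalence check uses $5\times10^4$
samples. The reference study scale (e.g. $10^5$ samples, $B \ge 100$)
tightens every estimate further but changes no conclusion of the checks.

## Numerical choices and degenerate inputs

* Windows are anchored at the first sample; a trailing remainder shorter
  than $M+1$ is discarded. Fewer than 2 windows is an error, fewer than 50
  a warning.
* One fresh permutation per bootstrap iteration (not one global
  permutation), reducing permutation-specific bias.
* Per-edge and per-iteration seeds are derived from the master seed by a
  Lehmer-style mix, so results are independent of evaluation order and
  safely below $2^{31}$.
* Constant channels make correlations undefined: `tlc`/`tlpc` raise an
  error, `infer_sign` skips such lags and returns `NA` if none remain;
  a constant binary target makes the normalization denominator zero and
  `normalize_di` errors.
* Normalized values outside $[0, 1]$ (estimator noise) are clipped with a
  warning.
* Collinear conditioning channels raise a rank-deficiency error rather
  than silently dropping directions.

## What the synthetic benchmarks do and do not show

The generators emulate the statistical structure the estimator must
resolve — directed lagged couplings, nonlinearity, binary sparseness,
masking of signs — under exactly known ground truth. They do not emulate
nonstationarity, measurement noise correlated across channels, volume
conduction, latent unrecorded confounders, or pattern-generating circuits
whose nodes are nearly interchangeable; on such data GDI inherits the
known failure modes of partial measures (unique information between
near-duplicate drivers approaches zero). Passing the suite therefore
validates the estimator and its implementation, not the fidelity of any
particular biological interpretation.

## Known limitations

* Edge significance is by threshold or rank only; principled data-driven
  edge selection is an open problem and out of scope.
* Sign inference is linear; even (sign-symmetric) couplings can defeat it.
* The DV plug-in estimator saturates for very large divergences; values
  beyond ~2 nats at a few thousand windows should be read as "large", not
  as calibrated magnitudes.
* Estimates carry a small negative bias that shrinks with sample size;
  comparisons across edges (ranking) are more reliable than absolute
  values at small $N$.
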