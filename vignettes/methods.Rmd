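---
title: "Methods: hierarchical Dirichlet process clustering of count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical Dirichlet process clustering of count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

countHDP models a matrix of digital gene expression counts `y[i, j]`
(gene i, sequencing library j) as negative binomial,

    y[i, j] ~ NB(m[i, j], phi[i]),   Var = m + phi * m^2,
    log m[i, j] = log(c[j]) + log(mu[i]) + beta[i, lambda(j)],

where `c[j]` is a known per-library normalisation factor, `mu[i]` the mean
expression level of gene i, `phi[i]` its dispersion, and
`beta[i, l]` the log-fold-change of gene i in sample group
`l = lambda(j)`.  A fold-change of 0 means no change; `phi = 0` is the
Poisson limit and is always evaluated on an explicit Poisson branch.

The fold-changes carry a two-level Dirichlet process prior:

    H       =  Normal(mu_beta, sigma2_beta)
    G0 | delta, H        ~ DP(delta, H)
    G_l | gamma_l, G0    ~ DP(gamma_l, G0)
    beta[i, l] | G_l     ~ G_l

Draws from a DP are discrete, so fold-changes are *shared*: within a group
(genes clustered by fold-change) and, because every `G_l` has the common
discrete base `G0`, across groups.  Writing `z[i, l]` for the index of the
atom that `beta[i, l]` takes, two fold-changes are equal exactly when
their indicators coincide.  Differential expression between groups A and B
is then simply the event `z[i, A] != z[i, B]`, and its posterior
probability is estimated without any gene-level test or multiplicity
correction.

The remaining gene parameters have conventional priors:
`log(phi[i]) ~ Normal(mu_phi, sigma2_phi)` and
`mu[i] = (1 - p[i]) / (p[i] * phi[i])` with `p[i] ~ Beta(0.5, 0.5)` —
`p[i]` is the success probability of the NB in its size/probability
parameterisation, which gives the mean a conditionally near-conjugate
update.  All four hyperparameters, the group concentrations `gamma_l` and
the global concentration `delta` are sampled too.

### Identifiability

`mu[i]` and a constant shift of all its `beta`s are confounded: the
likelihood only identifies per-gene *differences* of fold-changes across
groups.  No constraint pins the fold-change scale (no atom is forced to
zero).  This is deliberate: every reported quantity (posterior
co-clustering probabilities, similarity matrices, consensus clusters)
depends only on equality patterns of indicators, which are invariant to
the confounded scale.  Per-gene `mu` estimates are correspondingly *not*
interpretable in absolute terms and are not reported.

## Inference: truncated blocked Gibbs sampler

The sampler uses a finite two-layer stick-breaking representation.  A
shared dictionary of `K` atoms (default `trunc = 100`) carries the
fold-change values:

* global weights `w ~ Dirichlet(delta/K, ..., delta/K)` over the
  dictionary (`G0`);
* per group `l`, `T = K` group-level clusters ("tables") with weights
  `tw_l ~ Dirichlet(gamma_l/T, ..., gamma_l/T)` and table-to-atom maps
  `c[l, t] ~ Categorical(w)` (`G_l`);
* a gene's indicator is `z[i, l] = c[l, t[i, l]]` with
  `t[i, l] ~ Categorical(tw_l)`;
* atoms `beta'_k ~ H`.

As `K` grows this converges to the hierarchical stick-breaking
construction.  The two-layer form is essential for mixing, not just
faithfulness: re-sampling a map `c[l, t]` moves an *entire group cluster*
to another global atom in one blocked draw.  A collapsed one-layer scheme
(group weights `~ Dirichlet(gamma_l * w)` directly over atoms) was tried
first and is label-degenerate in practice — the two conditions' bulk
populations can settle on different but numerically equal atoms, and no
per-gene move can re-align them; every gene is then spuriously "DE".
Because the approximation is symmetric, atoms are exchangeable and there
is no ordered "last stick"; the analogue of occupying the last stick is a
*saturated dictionary*, and `run_chain()` warns if a post-burn-in sweep
occupies all `K` atoms.  (The first sweeps start from uniform weights and
transiently scatter indicators over the dictionary, so pre-burn-in
saturation is a start-up artifact and is ignored.)  In practice the
occupied count settles one to two orders of magnitude below `K`.

One sweep performs, in order:

1. **Indicators** — every `t[i, l]` is drawn from its exact categorical
   conditional `p(t) proportional to tw_l[t] * prod_{j in l} NB(y[i, j] |
   c_j mu_i e^{beta'_{c[l,t]}}, phi_i)`, all cells simultaneously from the
   same pre-update weights, maps and atoms (blocked, order-free,
   vectorised; the N x K x L likelihood is computed in C++ while all
   random numbers come from R's stream, keeping runs reproducible).
2. **Weights and maps** — every occupied table is re-mapped by the blocked
   categorical `p(c[l, t] = k) proportional to w_k * prod_{i in table t}
   lik(i, l, k)`; unoccupied tables are prior draws from
   `Categorical(w)`.  Then `tw_l ~ Dirichlet(gamma_l/T + table
   occupancies)` and `w ~ Dirichlet(delta/K + atom-usage counts of the
   occupied tables)`.
3. **Atoms** — occupied atoms take a Gaussian random-walk Metropolis step
   against prior x likelihood of their assigned observations; unoccupied
   atoms are refreshed from `H`.
4. **Gene parameters** — `log phi_i` by random-walk Metropolis (the mean
   level moves with `phi` at fixed `p`); `p_i` by an independence
   Metropolis step whose proposal is the conjugate
   `Beta(0.5 + M/phi_i, 0.5 + sum_j y_ij)`.  When all effective exposures
   `c_j e^{beta}` equal 1 the acceptance ratio is identically 1, i.e. the
   step *is* the exact conjugate draw; otherwise the ratio corrects the
   mismatch.
5. **Hyperparameters** — `(mu_beta, sigma2_beta)` from the
   Normal-Inverse-Gamma conditional given the *occupied* atoms, and
   `(mu_phi, sigma2_phi)` given all `log phi_i`.  Each concentration
   (`gamma_l`, `delta`) takes one Metropolis step on its *exact*
   finite-truncation conditional: with the weights marginalised out the
   occupancy counts follow a Dirichlet-multinomial, so the log target is
   available in closed form under the `Gamma(1, 1)` hyperprior.  (The
   classic Escobar-West auxiliary draw targets the infinite-DP marginal
   and is measurably biased at finite truncation — a joint-distribution
   check caught this.)  Conditioning on occupied atoms only, and
   marginalising the weights out of the concentration step, are valid as
   partially collapsed moves because the unoccupied atoms and the weights
   are immediately re-drawn under the *new* hyperparameter values at the
   end of this update — nothing ever consumes a stale draw.

### Numerical and tuning choices

* Proposal scales (one per atom, one per gene dispersion) adapt by a
  Robbins-Monro rule toward 30% acceptance during burn-in only, then
  freeze — adaptation inside burn-in does not disturb the stationary
  distribution of the retained samples.  Per-block scales matter: an atom
  carrying two thousand genes needs steps two orders of magnitude smaller
  than a five-gene atom.
* NIG hyperprior `m0 = 0, k0 = 0.01, a0 = 2, b0 = 2` (weakly informative;
  the source material is silent).  Concentration hyperpriors
  `Gamma(1, 1)`.
* Method-of-moments initialisation: dispersions from per-gene
  mean/variance of normalised counts floored at `1e-3`, `p` by inverting
  the mean reparameterisation, all indicators in one atom, uniform
  weights.  Genes with zero total count are a hard error
  (`drop_zero_rows()` mirrors the usual row filtering).
* Default run protocol: 10,000 sweeps, 5,000 burn-in, no thinning.
* A single root seed drives every draw; chains, chain stores and all
  result tables are byte-reproducible.  Interrupted stored runs resume
  from a checkpoint.

## Differential expression without P values

With stored post-burn-in samples `z^(1), ..., z^(T)`:

* `pi_i = (1/T) sum_t 1(z_iA = z_iB)` — the posterior probability that
  gene i is *not* DE between groups A and B (`compute_pi()`).
* The *conditional FDR* of the inclusive discovery set
  `D(pt) = {i : pi_i <= pt}` is `FDR(pt) = sum_{D} pi_i / |D|`
  (`fdr_at()`, `fdr_curve()`): the mean posterior probability that a
  discovery is false.  By construction `FDR(pt) <= pt`.
* `select_threshold()` sweeps the observed `pi` values (the FDR is a step
  function, so these are the only candidates) and returns the largest
  threshold whose FDR stays at or below the target; ties at the threshold
  are all included; an empty set has *undefined* (NA) FDR.  Multi-group
  data is handled per group pair.

Two posterior similarity matrices summarise the clustering:
`gene_similarity()` (fraction of (sample, group) slots in which two genes
co-cluster) feeds average-linkage consensus clustering of `1 - s` cut at
0.5, the cut that optimises the expectation of Binder's loss; and
`group_similarity()` (mean `pi` per group pair) feeds average-linkage
clustering under the Euclidean metric for group dendrograms
(`cluster_groups()`, exported as Newick).  With a cut at exactly 0.5,
classes of genes that share their fold-change atom in half of two groups
sit at the boundary; estimated similarities break the tie, which is why
consensus results on borderline structures should be read together with
the similarity matrix itself.

## The synthetic benchmark generator

`generate_dataset()` emulates the published benchmark protocol: two
conditions, negative binomial counts, a stated fraction of DE genes
(0/10/30%), optionally 50% Poisson (zero-dispersion) genes, and outliers
made by multiplying each cell independently with probability 5% by a
continuous Uniform(5, 10) factor (then rounding).  The original protocol
drew (mean, dispersion) pairs from empirical pools estimated from real
experiments, which are not reproducible offline; the generator substitutes
parametric stand-ins with realistic bulk RNA-seq shape:

* baseline means log-normal, `meanlog = 4`, `sdlog = 1.5`
  (median ~ 55 counts, long right tail);
* dispersion trend `phi = 3/m + 0.1` with mean-one log-normal scatter of
  `sdlog = 0.25` — the `a/m + b` shape of the usual dispersion-mean
  trends, asymptoting at biological CV^2 ~ 0.1;
* `|log2 FC| = 1.5 + Exponential(1)`, sign equiprobable, applied to
  condition 2.

All parameters are user-overridable; seeds make datasets exactly
regenerable.  What a green benchmark test establishes is therefore
performance on *this stated world* — NB counts with a smooth
dispersion-mean trend and symmetric, fairly large effects — not on any
particular real dataset: real data add unmodelled features (correlated
genes, batch effects, zero inflation, asymmetric DE) that the generator
deliberately omits.

`generate_from_model()` forward-simulates the hierarchical model itself
(truncated sticks for the global and group measures, indicators, gene
parameters, counts) and records the true indicator matrix; `fixed_atoms` /
`fixed_z` allow a controlled number of fold-change clusters for recovery
tests.  Because only fold-change *differences* are identifiable, a
recoverable truth must separate classes by their between-group
differences.

Recovery tests built on `generate_from_model()` additionally fix the
normalisation factors at their true value (1): median-of-ratios is a
large-sample estimator, and on a few hundred low-count genes with strongly
one-sided effects its between-group bias is absorbed by the model into the
fold-changes, which would test the normalisation scheme rather than the
sampler.  They also draw `p` from `Beta(1, 10)` so the simulated genes are
expressed at informative levels; under the model's own `Beta(0.5, 0.5)`
most genes have single-digit counts at which cluster membership is simply
not identifiable from `N = 200` genes.

Evaluation helpers: `roc_auc()` (Mann-Whitney with ties counted one half),
`fd_curve()` (false positives among the top-k ranked genes, stable tie
order), `realized_fdr()` (NA for empty discovery sets, mirroring the
published convention), `adjusted_rand_index()`.

## Scaling of the shipped checks

The package's acceptance checks run the full pipeline at a desk scale
(2,000 genes, 3,000 sweeps with 1,500 burn-in, 3 seeds) rather than the
published scale (10,000 genes, 10,000 sweeps): identical protocol, an
order of magnitude cheaper.  The discrimination (AUC) target transfers
essentially unchanged; false-discovery-rate calibration is the quantity
most sensitive to chain length and gene count, which is why the FDR check
uses the median over seeds.

## Known limitations

* The truncation is a shared-dictionary finite approximation, not exact
  stick-breaking; `trunc` must comfortably exceed the occupied-cluster
  count (watch the saturation warning).
* `pi` estimates are step functions with resolution `1/T`; very small
  target FDRs need correspondingly long chains.
* Per-gene `mu` (and any single `beta`) are not identifiable — only
  fold-change differences are.
* The p-step proposal is exact only at unit effective exposures; far from
  that regime it is a corrected independence proposal, whose acceptance
  can drop for genes with extreme fold-changes.
* No modelling of within-group structure (batch, pairing) beyond the
  group label; no zero inflation.
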