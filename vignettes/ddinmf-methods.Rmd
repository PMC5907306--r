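---
title: "Signed DDI prediction by semi-NMF: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed DDI prediction by semi-NMF: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddinmf)
```

## The problem and the model

A set of known drug–drug interactions (DDIs) is a signed network: the
symmetric adjacency matrix $A \in \{-1,0,+1\}^{m\times m}$ records an
enhancive interaction ($+1$, the drugs increase each other's
pharmaceutical behaviour), a degressive one ($-1$), or none ($0$).
Collapsing signs, $A_b = |A|$, gives the conventional binary DDI network.
Each drug additionally carries a binary descriptor vector (fingerprint
bits, side-effect flags), stacked as $F \in \{0,1\}^{m\times p}$.

The prediction target is the **cold start**: score the possible
interactions of a *new* drug — one with no known interactions, hence no
usable topology — against the $m$ known drugs, using only its features.

Training proceeds in two phases:

1. **Factorization.** $A \approx W H$ with latent dimension $r$. For the
   binary network, classical NMF ($W, H \ge 0$, Lee–Seung multiplicative
   updates). For the signed network, semi-NMF: $W$ mixed-sign, $H \ge 0$,
   alternating an exact least-squares step $W \leftarrow A H^{\dagger}$
   ($H^\dagger$ the Moore–Penrose pseudo-inverse) with the elementwise
   multiplicative update
   $$H \leftarrow H \odot \sqrt{
     \frac{(W^\top A)^{\mathrm{pos}} + (W^\top W)^{\mathrm{neg}} H}
          {(W^\top A)^{\mathrm{neg}} + (W^\top W)^{\mathrm{pos}} H}},$$
   where $M^{\mathrm{pos}} = (|M|+M)/2$ and $M^{\mathrm{neg}} = (|M|-M)/2$
   (`split_signs()`). Both algorithms monotonically decrease
   $\lVert A - WH \rVert_F^2$, which the implementation records per
   iteration and the test suite asserts. On an adjacency matrix the columns
   of $W$ behave as latent communities and the columns of $H$ as soft
   memberships, which is why the factors — unlike, say, PCA loadings —
   support the structural analyses below.
2. **Latent regression.** $H^\top = F B$ fitted by SIMPLS partial least
   squares with $k$ latent factors. PLSR is used because descriptor
   columns are strongly collinear; at $k$ equal to the rank of the
   centered predictors SIMPLS reproduces the least-squares fit (a test
   asserts this against a normal-equations oracle).

Prediction maps new-drug features into the latent space,
$H_x^\top = F_x B$, and reconstructs scores $A_x = (W H_x)^\top$. In
comprehensive mode the sign of a score carries the interaction type; the
default decision threshold in `classify_scores()` is $\tau = 0$, i.e. the
sign decides, consistent with enhancive scores concentrating above zero.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `r` | latent communities in $A \approx WH$ | `"auto"` = $\lfloor \operatorname{rank}(A)/2 \rfloor$ | the originating method fixes $r$ at half the numerical rank of the factorized matrix; rank uses the LAPACK-style tolerance $\max(m,n)\,\varepsilon\,\sigma_{\max}$ |
| `k` | SIMPLS latent factors | 20 (package), grid $\{10,\dots,100\}$ | selected by cold-start CV AUROC in the originating protocol; on the bundled synthetic benchmarks small $k$ (10–20) suffices because only a handful of latent directions are feature-predictable |
| `tol`, `max_iter` | factorization stopping | $10^{-6}$ relative change, 500 sweeps | the update rules have no natural stopping rule; relative objective change is scale-free |
| `bandwidth` | kernel variance $\sigma^2$ in $\exp(-\lVert x-y\rVert^2 / 2\sigma^2)$ | 4 | the "variance" of the Gaussian kernel is read as $\sigma^2$; the parameter is exposed so the $\sigma$ reading is one call away |
| `epsilon` | relative eigenvalue cutoff in `estimate_dimension()` | $10^{-6}$ | "components with near-zero eigenvalues" needs a number; relative to $\lambda_{\max}$ so it is scale-free |
| `tau` | classification threshold | 0 | sign decides enhancive vs degressive |

Numerical safeguards: every multiplicative-update denominator gets
$\varepsilon = 10^{-9}$ (avoids $0/0$ without moving fixed points
materially); pseudo-inverses truncate singular values below
$\sqrt{\varepsilon_{\mathrm{mach}}}\,\sigma_{\max}$.

## Initialization

The update rules converge to local optima, so initialization matters and
is seeded for reproducibility. NMF starts from i.i.d. Uniform(0,1) factors
scaled by $\sqrt{\bar A / r}$ so the initial product matches the data
scale. Semi-NMF defaults to the k-means scheme of the originating
semi-NMF literature: cluster the columns of $A$ into $r$ groups, set $H$
to the 0/1 indicator plus 0.2, $W = A H^\dagger$; a `"random"` fallback
( $|N(0,1)|$ for $H$ ) is used when k-means is infeasible (e.g. fewer
distinct columns than clusters) and in the repeat-run stability tests,
which accept final objectives within 20% across seeds — a tolerance
reflecting genuinely different local optima, not numerical noise.

## Evaluation design

Cold-start K-fold CV removes $1/K$ of the drugs per fold; the model trains
on the remaining drugs' pairwise submatrix and scores **test × train
pairs only**. Test × test pairs are excluded — both endpoints would be
cold, a different and harder task. A mocking-based test verifies no
held-out drug ever reaches training and no test × test pair is scored.

AUROC uses midrank tie handling (Mann–Whitney form); AUPR uses stepwise
average precision with tied scores processed as blocks, so neither metric
depends on the internal order of equal scores. For signed predictions,
enhancive and degressive pairs are both labelled positive and degressive
scores are negated before comparison with the non-interaction scores.
Non-interaction scores enter untransformed by default (`"raw"`); an
`"abs"` option instead folds them, treating a strongly negative score on
a non-pair as a confident (wrong) degressive call — the choice is exposed
because the literal protocol leaves this case open, and `"raw"` follows
its text.

Kernel-PCA feature reduction, when enabled in CV, is refit inside each
training fold by default so held-out drugs never influence the feature
map; a global pre-fit is possible by reducing `F` before calling
`run_cv()`, mimicking protocols that reduce once on the full matrix (at
the cost of a mild information leak).

## What the synthetic generator emulates — and what it does not

`generate_signed_network()` plants $c$ near-equal communities
(within/between edge probabilities `p_in`/`p_out`), gives each community a
polarity, signs each edge with the product of its endpoint polarities and
flips signs with probability `sign_noise`. Product signs make every
triangle's negative-edge count even, so at zero noise the network is
*provably* perfectly balanced (no unbalanced, no weakly balanced
triangles) — a generator property the tests exploit as ground truth. At
the default 5% noise roughly 90% of triangles remain balanced, matching
what curated DDI networks show. Features are block-structured: each
community owns `feature_signal` characteristic bits, flipped with
probability `feature_flip`, plus sparse background noise bits (density
0.1, fingerprint-like).

**Polarity is community-level.** The generator gives
`round(c * polarity_fraction)` communities negative polarity rather than
sampling drug-level polarities i.i.d. Features carry community information
only, so drug-level polarity would make edge signs unlearnable for a
cold-start drug, and the comprehensive pipeline would be untestable end to
end; community sizes are near-equal, so the drug-level negative fraction
still tracks `polarity_fraction`. Consequences: degressive edges
concentrate on cross-community pairs (plus flipped within-community
edges), and drugs in positive-polarity communities have
`pos_degree >= neg_degree` in expectation.

The defaults (`"default"` preset: $m=200$, $c=4$, `p_in` 0.3, `p_out`
0.02, `polarity_fraction` 0.25, `sign_noise` 0.05, 300 features, 40
signal bits per community, 5% bit flips) state a fixed benchmark world.
What the generator does **not** emulate: heavy-tailed degree
distributions, per-drug interaction propensities, overlapping
communities, or any coupling between a drug's features and its individual
edges beyond community membership. A green planted-recovery test
therefore establishes that the pipeline extracts the community and
polarity structure the features can expose — not that it would reach any
particular performance on curated pharmacological data.

That last limitation has a quantifiable consequence. Because features
identify only a drug's community, the Bayes-optimal cold-start score for
a test×train pair is a function of whether the pair is within-community.
For the default preset the closed-form Mann–Whitney value of that oracle
is
$q = 49/199$, $P(\text{within}\mid\text{edge}) = 0.830$,
$P(\text{within}\mid\text{non-edge}) = 0.189$, giving AUROC
$\approx 0.821$ (confirmed empirically at $0.8207 \pm 0.0033$ over ten
seeds). The package's binary-mode CV reaches 0.820–0.824 — the ceiling —
and the acceptance suite's stricter 0.85 bound for this world is
accordingly left failing rather than relaxed or silently skipped; the
comprehensive-mode bound (0.75) and the comprehensive-below-binary
ordering are met.

## Degenerate inputs and tie-breaks

- `read_signed_edge_list()`: conflicting duplicate pairs error in strict
  mode; otherwise first occurrence wins with a warning (curated sources
  do occasionally label a pair both ways; no claim is made about how the
  original datasets resolved this). Self-loops and malformed signs always
  error.
- All-zero matrices: rejected by semi-NMF (degenerate pseudo-inverse);
  accepted by NMF (fixed point at zero).
- `r` must satisfy $1 \le r < \min(m,n)$; non-integer rank/2 floors.
- Kernel-PCA components with numerically zero eigenvalues are dropped
  with a warning (double-centering always zeroes at least one).
- Zero new drugs predict an empty $0 \times m$ matrix rather than
  erroring, so callers can batch freely.

## Known limitations

- Factorizations converge to local optima; different seeds give different
  factors (the package seeds everything and documents the 20% objective
  spread across restarts).
- Transductive prediction among *known* drugs (matrix completion) is out
  of scope; the pipeline is strictly new-drug cold start.
- The triangle census is an $O(m^3)$ matrix-product computation — fine to
  a few thousand drugs, not for large pharmacovigilance graphs.
- Dense matrices throughout; intended scale is $m$ up to a few thousand.
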