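---
title: "Methods: pattern-filtered coevolutionary contact prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pattern-filtered coevolutionary contact prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Direct coupling analysis (DCA) infers residue–residue coevolutionary
couplings from a joint multiple sequence alignment of two interacting
protein domains and compresses each pair $(i, j)$ — $i$ in domain A, $j$ in
domain B — into a single score $F_{ij}$. Large scores are enriched in true
inter-domain contacts, but the enrichment degrades quickly with alignment
depth: below an effective sequence number $M_\mathrm{eff}$ of a few hundred,
the score distributions of contacts and non-contacts overlap heavily and a
per-pair ranking wastes most of its predictions on noise.

Contact maps, however, are not random. Secondary structure imprints strong
local patterns: a helix–helix interface repeats with the helical turn (one
contact-carrying face every ~3.6 residues), and strand–strand interfaces
form diagonal (parallel) or anti-diagonal (anti-parallel) lines. The same
patterns appear, attenuated, in the DCA score map around true contacts. This
package scores each pair not only by its own coupling but also by how much
its *neighbourhood* in the score map looks like a typical contact
neighbourhood.

## The model

Two features per residue pair:

$$x_1 = F_{ij}, \qquad
  x_2 = \max_{f \in S} \; \rho\!\left(f,\, D_{ij}\right),$$

where $D_{ij}$ is the $k \times k$ window of DCA scores centred on
$(i, j)$ ($k$ odd), $S$ is a bank of six structural filters, and $\rho$ is
the Pearson correlation **with the central element removed from both**
window and filter — the centre is a contact in every filter by
construction, and its score already enters as $x_1$; keeping it would make
the two features redundant.

The filters are built from truth contact maps of a collection of interfaces
kept disjoint from training and test families: all windows centred on
helix–helix (HH) contacts are pooled, likewise all windows on
strand–strand (EE) contacts, and each pool is clustered with 3-means. The
six centroids (three HH, three EE) are the filters; their entries are local
contact probabilities in $[0, 1]$. The filter score is computed for *all*
pairs, whatever their own secondary structure — pairs in other classes
simply tend to correlate weakly and fall back on $x_1$.

The two features are fused by logistic regression,

$$P(\oplus \mid \mathbf{x}) =
  \frac{e^{\mathbf{w}\cdot\mathbf{x} + w_0}}
       {1 + e^{\mathbf{w}\cdot\mathbf{x} + w_0}},$$

fitted on a family-level 50 % split (never by residue pair — pairs of one
interface are strongly dependent). Before fitting, $x_2$ is min–max scaled
with the training-set extremes,
$x_2 \to (x_2 - \min x_2)/(\max x_2 - \min x_2)$; the same stored bounds
are reused verbatim at prediction time, so test values may leave $[0, 1]$
(no clamping). The classifier itself is invariant under this affine map,
but the $\ell_2$ penalty is not, which is the reason for fixing the scale.

### Training restriction

Contacts are a ~1 % minority among all pairs. Training is restricted to
pairs with $F_{ij} > 0$, which discards the bulk of uninformative negative
couplings and concentrates the fit near the decision boundary. The
restriction applies to *training only*: at prediction time every
represented pair is scored and ranked.

### Border rule

For pairs closer than $(k-1)/2$ to the matrix border the window is
truncated; the correlation is then computed over the positions contained in
both the window and the filter (centre still excluded), falling back to 0
when fewer than two usable positions or a constant vector remain. The same
zero fallback covers degenerate (constant) windows everywhere, so that
ranking degrades gracefully to the raw DCA ranking — this value is the
package's choice; the behaviour of the reference method on constant windows
is unspecified.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 45 (pipeline), odd, 5–69 | filter window size in residues. Small `k` makes the decision essentially DCA-only; accuracy peaks around 45 and decays for larger windows, which average over too-distant, structurally variable regions. |
| contact threshold | 8 Å | minimal heavy-atom distance below which (strictly) a pair is a contact. |
| `l2_strength` | 1.0 | λ in the penalty (λ/2)(w₁² + w₂²) **added to the summed negative log-likelihood** (bias unpenalised). Larger λ = stronger penalty. Duplicating all rows is equivalent to halving λ. |
| split fraction | 0.5 | family-level training share. |
| $M_\mathrm{eff}$ bins | >200 / (50, 200] / (0, 50] | large / medium / small alignment depth; models are trained per bin and refuse (unless forced) to score families from another bin. The inclusive upper bounds make the bins a partition of the positive axis. |
| `n_clusters` | 3 | clusters per secondary-structure class in filter construction. |

## The synthetic world

The generator produces, per family: 3-state secondary-structure strings
(segment lengths H 8–20, E 4–8, O 2–6; a deficit-chasing sampler keeps the
composition near 35 % H / 25 % E / 40 % O), a contact map with planted
interface blocks, and a DCA-like score matrix

$$F_{ij} = s\, c_{ij} B_{ij} + \varepsilon_{ij}, \qquad
  B_{ij} \sim \mathrm{Bernoulli}(p_\mathrm{det}),\;
  \varepsilon_{ij} \sim \mathcal{N}(0, \sigma^2),$$

with defaults $s = 0.3$, $\sigma = 0.1$ — chosen so that, as in real data,
scores above ~0.3 are mostly contacts while the bulk of contacts hides in
the noise. $p_\mathrm{det}$ is the proxy for alignment depth: at
$p_\mathrm{det} \to 0$ the contact and non-contact score distributions
coincide (the shallow-alignment regime); no alignment or Potts-model
machinery is simulated.

**Helix-block periodicity.** Helix–helix blocks carry contacts on a
period-4 lattice (anchored at the helix starts, each cell realised with
probability 0.9). A lattice with mass at *both* ±3 and ±4 offsets — the
real helical turn is ~3.6 — is not shift-invariant: the offset set
$\{0, 3, 4\} \bmod 7$ is not a subgroup, so windows centred on different
contacts of one block would follow nine distinct shifted patterns, and no
single planted motif could be recovered by clustering at a tight tolerance.
The period-4 subgroup $4\mathbb{Z} \times 4\mathbb{Z}$ *is*
shift-invariant: every window of a block follows one template, which makes
"the planted motif" well defined and testable. The qualitative helical
signature — high mass at column offsets {0, ±3, ±4}, low at ±2 — is
preserved (0 and ±4 carry the mass; ±2 sits at background). Strand–strand
blocks are width-1 diagonal or anti-diagonal stripes.

**What a green test does and does not establish.** The synthetic world has
independent per-cell noise, no phylogenetic correlation, no homology
between families, no label ambiguity at the 8 Å threshold, and blocks far
more regular than real interfaces. Green tests establish that the
machinery — window extraction, clustering, correlation scoring, fusion,
ranking, calibration bookkeeping — is correct and that the method exploits
planted local coherence; they do not establish real-data accuracy.

## Numerical choices

* Pearson correlations are computed by one-pass sums over the valid-mask
  intersection; values are clamped to $[-1, 1]$; zero variance on either
  side yields 0.
* k-means uses k-means++ seeding, 10 restarts, Lloyd iterations; the best
  within-cluster sum of squares wins. Within each class, filters are
  ordered by decreasing cluster size (ties by centroid entries), so a bank
  is reproducible bit-for-bit under a fixed seed.
* The logistic fit is a penalised Newton (IRLS) iteration, converged at
  step size $10^{-12}$; it is deterministic — the `seed` argument exists
  only for interface stability.
* Ranking ties are broken by $(-\text{score}, i, j)$; with $w_2 = 0$ and
  $w_1 > 0$ the ranking provably equals the raw DCA ranking (the
  unsupervised baseline is a special case of the model).
* Family-averaged PPV at $n$ averages only families with at least $n$
  scorable pairs (no padding).
* Serialised models and filter banks store doubles at 17 significant
  digits; write–read round trips are bit-exact.

## Known limitations

* The calibration slope of the fused probability on the synthetic
  benchmark is systematically *above* one (~1.3–1.5): under the mixture
  score model the true log-odds is a convex, softplus-like function of the
  features, so the linear logistic is underconfident at the top and
  overconfident near zero. On real, heterogeneous corpora the dominant
  effect is the opposite (mild overfitting, slope slightly below one). The
  calibration curve is still close to linear and strongly increasing, and
  high-probability bins are strongly contact-enriched.
* Filters are built from fully valid (untruncated) windows only; very
  small matrices (smaller than $k$) therefore contribute nothing to filter
  construction, although they are still scored via the border rule.
* Secondary structure is an input (3-state, or 8-state collapsed by the
  standard DSSP rule H,G,I→H; E,B→E; rest→O); the package does not compute
  it from coordinates.
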