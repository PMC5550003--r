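---
title: "Dinucleotide weight tensors: models, inference, and design notes"
author: "dwtmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dinucleotide weight tensors: models, inference, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwtmotif)
```

## The model

A transcription factor binds DNA segments `s` of fixed length `l`. The
position-specific weight matrix (PSWM) assumes the letters at the `l`
positions are independent. The dinucleotide weight tensor (DWT) drops that
assumption while introducing no tunable parameters: it models the joint
distribution of letters as a *mixture over all spanning-tree
factorizations* into pairwise conditionals, with every unknown — the tree
topology and all pairwise letter distributions — marginalized analytically.

The building blocks are Dirichlet-multinomial marginal likelihoods. For an
alignment `S` of `n` sites, a single column with letter counts
$n^i_\alpha$ has marginal probability

$$P(S_i) = \frac{\Gamma(4\lambda)}{\Gamma(n+4\lambda)}
  \prod_\alpha \frac{\Gamma(n^i_\alpha+\lambda)}{\Gamma(\lambda)},$$

and a pair of columns with joint counts $n^{ij}_{\alpha\beta}$ has the
analogous 16-category marginal with pseudocount $\lambda' = \lambda/4$.
The 1:4 ratio is forced: it is the unique choice under which the
dinucleotide prior marginalizes to the mononucleotide prior. We use
Jeffreys' prior $\lambda = 1/2$ by default; results are insensitive for
$0 < \lambda \le 1$, and `lambda` is exposed on every constructor.

The evidence for a dependency between positions `i` and `j` is the Bayes
factor $R_{ij} = P(S_i, S_j) / (P(S_i) P(S_j))$, approximately
$e^{n I_{ij}}$ at large `n` (with $I_{ij}$ the empirical mutual
information). Summing the spanning-tree mixture with edge weights
$R_{ij}$ reduces, by the generalized matrix-tree theorem, to a single
$(l-1)\times(l-1)$ determinant $D(R)$ of a minor of the Laplacian of `R`.
The predictive probability of a new segment is

$$P(s\mid S) = \frac{D(R(s,S))}{D(R(S))}
  \prod_{i=1}^{l} \frac{n^i_{s_i}+\lambda}{n+4\lambda},$$

where $R(s,S)$ is the dependency matrix after adding `s` (with weight 1)
to the pair counts. The PSWM factor times a ratio of determinants: when
the counts carry no dependency evidence the ratio is asymptotically 1 and
the DWT behaves as a PSWM. `predictive_logprob()` evaluates this for any
of the three model kinds, and all three are *exactly* normalized over the
$4^l$ segments (the test suite checks this by exhaustive enumeration up to
`l = 6`).

One exactness caveat worth recording: the reduction of the DWT to the
PSWM is exact only when the per-segment augmentation leaves the
dependency matrix unchanged, which happens for empty counts (`n = 0`) and
for uniform marginals, not for arbitrary outer-product counts. A model
built from a single site, for instance, assigns its own site the exact
Bayesian pair predictive (0.375 at `l = 2`), not the PSWM value (0.25).
Both are exactly normalized; they answer slightly different questions at
very small `n`, and they agree rapidly as `n` grows.

The ADJ variant restricts dependencies to adjacent positions; the chain
`1–2–…–l` is then the unique spanning tree and the predictive factorizes
as a first-order Markov chain of Dirichlet-marginal conditionals. It is
implemented by the same machinery and serves as the comparison point for
the question "are distal dependencies worth modeling?".

## Numerical evaluation of the tree sum

With strong dependencies and hundreds of sites, entries of `R` span
hundreds of orders of magnitude ($\log R_{ij} \approx n I_{ij}$ reaches
several hundred in our fixtures), far beyond what a floating-point
determinant tolerates. Two mechanisms make the evaluation exact in
practice:

* **Uniform rescaling.** Dividing every edge weight by the largest one
  multiplies each spanning-tree weight by the same factor
  $e^{-(l-1)c}$ — every tree has exactly `l − 1` edges — so the
  compensation $(l-1)c$ is exact. This absorbs the overall scale but not
  the spread *within* a matrix.
* **Deletion–contraction of dominant edges.** When the edges within
  ~20 log-units of the maximum do not connect all positions, small edges
  paired with huge ones vanish below machine resolution and naive LU
  produces a zero or negative determinant. We then apply the exact
  identity $D(R) = R_e D(R/e) + D(R-e)$ to the maximum edge `e`
  (contracting it merges its endpoints; parallel edge weights add), and
  recurse. The deletion branch is dropped only when the maximum edge
  exceeds every other edge by 60 log-units, where a tree-swapping
  argument bounds its relative contribution by $l^2 e^{-60}$, far below
  double precision. The base case runs pivoted LU on the rescaled
  Laplacian minor.

`tree_logdet()` is validated against exhaustive Prüfer-sequence
enumeration (`brute_force_tree_sum()`) on hundreds of random matrices
with entries spanning $[-20, 20]$ — 17 orders of magnitude — to a
relative tolerance of $10^{-6}$ (observed error is around $10^{-9}$), and
on constructed extreme cases with entries near $e^{345}$. Degenerate
inputs: `l = 1` motifs bypass the tree algebra entirely; an all `-Inf`
matrix returns $\log D = -\infty$; a numerically non-positive determinant
raises rather than returning garbage.

Edge posteriors $P(i,j)$ — the probability that the factorization
contains a direct dependency between `i` and `j` — are
$R_{ij}\, \partial \log D/\partial R_{ij}$, computed through the
effective-resistance identity on the inverse of the Laplacian minor (one
$O(l^3)$ solve, not finite differences), with the same
deletion–contraction recursion on extreme inputs. They always sum to
`l − 1`.

Per-segment scoring is the hot loop of EM (about $10^5$ determinants per
iteration at our benchmark scale), so the package precomputes a *scan
plan* per model: dominant pairs that exceed every other pair's maximum
possible per-letter weight by the 60 log-unit margin are contracted once
up front, and the remaining graph's Laplacian is assembled per segment
from a lookup table of pre-exponentiated weights at a fixed model-level
scale — contraction becomes plain addition in the linear domain. Segments
whose reduced graph is not dominated-connected fall back to the exact
log-domain recursion. The plan changes the arithmetic path, not the
value; the suite checks plan-path scores against the reference
determinant evaluation.

## Binding energies and the sampling likelihood

The binding energy of a segment (units of kT) is the log-odds
$E(s) = \log P(s\mid M) - \log P(s\mid B)$ against a 0th-order background
`B`, which defaults to the letter frequencies of the input sequences. A
longer sequence is scored on all segments of both strands
($L_S = 2(|S|-l+1)$ of them) and summed on the exponential scale:
$E(S) = \log \sum_{s \in S} e^{E(s)}$.

`N` letters are ratio-neutral: an `N` position contributes 0 to both the
model and background terms, and pair terms involving it keep the training
`R` factor. This keeps `E(s)` a log-odds with the missing positions
marginalized under the background, and it is what makes N-padding of
short reads well defined.

Motif finding maximizes the probability of sampling the observed bound
sequences from a large background pool, where a sequence is sampled in
proportion to its total occupancy $e^{E(S)} + L_S e^{E_0}$ with a
non-specific binding energy $E_0$; the TF concentration cancels. Each EM
iteration: (1) scores all segments under the current model; (2)
re-optimizes $E_0$ as the root of the stationarity condition — because
that condition also decays to zero as $E_0 \to +\infty$, the root finder
scans a 101-point grid on $[-50, 50]$ for genuine sign changes and keeps
the stationary point with the best likelihood, falling back to the better
bracket endpoint when the optimum is at the boundary (common when nearly
every input sequence contains a real site); (3) forms per-segment binding
posteriors $e^{E(s)}/(e^{E(S)} + L_S e^{E_0})$; and (4) replaces the pair
counts with posterior-weighted dinucleotide counts, reverse-strand
segments contributing reverse-complemented letters. Under padding, an `N`
at a site position contributes its posterior times the model's current
marginal predictive (soft imputation), which preserves both mass
conservation and the marginal-consistency invariant of the tensor.

Iteration 0 scores with the initial PSWM alone — equivalent to a DWT with
no dependency evidence — so no initial pair tensor is needed, and the
identical loop fits PSWM, ADJ, and DWT models for like-for-like
comparisons. Convergence is declared at $|\Delta L| < 10^{-6} |L|$ or 200
iterations (both configurable); the best-likelihood state is returned.
Because motif finding can hit poor local optima, `restarts = k` reruns EM
from Dirichlet-perturbed initializations and keeps the best final
likelihood; all perturbations flow from one seed. The likelihood trace is
monitored in the test suite: any decrease beyond $10^{-6}$ fails.

## HT-SELEX likelihoods

Given per-round sequence counts $n_t(S)$ and model energies, the
selection likelihood takes the probability of drawing `S` from the
round-`t` pool to be $\propto f_t(S)\, e^{E(S)}$. Reads are padded with
$\lfloor l/2 \rfloor$ `N`s per side so motifs longer than the reads
remain scorable. Because observed round-to-round enrichment is usually
shallower than the raw energies predict, a selection temperature $\beta$
rescales the energies; the likelihood gain over selection-free resampling,

$$dL(E, \beta) = \sum_{t} N(t+1)\left(\beta \langle E \rangle_{t+1}
  - \log \langle e^{\beta E}\rangle_t\right),$$

is concave in $\beta$ (a cumulant generating function enters negatively)
and is maximized by golden-section search on $[0, 5]$ to $10^{-8}$; the
reported performance number is $dL/N$ per selected sequence. At
$\beta = 1$, $dL$ equals $L - L_0$ from the explicit likelihoods exactly;
the suite asserts this to $10^{-9}$ on every fixture. Sequences appearing
in a round but unseen in the previous one get the pseudo-frequency
$1/(N(t)+U)$ (`U` = distinct sequences across the two rounds) in both
$L$ and $L_0$ — chosen so the pseudo-term cancels from $dL$ and the
$\beta = 1$ identity stays exact — while the normalizing average always
runs over the observed round-`t` pool. The binned-enrichment diagnostic
(`energy_bin_enrichment()`) recovers $\beta$ as the slope of
log-enrichment against energy.

## Benchmarking

Decoys are sampled, per source sequence and at identical length, from a
first-order Markov chain fitted to the pooled dinucleotide frequencies of
the source set: what the benchmark requires is matched composition and
lengths, not exact per-sequence preservation, and chain sampling matches
composition in expectation while remaining seed-exact. An exact per-sequence
dinucleotide-preserving shuffle (random Eulerian walk with last-exit
edges rejection-sampled to form an in-tree) is available via
`method = "shuffle"`.

Precision–recall sweeps all distinct score thresholds with strict
`E(S) > E_c` membership, so tied scores enter and leave the positive set
together. Average precision is the step-wise sum
$\sum_k \Delta \mathrm{recall}_k \times \mathrm{precision}_k$ — not
trapezoidal — so results are bit-reproducible and invariant under
monotone score transformations. The randomized-dependency control
marginalizes a fitted DWT to its PSWM, samples the same number of sites
independently per position, rebuilds a DWT, and reports its edge
posteriors stratified by adjacency: apparent dependencies in the control
measure pure sampling noise.

## Dilogos

`build_dilogo()` assembles: the marginal predictive probabilities; the
full lattice of edge posteriors; a loop-free dependency set chosen
greedily from the highest posterior downward (Kruskal-style, yielding a
spanning forest — below-threshold edges are pruned from *display* only);
and for each selected edge the conditional tables
$P(s_\mathrm{child}\mid s_\mathrm{parent})$, whose rows sum to 1 exactly.
Edges are oriented by rooting each component at its position of maximal
information content and pointing away from the root, so conserved anchor
positions act as parents. The default display threshold is a posterior of
0.5. `render_dilogo()` is a pure function of the spec — identical specs
yield byte-identical SVG — drawing information-scaled letter stacks
(height $2 - H(w^i)$ bits, no small-sample correction), dependency
arrows, the shaded posterior lattice, and per-edge conditional logos with
one row per parent letter.

## Synthetic data: what it emulates, and what it does not

The generators produce the study conditions for every quantitative check
in the package. `planted_model()`/`sample_sites()` draw sites by
ancestral sampling down a dependency forest; `embed_in_background()`
plants each site at a uniform offset and strand inside background
sequences of chosen composition (peaks of 100–300 bp are typical of
ChIP-seq, we use 200 bp); `simulate_selex()` runs multinomial tempered
selection over rounds. All generators are seed-exact.

The standard `fixture_suite()` holds four l = 10 motifs: independent
(`null`), one distal coupling (`one_edge`, 2–9), two couplings
(`two_edge`, distal 2–9 plus adjacent 3–4), and a five-position chain. In
the coupled fixtures the coupled positions carry *uniform marginals* with
a 0.9 parent-copy probability: all of their information is in the
dependency, none in the marginals. This is the cleanest operationalization
of "strong coupling" — the PSWM receives, by construction, zero
information from those positions while the pairwise models receive about
1.3 bits per coupled pair — and it is what the recovery benchmark means
by the strong-coupling regime. Uncoupled positions keep an
85%-consensus letter so all model kinds retain a workable core motif.

What the simulations do not emulate: peak-shape and read-coverage
structure, sequencing error, PCR amplification bias in SELEX, genomic
repeat structure, or multi-motif composition of real enhancers. Passing
the recovery benchmarks therefore demonstrates correctness of the
inference machinery under the model's own assumptions, not performance on
any particular ENCODE or HT-SELEX dataset.

## Problem sizes used by the packaged checks

The acceptance-style checks run at desk scale, chosen as the package's
own benchmark conditions: 200 random matrices (l = 3..6) for the
tree-sum oracle; exhaustive $4^l$ normalization up to l = 6 on 10 random
training sets; EM monotonicity across all four fixtures and three model
kinds at 500 peaks of 200 bp (the scale at which the count-replacement
update behaves as an ascent step in practice; at much smaller n the
heuristic can descend after its maximum, and even at study scale
occasional decreases of order 1e-5 relative occur on some data
realizations, which is why the fitter returns the best-likelihood state
rather than the last one); the recovery benchmark at 500 training and
500 independently drawn test peaks of 200 bp with 4 decoys per test
sequence over 20 seeds; SELEX recovery at 3 rounds of $10^4$ draws from a
300-sequence pool over 20 seeds (true $\beta_0 = 0.3$); and the
randomized control at n = 500 over 20 seeds.

## Known limitations

* Motif length is fixed to the initial PSWM's length; no trimming,
  extension, insertion/deletion states, or palindrome-aware tying.
* Single-motif inference only; no mixtures and no phylogenetic
  information.
* The thermodynamic likelihood assumes unsaturated binding (TF
  concentration cancels); saturation would require the full occupancy
  form.
* EM monotonicity is a contract checked empirically: the Dirichlet
  predictive in the M-step is not the bare maximum-likelihood update, so
  monotonicity to $10^{-6}$ is asserted by the suite rather than proved.
* Exact predictive sampling (`simulate()`) enumerates $4^l$ segments and
  is limited to `l <= 8`.
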