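---
title: "Methods: differentiable approximate string matching for alignment-free distance estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differentiable approximate string matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmatch)
```

## The model and its assumptions

`asmatch` learns an embedding of nucleotide sequences under which cosine
distance approximates Needleman–Wunsch (NW) alignment distance. The model
is a bank of `N` learnable patterns, each an `M x 4` real matrix. A
pattern is matched against a sequence by a smoothed version of the
approximate-string-matching (ASM) dynamic program: the first DP row is
zero, so a match may begin anywhere; the answer is read off the last row,
so it may end anywhere; and the three-way branch maximum is replaced by
the smoothed maximum

$$\max{}_\gamma(a_1,\dots,a_J) = \gamma \log \sum_j \exp(a_j/\gamma),$$

a smooth upper bound on the hard maximum that converges to it as
$\gamma \to 0$. The substitution cost of the classic edit-distance DP
becomes the (negated) inner product between a pattern row and a one-hot
sequence column, and the unit gap cost becomes a learnable penalty `g`
shared by all patterns. The per-pattern score $v_n$ is the hard maximum of
the last DP row; the embedding is $u = \mathrm{ReLU}(v + b)$. Because the
DP scans the whole sequence, sequences of any length embed into the same
$N$-dimensional space with no padding or trimming — the property that
distinguishes this architecture from convolutional embedders, and the
reason it tolerates insertions and deletions.

Training is Siamese: both sequences of a pair pass through the same
parameters, and Adam minimizes the mean squared difference between the
cosine distance of their embeddings and their NW alignment distance.

Two modeling conventions are worth stating explicitly:

* **Distance normalization.** The NW score itself is unbounded, so the
  regression target is `1 - identical columns / alignment length`
  computed from the optimal traceback — a `[0, 1]` quantity comparable to
  cosine distance. A column counts as identical only when both residues
  are the same unambiguous base.
* **Score extraction.** The smoothing applies only inside the recursion;
  $v_n$ is extracted with the *hard* maximum over the last row (ties
  toward the smallest column), and its gradient is routed through that
  single argmax column.

## Gradients

The gradient of $v_n$ with respect to pattern rows and gap penalty is
computed analytically on the *best-matched subsequence only*: backtracking
from the last-row argmax yields a span, and a differentiable NW recursion
with global boundary conditions (both leading gaps penalized) is filled
over that span. Its terminal value approximates $v_n$, and its derivatives
are obtained in one backward sweep in which each cell distributes weight
to its three upstream neighbours according to the softmax of the branch
values — $O(M\tilde L)$ per pattern rather than $O(ML)$ through the full
scan. Gradients do not flow through the choice of span itself; this is the
approximation that makes training affordable, and the test suite bounds
its error by comparing against central finite differences (maximum
relative error below `1e-4` for $\gamma \ge 0.5$, below `1e-3` at
$\gamma = 0.1$). An empty span (the optimum deletes the whole pattern)
contributes zero pattern gradient and $-M$ to the gap gradient, the
all-gap limit.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_patterns` (N) | 300 | embedding dimension; accuracy plateaus as N grows, 300 balances accuracy and cost |
| `pattern_len` (M) | 20 | motif length (nt); below ~20 patterns are uninformative |
| `gamma` | 0.1 | smoothing temperature of the soft maximum (score units); smaller is closer to the hard DP but less smooth to optimize |
| `g` (init) | 1 | learnable gap penalty, floor-clamped at 1e-3 after each step to stay positive |
| `learning_rate` | 1e-4 | Adam step size |
| `epochs` | 200 | passes over the training pairs |
| `batch_size` | 32 | pairs per gradient step; the loss is the batch *mean*, so the learning-rate scale is batch-size independent |
| NW scoring | 2 / −3 / −5 / −2 | match / mismatch / gap open / gap extend; a length-k run costs open + (k−1)·extend |

Desk-scale runs in the tests and the acceptance script use `N = 50`,
`M = 12`, 2,000 training pairs of 150-nt sequences and 60 epochs, which
trains in a few minutes on one CPU core; the full-scale defaults above are
what a production model of a marker-gene region would use.

## Initialization

The package's default initialization (`init = "subsequence"`) seeds each
pattern with the one-hot encoding of a random length-`M` subsequence of
the training data and centers each unit by setting
$b_n = -\mathrm{median}(v_n)$ over (a sample of) the training sequences;
the gap penalty starts at 1. The alternative `init = "uniform"` draws
pattern entries i.i.d. uniform(0, 1) with $b = 0$.

The subsequence scheme is the default for a structural reason. With
uniform patterns and zero bias, every unit's score is large and positive
for every sequence ($v_n \approx 8$–$12$ at $M = 12$), so all embeddings
lie in a narrow positive cone and cosine distances start two orders of
magnitude smaller than typical alignment distances. Escaping that regime
requires moving the biases by roughly $-\mathrm{median}(v)$, which at a
learning rate of `1e-4` takes on the order of $10^5$ Adam steps — far
more than a desk-scale run performs. Data-seeded patterns with centered
pre-activations make units selective from the start (about half fire per
sequence), so embedding distances span their full range at step 0 and
training spends its budget calibrating rather than escaping a degenerate
corner.

## Numerical choices

* **Log-sum-exp stability.** The reference recursion subtracts the hard
  maximum before exponentiating, so it is stable for arbitrary magnitudes.
* **Exp-domain fast path.** For the embedding and training forward pass
  the recursion is evaluated in the exponential domain: with
  $E = \exp(F/\gamma)$ the recursion is *linear*,
  $E_{m,\ell} = E_{m-1,\ell-1}W_{m-1,\ell-1} + G(E_{m-1,\ell} +
  E_{m,\ell-1})$ with $W = \exp(R/\gamma)$ and $G = e^{-g/\gamma}$, and
  $W$ is gathered from the `M x 4` table $\exp(P/\gamma)$ for one-hot
  columns. This removes all transcendental calls from the inner loop
  (about an order of magnitude faster) and computes the same quantity up
  to rounding. A guard estimates $\max|F|/\gamma$ and falls back to the
  log-domain recursion whenever $\exp(F/\gamma)$ could leave double
  range (e.g. very small $\gamma$), so user-facing results never silently
  overflow.
* **Tie-breaking.** All backtracking is deterministic: last-row argmax
  ties resolve toward the smallest column, branch ties as diagonal > up >
  left, and the NW traceback prefers substitution over a gap in the
  second sequence over a gap in the first. Reruns are bitwise identical.
* **Cosine guard.** Norms are guarded with $\varepsilon = 10^{-8}$; two
  zero embeddings are at distance 1 by convention, and the zero-norm
  subgradient is 0.
* **Degenerate inputs.** Empty FASTA records are rejected at parse time;
  residues outside the DNA+IUPAC alphabet name their position; relative
  error is undefined at zero true distance, so such pairs are excluded
  from the MRE and their count reported.

## The synthetic-data generator

`make_families()` emulates amplicon-like family structure: one random
root sequence diversifies into family ancestors under a "between" mutation
model, and each ancestor into members under a "within" model. Mutations
are per-position substitutions (to a uniformly chosen different base) and
short indels with geometric(1/2) run lengths capped at 5 nt, matching the
short-indel divergence regime of rRNA amplicons. The defaults (within:
substitution 0.04, insertion 0.01, deletion 0.01; between: 0.22 / 0.04 /
0.04) place within-family identity near 95% and between-family identity
near 70–80%, the ballpark of genus-level 16S divergence. Seeding uses an
explicit substream scheme, so adding a family leaves earlier families
byte-identical.

What the generator does *not* emulate: sequencing-error profiles,
chimeras, primer artifacts, compositional bias, and — importantly — the
*hierarchical* relatedness of real taxonomies. All family ancestors
diverge from one root at the same depth, so between-family distances
concentrate in a narrow band instead of spanning a continuum as distances
in real reference databases do. Tests passing on this fixture show that
the machinery trains, generalizes to held-out pairs, and ranks references
correctly; they do not certify accuracy on real data, and rank-correlation
summaries computed on the fixture are pessimistic relative to datasets
whose distances spread widely (distinguishing equally-unrelated families
from one another is noise-dominated by construction).

## Problem sizes used by the tests and acceptance script

Oracle and gradient properties run on hundreds of random small instances
(`M <= 8`, `L <= 20`). The training fixture is 10 families × 20 members of
length 150 (seed 7), 2,000 training and 1,000 held-out pairs, `N = 50`,
`M = 12`, $\gamma = 0.1$, learning rate `1e-4`, 60 epochs, batch 32 — the
scale at which one model trains in a few minutes on a single core. The
taxonomy check embeds the 200 family members as references and 50 fresh
within-family mutants as queries, with the NW best-score reference as
ground truth.

## Known limitations

* Gradients are span-restricted by design; for very diffuse matches (no
  clear best window) the approximation is loosest, which the
  finite-difference bounds quantify only on small instances.
* The star-shaped synthetic taxonomy makes global rank correlation a hard
  target at desk scale (see above); evaluating on data with a continuum
  of relatedness is the informative regime for that metric.
* Training cost is linear in pairs × patterns × sequence length; the
  package is single-threaded by design so that results are reproducible
  bit-for-bit.
* Local (rather than global-over-a-window) comparison and multi-layer
  stacking of the ASM unit are out of scope.
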