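---
title: "Evolving codon block structure under competing reading systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving codon block structure under competing reading systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonevol)
```

## The model

The standard genetic code (SGC) maps 64 codons onto 20 amino acids plus a
stop signal, and its redundancy is organized: synonymous codons form blocks
that mostly differ at the third codon position, the position where wobble
pairing lets a single tRNA read several codons. `codonevol` simulates one
hypothesis for how such block structure can emerge: primordial coding systems
were *probabilistic* — a codon encoded each label only with some probability
— and evolution under selection for unambiguous, error-tolerant coding
concentrated these probabilities into wobble-like blocks.

A coding system (an "individual") is a pair of row-stochastic matrices:

* a **code matrix** $P \in [0,1]^{64 \times 21}$, where $p_{cl}$ is the
  probability that codon $c$ encodes label $l$ (21 abstract labels: 20
  amino-acid-like items plus a stop-like item, all treated identically — no
  physicochemical properties enter the model);
* a **reading matrix** $R \in [0,1]^{21 \times 3}$, where $r_{lj}$ is the
  probability that label $l$ is read through mechanism $M_j$.

The three reading mechanisms differ in how tolerant codon recognition is.
For a reference codon $c$, the neighborhood $N_j(c)$ contains $c$ plus every
codon differing from it at exactly one position among the varied positions:

| model | varied positions | $|N_j(c)|$ | interpretation |
|-------|------------------|-----------|----------------|
| M1    | 3                | 4         | wobble-like third-position reading |
| M2    | 1, 2             | 7         | first/second-position tolerance |
| M3    | 1, 2, 3          | 10        | any single-position tolerance |

`codon_neighborhood()` exposes these sets; M1's varied position is
configurable (`m1_position`) but defaults to the third position, the choice
that reproduces the canonical GGG example (`GGG, GGA, GGC, GGT`). Codons are
indexed $16 b_1 + 4 b_2 + b_3$ with A=0, C=1, G=2, T=3; any fixed bijection
would do, this one is declared so that serialized matrices are reproducible
bit for bit.

## Coding-strength fitness

For each label $l$, the **Bayes codon** $c_l$ maximizes the posterior
probability of the codon given the label under a uniform prior over codons,
which reduces to the column argmax $\arg\max_c p_{cl}$ (ties broken toward
the lowest codon index; a label whose column is identically zero is an
error). The fitness of an individual is

$$
F \;=\; \sum_{c_1' \in N_{j_1}(c_1)} \cdots \sum_{c_{21}' \in N_{j_{21}}(c_{21})}
\;\prod_{l=1}^{21} \frac{p_{c_l' l}\; r_{l j_l}}{|N_{j_l}(c_l)|}
\;=\; \prod_{l=1}^{21} \frac{r_{l j_l}}{|N_{j_l}(c_l)|}
\sum_{c' \in N_{j_l}(c_l)} p_{c' l},
$$

where $j_l$ is the reading mechanism in force for label $l$. The second
equality — the sum over all $4$–$10^{21}$ codon combinations collapsing into
a product of per-label neighborhood sums — holds because each factor ranges
over its own index set; `brute_force_fitness()` implements the left-hand
side literally on subsets of up to four labels and is the oracle against
which the factorized implementation is tested. Each factor has a direct
reading: the joint probability that mechanism $M_{j_l}$ is the one reading
the label and that a codon drawn uniformly from the resulting neighborhood
actually encodes it. $F = 1$ therefore demands that every label's
neighborhood consist entirely of codons encoding it with probability one —
unambiguous, fully error-tolerant coding.

Two evaluation modes exist:

* **sampled** (`fitness_sampled()`, the default in evolution): $j_l$ is
  drawn fresh from the label's reading row each evaluation, making fitness a
  random variable and the reading distribution itself selectable;
* **expected** (`fitness_expected()`): each factor is replaced by its
  expectation over the draw, $\sum_j r_{lj} \cdot (r_{lj}/|N_j|) \sum_{c'}
  p_{c'l}$ — note the draw probability enters twice (once as sampling
  weight, once as the formula's own factor), so mechanisms contribute with
  weight $r_{lj}^2$. This squared weighting is a consequence of the
  definition, not a modeling choice; it is what makes collapsing each
  reading row onto a single mechanism selectively favored and drives the
  reading entropy to zero. The expected mode is deterministic and is used
  for regression tests and monotone elitist trajectories.

All fitness arithmetic is accumulated in log space: at initialization a
product of 21 factors of order $10^{-2}$ underflows quickly, and log
fitness is the natural trajectory scale anyway. Natural logarithms are used
throughout. A per-label factor of exactly zero gives $\ln F = -\infty$; such
individuals rank below every finite-fitness individual in selection rather
than raising an error, and if an entire population degenerates this way,
selection falls back to uniform copying and flags the generation.

## The evolutionary algorithm

`evolve_code()` iterates, from flat-Dirichlet random individuals (the
maximum-entropy initialization — every code row uniform on the 21-simplex,
every reading row uniform on the 3-simplex, matching the assumption of
maximally ambiguous primordial coding):

1. **evaluate** every individual (sampled mode redraws each label's
   mechanism every generation, elites included — fitness is honestly
   stochastic for everyone);
2. **record** population means of $\ln F$, the entropies and the expected
   label counts every `record_every` generations;
3. **select**: `elite_count` top individuals are copied unchanged, the
   remaining slots are filled by tournament selection (draw
   `tournament_size` uniformly with replacement, copy the fittest, ties
   uniform);
4. **mutate** non-elite offspring: each code row independently with
   probability `mutation_row_prob`, and each reading row with
   `mutation_reading_prob`, is resampled from a Dirichlet centered on the
   current row, $\mathrm{Dir}(\kappa \cdot \text{row} + 0.01)$, where
   $\kappa$ is `mutation_concentration`. The 0.01 floor keeps the support
   full so no assignment is permanently lost.

There is no recombination; mutation and selection are the only operators.
One master seed drives a single RNG stream through initialization,
evaluation draws, selection and mutation, so a run is exactly reproducible
from its configuration.

### Why the mutation kernel is bold, not gentle

The Dirichlet-resampling operator has one interpretable strength knob. For
large $\kappa$ the resampled row is a small perturbation of the current one
— but this regime has a structural pathology: once a row reaches a simplex
vertex (probability one on a single label or mechanism), the concentration
vector $\kappa \cdot \text{row} + 0.01$ is dominated by one component and
resampling returns the same vertex almost surely. Vertices become absorbing.
In practice every reading row collapses quickly onto *some* mechanism (the
$r^2$ weighting rewards any vertex) and then freezes, leaving the population
permanently stuck with a mixture of M1-, M2- and M3-reading labels and a
fitness plateau well below what homogeneous wobble-like reading achieves;
increasing population size or run length does not unfreeze it.

The defaults therefore use a small concentration
(`mutation_concentration = ` $0.2$ scale), under which a resampled row is
close to a fresh spiky draw — a bold reassignment move that can relocate a
codon to a new label, or re-test a label's reading mechanism against the
current code, in a single step. Under this regime the simulations reproduce
the expected dynamics: reading entropy collapses early, the most tolerant
mechanism M3 is eliminated first, M2 persists for a while and then
disappears, and wobble-like M1 reading takes over all 21 labels, while the
code matrix concentrates into M1-shaped codon blocks of sizes 1–4. The
reading-row mutation probability is set higher than the code-row one
(0.2 vs 0.02 per row per generation): reading rows need repeated
re-testing for the M2-to-M1 transitions to complete within the run, whereas
code rows are 64 and already receive ample aggregate mutation. Tournament
size 6 provides selection pressure strong enough to fix the slightly
beneficial M1 flips and purge mutational contamination quickly; a single
elite guards the best solution without throttling diversity.

These four values (concentration, two row probabilities, tournament size)
are calibration choices, exposed in `evolution_config()` and revisable from
any configuration file; the package's defaults are fixed once, at the values
that robustly show the dynamics above at desk scale, and are used unchanged
by the test suite and the acceptance script.

## Observables

* `code_entropy()` — $H_c(P) = -\sum_{c,l} p_{cl}\ln p_{cl}$, the summed
  Shannon entropy of the codon rows, in nats: 0 for deterministic
  assignment, $64\ln 21 \approx 194.9$ for uniform ambiguity.
* `reading_entropy()` — $H_r(R) = -\sum_{l,j} r_{lj}\ln r_{lj}$, in nats:
  0 for a homogeneous reading system, $21\ln 3 \approx 23.1$ at uniform.
* `expected_label_counts()` — $E_j = \sum_l r_{lj}$, the expected number of
  labels read through each mechanism; the three components sum to 21 and
  $(21, 0, 0)$ is the homogeneous-M1 endpoint.
* `extract_blocks()` — the codon block of label $l$ at threshold $t$ is
  $\{c : p_{cl} > t\}$ (strictly greater; the default $t = 0.8$ means
  "confidently assigned"). For $t > 0.5$ blocks are automatically pairwise
  disjoint. Labels may have empty blocks — early-run snapshots are
  representable and reported, not dropped.
* `block_size_distribution()`, `m1_consistency()` — the size histogram over
  all 21 labels, and the fraction of non-empty blocks confined to a single
  third-position family (the block shape wobble reading produces).
* `sgc_block_spectrum()` — the reference point: the hard-coded standard
  genetic code (NCBI translation table 1, DNA alphabet) has 5 amino acids
  in four-codon blocks, 9 in two-codon blocks, 2 single-codon amino acids,
  3 six-codon amino acids (each splitting 4+2 across third-position
  families), and two three-codon items (Ile and stop) — 64 codons in all.

## What the simulator emulates, and what it does not

The random initial populations *are* the study conditions: maximally
ambiguous coding systems with no structure beyond row-stochasticity. The
simulator shows that wobble-like block structure can emerge from selection
on coding strength alone. It does not emulate: amino-acid
physicochemistry or substitution costs (labels are exchangeable), tRNA
copy-number or modified-base pairing chemistry, codon usage bias, or any
genomic sequence context. Passing tests therefore demonstrate properties of
the model, not claims about historical biochemistry; the SGC comparison is
structural (block sizes and shapes), not an alignment of specific codons to
specific amino acids.

## Numerical choices and degenerate inputs

* Row-stochasticity is enforced at `1e-9`; TSV serialization carries 12
  significant digits and round-trips bit-stably.
* $0 \ln 0 = 0$ in all entropies.
* Bayes-path ties break toward the lowest codon index; tournament ties
  break uniformly at random.
* Gamma draws with very small shape parameters can underflow to an all-zero
  row; the sampler then falls back to the uniform row rather than emitting
  NaNs.
* `brute_force_fitness()` refuses more than 4 labels (the enumeration is
  exponential); it exists as an oracle, not a production path.

## Scale of the shipped experiments

The default configuration reproduces the full protocol (1000 individuals,
100,000 generations, about an hour of compute). The package's own test
suite and the acceptance script run the scaled-down replication — 200
individuals, 20,000 generations, five seeds — which completes in a few
minutes and exhibits the same qualitative dynamics: best $\ln F$ rising
from about $-66$ to above $-20$ and stabilizing, both entropies falling,
reading entropy collapsing one order of magnitude earlier than code
entropy, M1 dominance, and M1-consistent blocks of sizes 1–4. Oracle-based
correctness tests (brute-force fitness enumeration, entropy summation,
neighborhood properties) run on 3-label subsystems and single matrices and
are exact to stated tolerances.

## Limitations

* With 21 labels and 16 third-position families, perfect four-codon
  coverage for every label is combinatorially impossible; evolved codes
  necessarily mix block sizes, which is also what the SGC does.
* The sampled fitness makes selection noisy by construction; runs shorter
  than a few thousand generations mostly measure that noise.
* Tournament selection plus a bold mutation kernel is one concrete
  instantiation of "selection with greater probability for fitter
  solutions" and "random modification"; other operator choices plausibly
  reproduce the same qualitative dynamics at different rates.
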