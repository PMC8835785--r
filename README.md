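# codonevol

An evolutionary simulator of genetic code structure. `codonevol` asks how
the standard genetic code's organization — synonymous codons grouped into
blocks that differ mostly at the third, wobble position — can emerge from
initially *ambiguous* coding systems, when the codon-recognition machinery
itself is allowed to evolve and compete.

It is aimed at researchers in molecular evolution who want a reproducible,
scriptable implementation of this class of model: populations of
probabilistic codon→label assignments evolving under mutation and selection,
with entropy, reading-system and block-structure observables, TSV/JSON
artifacts and a small CLI.

## The model in brief

An individual coding system is a pair of row-stochastic matrices:

* `P` (64 × 21): `p[c, l]` = probability that codon `c` encodes label `l`
  (20 amino-acid-like labels + a stop-like label, treated abstractly);
* `R` (21 × 3): `r[l, j]` = probability that label `l` is read through
  mechanism `Mj`.

A mechanism defines which codons near a reference codon are accepted as
encoding the same label: `M1` varies only the third position (neighborhood
size 4, wobble-like), `M2` one of the first two positions (size 7), `M3`
any single position (size 10). For each label the *Bayes codon*
`c_l = argmax_c p[c, l]` anchors the neighborhood, and the coding strength
of the whole system is

```
F = prod over labels l of  ( r[l, j_l] / |N_{j_l}(c_l)| ) * sum_{c' in N_{j_l}(c_l)} p[c', l]
```

with `j_l` drawn from the label's reading row at each evaluation. `F = 1`
means every label is encoded unambiguously by its entire neighborhood —
an error-tolerant, block-structured code. Populations evolve by
Dirichlet row mutation and tournament selection on `ln F`; entropies
`Hc = -sum p ln p` and `Hr = -sum r ln r` quantify the remaining coding
and reading ambiguity (nats).

## Worked example

A scaled-down run (the full protocol uses 1000 individuals and 100,000
generations; 200 × 20,000 finishes in about a minute):

```r
library(codonevol)
res <- evolve_code(evolution_config(population_size = 200,
                                    generations = 20000, seed = 1))
summary(res)
#> Run of 20000 generations, population 200, seed 1 (sampled fitness)
#>   ln F (best): -65.940 -> -6.931
#>   mean Hc: 169.25 -> 0.83 nats; mean Hr: 17.49 -> 0.23 nats
#>   final expected labels: M1 20.66, M2 0.20, M3 0.14
#>   best code: Hc = 0.000, Hr = 0.000, ln F = -6.931
#>   blocks (threshold 0.8): sizes {2, 4} with counts {10, 11}; M1-consistent 100%
```

Reading the output: best log-fitness climbs from −65.9 (random ambiguous
start) to −6.9 and both entropies collapse; reading entropy `Hr` reaches
~zero long before code entropy `Hc`. At the end, wobble-like `M1` reading
has taken over effectively all 21 labels (expected count 20.7 of 21), and
the best code's confident codon blocks (assignment probability > 0.8) all
sit inside single third-position families — 10 two-codon and 11 four-codon
blocks here, the same block anatomy class as the standard genetic code,
whose spectrum `sgc_block_spectrum()` reports for comparison (5 four-codon,
9 two-codon, 2 one-codon, 3 six-codon amino acids, Ile and stop with three
codons each).

`plot(res)` draws the fitness, entropy and reading-type trajectories.
`simulate_run()` writes the trajectory TSV, best-individual matrices and a
JSON summary; `analyze_code()` recomputes all observables from saved
matrices.

### Command line

```sh
Rscript inst/cli/codonevol.R simulate --config inst/extdata/example_config.yaml --out run_out
Rscript inst/cli/codonevol.R analyze --code run_out/best_code.tsv --reading run_out/best_reading.tsv
Rscript inst/cli/codonevol.R sgc-spectrum
```

### Configuration defaults

| key | default | meaning |
|-----|---------|---------|
| `population_size` | 1000 | coding systems per generation |
| `generations` | 100000 | generations to run |
| `seed` | 1 | master RNG seed (full reproducibility) |
| `mutation_row_prob` | 0.02 | per-generation resampling probability per code row |
| `mutation_reading_prob` | 0.2 | same, per reading row |
| `mutation_concentration` | 0.2 | Dirichlet kappa: resample ~ Dir(kappa·row + 0.01) |
| `tournament_size` | 6 | contestants per selection tournament |
| `elite_count` | 1 | top individuals copied unchanged |
| `fitness_mode` | `sampled` | `sampled` or deterministic `expected` |
| `record_every` | 100 | generations between trajectory records |
| `block_threshold` | 0.8 | coding-probability cutoff for block extraction |
| `output_directory` | `.` | where `simulate_run()` writes artifacts |

The mutation and selection defaults are calibration choices; the methods
vignette (`vignettes/genetic-code-evolution.Rmd`) explains why a small
concentration (bold row resampling) is required and what the defaults were
calibrated to show.

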