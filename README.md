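# hybnum — hybrid numbers of ploidy profiles

Polyploid species carry multiple complete chromosome sets, acquired
either by whole-genome doubling (autopolyploidy) or by hybridization
between lineages (allopolyploidy).  Given only the observed *ploidy
profile* of a dataset — a descending vector **m** = (m₁, …, mₙ) of
positive integers, one per taxon — a natural parsimony question is:
*how many polyploidization events are needed, at minimum, to explain
these numbers?*

`hybnum` answers that question in the framework of rooted phylogenetic
networks that may contain *beads* (pairs of parallel arcs, modelling
whole-genome doubling).  A network *N* *realizes* **m** when the number
of directed root-to-leaf paths to taxon *i* equals mᵢ; the *hybrid
number* of the network is h(N) = Σ_{v hybrid} (indeg(v) − 1), and the
hybrid number h(**m**) of the profile is the minimum of h(N) over all
binary realizations.  The package is aimed at phylogeneticists working
with polyploid complexes (plants especially) and at anyone studying the
underlying combinatorial problem: find a rooted leaf-labelled DAG with a
prescribed path-multiplicity vector and minimum cyclomatic number.

## What it computes

* **Network model** (`phylo_network`): rooted acyclic multigraph with
  parallel arcs, validation, path counting by dynamic programming with
  an independent path-enumeration cross-check (`unfold_leaf_multiset`),
  and the local surgeries (`subdivide_arc`, `expand_cherry`,
  `hybridize`, `add_pendant_leaf`) the constructions need.
* **Explicit realizations of simple profiles** (all components after the
  first equal one): `build_B` from the binary representation of the head
  (with closed-form vertex and hybrid counts, `theorem1_vertex_count`),
  `build_D` from its prime factor decomposition, `beaded_tree` for
  powers of two, and `naive_realization` for arbitrary profiles
  (h = Σ(mᵢ − 1)).
* **Simplification sequence** (`simplification_sequence`): repeatedly
  merge equal leading components or subtract the second from the first
  until the profile is simple, with per-step bookkeeping; statistics
  `s_of`, `c_of`, `line8_fired`.
* **Traceback** (`build_N`, `build_N_auto`): reverse the sequence from
  an attainment of the terminal profile; each merge reversal expands a
  cherry, each subtract reversal adds one binary hybrid vertex.
* **Exact search** (`min_hybrids_strictly_simple`): memoized
  iterative-deepening search over multisets of open-arc path counts,
  with a brute-force enumeration oracle (`enumerate_small_networks`)
  validating it on small instances.
* **The formula** (`hybrid_number`): when no simplification step ever
  subtracts more than the second component (the "line 8" case never
  fires) and the terminal attainment is certified,

      h(m) = h(m_t) + c(s(m))

  is exact and a verifying certificate network is returned.  Profiles
  whose components are all powers of two are exact with h = log₂ m₁.
  Otherwise certified lower/upper bounds are reported, never a guess.

## Worked example

```r
library(hybnum)
p <- ploidy_profile(c(12, 6, 6, 5))
simplification_sequence(p)
#> simplification sequence, s = 4 , c = 2
#>   (12, 6, 6, 5)
#>   (6, 6, 6, 5)
#>   (6, 6, 5)
#>   (6, 5)
#>   (5, 1)
res <- hybrid_number(p)
res
#> hybrid number: 5 (exact)
#>   - closed formula h(m) = h(m_t) + c(s(m))
#>   - exhaustive search; optimum met by the binary-representation construction
path_count_vector(res$certificate)
#> x1 x3 x2 x4
#> 12  6  6  5
```

The sequence shrinks (12, 6, 6, 5) to the simple terminal profile
(5, 1) in s = 4 steps, c = 2 of them subtract steps.  The terminal
profile needs h((5, 1)) = 3 hybrid vertices (no single-leaf binary
network with two hybrids has more than 2² = 4 root-to-leaf paths), so
h(**m**) = 3 + 2 = 5: five polyploidization events suffice and none can
be spared.  The certificate network realizes exactly the requested path
counts.

The bundled *Viola* dataset (12 taxa, ploidies 9, 7, 7, 4, 4, 4, 2, 2,
2, 2, 2, 1, simplified from a published allopolyploid phylogeny whose
network postulates nine events) gives:

```r
viola <- read_profile(system.file("extdata", "viola_profile.tsv", package = "hybnum"))
hybrid_number(viola)
#> hybrid number: 5 (exact)
```

so five events already explain the observed ploidies.

## File formats and command line

Profiles are two-column TSV (`label<TAB>ploidy`, `#` comments).
Networks are arc-list TSV (`tail<TAB>head`, parallel arcs repeated,
leaves named by their labels), an extended Newick dialect in which a
hybrid vertex appears as a `#Hk` tag — a bead serializes as
`((x1)#H1,#H1);` — and DOT for drawing (hybrid vertices filled).

```sh
Rscript -e 'quit(status = hybnum::main_cli())' --args \
  hybrid-number --profile viola.tsv --report report.json --certificate net.tsv
```

Subcommands: `simplify`, `construct` (`--method B|D|naive|beaded`),
`build-n`, `hybrid-number`, `check`, `fixtures`; exit status 0 on
success, 2 on validation failure.

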