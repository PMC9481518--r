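---
title: "Computing the hybrid number of a ploidy profile: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing the hybrid number of a ploidy profile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybnum)
```

## The model

A *ploidy profile* is a descending vector $\mathbf m = (m_1,\dots,m_n)$
of positive integers indexed by taxa: $m_i$ is the number of complete
chromosome-set copies carried by taxon $i$ (up to a constant factor for
the ploidy of the root ancestor).  The evolutionary events that multiply
chromosome sets — whole-genome doubling and hybrid speciation — are
both captured by *hybrid vertices* in a rooted phylogenetic network.

The networks used here are rooted, connected, acyclic multigraphs in
which parallel arcs are allowed but loops are not.  The root has
indegree 0 and outdegree 2; every other internal vertex is either a
*tree vertex* (indegree 1, outdegree 2) or a *hybrid vertex* (indegree
$\ge 2$, outdegree 1); leaves (indegree 1, outdegree 0) carry the taxon
labels.  A *bead* — two parallel arcs between the same pair of
vertices — models whole-genome doubling, and is the reason parallel
arcs are first-class citizens in the data structure: arcs are stored as
a multiset of rows, so "subdivide *this* copy of a parallel pair" is
well defined.  The network is *binary* when every hybrid vertex has
indegree exactly 2.  The one permitted degeneracy is the single-vertex
network (root = leaf) for the profile $(1)$, which cannot meet the
root-outdegree-2 convention; its hybrid number is 0 and nothing else
would be consistent.

$N$ *realizes* $\mathbf m$ when the number of directed root-to-leaf
paths to taxon $i$ equals $m_i$ (a bead doubles the count).  The
*hybrid number* of a network is $h(N)=\sum_{v\in H(N)}(\mathrm{indeg}(v)-1)$
and the hybrid number $h(\mathbf m)$ of the profile is the minimum over
binary realizations.  Since a single-leaf binary network with $h$
hybrid vertices has at most $2^h$ root-to-leaf paths,
$h(\mathbf m)\ge\lceil\log_2 m_1\rceil$ always.

Path counts are computed by dynamic programming over a topological
order.  Because essentially every result in the package rests on these
counts, a second, independent route is kept alongside: explicitly
enumerating all root-to-leaf paths (the leaf multiset of the unfolded
multi-labelled tree, `unfold_leaf_multiset()`).  The test suite checks
the two routes against each other on every constructed network family.

## Realizing simple profiles

A profile is *simple* when $m_i=1$ for $i\ge 2$, and *strictly simple*
when additionally $n=1$.  Two explicit realizations of a simple profile
are provided.

**From the binary representation** (`build_B`).  Write
$m_1=\sum_{j=1}^q 2^{i_j}$ with $i_1>\dots>i_q\ge 0$.  Start from the
beaded tree with $i_1$ beads (path count $2^{i_1}$).  Subdivide one of
the two root arcs with a chain $s_2,\dots,s_q$ and, for each lower-order
bit, add an arc from $s_j$ into a subdivision of the outgoing arc of the
bead hybrid with exactly $i_j$ hybrids strictly below it; that
subdivision vertex becomes a new binary hybrid and contributes exactly
$2^{i_j}$ additional paths.  The chain arc itself plays the role of the
leading bit, so only $q-1$ extra arcs exist ($j$ runs from 2): the
construction's description nominally indexes the extra arcs from
$j=1$, but only $s_2,\dots,s_q$ exist and the closed-form hybrid count
$i_1+q-1$ forces exactly $q-1$ added hybrids, so the package starts at
$j=2$.  Unit components hang off the *other* root arc as pendant leaves
on subdivision vertices whose path count is 1.  The result is binary,
realizes the profile, and has $i_1+q-1$ hybrid vertices and
$2(i_1+q-1+n-1)+1$ vertices (`theorem1_vertex_count`); both counts are
asserted structurally in the tests.  Placing the $s$-chain on the first
stored root arc and the pendant chain on the second, nearest the root
first, is an arbitrary but deterministic choice; path counts are
invariant to it.

**From the prime factorization** (`build_D`).  Write
$m_1=p_1^{a_1}\cdots p_k^{a_k}$ with $p_1>\dots>p_k$.  For each prime
take a minimum-hybrid single-leaf realization of $(p_i)$ (from the
exact search below, or supplied by the caller) and stack
$a_1+\dots+a_k$ blocks in descending-prime order, identifying the leaf
of each block with the root of the next; path counts multiply down a
cut arc, so the stack realizes $m_1$ with
$\sum_i a_i\,h(A(p_i))$ hybrid vertices.  Neither construction
dominates the other — $(15)$ favours D (5 vs 6), $(265)$ favours B
(10 vs 11) — which is precisely why the exact search exists.

`naive_realization` covers arbitrary profiles with
$h=\sum_i(m_i-1)$ via one parallel-path gadget per taxon (a hub hybrid
of indegree $m_i$); it is the fallback upper bound and a convenient
non-binary test case.

## The simplification sequence

`simplification_sequence()` shrinks a profile to a simple terminal
profile $\mathbf m_t$.  With $\alpha=m_1-m_2$:

* $\alpha=0$: *merge* — drop the first component (its taxon will later
  reappear as a cherry mate of the survivor's);
* $\alpha>0$: *subtract* — replace $m_1$ by $\alpha$, keeping the
  taxon label, and re-insert in descending order.

$s(\mathbf m)$ is the number of steps, $c(s(\mathbf m))$ the number of
subtract steps, and the *line-8 flag* records whether any subtract step
had $\alpha>m_2$ (equivalently, some profile had $m_1>2m_2$).  Two
tie-break rules make the sequence canonical: a shrunk head is
re-inserted *after* all components of equal value, and when several
components tie at the top the merge removes the first and records the
second as survivor.  No published convention fixes these ties and every
downstream contract (path counts, vertex accounting, hybrid counts) is
invariant to them; determinism is what matters for reproducible
serialization.

Closed forms validated as properties: $(k,\dots,k)$ with $q$ copies
gives $s=q-1$; arithmetic profiles $m_i=k(l-i)$ with $k\ge2$,
$l\ge q+2$ give $s=l+q-3$ (for $k=1$ the sequence terminates early at a
simple profile, so the property test excludes it); and the family
$(k^l,k)$ gives $s=k^{l-1}$ — the sequence can grow exponentially, which
is why the complexity of the overall pipeline is driven by $s$.

For the bundled 12-taxon *Viola* profile the sequence has 12 steps and
terminal profile $(2,1,1,1)$.  One published sentence counts "twelve
elements"; the reconstruction here yields 13 profiles, i.e. 12
*excluding the input*, which matches the definition of $s$ used
throughout and reproduces every downstream number, so the package reads
that count as $s=12$.

## Traceback

`build_N()` reverses the sequence starting from an attainment of
$\mathbf m_t$.  A merge step is undone by `expand_cherry()` (the
survivor leaf becomes a tree vertex with two leaf children, both
inheriting its count) and a subtract step by `hybridize()` (subdivide
the donor's and receiver's pendant arcs, add an arc between the new
vertices; the receiver's count grows by the donor's count).  Both
subtract cases ($\alpha>m_2$ and $\alpha\le m_2$) are reversed by the
same generic surgery; published drawings of the two cases differ in
local details (a deleted dashed arc, a suppressed vertex) that are not
recoverable from the text, but the generic surgery satisfies every
stated contract — counts, $+2$ vertices per step, $+1$ hybrid per
subtract, binarity — and reproduces every printed number, so the case
split survives only as metadata.  Each reversal adds exactly two
vertices, giving the accounting identity
$|V(N(\mathbf m))| = a(\mathbf m_t)+2s(\mathbf m)$ checked on every
seeded profile in the tests.  Worked illustrations sometimes combine
two steps into one arrow; the implementation never combines steps,
precisely to keep this identity exact.

## Exact search for strictly simple profiles

`min_hybrids_strictly_simple()` finds $h((m))$ by iterative-deepening
search over a quotient of the space of single-leaf binary networks: a
state is the *multiset of root-to-arc path counts of the open arcs* of
a partially built network.  The start state is $\{1,1\}$ (the root's
two arcs); a tree vertex duplicates one open count (free); a hybrid
vertex merges two open counts into their sum (cost 1; merging two
copies of the same count on one tail is a bead); the target is the
singleton $\{m\}$.  Every network induces such a move sequence via a
topological order and every move sequence rebuilds a valid network, so
the minima coincide — an argument guarded by a brute-force oracle
(`enumerate_small_networks`, $h\le3$, deduplicated up to
type-preserving isomorphism) that the tests compare against the search
for every reachable $m$.

The search core is in C++ (the only compiled code in the package) with
a memo of failed (state, merges-remaining) pairs, valid across
deepening iterations because "remaining" is measured from the node.
The pruning rules are exactly the invariants of the state space: the
sum of open counts is invariant under merges, grows under duplicates
and finishes at $m$, so sum $\le m$ always and a state with sum $=m$ is
feasible iff its size fits the remaining merges; the state size minus
one never exceeds the remaining merges; a merge at most doubles the
maximum; and the number of remaining duplicates is determined as
$r-(\text{size}-1)$, each at most doubling the sum.  The first feasible
depth is the minimum, and the winning move sequence is replayed into an
explicit certificate network that is re-verified by path counting.

A certification refinement: to attain $(m)$ it suffices to deepen only
to $h(B((m)))-1$.  If nothing is found there, $B((m))$ itself is
optimal, so the result is exact either way without ever searching the
final depth — this is what makes the prime 53 (needed for $D((265))$)
cheap: depths 6 and 7 are refuted and $h((53))=8$ follows from the B
construction.

**Tunable parameters.** `search_config(max_head = 512, max_budget =
12)` gates the search: profile heads above `max_head` (dimensionless;
ploidy numbers in real datasets rarely exceed two digits) or budgets
above `max_budget` hybrid vertices fall back to the better of B and D,
and the result is flagged *uncertified*.  The defaults cover every
input the package is designed for while keeping the worst-case search
below a second on one CPU.

## The hybrid number pipeline

`hybrid_number()` computes $\sigma(\mathbf m)$, attains
$\mathbf m_t$ (`attain_simple()`: search core plus free pendant unit
leaves on count-1 arcs), and distinguishes three regimes:

1. **Line 8 never fired and the terminal attainment is certified**:
   $h(\mathbf m)=h(\mathbf m_t)+c(s(\mathbf m))$ is exact and the
   traceback network is the certificate.
2. **All components are powers of two**: exact with
   $h=\log_2 m_1$ and a beaded-chain certificate (pendant leaves at the
   depth whose count matches each component).  This branch is taken
   *even when line 8 fires* — e.g. $(8,2)$, where the traceback yields
   4 hybrids but the true hybrid number is 3 — because the
   power-of-two case is proven exact independently of the sequence.
3. **Otherwise: certified bounds.**  Lower: $\lceil\log_2 m_1\rceil$,
   improved to the exact $h((m_1))$ when the search certifies it
   (deleting all other leaves of a realization of $\mathbf m$ yields a
   realization of $(m_1)$ without increasing the hybrid number).
   Upper: the best of the traceback network, the per-component star of
   B networks ($\sum_k(i_{k,1}+l_k-1)$, `proposition2_upper`) and the
   naive realization, with the winning network returned as the
   certificate.  No exactness procedure is known when line 8 fires
   outside the power-of-two case; the package deliberately reports
   bounds there rather than guessing.

Every certificate, exact or bound, is re-verified by `realizes()` and
`network_hybrid_number()` before being returned; a formula value that
disagreed with its certificate would stop the pipeline rather than be
reported.

## Synthetic data

`random_profile(seed, n = 5, max_entry = 32)` draws multiplicities
uniformly from $1{:}\texttt{max\_entry}$; the seed is mandatory and the
ambient RNG is left untouched.  The defaults mirror the scale of the
worked datasets: around a dozen taxa at most and ploidy numbers in the
low tens (the *Viola* dataset tops out at 9; the stress suite uses
entries up to 64, still far above observed ploidies).  Uniform draws
are a deliberate *worst-case* choice for the simplification sequence,
not a biological model: real ploidy profiles are strongly clustered on
powers and small multiples of the base number, which only shortens
$\sigma(\mathbf m)$.  A green property suite therefore establishes the
combinatorial contracts (realization, vertex accounting, bound
ordering) on harder-than-real inputs; it does not validate any model of
how ploidies arise, and it says nothing about profiles whose heads
exceed the search gate, where only bounds are certified.

## Numerical and degenerate-input choices

* Multiplicities are bounded in practice by the factorization gate
  ($10^6$) and path counts are held in doubles; all quantities compared
  for equality are integers well below $2^{53}$.
* Fresh vertices are numbered `v<k>` in creation order and every
  public constructor renumbers in depth-first preorder, so repeated
  runs serialize identically (stable goldens, diffable TSV).
* Profile $(1,\dots,1)$: realized by a caterpillar tree, $h=0$; for
  $n=1$ the single-vertex network.  These bypass every construction
  that assumes $m_1\ge2$.
* `validate_network()` is strict (it reports degree-(1,1) subdivision
  vertices), but the counting queries only require a rooted loop-free
  DAG, because surgeries legitimately pass through subdivision states
  and subdivision is count-preserving.

## Known limitations

* Exactness is certified only in regimes 1 and 2 above; when line 8
  fires on a non-power-of-two profile the gap between the reported
  bounds can be nonzero (it is 1 for $(9,2)$).
* The search is exponential in the hybrid number; heads beyond a few
  hundred fall back to uncertified constructions by design.
* Isomorphism testing exists only inside the enumeration oracle (tiny
  instances, type-preserving permutations); the package never decides
  equivalence of two arbitrary networks.
* The multi-labelled-tree fold-up machinery, guide sequences and
  stability testing that underpin the correctness proofs are not
  implemented: they are proof devices, not needed to compute
  $h(\mathbf m)$.
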