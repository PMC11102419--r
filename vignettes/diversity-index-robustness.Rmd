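---
title: "Phylogenetic diversity indices and their robustness to extinction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic diversity indices and their robustness to extinction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divindex)
```

## The model

A rooted phylogenetic X-tree $T=(V,E)$ has a distinguished root $\rho$,
edges directed away from it with strictly positive lengths
$\ell : E \to \mathbb{Q}^{>0}$, and leaves bijectively labelled by a taxon
set $X$, $|X| = n$. A *phylogenetic diversity index* is an allocation
function $\varphi_\ell(x) = \sum_{e \in E} \gamma(x,e)\,\ell(e)$ with
coefficients $\gamma(x,e) \in [0,1]$ that partitions total edge length
among the species ($\sum_x \varphi_\ell(x) = \sum_e \ell(e)$), subject to

* **descent**: $\gamma(x,e) = 0$ whenever $x$ is not descended from $e$, and
* **neutrality**: $\gamma(x,e)$ depends only on the shape of the pendant
  subtree below $e$, with leaves in corresponding positions of isomorphic
  subtrees receiving equal coefficients.

In the *consistent* form used throughout, an index is generated by a
**ratio of allocations** at every interior vertex $v$ of out-degree $d$:
proportions $\Gamma_1 : \cdots : \Gamma_d$ in which each ancestral edge's
length is shared among $v$'s child subtrees, as a function of the child
subtree shapes only. The coefficient $\gamma(x,e)$ is then the product of
the terms for $x$'s branch at every branching vertex strictly below $e$.
`allocation_rule()` encodes exactly this object; `scores()` and
`coefficients_table()` evaluate it.

The two indices in practical use are **Fair Proportion**
($FP(x) = \sum_{e \in P(\rho,x)} \ell(e)/|c_T(e)|$, with $c_T(e)$ the
cluster below $e$) and **Equal-Splits**
($ES(x) = \sum_{e} \ell(e)/\pi(e,x)$, $\pi$ the product of out-degrees on
the descent path). Both are available twice: as allocation rules and as
independent closed-form oracles (`fp_score_direct()`, `es_score_direct()`);
the test suite checks the two routes against each other on a thousand
seeded random trees. Seven further example rules (`alpha` … `eta`, plus
the table-bound `theta`) cover the breadth of the definition; they are
restricted to binary vertices, as defined.

## Exact arithmetic

Every length, coefficient and score is an exact rational (class
`rational`, backed by a compiled arbitrary-precision kernel), and the
constructions below additionally use symbolic infinitesimals $a + b\varepsilon$
(class `epslen`, compared lexicographically). This is not cosmetic: the
package's central outputs are *verdicts* — a ranking is strict or it is
not, reversed or not — and the non-rigid construction nests score
intervals recursively, producing denominators of hundreds of bits that
would silently collapse to ties in double precision. Printed decimals are
produced only at output time (`rat_decimal()`, round-half-away-from-zero
in integer arithmetic).

## Classifying indices

* **interior / boundary** (`classify_interior()`): boundary indices have
  some zero ratio term (some species is wholly cut off from an ancestral
  edge). The classification is concrete — computed on a given tree, with a
  witness vertex.
* **rigid / non-rigid** (`rigidity_probe()`): a rigid index gives the same
  ratio to two *singular* shape classes (a vertex parenting a leaf) of
  different breadth; Equal-Splits is the canonical example. Rigidity is an
  existential property over all trees, so the probe is a semi-decision: it
  enumerates caterpillar-type singular classes up to a breadth bound and
  returns a witness pair, or reports that none was found up to the bound.
  For every builtin rule the probe's verdict at the default bound agrees
  with the known classification (FP and `zeta` non-rigid; ES, `alpha`,
  `beta`, `gamma`, `delta`, `epsilon`, `eta` rigid).

## Extinction events and reversals

`prune_and_suppress()` restricts a tree to the survivors and the root,
merging the edges of suppressed out-degree-1 vertices (the root itself is
never suppressed). A ranking (higher score first, exact ties recorded) is
**strictly reversed** when both rankings are strict and every survivor
pair is discordant; the **relaxed** notion — every strictly ordered pair
flips, ties unconstrained, at least one pair flips — is the right yardstick
on ultrametric trees, where cherry mates always tie.

Necessity results implemented in `necessary_extinctions()`:

* any index: all but one leaf adjacent to each interior vertex must go;
* rigid indices: additionally all but one isolated leaf — all of them if
  some maximal pendant subtree is a single (root-adjacent, score-fixed)
  leaf.

A *fixed leaf* keeps its score for every length assignment;
`fixed_leaves()` decides this symbolically, by comparing each original
coefficient with the coefficient of the merged edge it lands in — no
length sampling, because the claim is universally quantified.

## The two constructions

**Rigid interior indices** (`theorem9_construct()`): delete all isolated
leaves and all but one leaf per interior vertex (survivor = natural-order
smallest label, so `x2` sorts before `x10`). Assign $\ell'$: every edge in
the set $F$ (edges above isolated-leaf parents, plus m-cherry parent edges
not below those) gets $M + k\varepsilon$, every other edge $\varepsilon$.
With $\Delta(\tilde x) = \varphi_{\tilde T,\ell'} - \varphi_{T,\ell'}$ and
$c_i$ the score midpoints, reassigning each survivor pendant to
$c - c_i + \varepsilon$ ($c = \max c_i$) lands the scores exactly on
$c \mp \Delta/2$, reversing the ranking. The package keeps $\varepsilon$
symbolic and verifies the closed-form identities exactly;
`realize_epsilon()` then picks a concrete $\varepsilon = 2^{-k}$ small
enough that the numeric tree verifies identically, so emitted Newick files
are self-contained evidence.

Two deviations from the source procedure, both forced by implementation:

1. *The event deletes all isolated leaves*, per the sufficiency statement
   — the weaker necessity bound (all but one) leaves a spared isolated
   leaf score-fixed under ES and the construction cannot work.
2. *The $k\varepsilon$ bookkeeping does not always separate the $\Delta$
   values.* On trees where two sibling pendant subtrees are isomorphic and
   carry the event's survivors in corresponding positions, with every
   coefficient change confined to shared ancestral edges (this happens for
   ES, whose ratios never react to the deletions inside those subtrees),
   the two survivors' $\Delta$s agree *as linear functionals of the
   lengths*. The constructor first retries with generically distinct
   $\varepsilon$-coefficients (powers of two per edge — unchanged
   $\varepsilon \to 0$ limits); if the tie survives that, it is genuine:
   the pair can never strictly flip under any length assignment, the
   claimed strict reversal does not exist for that tree and event, and a
   dedicated `divindex_inseparable` error is raised. The constructed
   lengths do still reverse every other pair (a valid *relaxed* reversal).
   About 1% of seeded random binary trees with $n \le 14$ hit this class,
   and the corresponding acceptance property is deliberately left failing
   on such seeds rather than excluded: the defect is in the source result,
   and hiding it would misstate what the package can certify.

**Non-rigid interior indices** (`theorem5_construct()`): delete only all
but one leaf per interior vertex. Lengths are assembled bottom-up: each
vertex's first child block is given a short stem (half the block's minimal
score gap), its $2m$ combined before/after survivor scores are made
pairwise distinct by exactly-computed edge extensions
(`lemma4_perturb()` — self-coincidences extend an edge whose coefficient
changes after pruning, which is where non-rigidity enters; cross-
coincidences extend the leaf's own pendant; candidate amounts are halved
until no new coincidence appears and no strict order breaks), and every
further block is scaled by $\delta/(2\max\Sigma_b)$ into the gap $\delta$
between the lower and upper half of the chain and shifted there by adding
the gap floor to its pendant edges, the possibly-single-leaf block last.
Dead leaves get pendants strictly shorter than their surviving sibling's,
and a final pass halves dead pendants (each adjustment moves only that
leaf's score) until the full pre-extinction ranking is strict — so the
top-ranked species of the original tree is always a survivor, which the
certificate checks.

Both constructions end in `verify_reversal()`, which recomputes both score
vectors from scratch through the index framework and never trusts
construction-side bookkeeping.

## The ultrametric setting

`generate_U(n)` builds, for even $n \ge 6$, the clock-like family member
with $m = n/2$ nested cherries: spine edges 1, cherry stems $n - 2i$,
pendants $i$ (the two deepest cherries both at $m-1$), every root-to-leaf
distance $n-1$. Deleting the even-indexed leaves reverses both FP and ES
in the relaxed sense. Only the 12-leaf instance's scores are published;
the internal lengths here are a reconstruction pinned by reproducing all
24 published cells at 3 d.p., and the extension to other $n$ is a
family-extrapolation property (tested for $n = 6 \dots 16$, flagged as
such). Necessary conditions: `check_prop10()` (a surviving non-cherry
leaf's whole out-group must be extinct) and `check_cor11()` (every leaf
must be in a cherry for one-per-cherry reversals); whether the converse
holds is open, and the checkers claim necessity only.

## Synthetic data

`synthetic_tree(n, seed, mode)` provides the random instances for the
property suites: `binary` grows a topology by random leaf attachment
(spanning balanced to caterpillar-like shapes), `multifurcating`
contracts internal edges with probability 1/3, `ultrametric` draws
integer node heights (exactly clock-like by construction), `caterpillar`
is deterministic in shape. Edge lengths are rationals $k/d$ with
$k \le 36$, $d \le 4$ — order-unity branch lengths like the published
examples, chosen once and not tuned. The generator emulates topology and
branch-length variety only; it does not emulate real phylogenies'
birth–death branch-length correlations or taxon sampling, so a green
property establishes correctness of the algorithms on diverse shapes, not
calibration to empirical trees. Generation restores the caller's RNG
state, and the same seed always returns the same tree.

## Numerical and design choices

* Survivor-per-group and witness sets use natural label order
  (`x2 < x10`); the published example's deletions follow this convention.
* `theorem9_construct(M = "auto")` starts at twice the edge count and
  doubles on failure; $M = 32$ reproduces the published worked table.
* Perturbation and realization loops halve their candidate values with
  generous iteration caps (collisions are zeros of finitely many linear
  functions, so halving always escapes); caps raise informative errors
  rather than looping.
* Ultrametricity is tested by exact equality of root-to-leaf sums — no
  tolerance. Imported empirical trees with near-clock lengths should be
  rounded by the caller first, deliberately outside this package's scope.
* Degenerate inputs: single-leaf trees score zero; two-leaf trees give the
  trivial one-survivor reversal; out-degree-1 vertices are rejected on
  input but tolerated internally (pruned roots, partially assembled
  subtrees) where they pass their full share through.

## Known limitations

* `rigidity_probe()` cannot prove non-rigidity, only fail to find a
  witness up to its bound.
* The `theta` index exists only on the shape classes of its defining
  11-leaf tree (plus cherries); elsewhere it errors by design.
* The strict Theorem-9-style claim fails on the inseparable class
  described above; the package detects and reports this rather than
  working around it.
* No search for globally minimal reversing extinction sets is attempted
  (posed as open for the ultrametric case); the tooling reports
  necessary conditions only.
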