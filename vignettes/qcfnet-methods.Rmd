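---
title: "qcfnet: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qcfnet: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcfnet)
```

## The model

`qcfnet` works with binary level-1 phylogenetic networks: every internal
tree node has degree 3, hybrid nodes have two parents carrying inheritance
probabilities $\gamma$ and $1-\gamma$, and no two cycles of the underlying
undirected graph share a node.  Under the network multispecies coalescent
(NMSC), gene lineages sampled at the leaves are traced backward in time;
within an edge of length $t$ coalescent units each pair of co-resident
lineages coalesces at rate 1, and at a hybrid node each lineage
independently follows a parent edge with probability $\gamma$.  The quartet
concordance factor $CF_{ab|cd}$ is the probability that the resulting gene
tree displays the quartet $ab|cd$; the three CFs of a quartet sum to one.
Reparameterizing by edge probabilities $\ell = e^{-t} \in (0,1]$ makes every
CF a polynomial with rational coefficients in the $\ell$s and $\gamma$s, and
CF tables depend only on the induced semidirected network (everything above
the least stable ancestor, and the root position, is invisible).

## The exact engine

CFs are computed by a dynamic program over a topologically ordered rooted
version of the induced 4-taxon network.  The state assigns each sampled
lineage to the node it has reached.  Three facts make the program exact and
small:

1. all lineages enter an edge at its child node, so any two lineages in the
   same edge are co-resident for its entire length; with $j$ lineages the
   probability of no coalescence is $\ell^{\binom j2}$ and the first merging
   pair is uniform among the $\binom j2$ pairs;
2. the first coalescence among the four sampled lineages determines the
   gene quartet, so any merge resolves the computation;
3. if all four lineages reach the root unresolved, exchangeability gives
   each quartet probability $1/3$ (at a hybrid node, the $2^j$ parent
   assignments are summed with their $\gamma$-weights; when two pairs sit in
   the two parent edges simultaneously, a merge in either edge yields the
   same split, which the transition accounts for jointly).

The program is written against a small ring interface, so identical code
produces doubles, exact rationals, values in a prime field GF($p$), or
multivariate polynomials (used for the symbolic statistics and the
Jacobians).  The within-edge merge-sequence distribution is also available
in closed form (`edge_transition`), derived once by exact convolution of the
competing exponentials.

## Exact arithmetic without big integers

Arbitrary-precision integers are not among the package's dependencies, so
exact rationals are stored as reduced fractions in doubles with a hard guard
at $2^{53}$: any operation that would lose exactness raises an error rather
than rounding.  Random rational parameter draws therefore default to dyadic
rationals with denominator 32, for which every intermediate of the engine
stays below the guard even for degree-10 CF polynomials.  Where the
magnitudes genuinely exceed the guard — the published 3-cycle
indistinguishability point, whose CF table has denominators near $10^{13}$,
and the cleared-denominator Jacobian minors — identities are certified by
modular arithmetic instead: the whole computation is repeated in GF($p$) for
two independent primes near $6.7\times10^7$ (squares still exact in
doubles).  Agreement of a rank or an equality across independent primes and
parameter points is the standard computer-algebra certificate: a nonzero
minor mod $p$ certifies a rank lower bound exactly, and the probability that
two unequal rationals of this size collide modulo two such primes is
vanishingly small.  Jacobian ranks are computed from symbolic derivatives of
the CF polynomials, evaluated at fixed generic rational points (distinct
primes over 100) and eliminated over GF($p$), then confirmed at a perturbed
second point.

## Detection statistics and classification

For a (2,2,1) partition of five taxa around a candidate node the package
evaluates $f_{abc} = 3\,CF_{ab|ac}CF_{ab|bc} - CF_{ab|ab}$, which vanishes
identically on the tree, is strictly positive when the singleton descends
from a 3-cycle's hybrid node, and takes either sign when a pair block does;
$\tilde f = f_{abc} - CF_{ab|ab}/2$ is strictly negative whenever a pair
block is hybrid, so a positive value pins the singleton.  For (2,2,2)
partitions the three bilinear $G$ statistics satisfy
$G_{abc}+G_{cab}+G_{bca}=0$ on every table and vanish on the three-cherry
tree, while $G_{xyz}>0$ when block $x$ is hybrid; the sign pattern
classifies the node as tree-like, hybrid-identified, or hybrid-ambiguous
between the two positive blocks.  In empirical mode the statistics are
averaged over the exchangeable subscript assignments and compared to zero at
a configurable tolerance; the package makes no attempt at calibrated
hypothesis tests beyond this multinomial-standard-error wrapper.

A 4-cycle's hybrid placement relative to a 2-taxon block (same node,
adjacent, or opposite) is decided by bounded least-squares fits of the three
candidate exact CF parameterizations (precomputed symbolically, evaluated by
fast monomial matrices, multistart seeded).  The candidate varieties nest,
so candidates are fitted in increasing dimension and membership in a smaller
variety takes precedence; the printed extra generators of the three
degenerate components of the intersection are evaluated as evidence.  The
residual threshold (1e-8 for exact input) and the 20-start default are
design choices: the ideal-membership test they approximate requires
generators that are not available in closed form.

## Parameter identification

All recovery formulas are rational in the CFs, so exact tables give exact
estimates.  The routes, in the order the orchestrator applies them:
internal edges that are neither hybrid nor adjacent to a hybrid edge are
*defined* by a quartet whose induced internal edge is exactly that edge
(checked structurally via edge provenance through restriction), giving
$t = -\log(3\,CF_{\text{discordant}})$; $k$-cycles with $k\ge5$ yield
$\gamma$ and the hybrid-adjacent cycle edges from differences of CF entries
over one-per-block representatives; a 4-cycle with a 2-taxon block adjacent
to the hybrid block yields $W=(M_1-M_0)/D$ and then $x$, $\gamma$ from the
pair-block combinations; given $\gamma,x_1,x_2$, the hybrid-edge lengths and
the edge below the hybrid node come from a linear $3\times3$ solve; the
opposite-pair (north-cherry) configuration has its own closed form in which
$\gamma$ enters linearly; and an edge joining two 4-cycles is recovered as
$\ell = W_A W_B / (3\,CF_{\text{cross}})$, each projection seeing $\ell$
times the other side's pair-passage factor.  Parameters around 3-cycles and
pendant edges are labelled not-identifiable/inert, matching the audit; the
audit also reports that with two samples per taxon the pendant and 4-cycle
exceptions lift.  Where the underlying propositions allow several
representative choices the implementation takes the lexicographically first
in exact mode and averages in empirical mode.

## The simulator and what a green test establishes

`empirical_cf_table` draws gene trees by exponential racing within edges,
Bernoulli($\gamma$) routing at hybrid nodes, and uniform exchangeable
pair-merging above the root (topology-equivalent to racing and cheaper,
since only topology probabilities enter CFs).  Each tree gets its own RNG
stream derived from the master seed, so runs are bit-reproducible.  The
generator emulates gene-tree *topologies* under the NMSC only: it does not
model sequence evolution, gene-tree estimation error, missing data, or
linkage between genes, so agreement between empirical and exact CFs
validates the engine's algebra, not the realism of CF estimates from
sequence data.  Pseudotaxon expansion (`add_pseudotaxa`) reduces
multi-sample inputs to the single-sample case; the cherry edges it adds
carry no length and permit no coalescence.

## Numerical choices and degenerate inputs

Sum-to-one is exact in rational/modular mode and checked to 1e-12 in float
mode.  Division-based recovery formulas raise on degenerate denominators
(e.g. a cycle edge with $y=1$); `edge_length_from_quartet` flags discordant
CFs above $1/3$ and returns negative lengths only in extended mode, which is
also the mode used internally for 3-cycle contraction adjustments and never
reported as a final estimate.  The internal rooting of a semidirected
network is the first valid rooting in a fixed edge order; CF tables are
rooting-invariant, so the choice is unobservable (and tested to be).

## Stated world of the fixtures

The named fixture networks reproduce the published figures' topologies with
their labelled parameter roles; edges on which no coalescence can occur
(pendant edges, hybrid edges over singleton hybrid blocks, pseudotaxon
cherries) carry no parameters.  Random parameter draws are uniform dyadic
rationals on [0.05, 0.95] (denominator 32 unless a deeper network requires
16 or a GF($p$) run allows 64/256) — uniform draws on the unit interval are
the published simulation design, and the dyadic grid is the exactness
compromise described above.  The two-cycles-joined fixtures reconstruct the
prose description of the joined-4-cycle figures; the extracted text does not
fully specify the middle variant, which this package fixes as the
child-opposite-the-second-hybrid configuration.  The published
indistinguishability example is instantiated by solving the six p-vector
fiber equations exactly with $\ell_2 = 1/2$ pinned, reproducing the
published rotated parameters ($\gamma_b = 236700/253367$, etc.); the
load-bearing claim — equality of the two CF tables — is asserted in two
prime fields rather than transcribed from the (typographically ambiguous)
printed fractions.

## Known limitations

* Level-2+ networks are rejected, not analyzed; non-binary nodes are errors.
* The A/B/C/D decomposition is implemented for 3-cycles only; larger cycles
  go through the generic dynamic program.
* The 4-cycle orientation test is a numerical fit, not an exact
  ideal-membership test; points on the measure-zero degenerate locus can be
  reported as ambiguous.
* Exact rational mode is bounded by the $2^{53}$ guard; beyond it the
  package certifies identities modularly rather than producing big-integer
  fractions.
* Rational formulas evaluated on noisy empirical tables are estimators of
  convenience: estimates outside valid ranges are clipped with a warning,
  and no confidence intervals are provided.
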