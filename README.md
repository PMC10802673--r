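# qcfnet

Exact quartet concordance factors and identifiability analysis on level-1
phylogenetic networks.

## The problem

When hybridization or other lateral gene transfer has occurred, species
relationships form a *network* rather than a tree, and individual gene trees
differ both because of incomplete lineage sorting (modelled by the coalescent)
and because lineages can take either parental path at a hybrid node.  Methods
such as SNaQ and NANUQ summarize gene trees by their **quartet concordance
factors** (CFs): for each set of four taxa `{a,b,c,d}`, the probabilities

    CF_abcd = ( CF_ab|cd , CF_ac|bd , CF_ad|bc ),   summing to 1,

that a gene tree displays each unrooted quartet.  Under the **network
multispecies coalescent (NMSC)** on a binary level-1 network, every scalar CF
is a polynomial in the edge probabilities `l = exp(-t)` (`t` = branch length
in coalescent units) and the inheritance probabilities `gamma` of the hybrid
edges.  This package is for people who want to know — exactly — what those
polynomials are, which network features and numerical parameters they do or
do not determine, and how to compute both directions:

* **forward**: exact CF tables (floating point, exact rational, modular
  GF(p), or fully symbolic) for any binary level-1 network, plus a
  Monte-Carlo NMSC gene-tree simulator for cross-validation;
* **inverse**: algebraic and semialgebraic statistics that detect 3-cycles
  (`f_abc = 3 CF_ab|ac CF_ab|bc - CF_ab|ab`, the three bilinear `G`
  statistics, and `f~ = f - CF_ab|ab/2`), a fitting-based test for the
  placement of the hybrid node in a 4-cycle, closed-form recovery of every
  identifiable edge length and inheritance probability, and a network-wide
  identifiability audit (2-cycles: never identifiable; 3-cycles: cycle yes,
  hybrid node only sometimes; 4-cycles: case-by-case; larger cycles: fully,
  up to inert hybrid edges).

## A worked example

```r
library(qcfnet)

# a 4-taxon species tree with one internal edge of 0.5 coalescent units
net <- parse_network("(((a:1.0,b:1.0):0.5,c:2.0):1.0,d:3.0);")
sapply(quartet_cf(net)$cf, rr_tonum)
#> [1] 0.5956462 0.2021769 0.2021769
# = (1 - 2 l/3, l/3, l/3) with l = exp(-0.5): the two discordant quartets
# each appear with probability exp(-0.5)/3 ~ 0.202.

# a 6-taxon network with a central 3-cycle, exact rational parameters
pars <- random_params("Na", seed = 5)        # dyadic rationals, seeded
tab  <- cf_table(make_named("Na"), params = pars)
g <- g_statistics(tab, list(A = c("a1","a2"), B = c("b1","b2"), C = c("c1","c2")))
sapply(g, rr_tonum)
#>          Gabc          Gcab          Gbca
#>  6.227789e-04 -6.978284e-04  7.504947e-05
classify_three_cycle(tab, list(A = c("a1","a2"), B = c("b1","b2"), C = c("c1","c2")))
#> 3-cycle call: 3-cycle-hybrid-ambiguous (hybrid: A/B)
# Gabc > 0 so block A (the true hybrid) is admissible; Gbca > 0 keeps B in
# play and the negative Gcab rules out C -- exactly the two-positive case of
# the sign table.  For other parameter values only one G is positive and the
# hybrid is pinned down uniquely.

# closed-form parameter recovery on a 6-taxon 4-cycle network: exact in,
# exact out
pars <- random_params("Nsw", seed = 7)
est  <- recover_parameters(make_named("Nsw"), cf_table(make_named("Nsw"), params = pars))
rr_tonum(est$gamma$value); rr_tonum(pars$gamma)
#> [1] 0.34375
#> [1] 0.34375                       # recovered exactly (same rational)
```

## Command line

```sh
Rscript inst/cli/qcfnet.R cftable  --network net.enewick --out cf.csv
Rscript inst/cli/qcfnet.R simulate --network net.enewick --reps 100000 --seed 7 --out emp.csv
Rscript inst/cli/qcfnet.R classify3 --cf cf.csv --blocks a1,a2/b1,b2/c1,c2
Rscript inst/cli/qcfnet.R identify --topology net.enewick --cf cf.csv --out params.json
Rscript inst/cli/qcfnet.R audit    --network net.enewick
```

Networks are extended Newick with `#H` hybrid tags and
`:length:support:gamma` fields; CF tables are CSV
(`taxon1..taxon4, CF12_34, CF13_24, CF14_23[, ngenes]`), optionally with
exact fraction entries such as `2989/30000`.

## Documentation

The methods vignette (`vignettes/qcfnet-methods.Rmd`) describes the model,
the exact-arithmetic design (including the modular-arithmetic certificates
used where rationals exceed the 2^53 double guard), what the simulator does
and does not emulate, and the known limitations.
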