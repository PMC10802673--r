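# Closed-form recovery of identifiable numerical parameters from CF tables,
# and the network-wide identifiability audit.
#
# All recovery formulas are rational functions of CF entries, so exact
# rational CF input yields exact rational estimates.  The routes:
#   * internal edges defined by 4 taxa:  t = -log(3 CF_discordant);
#   * k-cycles (k >= 5): gamma and the hybrid-adjacent cycle edges from
#     differences of CF entries over one-per-block representatives;
#   * 4-cycles with a 2-taxon block adjacent to the hybrid block: gamma and
#     both hybrid-adjacent cycle edges from the pair-block combinations
#     (W = (M1 - M0)/D, then x = M0/W);
#   * hybrid-edge lengths and the edge below the hybrid node, given gamma,
#     x1, x2: a linear 3x3 solve for (l1 g^2 h1, l1 (1-g)^2 h2, l1);
#   * a 4-cycle with the 2-taxon block opposite the hybrid: a dedicated
#     closed form in which gamma appears linearly;
#   * an edge joining two 4-cycles: l = W_A W_B / (3 CF_cross), the
#     two-projection scheme.

#' Edge length from a defining quartet
#'
#' For an edge defined by 4 taxa inducing the split ab|cd, the discordant CF
#' is exp(-t)/3, so t = -log(3 CF_discordant).
#'
#' @param tab a `cf_table`
#' @param quartet four taxon labels (a, b, c, d with ab|cd the edge's split)
#' @param tol tolerance for the validity checks
#' @param extended allow negative recovered lengths
#' @return a `param_estimate` list: value (ell, ring element), t, status,
#'   provenance
#' @export
edge_length_from_quartet <- function(tab, quartet, tol = 1e-9, extended = FALSE) {
  disc <- cf_entry(tab, quartet[1], quartet[3], quartet[2], quartet[4])
  ell <- rr_mul(rr_fromint(disc, 3), disc)
  elln <- rr_tonum(ell)
  if (elln <= 0) stop("discordant CF must be positive")
  if (elln > 1 + tol && !extended)
    stop("discordant CF exceeds 1/3: no valid nonnegative length (use extended mode)")
  list(value = ell, t = -log(elln),
       status = "identified", provenance = "edge defined by 4 taxa")
}

# D-statistics of a 4-cycle (or k-cycle) from one-per-block representatives:
#   D1 = CF_{h s1|o s2} - CF_{h o|s1 s2} = gamma (1 - x1)
#   D2 = CF_{h s2|s1 o} - CF_{h o|s1 s2} = (1 - gamma)(1 - x2)
# h: hybrid-block rep; s1: gamma-side adjacent block rep; o: opposite-side
# rep; s2: other adjacent block rep.
.cycle_D <- function(tab, h, s1, o, s2) {
  base <- cf_entry(tab, h, o, s1, s2)
  list(D1 = rr_sub(cf_entry(tab, h, s1, o, s2), base),
       D2 = rr_sub(cf_entry(tab, h, s2, s1, o), base))
}

# pair-block combinations: pair p,q in an adjacent block; on side 2:
#   M0 = 3 CF_{p s1|q o} = x2 W,  M1 = 3 CF_{p h|q o} = (1 - g(1-x2)) W
# where W = (effective pair passage) and M1 - M0 = D2 W; mirrored on side 1.
.pair_M <- function(tab, h, single, o, p, q) {
  three <- function(x) rr_mul(rr_fromint(x, 3), x)
  list(M0 = three(cf_entry(tab, p, single, q, o)),
       M1 = three(cf_entry(tab, p, h, q, o)))
}

# gamma, x1, x2 of a 4-cycle from a pair block adjacent to the hybrid block.
# side = 2 when the pair block is opposite the gamma-side edge, 1 otherwise.
.fourcycle_pair_recovery <- function(tab, h, s1, o, s2, pair, side) {
  one <- rr_fromint(cf_entry(tab, h, o, s1, s2), 1)
  D <- .cycle_D(tab, h, s1, o, s2)
  if (side == 2) {
    M <- .pair_M(tab, h, s1, o, pair[1], pair[2])
    W <- .rdiv(rr_sub(M$M1, M$M0), D$D2)
    x2 <- .rdiv(M$M0, W)
    g <- rr_sub(one, .rdiv(D$D2, rr_sub(one, x2)))
    x1 <- rr_sub(one, .rdiv(D$D1, g))
  } else {
    M <- .pair_M(tab, h, s2, o, pair[1], pair[2])
    W <- .rdiv(rr_sub(M$M1, M$M0), D$D1)
    x1 <- .rdiv(M$M0, W)
    g <- .rdiv(D$D1, rr_sub(one, x1))
    x2 <- rr_sub(one, .rdiv(D$D2, rr_sub(one, g)))
  }
  list(gamma = g, x1 = x1, x2 = x2, W = W)
}

# exact division in any ring with a multiplicative inverse for qq / numerics;
# for qq divide exactly, for doubles plain division
.rdiv <- function(a, b) {
  if (inherits(a, "qq") || inherits(b, "qq")) {
    if (b$n == 0) stop("degenerate division in recovery formula")
    rr_mul(a, structure(qreduce(b$d, b$n), class = "qq"))
  } else if (inherits(b, "gfp")) {
    rr_mul(a, gfp(.gfp_inv(b$v, b$p), b$p))
  } else {
    if (abs(b) < 1e-14) stop("degenerate division in recovery formula")
    a / b
  }
}

# Given gamma, x1, x2 and the three pair-over-hybrid-block equations
#   E1 = a + x2 b + w (3 - x1) L        (pair with s1 and o)
#   E2 = x1 a + b + w (3 - x2) L        (pair with s2 and o)
#   E3 = a + b + w (3 - x1 x2) L        (pair with s1 and s2)
# solve for a = L g^2 h1, b = L (1-g)^2 h2, L = l1 (Cramer, exact).
.solve_abl <- function(E1, E2, E3, g, x1, x2) {
  one <- rr_fromint(g, 1); three <- rr_fromint(g, 3)
  w <- rr_mul(g, rr_sub(one, g))
  M <- list(
    list(one, x2, rr_mul(w, rr_sub(three, x1))),
    list(x1, one, rr_mul(w, rr_sub(three, x2))),
    list(one, one, rr_mul(w, rr_sub(three, rr_mul(x1, x2)))))
  b <- list(E1, E2, E3)
  det3 <- function(M) {
    rr_add(rr_sub(rr_mul(M[[1]][[1]], rr_sub(rr_mul(M[[2]][[2]], M[[3]][[3]]),
                                             rr_mul(M[[2]][[3]], M[[3]][[2]]))),
                  rr_mul(M[[1]][[2]], rr_sub(rr_mul(M[[2]][[1]], M[[3]][[3]]),
                                             rr_mul(M[[2]][[3]], M[[3]][[1]])))),
           rr_mul(M[[1]][[3]], rr_sub(rr_mul(M[[2]][[1]], M[[3]][[2]]),
                                      rr_mul(M[[2]][[2]], M[[3]][[1]]))))
  }
  D <- det3(M)
  rep_col <- function(j) {
    Mj <- M
    for (i in 1:3) Mj[[i]][[j]] <- b[[i]]
    det3(Mj)
  }
  alpha <- .rdiv(rep_col(1), D)
  beta <- .rdiv(rep_col(2), D)
  lambda <- .rdiv(rep_col(3), D)
  g2 <- rr_mul(g, g); og2 <- rr_mul(rr_sub(one, g), rr_sub(one, g))
  list(alpha = alpha, beta = beta, l1 = lambda,
       h1 = .rdiv(alpha, rr_mul(lambda, g2)),
       h2 = .rdiv(beta, rr_mul(lambda, og2)))
}

# closed-form recovery for a 4-cycle whose 2-taxon block sits opposite the
# hybrid block (Nsn shape); all parameters including gamma are rational in
# the CFs (gamma enters the final relation linearly).
.nsn_recovery <- function(tab, apair, bpair, s1, s2) {
  a1 <- apair[1]; a2 <- apair[2]; b1 <- bpair[1]; b2 <- bpair[2]
  one <- rr_fromint(cf_entry(tab, a1, a2, b1, b2), 1)
  two <- rr_fromint(one, 2); three <- rr_fromint(one, 3)
  l2 <- rr_mul(three, cf_entry(tab, b1, s1, b2, s2))
  A1 <- rr_sub(one, .rdiv(rr_mul(three, cf_entry(tab, a1, b1, b2, s1)), l2))
  A2 <- .rdiv(rr_mul(three, cf_entry(tab, a1, b1, b2, s2)), l2)
  E1 <- rr_mul(three, cf_entry(tab, a1, b1, a2, s1))
  E2 <- rr_mul(three, cf_entry(tab, a1, b1, a2, s2))
  E3 <- rr_mul(three, cf_entry(tab, a1, s1, a2, s2))
  E4 <- .rdiv(rr_mul(three, cf_entry(tab, a1, b1, a2, b2)), l2)
  S <- rr_sub(rr_add(E1, E2), rr_add(E3, E4))
  lam <- .rdiv(S, rr_mul(A1, rr_sub(one, A2)))
  U1 <- rr_sub(E3, E2); U2 <- rr_sub(E3, E1)
  numer <- rr_sub(rr_add(E4, U1),
                  rr_add(.rdiv(rr_mul(A2, U2), rr_sub(one, A2)),
                         rr_mul(rr_mul(two, lam), rr_mul(A1, A2))))
  denom <- rr_sub(rr_sub(.rdiv(U1, A1), .rdiv(U2, rr_sub(one, A2))),
                  rr_mul(rr_mul(two, lam), rr_sub(rr_add(A1, A2), one)))
  g <- .rdiv(numer, denom)
  x1 <- rr_sub(one, .rdiv(A1, g))
  x2 <- .rdiv(rr_sub(A2, g), rr_sub(one, g))
  alpha <- rr_sub(.rdiv(rr_mul(g, U1), A1), rr_mul(lam, rr_mul(g, rr_sub(A2, g))))
  beta <- rr_sub(.rdiv(rr_mul(rr_sub(one, g), U2), rr_sub(one, A2)),
                 rr_mul(lam, rr_mul(rr_sub(one, g), rr_sub(g, A1))))
  g2 <- rr_mul(g, g); og2 <- rr_mul(rr_sub(one, g), rr_sub(one, g))
  list(gamma = g, x1 = x1, x2 = x2, l1 = lam, l2 = l2,
       h1 = .rdiv(alpha, rr_mul(lam, g2)),
       h2 = .rdiv(beta, rr_mul(lam, og2)))
}

#' Numerical parameters of a k-cycle (k >= 5) from CFs
#'
#' Implements the sunlet identities: with y the (quartet-identified) product
#' of the cycle edges between the chosen non-adjacent blocks,
#' gamma = (CF_ac|de - CF_ad|ce)/(1 - y), and the hybrid-adjacent cycle
#' edges follow from x = 1 - D/gamma.  Hybrid edge lengths are recovered via
#' the 4-cycle reduction only when the hybrid block has >= 2 taxa, else
#' reported inert.
#'
#' @param tab a `cf_table`
#' @param cyc a cycle record from [find_cycles()]
#' @param net the network the cycle belongs to
#' @return list of `param_estimate`s keyed by edge role (or edge endpoints)
#' @export
sunlet_cycle_params <- function(tab, cyc, net) {
  k <- cyc$m
  stopifnot(k >= 5)
  reps <- vapply(cyc$blocks, function(b) b[1], "")
  one <- rr_fromint(cf_entry(tab, reps[1], reps[2], reps[3], reps[4]), 1)
  # gamma side: the hybrid edge whose parent is cyc$block_nodes[2]
  # (cycle order starts at the hybrid node)
  hedges <- cyc$edges[net$edges$hybrid[cyc$edges]]
  gside_edge <- hedges[net$edges$n1[hedges] == cyc$block_nodes[2]]
  # y: cycle edge(s) between blocks 3 and k-? -- use blocks 3 and 4
  h <- reps[1]; r2 <- reps[2]; r3 <- reps[3]; r4 <- reps[4]; rk <- reps[k]
  y <- rr_mul(rr_fromint(one, 3), cf_entry(tab, r2, r4, r3, rk))
  # y: the single cycle edge between the 3rd and 4th blocks, defined by the
  # quartet {r2, r3, r4, rk}
  Dk <- .cycle_D(tab, h, r3, r4, rk)    # D1 = g(1-y), D2 = (1-g)(1-z_{k-1})
  g <- .rdiv(Dk$D1, rr_sub(one, y))
  D <- .cycle_D(tab, h, r2, r3, rk)     # D1 = g(1-z_2)
  x1 <- rr_sub(one, .rdiv(D$D1, g))
  xk <- rr_sub(one, .rdiv(Dk$D2, rr_sub(one, g)))
  est <- list()
  put <- function(edge, value, status, prov) {
    rl <- net$roles[[edge]]
    nm <- if (length(rl) == 1) rl else paste0("edge_", net$edges$n1[edge], "_",
                                              net$edges$n2[edge])
    est[[nm]] <<- list(value = value, status = status, provenance = prov)
  }
  # cycle tree edge between block_nodes[2] and [3] is x1; [k] and [k-1]... x2
  tree_edge_between <- function(i, j) {
    v1 <- cyc$block_nodes[i]; v2 <- cyc$block_nodes[j]
    e <- cyc$edges[(net$edges$n1[cyc$edges] == v1 & net$edges$n2[cyc$edges] == v2) |
                   (net$edges$n2[cyc$edges] == v1 & net$edges$n1[cyc$edges] == v2)]
    e[!net$edges$hybrid[e]]
  }
  hedges2 <- setdiff(hedges, gside_edge)
  gq <- .gamma_value_for(net, gside_edge, hedges2, g)
  est[[gq$name]] <- list(value = gq$value, status = "identified",
                         provenance = "k-cycle inheritance probability")
  put(tree_edge_between(2, 3), x1, "identified", "cycle edge adjacent to hybrid edge")
  put(tree_edge_between(k, k - 1), xk, "identified", "cycle edge adjacent to hybrid edge")
  hyb_lengths_status <- if (cyc$k >= 2) "identified" else "inert"
  if (cyc$k >= 2) {
    # reduce to the 4-cycle on {a1, a2, r2, r3, rk}: x2 of that cycle is the
    # product of the remaining cycle edges
    ap <- cyc$blocks[[1]][1:2]
    three <- rr_fromint(one, 3)
    E1 <- rr_mul(three, cf_entry(tab, ap[1], r2, ap[2], r3))
    E2 <- rr_mul(three, cf_entry(tab, ap[1], r3, ap[2], rk))
    E3 <- rr_mul(three, cf_entry(tab, ap[1], r2, ap[2], rk))
    xprod <- one
    for (i in 3:(k - 1)) {
      e <- tree_edge_between(i, i + 1)
      # all interior cycle edges are quartet-defined; recover each
      qd <- rr_mul(three, cf_entry(tab, reps[i - 1], reps[i + 1], reps[i], reps[1]))
      xprod <- rr_mul(xprod, qd)
    }
    sol <- .solve_abl(E1, E2, E3, g, x1, xprod)
    for (e in hedges) {
      val <- if (net$edges$n1[e] == cyc$block_nodes[2]) sol$h1 else sol$h2
      put(e, val, "identified", "hybrid edge length via 4-cycle reduction")
    }
    cut_e <- setdiff(.inc(net, cyc$hybrid_node), cyc$edges)
    put(cut_e, sol$l1, "identified", "edge below hybrid node via 4-cycle reduction")
  } else {
    for (e in hedges) put(e, NULL, "inert",
                          "hybrid edge with single descendant: no coalescence")
  }
  est
}

#' Prop-style case label of a 4-cycle
#'
#' Cases by the block sizes (nA the hybrid block; B, D adjacent; C opposite)
#' and whether the child of the edge below the hybrid node lies in a
#' 3-cycle: a and b-i identify nothing; b-ii identifies x1, x2, gamma; c-i
#' everything; c-ii everything but the edge below the hybrid node.
#'
#' @param net a `qcf_net`
#' @param cyc a 4-cycle record
#' @return list(case, identifiable, not_identifiable)
#' @export
four_cycle_case <- function(net, cyc) {
  stopifnot(cyc$m == 4)
  nA <- length(cyc$blocks[[1]])
  nB <- length(cyc$blocks[[2]])
  nC <- length(cyc$blocks[[3]])
  nD <- length(cyc$blocks[[4]])
  base <- c("x1", "x2", "h1", "h2", "gamma", "l")
  child_in_3cycle <- FALSE
  cut_e <- setdiff(.inc(net, cyc$hybrid_node), cyc$edges)
  if (length(cut_e) == 1) {
    child <- setdiff(c(net$edges$n1[cut_e], net$edges$n2[cut_e]), cyc$hybrid_node)
    for (c2 in find_cycles(net)) {
      if (c2$m == 3 && child %in% c2$nodes) child_in_3cycle <- TRUE
    }
  }
  if (nB == 1 && nC == 1 && nD == 1) {
    list(case = "a", identifiable = character(0), not_identifiable = base)
  } else if (nA == 1 && nB == 1 && nD == 1) {
    list(case = "b-i", identifiable = character(0), not_identifiable = base)
  } else if (nA == 1) {
    list(case = "b-ii", identifiable = c("x1", "x2", "gamma"),
         not_identifiable = c("h1", "h2", "l"))
  } else if (!child_in_3cycle) {
    list(case = "c-i", identifiable = base, not_identifiable = character(0))
  } else {
    list(case = "c-ii", identifiable = setdiff(base, "l"),
         not_identifiable = "l")
  }
}

#' Effective cherry probability of a contracted 3-cycle
#'
#' z = gamma^2 h1 + (1-gamma)^2 h2 + gamma (1-gamma)(3 - x); when z <= 1 the
#' 3-cycle's CFs are mimicked by a tree cherry of probability z; z > 1 flags
#' a (potentially) anomalous, hence detectable, 3-cycle.
#'
#' @param gamma,h1,h2,x numeric parameters
#' @return list(z, anomalous)
#' @export
effective_cherry_z <- function(gamma, h1, h2, x) {
  z <- gamma^2 * h1 + (1 - gamma)^2 * h2 + gamma * (1 - gamma) * (3 - x)
  list(z = z, anomalous = z > 1)
}

## ---- the audit --------------------------------------------------------------

#' Identifiability audit of a level-1 network
#'
#' Reports, per cycle and per edge, what is identifiable from quartet CFs
#' with the given number of samples per taxon: 2-cycles never; 3-cycles by
#' the induced block partition; 4-cycles by the case table; k-cycles (k >= 5)
#' fully except hybrid-edge lengths over singleton hybrid blocks; pendant
#' edges inert.  With >= 2 samples per taxon, the pendant and 4-cycle
#' exceptions lift.
#'
#' @param net a `qcf_net`
#' @param samples_per_taxon assumed number of sampled individuals per taxon
#' @return an `identifiability_report`
#' @export
identifiability_audit <- function(net, samples_per_taxon = 1) {
  if (net$rooted) net <- to_semidirected(net)
  ed <- net$edges
  cycles <- find_cycles(net)
  multi <- samples_per_taxon >= 2
  eff_block <- function(b) length(b) * samples_per_taxon
  cyc_reports <- lapply(cycles, function(cyc) {
    sizes <- vapply(cyc$blocks, eff_block, 0)
    if (cyc$m == 2) {
      list(m = 2, verdict = "never identifiable: replace by an edge (effective length)")
    } else if (cyc$m == 3) {
      n <- sum(sizes)
      v <- if (sum(sizes == 1) == 2) {
        if (sizes[1] == 1)
          "indistinguishable from contracted node and from swapped singleton"
        else
          "detectable only on a positive-measure parameter subset (z > 1)"
      } else if (sum(sizes == 1) == 1) {
        "undirected 3-cycle identifiable; hybrid node only on a positive-measure subset"
      } else {
        "undirected 3-cycle identifiable; one non-hybrid block identifiable; hybrid node only on a positive-measure subset"
      }
      list(m = 3, verdict = v)
    } else if (cyc$m == 4) {
      cs <- four_cycle_case(net, cyc)
      if (multi) cs <- list(case = paste0(cs$case, " (lifted by multi-sampling)"),
                            identifiable = c("x1", "x2", "h1", "h2", "gamma", "l"),
                            not_identifiable = character(0))
      c(list(m = 4, verdict = "orientation identifiable for generic parameters"), cs)
    } else {
      list(m = cyc$m,
           verdict = "cycle fully identifiable; hybrid edge lengths require >= 2 hybrid-block taxa",
           hybrid_lengths = if (sizes[1] >= 2) "identified" else "inert")
    }
  })
  # per-edge statuses
  cyc_edge_of <- rep(NA_integer_, nrow(ed))
  for (i in seq_along(cycles)) cyc_edge_of[cycles[[i]]$edges] <- i
  near3 <- rep(FALSE, nrow(ed))
  for (cyc in cycles) if (cyc$m == 3) {
    for (e in seq_len(nrow(ed)))
      if (ed$n1[e] %in% cyc$nodes || ed$n2[e] %in% cyc$nodes) near3[e] <- TRUE
  }
  estat <- character(nrow(ed))
  for (e in seq_len(nrow(ed))) {
    pend <- ed$n1[e] %in% net$leaves || ed$n2[e] %in% net$leaves
    if (pend) {
      estat[e] <- if (multi) "identified (multi-sample)" else "inert (pendant)"
    } else if (near3[e]) {
      estat[e] <- "not-identifiable (3-cycle)"
    } else if (!is.na(cyc_edge_of[e])) {
      cyc <- cycles[[cyc_edge_of[e]]]
      if (cyc$m == 2) estat[e] <- "not-identifiable (2-cycle)"
      else if (cyc$m == 4) {
        cs <- cyc_reports[[cyc_edge_of[e]]]
        role <- .edge_cycle_role(net, cyc, e)
        estat[e] <- if (role %in% cs$identifiable || multi) "identified"
          else "not-identifiable (4-cycle case)"
      } else {
        if (ed$hybrid[e]) {
          estat[e] <- if (eff_block(cyc$blocks[[1]]) >= 2) "identified" else
            "inert (single hybrid descendant)"
        } else estat[e] <- "identified"
      }
    } else {
      # internal cut/tree edge: identified via a defining quartet or the
      # hybrid-adjacent propositions unless next to a 3-cycle (handled above)
      adj_hyb <- any(ed$hybrid[.inc(net, ed$n1[e])]) || any(ed$hybrid[.inc(net, ed$n2[e])])
      if (!adj_hyb) estat[e] <- "identified (defining quartet)"
      else {
        # below a hybrid node or adjacent to a cycle: 4-cycle case rules
        below_hyb <- ed$n1[e] %in% .hybrid_nodes(net)
        if (below_hyb) {
          cyc <- NULL
          for (c2 in cycles) if (ed$n1[e] == c2$hybrid_node) cyc <- c2
          if (!is.null(cyc) && cyc$m == 4) {
            cs <- cyc_reports[[which(vapply(cycles, function(z)
              identical(z$hybrid_node, cyc$hybrid_node), TRUE))]]
            estat[e] <- if ("l" %in% cs$identifiable || multi) "identified"
              else "not-identifiable (4-cycle case)"
          } else estat[e] <- "identified"
        } else estat[e] <- "identified"
      }
    }
  }
  structure(list(cycles = cyc_reports,
                 edges = data.frame(n1 = ed$n1, n2 = ed$n2, hybrid = ed$hybrid,
                                    status = estat),
                 samples_per_taxon = samples_per_taxon),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat("Identifiability audit (", x$samples_per_taxon, "sample(s)/taxon )\n")
  for (cyc in x$cycles) cat("  ", cyc$m, "-cycle: ", cyc$verdict, "\n", sep = "")
  print(x$edges)
  invisible(x)
}

# role of a 4-cycle edge: x1 (gamma-side tree), x2 (other tree), h1, h2
.edge_cycle_role <- function(net, cyc, e) {
  ed <- net$edges
  if (ed$hybrid[e]) {
    if (ed$n1[e] == cyc$block_nodes[2]) "h1" else "h2"
  } else {
    if (cyc$block_nodes[2] %in% c(ed$n1[e], ed$n2[e])) "x1" else "x2"
  }
}

## ---- orchestrated recovery --------------------------------------------------

#' Recover all identifiable numerical parameters from a CF table
#'
#' Walks the network topology (assumed correct, 2-cycles already replaced)
#' and applies the closed-form routes edge by edge and cycle by cycle.
#' Every parameter is labelled; on engine-generated exact CF tables every
#' value labelled "identified" is exact.
#'
#' @param net a `qcf_net` whose edges carry parameter roles (fixture style)
#'   or numeric lengths
#' @param tab a `cf_table` for the same taxa
#' @return named list of `param_estimate`s (by role name where available)
#' @export
recover_parameters <- function(net, tab) {
  if (net$rooted) net <- to_semidirected(net)
  net <- .ensure_ids(net)
  ed <- net$edges
  cycles <- find_cycles(net)
  est <- list()
  put <- function(edge, value, status, prov) {
    rl <- net$roles[[edge]]
    nm <- if (length(rl) == 1) rl else paste0("edge_", ed$n1[edge], "_", ed$n2[edge])
    if (!is.null(est[[nm]]) && est[[nm]]$status == "identified") return(invisible())
    est[[nm]] <<- list(value = value, status = status, provenance = prov)
  }
  put_role <- function(nm, value, status, prov) {
    if (!is.null(est[[nm]]) && est[[nm]]$status == "identified") return(invisible())
    est[[nm]] <<- list(value = value, status = status, provenance = prov)
  }
  near3 <- rep(FALSE, nrow(ed))
  for (cyc in cycles) if (cyc$m == 3) {
    for (e in seq_len(nrow(ed)))
      if (ed$n1[e] %in% cyc$nodes || ed$n2[e] %in% cyc$nodes) near3[e] <- TRUE
  }
  # 1. pendant edges: inert
  for (e in seq_len(nrow(ed))) {
    if (ed$n1[e] %in% net$leaves || ed$n2[e] %in% net$leaves)
      put(e, NULL, "inert", "pendant edge: no coalescence with 1 sample")
  }
  # 2. quartet-defined internal edges
  for (e in seq_len(nrow(ed))) {
    if (ed$n1[e] %in% net$leaves || ed$n2[e] %in% net$leaves) next
    if (ed$hybrid[e]) next
    adj_hyb <- any(ed$hybrid[setdiff(c(.inc(net, ed$n1[e]), .inc(net, ed$n2[e])), e)])
    if (adj_hyb) next
    qs <- defining_quartets(net, e)
    if (length(qs) == 0) next
    q <- qs[[1]]
    sp <- .edge_image_split(net, e, q)
    if (is.null(sp)) next
    quart <- c(sp$A, sp$B)
    r <- edge_length_from_quartet(tab, quart)
    put(e, r$value, "identified", r$provenance)
  }
  # 3. 3-cycles: everything in or adjacent not identifiable
  for (cyc in cycles) if (cyc$m == 3) {
    for (e in which(near3)) {
      if (ed$n1[e] %in% net$leaves || ed$n2[e] %in% net$leaves) next
      put(e, NULL, "not-identifiable", "edge in or adjacent to a 3-cycle")
    }
    hedges <- cyc$edges[ed$hybrid[cyc$edges]]
    for (e in hedges) {
      put(e, NULL, "not-identifiable", "3-cycle hybridization parameter")
      if (!is.na(net$groles[e]))
        put_role(net$groles[e], NULL, "not-identifiable",
                 "3-cycle hybridization parameter")
    }
  }
  # 4. 4-cycles
  for (cyc in cycles) {
    if (cyc$m != 4) next
    cs <- four_cycle_case(net, cyc)
    reps <- vapply(cyc$blocks, function(b) b[1], "")
    h <- reps[1]; s1 <- reps[2]; o <- reps[3]; s2 <- reps[4]
    hedges <- cyc$edges[ed$hybrid[cyc$edges]]
    e_h1 <- hedges[ed$n1[hedges] == cyc$block_nodes[2]]
    e_h2 <- setdiff(hedges, e_h1)
    tree_e <- setdiff(cyc$edges, hedges)
    e_x1 <- tree_e[ed$n1[tree_e] %in% cyc$block_nodes[c(2, 3)] &
                     ed$n2[tree_e] %in% cyc$block_nodes[c(2, 3)]]
    e_x2 <- setdiff(tree_e, e_x1)
    cut_e <- setdiff(.inc(net, cyc$hybrid_node), cyc$edges)
    if (cs$case %in% c("a", "b-i")) {
      for (e in c(hedges, tree_e, cut_e))
        put(e, NULL, "not-identifiable", paste0("4-cycle case ", cs$case))
      put_role(.gamma_name(net, e_h1), NULL, "not-identifiable",
               paste0("4-cycle case ", cs$case))
      if (!is.na(net$groles[e_h2]))
        put_role(net$groles[e_h2], NULL, "not-identifiable",
                 paste0("4-cycle case ", cs$case))
      next
    }
    # which adjacent block has >= 2 taxa for the pair combination?
    nB <- length(cyc$blocks[[2]]); nC <- length(cyc$blocks[[3]])
    nD <- length(cyc$blocks[[4]])
    if (length(cyc$blocks[[1]]) >= 2 && nC >= 2 && nB == 1 && nD == 1) {
      # pair block opposite the hybrid: dedicated closed form
      r <- .nsn_recovery(tab, cyc$blocks[[1]][1:2], cyc$blocks[[3]][1:2], s1, s2)
      put(e_h1, r$h1, "identified", "4-cycle opposite-pair closed form")
      put(e_h2, r$h2, "identified", "4-cycle opposite-pair closed form")
      gq <- .gamma_value_for(net, e_h1, e_h2, r$gamma)
      put_role(gq$name, gq$value, "identified", "4-cycle opposite-pair closed form")
      put(e_x1, r$x1, "identified", "4-cycle opposite-pair closed form")
      put(e_x2, r$x2, "identified", "4-cycle opposite-pair closed form")
      put(cut_e, r$l1, "identified", "4-cycle opposite-pair closed form")
      pcut <- .block_cut_edge(net, cyc, 3L)
      if (.is_cherry_block(net, pcut, cyc$blocks[[3]][1:2]))
        put(pcut, r$l2, "identified", "4-cycle opposite-pair closed form")
      next
    }
    side <- if (nB >= 2) 1 else if (nD >= 2) 2 else NA
    if (is.na(side)) next
    pair <- if (side == 1) cyc$blocks[[2]][1:2] else cyc$blocks[[4]][1:2]
    r <- .fourcycle_pair_recovery(tab, h, s1, o, s2, pair, side)
    gq <- .gamma_value_for(net, e_h1, e_h2, r$gamma)
    put_role(gq$name, gq$value, "identified", "4-cycle adjacent-pair combination")
    put(e_x1, r$x1, "identified", "4-cycle adjacent-pair combination")
    put(e_x2, r$x2, "identified", "4-cycle adjacent-pair combination")
    # a cherry pair block sees its own cut edge as the pair-passage factor W
    pcut <- .block_cut_edge(net, cyc, if (side == 1) 2L else 4L)
    if (.is_cherry_block(net, pcut, pair))
      put(pcut, r$W, "identified", "cut edge of cherry block adjacent to hybrid edge")
    if ("h1" %in% cs$identifiable && length(cyc$blocks[[1]]) >= 2) {
      ap <- cyc$blocks[[1]][1:2]
      three <- rr_fromint(r$gamma, 3)
      E1 <- rr_mul(three, cf_entry(tab, ap[1], s1, ap[2], o))
      E2 <- rr_mul(three, cf_entry(tab, ap[1], o, ap[2], s2))
      E3 <- rr_mul(three, cf_entry(tab, ap[1], s1, ap[2], s2))
      sol <- .solve_abl(E1, E2, E3, r$gamma, r$x1, r$x2)
      put(e_h1, sol$h1, "identified", "4-cycle hybrid lengths given gamma")
      put(e_h2, sol$h2, "identified", "4-cycle hybrid lengths given gamma")
      if ("l" %in% cs$identifiable)
        put(cut_e, sol$l1, "identified", "4-cycle edge below hybrid given gamma")
      else put(cut_e, NULL, "not-identifiable", "child in 3-cycle")
    } else {
      put(e_h1, NULL, if (length(cyc$blocks[[1]]) == 1) "inert" else "not-identifiable",
          paste0("4-cycle case ", cs$case))
      put(e_h2, NULL, if (length(cyc$blocks[[1]]) == 1) "inert" else "not-identifiable",
          paste0("4-cycle case ", cs$case))
      put(cut_e, NULL, if (length(cyc$blocks[[1]]) == 1) "inert" else "not-identifiable",
          paste0("4-cycle case ", cs$case))
    }
  }
  # 5. k >= 5 cycles
  for (cyc in cycles) {
    if (cyc$m < 5) next
    r <- sunlet_cycle_params(tab, cyc, net)
    for (nm in names(r)) put_role(nm, r[[nm]]$value, r[[nm]]$status, r[[nm]]$provenance)
  }
  # 6. edges joining two 4-cycles (two-projection scheme)
  for (e in seq_len(nrow(ed))) {
    if (!is.null(est[[.ename(net, e)]]) &&
        est[[.ename(net, e)]]$status %in% c("identified", "inert")) next
    if (ed$hybrid[e]) next
    if (ed$n1[e] %in% net$leaves || ed$n2[e] %in% net$leaves) next
    cycA <- NULL; cycB <- NULL
    for (cyc in cycles) {
      if (cyc$m != 4) next
      hedges <- cyc$edges[ed$hybrid[cyc$edges]]
      touch <- any(ed$n1[hedges] %in% c(ed$n1[e], ed$n2[e]))
      if (touch && e %in% setdiff(seq_len(nrow(ed)), cyc$edges)) {
        if (is.null(cycA)) cycA <- cyc else cycB <- cyc
      }
    }
    if (is.null(cycA) || is.null(cycB)) next
    rA <- .twin_side(tab, net, cycA)
    rB <- .twin_side(tab, net, cycB)
    if (is.null(rA) || is.null(rB)) next
    # l = W_A W_B / R with R = 3 CF_{pA1 pB1|pA2 pB2}: each projection sees
    # l times the other side's pair-passage factor, and the cross quartet
    # sees l times both
    R <- rr_mul(rr_fromint(rA$W, 3),
                cf_entry(tab, rA$pair[1], rB$pair[1], rA$pair[2], rB$pair[2]))
    ell <- .rdiv(rr_mul(rA$W, rB$W), R)
    put(e, ell, "identified", "edge joining two 4-cycles (two-projection)")
  }
  # 7. anything untouched: label not-identifiable
  for (e in seq_len(nrow(ed))) {
    nm <- .ename(net, e)
    if (is.null(est[[nm]]))
      est[[nm]] <- list(value = NULL, status = "not-identifiable",
                        provenance = "no recovery route")
  }
  est
}

# the non-cycle (cut) edge hanging off cycle node i
.block_cut_edge <- function(net, cyc, i) {
  setdiff(.inc(net, cyc$block_nodes[i]), cyc$edges)[1]
}

# TRUE when the cut edge leads directly to a cherry of the two given taxa
.is_cherry_block <- function(net, cut_e, pair) {
  ed <- net$edges
  ends <- c(ed$n1[cut_e], ed$n2[cut_e])
  for (v in ends) {
    inc <- setdiff(.inc(net, v), cut_e)
    if (length(inc) == 2) {
      kids <- setdiff(unique(c(ed$n1[inc], ed$n2[inc])), v)
      if (setequal(kids, unname(net$leaves[pair]))) return(TRUE)
    }
  }
  FALSE
}

.ename <- function(net, e) {
  rl <- net$roles[[e]]
  if (length(rl) == 1) rl else paste0("edge_", net$edges$n1[e], "_", net$edges$n2[e])
}

.gamma_name <- function(net, e) {
  gr <- net$groles[e]
  if (!is.na(gr)) gr else paste0("gamma_", net$edges$n2[e])
}

# a recovered inheritance probability g refers to the hybrid edge e1; report
# it under whichever of e1/e2 carries the named gamma role (as 1-g if the
# role sits on the partner edge)
.gamma_value_for <- function(net, e1, e2, g) {
  if (!is.na(net$groles[e1]))
    return(list(name = net$groles[e1], value = g))
  if (length(e2) == 1 && !is.na(net$groles[e2]))
    return(list(name = net$groles[e2], value = rr_sub(rr_fromint(g, 1), g)))
  list(name = paste0("gamma_", net$edges$n2[e1]), value = g)
}

# pair-combination recovery on one 4-cycle of a twin configuration; the pair
# is the block reached through the joining edge
.twin_side <- function(tab, net, cyc) {
  sizes <- vapply(cyc$blocks, length, 0L)
  big <- which(sizes >= 2)
  big <- setdiff(big, 1)
  if (length(big) == 0) return(NULL)
  big <- big[1]
  if (big == 3) return(NULL)                       # opposite: not this scheme
  reps <- vapply(cyc$blocks, function(b) b[1], "")
  pair <- cyc$blocks[[big]][1:2]
  side <- if (big == 2) 1 else 2
  r <- .fourcycle_pair_recovery(tab, reps[1], reps[2], reps[3], reps[4], pair, side)
  r$pair <- pair
  r
}


# the image edge of `e` in the induced network on taxa q
.find_image_edge <- function(net, e, q) {
  ind <- induced_network(net, q)
  eid <- net$edges$id[e]
  which(vapply(ind$edges$prov, function(p) eid %in% p, TRUE))[1]
}
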