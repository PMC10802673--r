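# Lineage-level building blocks: within-edge coalescent transitions, the
# conditional resolution probabilities of subnetwork fragments, the 3-cycle
# block's p-vector, and CF assembly through the A/B/C/D decomposition of a
# network cut at a 3-cycle.

## ---- within-edge transitions ------------------------------------------------

# With j lineages in an edge, merges race at rate 1 per pair; the iterated
# convolution of the competing exponentials gives each ordered merge sequence
# a probability that is a rational linear combination of powers ell^C(i,2).
# Computed once symbolically (exact fractions), evaluated in any ring.

# coefficients of P(specific ordered sequence of m merges, no further merge)
# as c[e] on ell^e; j = entering lineage count
.edge_seq_coefs <- function(j, m) {
  # survival only
  coefs <- stats::setNames(list(), character(0))
  qs <- function(i) choose(i, 2)
  # h_0 for i lineages: e^{-qs(i) t}
  h <- list(stats::setNames(c(1), as.character(qs(j - m))))
  # build up from the last surviving phase backwards
  cur <- stats::setNames(c(1), as.character(qs(j - m)))
  for (step in seq_len(m)) {
    a <- qs(j - m + step)     # rate while waiting for this (counted backward)
    out <- numeric(0)
    for (enm in names(cur)) {
      e <- as.numeric(enm); ce <- cur[[enm]]
      # \int_0^t e^{-a s} ce e^{-e (t-s)} ds = ce (e^{-e t} - e^{-a t})/(a - e)
      out[enm] <- (if (enm %in% names(out)) out[[enm]] else 0) + ce / (a - e)
      anm <- as.character(a)
      out[anm] <- (if (anm %in% names(out)) out[[anm]] else 0) - ce / (a - e)
    }
    cur <- out
  }
  cur
}

#' Within-edge coalescent transition distribution
#'
#' All ordered sequences of labelled pair merges that j lineages can undergo
#' within one edge of probability ell, with exact probabilities (polynomials
#' in ell).  Outcomes sum to one; relabelling lineages permutes outcomes of
#' equal probability.
#'
#' @param j number of entering lineages (1..4)
#' @param ell edge probability, any ring element
#' @return list of outcomes, each with `merges` (list of integer pairs, in
#'   order) and `prob` (ring element)
#' @export
edge_transition <- function(j, ell) {
  if (j > 4 || j < 1) stop("j must be between 1 and 4")
  tmpl <- ell
  evalc <- function(coefs) {
    acc <- rr_fromint(tmpl, 0)
    for (enm in names(coefs)) {
      e <- as.numeric(enm)
      den <- 1
      cv <- coefs[[enm]]
      # coefficients are exact dyadic/rational doubles built from small integers
      fr <- .as_fraction(cv)
      term <- rr_fromint(tmpl, fr$n, fr$d)
      if (e > 0) term <- rr_mul(term, rr_pow(ell, e))
      acc <- rr_add(acc, term)
    }
    acc
  }
  # enumerate merge sequences on lineages 1..j (groups tracked as sorted sets)
  out <- list()
  rec <- function(groups, merges) {
    m <- length(merges)
    coefs <- .edge_seq_coefs(j, m)
    out[[length(out) + 1]] <<- list(merges = merges, prob = evalc(coefs))
    if (length(groups) >= 2) {
      for (a in seq_len(length(groups) - 1)) for (b in (a + 1):length(groups)) {
        g2 <- groups
        g2[[a]] <- sort(c(groups[[a]], groups[[b]]))
        g2[[b]] <- NULL
        rec(g2, c(merges, list(c(a, b, recursive = TRUE))))
      }
    }
  }
  # note: merge identities recorded as the merged groups' member sets
  rec2 <- function(groups, merges) {
    m <- length(merges)
    coefs <- .edge_seq_coefs(j, m)
    out[[length(out) + 1]] <<- list(merges = merges, prob = evalc(coefs))
    if (length(groups) >= 2) {
      for (a in seq_len(length(groups) - 1)) for (b in (a + 1):length(groups)) {
        g2 <- groups
        g2[[a]] <- sort(c(groups[[a]], groups[[b]]))
        g2 <- g2[-b]
        rec2(g2, c(merges, list(list(groups[[a]], groups[[b]]))))
      }
    }
  }
  rec2(as.list(seq_len(j)), list())
  out
}

# exact small fraction from a double that arose as a ratio of small integers
.as_fraction <- function(x, maxden = 10000) {
  for (d in 1:maxden) {
    n <- x * d
    if (abs(n - round(n)) < 1e-9) return(list(n = round(n), d = d))
  }
  stop("coefficient is not a small rational")
}

## ---- fragment DP ------------------------------------------------------------

# DP identical in spirit to the CF engine, but on an open fragment: lineages
# enter at given nodes, and as soon as >=3 of them share a node the quartet
# is determined with conditional probability 1/3 each (exchangeability).
# Returns split probabilities and the probability of exiting undetermined.
.fragment_dp <- function(net, entry, params = NULL, open_top = TRUE) {
  tmpl <- .ring_template(params)
  one <- rr_fromint(tmpl, 1); zero <- rr_fromint(tmpl, 0)
  ed <- net$edges
  ells <- lapply(seq_len(nrow(ed)), function(i) .edge_ell(net, i, params, tmpl))
  samp <- sort(as.integer(names(entry)))   # which of samples 1..4 enter
  pos0 <- rep(NA_integer_, 4)
  for (s in names(entry)) pos0[as.integer(s)] <- entry[[s]]
  out <- list(zero, zero, zero)
  undet <- zero
  resolve_third <- function(w) {
    third <- rr_divint(w, 3)
    for (s in 1:3) out[[s]] <<- rr_add(out[[s]], third)
  }
  gather_check <- function(pos, w) {
    # TRUE (and accounts for it) if >=3 entered lineages share a node
    at <- pos[!is.na(pos)]
    tab <- table(at)
    if (any(tab >= 3)) { resolve_third(w); return(TRUE) }
    FALSE
  }
  states <- list()
  if (!gather_check(pos0, one))
    states[[paste(pos0, collapse = ",")]] <- list(pos = pos0, w = one)
  topo <- rev(.topo_order(net))
  root <- net$root
  for (v in topo) {
    pe <- which(ed$n2 == v)
    new_states <- list()
    put <- function(pos, w) {
      if (gather_check(pos, w)) return(invisible())
      key <- paste(pos, collapse = ",")
      if (is.null(new_states[[key]])) new_states[[key]] <<- list(pos = pos, w = w)
      else new_states[[key]]$w <<- rr_add(new_states[[key]]$w, w)
    }
    for (st in states) {
      idx <- which(!is.na(st$pos) & st$pos == v)
      j <- length(idx)
      if (length(pe) == 0) {              # top of the fragment
        if (j == 0) { put(st$pos, st$w); next }
        if (open_top) {
          undet <- rr_add(undet, st$w)    # j <= 2 or gather already handled
        } else {
          # closed top: remaining lineages coalesce to completion (root rule)
          if (j >= 2) resolve_third(st$w) else undet <- rr_add(undet, st$w)
        }
      } else if (j == 0) {
        put(st$pos, st$w)
      } else if (length(pe) == 1) {
        e <- pe[1]; up <- ed$n1[e]
        if (j == 1 || ed$nocoal[e]) {
          pos <- st$pos; pos[idx] <- up; put(pos, st$w)
        } else {
          ell <- ells[[e]]
          if (is.null(ell)) stop("edge with missing length carries 2+ lineages")
          q <- choose(j, 2)
          pnm <- rr_pow(ell, q)
          pos <- st$pos; pos[idx] <- up
          put(pos, rr_mul(st$w, pnm))
          wpm <- rr_mul(st$w, rr_divint(rr_sub(one, pnm), q))
          for (a in seq_len(j - 1)) for (b in (a + 1):j) {
            s <- .SPLIT_OF_PAIR[idx[a], idx[b]]
            out[[s]] <- rr_add(out[[s]], wpm)
          }
        }
      } else {                            # hybrid node
        e1 <- pe[1]; e2 <- pe[2]
        g1 <- .edge_gamma(net, e1, params, tmpl)
        g2 <- .edge_gamma(net, e2, params, tmpl)
        up1 <- ed$n1[e1]; up2 <- ed$n1[e2]
        for (mask in 0:(2^j - 1)) {
          grp1 <- idx[bitwAnd(bitwShiftR(mask, seq_len(j) - 1L), 1L) == 1L]
          grp2 <- setdiff(idx, grp1)
          gw <- one
          for (k in seq_along(grp1)) gw <- rr_mul(gw, g1)
          for (k in seq_along(grp2)) gw <- rr_mul(gw, g2)
          w <- rr_mul(st$w, gw)
          j1 <- length(grp1); j2 <- length(grp2)
          tr <- function(e, jj) {
            if (jj <= 1 || ed$nocoal[e]) return(list(pnm = one, q = 0))
            ell <- ells[[e]]
            if (is.null(ell)) stop("hybrid edge with missing length carries 2+ lineages")
            q <- choose(jj, 2)
            list(pnm = rr_pow(ell, q), q = q)
          }
          t1 <- tr(e1, j1); t2 <- tr(e2, j2)
          pos <- st$pos; pos[grp1] <- up1; pos[grp2] <- up2
          put(pos, rr_mul(w, rr_mul(t1$pnm, t2$pnm)))
          if (j1 >= 2 && j2 >= 2) {
            s <- .SPLIT_OF_PAIR[grp1[1], grp1[2]]
            out[[s]] <- rr_add(out[[s]], rr_mul(w, rr_sub(one, rr_mul(t1$pnm, t2$pnm))))
          } else {
            if (j1 >= 2) {
              wpm <- rr_mul(w, rr_divint(rr_sub(one, t1$pnm), t1$q))
              for (a in seq_len(j1 - 1)) for (b in (a + 1):j1) {
                s <- .SPLIT_OF_PAIR[grp1[a], grp1[b]]
                out[[s]] <- rr_add(out[[s]], wpm)
              }
            }
            if (j2 >= 2) {
              wpm <- rr_mul(w, rr_divint(rr_sub(one, t2$pnm), t2$q))
              for (a in seq_len(j2 - 1)) for (b in (a + 1):j2) {
                s <- .SPLIT_OF_PAIR[grp2[a], grp2[b]]
                out[[s]] <- rr_add(out[[s]], wpm)
              }
            }
          }
        }
      }
    }
    states <- new_states
  }
  list(split = out, undetermined = undet)
}

#' Conditional quartet-resolution probabilities of a network fragment
#'
#' The fragment is a rooted piece of a network whose root is the cut vertex
#' through which lineages exit; `entry` assigns sampled lineages (numbered
#' 1..4 in the canonical taxon order of the enclosing quartet) to the nodes
#' where they enter, conditioned on entering distinctly.  Returns the
#' conditional probabilities that the fragment determines each quartet
#' resolution -- by a first coalescence inside it, or by three or more
#' lineages reaching a common node (after which each quartet has probability
#' 1/3) -- and the probability of exiting undetermined.
#'
#' @param fragment rooted `qcf_net` piece (leaves need not be taxa)
#' @param entry named list: sample index ("1".."4") -> node id
#' @param params named ring-element parameter list
#' @return list with `split` (3 ring elements, canonical split order),
#'   `undetermined` (ring element), `j_exit` (lineages surviving if
#'   undetermined)
#' @export
conditional_resolution <- function(fragment, entry, params = NULL) {
  if (length(entry) > 4) stop("more than 4 entering lineages")
  r <- .fragment_dp(fragment, entry, params, open_top = TRUE)
  r$j_exit <- length(entry)
  r
}

## ---- the 3-cycle p-vector ---------------------------------------------------

#' The six 3-cycle block probabilities
#'
#' Closed forms for the conditional resolution probabilities of the 3-cycle
#' block D (cycle plus adjacent cut edges, hybrid-side block a, cut edges
#' l1 below the hybrid node, l2 to block b, l3 rootward to block c; cycle
#' tree edge x; hybrid edge probabilities h1, h2 and inheritance gamma):
#'   p1 = P(D -> ab|cc), p2 = P(D -> aa|cc), p3 = P(D -> bb|cc),
#'   p4 = P(D -> ab|bc), p5 = P(D -> ab|ac), p6 = P(D -> ab|ab),
#' with complements P(D -> bb|ac) = 1-2 p4, P(D -> aa|bc) = 1-2 p5,
#' P(D -> aa|bb) = 1-2 p6.
#'
#' @param gamma,l1,l2,l3,h1,h2,x ring elements (probabilities in (0,1];
#'   strict range checking only applies to numeric input when `strict`)
#' @param strict error on out-of-range numeric input
#' @return list p1..p6 of ring elements
#' @export
p_vector <- function(gamma, l1, l2, l3, h1, h2, x, strict = TRUE) {
  if (strict) {
    for (v in list(gamma, l1, l2, l3, h1, h2, x)) {
      if (is.numeric(v) && (v <= 0 || v > 1)) stop("parameter out of range (0,1]")
    }
    if (is.numeric(gamma) && gamma >= 1) stop("gamma must lie in (0,1)")
  }
  tmpl <- gamma
  one <- rr_fromint(tmpl, 1)
  omg <- rr_sub(one, gamma)              # 1 - gamma
  g2 <- rr_mul(gamma, gamma)
  omg2 <- rr_mul(omg, omg)
  gog <- rr_mul(gamma, omg)
  p1 <- rr_sub(one, rr_mul(l3, rr_add(rr_sub(one, gamma), rr_mul(gamma, x))))
  p2 <- rr_sub(one, rr_mul(rr_mul(l1, l3),
         rr_add(rr_add(rr_mul(g2, rr_mul(h1, x)), rr_mul(rr_fromint(tmpl, 2), gog)),
                rr_mul(omg2, h2))))
  p3 <- rr_sub(one, rr_mul(x, rr_mul(l2, l3)))
  p4 <- rr_divint(rr_mul(l2, rr_add(gamma, rr_mul(omg, x))), 3)
  p5 <- rr_divint(rr_mul(l1,
         rr_add(rr_add(rr_mul(g2, h1),
                       rr_mul(gog, rr_sub(rr_fromint(tmpl, 3), x))),
                rr_mul(omg2, h2))), 3)
  p6 <- rr_divint(rr_mul(rr_mul(l1, l2),
         rr_add(rr_add(rr_mul(g2, h1), rr_mul(rr_fromint(tmpl, 2), gog)),
                rr_mul(omg2, rr_mul(h2, x)))), 3)
  list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6)
}

#' The explicit 3-cycle block as a fragment network
#'
#' The D block of the decomposition: a 3-cycle with pendant entry vertices a
#' (below the hybrid node, cut edge l1), b (cut edge l2) and top vertex c
#' (cut edge l3), rooted at c.  Used to validate [p_vector()] against
#' [conditional_resolution()].
#'
#' @return a rooted `qcf_net` fragment
#' @export
three_cycle_fragment <- function() {
  build_network(list(
    list(from = "c", to = "w", role = "l3"),
    list(from = "w", to = "u", role = "x"),
    list(from = "u", to = "h", hybrid = TRUE, grole = "gamma", role = "h1"),
    list(from = "w", to = "h", hybrid = TRUE, role = "h2"),
    list(from = "h", to = "a", role = "l1"),
    list(from = "u", to = "b", role = "l2")),
    leaves = c(a = "a", b = "b"), root = "c")
}

## ---- CF assembly through the decomposition ----------------------------------

#' CF table assembled through the 3-cycle A/B/C/D decomposition
#'
#' Cuts the network at a 3-cycle into the block D (cycle plus adjacent cut
#' edges) and the three attached pieces A, B, C (C containing the root), and
#' assembles every quartet CF as the chain
#' P(resolved in A or B) + P(undetermined) P(resolved in D) + ... P(in C).
#' Agrees exactly with [cf_table()].
#'
#' @param net rooted `qcf_net` with at least one 3-cycle
#' @param params named ring-element parameter list
#' @return a `cf_table`
#' @export
cf_via_decomposition <- function(net, params = NULL) {
  stopifnot(net$rooted)
  cyc <- find_cycles(net)
  cyc <- Filter(function(r) r$m == 3, cyc)
  if (length(cyc) == 0) stop("no 3-cycle")
  rec <- cyc[[1]]
  ed <- net$edges
  # cut edges: the non-cycle edge at each cycle node
  cut <- vapply(rec$block_nodes, function(v)
    setdiff(.inc(net, v), rec$edges)[1], 0L)
  # pendant vertex of each cut edge (the endpoint outside the cycle)
  pend <- vapply(seq_along(cut), function(i) {
    e <- cut[i]
    setdiff(c(ed$n1[e], ed$n2[e]), rec$block_nodes[i])
  }, 0L)
  # D piece: cycle + cut edges; vertex roles: index 1 = hybrid side (a)
  dedges <- c(rec$edges, cut)
  # which pendant vertex is rootward?  the one whose cut edge points INTO the cycle
  topi <- which(vapply(seq_along(cut), function(i) ed$n2[cut[i]] == rec$block_nodes[i], TRUE))
  if (length(topi) != 1) stop("decomposition needs the root outside the cycle")
  ai <- 1L                                 # hybrid block index
  bi <- setdiff(seq_along(cut), c(ai, topi))
  Dnet <- net
  Dnet$edges <- ed[dedges, , drop = FALSE]
  Dnet$roles <- net$roles[dedges]; Dnet$groles <- net$groles[dedges]
  Dnet$root <- pend[topi]
  Dnet$leaves <- stats::setNames(pend[c(ai, bi)], c("entA", "entB"))
  piece <- function(keepnode) {
    # connected component of `keepnode` after removing D's edges
    keep <- setdiff(seq_len(nrow(ed)), dedges)
    comp <- .components(ed[keep, , drop = FALSE], net_nodes(net))
    inpiece <- names(comp)[comp == comp[as.character(keepnode)]]
    sel <- keep[ed$n1[keep] %in% as.integer(inpiece) &
                  ed$n2[keep] %in% as.integer(inpiece)]
    p <- net
    p$edges <- ed[sel, , drop = FALSE]
    p$roles <- net$roles[sel]; p$groles <- net$groles[sel]
    p$leaves <- net$leaves[net$leaves %in% as.integer(inpiece)]
    p
  }
  A <- piece(pend[ai]); A$root <- pend[ai]
  B <- piece(pend[bi]); B$root <- pend[bi]
  C <- piece(pend[topi]); C$root <- net$root
  blockof <- function(tx) {
    if (tx %in% names(A$leaves)) "A" else if (tx %in% names(B$leaves)) "B" else "C"
  }
  tmpl <- .ring_template(params)
  one <- rr_fromint(tmpl, 1); zero <- rr_fromint(tmpl, 0)
  taxa <- network_taxa(net)
  combs <- utils::combn(taxa, 4, simplify = FALSE)
  quartets <- lapply(combs, function(q) {
    blocks <- vapply(q, blockof, "")
    acc <- list(zero, zero, zero)
    undet <- one
    run_stage <- function(frag, entry, open_top) {
      if (length(entry) == 0) return(invisible())
      r <- .fragment_dp(frag, entry, params, open_top = open_top)
      for (s in 1:3) acc[[s]] <<- rr_add(acc[[s]], rr_mul(undet, r$split[[s]]))
      undet <<- rr_mul(undet, r$undetermined)
    }
    entry_for <- function(piece_net, blockname, extra = list()) {
      e <- extra
      for (i in seq_along(q)) if (blocks[i] == blockname)
        e[[as.character(i)]] <- unname(piece_net$leaves[[q[i]]])
      e
    }
    # stage A (samples in A walk to vertex a), then B, then D, then C
    run_stage(A, entry_for(A, "A"), open_top = TRUE)
    run_stage(B, entry_for(B, "B"), open_top = TRUE)
    # entering D: survivors from A at vertex a, from B at vertex b
    dentry <- list()
    for (i in seq_along(q)) {
      if (blocks[i] == "A") dentry[[as.character(i)]] <- pend[ai]
      if (blocks[i] == "B") dentry[[as.character(i)]] <- pend[bi]
    }
    if (length(dentry) > 0) {
      r <- .fragment_dp(Dnet, dentry, params, open_top = TRUE)
      for (s in 1:3) acc[[s]] <- rr_add(acc[[s]], rr_mul(undet, r$split[[s]]))
      undet <- rr_mul(undet, r$undetermined)
    }
    centry <- entry_for(C, "C")
    for (i in seq_along(q)) if (blocks[i] %in% c("A", "B"))
      centry[[as.character(i)]] <- pend[topi]
    r <- .fragment_dp(C, centry, params, open_top = FALSE)
    for (s in 1:3) acc[[s]] <- rr_add(acc[[s]], rr_mul(undet, r$split[[s]]))
    list(taxa = q, cf = acc)
  })
  structure(list(taxa = taxa, quartets = quartets), class = "cf_table")
}
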