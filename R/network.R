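# Data model and graph operations for binary level-1 rooted and semidirected
# metric phylogenetic networks.
#
# A network is a list of edges over integer node ids.  Directed edges store the
# parent in n1 and the child in n2; hybrid edges (child is a hybrid node) are
# always directed, tree edges are directed only while the network is rooted.
# Edge lengths are kept in coalescent units (t, NA = no length / inert); the
# edge probability ell = exp(-t) is always derived, never stored.  For fixture
# networks, edges may instead carry symbolic parameter roles: `roles[[i]]` is a
# character vector of ell-parameter names whose product gives the edge
# probability, and `groles[i]` names the gamma parameter of a hybrid edge.

new_network <- function(edges, leaves, rooted, root = NA_integer_,
                        roles = NULL, groles = NULL) {
  stopifnot(is.data.frame(edges))
  if (is.null(roles)) roles <- rep(list(character(0)), nrow(edges))
  if (is.null(groles)) groles <- rep(NA_character_, nrow(edges))
  if (is.null(edges$nocoal)) edges$nocoal <- FALSE
  structure(list(edges = edges, leaves = leaves, rooted = rooted,
                 root = root, roles = roles, groles = groles),
            class = "qcf_net")
}

#' @export
print.qcf_net <- function(x, ...) {
  cat(sprintf("<qcf_net: %d taxa, %d edges, %d hybrid, %s>\n",
              length(x$leaves), nrow(x$edges), sum(x$edges$hybrid),
              if (x$rooted) "rooted" else "semidirected"))
  invisible(x)
}

net_nodes <- function(net) sort(unique(c(net$edges$n1, net$edges$n2)))

#' Taxa of a network
#' @param net a `qcf_net`
#' @return character vector of taxon labels
#' @export
network_taxa <- function(net) sort(names(net$leaves))

# incident edge indices of node v
.inc <- function(net, v) which(net$edges$n1 == v | net$edges$n2 == v)

# for rooted nets: edges into / out of v
.in_edges <- function(net, v) which(net$edges$n2 == v &
                                      (net$edges$directed | net$edges$hybrid))
.out_edges <- function(net, v) which(net$edges$n1 == v &
                                       (net$edges$directed | net$edges$hybrid))

.hybrid_nodes <- function(net) sort(unique(net$edges$n2[net$edges$hybrid]))

# topological order (children before parents is the reverse) for a rooted net
.topo_order <- function(net) {
  nodes <- net_nodes(net)
  indeg <- vapply(nodes, function(v) length(.in_edges(net, v)), 0L)
  names(indeg) <- nodes
  queue <- nodes[indeg == 0L]
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (e in .out_edges(net, v)) {
      w <- net$edges$n2[e]
      indeg[as.character(w)] <- indeg[as.character(w)] - 1L
      if (indeg[as.character(w)] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(nodes)) stop("network is not acyclic as directed")
  out
}

## ---- validation -------------------------------------------------------------

#' Validate a network
#'
#' Checks binary degree rules, gamma pairing on hybrid edges, and the level-1
#' condition (no two undirected cycles share a node).
#'
#' @param net a `qcf_net`
#' @return `net`, invisibly; errors on violation
#' @export
validate_network <- function(net) {
  ed <- net$edges
  if (anyDuplicated(names(net$leaves))) stop("duplicate taxon labels")
  hyb <- .hybrid_nodes(net)
  for (h in hyb) {
    ein <- which(ed$hybrid & ed$n2 == h)
    if (length(ein) != 2) stop("hybrid node must have exactly 2 hybrid parent edges")
    g <- ed$gamma[ein]
    if (!any(is.na(g))) {
      if (abs(sum(g) - 1) > 1e-9) stop("gamma pair does not sum to 1")
      if (any(g <= 0 | g >= 1)) stop("gamma must lie in (0,1)")
    } else if (all(is.na(net$groles[ein]))) {
      stop("hybrid edges need gamma values or gamma roles")
    }
  }
  nodes <- net_nodes(net)
  if (net$rooted) {
    for (v in nodes) {
      ind <- length(.in_edges(net, v)); outd <- length(.out_edges(net, v))
      if (v == net$root) {
        if (ind != 0 || !(outd %in% c(1L, 2L)))
          stop("root must have indegree 0 and outdegree 1 or 2")
      } else if (v %in% net$leaves) {
        if (ind != 1 || outd != 0) stop("leaf degree violation")
      } else if (v %in% hyb) {
        if (ind != 2 || outd != 1) stop("hybrid node degree violation")
      } else {
        if (ind != 1 || outd != 2) stop("non-binary tree node")
      }
    }
    .topo_order(net)
  } else {
    for (v in nodes) {
      d <- length(.inc(net, v))
      if (v %in% net$leaves) {
        if (d != 1) stop("leaf degree violation")
      } else if (d != 3) stop("non-binary internal node in semidirected network")
    }
  }
  find_cycles(net)   # errors if not level-1
  invisible(net)
}

## ---- extended Newick parsing ------------------------------------------------

#' Parse an extended Newick string into a network
#'
#' Hybrid nodes are tagged `#H<k>`; the convention `...:length:support:gamma`
#' supplies branch length (coalescent units) and inheritance probability on
#' hybrid edges.  The gamma on the major edge may be omitted and is inferred
#' as 1 - gamma.  A top-level trifurcation is read as a semidirected network.
#'
#' @param text an extended Newick string
#' @param extended permit negative branch lengths (edge probabilities above
#'   1), used only by contraction adjustments; rejected by default
#' @return a validated `qcf_net`
#' @export
parse_network <- function(text, extended = FALSE) {
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s) || substring(s, nchar(s)) != ";") stop("malformed Newick: missing ';'")
  s <- substring(s, 1, nchar(s) - 1)
  pos <- 1L
  peek <- function() if (pos <= nchar(s)) substring(s, pos, pos) else ""
  adv <- function() pos <<- pos + 1L

  read_label <- function() {
    out <- ""
    while (pos <= nchar(s) && !(peek() %in% c("(", ")", ",", ":", ";"))) {
      out <- paste0(out, peek()); adv()
    }
    out
  }
  read_fields <- function() {
    f <- list(t = NA_real_, gamma = NA_real_)
    k <- 0
    while (peek() == ":") {
      adv(); k <- k + 1
      num <- ""
      while (pos <= nchar(s) && grepl("[0-9eE.+-]", peek())) { num <- paste0(num, peek()); adv() }
      val <- if (nzchar(num)) as.numeric(num) else NA_real_
      if (k == 1) f$t <- val
      if (k == 3) f$gamma <- val
      if (k > 3) stop("malformed Newick: too many ':' fields")
    }
    f
  }
  parse_subtree <- function() {
    if (peek() == "(") {
      adv()
      kids <- list(parse_branch())
      while (peek() == ",") { adv(); kids[[length(kids) + 1]] <- parse_branch() }
      if (peek() != ")") stop("malformed Newick: expected ')'")
      adv()
      lab <- read_label()
      list(kind = "internal", label = lab, children = kids)
    } else {
      lab <- read_label()
      if (!nzchar(lab)) stop("malformed Newick: empty leaf label")
      list(kind = "leaf", label = lab, children = list())
    }
  }
  parse_branch <- function() {
    node <- parse_subtree()
    f <- read_fields()
    node$t <- f$t; node$gamma <- f$gamma
    node
  }
  top <- parse_subtree()
  if (pos <= nchar(s)) stop("malformed Newick: trailing characters")

  # assemble the graph, merging #H occurrences
  nid <- 0L
  new_id <- function() { nid <<- nid + 1L; nid }
  hyb_ids <- list()
  e_n1 <- integer(0); e_n2 <- integer(0); e_t <- numeric(0)
  e_gamma <- numeric(0); e_hyb <- logical(0)
  leaves <- integer(0)
  add_edge <- function(a, b, t, gamma, hybrid) {
    e_n1 <<- c(e_n1, a); e_n2 <<- c(e_n2, b); e_t <<- c(e_t, t)
    e_gamma <<- c(e_gamma, gamma); e_hyb <<- c(e_hyb, hybrid)
  }
  build <- function(node, parent) {
    lab <- node$label
    htag <- if (grepl("#", lab)) sub("^[^#]*#", "#", lab) else NA_character_
    base <- if (grepl("#", lab)) sub("#.*$", "", lab) else lab
    if (!is.na(htag)) {
      if (is.null(hyb_ids[[htag]])) hyb_ids[[htag]] <<- new_id()
      v <- hyb_ids[[htag]]
    } else v <- new_id()
    if (!is.na(parent)) add_edge(parent, v, node$t, node$gamma, !is.na(htag))
    if (node$kind == "leaf" && is.na(htag)) {
      if (base %in% names(leaves)) stop("duplicate taxon labels")
      leaves[[base]] <<- v
    }
    for (k in node$children) build(k, v)
    v
  }
  root <- build(top, NA)

  edges <- data.frame(n1 = e_n1, n2 = e_n2, hybrid = e_hyb, directed = TRUE,
                      t = e_t, gamma = e_gamma, nocoal = FALSE)
  # infer missing gamma on the partner edge
  for (h in unique(edges$n2[edges$hybrid])) {
    i <- which(edges$hybrid & edges$n2 == h)
    g <- edges$gamma[i]
    if (sum(is.na(g)) == 1) edges$gamma[i[is.na(g)]] <- 1 - g[!is.na(g)]
  }
  if (!extended && any(edges$t < 0, na.rm = TRUE))
    stop("negative branch length (use extended = TRUE)")
  topdeg <- sum(edges$n1 == root)
  rooted <- topdeg == 2
  net <- new_network(edges, leaves, rooted, if (rooted) root else NA_integer_)
  if (!rooted) {
    if (topdeg != 3) stop("top-level node must have 2 (rooted) or 3 (unrooted) children")
    net$edges$directed[!net$edges$hybrid] <- FALSE
  }
  validate_network(net)
  net
}

#' Write a network as an extended Newick string
#'
#' Semidirected networks are first given a valid rooting; the minor hybrid
#' edge of each hybrid node is written as a duplicate `#H` leaf occurrence
#' with its gamma in the third colon field.
#'
#' @param net a `qcf_net`
#' @return a single string
#' @export
write_network <- function(net) {
  if (!net$rooted) net <- root_network(net)
  ed <- net$edges
  hyb <- .hybrid_nodes(net)
  htag <- stats::setNames(paste0("#H", seq_along(hyb)), hyb)
  # the major (largest-gamma, first on tie) parent edge carries the subtree
  major <- integer(0)
  for (h in hyb) {
    i <- which(ed$hybrid & ed$n2 == h)
    g <- ed$gamma[i]
    major[as.character(h)] <- if (any(!is.na(g))) i[which.max(g)] else i[1]
  }
  fmt_fields <- function(t, gamma) {
    if (is.na(t) && is.na(gamma)) return("")
    out <- paste0(":", if (is.na(t)) "" else format(t, digits = 15))
    if (!is.na(gamma)) out <- paste0(out, "::", format(gamma, digits = 15))
    out
  }
  wr <- function(v, via) {
    # via: edge index used to reach v (NA at root); the caller appends the
    # edge's :length::gamma fields
    if (!is.na(via) && ed$hybrid[via] && via != major[as.character(v)]) {
      return(htag[as.character(v)])
    }
    kids <- .out_edges(net, v)
    lab <- if (v %in% net$leaves) names(net$leaves)[match(v, net$leaves)] else ""
    if (v %in% hyb) lab <- paste0(lab, htag[as.character(v)])
    body <- if (length(kids) == 0) lab else {
      paste0("(", paste(vapply(kids, function(e)
        paste0(wr(ed$n2[e], e), fmt_fields(ed$t[e], ed$gamma[e])), ""),
        collapse = ","), ")", lab)
    }
    body
  }
  paste0(wr(net$root, NA_integer_), ";")
}

## ---- rooting and semidirecting ----------------------------------------------

# least stable ancestor: deepest node lying on every root-to-leaf path
.lsa <- function(net) {
  stopifnot(net$rooted)
  nodes <- net_nodes(net)
  leaves <- unname(net$leaves)
  on_all <- vapply(nodes, function(v) {
    if (v == net$root) return(TRUE)
    if (v %in% leaves && length(leaves) > 1) return(FALSE)
    # does removing v disconnect every leaf from the root?
    keep <- !(net$edges$n1 == v | net$edges$n2 == v)
    reach <- .reachable(net$edges[keep, , drop = FALSE], net$root)
    !any(leaves %in% reach)
  }, TRUE)
  cand <- nodes[on_all]
  depth <- vapply(cand, function(v) .depth_from_root(net, v), 0L)
  cand[which.max(depth)]
}

.reachable <- function(edges, from) {
  reach <- from; grow <- TRUE
  while (grow) {
    nxt <- edges$n2[edges$n1 %in% reach]
    new <- setdiff(nxt, reach)
    grow <- length(new) > 0
    reach <- c(reach, new)
  }
  reach
}

.depth_from_root <- function(net, v) {
  d <- 0L; cur <- v
  while (cur != net$root) {
    e <- .in_edges(net, cur)[1]
    cur <- net$edges$n1[e]; d <- d + 1L
  }
  d
}

# suppress all degree-2 nodes (and a rooted net's outdegree-1 root chain)
.suppress_deg2 <- function(net) {
  repeat {
    ed <- net$edges
    changed <- FALSE
    if (net$rooted) {
      outs <- which(ed$n1 == net$root)
      if (length(outs) == 1 && length(.in_edges(net, net$root)) == 0) {
        child <- ed$n2[outs]
        net$edges <- ed[-outs, , drop = FALSE]
        net$roles <- net$roles[-outs]; net$groles <- net$groles[-outs]
        net$root <- child
        changed <- TRUE
      }
    }
    if (!changed) {
      for (v in net_nodes(net)) {
        if (v %in% net$leaves) next
        if (net$rooted && v == net$root) next
        inc <- .inc(net, v)
        if (length(inc) != 2) next
        ein <- inc[net$edges$n2[inc] == v & (net$edges$directed[inc] | net$edges$hybrid[inc])]
        eout <- inc[net$edges$n1[inc] == v & (net$edges$directed[inc] | net$edges$hybrid[inc])]
        if (net$rooted || (length(ein) + length(eout) == 2 && length(ein) == 1)) {
          if (length(ein) != 1 || length(eout) != 1) next
          a <- net$edges$n1[ein]; b <- net$edges$n2[eout]
        } else {
          # undirected pair in a semidirected net
          a <- setdiff(c(net$edges$n1[inc[1]], net$edges$n2[inc[1]]), v)
          b <- setdiff(c(net$edges$n1[inc[2]], net$edges$n2[inc[2]]), v)
          ein <- inc[1]; eout <- inc[2]
        }
        t1 <- net$edges$t[ein]; t2 <- net$edges$t[eout]
        tt <- if (is.na(t1) && is.na(t2)) NA_real_ else sum(c(t1, t2), na.rm = TRUE)
        keep_hyb <- net$edges$hybrid[ein] || net$edges$hybrid[eout]
        gsrc <- if (net$edges$hybrid[eout]) eout else ein
        newrow <- net$edges[gsrc, , drop = FALSE]   # row template keeps extra columns
        newrow$n1 <- a; newrow$n2 <- b; newrow$hybrid <- keep_hyb
        newrow$directed <- net$edges$directed[ein] || net$edges$directed[eout] || keep_hyb
        newrow$t <- tt; newrow$gamma <- net$edges$gamma[gsrc]
        newrow$nocoal <- net$edges$nocoal[ein] && net$edges$nocoal[eout]
        if (!is.null(newrow$prov))
          newrow$prov <- I(list(c(net$edges$prov[[ein]], net$edges$prov[[eout]])))
        newroles <- list(c(net$roles[[ein]], net$roles[[eout]]))
        newgrole <- net$groles[gsrc]
        drop <- c(ein, eout)
        net$edges <- rbind(net$edges[-drop, , drop = FALSE], newrow)
        net$roles <- c(net$roles[-drop], newroles)
        net$groles <- c(net$groles[-drop], newgrole)
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  rownames(net$edges) <- NULL
  net
}

#' Reduce a rooted network to its induced semidirected network
#'
#' Deletes all structure above the least stable ancestor, undirects tree
#' edges, and suppresses the LSA; quartet CF tables are invariant under this
#' reduction.
#'
#' @param net a rooted `qcf_net`
#' @return a semidirected `qcf_net`
#' @export
to_semidirected <- function(net) {
  if (!net$rooted) return(net)
  if (length(net$leaves) < 2) stop("need at least 2 taxa")
  lsa <- .lsa(net)
  below <- .reachable(net$edges, lsa)
  keep <- net$edges$n1 %in% below & net$edges$n2 %in% below
  net$edges <- net$edges[keep, , drop = FALSE]
  net$roles <- net$roles[keep]; net$groles <- net$groles[keep]
  net$root <- lsa
  net$rooted <- FALSE
  net$edges$directed[!net$edges$hybrid] <- FALSE
  # suppress the LSA (now degree 2) and any other degree-2 nodes
  net$root <- NA_integer_
  net <- .suppress_deg2(net)
  rownames(net$edges) <- NULL
  net
}

#' Root a semidirected network
#'
#' Tries each tree edge (and each node) as a root position, orienting tree
#' edges away from the root while respecting hybrid edge directions, and
#' returns the first (lexicographically least by edge endpoints) valid
#' rooting.  CF tables are invariant under the choice (rooting invariance).
#'
#' @param net a semidirected `qcf_net`
#' @param at optional edge index to root along
#' @return a rooted `qcf_net`
#' @export
root_network <- function(net, at = NULL) {
  if (net$rooted) return(net)
  cand <- which(!net$edges$hybrid)
  o <- order(pmin(net$edges$n1[cand], net$edges$n2[cand]),
             pmax(net$edges$n1[cand], net$edges$n2[cand]))
  cand <- cand[o]
  if (!is.null(at)) cand <- at
  for (e in cand) {
    res <- .try_root_edge(net, e)
    if (!is.null(res)) return(res)
  }
  stop("no valid rooting exists")
}

.try_root_edge <- function(net, e) {
  # subdivide edge e with a new root node
  ed <- net$edges
  r <- max(net_nodes(net)) + 1L
  a <- ed$n1[e]; b <- ed$n2[e]
  t <- ed$t[e]
  # root at the a-endpoint of the edge: the whole length/role goes on the b
  # half and the a half is instantaneous -- CFs are invariant to the choice
  add <- data.frame(n1 = c(r, r), n2 = c(a, b), hybrid = FALSE, directed = TRUE,
                    t = c(0, t), gamma = NA_real_, nocoal = ed$nocoal[e])
  if (!is.null(ed$id)) add$id <- ed$id[e]
  for (cn in setdiff(names(ed), names(add))) {
    v <- ed[[cn]][e]
    add[[cn]] <- if (is.list(ed[[cn]])) I(list(ed[[cn]][[e]], ed[[cn]][[e]])) else v
  }
  roles_e <- net$roles[[e]]
  newroles <- list(character(0), roles_e)
  ed2 <- rbind(ed[-e, , drop = FALSE], add)
  roles2 <- c(net$roles[-e], newroles)
  groles2 <- c(net$groles[-e], NA_character_, NA_character_)
  net2 <- new_network(ed2, net$leaves, TRUE, r, roles2, groles2)
  net2 <- .orient_from_root(net2)
  if (is.null(net2)) return(NULL)
  # rejoin: suppressing the added root later would undo this; keep the root
  net2
}

# orient all tree edges away from the root; NULL if impossible
.orient_from_root <- function(net) {
  ed <- net$edges
  n <- nrow(ed)
  fixed <- ed$hybrid | (ed$n1 == net$root)  # hybrid edges keep direction
  ed$directed <- TRUE
  # constraint propagation on required indegrees
  nodes <- net_nodes(net)
  need_in <- stats::setNames(ifelse(nodes %in% .hybrid_nodes(net), 2L, 1L), nodes)
  need_in[as.character(net$root)] <- 0L
  oriented <- fixed
  # root's incident tree edges point away
  for (e in which(!ed$hybrid & (ed$n2 == net$root))) {
    tmp <- ed$n1[e]; ed$n1[e] <- ed$n2[e]; ed$n2[e] <- tmp
    oriented[e] <- TRUE
  }
  oriented[!ed$hybrid & ed$n1 == net$root] <- TRUE
  repeat {
    changed <- FALSE
    for (v in nodes) {
      vo <- as.character(v)
      ein <- which(oriented & ed$n2 == v)
      if (length(ein) > need_in[vo]) return(NULL)
      if (length(ein) == need_in[vo]) {
        # all other incident unoriented edges point away
        for (e in which(!oriented & (ed$n1 == v | ed$n2 == v))) {
          if (ed$n2[e] == v) { tmp <- ed$n1[e]; ed$n1[e] <- ed$n2[e]; ed$n2[e] <- tmp }
          oriented[e] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  if (!all(oriented)) return(NULL)
  for (v in nodes) {
    vo <- as.character(v)
    if (length(which(ed$n2 == v)) != need_in[vo]) return(NULL)
  }
  net$edges <- ed
  # reject if not acyclic
  ok <- tryCatch({ .topo_order(net); TRUE }, error = function(e) FALSE)
  if (!ok) return(NULL)
  net
}

## ---- cycles and level-1 -----------------------------------------------------

#' Find all cycles of a level-1 network
#'
#' Each cycle of a binary level-1 network contains exactly one hybrid node.
#' Returns one record per cycle with its size m, hybrid-descendant count k,
#' and the ordered taxon-block partition; errors if two cycles share a node
#' (level-1 violation).
#'
#' @param net a `qcf_net`
#' @return list of records with fields `edges`, `nodes`, `hybrid_node`, `m`,
#'   `k`, `blocks`, `block_nodes`, `hybrid_block`
#' @export
find_cycles <- function(net) {
  ed <- net$edges
  hyb <- .hybrid_nodes(net)
  nnode <- length(net_nodes(net))
  ncomp <- 1L  # networks here are connected
  if (nrow(ed) - nnode + ncomp != length(hyb))
    stop("cycle count does not match hybrid count: not a valid level-1 network")
  out <- list()
  for (h in hyb) {
    ei <- which(ed$hybrid & ed$n2 == h)
    u <- ed$n1[ei]
    # all simple paths u[1] -> u[2] avoiding h and the hybrid edges
    paths <- .simple_paths(ed[-ei, , drop = FALSE], u[1], u[2], avoid = h)
    if (length(paths) == 0) stop("hybrid node not in a cycle")
    if (length(paths) > 1) stop("two cycles share a node: not level-1")
    pnodes <- paths[[1]]
    cyc_nodes <- c(h, pnodes)
    cyc_edges <- c(ei, .path_edges(ed, pnodes))
    rec <- list(edges = cyc_edges, nodes = cyc_nodes, hybrid_node = h,
                m = length(cyc_nodes))
    out[[length(out) + 1]] <- rec
  }
  # pairwise node-disjoint
  if (length(out) > 1) {
    for (i in seq_len(length(out) - 1)) for (j in (i + 1):length(out)) {
      if (length(intersect(out[[i]]$nodes, out[[j]]$nodes)) > 0)
        stop("two cycles share a node: not level-1")
    }
  }
  # blocks
  for (i in seq_along(out)) {
    rec <- out[[i]]
    keep <- setdiff(seq_len(nrow(ed)), rec$edges)
    comp <- .components(ed[keep, , drop = FALSE], net_nodes(net))
    blocks <- list(); block_nodes <- integer(0)
    # order blocks starting at the hybrid node, following the cycle
    ord <- .cycle_node_order(ed, rec$edges, rec$hybrid_node)
    for (v in ord) {
      cv <- comp[as.character(v)]
      taxa <- sort(names(net$leaves)[comp[as.character(net$leaves)] == cv])
      blocks[[length(blocks) + 1]] <- taxa
      block_nodes <- c(block_nodes, v)
    }
    rec$blocks <- blocks
    rec$block_nodes <- block_nodes
    rec$hybrid_block <- 1L
    rec$k <- length(blocks[[1]])
    out[[i]] <- rec
  }
  out
}

# connected components of an undirected edge set; returns component id per node
.components <- function(edges, nodes) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- as.character(edges$n1[i]); b <- as.character(edges$n2[i])
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) { comp[a] <- m; comp[b] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  comp
}

# all simple undirected paths from a to b avoiding node `avoid`
.simple_paths <- function(edges, a, b, avoid = integer(0)) {
  res <- list()
  walk <- function(v, visited) {
    if (v == b) { res[[length(res) + 1]] <<- visited; return(invisible()) }
    inc <- which(edges$n1 == v | edges$n2 == v)
    for (e in inc) {
      w <- if (edges$n1[e] == v) edges$n2[e] else edges$n1[e]
      if (w %in% visited || w %in% avoid) next
      walk(w, c(visited, w))
    }
  }
  if (a == b) return(list(a))
  walk(a, a)
  res
}

# edge indices along a node path
.path_edges <- function(edges, pnodes) {
  if (length(pnodes) < 2) return(integer(0))
  vapply(seq_len(length(pnodes) - 1), function(i) {
    which((edges$n1 == pnodes[i] & edges$n2 == pnodes[i + 1]) |
            (edges$n2 == pnodes[i] & edges$n1 == pnodes[i + 1]))[1]
  }, 0L)
}

# cycle nodes in order around the cycle, starting at the hybrid node
.cycle_node_order <- function(edges, cyc_edges, h) {
  sub <- edges[cyc_edges, , drop = FALSE]
  ord <- h
  prev <- NA_integer_; cur <- h
  repeat {
    inc <- which(sub$n1 == cur | sub$n2 == cur)
    nxts <- setdiff(unique(c(sub$n1[inc], sub$n2[inc])), c(cur, prev))
    if (length(ord) == 1) nxts <- nxts[1]
    if (length(nxts) == 0) break
    prev <- cur; cur <- nxts[1]
    if (cur == h) break
    ord <- c(ord, cur)
  }
  ord
}

## ---- induced quartet networks -----------------------------------------------

#' Induced network on a subset of taxa
#'
#' Retains only nodes and edges ancestral to the chosen taxa, suppresses
#' degree-2 nodes (lengths summed, parameter roles concatenated), and trims
#' the root down to the last common ancestor structure.  Each surviving edge
#' records which original edges it absorbed in `provenance`.
#'
#' @param net a `qcf_net` (rooted or semidirected)
#' @param taxa character vector of taxa (length >= 2; 4 for quartets)
#' @return a rooted `qcf_net` on `taxa` with a `provenance` attribute
#' @export
induced_network <- function(net, taxa) {
  if (!all(taxa %in% names(net$leaves))) stop("taxon not in network")
  net <- .ensure_ids(net)
  rooted <- if (net$rooted) net else root_network(net)
  keep_leaves <- rooted$leaves[taxa]
  # ancestral closure: nodes from which a kept leaf is reachable
  anc <- unname(keep_leaves)
  repeat {
    more <- rooted$edges$n1[rooted$edges$n2 %in% anc]
    new <- setdiff(more, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  keep <- rooted$edges$n1 %in% anc & rooted$edges$n2 %in% anc
  net2 <- rooted
  net2$edges <- rooted$edges[keep, , drop = FALSE]
  net2$roles <- rooted$roles[keep]
  net2$groles <- rooted$groles[keep]
  net2$leaves <- keep_leaves
  net2$edges$prov <- I(as.list(net2$edges$id))
  net2 <- .suppress_deg2_prov(net2)
  rownames(net2$edges) <- NULL
  net2
}

# like .suppress_deg2 but for rooted nets with a `prov` list column
.suppress_deg2_prov <- function(net) {
  repeat {
    ed <- net$edges
    changed <- FALSE
    outs <- which(ed$n1 == net$root)
    if (length(outs) == 1) {
      child <- ed$n2[outs]
      net$edges <- ed[-outs, , drop = FALSE]
      net$roles <- net$roles[-outs]; net$groles <- net$groles[-outs]
      net$root <- child
      changed <- TRUE
    }
    if (!changed) {
      for (v in net_nodes(net)) {
        if (v %in% net$leaves || v == net$root) next
        ein <- .in_edges(net, v); eout <- .out_edges(net, v)
        if (length(ein) == 1 && length(eout) == 1) {
          a <- net$edges$n1[ein]; b <- net$edges$n2[eout]
          t1 <- net$edges$t[ein]; t2 <- net$edges$t[eout]
          tt <- if (is.na(t1) && is.na(t2)) NA_real_ else sum(c(t1, t2), na.rm = TRUE)
          keep_hyb <- net$edges$hybrid[ein] || net$edges$hybrid[eout]
          gsrc <- if (net$edges$hybrid[eout]) eout else ein
          newrow <- net$edges[ein, , drop = FALSE]
          newrow$n1 <- a; newrow$n2 <- b; newrow$t <- tt
          newrow$hybrid <- keep_hyb; newrow$directed <- TRUE
          newrow$gamma <- net$edges$gamma[gsrc]
          newrow$nocoal <- net$edges$nocoal[ein] && net$edges$nocoal[eout]
          newrow$prov <- I(list(c(net$edges$prov[[ein]], net$edges$prov[[eout]])))
          newroles <- list(c(net$roles[[ein]], net$roles[[eout]]))
          drop <- c(ein, eout)
          net$edges <- rbind(net$edges[-drop, , drop = FALSE], newrow)
          net$roles <- c(net$roles[-drop], newroles)
          net$groles <- c(net$groles[-drop], net$groles[gsrc])
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  net
}

## ---- 2-cycles, pseudotaxa ---------------------------------------------------

#' Replace every 2-cycle by a single edge
#'
#' A 2-cycle (parallel hybrid edges with probabilities h1, h2 and inheritance
#' gamma) is replaced by one tree edge whose probability ell satisfies
#' 1 - ell = gamma^2 (1-h1) + (1-gamma)^2 (1-h2); quartet CFs are unchanged.
#'
#' @param net a `qcf_net` with numeric lengths
#' @return a `qcf_net` without 2-cycles
#' @export
replace_two_cycles <- function(net) {
  repeat {
    ed <- net$edges
    two <- NULL
    for (h in .hybrid_nodes(net)) {
      i <- which(ed$hybrid & ed$n2 == h)
      if (ed$n1[i[1]] == ed$n1[i[2]]) { two <- i; break }
    }
    if (is.null(two)) break
    g1 <- ed$gamma[two[1]]
    h1 <- exp(-ed$t[two[1]]); h2 <- exp(-ed$t[two[2]])
    if (is.na(h1)) h1 <- 1
    if (is.na(h2)) h2 <- 1
    ell <- 1 - (g1^2 * (1 - h1) + (1 - g1)^2 * (1 - h2))
    newrow <- ed[two[1], , drop = FALSE]
    newrow$hybrid <- FALSE
    newrow$t <- -log(ell)
    newrow$gamma <- NA_real_
    newrow$nocoal <- FALSE
    net$edges <- rbind(ed[-two, , drop = FALSE], newrow)
    net$roles <- c(net$roles[-two], list(character(0)))
    net$groles <- c(net$groles[-two], NA_character_)
    net <- .suppress_deg2(net)
  }
  rownames(net$edges) <- NULL
  net
}

#' Expand a leaf into pseudotaxa
#'
#' Replaces leaf `taxon` by a cherry/caterpillar of `k` pseudotaxa named
#' `taxon.1 .. taxon.k`.  The new edges carry no length and permit no
#' coalescence, so CFs for the expanded network equal those of the original
#' network under multiple sampling.
#'
#' @param net a `qcf_net`
#' @param taxon a leaf label
#' @param k number of samples (>= 1)
#' @return a `qcf_net`
#' @export
add_pseudotaxa <- function(net, taxon, k) {
  if (!taxon %in% names(net$leaves)) stop("unknown taxon")
  stopifnot(k >= 1)
  v <- net$leaves[[taxon]]
  net$leaves <- net$leaves[names(net$leaves) != taxon]
  if (k == 1) {
    net$leaves[[paste0(taxon, ".1")]] <- v
    return(net)
  }
  nid <- max(net_nodes(net))
  attach_at <- v
  for (i in seq_len(k - 1)) {
    # attach_at becomes internal: add pseudotaxon leaf i and (for the last
    # split) leaf i+1
    leaf_i <- nid + 1L; nid <- nid + 1L
    add <- data.frame(n1 = attach_at, n2 = leaf_i, hybrid = FALSE,
                      directed = net$rooted, t = NA_real_, gamma = NA_real_,
                      nocoal = TRUE)
    net$edges <- rbind(net$edges, add)
    net$roles <- c(net$roles, list(character(0)))
    net$groles <- c(net$groles, NA_character_)
    net$leaves[[paste0(taxon, ".", i)]] <- leaf_i
    if (i < k - 1) {
      nxt <- nid + 1L; nid <- nid + 1L
      add <- data.frame(n1 = attach_at, n2 = nxt, hybrid = FALSE,
                        directed = net$rooted, t = NA_real_, gamma = NA_real_,
                        nocoal = TRUE)
      net$edges <- rbind(net$edges, add)
      net$roles <- c(net$roles, list(character(0)))
      net$groles <- c(net$groles, NA_character_)
      attach_at <- nxt
    } else {
      last <- nid + 1L; nid <- nid + 1L
      add <- data.frame(n1 = attach_at, n2 = last, hybrid = FALSE,
                        directed = net$rooted, t = NA_real_, gamma = NA_real_,
                        nocoal = TRUE)
      net$edges <- rbind(net$edges, add)
      net$roles <- c(net$roles, list(character(0)))
      net$groles <- c(net$groles, NA_character_)
      net$leaves[[paste0(taxon, ".", k)]] <- last
    }
  }
  rownames(net$edges) <- NULL
  net
}

#' Expand a multi-sample map into pseudotaxa
#' @param net a `qcf_net`
#' @param samples named integer vector taxon -> count
#' @return a `qcf_net`
#' @export
expand_samples <- function(net, samples) {
  for (taxon in names(samples)) {
    if (samples[[taxon]] > 1) net <- add_pseudotaxa(net, taxon, samples[[taxon]])
  }
  net
}

## ---- defining quartets ------------------------------------------------------

# give every edge a persistent id that survives rooting and restriction
.ensure_ids <- function(net) {
  if (is.null(net$edges$id)) net$edges$id <- seq_len(nrow(net$edges))
  net
}

#' Quartet sets defining an edge
#'
#' A set Q of 4 taxa defines edge e when, in the induced network on Q, the
#' image of e is a cut edge separating two pairs and its four neighbouring
#' edges are cut edges each separating one taxon (an internal edge of a plain
#' quartet tree).  Nonempty exactly when e is internal, non-hybrid and not
#' adjacent to a hybrid edge.
#'
#' @param net a semidirected (or rooted) `qcf_net`
#' @param edge edge index into `net$edges`
#' @return list of character 4-vectors (possibly empty)
#' @export
defining_quartets <- function(net, edge) {
  net <- .ensure_ids(net)
  ed <- net$edges
  v1 <- ed$n1[edge]; v2 <- ed$n2[edge]
  if (v1 %in% net$leaves || v2 %in% net$leaves) stop("pendant edge")
  taxa <- network_taxa(net)
  combs <- utils::combn(taxa, 4, simplify = FALSE)
  out <- list()
  for (q in combs) {
    if (.defines_edge(net, edge, q)) out[[length(out) + 1]] <- q
  }
  out
}

.defines_edge <- function(net, edge, q) {
  !is.null(.edge_image_split(net, edge, q))
}

# the 2|2 taxon split witnessed by edge `edge` in the induced network on q,
# with all four neighbouring edges cut and separating single taxa; NULL if
# the conditions of a defining quartet fail.  The image of `edge` may be two
# rows when the internal rooting subdivides it.
.edge_image_split <- function(net, edge, q) {
  ind <- induced_network(net, q)
  eid <- net$edges$id[edge]
  hit <- which(vapply(ind$edges$prov, function(p) eid %in% p, TRUE))
  if (length(hit) == 0 || length(hit) > 2) return(NULL)
  # the image must be exactly e (possibly split by the internal root), not a
  # merged path through suppressed nodes: otherwise a neighbouring internal
  # edge was absorbed and the quartet does not define e
  if (!all(vapply(ind$edges$prov[hit], function(p) identical(p, eid), TRUE)))
    return(NULL)
  ed <- ind$edges
  endpoints <- unique(c(ed$n1[hit], ed$n2[hit]))
  if (length(hit) == 2) {
    # must be the two halves around the internal root
    shared <- intersect(c(ed$n1[hit[1]], ed$n2[hit[1]]),
                        c(ed$n1[hit[2]], ed$n2[hit[2]]))
    if (length(shared) != 1) return(NULL)
    endpoints <- setdiff(endpoints, shared)
  }
  if (any(endpoints %in% ind$leaves)) return(NULL)
  split <- .cut_split(ind, hit, ends = endpoints)
  if (is.null(split) || length(split$A) != 2 || length(split$B) != 2) return(NULL)
  nb <- setdiff(which(ed$n1 %in% endpoints | ed$n2 %in% endpoints), hit)
  if (length(nb) != 4) return(NULL)
  for (e in nb) {
    s <- .cut_split(ind, e)
    if (is.null(s) || min(length(s$A), length(s$B)) != 1) return(NULL)
  }
  split
}

# if removing edge rows `e` disconnects the graph, the taxa on each side;
# NULL otherwise.  `ends` overrides the reference endpoints (used when e is
# two rows around an internal root).
.cut_split <- function(net, e, ends = NULL) {
  ed <- net$edges[-e, , drop = FALSE]
  comp <- .components(ed, net_nodes(net))
  if (is.null(ends)) ends <- unique(c(net$edges$n1[e], net$edges$n2[e]))
  a <- ends[1]
  bcands <- setdiff(ends, a)
  lv <- comp[as.character(net$leaves)]
  sideA <- sort(names(net$leaves)[lv == comp[as.character(a)]])
  for (b in bcands) {
    if (comp[as.character(b)] != comp[as.character(a)]) {
      sideB <- sort(names(net$leaves)[lv == comp[as.character(b)]])
      if (length(sideA) + length(sideB) == length(net$leaves))
        return(list(A = sideA, B = sideB))
      return(NULL)
    }
  }
  NULL
}
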