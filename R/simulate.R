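# Monte-Carlo NMSC gene-tree sampler on rooted metric level-1 networks, and
# empirical CF estimation used to cross-validate the exact engine.
#
# Lineages are traced backward in time.  Within an edge of length t
# (coalescent units) each pair of co-resident lineages coalesces at rate 1;
# at a hybrid node each lineage independently follows a parent edge with
# probability gamma / 1-gamma; above the root, remaining lineages merge by
# uniformly random pairs (topology-equivalent to exponential racing).
# Clusters are tracked as bitmasks over leaves so displayed quartets can be
# read off each sampled tree cheaply.

# per-tree RNG stream from a master seed (counter-based splitting)
.tree_seed <- function(master, i) {
  (master %% 2147483647 + (i * 48271) %% 2147483647) %% 2147483647 + 1
}

.sim_prep <- function(net) {
  stopifnot(net$rooted)
  list(topo = rev(.topo_order(net)), ed = net$edges,
       leaves = net$leaves, root = net$root)
}

# simulate one gene tree; returns list(merges = list of cluster masks in merge
# order, children = list of pairs of cluster ids, leafmask per taxon)
.sim_one <- function(prep) {
  ed <- prep$ed
  nl <- length(prep$leaves)
  taxa <- names(prep$leaves)
  # cluster state: id, mask; lineage positions: node per active cluster
  masks <- as.list(2^(seq_len(nl) - 1))
  pos <- unname(prep$leaves)
  ids <- seq_len(nl)
  nxt <- nl
  merges <- list(); children <- list()
  for (v in prep$topo) {
    pe <- which(ed$n2 == v)
    at <- which(pos == v)
    if (length(at) == 0) next
    if (length(pe) == 0) {                       # root: merge to completion
      while (length(pos) >= 2) {
        pick <- if (length(pos) == 2) c(1, 2) else sample(length(pos), 2)
        i <- pick[1]; j <- pick[2]
        nxt <- nxt + 1
        masks[[nxt]] <- bitwOr(masks[[ids[i]]], masks[[ids[j]]])
        merges[[length(merges) + 1]] <- masks[[nxt]]
        children[[length(children) + 1]] <- c(ids[i], ids[j])
        ids[i] <- nxt
        pos <- pos[-j]; ids <- ids[-j]
      }
    } else if (length(pe) == 1) {
      e <- pe[1]
      at2 <- at
      if (length(at2) >= 2 && !ed$nocoal[e]) {
        t <- ed$t[e]
        if (is.na(t)) stop("missing length on an edge that can carry 2+ lineages")
        s <- 0
        while (length(at2) >= 2) {
          s <- s + stats::rexp(1, rate = choose(length(at2), 2))
          if (s > t) break
          pick <- sample(length(at2), 2)
          i <- at2[pick[1]]; j <- at2[pick[2]]
          nxt <- nxt + 1
          masks[[nxt]] <- bitwOr(masks[[ids[i]]], masks[[ids[j]]])
          merges[[length(merges) + 1]] <- masks[[nxt]]
          children[[length(children) + 1]] <- c(ids[i], ids[j])
          ids[i] <- nxt
          pos <- pos[-j]; ids <- ids[-j]
          at2 <- setdiff(at2, j); at2[at2 > j] <- at2[at2 > j] - 1
        }
      }
      pos[at2] <- ed$n1[e]
    } else {                                     # hybrid node
      g <- ed$gamma[pe[1]]
      if (is.na(g)) g <- 1 - ed$gamma[pe[2]]
      if (is.na(g)) stop("hybrid edge without numeric gamma")
      choice <- stats::runif(length(at)) < g
      for (side in 1:2) {
        e <- pe[side]
        at2 <- at[if (side == 1) choice else !choice]
        if (length(at2) >= 2 && !ed$nocoal[e]) {
          t <- ed$t[e]
          if (is.na(t)) stop("missing length on an edge that can carry 2+ lineages")
          s <- 0
          while (length(at2) >= 2) {
            s <- s + stats::rexp(1, rate = choose(length(at2), 2))
            if (s > t) break
            pick <- sample(length(at2), 2)
            i <- at2[pick[1]]; j <- at2[pick[2]]
            nxt <- nxt + 1
            masks[[nxt]] <- bitwOr(masks[[ids[i]]], masks[[ids[j]]])
            merges[[length(merges) + 1]] <- masks[[nxt]]
            children[[length(children) + 1]] <- c(ids[i], ids[j])
            ids[i] <- nxt
            pos <- pos[-j]; ids <- ids[-j]
            # reindex the untouched side too
            at[at > j] <- at[at > j] - 1
            at2 <- setdiff(at2, j); at2[at2 > j] <- at2[at2 > j] - 1
          }
        }
        pos[at2] <- ed$n1[e]
      }
    }
  }
  list(merges = merges, children = children, taxa = taxa, ntip = nl,
       masks = masks, rootid = nxt)
}


#' Sample one gene tree under the NMSC
#'
#' @param net rooted metric `qcf_net` (all internal edges with lengths)
#' @param samples optional named vector taxon -> sample count
#' @param seed integer seed
#' @return object of class `gene_tree` with the merge history, taxa and seed
#' @export
sample_gene_tree <- function(net, samples = NULL, seed = 1) {
  if (!is.null(samples)) net <- expand_samples(net, samples)
  prep <- .sim_prep(net)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.tree_seed(seed, 1))
  g <- .sim_one(prep)
  g$seed <- seed
  class(g) <- "gene_tree"
  g
}

#' Newick string of a sampled gene tree
#' @param g a `gene_tree`
#' @return a string
#' @export
gene_tree_newick <- function(g) {
  wr <- function(id) {
    if (id <= g$ntip) return(g$taxa[id])
    ch <- g$children[[id - g$ntip]]
    paste0("(", wr(ch[1]), ",", wr(ch[2]), ")")
  }
  paste0(wr(g$rootid), ";")
}

#' Displayed quartet of a gene tree
#'
#' The quartet topology induced by restricting the gene tree to four leaves:
#' the first merge cluster containing exactly two of them names the cherry
#' pair.
#'
#' @param g a `gene_tree`
#' @param taxa4 four taxon labels
#' @return integer split index 1..3 against the sorted taxa (1 = 12|34, ...)
#' @export
displayed_quartet <- function(g, taxa4) {
  ix <- match(sort(taxa4), g$taxa)
  qmask <- sum(2^(ix - 1))
  for (m in g$merges) {
    inter <- bitwAnd(m, qmask)
    pc <- sum(bitwAnd(bitwShiftR(inter, 0:30), 1L))
    if (pc == 2) {
      pair <- which(bitwAnd(inter, 2^(ix - 1)) > 0)
      return(.SPLIT_OF_PAIR[pair[1], pair[2]])
    }
  }
  stop("gene tree does not resolve the quartet")  # cannot happen: binary tree
}

#' Empirical CF table from simulated gene trees
#'
#' Counts displayed quartets over R independent gene trees; per-entry
#' standard errors are the multinomial sqrt(CF (1-CF) / R).
#'
#' @param net rooted metric `qcf_net`
#' @param samples optional named vector taxon -> count
#' @param R number of gene trees
#' @param seed integer master seed (one derived stream per tree)
#' @return a `cf_table` with per-quartet `ngenes` and `se`
#' @export
empirical_cf_table <- function(net, samples = NULL, R = 1000, seed = 1) {
  if (!is.null(samples)) net <- expand_samples(net, samples)
  taxa <- network_taxa(net)
  if (length(taxa) < 4) stop("need at least 4 taxa")
  prep <- .sim_prep(net)
  combs <- utils::combn(taxa, 4, simplify = FALSE)
  # leaf order inside masks is the order of prep$leaves
  taxord <- names(prep$leaves)
  qmasks <- lapply(combs, function(q) {
    ix <- match(sort(q), taxord)
    list(ix = ix, mask = sum(2^(ix - 1)), bits = 2^(ix - 1))
  })
  counts <- matrix(0L, length(combs), 3)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (r in seq_len(R)) {
    set.seed(.tree_seed(seed, r))
    g <- .sim_one(prep)
    merges <- g$merges
    for (qi in seq_along(qmasks)) {
      qm <- qmasks[[qi]]
      for (m in merges) {
        inter <- bitwAnd(m, qm$mask)
        if (inter == 0) next
        pc <- sum(bitwAnd(inter, qm$bits) > 0)
        if (pc == 2) {
          pair <- which(bitwAnd(inter, qm$bits) > 0)
          s <- .SPLIT_OF_PAIR[pair[1], pair[2]]
          counts[qi, s] <- counts[qi, s] + 1L
          break
        }
        if (pc >= 3) next
      }
    }
  }
  quartets <- lapply(seq_along(combs), function(qi) {
    cf <- counts[qi, ] / R
    list(taxa = sort(combs[[qi]]), cf = as.list(cf), ngenes = R,
         se = sqrt(cf * (1 - cf) / R))
  })
  structure(list(taxa = taxa, quartets = quartets), class = "cf_table")
}

#' Write gene trees as Newick lines
#' @param trees list of `gene_tree`
#' @param path file path
#' @export
write_gene_trees <- function(trees, path) {
  writeLines(vapply(trees, gene_tree_newick, ""), path)
}
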