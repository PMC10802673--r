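# Generators for the named fixture networks.
#
# Each generator wires a figure's topology with its labelled edge roles, so
# the same network can be evaluated numerically (doubles), exactly (qq /
# GF(p)) or symbolically (mpol) by passing parameter values for the roles.
# Edges on which no coalescence can occur (pendant edges, hybrid edges with a
# single descendant taxon, pseudotaxon cherries) carry no role: their lengths
# never enter CF formulas and are not parameters.

#' Build a network from an edge list
#'
#' @param edges list of lists with fields `from`, `to` (node names), and
#'   optionally `hybrid`, `t`, `gamma`, `role` (character vector of ell
#'   parameter names), `grole` (gamma parameter name), `nocoal`
#' @param leaves named character vector taxon -> node name
#' @param root root node name
#' @return a rooted `qcf_net`
#' @export
build_network <- function(edges, leaves, root) {
  nodenames <- unique(c(vapply(edges, `[[`, "", "from"),
                        vapply(edges, `[[`, "", "to")))
  id <- stats::setNames(seq_along(nodenames), nodenames)
  get <- function(e, f, default) if (is.null(e[[f]])) default else e[[f]]
  ed <- do.call(rbind, lapply(edges, function(e) {
    data.frame(n1 = id[[e$from]], n2 = id[[e$to]],
               hybrid = get(e, "hybrid", FALSE), directed = TRUE,
               t = get(e, "t", NA_real_), gamma = get(e, "gamma", NA_real_),
               nocoal = get(e, "nocoal", FALSE))
  }))
  roles <- lapply(edges, function(e) as.character(get(e, "role", character(0))))
  groles <- vapply(edges, function(e) get(e, "grole", NA_character_), "")
  lv <- stats::setNames(unname(id[leaves]), names(leaves))
  new_network(ed, lv, TRUE, id[[root]], roles, groles)
}

.cherry <- function(node, t1, t2) {
  # edges attaching taxa t1,t2 at `node` (pendant: inert, no role)
  list(list(from = node, to = t1), list(from = node, to = t2))
}

# central 3-cycle with three attached blocks; used by N5-3x, Na/Nb/Nc, T6.
# hy/uu/ww are the block specs at the hybrid node, the l2 node and the l3
# (rootward) node: each either c(taxon) or c(taxon1, taxon2) for a cherry.
.three_cycle_net <- function(hy, uu, ww, l1 = "l1", l2 = "l2", l3 = "l3",
                             h1 = "h1", h2 = "h2", x = "x") {
  edges <- list()
  att <- function(node, block, role) {
    if (length(block) == 1) {
      edges[[length(edges) + 1]] <<- list(from = node, to = block)  # pendant
    } else {
      bn <- paste0(node, "cher")
      edges[[length(edges) + 1]] <<- list(from = node, to = bn, role = role)
      edges[[length(edges) + 1]] <<- list(from = bn, to = block[1])
      edges[[length(edges) + 1]] <<- list(from = bn, to = block[2])
    }
  }
  # root inside the rootward block
  if (length(ww) == 2) {
    edges[[length(edges) + 1]] <- list(from = "r", to = ww[1])
    edges[[length(edges) + 1]] <- list(from = "r", to = "wn", t = 0)
    edges[[length(edges) + 1]] <- list(from = "wn", to = ww[2])
    edges[[length(edges) + 1]] <- list(from = "wn", to = "w", role = l3)
  } else {
    edges[[length(edges) + 1]] <- list(from = "r", to = ww[1])
    edges[[length(edges) + 1]] <- list(from = "r", to = "w", t = 0)
  }
  edges[[length(edges) + 1]] <- list(from = "w", to = "u", role = x)
  edges[[length(edges) + 1]] <- list(from = "u", to = "h", hybrid = TRUE,
                                     grole = "gamma", role = h1)
  edges[[length(edges) + 1]] <- list(from = "w", to = "h", hybrid = TRUE,
                                     role = h2)
  att("h", hy, l1)
  att("u", uu, l2)
  lv <- c(hy, uu, ww)
  build_network(edges, stats::setNames(lv, lv), "r")
}

# 4-cycle with hybrid at south; block specs below s / at w / at n / at e.
.four_cycle_net <- function(ss, wwb, nnb, eeb, lroles = list()) {
  edges <- list()
  role_of <- function(nm) if (is.null(lroles[[nm]])) character(0) else lroles[[nm]]
  att <- function(node, block, rolenm) {
    if (length(block) == 1) {
      edges[[length(edges) + 1]] <<- list(from = node, to = block)
    } else {
      bn <- paste0(node, "cher")
      edges[[length(edges) + 1]] <<- list(from = node, to = bn, role = role_of(rolenm))
      edges[[length(edges) + 1]] <<- list(from = bn, to = block[1])
      edges[[length(edges) + 1]] <<- list(from = bn, to = block[2])
    }
  }
  # root inside the north block (always above the hybrid)
  if (length(nnb) == 2) {
    edges[[length(edges) + 1]] <- list(from = "r", to = nnb[1])
    edges[[length(edges) + 1]] <- list(from = "r", to = "ncher", t = 0)
    edges[[length(edges) + 1]] <- list(from = "ncher", to = nnb[2])
    edges[[length(edges) + 1]] <- list(from = "ncher", to = "n", role = role_of("ln"))
  } else {
    edges[[length(edges) + 1]] <- list(from = "r", to = nnb[1])
    edges[[length(edges) + 1]] <- list(from = "r", to = "n", t = 0)
  }
  edges[[length(edges) + 1]] <- list(from = "n", to = "w", role = "x1")
  edges[[length(edges) + 1]] <- list(from = "n", to = "e", role = "x2")
  edges[[length(edges) + 1]] <- list(from = "w", to = "s", hybrid = TRUE,
                                     grole = "gamma", role = role_of("h1"))
  edges[[length(edges) + 1]] <- list(from = "e", to = "s", hybrid = TRUE,
                                     role = role_of("h2"))
  if (length(ss) == 1) {
    edges[[length(edges) + 1]] <- list(from = "s", to = ss)
  } else {
    edges[[length(edges) + 1]] <- list(from = "s", to = "scher", role = role_of("ls"))
    edges[[length(edges) + 1]] <- list(from = "scher", to = ss[1])
    edges[[length(edges) + 1]] <- list(from = "scher", to = ss[2])
  }
  att("w", wwb, "lw")
  lv <- c(ss, wwb, nnb, eeb)
  att("e", eeb, "le")
  build_network(edges, stats::setNames(lv, lv), "r")
}

#' Named fixture networks
#'
#' Builds one of the named networks by topology, with symbolic parameter
#' roles on every edge that can carry a coalescence.  `fixture_params(name)`
#' lists the exact role names the network expects.
#'
#' Available names: T5, N5-31, N5-32, N5-32p, T6, Na, Nb, Nc, N6-32, Ns, Nw,
#' Nn, Nsw, Nsn, sunlet(k) (as `"sunlet5"`, `"sunlet6"`, ...),
#' twin4cycles-L, twin4cycles-C, twin4cycles-R, fig14-template.
#'
#' @param name fixture name
#' @param params optional named parameter list; when given, names are checked
#'   against the fixture's roles
#' @param blocks for fig14-template: integer vector of the four block sizes
#'   (hybrid block first), each 1 or 2
#' @return a rooted `qcf_net`
#' @export
make_named <- function(name, params = NULL, blocks = c(2, 1, 1, 1)) {
  net <- switch(name,
    "T5" = build_network(c(list(
      list(from = "r", to = "c"),
      list(from = "r", to = "v", t = 0),
      list(from = "v", to = "A", role = "l1"),
      list(from = "v", to = "B", role = "l2")),
      .cherry("A", "a1", "a2"), .cherry("B", "b1", "b2")),
      leaves = c(a1 = "a1", a2 = "a2", b1 = "b1", b2 = "b2", c = "c"),
      root = "r"),
    "N5-31" = build_network(c(list(
      list(from = "r", to = "u", role = "x"),
      list(from = "r", to = "w", t = 0),
      list(from = "u", to = "h", hybrid = TRUE, grole = "gamma"),
      list(from = "w", to = "h", hybrid = TRUE),
      list(from = "h", to = "c"),
      list(from = "u", to = "A", role = "l1"),
      list(from = "w", to = "B", role = "l2")),
      .cherry("A", "a1", "a2"), .cherry("B", "b1", "b2")),
      leaves = c(a1 = "a1", a2 = "a2", b1 = "b1", b2 = "b2", c = "c"),
      root = "r"),
    "N5-32" = .three_cycle_net(c("a1", "a2"), c("b1", "b2"), "c"),
    "N5-32p" = .three_cycle_net(c("b1", "b2"), c("a1", "a2"), "c"),
    "T6" = build_network(c(list(
      list(from = "r", to = "c1"),
      list(from = "r", to = "Cn", t = 0),
      list(from = "Cn", to = "c2"),
      list(from = "Cn", to = "z", role = "l3"),
      list(from = "z", to = "A", role = "l1"),
      list(from = "z", to = "B", role = "l2")),
      .cherry("A", "a1", "a2"), .cherry("B", "b1", "b2")),
      leaves = c(a1 = "a1", a2 = "a2", b1 = "b1", b2 = "b2",
                 c1 = "c1", c2 = "c2"),
      root = "r"),
    "Na" = .three_cycle_net(c("a1", "a2"), c("b1", "b2"), c("c1", "c2")),
    "N6-32" = .three_cycle_net(c("a1", "a2"), c("b1", "b2"), c("c1", "c2")),
    "Nb" = .three_cycle_net(c("b1", "b2"), c("c1", "c2"), c("a1", "a2")),
    "Nc" = .three_cycle_net(c("c1", "c2"), c("a1", "a2"), c("b1", "b2")),
    "Ns" = .four_cycle_net(c("a1", "a2"), "b", "c", "d",
                           lroles = list(ls = "l", h1 = "h1", h2 = "h2")),
    "Nw" = .four_cycle_net("b", c("a1", "a2"), "c", "d",
                           lroles = list(lw = "l")),
    "Nn" = .four_cycle_net("b", "c", c("a1", "a2"), "d",
                           lroles = list(ln = "l")),
    "Nsw" = .four_cycle_net(c("a1", "a2"), c("b1", "b2"), "c", "d",
                            lroles = list(ls = "l1", lw = "l2",
                                          h1 = "h1", h2 = "h2")),
    "Nsn" = .four_cycle_net(c("a1", "a2"), "c", c("b1", "b2"), "d",
                            lroles = list(ls = "l1", ln = "l2",
                                          h1 = "h1", h2 = "h2")),
    "twin4cycles-L" = .twin_L(),
    "twin4cycles-C" = .twin_C(),
    "twin4cycles-R" = .twin_R(),
    "fig14-template" = .fig14(blocks),
    {
      if (grepl("^sunlet[0-9]+$", name))
        .sunlet(as.integer(sub("sunlet", "", name)))
      else stop("unknown fixture name: ", name)
    })
  if (!is.null(params)) {
    want <- fixture_params(name, blocks = blocks)
    if (!setequal(names(params), want))
      stop("parameter keys must be exactly {", paste(want, collapse = ","),
           "}; got {", paste(names(params), collapse = ","), "}")
  }
  net
}

#' Parameter role names of a fixture
#' @param name fixture name
#' @param blocks block sizes for fig14-template
#' @return character vector
#' @export
fixture_params <- function(name, blocks = c(2, 1, 1, 1)) {
  switch(name,
    "T5" = c("l1", "l2"),
    "T6" = c("l1", "l2", "l3"),
    "N5-31" = c("gamma", "x", "l1", "l2"),
    "N5-32" = , "N5-32p" = c("gamma", "h1", "h2", "x", "l1", "l2"),
    "Na" = , "Nb" = , "Nc" = , "N6-32" =
      c("gamma", "h1", "h2", "x", "l1", "l2", "l3"),
    "Ns" = c("gamma", "h1", "h2", "x1", "x2", "l"),
    "Nw" = , "Nn" = c("gamma", "x1", "x2", "l"),
    "Nsw" = , "Nsn" = c("gamma", "h1", "h2", "x1", "x2", "l1", "l2"),
    "twin4cycles-L" = c("gA", "xA1", "xA2", "gB", "xB1", "xB2", "l"),
    "twin4cycles-C" = c("gA", "xA1", "xA2", "gB", "xB1", "xB2", "l"),
    "twin4cycles-R" = c("gA", "xA1", "xA2", "hA1", "hA2",
                        "gB", "xB1", "xB2", "l"),
    "fig14-template" = {
      out <- c("gamma", "x1", "x2")
      if (blocks[1] >= 2) out <- c(out, "h1", "h2", "l")
      if (blocks[2] >= 2) out <- c(out, "lw")
      if (blocks[3] >= 2) out <- c(out, "ln")
      if (blocks[4] >= 2) out <- c(out, "le")
      out
    },
    {
      if (grepl("^sunlet[0-9]+$", name)) {
        k <- as.integer(sub("sunlet", "", name))
        c("gamma", paste0("z", 2:(k - 1)))
      } else stop("unknown fixture name: ", name)
    })
}

# k-cycle sunlet: one taxon per cycle node, hybrid node v1, taxa named by
# letters a (hybrid), b, c, ... around the cycle.  Cycle tree edge between
# v_i and v_{i+1} has role z<i>; hybrid-edge lengths are inert (1 taxon).
.sunlet <- function(k) {
  stopifnot(k >= 4)
  taxa <- letters[1:k]
  m <- ceiling(k / 2)   # root subdivides cycle edge (v_m, v_m+1)
  edges <- list(list(from = "r", to = paste0("v", m), role = paste0("z", m)),
                list(from = "r", to = paste0("v", m + 1), t = 0))
  for (i in 2:(k - 1)) {
    if (i == m) next
    # orient away from the root on the cycle arc
    a <- if (i < m) paste0("v", i + 1) else paste0("v", i)
    b <- if (i < m) paste0("v", i) else paste0("v", i + 1)
    edges[[length(edges) + 1]] <- list(from = a, to = b, role = paste0("z", i))
  }
  edges[[length(edges) + 1]] <- list(from = "v2", to = "v1", hybrid = TRUE,
                                     grole = "gamma")
  edges[[length(edges) + 1]] <- list(from = paste0("v", k), to = "v1",
                                     hybrid = TRUE)
  for (i in 1:k)
    edges[[length(edges) + 1]] <- list(from = paste0("v", i), to = taxa[i])
  build_network(edges, stats::setNames(taxa, taxa), "r")
}

.twin_L <- function() {
  half <- function(tag, taxa) {
    # returns edges of one 4-cycle half hanging below node r<tag>
    p <- paste0("p", tag); n <- paste0("n", tag); rr <- paste0("r", tag)
    h <- paste0("h", tag)
    list(list(from = rr, to = n, role = paste0("x", tag, "2")),
         list(from = n, to = p, role = paste0("x", tag, "1")),
         list(from = p, to = h, hybrid = TRUE, grole = paste0("g", tag)),
         list(from = rr, to = h, hybrid = TRUE),
         list(from = h, to = taxa[1]),
         list(from = p, to = taxa[2]),
         list(from = n, to = taxa[3]))
  }
  edges <- c(list(list(from = "r", to = "rA", role = "l"),
                  list(from = "r", to = "rB", t = 0)),
             half("A", c("a", "b", "c")), half("B", c("d", "e", "f")))
  lv <- c("a", "b", "c", "d", "e", "f")
  build_network(edges, stats::setNames(lv, lv), "r")
}

.twin_R <- function() {
  edges <- list(
    # cycle A, root on its (nA,pA) edge
    list(from = "r", to = "pA", role = "xA1"),
    list(from = "r", to = "nA", t = 0),
    list(from = "nA", to = "rA", role = "xA2"),
    list(from = "pA", to = "hA", hybrid = TRUE, grole = "gA", role = "hA1"),
    list(from = "rA", to = "hA", hybrid = TRUE, role = "hA2"),
    list(from = "pA", to = "b"),
    list(from = "nA", to = "c"),
    list(from = "rA", to = "d"),
    list(from = "hA", to = "pB", role = "l"),
    # cycle B below, hybrid block a singleton
    list(from = "pB", to = "nB", role = "xB1"),
    list(from = "nB", to = "rB", role = "xB2"),
    list(from = "pB", to = "hB", hybrid = TRUE, grole = "gB"),
    list(from = "rB", to = "hB", hybrid = TRUE),
    list(from = "hB", to = "a"),
    list(from = "nB", to = "e"),
    list(from = "rB", to = "f"))
  lv <- c("a", "b", "c", "d", "e", "f")
  build_network(edges, stats::setNames(lv, lv), "r")
}

.twin_C <- function() {
  edges <- list(
    list(from = "r", to = "pA", role = "xA1"),
    list(from = "r", to = "nA", t = 0),
    list(from = "nA", to = "rA", role = "xA2"),
    list(from = "pA", to = "hA", hybrid = TRUE, grole = "gA", role = "hA1"),
    list(from = "rA", to = "hA", hybrid = TRUE, role = "hA2"),
    list(from = "pA", to = "b"),
    list(from = "nA", to = "c"),
    list(from = "rA", to = "d"),
    # cycle B attached at the node opposite its hybrid
    list(from = "hA", to = "nB", role = "l"),
    list(from = "nB", to = "pB", role = "xB1"),
    list(from = "nB", to = "rB", role = "xB2"),
    list(from = "pB", to = "hB", hybrid = TRUE, grole = "gB"),
    list(from = "rB", to = "hB", hybrid = TRUE),
    list(from = "hB", to = "a"),
    list(from = "pB", to = "e"),
    list(from = "rB", to = "f"))
  lv <- c("a", "b", "c", "d", "e", "f")
  build_network(edges, stats::setNames(lv, lv), "r")
}

.fig14 <- function(blocks) {
  stopifnot(length(blocks) == 4, all(blocks %in% 1:2))
  bl <- function(letter, k) if (k == 1) letter else paste0(letter, 1:2)
  lr <- list()
  if (blocks[1] >= 2) lr <- c(lr, list(ls = "l", h1 = "h1", h2 = "h2"))
  if (blocks[2] >= 2) lr <- c(lr, list(lw = "lw"))
  if (blocks[3] >= 2) lr <- c(lr, list(ln = "ln"))
  if (blocks[4] >= 2) lr <- c(lr, list(le = "le"))
  .four_cycle_net(bl("a", blocks[1]), bl("b", blocks[2]),
                  bl("c", blocks[3]), bl("d", blocks[4]), lroles = lr)
}

#' Random rational parameters for a fixture
#'
#' Uniform dyadic rationals (denominator `den`) in `bounds`, seeded; exact
#' `qq` values so CF round trips can be tested exactly.  The default
#' denominator 32 keeps every intermediate of the exact engine below the
#' 2^53 overflow guard even for degree-10 CF polynomials.
#'
#' @param name fixture name
#' @param seed integer seed
#' @param bounds length-2 numeric within (0,1)
#' @param den dyadic denominator of the draws
#' @param blocks block sizes for fig14-template
#' @return named list of `qq` values
#' @export
random_params <- function(name, seed, bounds = c(0.05, 0.95), den = 32,
                          blocks = c(2, 1, 1, 1)) {
  keys <- fixture_params(name, blocks = blocks)
  lo <- max(1, ceiling(bounds[1] * den)); hi <- min(den - 1, floor(bounds[2] * den))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vals <- sample(lo:hi, length(keys), replace = TRUE)
  stats::setNames(lapply(vals, function(v) qq(v, den)), keys)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Instantiate a role-labelled network as a metric network
#'
#' Replaces every edge's parameter roles by numeric branch lengths
#' t = -log(prod ell) and resolves gamma roles to numeric inheritance
#' probabilities, so the network can be fed to the gene-tree simulator or
#' written as extended Newick.
#'
#' @param net a `qcf_net` with parameter roles
#' @param params named list of parameter values (ring elements or numerics)
#' @return a metric `qcf_net`
#' @export
as_metric <- function(net, params) {
  pn <- lapply(params, rr_tonum)
  for (i in seq_len(nrow(net$edges))) {
    rl <- net$roles[[i]]
    if (length(rl)) {
      ell <- prod(unlist(pn[rl]))
      base <- if (is.na(net$edges$t[i])) 0 else net$edges$t[i]
      net$edges$t[i] <- base - log(ell)
      net$roles[[i]] <- character(0)
    }
    if (!is.na(net$groles[i])) {
      net$edges$gamma[i] <- pn[[net$groles[i]]]
      net$groles[i] <- NA_character_
    }
  }
  # fill partner gammas
  for (h in .hybrid_nodes(net)) {
    ei <- which(net$edges$hybrid & net$edges$n2 == h)
    g <- net$edges$gamma[ei]
    if (sum(is.na(g)) == 1) net$edges$gamma[ei[is.na(g)]] <- 1 - g[!is.na(g)]
  }
  net
}

#' Numeric view of a parameter list
#' @param params named list of ring elements
#' @return named numeric vector
#' @export
params_num <- function(params) {
  vapply(params, rr_tonum, 0)
}

#' Symbolic view of a fixture's parameters
#' @param name fixture name
#' @param blocks block sizes for fig14-template
#' @return named list of `mpol` variables over the fixture's roles
#' @export
params_sym <- function(name, blocks = c(2, 1, 1, 1)) {
  keys <- fixture_params(name, blocks = blocks)
  stats::setNames(lapply(keys, mpol_var, vars = keys), keys)
}
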