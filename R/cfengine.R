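# Exact quartet concordance factors under the network multispecies coalescent.
#
# The computation is a dynamic program over a topologically ordered rooted
# version of the (induced) quartet network.  A state assigns each of the four
# sampled lineages, traced backward in time, to the node it has reached; all
# lineages entering an edge do so at its child node and are co-resident for
# the whole edge, so within an edge with j lineages the first coalescence
# occurs before the top with probability 1 - ell^C(j,2) (ell = exp(-t)) and
# the first merging pair is uniform among the C(j,2) pairs.  The first
# coalescence among the four sampled lineages determines the gene quartet, so
# any merge resolves the state; at a hybrid node each lineage independently
# follows a parent edge with probability gamma / 1-gamma; if all four
# lineages reach the root unresolved, exchangeability gives each quartet
# probability 1/3.  All operations run over any coefficient ring (see
# arith.R), so the same code produces floats, exact rationals, values in
# GF(p), or symbolic polynomials.

# split index of the quartet resolved when samples i and j merge first,
# with samples in canonical (sorted-taxon) order 1..4:
#   1 = 12|34, 2 = 13|24, 3 = 14|23
.SPLIT_OF_PAIR <- matrix(c(0, 1, 2, 3,
                           1, 0, 3, 2,
                           2, 3, 0, 1,
                           3, 2, 1, 0), 4, 4)

# resolve the edge probability of edge i as a ring element (NULL = inert)
.edge_ell <- function(net, i, params, tmpl) {
  parts <- list()
  rl <- net$roles[[i]]
  for (r in rl) {
    if (is.null(params[[r]])) stop("missing parameter: ", r)
    parts[[length(parts) + 1]] <- params[[r]]
  }
  t <- net$edges$t[i]
  if (!is.na(t) && t != 0) {
    if (!is.numeric(tmpl)) stop("numeric branch length on edge ", i,
                                " cannot be used in an exact/symbolic ring")
    parts[[length(parts) + 1]] <- exp(-t)
  }
  if (length(parts) == 0) {
    if (!is.na(t)) return(rr_fromint(tmpl, 1))   # explicit zero length
    return(NULL)                                 # inert: no length given
  }
  out <- parts[[1]]
  for (p in parts[-1]) out <- rr_mul(out, p)
  out
}

.edge_gamma <- function(net, i, params, tmpl) {
  gr <- net$groles[i]
  if (!is.na(gr)) {
    if (!is.null(params[[gr]])) return(params[[gr]])
    # partner's role: compute 1 - gamma(partner)
    h <- net$edges$n2[i]
    j <- setdiff(which(net$edges$hybrid & net$edges$n2 == h), i)
    grj <- net$groles[j]
    if (!is.na(grj) && !is.null(params[[grj]]))
      return(rr_sub(rr_fromint(tmpl, 1), params[[grj]]))
    stop("missing gamma parameter: ", gr)
  }
  g <- net$edges$gamma[i]
  if (is.na(g)) {
    h <- net$edges$n2[i]
    j <- setdiff(which(net$edges$hybrid & net$edges$n2 == h), i)
    if (!is.na(net$groles[j]) && !is.null(params[[net$groles[j]]]))
      return(rr_sub(rr_fromint(tmpl, 1), params[[net$groles[j]]]))
    if (!is.na(net$edges$gamma[j])) g <- 1 - net$edges$gamma[j] else
      stop("hybrid edge without gamma")
  }
  if (!is.numeric(tmpl)) stop("numeric gamma cannot be used in an exact/symbolic ring")
  g
}

.ring_template <- function(params) {
  if (!is.null(params)) {
    for (p in params) if (!is.numeric(p)) return(p)
  }
  1.0
}

#' Quartet CF of a 4-taxon rooted network
#'
#' @param net rooted `qcf_net` with exactly 4 leaves
#' @param params named list of ring elements for parameter roles (NULL for
#'   purely metric networks, computed in doubles)
#' @return list with `taxa` (canonical order) and `cf` (3 ring elements for
#'   splits 12|34, 13|24, 14|23)
#' @export
quartet_cf_rooted <- function(net, params = NULL) {
  stopifnot(net$rooted, length(net$leaves) == 4)
  tmpl <- .ring_template(params)
  one <- rr_fromint(tmpl, 1); zero <- rr_fromint(tmpl, 0)
  taxa <- sort(names(net$leaves))
  pos0 <- unname(net$leaves[taxa])
  ed <- net$edges
  ells <- lapply(seq_len(nrow(ed)), function(i) .edge_ell(net, i, params, tmpl))
  out <- list(zero, zero, zero)
  states <- list(); states[[paste(pos0, collapse = ",")]] <- list(pos = pos0, w = one)
  topo <- rev(.topo_order(net))
  resolve <- function(widx, i, j, w) {
    s <- .SPLIT_OF_PAIR[i, j]
    out[[s]] <<- rr_add(out[[s]], w)
  }
  for (v in topo) {
    pe <- which(ed$n2 == v)    # parent edges of v
    new_states <- list()
    put <- function(pos, w) {
      key <- paste(pos, collapse = ",")
      if (is.null(new_states[[key]])) new_states[[key]] <<- list(pos = pos, w = w)
      else new_states[[key]]$w <<- rr_add(new_states[[key]]$w, w)
    }
    for (st in states) {
      idx <- which(st$pos == v)
      j <- length(idx)
      if (length(pe) == 0) {                      # root
        if (j == 0) { put(st$pos, st$w) ; next }
        if (j != 4 || any(st$pos != v)) stop("internal error: lineages missed the root")
        third <- rr_divint(st$w, 3)
        for (s in 1:3) out[[s]] <- rr_add(out[[s]], third)
      } else if (j == 0) {
        put(st$pos, st$w)
      } else if (length(pe) == 1) {               # tree node or leaf
        e <- pe[1]
        up <- ed$n1[e]
        if (j == 1) {
          pos <- st$pos; pos[idx] <- up
          put(pos, st$w)
        } else {
          ell <- ells[[e]]
          if (ed$nocoal[e]) {
            pos <- st$pos; pos[idx] <- up
            put(pos, st$w)
          } else {
            if (is.null(ell)) stop("edge with missing length carries 2+ lineages")
            q <- choose(j, 2)
            pnm <- rr_pow(ell, q)
            pos <- st$pos; pos[idx] <- up
            put(pos, rr_mul(st$w, pnm))
            pmerge <- rr_divint(rr_sub(one, pnm), q)
            wpm <- rr_mul(st$w, pmerge)
            for (a in seq_len(j - 1)) for (b in (a + 1):j)
              resolve(NULL, idx[a], idx[b], wpm)
          }
        }
      } else {                                    # hybrid node: 2 parent edges
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
            # (2,2): a merge in either edge resolves to the same split
            s <- .SPLIT_OF_PAIR[grp1[1], grp1[2]]
            out[[s]] <- rr_add(out[[s]], rr_mul(w, rr_sub(one, rr_mul(t1$pnm, t2$pnm))))
          } else {
            if (j1 >= 2) {
              wpm <- rr_mul(w, rr_divint(rr_sub(one, t1$pnm), t1$q))
              for (a in seq_len(j1 - 1)) for (b in (a + 1):j1)
                resolve(NULL, grp1[a], grp1[b], wpm)
            }
            if (j2 >= 2) {
              wpm <- rr_mul(w, rr_divint(rr_sub(one, t2$pnm), t2$q))
              for (a in seq_len(j2 - 1)) for (b in (a + 1):j2)
                resolve(NULL, grp2[a], grp2[b], wpm)
            }
          }
        }
      }
    }
    states <- new_states
  }
  list(taxa = taxa, cf = out)
}

#' Quartet CF on any network
#'
#' Induces the quartet network on four taxa (choosing a valid rooting if the
#' input is semidirected) and runs the exact NMSC computation.
#'
#' @param net a `qcf_net`
#' @param taxa four taxon labels (default: the network's 4 taxa)
#' @param params named list of ring-element parameter values for role-labelled
#'   edges; NULL for metric networks
#' @return list with `taxa` and `cf` as in [quartet_cf_rooted()]
#' @export
quartet_cf <- function(net, taxa = NULL, params = NULL) {
  if (is.null(taxa)) {
    if (length(net$leaves) != 4) stop("network does not have exactly 4 taxa; give `taxa`")
    taxa <- names(net$leaves)
  }
  ind <- induced_network(net, taxa)
  quartet_cf_rooted(ind, params)
}

#' Full CF table of a network
#'
#' One CF vector for every 4-subset of the taxa (after optional pseudotaxon
#' expansion of a multi-sample map), each computed on the induced quartet
#' network.
#'
#' @param net a `qcf_net`
#' @param params named list of ring-element parameter values (optional)
#' @param samples optional named vector taxon -> sample count
#' @return a `cf_table` object
#' @export
cf_table <- function(net, params = NULL, samples = NULL) {
  if (!is.null(samples)) net <- expand_samples(net, samples)
  taxa <- network_taxa(net)
  if (length(taxa) < 4) stop("need at least 4 taxa")
  rooted <- if (net$rooted) net else root_network(net)
  combs <- utils::combn(taxa, 4, simplify = FALSE)
  quartets <- lapply(combs, function(q) {
    ind <- induced_network(rooted, q)
    quartet_cf_rooted(ind, params)
  })
  structure(list(taxa = taxa, quartets = quartets), class = "cf_table")
}

#' @export
print.cf_table <- function(x, ...) {
  cat(sprintf("<cf_table: %d taxa, %d quartets>\n", length(x$taxa), length(x$quartets)))
  invisible(x)
}

#' Convert a CF table to a data frame (numeric)
#' @param x a `cf_table`
#' @param ... unused
#' @return data.frame with taxon1..4, CF12_34, CF13_24, CF14_23
#' @export
as.data.frame.cf_table <- function(x, ...) {
  do.call(rbind, lapply(x$quartets, function(q) {
    data.frame(taxon1 = q$taxa[1], taxon2 = q$taxa[2], taxon3 = q$taxa[3],
               taxon4 = q$taxa[4],
               CF12_34 = rr_tonum(q$cf[[1]]), CF13_24 = rr_tonum(q$cf[[2]]),
               CF14_23 = rr_tonum(q$cf[[3]]))
  }))
}

# locate the CF vector of a quartet (canonical order) in a table
.cf_lookup <- function(tab, taxa4) {
  key <- paste(sort(taxa4), collapse = "|")
  for (q in tab$quartets) if (paste(q$taxa, collapse = "|") == key) return(q)
  stop("quartet not in table: ", key)
}

#' A single scalar CF entry
#'
#' `cf_entry(tab, a, b, c, d)` is the probability that a gene tree displays
#' the quartet ab|cd, looked up against the table's canonical ordering.
#'
#' @param tab a `cf_table`
#' @param a,b,c,d taxon labels
#' @return a ring element
#' @export
cf_entry <- function(tab, a, b, c, d) {
  q <- .cf_lookup(tab, c(a, b, c, d))
  i <- match(a, q$taxa)
  partner <- match(b, q$taxa)
  other <- setdiff(1:4, c(i, partner))
  s <- .SPLIT_OF_PAIR[i, partner]
  q$cf[[s]]
}

## ---- CF table CSV -----------------------------------------------------------

#' Write a CF table to CSV
#'
#' Columns taxon1..taxon4, CF12_34, CF13_24, CF14_23 (and ngenes when
#' present); taxa in canonical order per row.  With `exact = TRUE`, rational
#' entries are serialized as fraction strings (e.g. "2989/30000").
#'
#' @param tab a `cf_table`
#' @param path file path
#' @param exact write fraction strings for `qq` entries
#' @export
write_cf_table <- function(tab, path, exact = FALSE) {
  rows <- lapply(tab$quartets, function(q) {
    vals <- if (exact && inherits(q$cf[[1]], "qq")) {
      vapply(q$cf, function(v) paste0(v$n, "/", v$d), "")
    } else vapply(q$cf, function(v) format(rr_tonum(v), digits = 17), "")
    r <- data.frame(taxon1 = q$taxa[1], taxon2 = q$taxa[2], taxon3 = q$taxa[3],
                    taxon4 = q$taxa[4], CF12_34 = vals[1], CF13_24 = vals[2],
                    CF14_23 = vals[3])
    if (!is.null(q$ngenes)) r$ngenes <- q$ngenes
    r
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
}

#' Read a CF table from CSV
#'
#' Fraction strings are parsed into exact rationals; plain numbers into
#' doubles.
#'
#' @param path file path
#' @return a `cf_table`
#' @export
read_cf_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  parse_val <- function(s) {
    if (grepl("/", s)) {
      p <- as.numeric(strsplit(s, "/")[[1]])
      qq(p[1], p[2])
    } else as.numeric(s)
  }
  quartets <- lapply(seq_len(nrow(df)), function(i) {
    taxa <- unname(unlist(df[i, c("taxon1", "taxon2", "taxon3", "taxon4")]))
    if (is.unsorted(taxa)) stop("CF table rows must list taxa in sorted order")
    q <- list(taxa = taxa,
              cf = list(parse_val(df$CF12_34[i]), parse_val(df$CF13_24[i]),
                        parse_val(df$CF14_23[i])))
    if ("ngenes" %in% names(df)) q$ngenes <- as.numeric(df$ngenes[i])
    q
  })
  taxa <- sort(unique(unlist(lapply(quartets, `[[`, "taxa"))))
  structure(list(taxa = taxa, quartets = quartets), class = "cf_table")
}
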