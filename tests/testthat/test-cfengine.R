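test_that("quartet species tree CFs follow the coalescent closed form", {
  for (t in c(0.2, 0.5, 2)) {
    cf <- vapply(quartet_cf(quartet_tree(t))$cf, rr_tonum, 0)
    l <- exp(-t)
    expect_equal(cf, c(1 - 2 * l / 3, l / 3, l / 3), tolerance = 1e-14)
  }
})

test_that("the contracted 3_2-cycle quartet network reproduces its closed form", {
  # cherry of two c-samples below the hybrid node, cut edge contracted to 0;
  # CF_ac|bc = (g^2 h1 + (1-g)^2 h2)/3 + g(1-g)(1 - x/3)
  q <- build_network(list(
    list(from = "r", to = "u", role = "x"),
    list(from = "r", to = "w", t = 0),
    list(from = "u", to = "h", hybrid = TRUE, grole = "gamma", role = "h1"),
    list(from = "w", to = "h", hybrid = TRUE, role = "h2"),
    list(from = "u", to = "a"),
    list(from = "w", to = "b"),
    list(from = "h", to = "CC", t = 0),
    list(from = "CC", to = "c1"),
    list(from = "CC", to = "c2")),
    leaves = c(a = "a", b = "b", c1 = "c1", c2 = "c2"), root = "r")
  for (seed in 1:5) {
    pars <- random_params("N5-32", seed)[c("gamma", "h1", "h2", "x")]
    cf <- quartet_cf(q, params = pars)
    g <- rr_tonum(pars$gamma); h1 <- rr_tonum(pars$h1)
    h2 <- rr_tonum(pars$h2); x <- rr_tonum(pars$x)
    cfac_bc <- (g^2 * h1 + (1 - g)^2 * h2) / 3 + g * (1 - g) * (1 - x / 3)
    expect_equal(rr_tonum(cf$cf[[2]]), cfac_bc, tolerance = 1e-14)
    expect_equal(rr_tonum(cf$cf[[1]]), 1 - 2 * cfac_bc, tolerance = 1e-14)
  }
})

test_that("CF vectors are normalized exactly in rational mode", {
  for (nm in c("T5", "N5-31", "N5-32", "Na", "Ns", "sunlet5")) {
    pars <- random_params(nm, 11)
    tab <- cf_table(make_named(nm), params = pars)
    for (q in tab$quartets) {
      s <- rr_add(rr_add(q$cf[[1]], q$cf[[2]]), q$cf[[3]])
      expect_qq_equal(s, qq(1))
    }
  }
})

test_that("the p-vector closed forms agree with the explicit fragment", {
  frag <- three_cycle_fragment()
  ent <- function(...) {
    e <- list(...)
    stats::setNames(lapply(e, function(x) frag$leaves[[x]]),
                    as.character(seq_along(e)))
  }
  for (seed in 1:10) {
    pars <- random_params("Na", seed)
    pv <- p_vector(pars$gamma, pars$l1, pars$l2, pars$l3,
                   pars$h1, pars$h2, pars$x)
    r1 <- conditional_resolution(frag, ent("a", "b"), params = pars)
    expect_qq_equal(r1$split[[1]], pv$p1)
    r2 <- conditional_resolution(frag, ent("a", "a"), params = pars)
    expect_qq_equal(r2$split[[1]], pv$p2)
    r3 <- conditional_resolution(frag, ent("b", "b"), params = pars)
    expect_qq_equal(r3$split[[1]], pv$p3)
    r4 <- conditional_resolution(frag, ent("a", "b", "b"), params = pars)
    expect_qq_equal(r4$split[[2]], pv$p4)                       # ab|bc
    expect_qq_equal(r4$split[[3]],
                    rr_sub(qq(1), rr_mul(qq(2), pv$p4)))        # bb|ac
    r5 <- conditional_resolution(frag, ent("a", "a", "b"), params = pars)
    expect_qq_equal(r5$split[[2]], pv$p5)
    expect_qq_equal(r5$split[[1]],
                    rr_sub(qq(1), rr_mul(qq(2), pv$p5)))        # aa|bc
    r6 <- conditional_resolution(frag, ent("a", "a", "b", "b"), params = pars)
    expect_qq_equal(r6$split[[2]], pv$p6)
    expect_qq_equal(r6$split[[1]],
                    rr_sub(qq(1), rr_mul(qq(2), pv$p6)))        # aa|bb
  }
  # gamma -> 0 limit of p1 is 1 - l3 (plain substitution)
  pv0 <- p_vector(1e-12, 0.9, 0.8, 0.5, 0.7, 0.6, 0.3)
  expect_equal(pv0$p1, 1 - 0.5 * (1 - 1e-12 + 1e-12 * 0.3))
  # strict range checking
  expect_error(p_vector(1.2, 1, 1, 1, 1, 1, 1), "range|gamma")
})

test_that("a single-node fragment leaves everything undetermined", {
  frag <- build_network(list(list(from = "top", to = "a", t = 0)),
                        leaves = c(a = "a"), root = "top")
  r <- conditional_resolution(frag,
                              list("1" = frag$leaves[["a"]],
                                   "2" = frag$leaves[["a"]]))
  expect_equal(rr_tonum(r$undetermined), 1)
  expect_true(all(vapply(r$split, rr_tonum, 0) == 0))
})

test_that("decomposition assembly equals the direct CF table", {
  for (nm in c("Na", "N6-32")) {
    pars <- random_params(nm, 23)
    net <- make_named(nm)
    t_direct <- cf_table(net, params = pars)
    t_dec <- cf_via_decomposition(net, params = pars)
    for (i in seq_along(t_direct$quartets)) {
      for (s in 1:3)
        expect_qq_equal(t_dec$quartets[[i]]$cf[[s]],
                        t_direct$quartets[[i]]$cf[[s]])
    }
  }
  # degenerate cycle (x = 1, h1 = h2 = 1) reduces to the tree T6
  pars <- random_params("Na", 2)
  pars$x <- qq(1); pars$h1 <- qq(1); pars$h2 <- qq(1)
  t_na <- cf_table(make_named("Na"), params = pars)
  t_t6 <- cf_table(make_named("T6"),
                   params = pars[c("l1", "l2", "l3")])
  for (i in seq_along(t_na$quartets))
    for (s in 1:3)
      expect_qq_equal(t_na$quartets[[i]]$cf[[s]], t_t6$quartets[[i]]$cf[[s]])
  expect_error(cf_via_decomposition(make_named("Ns"),
                                    params = random_params("Ns", 1)),
               "3-cycle")
})

test_that("CF tables are invariant under rooting choice and pseudotaxon permutation", {
  pars <- random_params("Ns", 31)
  net <- to_semidirected(as_metric(make_named("Ns"), lapply(pars, rr_tonum)))
  tabs <- list()
  for (e in which(!net$edges$hybrid)) {
    r <- tryCatch(root_network(net, at = e), error = function(e) NULL)
    if (is.null(r)) next
    tabs[[length(tabs) + 1]] <- cf_table(r)
  }
  expect_gte(length(tabs), 3)
  for (i in seq_along(tabs)[-1]) expect_cf_equal(tabs[[1]], tabs[[i]], tol = 1e-13)

  # permuting pseudotaxa of one taxon leaves the table invariant
  nw <- add_pseudotaxa(quartet_tree(0.4), "a", 2)
  tab <- cf_table(nw)
  e1 <- rr_tonum(cf_entry(tab, "a.1", "b", "c", "d"))
  e2 <- rr_tonum(cf_entry(tab, "a.2", "b", "c", "d"))
  expect_equal(e1, e2)
})

test_that("symbolic engine output is polynomial with exact rational coefficients", {
  sc <- symbolic_cf("N5-31")
  expect_true(all(vapply(sc$polys, inherits, TRUE, "mpol")))
  # spot check degree and exactness: coefficients have denominators 3^k
  for (p in sc$polys) {
    if (nrow(p$E) == 0) next
    expect_true(all(p$cd %in% c(1, 3, 9, 27)))
  }
})

test_that("CF table CSV round-trips exactly with fraction serialization", {
  pars <- random_params("N5-31", 17)
  tab <- cf_table(make_named("N5-31"), params = pars)
  f <- tempfile(fileext = ".csv")
  write_cf_table(tab, f, exact = TRUE)
  back <- read_cf_table(f)
  for (i in seq_along(tab$quartets))
    for (s in 1:3)
      expect_qq_equal(back$quartets[[i]]$cf[[s]], tab$quartets[[i]]$cf[[s]])
  unlink(f)
})
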