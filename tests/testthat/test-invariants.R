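test_that("f vanishes identically on T5, symbolically and at random points", {
  ps <- params_sym("T5")
  tab <- cf_table(make_named("T5"), params = ps)
  f <- f_statistic(tab, std_blocks5)
  expect_true(qcfnet:::rr_iszero(f))
  for (seed in 1:25) {
    tabq <- cf_table(make_named("T5"), params = random_params("T5", seed))
    expect_qq_equal(f_statistic(tabq, std_blocks5), qq(0))
  }
})

test_that("the three G statistics vanish identically on T6 and sum to zero always", {
  ps <- params_sym("T6")
  tab <- cf_table(make_named("T6"), params = ps)
  g <- g_statistics(tab, std_blocks6)
  for (v in g) expect_true(qcfnet:::rr_iszero(v))
  # sum identity on arbitrary tables: treat the six entries as free symbols
  vars <- c("pab", "pac", "pbc", "mabac", "mabbc", "sacbc")
  sy <- stats::setNames(lapply(vars, mpol_var, vars = vars), vars)
  Gabc <- rr_add(rr_sub(rr_mul(sy$pac, sy$mabbc),
                        rr_mul(mpol_const(vars, 2), rr_mul(sy$pbc, sy$mabac))),
                 rr_mul(sy$pab, sy$sacbc))
  Gcab <- rr_add(rr_sub(rr_mul(sy$pbc, sy$mabac),
                        rr_mul(mpol_const(vars, 2), rr_mul(sy$pab, sy$sacbc))),
                 rr_mul(sy$pac, sy$mabbc))
  Gbca <- rr_add(rr_sub(rr_mul(sy$pab, sy$sacbc),
                        rr_mul(mpol_const(vars, 2), rr_mul(sy$pac, sy$mabbc))),
                 rr_mul(sy$pbc, sy$mabac))
  expect_true(qcfnet:::rr_iszero(rr_add(rr_add(Gabc, Gcab), Gbca)))
  # and on exact engine tables of a network
  for (seed in 1:10) {
    tabq <- cf_table(make_named("Na"), params = random_params("Na", seed, den = 16))
    gq <- g_statistics(tabq, std_blocks6)
    expect_qq_equal(rr_add(rr_add(gq$Gabc, gq$Gcab), gq$Gbca), qq(0))
    expect_true(rr_tonum(gq$Gabc) > 0)             # hybrid block is A on Na
  }
})

test_that("sign conditions: f > 0 on N5-31, f-tilde < 0 on N5-32, both signs occur", {
  seen_pos <- FALSE; seen_neg <- FALSE
  for (seed in 1:25) {
    p31 <- random_params("N5-31", seed)
    t31 <- cf_table(make_named("N5-31"), params = p31)
    f <- f_statistic(t31, std_blocks5)
    # closed form l1 l2 g (1-g) (x-1)^2 / 3
    g <- p31$gamma; x <- p31$x
    cf <- rr_divint(rr_mul(rr_mul(p31$l1, p31$l2),
                           rr_mul(rr_mul(g, rr_sub(qq(1), g)),
                                  rr_pow(rr_sub(x, qq(1)), 2))), 3)
    expect_qq_equal(f, cf)
    expect_gt(rr_tonum(f), 0)

    p32 <- random_params("N5-32", seed, den = 16)
    t32 <- cf_table(make_named("N5-32"), params = p32)
    expect_lt(rr_tonum(f_tilde_statistic(t32, std_blocks5)), 0)
    fv <- rr_tonum(f_statistic(t32, std_blocks5))
    if (fv > 0) seen_pos <- TRUE
    if (fv < 0) seen_neg <- TRUE
    # f is invariant under interchanging the a and b blocks (N5-32')
    t32p <- cf_table(make_named("N5-32p"), params = p32)
    expect_qq_equal(f_statistic(t32, std_blocks5), f_statistic(t32p, std_blocks5))
  }
  expect_true(seen_pos && seen_neg)
  # on T5, f-tilde = -CF_ab|ab / 2 < 0
  pt <- random_params("T5", 4)
  tt <- cf_table(make_named("T5"), params = pt)
  ft <- f_tilde_statistic(tt, std_blocks5)
  expect_qq_equal(ft, rr_divint(cf_entry(tt, "a1", "b1", "a2", "b2"), -2))
})

test_that("an f-tilde > 0 point exists on N5-31 (c identified as hybrid)", {
  found <- FALSE
  for (seed in 1:80) {
    p <- random_params("N5-31", seed, bounds = c(0.02, 0.98), den = 64)
    tab <- cf_table(make_named("N5-31"), params = p)
    if (rr_tonum(f_tilde_statistic(tab, std_blocks5)) > 0) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("the 9 G_abc closed form holds symbolically on Na", {
  sc <- params_sym("Na")
  tab <- cf_table(make_named("Na"), params = sc)
  g <- g_statistics(tab, std_blocks6)
  nine_g <- rr_mul(mpol_const(names(sc), 9), g$Gabc)
  # printed: g(1-g)(1-x)^2 l1 l2 l3 [h1 g + h2 (1-g) + 2]
  v <- sc
  one <- mpol_const(names(sc), 1)
  closed <- rr_mul(
    rr_mul(rr_mul(v$gamma, rr_sub(one, v$gamma)),
           rr_pow(rr_sub(one, v$x), 2)),
    rr_mul(rr_mul(v$l1, rr_mul(v$l2, v$l3)),
           rr_add(rr_add(rr_mul(v$h1, v$gamma),
                         rr_mul(v$h2, rr_sub(one, v$gamma))),
                  mpol_const(names(sc), 2))))
  expect_true(qcfnet:::rr_iszero(rr_sub(nine_g, closed)))
})

test_that("no-ILS limit: f and G tend to zero as edge probabilities vanish", {
  fat <- function(eps) {
    p31 <- random_params("N5-31", 5, den = 8)
    p31$l1 <- eps; p31$l2 <- eps
    rr_tonum(f_statistic(cf_table(make_named("N5-31"), params = p31),
                         std_blocks5))
  }
  f1 <- fat(qq(1, 16)); f2 <- fat(qq(1, 64))
  expect_lt(abs(f2), abs(f1) / 4)
  expect_lt(abs(f2), 1e-3)
  gat <- function(eps) {
    pna <- random_params("Na", 5, den = 8)
    pna$l1 <- eps; pna$l2 <- eps; pna$l3 <- eps
    max(abs(vapply(g_statistics(cf_table(make_named("Na"), params = pna),
                                std_blocks6), rr_tonum, 0)))
  }
  g1 <- gat(qq(1, 16)); g2 <- gat(qq(1, 64))
  expect_lt(g2, g1 / 4)
  expect_lt(g2, 1e-3)
})

test_that("classification follows the printed case tables", {
  # tree node
  call <- classify_three_cycle(cf_table(make_named("T6"),
                                        params = random_params("T6", 9)),
                               std_blocks6)
  expect_equal(call$verdict, "tree-node")
  # 3-cycle on Na: A never excluded, verdict names A among candidates
  call2 <- classify_three_cycle(cf_table(make_named("Na"),
                                         params = random_params("Na", 9)),
                                std_blocks6)
  expect_true(call2$verdict %in% c("3-cycle-hybrid-identified",
                                   "3-cycle-hybrid-ambiguous"))
  expect_true("A" %in% call2$hybrid)
  expect_false("A" %in% call2$excluded)
  # singleton route: on N5-32 (hybrid is the a-pair) f < 0 excludes c
  call3 <- classify_three_cycle(cf_table(make_named("N5-32"),
                                         params = random_params("N5-32", 2)),
                                std_blocks5)
  if (call3$verdict == "3-cycle-hybrid-ambiguous") expect_equal(call3$excluded, "C")
  # tree via f: T5
  call4 <- classify_three_cycle(cf_table(make_named("T5"),
                                         params = random_params("T5", 2)),
                                std_blocks5)
  expect_equal(call4$verdict, "tree-node")
})

test_that("G factorizes through the 3-cycle block on a larger network", {
  # 7-taxon network: Na with a third taxon appended above the c-cherry; the
  # G statistics on representatives factor as a positive multiple of the
  # N6-32 values, so sign patterns match exactly
  edges <- list(
    list(from = "r", to = "c3"),
    list(from = "r", to = "v", t = 0),
    list(from = "v", to = "Cc", role = "lc"),
    list(from = "Cc", to = "c1"), list(from = "Cc", to = "c2"),
    list(from = "v", to = "w", role = "l3"),
    list(from = "w", to = "u", role = "x"),
    list(from = "u", to = "h", hybrid = TRUE, grole = "gamma", role = "h1"),
    list(from = "w", to = "h", hybrid = TRUE, role = "h2"),
    list(from = "h", to = "A", role = "l1"),
    list(from = "A", to = "a1"), list(from = "A", to = "a2"),
    list(from = "u", to = "B", role = "l2"),
    list(from = "B", to = "b1"), list(from = "B", to = "b2"))
  lv <- c("a1", "a2", "b1", "b2", "c1", "c2", "c3")
  big <- build_network(edges, stats::setNames(lv, lv), "r")
  pars <- c(random_params("Na", 6, den = 16), list(lc = qq(5, 8)))
  tab_big <- cf_table(big, params = pars)
  tab_na <- cf_table(make_named("Na"), params = pars[fixture_params("Na")])
  g_big <- g_statistics(tab_big, std_blocks6)
  g_na <- g_statistics(tab_na, std_blocks6)
  # same sign pattern and a common positive ratio across the three G's
  ratio <- rr_tonum(g_big$Gabc) / rr_tonum(g_na$Gabc)
  expect_gt(ratio, 0)
  expect_equal(rr_tonum(g_big$Gcab) / rr_tonum(g_na$Gcab), ratio, tolerance = 1e-9)
  expect_equal(rr_tonum(g_big$Gbca) / rr_tonum(g_na$Gbca), ratio, tolerance = 1e-9)
})

test_that("averaged (empirical-mode) statistics agree with exact mode on exact tables", {
  pars <- random_params("Na", 3)
  tab <- cf_table(make_named("Na"), params = pars)
  ge <- g_statistics(tab, std_blocks6, mode = "exact")
  ga <- g_statistics(tab, std_blocks6, mode = "average")
  for (nm in names(ge))
    expect_equal(rr_tonum(ge[[nm]]), rr_tonum(ga[[nm]]), tolerance = 1e-12)
})

test_that("Jacobian ranks of the CF parameterizations match the variety dimensions", {
  expect_equal(as.integer(variety_dimension("Ns")), 5L)
  expect_equal(as.integer(variety_dimension("Nw")), 4L)
  expect_equal(as.integer(variety_dimension("Nn")), 3L)
  expect_equal(as.integer(variety_dimension("pmap")), 6L)
})

test_that("orientation is recovered for each hybrid placement and flags degeneracy", {
  cases <- list(
    Ns = list(A = c("a1", "a2"), W = "b", N = "c", E = "d"),
    Nw = list(A = c("a1", "a2"), W = "b", N = "d", E = "c"),
    Nn = list(A = c("a1", "a2"), W = "c", N = "b", E = "d"))
  for (nm in names(cases)) {
    pars <- lapply(random_params(nm, 41), rr_tonum)
    tab <- cf_table(make_named(nm), params = pars)
    v <- orient_four_cycle(tab, cases[[nm]], seed = 7)
    expect_identical(v$verdict, tolower(substr(nm, 2, 2)))
  }
  # degenerate all-1/3 table: inconclusive
  deg <- cf_table(make_named("Ns"),
                  params = list(gamma = 0.5, h1 = 1, h2 = 1, x1 = 1,
                                x2 = 1, l = 1))
  v <- orient_four_cycle(deg, cases$Ns, seed = 1)
  expect_true(v$inconclusive || length(v$verdict) == 0)
})

test_that("the printed V1/V2/V3 generators vanish on their degenerate loci", {
  # V3: l -> 0 on Nw (infinite cherry edge): the three generators vanish
  pars <- lapply(random_params("Nw", 8), rr_tonum)
  pars$l <- 0
  tab <- cf_table(make_named("Nw"), params = pars)
  gens <- qcfnet:::.v123_generators(tab, list(A = c("a1", "a2"), W = "b",
                                              N = "d", E = "c"))
  expect_true(all(abs(gens$V3) < 1e-12))
})
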