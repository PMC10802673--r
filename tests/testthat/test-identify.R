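test_that("edge lengths are exact from defining quartets", {
  # 7-taxon tree: every internal edge recovered from its defining quartet
  nw <- parse_network(
    "(((a:1,b:1):0.4,(c:1,d:1):0.7):0.6,((e:1,f:1):0.3,g:1):0.2);")
  tab <- cf_table(nw)
  sd <- to_semidirected(nw)
  ed <- sd$edges
  internal <- which(!(ed$n1 %in% sd$leaves) & !(ed$n2 %in% sd$leaves))
  expect_gte(length(internal), 3)
  est <- recover_parameters(sd, tab)
  for (e in internal) {
    nm <- qcfnet:::.ename(sd, e)
    expect_equal(est[[nm]]$status, "identified")
    expect_equal(-log(rr_tonum(est[[nm]]$value)), ed$t[e], tolerance = 1e-12)
  }
  # direct formula check: quartet {a,b,c,g} defines the 0.4 edge (the other
  # internal edges absorb into pendant paths under restriction)
  r <- edge_length_from_quartet(tab, c("a", "b", "c", "g"))
  expect_equal(r$t, 0.4, tolerance = 1e-12)
  # CF_discordant = 1/3 gives t = 0; > 1/3 errors unless extended
  flat <- structure(list(taxa = c("a", "b", "c", "d"),
                         quartets = list(list(taxa = c("a", "b", "c", "d"),
                                              cf = list(1 / 3, 1 / 3, 1 / 3)))),
                    class = "cf_table")
  expect_equal(edge_length_from_quartet(flat, c("a", "b", "c", "d"))$t, 0)
  hot <- structure(list(taxa = c("a", "b", "c", "d"),
                        quartets = list(list(taxa = c("a", "b", "c", "d"),
                                             cf = list(0.2, 0.4, 0.4)))),
                   class = "cf_table")
  expect_error(edge_length_from_quartet(hot, c("a", "b", "c", "d")), "extended")
  expect_lt(edge_length_from_quartet(hot, c("a", "b", "c", "d"),
                                     extended = TRUE)$t, 0)
})

test_that("identifiable parameters are recovered exactly on the acceptance fixtures", {
  run <- function(name, seed, den = 32) {
    pars <- random_params(name, seed, den = den)
    net <- make_named(name)
    tab <- cf_table(net, params = pars)
    est <- recover_parameters(net, tab)
    list(pars = pars, est = est)
  }
  for (seed in c(3, 19)) {
    for (name in c("sunlet5", "Nsw", "Nsn")) {
      r <- run(name, seed)
      aud_idf <- setdiff(names(r$pars), "z3")
      for (nm in names(r$pars)) {
        e <- r$est[[nm]]
        expect_false(is.null(e), label = paste(name, nm))
        if (e$status == "identified") expect_qq_equal(e$value, r$pars[[nm]])
      }
      # on these fixtures the audit says every named parameter is identifiable
      expect_true(all(vapply(names(r$pars), function(nm)
        r$est[[nm]]$status == "identified", TRUE)))
    }
    r <- run("twin4cycles-L", seed)
    for (nm in names(r$pars))
      expect_qq_equal(r$est[[nm]]$value, r$pars[[nm]])
  }
  # twin-R: only cycle B's gamma and adjacent edges are identifiable
  # (cycle A falls under the all-singleton-adjacent-blocks case); verify the
  # identified ones exactly in GF(p), where magnitudes exceed the qq guard
  p <- GFP_PRIMES[2]
  pars <- random_params("twin4cycles-R", 5, den = 64)
  parsg <- gfp_params(pars, p)
  net <- make_named("twin4cycles-R")
  est <- recover_parameters(net, cf_table(net, params = parsg))
  for (nm in c("gB", "xB1", "xB2")) {
    expect_equal(est[[nm]]$status, "identified")
    expect_equal(est[[nm]]$value$v, parsg[[nm]]$v)
  }
  for (nm in c("gA", "xA1", "xA2", "hA1", "hA2", "l"))
    expect_equal(est[[nm]]$status, "not-identifiable")
})

test_that("four_cycle_case labels the named networks as printed", {
  case_of <- function(name) {
    net <- to_semidirected(make_named(name))
    cyc <- Filter(function(c) c$m == 4, find_cycles(net))[[1]]
    four_cycle_case(net, cyc)$case
  }
  expect_equal(case_of("Ns"), "a")
  expect_equal(case_of("Nn"), "b-i")
  expect_equal(case_of("Nw"), "b-ii")
  expect_equal(case_of("Nsw"), "c-i")
  expect_equal(case_of("Nsn"), "c-i")
})

test_that("sunlet cycle params flag degenerate and inert cases", {
  net <- make_named("sunlet5")
  pars <- random_params("sunlet5", 2)
  est <- recover_parameters(net, cf_table(net, params = pars))
  # hybrid block is a singleton: hybrid edge lengths inert
  inert <- Filter(function(e) e$status == "inert", est)
  expect_gte(length(inert), 2)
  # y -> 1 degenerate: division by (1 - y) errors
  pars$z3 <- qq(1)
  sd <- to_semidirected(net)
  cyc <- find_cycles(sd)[[1]]
  expect_error(sunlet_cycle_params(cf_table(net, params = pars), cyc, sd),
               "degenerate")
})

test_that("the audit reports the printed identifiability structure", {
  # 2-cycle flagged
  two <- parse_network("((a:1,b:1):0.5,((c:1)#H1:0.3::0.4,#H1:0.6::0.6):0.7,d:2);")
  rep2 <- identifiability_audit(two)
  expect_true(any(vapply(rep2$cycles, function(c) c$m == 2, TRUE)))
  expect_match(rep2$cycles[[1]]$verdict, "never")

  # N5-31's 3-cycle induces (1,2,2): undirected cycle identifiable only
  rep31 <- identifiability_audit(make_named("N5-31"))
  expect_match(rep31$cycles[[1]]$verdict, "undirected 3-cycle identifiable")

  # a 3_1-cycle inducing (1,1,n-2): swapped-singleton indistinguishability
  n31 <- build_network(list(
    list(from = "r", to = "S", t = 0),
    list(from = "S", to = "b"),
    list(from = "S", to = "DE", t = 0.4),
    list(from = "DE", to = "d"), list(from = "DE", to = "e"),
    list(from = "r", to = "w", t = 0.5),
    list(from = "w", to = "u", t = 0.3),
    list(from = "u", to = "h", hybrid = TRUE, gamma = 0.4),
    list(from = "w", to = "h", hybrid = TRUE, gamma = 0.6),
    list(from = "h", to = "c"),
    list(from = "u", to = "a")),
    leaves = c(a = "a", b = "b", c = "c", d = "d", e = "e"), root = "r")
  rep11 <- identifiability_audit(n31)
  expect_match(rep11$cycles[[1]]$verdict, "swapped singleton")

  # 5-taxon 4-cycle: orientation identifiable; pendant edges inert
  repNs <- identifiability_audit(make_named("Ns"))
  c4 <- Filter(function(c) c$m == 4, repNs$cycles)[[1]]
  expect_match(c4$verdict, "orientation identifiable")
  expect_true(any(grepl("inert", repNs$edges$status)))

  # multi-sampling lifts pendant and 4-cycle exceptions
  repNs2 <- identifiability_audit(make_named("Ns"), samples_per_taxon = 2)
  expect_false(any(grepl("4-cycle case", repNs2$edges$status)))
  expect_true(any(grepl("multi-sample", repNs2$edges$status)))

  # k-cycle report
  rep5 <- identifiability_audit(make_named("sunlet5"))
  c5 <- Filter(function(c) c$m == 5, rep5$cycles)[[1]]
  expect_equal(c5$hybrid_lengths, "inert")
})

test_that("2-cycle non-identifiability is witnessed by identical CF tables", {
  # distinct 2-cycle parameter choices with the same effective ell give the
  # same CF table; recovery on the collapsed network returns the effective
  # edge probability of the replacement formula
  mk <- function(g, h1, h2) parse_network(sprintf(
    "((a:1,b:1):0.5,(((c:1,d:1):0.3)#H1:%.15g::%g,#H1:%.15g::%g):0.7,e:2);",
    -log(h1), g, -log(h2), 1 - g))
  h <- 0.8
  netA <- mk(0.5, h, h)                    # 1 - ell = (1-h)/2 = 0.1
  ellA <- 0.9
  netB <- mk(0.25, 0.9, 0.95)              # 1 - ell = 0.0625*0.1+0.5625*0.05
  ellB <- 1 - (0.25^2 * 0.1 + 0.75^2 * 0.05)
  tA <- cf_table(netA)
  tColl <- cf_table(replace_two_cycles(netA))
  expect_cf_equal(tA, tColl, tol = 1e-13)
  # and two networks with equal effective ell have equal CF tables
  netB2 <- mk(0.5, 1 - 2 * (1 - ellB), 1 - 2 * (1 - ellB))
  expect_cf_equal(cf_table(netB), cf_table(netB2), tol = 1e-13)
  # the recovered internal edge carries exp(-1.0) * ellA (path 0.3 + cycle + 0.7)
  sd <- to_semidirected(replace_two_cycles(netA))
  est <- recover_parameters(sd, tA)
  ell_est <- Filter(function(e) e$status == "identified", est)
  expect_gte(length(ell_est), 1)
  expect_true(any(vapply(ell_est, function(e)
    abs(rr_tonum(e$value) - exp(-1.0) * ellA) < 1e-12, TRUE)))
})

test_that("effective cherry z flags the anomalous regime", {
  r0 <- effective_cherry_z(0.3, 1, 1, 1)
  expect_equal(r0$z, 1)
  expect_false(r0$anomalous)
  # z <= 1: mimicked by a tree cherry with edge probability z
  r1 <- effective_cherry_z(0.3, 0.5, 0.6, 0.9)
  expect_lt(r1$z, 1)
  # search for an anomalous point (z > 1): large x small h
  found <- NULL
  for (g in seq(0.3, 0.7, 0.1)) for (x in c(0.05, 0.1)) {
    r <- effective_cherry_z(g, 1, 1, x)
    if (r$anomalous) found <- c(g = g, x = x)
  }
  expect_false(is.null(found))
  # and the anomaly is visible in CFs: CF_ac|bc > 1/3 for strong downstream p
  q <- build_network(list(
    list(from = "r", to = "u", role = "x"),
    list(from = "r", to = "w", t = 0),
    list(from = "u", to = "h", hybrid = TRUE, grole = "gamma", role = "h1"),
    list(from = "w", to = "h", hybrid = TRUE, role = "h2"),
    list(from = "u", to = "a"),
    list(from = "w", to = "b"),
    list(from = "h", to = "CC", t = 0),
    list(from = "CC", to = "c1"), list(from = "CC", to = "c2")),
    leaves = c(a = "a", b = "b", c1 = "c1", c2 = "c2"), root = "r")
  pars <- list(gamma = found[["g"]], h1 = 1, h2 = 1, x = found[["x"]])
  cf <- quartet_cf(q, params = pars)
  expect_gt(rr_tonum(cf$cf[[2]]), 1 / 3)
})
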